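# Circular open reading frames, Kozak motif scanning, IRES filtering,
# peptide match classification and database matching by length and locus.

#' @noRd
.validate_dna <- function(seq) {
  up <- toupper(seq)
  if (grepl("[^ACGTN]", up)) {
    stop("sequence contains symbols outside ACGTN")
  }
  up
}

#' @noRd
.translate_codons <- function(codons) {
  code <- Biostrings::GENETIC_CODE
  aa <- unname(code[codons])
  aa[is.na(aa)] <- "X" # codons containing N
  aa
}

#' Find open reading frames on a circular sequence
#'
#' The sequence is treated as circular: ATG start codons are scanned at
#' every position `0..L-1` on the doubled sequence and each frame is
#' translated until its first in-frame stop. An ORF whose extent
#' `start + length_nt` exceeds `L` crosses the back-splice junction. A
#' frame with no stop within one full pass of the circle is flagged
#' `rolling_circle` and capped at `L - (L %% 3)` nt.
#'
#' @param seq Circular nucleotide sequence (ACGTN, length >= 3).
#' @param min_aa Minimum peptide length in residues (default 20).
#' @return Data frame: `start` (0-based circular), `length_nt`
#'   (including the stop codon when present), `peptide`,
#'   `crosses_junction`, `rolling_circle`.
#' @export
find_circular_orfs <- function(seq, min_aa = 20L) {
  s <- .validate_dna(seq)
  L <- nchar(s)
  if (L < 3L) stop("sequence must be at least 3 nt")
  doubled <- paste0(s, s)
  stops <- c("TAA", "TAG", "TGA")
  starts <- gregexpr("ATG", doubled, fixed = TRUE)[[1L]]
  starts <- starts[starts != -1L & starts <= L] # 1-based, start in circle
  rows <- lapply(starts, function(p) {
    max_codons <- L %/% 3L # one full pass
    n_codon <- 0L
    stopped <- FALSE
    while (n_codon < max_codons) {
      codon <- substr(doubled, p + 3L * n_codon, p + 3L * n_codon + 2L)
      if (n_codon > 0L && codon %in% stops) {
        stopped <- TRUE
        break
      }
      n_codon <- n_codon + 1L
    }
    if (stopped) {
      length_nt <- 3L * (n_codon + 1L) # stop codon counted, not translated
      pep_codons <- vapply(seq_len(n_codon) - 1L, function(i) {
        substr(doubled, p + 3L * i, p + 3L * i + 2L)
      }, "")
      rolling <- FALSE
    } else {
      length_nt <- L - (L %% 3L)
      pep_codons <- vapply(seq_len(length_nt %/% 3L) - 1L, function(i) {
        substr(doubled, p + 3L * i, p + 3L * i + 2L)
      }, "")
      rolling <- TRUE
    }
    peptide <- paste(.translate_codons(pep_codons), collapse = "")
    data.frame(
      start = p - 1L, length_nt = length_nt, peptide = peptide,
      crosses_junction = (p - 1L) + length_nt > L,
      rolling_circle = rolling, stringsAsFactors = FALSE
    )
  })
  out <- if (length(rows)) do.call(rbind, rows) else {
    data.frame(start = integer(), length_nt = integer(),
               peptide = character(), crosses_junction = logical(),
               rolling_circle = logical(), stringsAsFactors = FALSE)
  }
  out <- out[nchar(out$peptide) >= min_aa, , drop = FALSE]
  out <- out[!duplicated(paste(out$start %% L, out$start %% 3L)), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Scan a circular sequence for the Kozak consensus GCCRCCATGG
#'
#' Exact IUPAC matching (R = A or G), case-insensitive, circularised via
#' the doubled sequence; positions are reported 0-based modulo the
#' sequence length, deduplicated and sorted.
#'
#' @param seq Circular nucleotide sequence (ACGTN).
#' @return Integer vector of 0-based circular start positions.
#' @export
kozak_scan <- function(seq) {
  s <- .validate_dna(seq)
  L <- nchar(s)
  doubled <- Biostrings::DNAString(paste0(s, s))
  hits <- Biostrings::matchPattern("GCCRCCATGG", doubled, fixed = FALSE)
  pos <- Biostrings::start(hits) - 1L
  sort(unique(pos[pos < L] %% L))
}

#' Classify a circRNA-encoded peptide against a reference protein set
#'
#' Best local alignment (BLOSUM62, affine gaps open 11 / extend 1)
#' against each reference protein; Karlin-Altschul normalisation with
#' lambda = 0.267, K = 0.041 over a search space of query length times
#' total database length. Categories: `near_perfect` (E < 1e-4),
#' `partial` (1e-4 <= E < 10), `none` otherwise.
#'
#' @param pep Query peptide (amino-acid string).
#' @param refdb Data frame with columns `subject` (accession), `gene`,
#'   `seq` (protein sequence). Must be non-empty.
#' @param query_gene Gene label of the query circRNA (for `same_gene`).
#' @param lambda,k Karlin-Altschul parameters.
#' @return One-row data frame: `category`, `pident`, `evalue`,
#'   `bitscore`, `subject`, `same_gene`.
#' @export
classify_peptide_match <- function(pep, refdb, query_gene = NA_character_,
                                   lambda = 0.267, k = 0.041) {
  if (is.null(refdb) || nrow(refdb) == 0L) stop("reference database is empty")
  db_len <- sum(nchar(refdb$seq))
  best <- NULL
  for (i in seq_len(nrow(refdb))) {
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(pep), Biostrings::AAString(refdb$seq[i]),
      type = "local", substitutionMatrix = "BLOSUM62",
      gapOpening = 11, gapExtension = 1
    )
    sc <- as.numeric(Biostrings::score(aln))
    if (is.null(best) || sc > best$score) {
      len <- Biostrings::nchar(aln)
      best <- list(
        score = sc, subject = refdb$subject[i], gene = refdb$gene[i],
        pident = if (len > 0) 100 * Biostrings::nmatch(aln) / len else 0
      )
    }
  }
  bit <- (lambda * best$score - log(k)) / log(2)
  ev <- nchar(pep) * db_len * 2^(-bit)
  category <- if (ev < 1e-4) "near_perfect" else if (ev < 10) "partial" else "none"
  data.frame(
    category = category, pident = best$pident, evalue = ev,
    bitscore = bit, subject = best$subject,
    same_gene = if (category == "none") NA else
      identical(best$gene, query_gene),
    stringsAsFactors = FALSE
  )
}

#' Filter IRES annotations by R-value and pseudoknot
#'
#' Keeps records with `r_value > r_cutoff` (strict) and, when required,
#' a predicted pseudoknot structure.
#'
#' @param records Data frame with `r_value` and `has_pseudoknot`.
#' @param r_cutoff Strict lower cutoff on the IRES R-value.
#' @param require_pseudoknot Also require `has_pseudoknot`.
#' @return The filtered sub-data-frame.
#' @export
filter_ires <- function(records, r_cutoff = 1.54,
                        require_pseudoknot = TRUE) {
  keep <- records$r_value > r_cutoff
  if (require_pseudoknot) keep <- keep & records$has_pseudoknot
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Match a circRNA to database entries by gene and genomic length
#'
#' Returns database rows whose gene symbol equals the record's and whose
#' genomic length equals `end - start`.
#'
#' @param circ A one-row back-splice junction record (needs
#'   `gene_symbol`, `start`, `end`).
#' @param db Data frame with columns `gene_symbol` and `genomic_length`.
#' @return The matching rows of `db` (possibly empty).
#' @export
match_by_length_and_locus <- function(circ, db) {
  len <- circ$end - circ$start
  out <- db[db$gene_symbol == circ$gene_symbol &
              db$genomic_length == len, , drop = FALSE]
  rownames(out) <- NULL
  out
}
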