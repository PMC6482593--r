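# Readers and writers for the external table dialects the workflow touches.
# Internal coordinates are always 0-based half-open (BED convention); the
# CIRI dialect (1-based inclusive) is converted at the boundary.

#' @noRd
.circ_columns <- c(
  "circ_key", "gene_symbol", "gene_id", "db_id", "chrom", "start", "end",
  "strand", "exon_indices", "exon_count", "reads_control", "reads_treated",
  "intron5_interval", "intron3_interval"
)

#' @noRd
.circ_key <- function(chrom, start, end, strand) {
  sprintf("%s:%d-%d:%s", chrom, start, end, strand)
}

#' Read a CIRCexplorer2 "annotate" back-splice junction table
#'
#' Parses the tab-separated, BED12-like dialect written by CIRCexplorer2
#' annotate (18 columns, no header): chrom, start, end, name, score, strand,
#' thickStart, thickEnd, itemRgb, exonCount, exonSizes, exonOffsets,
#' readNumber, circType, geneName, isoformName, index, flankIntron.
#' Coordinates are 0-based half-open and are stored unchanged.
#'
#' @param path Path to the table.
#' @param condition Which read-count slot the file's `readNumber` column
#'   fills: `"control"` or `"treated"`.
#' @return A data frame of back-splice junction records, one row per
#'   circRNA, with columns `circ_key`, `gene_symbol`, `gene_id`, `db_id`,
#'   `chrom`, `start`, `end`, `strand`, `exon_indices`, `exon_count`,
#'   `reads_control`, `reads_treated`, `intron5_interval`,
#'   `intron3_interval`. The unused read slot is `NA`.
#' @export
read_circexplorer2 <- function(path, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_circ_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 18L)) {
    stop("malformed CIRCexplorer2 line ", which(nf != 18L)[1L],
         ": expected 18 tab-separated fields, got ", nf[nf != 18L][1L])
  }
  m <- do.call(rbind, fields)
  strand <- m[, 6L]
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand symbol on line ", which(!strand %in% c("+", "-"))[1L])
  }
  start <- as.integer(m[, 2L])
  end <- as.integer(m[, 3L])
  if (anyNA(start) || anyNA(end) || any(start >= end)) {
    stop("malformed coordinates: start must be a non-negative integer < end")
  }
  flank <- .parse_flank_intron(m[, 18L])
  reads <- as.integer(m[, 13L])
  out <- data.frame(
    circ_key = .circ_key(m[, 1L], start, end, strand),
    gene_symbol = m[, 15L],
    gene_id = "",
    db_id = "",
    chrom = m[, 1L],
    start = start,
    end = end,
    strand = strand,
    exon_indices = m[, 17L],
    exon_count = as.integer(m[, 10L]),
    reads_control = if (condition == "control") reads else NA_integer_,
    reads_treated = if (condition == "treated") reads else NA_integer_,
    intron5_interval = flank$intron5,
    intron3_interval = flank$intron3,
    stringsAsFactors = FALSE
  )
  out
}

#' @noRd
.empty_circ_table <- function() {
  out <- data.frame(matrix(nrow = 0L, ncol = length(.circ_columns)))
  names(out) <- .circ_columns
  out
}

#' @noRd
.parse_flank_intron <- function(x) {
  intron5 <- rep(NA_character_, length(x))
  intron3 <- rep(NA_character_, length(x))
  has <- x != "None" & nzchar(x)
  if (any(has)) {
    parts <- strsplit(x[has], "|", fixed = TRUE)
    bad <- lengths(parts) != 2L
    if (any(bad)) stop("malformed flankIntron field: ", x[has][bad][1L])
    intron5[has] <- vapply(parts, `[`, "", 1L)
    intron3[has] <- vapply(parts, `[`, "", 2L)
  }
  list(intron5 = intron5, intron3 = intron3)
}

#' Write a back-splice junction table in the CIRCexplorer2 dialect
#'
#' @param records Data frame as returned by [read_circexplorer2()].
#' @param path Output path.
#' @param condition Which read slot to emit as `readNumber`.
#' @return `path`, invisibly.
#' @export
write_circexplorer2 <- function(records, path,
                                condition = c("control", "treated")) {
  condition <- match.arg(condition)
  reads <- if (condition == "control") records$reads_control else records$reads_treated
  flank <- ifelse(
    is.na(records$intron5_interval) | is.na(records$intron3_interval),
    "None",
    paste0(records$intron5_interval, "|", records$intron3_interval)
  )
  m <- cbind(
    records$chrom, records$start, records$end,
    paste0("circ/", seq_len(nrow(records))), 0L, records$strand,
    records$start, records$end, "0,0,0", records$exon_count,
    "0", "0", reads, "circRNA", records$gene_symbol,
    "NA", records$exon_indices, flank
  )
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a CIRI v2 circRNA call table
#'
#' CIRI reports 1-based inclusive coordinates; they are converted to the
#' internal 0-based half-open convention on read
#' (`start_internal = start_ciri - 1`).
#'
#' @param path Path to a CIRI v2 output table (header line starting with
#'   `circRNA_ID`).
#' @inheritParams read_circexplorer2
#' @return A back-splice junction data frame (see [read_circexplorer2()]).
#' @export
read_ciri <- function(path, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  lines <- readLines(path)
  if (length(lines) == 0L || !startsWith(lines[1L], "circRNA_ID")) {
    stop("CIRI header missing: first line must start with 'circRNA_ID'")
  }
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(.empty_circ_table())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 11L)) {
    stop("malformed CIRI line ", which(nf < 11L)[1L] + 1L,
         ": expected at least 11 fields")
  }
  m <- do.call(rbind, lapply(fields, `[`, 1:11))
  start <- as.integer(m[, 3L]) - 1L
  end <- as.integer(m[, 4L])
  if (anyNA(start) || anyNA(end) || any(start < 0L)) {
    stop("negative coordinate after CIRI 1-based to 0-based conversion")
  }
  strand <- m[, 11L]
  if (!all(strand %in% c("+", "-"))) {
    stop("unknown strand symbol on line ",
         which(!strand %in% c("+", "-"))[1L] + 1L)
  }
  reads <- as.integer(m[, 5L])
  out <- data.frame(
    circ_key = .circ_key(m[, 2L], start, end, strand),
    gene_symbol = sub(",.*$", "", m[, 10L]),
    gene_id = m[, 10L],
    db_id = "",
    chrom = m[, 2L],
    start = start,
    end = end,
    strand = strand,
    exon_indices = "",
    exon_count = NA_integer_,
    reads_control = if (condition == "control") reads else NA_integer_,
    reads_treated = if (condition == "treated") reads else NA_integer_,
    intron5_interval = NA_character_,
    intron3_interval = NA_character_,
    stringsAsFactors = FALSE
  )
  out
}

#' Write a circRNA table in the CIRI v2 dialect
#'
#' Internal 0-based half-open coordinates are converted back to CIRI's
#' 1-based inclusive convention.
#'
#' @inheritParams write_circexplorer2
#' @export
write_ciri <- function(records, path, condition = c("control", "treated")) {
  condition <- match.arg(condition)
  reads <- if (condition == "control") records$reads_control else records$reads_treated
  header <- paste(
    "circRNA_ID", "chr", "circRNA_start", "circRNA_end", "#junction_reads",
    "SM_MS_SMS", "#non_junction_reads", "junction_reads_ratio",
    "circRNA_type", "gene_id", "strand", sep = "\t"
  )
  body <- paste(
    sprintf("%s:%d|%d", records$chrom, records$start + 1L, records$end),
    records$chrom, records$start + 1L, records$end, reads,
    paste0(reads, "_0_0"), 0L, "1.0", "exon", records$gene_symbol,
    records$strand, sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Merge control and treated circRNA call tables
#'
#' Keeps only back-splice junctions (keyed by `chrom:start-end:strand`)
#' detected in both conditions, filling both read-count slots. This is the
#' two-condition intersection step that precedes ratio computation.
#'
#' @param control,treated Back-splice junction data frames with unique
#'   `circ_key`s; `control` must carry `reads_control`, `treated`
#'   `reads_treated`.
#' @return A merged data frame, sorted by `circ_key`, with both read
#'   slots filled. Annotation fields are taken from the control table.
#' @export
merge_conditions <- function(control, treated) {
  for (nm in c("control", "treated")) {
    tab <- if (nm == "control") control else treated
    if (anyDuplicated(tab$circ_key)) {
      stop("duplicate circ_key within the ", nm, " table: ",
           tab$circ_key[duplicated(tab$circ_key)][1L])
    }
  }
  shared <- intersect(control$circ_key, treated$circ_key)
  shared <- sort(shared)
  out <- control[match(shared, control$circ_key), , drop = FALSE]
  out$reads_treated <- treated$reads_treated[match(shared, treated$circ_key)]
  rownames(out) <- NULL
  out
}

#' Read a 4DGenome-schema chromatin interaction table
#'
#' Tab-separated with columns InteractorAChr, InteractorAStart,
#' InteractorAEnd, InteractorBChr, InteractorBStart, InteractorBEnd,
#' Agene, Bgene, Cell/Tissue, Detection_Method, Confidence_Score1,
#' Confidence_Score2, Contact_Frequency, Organism. Multi-gene fields
#' (`;`-separated) are expanded to one row per (gene_a, gene_b) pair.
#' Trans-chromosomal rows are retained; distance computation excludes
#' them later.
#'
#' @param path Path to the table (with header).
#' @return A data frame with columns `chrom_a`, `start_a`, `end_a`,
#'   `chrom_b`, `start_b`, `end_b`, `gene_a`, `gene_b`, `method`.
#' @export
read_4dgenome <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L) stop("empty 4DGenome file")
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  if (length(header) != 14L) {
    stop("wrong 4DGenome column count (", length(header),
         " instead of 14); header was: ", lines[1L])
  }
  lines <- lines[-1L]
  lines <- lines[nzchar(lines)]
  empty <- data.frame(
    chrom_a = character(), start_a = integer(), end_a = integer(),
    chrom_b = character(), start_b = integer(), end_b = integer(),
    gene_a = character(), gene_b = character(), method = character(),
    stringsAsFactors = FALSE
  )
  if (length(lines) == 0L) return(empty)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 14L)) {
    stop("wrong 4DGenome column count on line ", which(nf != 14L)[1L] + 1L,
         "; header was: ", paste(header, collapse = "\t"))
  }
  m <- do.call(rbind, fields)
  rows <- lapply(seq_len(nrow(m)), function(i) {
    ga <- strsplit(m[i, 7L], ";", fixed = TRUE)[[1L]]
    gb <- strsplit(m[i, 8L], ";", fixed = TRUE)[[1L]]
    if (length(ga) == 0L) ga <- ""
    if (length(gb) == 0L) gb <- ""
    grid <- expand.grid(gene_a = ga, gene_b = gb,
                        stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)
    data.frame(
      chrom_a = m[i, 1L], start_a = as.integer(m[i, 2L]),
      end_a = as.integer(m[i, 3L]),
      chrom_b = m[i, 4L], start_b = as.integer(m[i, 5L]),
      end_b = as.integer(m[i, 6L]),
      gene_a = grid$gene_a, gene_b = grid$gene_b,
      method = m[i, 10L],
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  if (any(out$start_a >= out$end_a | out$start_b >= out$end_b)) {
    stop("interval with start >= end in 4DGenome table")
  }
  rownames(out) <- NULL
  out
}

#' Write a chromatin interaction table in the 4DGenome dialect
#'
#' @param rows Data frame as returned by [read_4dgenome()].
#' @param path Output path.
#' @param cell Cell/tissue label to emit.
#' @export
write_4dgenome <- function(rows, path, cell = "HUVEC") {
  header <- paste(
    "InteractorAChr", "InteractorAStart", "InteractorAEnd",
    "InteractorBChr", "InteractorBStart", "InteractorBEnd",
    "Agene", "Bgene", "Cell/Tissue", "Detection_Method",
    "Confidence_Score1", "Confidence_Score2", "Contact_Frequency",
    "Organism", sep = "\t"
  )
  body <- paste(
    rows$chrom_a, rows$start_a, rows$end_a,
    rows$chrom_b, rows$start_b, rows$end_b,
    rows$gene_a, rows$gene_b, cell, rows$method,
    "NA", "NA", "NA", "Homo sapiens", sep = "\t"
  )
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read/write FASTA sequence sets
#'
#' Thin wrappers over Biostrings, returning plain named character vectors
#' so downstream code stays dialect-free.
#'
#' @param path FASTA path.
#' @return `read_fasta`: a named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' @rdname read_fasta
#' @param seqs Named character vector of sequences.
#' @export
write_fasta <- function(seqs, path) {
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Write/read the merged two-condition circRNA table
#'
#' Tab-separated with the fixed header matching the internal column set.
#'
#' @param records Merged back-splice junction data frame.
#' @param path Path.
#' @export
write_merged_table <- function(records, path) {
  write.table(records[, .circ_columns], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_merged_table
#' @export
read_merged_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE)
}
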