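# Reverse-complement homology between the 5' and 3' flanking introns of
# each circRNA, scored as a local alignment with Karlin-Altschul
# normalisation, and the across-group bitscore tests.

#' Nucleotide local-alignment scoring scheme
#'
#' Match/mismatch rewards, affine gap penalties and Karlin-Altschul
#' parameters used to normalise a raw local-alignment score S to a bit
#' score `S' = (lambda*S - ln K) / ln 2` and an E-value
#' `E = m*n*2^(-S')` over a pairwise search space of the two sequence
#' lengths. The default +1/-2 scheme with lambda = 1.28, K = 0.46 uses
#' the published ungapped values as an approximation for the gapped
#' case.
#'
#' @param match Positive match reward.
#' @param mismatch Negative mismatch score.
#' @param gap_open,gap_extend Non-negative gap penalties.
#' @param lambda,k Karlin-Altschul parameters (> 0).
#' @return A list of class `scoring_scheme`.
#' @export
scoring_scheme <- function(match = 1, mismatch = -2, gap_open = 5,
                           gap_extend = 2, lambda = 1.28, k = 0.46) {
  if (match <= 0 || mismatch >= 0) stop("need match > 0 > mismatch")
  if (gap_open < 0 || gap_extend < 0) stop("gap penalties must be >= 0")
  if (lambda <= 0 || k <= 0) stop("lambda and k must be > 0")
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k = k),
            class = "scoring_scheme")
}

#' Reverse complement of a DNA sequence
#'
#' Alphabet ACGTN, case-insensitive; N maps to N. Vectorised.
#'
#' @param seq Character vector of sequences.
#' @return Character vector of reverse complements (upper case).
#' @export
reverse_complement <- function(seq) {
  up <- toupper(seq)
  bad <- grepl("[^ACGTN]", up)
  if (any(bad)) {
    stop("sequence contains symbols outside ACGTN: ",
         substr(up[bad][1L], 1L, 30L))
  }
  comp <- chartr("ACGTN", "TGCAN", up)
  vapply(strsplit(comp, "", fixed = TRUE), function(x) {
    paste(rev(x), collapse = "")
  }, "")
}

#' @noRd
.bitscore <- function(raw, scheme) {
  (scheme$lambda * raw - log(scheme$k)) / log(2)
}

#' Score reverse-complement homology between two flanking introns
#'
#' Best local alignment (affine gaps) of the 5' intron against the
#' reverse complement of the 3' intron, reported with percent identity,
#' raw score, Karlin-Altschul bit score and pairwise E-value
#' (`E = m*n*2^(-bitscore)` with m, n the intron lengths). A pair is
#' `significant` when `E < 1e-20`.
#'
#' @param intron5,intron3 Non-empty nucleotide sequences.
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff Significance threshold on the E-value.
#' @return A one-row data frame: `pident`, `raw_score`, `bitscore`,
#'   `evalue`, `aln_len`, `significant`.
#' @export
align_rc <- function(intron5, intron3, scheme = scoring_scheme(),
                     e_cutoff = 1e-20) {
  if (!nzchar(intron5) || !nzchar(intron3)) {
    stop("flanking intron sequences must be non-empty")
  }
  subject <- reverse_complement(intron3)
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = scheme$match, mismatch = scheme$mismatch, baseOnly = FALSE
  )
  aln <- Biostrings::pairwiseAlignment(
    toupper(intron5), subject, type = "local",
    substitutionMatrix = mat,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend
  )
  raw <- as.numeric(Biostrings::score(aln))
  len <- Biostrings::nchar(aln)
  nmatch <- Biostrings::nmatch(aln)
  pident <- if (len > 0) 100 * nmatch / len else 0
  bit <- .bitscore(raw, scheme)
  ev <- nchar(intron5) * nchar(intron3) * 2^(-bit)
  data.frame(pident = pident, raw_score = raw, bitscore = bit,
             evalue = ev, aln_len = len, significant = ev < e_cutoff)
}

#' Score all flanking-intron pairs of a circRNA table
#'
#' One row per circRNA. Pairs without a significant reverse-complement
#' alignment, and records with missing introns, carry bit score 0 and
#' `significant = FALSE`, keeping the design matrix complete for the
#' group tests.
#'
#' @param pairs Data frame with columns `key`, `intron5`, `intron3`
#'   (`NA` for missing introns).
#' @param scheme A [scoring_scheme()].
#' @param e_cutoff Significance threshold on the E-value.
#' @return Data frame: `key`, `pident`, `raw_score`, `bitscore`,
#'   `evalue`, `aln_len`, `significant`. Non-significant rows have
#'   `bitscore` 0.
#' @export
score_all <- function(pairs, scheme = scoring_scheme(), e_cutoff = 1e-20) {
  missing <- is.na(pairs$intron5) | is.na(pairs$intron3) |
    !nzchar(ifelse(is.na(pairs$intron5), "", pairs$intron5)) |
    !nzchar(ifelse(is.na(pairs$intron3), "", pairs$intron3))
  if (any(missing)) {
    warning(sum(missing), " record(s) with missing flanking introns ",
            "scored 0")
  }
  res <- lapply(seq_len(nrow(pairs)), function(i) {
    if (missing[i]) {
      data.frame(pident = NA_real_, raw_score = 0, bitscore = 0,
                 evalue = Inf, aln_len = 0L, significant = FALSE)
    } else {
      align_rc(pairs$intron5[i], pairs$intron3[i], scheme, e_cutoff)
    }
  })
  out <- do.call(rbind, res)
  out$bitscore[!out$significant] <- 0
  cbind(data.frame(key = pairs$key, stringsAsFactors = FALSE), out)
}

#' Across-group tests on flanking-intron bit scores
#'
#' One-way ANOVA and Kruskal-Wallis on (zero-filled) bit scores across
#' the six circRNA/mRNA groups. With `drop_max = TRUE` the single global
#' maximum observation is removed first, the outlier-robustness check
#' used when one extreme score dominates a small group.
#'
#' @param bitscore Numeric vector (zero-filled over all circRNAs).
#' @param group Group labels.
#' @param drop_max Remove the single global maximum before testing.
#' @param tie_correct Apply the tie correction to the Kruskal-Wallis
#'   statistic (the standard choice). `FALSE` reproduces plain
#'   average-rank spreadsheet computation.
#' @return A list with `anova_p` and `kw_p`.
#' @export
group_bitscore_tests <- function(bitscore, group, drop_max = FALSE,
                                 tie_correct = TRUE) {
  group <- factor(group)
  if (drop_max) {
    i <- which.max(bitscore)
    bitscore <- bitscore[-i]
    group <- droplevels(group[-i])
  }
  tab <- table(group)
  if (sum(tab > 0L) < 2L) stop("need at least 2 non-empty groups")
  fit <- aov(bitscore ~ group)
  kw <- if (tie_correct) {
    kruskal.test(bitscore, group)$p.value
  } else {
    .kw_uncorrected(bitscore, group)
  }
  list(anova_p = summary(fit)[[1L]][["Pr(>F)"]][1L], kw_p = kw)
}

# Kruskal-Wallis H on average ranks without the tie-correction divisor.
#' @noRd
.kw_uncorrected <- function(x, g) {
  g <- factor(g)
  N <- length(x)
  r <- rank(x)
  Rg <- tapply(r, g, sum)
  n <- tapply(r, g, length)
  H <- 12 / (N * (N + 1)) * sum(Rg^2 / n) - 3 * (N + 1)
  pchisq(H, df = nlevels(g) - 1L, lower.tail = FALSE)
}
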