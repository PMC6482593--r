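# Loaders for the bundled reference tables transcribed from the printed
# results of the LPC-activated HAEC circRNA screen that this workflow
# mirrors. They are the desk-scale inputs for the classification,
# exon-count, bitscore and spliceosome analyses.

#' @noRd
.extdata <- function(file) {
  path <- system.file("extdata", file, package = "circlpc")
  if (!nzchar(path)) stop("bundled table not found: ", file)
  path
}

#' Bundled 77-circRNA screen table with six-group labels
#'
#' The significantly changed circRNAs of the LPC-activated HAEC screen:
#' junction read counts in both conditions, read-count ratio and log2
#' ratio, related-mRNA fold change, exon indices and counts, and the
#' printed six-group label (`group`, one of [six_group_labels()]).
#'
#' @return A 77-row data frame.
#' @export
lpc_circ_groups <- function() {
  read.delim(.extdata("lpc_haec_circ_groups.tsv"),
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Bundled housekeeping fold-change table
#'
#' Fold changes of the ten housekeeping genes used to calibrate the
#' "unchanged" mRNA interval.
#'
#' @return A 10-row data frame (`gene`, `fold_change`).
#' @export
housekeeping_fold_changes <- function() {
  read.delim(.extdata("housekeeping_fold_changes.tsv"),
             stringsAsFactors = FALSE)
}

#' Bundled flanking-intron alignment table
#'
#' Percent identity and bit score of the significant reverse-complement
#' flanking-intron alignments (53 of the 77 circRNAs), with the printed
#' six-group label. E-values below display precision are stored as 0.
#'
#' @return A 53-row data frame (`gene`, `db_id`, `pident`, `evalue`,
#'   `bitscore`, `group`).
#' @export
flanking_intron_bitscores <- function() {
  read.delim(.extdata("flanking_intron_bitscores.tsv"),
             stringsAsFactors = FALSE, na.strings = c("NA", ""))
}

#' Zero-filled bitscores for all 77 circRNAs
#'
#' Joins [flanking_intron_bitscores()] onto [lpc_circ_groups()] by gene
#' symbol, assigning bit score 0 to circRNAs whose flanking introns show
#' no significant reverse complementarity.
#'
#' @return A 77-row data frame (`gene`, `group`, `bitscore`).
#' @export
zero_filled_bitscores <- function() {
  groups <- lpc_circ_groups()
  bits <- flanking_intron_bitscores()
  i <- match(groups$gene, bits$gene)
  data.frame(
    gene = groups$gene,
    group = groups$group,
    bitscore = ifelse(is.na(i), 0, bits$bitscore[i]),
    stringsAsFactors = FALSE
  )
}

#' Bundled spliceosome-component fold-change table
#'
#' Fold changes of the 17 spliceosome genes that fall outside the
#' housekeeping confidence interval in the screen.
#'
#' @return A 17-row data frame (`gene`, `fold_change`).
#' @export
spliceosome_fold_changes <- function() {
  read.delim(.extdata("spliceosome_fold_changes.tsv"),
             stringsAsFactors = FALSE)
}
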