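# Significance filtering, six-group classification and the exact
# binomial direction-bias statistic.

#' Construct an expression confidence interval
#'
#' An interval `center +/- half_width` used for significance calls. The
#' workflow's intervals are of the "mean +/- 2*SD" kind, fitted from data
#' with [fit_ci()] or supplied as printed overrides.
#'
#' @param center Interval centre (mean).
#' @param half_width Non-negative half width (2 x sample SD for fitted
#'   intervals).
#' @param source `"fitted"` or `"override"`.
#' @return A list of class `expression_ci` with `center`, `half_width`,
#'   `lower`, `upper`, `source`.
#' @export
expression_ci <- function(center, half_width, source = "override") {
  if (!is.finite(center) || !is.finite(half_width) || half_width < 0) {
    stop("center must be finite and half_width a finite non-negative number")
  }
  structure(
    list(center = center, half_width = half_width,
         lower = center - half_width, upper = center + half_width,
         source = source),
    class = "expression_ci"
  )
}

#' @export
print.expression_ci <- function(x, ...) {
  cat(sprintf("expression CI (%s): %.4f +/- %.4f  [%.4f, %.4f]\n",
              x$source, x$center, x$half_width, x$lower, x$upper))
  invisible(x)
}

#' Fit a mean +/- 2*SD interval from values
#'
#' `center` is the arithmetic mean and `half_width` twice the sample
#' standard deviation (n-1 denominator), the "95% confidence interval"
#' convention used for both the log-ratio and the housekeeping
#' fold-change filters.
#'
#' @param values Numeric vector, length >= 2.
#' @return An [expression_ci()] with `source = "fitted"`.
#' @export
fit_ci <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L || anyNA(values)) {
    stop("fit_ci needs at least 2 non-missing values")
  }
  expression_ci(mean(values), 2 * sd(values), source = "fitted")
}

#' Read-count ratio and log2 ratio for a merged circRNA
#'
#' @param reads_treated,reads_control Junction read counts, both >= 1
#'   (a merged record cannot have zero reads). Vectorised.
#' @return A data frame with columns `ratio` (= treated/control) and
#'   `log2_ratio`.
#' @export
compute_ratio <- function(reads_treated, reads_control) {
  if (any(reads_treated < 1 | reads_control < 1, na.rm = FALSE) ||
      anyNA(reads_treated) || anyNA(reads_control)) {
    stop("merged records must have read counts >= 1 in both conditions")
  }
  ratio <- reads_treated / reads_control
  data.frame(ratio = ratio, log2_ratio = log2(ratio))
}

#' Classify circRNA log2 ratios against a confidence interval
#'
#' The interval is closed: values exactly on a bound are
#' `not_significant`.
#'
#' @param log2_ratio Numeric vector.
#' @param ci An [expression_ci()].
#' @return Character vector in `up` / `down` / `not_significant`.
#' @export
classify_circ <- function(log2_ratio, ci) {
  stopifnot(inherits(ci, "expression_ci"))
  ifelse(log2_ratio > ci$upper, "up",
         ifelse(log2_ratio < ci$lower, "down", "not_significant"))
}

#' Classify mRNA fold changes against the housekeeping interval
#'
#' The interval is closed: values exactly on a bound are `unchanged`.
#' Missing fold changes give `unknown`.
#'
#' @param fc Positive fold changes (`NA` allowed).
#' @param ci An [expression_ci()].
#' @return Character vector in `increased` / `unchanged` / `decreased` /
#'   `unknown`.
#' @export
classify_mrna <- function(fc, ci) {
  stopifnot(inherits(ci, "expression_ci"))
  if (any(fc <= 0, na.rm = TRUE)) stop("fold changes must be positive")
  out <- ifelse(fc > ci$upper, "increased",
                ifelse(fc < ci$lower, "decreased", "unchanged"))
  out[is.na(fc)] <- "unknown"
  out
}

#' The six circRNA/mRNA group labels, in canonical order
#' @return Character vector of the six labels.
#' @export
six_group_labels <- function() {
  c("up_increased", "down_increased", "up_unchanged",
    "down_unchanged", "up_decreased", "down_decreased")
}

#' Assign significant circRNAs to the six circRNA/mRNA groups
#'
#' Each record is classified by its circRNA log2 ratio (up/down against
#' `circ_ci`) and its related mRNA fold change (increased / unchanged /
#' decreased against `mrna_ci`). Significant records with a known mRNA
#' class land in exactly one of the six groups
#' `{up,down} x {increased,unchanged,decreased}`.
#'
#' @param records Merged circRNA data frame with columns `log2_ratio` and
#'   `mrna_fc` (`NA` for missing mRNA data).
#' @param circ_ci,mrna_ci [expression_ci()] objects.
#' @return `records` with added columns `circ_class`, `mrna_class`, and
#'   `group` (one of [six_group_labels()] or `NA`).
#' @export
assign_six_groups <- function(records, circ_ci, mrna_ci) {
  records$circ_class <- classify_circ(records$log2_ratio, circ_ci)
  records$mrna_class <- classify_mrna(records$mrna_fc, mrna_ci)
  grp <- ifelse(
    records$circ_class == "not_significant" |
      records$mrna_class == "unknown",
    NA_character_,
    paste(records$circ_class, records$mrna_class, sep = "_")
  )
  records$group <- factor(grp, levels = six_group_labels())
  records
}

#' Group sizes of a six-group assignment
#'
#' @param records Output of [assign_six_groups()].
#' @return Named integer vector over [six_group_labels()].
#' @export
group_counts <- function(records) {
  table(factor(records$group, levels = six_group_labels()))
}

# ---- exact binomial tail -------------------------------------------------

# Minimal non-negative big integers as base-1e9 limb vectors (little
# endian), enough for exact Pascal-row sums: C(u, i) exceeds 2^53 already
# at u = 77, so double-precision summation would not be exact.
#' @noRd
.big_add <- function(a, b) {
  n <- max(length(a), length(b))
  a <- c(a, numeric(n - length(a)))
  b <- c(b, numeric(n - length(b)))
  s <- a + b
  carry <- 0
  for (i in seq_len(n)) {
    s[i] <- s[i] + carry
    carry <- s[i] %/% 1e9
    s[i] <- s[i] %% 1e9
  }
  while (carry > 0) {
    s <- c(s, carry %% 1e9)
    carry <- carry %/% 1e9
  }
  s
}

#' @noRd
.big_to_double <- function(a) {
  sum(a * 1e9^(seq_along(a) - 1))
}

#' Exact binomial direction-bias tail probability
#'
#' The probability, under equal chance, of observing at least `n` of `u`
#' items in one direction: `sum_{i=n..u} C(u, i) / 2^u`. The binomial
#' coefficients are summed with exact big-integer arithmetic (Pascal's
#' row built by addition only) and divided by `2^u` as the final step, so
#' the only rounding is the conversion of the exact rational to double.
#'
#' @param u Total number of genes considered (>= 1).
#' @param n Count in the larger direction, `0 <= n <= u`.
#' @return The tail probability, in (0, 1].
#' @export
direction_bias_p <- function(u, n) {
  u <- as.integer(u); n <- as.integer(n)
  if (u < 1L) stop("u must be >= 1")
  if (n < 0L || n > u) stop("n must satisfy 0 <= n <= u")
  # Pascal's row u via repeated addition: row[i+1] = C(u, i)
  row <- list(1) # row 0
  for (k in seq_len(u)) {
    prev <- row
    row <- vector("list", k + 1L)
    row[[1L]] <- 1
    row[[k + 1L]] <- 1
    if (k > 1L) {
      for (i in 2:k) row[[i]] <- .big_add(prev[[i - 1L]], prev[[i]])
    }
  }
  tail_sum <- 0
  for (i in n:u) tail_sum <- .big_add(tail_sum, row[[i + 1L]])
  .big_to_double(tail_sum) / 2^u
}

#' One-way ANOVA and Kruskal-Wallis on exon counts across groups
#'
#' @param exon_count Integer vector of exons per circRNA transcript.
#' @param group Group labels (coerced to factor).
#' @return A list with `anova_p` (one-way fixed-effects ANOVA) and `kw_p`
#'   (tie-corrected Kruskal-Wallis).
#' @export
compare_exon_counts <- function(exon_count, group) {
  group <- factor(group)
  group <- droplevels(group)
  if (nlevels(group) < 2L) stop("need at least 2 non-empty groups")
  if (length(unique(exon_count)) == 1L) {
    stop("all exon counts equal across groups: F statistic undefined")
  }
  fit <- aov(exon_count ~ group)
  list(
    anova_p = summary(fit)[[1L]][["Pr(>F)"]][1L],
    kw_p = kruskal.test(exon_count, group)$p.value
  )
}
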