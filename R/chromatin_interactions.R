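# Signed chromatin long-range interaction distances and the
# distribution-comparison battery (KS, Hodges-Lehmann, Fligner-Policello,
# Ansari-Bradley, DSCF, kernel densities).

#' Signed interaction distance between anchor and partner
#'
#' `distance = anchor_start - partner_start` on genome-forward
#' coordinates: positive means the anchor (circRNA-related gene) lies
#' downstream of its partner, negative upstream. Trans-chromosomal pairs
#' are excluded (`NA`). Vectorised.
#'
#' @param anchor_start,partner_start Gene start coordinates (bp >= 0).
#' @param same_chrom Logical; `FALSE` rows give `NA`.
#' @return Integer-valued numeric vector of signed distances (`NA` for
#'   trans-chromosomal pairs).
#' @export
signed_distance <- function(anchor_start, partner_start, same_chrom) {
  ifelse(same_chrom, anchor_start - partner_start, NA_real_)
}

#' Build the signed-distance table from an interaction table
#'
#' Filters rows to a detection method (case-insensitive exact match,
#' default Hi-C) and to interactions involving a gene from `genes`
#' (matched on `gene_a`, else `gene_b`); the matched gene is the anchor.
#' The anchor start comes from `genes`; the partner start is the other
#' interactor's interval start. Trans-chromosomal rows are dropped.
#'
#' @param rows Interaction data frame from [read_4dgenome()].
#' @param genes Data frame with `gene`, `chrom`, `start`, `group`.
#' @param method_filter Detection method to keep.
#' @return Data frame: `anchor_gene`, `group`, `distance`, `side`
#'   (`downstream` for distance > 0, `upstream` for < 0, `NA` at 0).
#' @export
build_signed_distances <- function(rows, genes, method_filter = "Hi-C") {
  keep <- tolower(rows$method) == tolower(method_filter)
  rows <- rows[keep, , drop = FALSE]
  ia <- match(rows$gene_a, genes$gene)
  ib <- match(rows$gene_b, genes$gene)
  use_a <- !is.na(ia)
  gi <- ifelse(use_a, ia, ib)
  rows <- rows[!is.na(gi), , drop = FALSE]
  use_a <- use_a[!is.na(gi)]
  gi <- gi[!is.na(gi)]
  anchor_start <- genes$start[gi]
  anchor_chrom <- genes$chrom[gi]
  partner_start <- ifelse(use_a, rows$start_b, rows$start_a)
  partner_chrom <- ifelse(use_a, rows$chrom_b, rows$chrom_a)
  d <- signed_distance(anchor_start, partner_start,
                       anchor_chrom == partner_chrom)
  out <- data.frame(
    anchor_gene = genes$gene[gi],
    group = genes$group[gi],
    distance = d,
    stringsAsFactors = FALSE
  )
  out <- out[!is.na(out$distance), , drop = FALSE]
  out$side <- ifelse(out$distance > 0, "downstream",
                     ifelse(out$distance < 0, "upstream", NA_character_))
  rownames(out) <- NULL
  out
}

#' Sign-preserving monotone transformations of signed distances
#'
#' `identity`; `signed_log10` = `sign(d) * log10(1 + |d|)`;
#' `signed_cbrt` = `sign(d) * |d|^(1/3)`.
#'
#' @param values Numeric vector of signed distances.
#' @param method One of `"identity"`, `"signed_log10"`, `"signed_cbrt"`.
#' @return Transformed numeric vector.
#' @export
transform_distances <- function(values,
                                method = c("identity", "signed_log10",
                                           "signed_cbrt")) {
  method <- match.arg(method)
  switch(method,
    identity = values,
    signed_log10 = sign(values) * log10(1 + abs(values)),
    signed_cbrt = sign(values) * abs(values)^(1 / 3)
  )
}

#' @noRd
.skewness <- function(x) {
  m <- mean(x)
  s2 <- mean((x - m)^2)
  if (s2 == 0) return(NaN)
  mean((x - m)^3) / s2^1.5
}

#' Pick the transformation that best symmetrises the data
#'
#' Among identity, signed_log10 and signed_cbrt (in that order), returns
#' the one minimising |sample skewness|; ties and undefined skewness
#' (constant input) resolve to the earliest candidate.
#'
#' @param values Numeric vector (>= 20 values).
#' @return The selected method name.
#' @export
select_transform <- function(values) {
  if (length(values) < 20L) stop("select_transform needs >= 20 values")
  candidates <- c("identity", "signed_log10", "signed_cbrt")
  sk <- vapply(candidates, function(m) {
    abs(.skewness(transform_distances(values, m)))
  }, 0)
  if (all(!is.finite(sk))) return(candidates[1L])
  sk[!is.finite(sk)] <- Inf
  candidates[which.min(sk)]
}

#' Gaussian kernel density estimate
#'
#' Normal-weight kernel density on a 512-point grid spanning the data
#' range plus 3 bandwidths on each side; the automatic bandwidth is
#' Silverman's rule of thumb.
#'
#' @param values Numeric vector with >= 2 distinct values.
#' @param bandwidth Positive bandwidth, or `"auto"` for Silverman.
#' @return A list with `grid` and `density` (each length 512) and `bw`.
#' @export
kde <- function(values, bandwidth = "auto") {
  if (length(unique(values)) < 2L) {
    stop("kde needs at least 2 distinct values")
  }
  bw <- if (identical(bandwidth, "auto")) bw.nrd0(values) else bandwidth
  if (!is.numeric(bw) || bw <= 0) stop("bandwidth must be positive")
  d <- density(values, bw = bw, kernel = "gaussian", n = 512L, cut = 3)
  list(grid = d$x, density = d$y, bw = d$bw)
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum of the ECDF difference; the p-value is the
#' asymptotic two-sided approximation.
#'
#' @param x,y Numeric samples (each >= 2 values).
#' @return A list with `D` and `p`.
#' @export
ks_2sample <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("both samples must have >= 2 values")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = kt$p.value)
}

#' Hodges-Lehmann two-sample location shift
#'
#' Median over all pairwise differences `x_i - y_j`.
#'
#' @param x,y Non-empty numeric samples.
#' @return The shift estimate.
#' @export
hodges_lehmann <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("samples must be non-empty")
  median(outer(x, y, "-"))
}

#' Fligner-Policello robust rank test for location
#'
#' Placement-based test robust to unequal variances. With placements
#' `P_i = #{y_j < x_i} + 1/2 #{y_j = x_i}` and `Q_j` defined
#' symmetrically, the statistic is
#' `z = (sum Q - sum P) / (2 sqrt(V_P + V_Q + Pbar*Qbar))` with `V` the
#' sums of squared placement deviations; the p-value is two-sided
#' normal. Ties are handled by half-placements.
#'
#' @param x,y Numeric samples, each >= 3 values.
#' @return A list with `z` and `p`.
#' @export
fligner_policello <- function(x, y) {
  if (length(x) < 3L || length(y) < 3L) stop("each sample needs >= 3 values")
  P <- vapply(x, function(xi) sum(y < xi) + 0.5 * sum(y == xi), 0)
  Q <- vapply(y, function(yj) sum(x < yj) + 0.5 * sum(x == yj), 0)
  V1 <- sum((P - mean(P))^2)
  V2 <- sum((Q - mean(Q))^2)
  denom <- 2 * sqrt(V1 + V2 + mean(P) * mean(Q))
  num <- sum(Q) - sum(P)
  if (denom == 0) {
    if (num == 0) return(list(z = 0, p = 1))
    stop("Fligner-Policello denominator is zero (degenerate samples)")
  }
  z <- num / denom
  list(z = z, p = 2 * pnorm(-abs(z)))
}

#' Ansari-Bradley two-sample scale test
#'
#' Rank test for a difference in dispersion, normal approximation with
#' mid-rank tie handling.
#'
#' @param x,y Numeric samples, each >= 2 values.
#' @return A list with `stat` (the AB statistic) and `p` (two-sided).
#' @export
ansari_bradley <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("both samples must have >= 2 values")
  at <- suppressWarnings(ansari.test(x, y, exact = FALSE))
  list(stat = unname(at$statistic), p = at$p.value)
}

#' Dwass-Steel-Critchlow-Fligner pairwise comparisons
#'
#' For each pair of groups, the two-sample Wilcoxon rank-sum statistic
#' (mid-ranks, tie-corrected variance) is standardised and referred to
#' the Studentized range distribution with `k` = number of groups:
#' `p_pair = P(Q_k >= |z| * sqrt(2))`.
#'
#' @param groups Named list of >= 3 numeric samples (each >= 2 values).
#' @return A symmetric matrix of adjusted p-values (diagonal `NA`).
#' @export
dscf_pairwise <- function(groups) {
  k <- length(groups)
  if (k < 3L) stop("DSCF needs >= 3 groups; use a pairwise Wilcoxon test")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_len(k))
  p <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      x <- groups[[i]]; y <- groups[[j]]
      ni <- length(x); nj <- length(y); N <- ni + nj
      r <- rank(c(x, y))
      W <- sum(r[seq_len(ni)])
      ties <- table(c(x, y))
      varW <- ni * nj / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
      if (varW <= 0) { p[i, j] <- p[j, i] <- 1; next }
      z <- (W - ni * (N + 1) / 2) / sqrt(varW)
      pv <- ptukey(abs(z) * sqrt(2), nmeans = k, df = Inf,
                   lower.tail = FALSE)
      p[i, j] <- p[j, i] <- pv
    }
  }
  p
}

#' @noRd
.circ_direction <- function(group) {
  sub("_.*$", "", as.character(group))
}

#' @noRd
.mrna_class_of_group <- function(group) {
  sub("^[^_]*_", "", as.character(group))
}

#' Run the full distance-distribution comparison battery
#'
#' For each side (downstream: distance > 0; upstream: distance < 0), and
#' for each stratum (overall up- vs down-regulated circRNAs, and up vs
#' down within each mRNA class), computes the two-sample KS test, the
#' Hodges-Lehmann shift, the Fligner-Policello location test and the
#' Ansari-Bradley scale test; plus DSCF pairwise comparisons across all
#' six groups and per-group kernel densities on the transformation
#' selected for that side. Zero distances have no side and are excluded.
#' Strata with fewer than 3 observations in either sample are skipped
#' with a warning.
#'
#' @param distances Data frame from [build_signed_distances()].
#' @return A nested list, one element per side, each with `transform`,
#'   `strata` (per-stratum test results), `dscf` and `kde` (per group);
#'   class `interaction_battery`.
#' @export
run_battery <- function(distances) {
  out <- list()
  for (side in c("downstream", "upstream")) {
    d <- distances[!is.na(distances$side) & distances$side == side, ,
                   drop = FALSE]
    if (nrow(d) == 0L) next
    tr <- if (nrow(d) >= 20L) select_transform(d$distance) else "identity"
    v <- transform_distances(d$distance, tr)
    dir <- .circ_direction(d$group)
    mcls <- .mrna_class_of_group(d$group)
    strata <- list()
    run_one <- function(label, x, y) {
      if (length(x) < 3L || length(y) < 3L) {
        warning("stratum '", label, "' (", side, ") has < 3 observations; ",
                "skipped")
        return(NULL)
      }
      fp <- tryCatch(fligner_policello(x, y),
                     error = function(e) list(z = NA_real_, p = NA_real_))
      ks <- ks_2sample(x, y)
      ab <- ansari_bradley(x, y)
      list(n_up = length(x), n_down = length(y),
           ks_D = ks$D, ks_p = ks$p,
           hl_shift = hodges_lehmann(x, y),
           fp_z = fp$z, fp_p = fp$p,
           ab_stat = ab$stat, ab_p = ab$p)
    }
    strata[["overall"]] <- run_one("overall", v[dir == "up"],
                                   v[dir == "down"])
    for (mc in c("increased", "unchanged", "decreased")) {
      strata[[paste0("mrna_", mc)]] <- run_one(
        paste0("mrna_", mc),
        v[dir == "up" & mcls == mc],
        v[dir == "down" & mcls == mc]
      )
    }
    glist <- split(v, factor(as.character(d$group)))
    glist <- glist[lengths(glist) >= 2L]
    dscf <- if (length(glist) >= 3L) dscf_pairwise(glist) else NULL
    kdes <- lapply(glist[vapply(glist, function(x) {
      length(unique(x)) >= 2L
    }, TRUE)], kde)
    out[[side]] <- list(transform = tr, strata = strata, dscf = dscf,
                        kde = kdes)
  }
  structure(out, class = "interaction_battery")
}
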