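# Seeded synthetic-data generators. Every generator is a pure function of
# a sim_config: it derives its own RNG stream from cfg$seed and restores
# the caller's RNG state, so identical configs give identical outputs.

#' Simulation configuration for the synthetic inputs
#'
#' Defaults encode the study conditions the analysis assumes: 1,093
#' back-splice junctions shared between conditions (with roughly 2,200
#' extra per condition), low overdispersed junction-read counts (1-29
#' reads), a ~5% / ~2.4% planted up/down split at |log2 ratio| 3,
#' housekeeping fold changes tightly centred on 1, a 53/77 fraction of
#' flanking-intron pairs with a planted reverse-complement segment,
#' log-normal interaction distances on a 10^6 bp scale, and a 57/77
#' fraction of circular sequences with a junction-crossing ORF.
#'
#' @param seed Integer seed; identical seeds give identical outputs.
#' @param n_shared Number of circRNAs present in both conditions.
#' @param n_condition_specific Number of extra circRNAs per condition.
#' @param nb_mean,nb_dispersion Mean and size (dispersion) of the
#'   zero-truncated negative binomial junction-read distribution.
#' @param frac_up,frac_down Fractions of shared circRNAs with a planted
#'   +/- `effect_log2` expression effect.
#' @param effect_log2 Planted |log2 ratio| for affected circRNAs.
#' @param hk_sd Standard deviation of housekeeping fold changes about 1.
#' @param mrna_frac_increased,mrna_frac_decreased Mixture fractions of
#'   planted increased/decreased mRNA classes for non-housekeeping genes.
#' @param mrna_effect Planted |fold-change shift| for affected mRNAs.
#' @param frac_rc_introns Fraction of intron pairs with a planted
#'   reverse-complement segment.
#' @param rc_len Planted segment length (bp).
#' @param rc_identity Fraction of planted bases kept identical.
#' @param intron_len Flanking intron length (bp).
#' @param n_interactions_per_gene Interactions simulated per gene.
#' @param upstream_bias Probability that an interaction lies on the
#'   upstream side (signed distance < 0). Scalar default; per-group
#'   values can be passed to [generate_interactions()].
#' @param dist_scale Median |distance| (bp) of the log-normal distance
#'   magnitude distribution (sdlog 1, truncated at 5e7 bp).
#' @param n_sequences Number of circular transcript sequences.
#' @param circ_seq_len Length (nt) of each circular sequence (>= 300).
#' @param orf_plant_rate Fraction of circular sequences given a planted
#'   junction-crossing ORF.
#' @param kozak_plant_rate Fraction given an exact GCCRCCATGG motif.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_shared = 1093L,
                       n_condition_specific = 2235L,
                       nb_mean = 10,
                       nb_dispersion = 30,
                       frac_up = 51 / 1093,
                       frac_down = 26 / 1093,
                       effect_log2 = 3,
                       hk_sd = 0.02,
                       mrna_frac_increased = 0.09,
                       mrna_frac_decreased = 0.22,
                       mrna_effect = 0.3,
                       frac_rc_introns = 53 / 77,
                       rc_len = 300L,
                       rc_identity = 0.9,
                       intron_len = 2000L,
                       n_interactions_per_gene = 50L,
                       upstream_bias = 0.5,
                       dist_scale = 1e6,
                       n_sequences = 77L,
                       circ_seq_len = 400L,
                       orf_plant_rate = 57 / 77,
                       kozak_plant_rate = 0) {
  cfg <- list(
    seed = as.integer(seed), n_shared = as.integer(n_shared),
    n_condition_specific = as.integer(n_condition_specific),
    nb_mean = nb_mean, nb_dispersion = nb_dispersion,
    frac_up = frac_up, frac_down = frac_down, effect_log2 = effect_log2,
    hk_sd = hk_sd, mrna_frac_increased = mrna_frac_increased,
    mrna_frac_decreased = mrna_frac_decreased, mrna_effect = mrna_effect,
    frac_rc_introns = frac_rc_introns, rc_len = as.integer(rc_len),
    rc_identity = rc_identity, intron_len = as.integer(intron_len),
    n_interactions_per_gene = as.integer(n_interactions_per_gene),
    upstream_bias = upstream_bias, dist_scale = dist_scale,
    n_sequences = as.integer(n_sequences),
    circ_seq_len = as.integer(circ_seq_len),
    orf_plant_rate = orf_plant_rate, kozak_plant_rate = kozak_plant_rate
  )
  fracs <- c("frac_up", "frac_down", "hk_sd", "mrna_frac_increased",
             "mrna_frac_decreased", "frac_rc_introns", "rc_identity",
             "upstream_bias", "orf_plant_rate", "kozak_plant_rate")
  for (f in fracs) {
    if (cfg[[f]] < 0 || (f != "hk_sd" && cfg[[f]] > 1)) {
      stop(f, " must lie in [0, 1]")
    }
  }
  if (cfg$frac_up + cfg$frac_down > 1) stop("frac_up + frac_down > 1")
  counts <- c("n_shared", "n_condition_specific", "rc_len", "intron_len",
              "n_interactions_per_gene", "n_sequences", "circ_seq_len")
  for (f in counts) if (cfg[[f]] < 0L) stop(f, " must be >= 0")
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (cfg$nb_mean <= 1) stop("nb_mean must be > 1")
  if (cfg$rc_len >= cfg$intron_len) stop("rc_len must be < intron_len")
  if (cfg$circ_seq_len < 300L) stop("circ_seq_len must be >= 300")
  structure(cfg, class = "sim_config")
}

# Run `expr` under a derived seed without disturbing the caller's RNG.
#' @noRd
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  expr
}

# Zero-truncated negative binomial via inverse-CDF, so counts are >= 1
# as required of junction reads that were actually detected.
#' @noRd
.rztnb <- function(n, mu, size) {
  if (n == 0L) return(integer())
  p0 <- stats::pnbinom(0L, mu = mu, size = size)
  u <- runif(n, p0, 1)
  pmax(1L, qnbinom(u, mu = mu, size = size))
}

#' @noRd
.random_dna <- function(n, len) {
  vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
  }, "")
}

#' Generate paired control/treated circRNA call tables with known truth
#'
#' Shared circRNAs receive zero-truncated negative binomial junction
#' reads; a planted subset has treated-count mean equal to the control
#' mean times `2^(+/- effect_log2)`. Each condition additionally gets
#' `n_condition_specific` private circRNAs, so the two-condition merge
#' recovers exactly the shared set.
#'
#' @param cfg A [sim_config()].
#' @return A list with `control` and `treated` back-splice junction data
#'   frames (CIRCexplorer2-compatible, see [write_circexplorer2()]) and a
#'   `truth` data frame (`circ_key`, `gene_symbol`, `class` in
#'   up/down/null, `true_log2_effect`, `shared`).
#' @export
generate_circ_tables <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 101L, {
    n <- cfg$n_shared
    n_spec <- cfg$n_condition_specific
    total <- n + 2L * n_spec
    chrom <- sample(paste0("chr", c(1:22, "X")), total, replace = TRUE)
    start <- sample.int(9e7L, total) + 10000L
    span <- sample(200:50000, total, replace = TRUE)
    end <- start + span
    strand <- sample(c("+", "-"), total, replace = TRUE)
    gene <- sprintf("SGENE%05d", seq_len(total))
    exon_count <- pmax(1L, stats::rpois(total, 3))
    first_exon <- sample.int(20L, total, replace = TRUE)
    exon_idx <- vapply(seq_len(total), function(i) {
      paste(seq(first_exon[i], length.out = exon_count[i]), collapse = ",")
    }, "")
    key <- .circ_key(chrom, start, end, strand)
    if (anyDuplicated(key)) { # regenerate clashing spans deterministically
      dup <- which(duplicated(key))
      end[dup] <- end[dup] + seq_along(dup)
      key <- .circ_key(chrom, start, end, strand)
    }
    intron5 <- sprintf("%s:%d-%d", chrom, start - cfg$intron_len, start)
    intron3 <- sprintf("%s:%d-%d", chrom, end, end + cfg$intron_len)

    n_up <- round(cfg$frac_up * n)
    n_down <- round(cfg$frac_down * n)
    class <- rep("null", n)
    class[sample.int(n, n_up + n_down)] <-
      rep(c("up", "down"), c(n_up, n_down))
    effect <- ifelse(class == "up", cfg$effect_log2,
                     ifelse(class == "down", -cfg$effect_log2, 0))

    shared_idx <- seq_len(n)
    ctrl_idx <- c(shared_idx, n + seq_len(n_spec))
    trt_idx <- c(shared_idx, n + n_spec + seq_len(n_spec))

    reads_ctrl <- .rztnb(length(ctrl_idx), cfg$nb_mean, cfg$nb_dispersion)
    mu_trt <- c(cfg$nb_mean * 2^effect, rep(cfg$nb_mean, n_spec))
    reads_trt <- .rztnb(length(trt_idx), mu_trt, cfg$nb_dispersion)

    build <- function(idx, reads, condition) {
      data.frame(
        circ_key = key[idx], gene_symbol = gene[idx], gene_id = "",
        db_id = "", chrom = chrom[idx], start = start[idx], end = end[idx],
        strand = strand[idx], exon_indices = exon_idx[idx],
        exon_count = exon_count[idx],
        reads_control = if (condition == "control") reads else NA_integer_,
        reads_treated = if (condition == "treated") reads else NA_integer_,
        intron5_interval = intron5[idx], intron3_interval = intron3[idx],
        stringsAsFactors = FALSE
      )
    }
    truth <- data.frame(
      circ_key = key[seq_len(n + 2L * n_spec)],
      gene_symbol = gene[seq_len(n + 2L * n_spec)],
      class = c(class, rep(NA_character_, 2L * n_spec)),
      true_log2_effect = c(effect, rep(NA_real_, 2L * n_spec)),
      shared = c(rep(TRUE, n), rep(FALSE, 2L * n_spec)),
      stringsAsFactors = FALSE
    )
    list(
      control = build(ctrl_idx, reads_ctrl, "control"),
      treated = build(trt_idx, reads_trt, "treated"),
      truth = truth
    )
  })
}

#' Generate an mRNA fold-change table with planted classes
#'
#' Housekeeping genes draw fold changes from a positive-truncated
#' Normal(1, `hk_sd`); other genes from a three-component mixture of
#' increased (1 + `mrna_effect`), unchanged (1) and decreased
#' (1 - `mrna_effect`) centres, each with the same `hk_sd` noise.
#'
#' @param cfg A [sim_config()].
#' @param genes Character vector of gene symbols; the ten canonical
#'   housekeeping names are appended if absent.
#' @return A list with `table` (`gene`, `fold_change`) and `truth`
#'   (`gene`, `class` in increased/unchanged/decreased/housekeeping).
#' @export
generate_mrna_table <- function(cfg, genes) {
  stopifnot(inherits(cfg, "sim_config"))
  hk <- housekeeping_genes()
  genes <- unique(c(setdiff(genes, hk), hk))
  .with_seed(cfg$seed + 202L, {
    is_hk <- genes %in% hk
    n_other <- sum(!is_hk)
    class <- rep("housekeeping", length(genes))
    if (n_other > 0L) {
      class[!is_hk] <- sample(
        c("increased", "unchanged", "decreased"), n_other, replace = TRUE,
        prob = c(cfg$mrna_frac_increased,
                 1 - cfg$mrna_frac_increased - cfg$mrna_frac_decreased,
                 cfg$mrna_frac_decreased)
      )
    }
    centre <- ifelse(class == "increased", 1 + cfg$mrna_effect,
                     ifelse(class == "decreased", 1 - cfg$mrna_effect, 1))
    fc <- if (cfg$hk_sd == 0) {
      centre
    } else {
      p0 <- stats::pnorm(0, mean = centre, sd = cfg$hk_sd)
      qnorm(runif(length(genes), p0, 1), mean = centre, sd = cfg$hk_sd)
    }
    list(
      table = data.frame(gene = genes, fold_change = fc,
                         stringsAsFactors = FALSE),
      truth = data.frame(gene = genes, class = class,
                         stringsAsFactors = FALSE)
    )
  })
}

#' The ten housekeeping genes used to calibrate the "unchanged" interval
#' @return Character vector of gene symbols.
#' @export
housekeeping_genes <- function() {
  c("C1orf43", "CHMP2A", "GAPDH", "EMC7", "GPI",
    "PSMB2", "PSMB4", "RAB7A", "SNRPD3", "VPS29")
}

#' Generate flanking-intron sequence pairs with planted reverse complements
#'
#' Each pair is a uniform-random 5' and 3' intron of `intron_len` bp. For
#' a planted pair, an `rc_len` bp segment of the 5' intron is copied, a
#' `1 - rc_identity` fraction of its bases mutated, and its reverse
#' complement written into the 3' intron at a random offset.
#'
#' @param cfg A [sim_config()].
#' @param n_pairs Number of pairs (defaults to `cfg$n_sequences`).
#' @return A list with `pairs` (`key`, `intron5`, `intron3`) and `truth`
#'   (`key`, `planted`).
#' @export
generate_intron_pairs <- function(cfg, n_pairs = cfg$n_sequences) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 303L, {
    n <- as.integer(n_pairs)
    key <- sprintf("pair%03d", seq_len(n))
    i5 <- .random_dna(n, cfg$intron_len)
    i3 <- .random_dna(n, cfg$intron_len)
    planted <- seq_len(n) <= round(cfg$frac_rc_introns * n)
    planted <- sample(planted) # random positions, fixed count
    n_mut <- round((1 - cfg$rc_identity) * cfg$rc_len)
    for (i in which(planted)) {
      p5 <- sample.int(cfg$intron_len - cfg$rc_len + 1L, 1L)
      seg <- substr(i5[i], p5, p5 + cfg$rc_len - 1L)
      if (n_mut > 0L) {
        pos <- sample.int(cfg$rc_len, n_mut)
        ch <- strsplit(seg, "", fixed = TRUE)[[1L]]
        for (p in pos) {
          ch[p] <- sample(setdiff(c("A", "C", "G", "T"), ch[p]), 1L)
        }
        seg <- paste(ch, collapse = "")
      }
      rcseg <- reverse_complement(seg)
      p3 <- sample.int(cfg$intron_len - cfg$rc_len + 1L, 1L)
      substr(i3[i], p3, p3 + cfg$rc_len - 1L) <- rcseg
    }
    list(
      pairs = data.frame(key = key, intron5 = i5, intron3 = i3,
                         stringsAsFactors = FALSE),
      truth = data.frame(key = key, planted = planted,
                         stringsAsFactors = FALSE)
    )
  })
}

#' Generate a 4DGenome-dialect chromatin interaction table
#'
#' Each gene receives `cfg$n_interactions_per_gene` Hi-C interactions.
#' The partner lies on the upstream side (signed distance
#' anchor_start - partner_start < 0) with probability `upstream_bias`,
#' and |distance| is log-normal with median `dist_scale` bp (sdlog 1,
#' truncated at 5e7 bp so partner coordinates stay positive).
#'
#' @param cfg A [sim_config()].
#' @param genes_with_groups Data frame with columns `gene` and `group`
#'   (six-group label); optional `chrom`/`start` columns are honoured,
#'   otherwise coordinates are simulated.
#' @param upstream_bias Scalar, or named vector keyed by group label,
#'   overriding `cfg$upstream_bias`.
#' @return A list with `interactions` (a [read_4dgenome()]-shaped data
#'   frame), `genes` (gene, chrom, start, group) and `truth`
#'   (`gene`, `group`, `upstream_bias`).
#' @export
generate_interactions <- function(cfg, genes_with_groups,
                                  upstream_bias = cfg$upstream_bias) {
  stopifnot(inherits(cfg, "sim_config"))
  g <- genes_with_groups
  stopifnot(all(c("gene", "group") %in% names(g)))
  .with_seed(cfg$seed + 404L, {
    n_gene <- nrow(g)
    if (is.null(g$chrom)) g$chrom <- sample(paste0("chr", 1:22), n_gene,
                                            replace = TRUE)
    if (is.null(g$start)) g$start <- sample.int(1e8L, n_gene) + 1e8L
    bias <- if (length(upstream_bias) == 1L && is.null(names(upstream_bias))) {
      rep(upstream_bias, n_gene)
    } else {
      b <- upstream_bias[as.character(g$group)]
      if (anyNA(b)) stop("upstream_bias missing for some group labels")
      as.numeric(b)
    }
    k <- cfg$n_interactions_per_gene
    idx <- rep(seq_len(n_gene), each = k)
    f_cap <- stats::plnorm(5e7, meanlog = log(cfg$dist_scale), sdlog = 1)
    mag <- qlnorm(runif(n_gene * k, 0, f_cap),
                  meanlog = log(cfg$dist_scale), sdlog = 1)
    upstream <- runif(n_gene * k) < bias[idx]
    d <- ifelse(upstream, -1, 1) * round(mag)
    d[d == 0L] <- 1L
    anchor_start <- g$start[idx]
    partner_start <- anchor_start - d
    rows <- data.frame(
      chrom_a = g$chrom[idx],
      start_a = anchor_start, end_a = anchor_start + 5000L,
      chrom_b = g$chrom[idx],
      start_b = partner_start, end_b = partner_start + 5000L,
      gene_a = g$gene[idx],
      gene_b = sprintf("PARTNER%06d", seq_len(n_gene * k)),
      method = "Hi-C",
      stringsAsFactors = FALSE
    )
    list(
      interactions = rows,
      genes = g[, c("gene", "chrom", "start", "group")],
      truth = data.frame(gene = g$gene, group = g$group,
                         upstream_bias = bias, stringsAsFactors = FALSE)
    )
  })
}

#' Generate circular transcript sequences with planted ORFs and motifs
#'
#' Sequences are uniform random over A/C/G/T. A planted ORF is written as
#' explicit codons (ATG, non-stop codons, stop) starting close enough to
#' the sequence end that it crosses the back-splice junction. Planted
#' Kozak motifs are exact `GCCRCCATGG` instances at random positions. An
#' IRES annotation table carries an R-value and pseudoknot flag per
#' sequence.
#'
#' @param cfg A [sim_config()].
#' @return A list with `seqs` (named character vector), `ires`
#'   (`circ_key`, `r_value`, `has_pseudoknot`) and `truth` (`circ_key`,
#'   `orf_planted`, `orf_start`, `orf_len_nt`, `kozak_planted`,
#'   `kozak_pos`).
#' @export
generate_circ_sequences <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  .with_seed(cfg$seed + 505L, {
    n <- cfg$n_sequences
    L <- cfg$circ_seq_len
    stops <- c("TAA", "TAG", "TGA")
    codons <- apply(expand.grid(c("A", "C", "G", "T"), c("A", "C", "G", "T"),
                                c("A", "C", "G", "T")), 1L, paste,
                    collapse = "")
    sense <- setdiff(codons, stops)
    seqs <- .random_dna(n, L)
    key <- sprintf("scirc%03d", seq_len(n))
    orf_planted <- runif(n) < cfg$orf_plant_rate
    kozak_planted <- runif(n) < cfg$kozak_plant_rate
    orf_start <- rep(NA_integer_, n)
    orf_len <- rep(NA_integer_, n)
    kozak_pos <- rep(NA_integer_, n)
    write_circular <- function(s, pos0, text) {
      # pos0 is 0-based circular; write text wrapping around
      ch <- strsplit(s, "", fixed = TRUE)[[1L]]
      tx <- strsplit(text, "", fixed = TRUE)[[1L]]
      at <- (pos0 + seq_along(tx) - 1L) %% nchar(s) + 1L
      ch[at] <- tx
      paste(ch, collapse = "")
    }
    for (i in seq_len(n)) {
      if (orf_planted[i]) {
        # start within 90 nt of the junction; >= 30 codons so the ORF
        # both clears the junction and passes a 20-aa floor
        start0 <- L - sample(10:90, 1L)
        n_codon <- sample(30:60, 1L)
        body <- paste(sample(sense, n_codon, replace = TRUE),
                      collapse = "")
        orf <- paste0("ATG", body, sample(stops, 1L))
        seqs[i] <- write_circular(seqs[i], start0, orf)
        orf_start[i] <- start0
        orf_len[i] <- nchar(orf)
      }
      if (kozak_planted[i]) {
        r <- sample(c("A", "G"), 1L)
        motif <- paste0("GCC", r, "CCATGG")
        pos0 <- sample.int(L, 1L) - 1L
        seqs[i] <- write_circular(seqs[i], pos0, motif)
        kozak_pos[i] <- pos0
      }
    }
    names(seqs) <- key
    ires <- data.frame(
      circ_key = key,
      r_value = rnorm(n, mean = 1.5, sd = 0.3),
      has_pseudoknot = runif(n) < 0.5,
      stringsAsFactors = FALSE
    )
    truth <- data.frame(
      circ_key = key, orf_planted = orf_planted, orf_start = orf_start,
      orf_len_nt = orf_len, kozak_planted = kozak_planted,
      kozak_pos = kozak_pos, stringsAsFactors = FALSE
    )
    list(seqs = seqs, ires = ires, truth = truth)
  })
}
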