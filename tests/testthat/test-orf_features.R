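test_that("linear ORFs on the circle are reported with exact arithmetic", {
  orfs <- find_circular_orfs("ATGAAATAA", min_aa = 1L)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 0L)
  expect_equal(orfs$peptide, "MK")
  expect_equal(orfs$length_nt, 9L)
  expect_false(orfs$crosses_junction)
  expect_false(orfs$rolling_circle)
  expect_error(find_circular_orfs("AU"), "ACGTN|at least 3")
})

test_that("an ORF that runs past the junction is flagged as crossing", {
  # L = 30; ATG at 24; in-frame stop TAA at circular positions 6-8,
  # i.e. doubled positions 36-38: length 15 nt, 24 + 15 > 30
  s <- paste0("AAAAAATAA", strrep("C", 15), "ATGAAA")
  orfs <- find_circular_orfs(s, min_aa = 1L)
  hit <- orfs[orfs$start == 24L, ]
  expect_equal(nrow(hit), 1L)
  expect_equal(hit$length_nt, 15L)
  expect_equal(hit$peptide, "MKKK")
  expect_true(hit$crosses_junction)
})

test_that("frames without a stop in one full pass are rolling-circle capped", {
  s <- paste0("ATG", strrep("C", 27)) # no stop anywhere
  orfs <- find_circular_orfs(s, min_aa = 1L)
  expect_equal(nrow(orfs), 1L)
  expect_true(orfs$rolling_circle)
  expect_equal(orfs$length_nt, 30L)
  expect_equal(orfs$peptide, paste0("M", strrep("P", 9)))
})

test_that("ORF and Kozak scans are invariant under sequence rotation", {
  cfg <- sim_config(seed = 61, n_sequences = 3L, orf_plant_rate = 1)
  seqs <- generate_circ_sequences(cfg)$seqs
  rotate <- function(s, r) {
    L <- nchar(s)
    r <- r %% L
    if (r == 0) s else paste0(substr(s, r + 1, L), substr(s, 1, r))
  }
  set.seed(61)
  for (s in seqs) {
    L <- nchar(s)
    r <- sample.int(L - 1L, 1L)
    o1 <- find_circular_orfs(s, min_aa = 10L)
    o2 <- find_circular_orfs(rotate(s, r), min_aa = 10L)
    expect_setequal(o2$start, (o1$start - r) %% L)
    expect_setequal(o2$peptide, o1$peptide)
    k1 <- kozak_scan(s)
    k2 <- kozak_scan(rotate(s, r))
    expect_setequal(k2, (k1 - r) %% L)
  }
})

test_that("translating a reported ORF's nucleotides reproduces its peptide", {
  cfg <- sim_config(seed = 62, n_sequences = 4L, orf_plant_rate = 1)
  seqs <- generate_circ_sequences(cfg)$seqs
  for (s in seqs) {
    orfs <- find_circular_orfs(s, min_aa = 20L)
    orfs <- orfs[!orfs$rolling_circle, , drop = FALSE]
    for (i in seq_len(nrow(orfs))) {
      dd <- paste0(s, s)
      nt <- substr(dd, orfs$start[i] + 1L,
                   orfs$start[i] + orfs$length_nt[i] - 3L) # strip stop
      pep <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
      expect_equal(pep, orfs$peptide[i])
    }
  }
})

test_that("Kozak scan does exact IUPAC matching, including across the junction", {
  expect_equal(kozak_scan(paste0(strrep("T", 50), "GCCACCATGG",
                                 strrep("T", 40))), 50L)
  expect_equal(length(kozak_scan(paste0(strrep("T", 50), "GCCTCCATGG",
                                        strrep("T", 40)))), 0L)
  # suffix GCCGC at the end + prefix CATGG at the start: one hit at L-5
  s <- paste0("CATGG", strrep("T", 90), "GCCGC")
  expect_equal(kozak_scan(s), 95L)
})

test_that("peptide matches are categorised by E-value band", {
  set.seed(63)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref_seq <- paste(sample(aas, 200, TRUE), collapse = "")
  refdb <- data.frame(subject = "REF1", gene = "GENE1", seq = ref_seq,
                      stringsAsFactors = FALSE)

  # identical peptide: near-perfect, same gene
  hit <- classify_peptide_match(ref_seq, refdb, query_gene = "GENE1")
  expect_equal(hit$category, "near_perfect")
  expect_equal(hit$pident, 100)
  expect_true(hit$same_gene)
  expect_lt(hit$evalue, 1e-4)

  # a shuffled query's best chance alignment has E of order 1 under the
  # pairwise Karlin-Altschul model, so it must never be called a
  # near-perfect (same-protein) match
  cats <- vapply(1:10, function(s) {
    set.seed(s)
    q <- paste(sample(strsplit(ref_seq, "")[[1]]), collapse = "")
    classify_peptide_match(q, refdb, query_gene = "GENE1")$category
  }, "")
  expect_gte(sum(cats != "near_perfect"), 9L)

  expect_error(classify_peptide_match("MKL", refdb[0, ]), "empty")
})

test_that("a weak fragment lands in the partial band, scored as the oracle scores it", {
  set.seed(64)
  aas <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  ref_seq <- paste(sample(aas, 200, TRUE), collapse = "")
  refdb <- data.frame(subject = "REF1", gene = "GENE1", seq = ref_seq,
                      stringsAsFactors = FALSE)
  # 15-aa fragment with every second residue replaced: ~50% identity,
  # weak enough to fall between the two E-value thresholds
  frag <- strsplit(substr(ref_seq, 50, 64), "")[[1]]
  frag[seq(2, 15, 2)] <- "A"
  q <- paste(frag, collapse = "")
  hit <- classify_peptide_match(q, refdb, query_gene = "GENE1")
  data("BLOSUM62", package = "Biostrings", envir = environment())
  raw_oracle <- oracle_local_score(q, ref_seq, gap_open = 11,
                                   gap_extend = 1, submat = BLOSUM62)
  expect_equal((0.267 * raw_oracle - log(0.041)) / log(2), hit$bitscore)
  expect_gte(hit$evalue, 1e-4)
  expect_lt(hit$evalue, 10)
  expect_equal(hit$category, "partial")
})

test_that("IRES filtering is strict and monotone in the cutoff", {
  rec <- data.frame(
    circ_key = c("a", "b", "c", "d"),
    r_value = c(1.6, 1.54, 2.0, 1.8),
    has_pseudoknot = c(TRUE, TRUE, FALSE, TRUE)
  )
  kept <- filter_ires(rec)
  expect_setequal(kept$circ_key, c("a", "d"))
  expect_equal(nrow(filter_ires(rec, require_pseudoknot = FALSE)), 3L)
  # monotone: raising the cutoff never enlarges the output
  cuts <- seq(1.0, 2.2, by = 0.1)
  sizes <- vapply(cuts, function(ct) nrow(filter_ires(rec, r_cutoff = ct)),
                  0L)
  expect_true(all(diff(sizes) <= 0))
})

test_that("database matching requires both gene and genomic length", {
  circ <- data.frame(gene_symbol = "TP53", start = 100L, end = 600L)
  db <- data.frame(
    gene_symbol = c("TP53", "TP53", "EGFR"),
    genomic_length = c(500L, 900L, 500L),
    db_id = c("hsa_circ_1", "hsa_circ_2", "hsa_circ_3"),
    stringsAsFactors = FALSE
  )
  hit <- match_by_length_and_locus(circ, db)
  expect_equal(hit$db_id, "hsa_circ_1")
  none <- match_by_length_and_locus(
    data.frame(gene_symbol = "BRCA1", start = 0L, end = 500L), db)
  expect_equal(nrow(none), 0L)
})
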