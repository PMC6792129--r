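# Expression summarization, counting, classification, conservation, profiles.

tx2g <- function(tx, g) data.frame(transcript_id = tx, gene_id = g,
                                   stringsAsFactors = FALSE)

test_that("gene expression sums transcripts then means replicates with both filters", {
  tpm <- data.frame(transcript_id = c("t1", "t2"),
                    rep1 = c(0.6, 0.6), rep2 = c(0.6, 0.6))
  got <- summarize_gene_expression(tpm, tx2g(c("t1", "t2"), c("g1", "g1")))
  expect_equal(got$mean_tpm, 1.2)
  expect_equal(nrow(got), 1L)

  # mean 0.9 < 1 fails the total filter even though one replicate passes
  tpm2 <- data.frame(transcript_id = "t1", rep1 = 1.8, rep2 = 0.0)
  expect_equal(nrow(summarize_gene_expression(tpm2, tx2g("t1", "g1"))), 0L)

  # mean >= 1 but no single replicate at 1: second filter fails
  tpm3 <- data.frame(transcript_id = "t1", rep1 = 0.99, rep2 = 1.01)
  expect_equal(nrow(summarize_gene_expression(tpm3, tx2g("t1", "g1"))), 1L)
  tpm4 <- data.frame(transcript_id = "t1", rep1 = 2.05, rep2 = 0.0)
  got4 <- summarize_gene_expression(tpm4, tx2g("t1", "g1"))
  expect_equal(got4$mean_tpm, 1.025)

  # empty input, unmapped transcripts
  empty <- data.frame(transcript_id = character(), rep1 = numeric())
  expect_equal(nrow(summarize_gene_expression(empty, tx2g("t", "g"))), 0L)
  expect_message(
    summarize_gene_expression(data.frame(transcript_id = c("t1", "zz"),
                                         rep1 = c(2, 2), rep2 = c(2, 2)),
                              tx2g("t1", "g1")),
    "absent")
})

test_that("median-of-ratios normalization matches hand computation and DESeq2", {
  # identical samples: unit factors, normalized == raw
  m <- matrix(c(10, 20, 30, 10, 20, 30), ncol = 2,
              dimnames = list(paste0("m", 1:3), c("s1", "s2")))
  got <- normalize_mirna_counts(m)
  expect_equal(unname(got$size_factors), c(1, 1))
  expect_equal(unname(got$normalized), unname(m))

  # sample B = 2 x sample A on a 3x2 matrix, hand-computed:
  # geomeans = sqrt(2)*A; ratios col1 = 1/sqrt(2), col2 = sqrt(2)
  m2 <- matrix(c(10, 20, 30, 20, 40, 60), ncol = 2,
               dimnames = list(paste0("m", 1:3), c("s1", "s2")))
  got2 <- normalize_mirna_counts(m2)
  expect_equal(unname(got2$size_factors), c(1 / sqrt(2), sqrt(2)))
  expect_equal(got2$size_factors[[2]] / got2$size_factors[[1]], 2)
  expect_equal(unname(got2$normalized[, 1]), c(10, 20, 30) * sqrt(2))

  # expressed call boundary: (2,2) counts stay below the 3-count cutoff
  m3 <- rbind(m, low = c(2, 2))
  t3 <- normalize_mirna_counts(m3)$table
  expect_false(t3$expressed[t3$mirna == "low"])
  expect_true(all(t3$expressed[t3$mirna != "low"]))

  # independent oracle: DESeq2's median-of-ratios size factors
  skip_if_not_installed("DESeq2")
  set.seed(9)
  m4 <- matrix(rpois(60, 50) + 1L, ncol = 3)
  expect_equal(unname(normalize_mirna_counts(m4)$size_factors),
               unname(DESeq2::estimateSizeFactorsForMatrix(m4)),
               tolerance = 1e-8)

  # all-zero-containing rows: factors fall back to 1 with a warning
  m5 <- matrix(c(0, 5, 3, 0), ncol = 2)
  expect_warning(got5 <- normalize_mirna_counts(m5), "zero")
  expect_equal(unname(got5$size_factors), c(1, 1))
})

test_that("scaling one sample rescales others only by a common factor", {
  set.seed(4)
  m <- matrix(rpois(40, 80) + 1L, ncol = 4)
  base <- normalize_mirna_counts(m)$normalized
  m2 <- m; m2[, 2] <- m2[, 2] * 8L
  scaled <- normalize_mirna_counts(m2)$normalized
  for (j in c(1, 3, 4)) {
    ratio <- scaled[, j] / base[, j]
    expect_equal(max(ratio) / min(ratio), 1, tolerance = 1e-10)
    expect_equal(unname(ratio[1]), 8^(1 / 4), tolerance = 1e-10)
  }
})

test_that("interaction counts are record-level with distinct partners alongside", {
  ints <- rbind(
    make_interactions("chr1", c(0, 10, 20), c(5, 15, 25),
                      mirna = "miR-1", chimera = c("c1", "c2", "c3")),
    make_interactions("chr1", 30, 35, mirna = "miR-2", chimera = "c4"))
  ints$gene_id <- "g1"
  byg <- count_interactions(ints, "gene")
  expect_equal(byg$n_interactions, 4L)
  expect_equal(byg$n_distinct_partners, 2L)
  bym <- count_interactions(ints, "mirna")
  expect_equal(bym$n_interactions[bym$mirna == "miR-1"], 3L)
  expect_equal(bym$n_distinct_partners[bym$mirna == "miR-1"], 1L)

  # a multi-block chimera still counts once
  mb <- make_interactions("chr1", c(0, 50), c(10, 60), chimera = c("cc", "cc"))
  mb$gene_id <- "g2"
  expect_equal(count_interactions(mb, "gene")$n_interactions, 1L)

  expect_equal(nrow(count_interactions(ints[0, ], "gene")), 0L)
})

test_that("gene categories split at the 9 and 50 interaction boundaries", {
  expr <- data.frame(gene_id = paste0("g", 1:5),
                     mean_tpm = c(10, 10, 10, 10, 10))
  cnt <- data.frame(gene_id = c("g1", "g2", "g3", "g4", "gx"),
                    n_interactions = c(9L, 8L, 50L, 0L, 1L),
                    n_distinct_partners = c(5L, 4L, 30L, 0L, 1L))
  got <- categorize_genes(expr, cnt)
  cat_of <- function(g) got$category[got$gene_id == g]
  expect_equal(cat_of("g1"), "high_interacting")
  expect_equal(cat_of("g2"), "expressed_1_8")
  expect_equal(cat_of("g3"), "sponge_like")
  expect_equal(cat_of("g4"), "expressed_0")
  expect_equal(cat_of("g5"), "expressed_0")
  expect_equal(cat_of("gx"), "non_expressed_interacting")

  # partition is exhaustive and exclusive
  expect_true(all(table(got$gene_id) == 1L))
  expect_false(any(is.na(got$category)))

  # raising cutoffs never grows the respective category
  for (hc in c(9L, 12L, 20L)) {
    n_hi <- sum(categorize_genes(expr, cnt, high_cutoff = hc)$category %in%
                  c("high_interacting", "sponge_like"))
    if (exists("prev_hi")) expect_lte(n_hi, prev_hi)
    prev_hi <- n_hi
  }
})

test_that("miRNA typing uses strict nearest-rank percentile cutoffs", {
  # background cohort with constant R (expression proportional to
  # interactions) plus planted extremes
  n <- 100L
  cohort <- data.frame(mirna = sprintf("m%03d", 1:n),
                       expression = 10 * seq_len(n),
                       n_interactions = seq_len(n))
  cohort$expression[1] <- 50000   # max expression...
  cohort$n_interactions[1] <- 2L  # ...over few interactions: max R
  cohort$n_interactions[2] <- 500L # max interactions...
  cohort$expression[2] <- 30      # ...at low expression: min R
  got <- classify_mirna_types(cohort)
  expect_equal(got$mirna[got$type == "type1"], "m001")
  expect_equal(got$mirna[got$type == "type2"], "m002")

  # hand-computed nearest-rank cutoffs on the same cohort
  cuts <- attr(got, "cutoffs")
  R <- cohort$expression / cohort$n_interactions
  expect_equal(cuts$expression_hi, sort(cohort$expression)[90])
  expect_equal(cuts$ratio_hi, sort(R)[90])
  expect_equal(cuts$ratio_lo, sort(R)[10])
  expect_equal(cuts$interactions_hi, sort(cohort$n_interactions)[90])

  # all-identical cohort: no strict exceedance anywhere
  same <- data.frame(mirna = sprintf("m%02d", 1:20), expression = 100,
                     n_interactions = 5L)
  expect_true(all(classify_mirna_types(same)$type == "none"))

  # type sets are disjoint
  expect_false(any(got$type == "type1" & got$type == "type2"))

  # small cohorts refuse to type
  expect_warning(small <- classify_mirna_types(cohort[1:5, ]), "fewer than 10")
  expect_true(all(small$type == "none"))
})

test_that("conservation means average per-miRNA means within groups", {
  coords <- data.frame(mirna = c("a", "b", "c"), seqid = "chrM",
                       start = c(0L, 10L, 50L), end = c(4L, 14L, 54L),
                       strand = "+")
  phylop <- data.frame(seqid = "chrM", pos = c(0:3, 10:13),
                       score = c(rep(0.5, 4), rep(0.2, 2), rep(0.4, 2)))
  got <- conservation_means(list(g1 = "a", g2 = c("a", "b")), phylop, coords)
  expect_equal(got$mean_phylop[got$group == "g1"], 0.5)
  expect_equal(got$mean_phylop[got$group == "g2"], mean(c(0.5, 0.3)))

  # miRNA with no scored bases is excluded with a message
  expect_message(
    got2 <- conservation_means(list(g = c("a", "c")), phylop, coords),
    "no scored bases")
  expect_equal(got2$mean_phylop, 0.5)
  expect_equal(got2$n_mirnas, 1L)

  expect_error(conservation_means(list(g = character()), phylop, coords),
               "empty")
})

test_that("interaction profiles count per 50-nt bin with partial last bin", {
  p1 <- interaction_profile(data.frame(start = 0L, end = 50L), 150L)
  expect_equal(p1$count, c(1L, 0L, 0L))

  # boundary-spanning interaction increments both bins
  p2 <- interaction_profile(data.frame(start = 45L, end = 55L), 150L)
  expect_equal(p2$count, c(1L, 1L, 0L))

  # transcript length 120: bins of 50, 50, 20 nt
  p3 <- interaction_profile(data.frame(start = integer(), end = integer()), 120L)
  expect_equal(nrow(p3), 3L)
  expect_equal(p3$end - p3$start, c(50L, 50L, 20L))
})
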