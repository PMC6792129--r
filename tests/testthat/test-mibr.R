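# Per-position evidence profiles and consensus region extraction.

test_that("evidence units deduplicate within datasets and count chimeras singly", {
  # two peaks from one GSM over a shared position: one unit there
  pk <- make_peaks("chr1", c(100, 120), c(150, 170), dataset = "GSM1")
  prof <- build_support_profile(peaks = pk)
  reg1 <- extract_regions(prof, L = 5, n = 1)
  expect_equal(nrow(reg1), 1L)
  expect_equal(reg1$max_support, 1L)
  expect_equal(c(reg1$start, reg1$end), c(100L, 170L))
  expect_equal(nrow(extract_regions(prof, L = 5, n = 2)), 0L)

  # one GSM peak plus one chimera: count 2
  ch <- make_interactions("chr1", 110, 140, dataset = "DSX", chimera = "c1")
  prof2 <- build_support_profile(peaks = pk[1, ], interactions = ch)
  reg2 <- extract_regions(prof2, L = 10, n = 2)
  expect_equal(c(reg2$start, reg2$end), c(110L, 140L))

  # two chimeras from the same dataset: count 2
  ch2 <- make_interactions("chr1", c(200, 205), c(240, 245), dataset = "DSX",
                           chimera = c("c1", "c2"))
  prof3 <- build_support_profile(interactions = ch2)
  reg3 <- extract_regions(prof3, L = 10, n = 2)
  expect_equal(c(reg3$start, reg3$end), c(205L, 240L))
})

test_that("region extraction returns maximal runs of length >= L", {
  # constant support 2 over [100, 200)
  pk <- rbind(make_peaks("chr1", 100, 200, dataset = "GSM1"),
              make_peaks("chr1", 100, 200, dataset = "GSM2"))
  prof <- build_support_profile(peaks = pk)
  reg <- extract_regions(prof, L = 10, n = 2)
  expect_equal(c(reg$start, reg$end, reg$min_support), c(100L, 200L, 2L))

  # qualifying runs of only 3 nt: nothing at L = 10
  pk2 <- rbind(make_peaks("chr1", c(0, 4, 8), c(3, 7, 11), dataset = "GSM1"),
               make_peaks("chr1", c(0, 4, 8), c(3, 7, 11), dataset = "GSM2"))
  prof2 <- build_support_profile(peaks = pk2)
  expect_equal(nrow(extract_regions(prof2, L = 10, n = 2)), 0L)
  expect_equal(nrow(extract_regions(prof2, L = 3, n = 2)), 3L)
})

test_that("extraction agrees with the brute-force per-position oracle", {
  set.seed(101)
  for (i in 1:60) {
    inp <- random_profile_inputs(len = 3000L, n_units = sample(2:10, 1))
    prof <- build_support_profile(peaks = inp$peaks,
                                  interactions = inp$interactions)
    L <- sample(c(1L, 5L, 10L, 15L), 1L)
    n <- sample(1:4, 1L)
    got <- region_coords(extract_regions(prof, L = L, n = n))
    want <- oracle_regions(inp$peaks, inp$interactions, L, n, len = inp$len)
    expect_equal(got, want, info = sprintf("profile %d (L=%d n=%d)", i, L, n))
  }
})

test_that("profiles are order-invariant and idempotent under duplication", {
  set.seed(55)
  inp <- random_profile_inputs()
  prof_a <- build_support_profile(inp$peaks, inp$interactions)
  shuffled <- inp$peaks[sample(nrow(inp$peaks)), ]
  prof_b <- build_support_profile(shuffled, inp$interactions)
  duplicated_pk <- rbind(inp$peaks, inp$peaks)
  prof_c <- build_support_profile(duplicated_pk, inp$interactions)
  r_a <- extract_regions(prof_a, 10, 2)
  expect_equal(region_coords(r_a), region_coords(extract_regions(prof_b, 10, 2)))
  expect_equal(region_coords(r_a), region_coords(extract_regions(prof_c, 10, 2)))
})

test_that("n=1, L=1 recovers the merged evidence footprint", {
  set.seed(77)
  inp <- random_profile_inputs()
  prof <- build_support_profile(inp$peaks, inp$interactions)
  reg <- extract_regions(prof, L = 1, n = 1)
  # total covered positions equal the union of all input intervals per strand
  for (s in c("+", "-")) {
    pk <- inp$peaks[inp$peaks$strand %in% c(s, "."), ]
    ch <- inp$interactions[inp$interactions$strand == s, ]
    ivs <- rbind(pk[c("start", "end")],
                 if (!is.null(ch)) ch[c("start", "end")])
    want <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(ivs$start + 1L, ivs$end))))
    expect_equal(sum(reg$length[reg$strand == s]), want)
  }
})

test_that("stricter (L, n) regions are nested within looser ones", {
  set.seed(31)
  for (i in 1:20) {
    inp <- random_profile_inputs(n_units = 6L)
    prof <- build_support_profile(inp$peaks, inp$interactions)
    loose <- extract_regions(prof, L = 5, n = 1)
    strict <- extract_regions(prof, L = 12, n = 2)
    if (!nrow(strict)) next
    for (r in seq_len(nrow(strict))) {
      containing <- loose$seqid == strict$seqid[r] &
        loose$strand == strict$strand[r] &
        loose$start <= strict$start[r] & strict$end[r] <= loose$end
      expect_true(any(containing))
    }
  }
})

test_that("the parameter grid counts regions and is monotone", {
  # empty profile: all-zero matrix
  empty <- build_support_profile()
  g0 <- parameter_grid(empty, 1:5, 1:3)
  expect_true(all(g0 == 0L))

  # a single 12-nt run at support 3
  pk <- do.call(rbind, lapply(1:3, function(d)
    make_peaks("chr1", 100, 112, dataset = paste0("GSM", d))))
  g1 <- parameter_grid(build_support_profile(peaks = pk), 1:25, 1:10)
  want <- outer(1:25 <= 12, 1:10 <= 3) * 1L
  expect_equal(unname(g1), unname(want))

  # grid cells equal the merged-region count and are monotone; trimmed runs
  # may split as n rises, merged footprints cannot
  set.seed(13)
  for (i in 1:15) {
    inp <- random_profile_inputs(len = 1500L, n_units = 6L)
    prof <- build_support_profile(inp$peaks, inp$interactions)
    g <- parameter_grid(prof, c(1L, 8L, 15L), 1:4)
    expect_equal(g["8", "2"],
                 nrow(extract_regions(prof, 8, 2, mode = "merged")))
    expect_true(all(apply(g, 1, diff) <= 0)) # non-increasing in n
    expect_true(all(apply(g, 2, diff) <= 0)) # non-increasing in L
  }
  # every trimmed run lies inside exactly one merged region
  inp <- random_profile_inputs(len = 1500L, n_units = 6L)
  prof <- build_support_profile(inp$peaks, inp$interactions)
  runs <- extract_regions(prof, 8, 2)
  merged <- extract_regions(prof, 8, 2, mode = "merged")
  for (r in seq_len(nrow(runs))) {
    inside <- merged$seqid == runs$seqid[r] & merged$strand == runs$strand[r] &
      merged$start <= runs$start[r] & runs$end[r] <= merged$end
    expect_equal(sum(inside), 1L)
  }
})

test_that("characterization attaches annotation, datasets and deduplicated miRNAs", {
  gm <- utr_model()
  pk <- rbind(make_peaks("chr1", 200, 260, dataset = "GSM1"),
              make_peaks("chr1", 200, 260, dataset = "GSM2",
                         cell_line = "Huh7.5"))
  ch <- make_interactions("chr1", c(210, 215, 220), c(250, 255, 260),
                          mirna = c("miR-a", "miR-b", "miR-a"),
                          dataset = "CHIM", chimera = c("c1", "c2", "c3"))
  prof <- build_support_profile(pk, ch)
  reg <- characterize_regions(extract_regions(prof, 10, 2), gm, prof)
  expect_equal(reg$part, "CDS")
  expect_equal(reg$gene_id, "g1")
  expect_equal(reg$datasets, "CHIM,GSM1,GSM2")
  expect_equal(reg$mirnas, "miR-a,miR-b")
  expect_equal(reg$cell_lines, "HEK293,Huh7.5")

  # peaks-only region: empty miRNA list; unannotated space: intergenic
  pk2 <- rbind(make_peaks("chr9", 10, 60, dataset = "GSM1"),
               make_peaks("chr9", 10, 60, dataset = "GSM2"))
  prof2 <- build_support_profile(peaks = pk2)
  reg2 <- characterize_regions(extract_regions(prof2, 10, 2), gm, prof2)
  expect_equal(reg2$mirnas, "")
  expect_equal(reg2$part, "intergenic")
})

test_that("tissue summaries flag ubiquity at the k-cell-line boundary", {
  mk <- function(id, cl) data.frame(region_id = id, seqid = "chr1",
                                    start = 0L, end = 10L, strand = "+",
                                    cell_lines = cl, stringsAsFactors = FALSE)
  regs <- rbind(mk("r1", "a,b,c,d,e,f,g"), # exactly 7 cell lines
                mk("r2", "a,b"),
                mk("r3", "HEK293"))
  ts <- tissue_summary(regs, k = 7)
  expect_equal(ts$per_region$ubiquitous, c(TRUE, FALSE, FALSE))
  expect_equal(ts$n_ubiquitous, 1L)
  expect_equal(ts$per_class$n_exclusive[ts$per_class$class == "HEK293"], 1L)
  expect_equal(ts$n_shared, 2L)

  empty <- tissue_summary(regs[0, ])
  expect_equal(empty$n_ubiquitous, 0L)
  expect_equal(nrow(empty$per_region), 0L)
})

test_that("sequence coverage unions regions and tallies touched genes", {
  gm <- utr_model()
  regs <- data.frame(region_id = c("r1", "r2"), seqid = "chr1",
                     start = c(0L, 50L), end = c(50L, 100L), strand = "+",
                     stringsAsFactors = FALSE)
  # two abutting regions cover [0, 100) of a 100-nt sequence fully
  got <- sequence_coverage(regs, "chr1", 100L, gm)
  expect_equal(got$fraction_covered, 1.0)
  expect_equal(got$n_genes_touched, 1L)
  expect_equal(got$n_genes_total, 1L)

  half <- sequence_coverage(regs[1, ], "chr1", 100L)
  expect_equal(half$fraction_covered, 0.5)

  none <- sequence_coverage(regs[0, ], "chr1", 100L, gm)
  expect_equal(none$fraction_covered, 0.0)
  expect_equal(none$n_genes_touched, 0L)

  expect_error(sequence_coverage(regs, "chrZ", 100L, gm), "chrZ")
})

test_that("region tables round trip through TSV and BED", {
  pk <- rbind(make_peaks("chr1", 100, 160, dataset = "GSM1"),
              make_peaks("chr1", 110, 150, dataset = "GSM2"))
  prof <- build_support_profile(peaks = pk)
  reg <- characterize_regions(extract_regions(prof, 10, 2), NULL, prof)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_mibr_table(reg, tsv, bed)
  back <- read_mibr_table(tsv)
  expect_equal(back$start, reg$start)
  expect_equal(back$n_datasets, reg$n_datasets)
  expect_equal(read_bed(bed)$name, reg$region_id)
})
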