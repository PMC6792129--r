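# Data model, file I/O and coordinate projection.

test_that("read_interactions groups blocks by chimera and rejects malformed rows", {
  f <- withr::local_tempfile(fileext = ".tsv")
  df <- make_interactions("chr1", c(0, 100, 200), c(50, 150, 250),
                          chimera = c("c1", "c2", "c3"))
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got <- read_interactions(f)
  expect_equal(attr(got, "n_records"), 3L)
  expect_equal(nrow(got), 3L)

  # two rows sharing a chimera id on adjacent exons form one 2-block record
  df2 <- make_interactions("chr1", c(1090, 2000), c(1100, 2010),
                           chimera = c("c7", "c7"))
  write.table(df2, f, sep = "\t", quote = FALSE, row.names = FALSE)
  got2 <- read_interactions(f)
  expect_equal(attr(got2, "n_records"), 1L)
  expect_equal(nrow(got2), 2L)

  # a row with end < start yields no record and one logged rejection
  df3 <- make_interactions("chr1", c(10, 500), c(60, 400),
                           chimera = c("a", "b"))
  write.table(df3, f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_message(got3 <- read_interactions(f), "rejected 1 row")
  expect_equal(attr(got3, "n_records"), 1L)
  expect_equal(attr(got3, "rejected")$line, 3L)

  # missing required column is a hard error
  write.table(df[, -5], f, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_interactions(f), "mirna")
})

test_that("project_to_genome matches a per-base coordinate walk", {
  # single-exon plus strand: pure offset
  ex1 <- data.frame(seqid = "chr1", start = 1000L, end = 1100L, strand = "+")
  got <- project_to_genome(10, 20, ex1)
  expect_equal(got$start, 1010L)
  expect_equal(got$end, 1020L)

  # junction-spanning interval splits into two blocks (expected blocks
  # frozen from an independent per-base enumeration of the mapping)
  gm <- two_exon_model()
  ex2 <- gm$exons[gm$exons$transcript_id == "g1.t1",
                  c("seqid", "start", "end", "strand")]
  got2 <- project_to_genome(95, 110, ex2)
  expect_equal(got2$start, c(1095L, 2000L))
  expect_equal(got2$end, c(1100L, 2010L))
  walk <- per_base_map(ex2)
  expect_setequal(unlist(Map(seq.int, got2$start, got2$end - 1L)),
                  walk[96:110])

  # minus strand: transcript position 0 is the rightmost genomic base
  ex3 <- data.frame(seqid = "chr1", start = 500L, end = 600L, strand = "-")
  got3 <- project_to_genome(0, 10, ex3)
  expect_equal(got3$start, 590L)
  expect_equal(got3$end, 600L)
  expect_equal(sort(per_base_map(ex3)[1:10]), seq.int(590L, 599L))

  expect_error(project_to_genome(50, 300, ex3, "txX"), "txX")
})

test_that("project_to_transcript inverts project_to_genome and rejects bad blocks", {
  gm <- two_exon_model()
  ex <- gm$exons[, c("seqid", "start", "end", "strand")]
  for (iv in list(c(10, 20), c(95, 110), c(0, 200))) {
    blocks <- project_to_genome(iv[1], iv[2], ex)
    back <- project_to_transcript(blocks, ex)
    expect_equal(unname(back), iv)
  }
  expect_error(project_to_transcript(ex[0, ], ex), "no blocks")
  straddle <- data.frame(seqid = "chr1", start = 1095L, end = 1105L, strand = "+")
  expect_error(project_to_transcript(straddle, ex), "single exon")
})

test_that("projection round trip is the identity on randomized structures", {
  set.seed(42)
  for (i in 1:250) {
    ex <- random_exons()
    txlen <- sum(ex$end - ex$start)
    s <- sample.int(txlen - 1L, 1L) - 1L
    e <- s + sample.int(txlen - s, 1L)
    blocks <- project_to_genome(s, e, ex)
    expect_equal(sum(blocks$end - blocks$start), e - s)
    expect_equal(unname(project_to_transcript(blocks, ex)), c(s, e))
  }
})

test_that("annotate_interval applies the CDS-first precedence and is total", {
  gm <- utr_model()
  q <- data.frame(seqid = "chr1",
                  start = c(300L, 650L, 10L, 800L, 300L),
                  end = c(350L, 750L, 60L, 900L, 350L),
                  strand = c("+", "+", "+", "+", "+"),
                  stringsAsFactors = FALSE)
  got <- annotate_interval(q, gm)
  # fully inside CDS; spanning CDS/3'UTR junction takes CDS; 5'UTR; 3'UTR
  expect_equal(got$part[1:4], c("CDS", "CDS", "UTR5", "UTR3"))
  expect_equal(got$gene_id[1], "g1")

  # unknown seqid -> intergenic with no gene
  off <- annotate_interval(data.frame(seqid = "chrZ", start = 1L, end = 10L,
                                      strand = "+"), gm)
  expect_equal(off$part, "intergenic")
  expect_true(is.na(off$gene_id))

  # minus-strand gene flips the UTR labels
  gm_minus <- utr_model("-")
  gotm <- annotate_interval(data.frame(seqid = "chr1", start = c(10L, 800L),
                                       end = c(60L, 900L), strand = "-"), gm_minus)
  expect_equal(gotm$part, c("UTR3", "UTR5"))

  # noncoding exonic and intronic labels
  gm2 <- gene_model(data.frame(
    gene_id = "n1", gene_name = "N1", biotype = "noncoding",
    transcript_id = "n1.t1", feature = "exon", seqid = "chr2",
    start = c(0L, 500L), end = c(100L, 600L), strand = "+",
    stringsAsFactors = FALSE))
  got2 <- annotate_interval(data.frame(seqid = "chr2", start = c(20L, 200L),
                                       end = c(40L, 260L), strand = "+"), gm2)
  expect_equal(got2$part, c("ncRNA_exonic", "intronic"))

  # determinism
  expect_identical(annotate_interval(q, gm), got)
})

test_that("VCF parsing follows the 1-based to 0-based convention", {
  f <- withr::local_tempfile(fileext = ".vcf")
  write_vcf_fixture(f, "chr1\t100\t.\tA\tG\t.\tPASS\t.")
  v <- read_vcf(f)
  expect_equal(v$body$start, 99L)
  expect_equal(v$body$end, 100L)
  expect_equal(v$version, "4.1")

  # empty body, valid header
  write_vcf_fixture(f, character(0))
  v0 <- read_vcf(f)
  expect_equal(nrow(v0$body), 0L)

  # unparseable header is a hard error
  writeLines(c("##notvcf", "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO"), f)
  expect_error(read_vcf(f), "fileformat")

  # oversized file refusal
  write_vcf_fixture(f, "chr1\t100\t.\tA\tG\t.\tPASS\t.")
  expect_error(read_vcf(f, size_limit = 10), "limit")
})

test_that("BED6 rows round trip byte-identically", {
  f <- withr::local_tempfile(fileext = ".bed")
  writeLines("chr1\t10\t20\tx\t0\t+", f)
  bed <- read_bed(f)
  f2 <- withr::local_tempfile(fileext = ".bed")
  write_bed(bed, f2)
  expect_identical(readLines(f2), readLines(f))
})

test_that("project_interactions reports retained and failed record counts", {
  gm <- gene_model(data.frame(
    gene_id = "g1", gene_name = "G1", biotype = "coding",
    transcript_id = "t1", feature = "exon", seqid = "chr1",
    start = 0L, end = 500L, strand = "+", stringsAsFactors = FALSE))
  ints <- make_interactions("t1", c(0, 100, 480), c(40, 140, 520),
                            chimera = c("a", "b", "c"))
  got <- project_interactions(ints, gm)
  expect_equal(got$n_input, 3L)
  expect_equal(got$n_failed, 1L)    # record "c" exceeds the transcript
  expect_equal(got$n_retained, 2L)
  expect_equal(sort(unique(got$interactions$chimera)), c("a", "b"))
})
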