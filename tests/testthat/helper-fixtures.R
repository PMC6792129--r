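# Fixtures built in code and independent brute-force oracles used across
# the suite. Oracles are deliberately naive (per-base vectors, exhaustive
# scans) and share no code with the implementation paths they check.

# -- gene models ------------------------------------------------------------

# plus-strand two-exon coding transcript:
# tx coords [0,100) -> genome [1000,1100), [100,200) -> [2000,2100)
two_exon_model <- function() {
  gene_model(data.frame(
    gene_id = "g1", gene_name = "G1", biotype = "coding",
    transcript_id = "g1.t1",
    feature = c("exon", "exon", "CDS"),
    seqid = "chr1",
    start = c(1000L, 2000L, 1050L),
    end = c(1100L, 2100L, 2050L),
    strand = "+", stringsAsFactors = FALSE
  ))
}

# single coding gene on chr1 [0,1000): CDS genomic [100,700),
# so UTR5 = [0,100), UTR3 = [700,1000) on the plus strand
utr_model <- function(strand = "+") {
  gene_model(data.frame(
    gene_id = "g1", gene_name = "G1", biotype = "coding",
    transcript_id = "g1.t1", feature = c("exon", "CDS"),
    seqid = "chr1", start = c(0L, 100L), end = c(1000L, 700L),
    strand = strand, stringsAsFactors = FALSE
  ))
}

# random 1-5 exon transcript structure for projection round trips
random_exons <- function(n_exons = sample.int(5L, 1L),
                         strand = sample(c("+", "-"), 1L)) {
  widths <- sample(20:200, n_exons, replace = TRUE)
  gaps <- sample(10:300, n_exons, replace = TRUE)
  starts <- cumsum(gaps) + c(0L, cumsum(widths[-n_exons]))
  data.frame(seqid = "chrR", start = starts, end = starts + widths,
             strand = strand, stringsAsFactors = FALSE)
}

# independent per-base oracle for projection: the genomic position of each
# transcript base, walked one base at a time in transcription order
per_base_map <- function(exons) {
  exons <- exons[order(exons$start), , drop = FALSE]
  pos <- unlist(lapply(seq_len(nrow(exons)), function(i) {
    seq.int(exons$start[i], exons$end[i] - 1L)
  }))
  if (exons$strand[1] == "-") rev(pos) else pos
}

# -- interaction / peak builders -------------------------------------------

make_interactions <- function(seqid, start, end, strand = "+", mirna = "miR-x",
                              dataset = "DS1", chimera = NULL,
                              cell_line = "HEK293") {
  n <- length(start)
  if (is.null(chimera)) chimera <- sprintf("c%03d", seq_len(n))
  data.frame(seqid = seqid, start = as.integer(start), end = as.integer(end),
             strand = strand, mirna = mirna, dataset = dataset,
             chimera = chimera, cell_line = cell_line,
             stringsAsFactors = FALSE)
}

make_peaks <- function(seqid, start, end, strand = "+", dataset = "GSM1",
                       cell_line = "HEK293", method = "HITS-CLIP") {
  data.frame(seqid = seqid, start = as.integer(start), end = as.integer(end),
             strand = strand, dataset = dataset, cell_line = cell_line,
             method = method, stringsAsFactors = FALSE)
}

# -- brute-force region oracle ---------------------------------------------

# per-base evidence counting on a dense vector, then rle run extraction;
# independent of GRanges coverage/slice
oracle_regions <- function(peaks, interactions, L, n, len = 6000L) {
  combos <- unique(rbind(
    if (!is.null(peaks) && nrow(peaks))
      data.frame(seqid = peaks$seqid, strand = "x", stringsAsFactors = FALSE),
    if (!is.null(interactions) && nrow(interactions))
      data.frame(seqid = interactions$seqid, strand = "x",
                 stringsAsFactors = FALSE)
  )["seqid"])
  out <- list()
  for (sq in unique(combos$seqid)) {
    for (s in c("+", "-")) {
      counts <- integer(len)
      # dataset units: union of each dataset's peak positions
      if (!is.null(peaks) && nrow(peaks)) {
        pk <- peaks[peaks$seqid == sq & (peaks$strand == s | peaks$strand == "."), ]
        for (d in unique(pk$dataset)) {
          mask <- logical(len)
          rows <- pk[pk$dataset == d, ]
          for (i in seq_len(nrow(rows))) {
            mask[seq.int(rows$start[i] + 1L, rows$end[i])] <- TRUE
          }
          counts <- counts + mask
        }
      }
      # chimera units
      if (!is.null(interactions) && nrow(interactions)) {
        ch <- interactions[interactions$seqid == sq & interactions$strand == s, ]
        for (u in unique(paste(ch$dataset, ch$chimera))) {
          mask <- logical(len)
          rows <- ch[paste(ch$dataset, ch$chimera) == u, ]
          for (i in seq_len(nrow(rows))) {
            mask[seq.int(rows$start[i] + 1L, rows$end[i])] <- TRUE
          }
          counts <- counts + mask
        }
      }
      r <- rle(counts >= n)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      keep <- r$values & r$lengths >= L
      if (any(keep)) {
        out[[length(out) + 1L]] <- data.frame(
          seqid = sq, start = starts[keep] - 1L, end = ends[keep], strand = s,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(seqid = character(), start = integer(),
                      end = integer(), strand = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$seqid, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# random profile inputs: up to n_units evidence sources over [0, len)
random_profile_inputs <- function(len = 3000L, n_units = 8L) {
  n_ds <- sample.int(max(1L, n_units - 1L), 1L)
  n_ch <- n_units - n_ds
  pk <- do.call(rbind, lapply(seq_len(n_ds), function(d) {
    k <- sample.int(6L, 1L)
    st <- sample.int(len - 120L, k) - 1L
    w <- sample(10:100, k, replace = TRUE)
    make_peaks("chrP", st, pmin(st + w, len), strand = sample(c("+", "-", "."), 1L),
               dataset = sprintf("GSM%02d", d),
               cell_line = sample(c("HEK293", "Huh7.5", "HeLa"), 1L))
  }))
  ch <- if (n_ch > 0L) do.call(rbind, lapply(seq_len(n_ch), function(cix) {
    st <- sample.int(len - 80L, 1L) - 1L
    make_interactions("chrP", st, st + sample(10:60, 1L),
                      strand = sample(c("+", "-"), 1L),
                      mirna = sprintf("miR-%d", cix),
                      dataset = "CHIMDS", chimera = sprintf("chim%02d", cix))
  })) else NULL
  list(peaks = pk, interactions = ch, len = len)
}

region_coords <- function(regions) {
  df <- as.data.frame(regions)[, c("seqid", "start", "end", "strand")]
  df <- df[order(df$seqid, df$start, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  df
}

# -- VCF fixture ------------------------------------------------------------

write_vcf_fixture <- function(path, rows, version = "4.1") {
  header <- c(paste0("##fileformat=VCFv", version),
              "##source=mibrkit-test",
              "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO")
  writeLines(c(header, rows), path)
  path
}
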