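# Deterministic synthetic-data generators with a planted-truth manifest.
#
# The generators emulate the statistical structure of chimera-based
# interactome data: interaction lengths around 37.2 +/- 19.4 nt (truncated
# normal on [8, 200]), about 19% of target regions split across two exons,
# replicate CLIP peak sets sharing true binding regions, expression tables
# with planted sponge genes and type-1/type-2 miRNAs at percentile extremes,
# and a 9-name cell-line vocabulary so ubiquity summaries are exercised.

.CELL_LINES <- c("HEK293", "Huh7.5", "HeLa", "HFF", "BC-1", "BC-3", "EF3D",
                 "LCL35", "LCL")

# truncated-normal sampler (rejection), bounded integer lengths
.rtrunc_len <- function(n, mean = 37.2, sd = 19.4, lo = 8L, hi = 200L) {
  out <- integer(0)
  while (length(out) < n) {
    x <- as.integer(round(stats::rnorm(n, mean, sd)))
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Generate a synthetic gene model
#'
#' Genes are packed left-to-right on each sequence with random intergenic
#' gaps; every gene has one transcript of 1-5 exons (both strands), and
#' coding genes carry a CDS span leaving 5' and 3' UTRs inside the exon
#' union. Deterministic for a seed.
#'
#' @param seed RNG seed.
#' @param n_genes total genes.
#' @param n_seqids number of sequences (named `chrS1`, `chrS2`, ...).
#' @param seq_length length of each sequence in nt.
#' @param noncoding_frac fraction of noncoding genes.
#' @param exon_len,intron_len,gap_len integer ranges (min, max) for exon,
#'   intron and intergenic-gap lengths.
#' @return list with `model` (a [gene_model]) and `seq_lengths` (named
#'   integer vector).
#' @export
gen_genome <- function(seed = 1L, n_genes = 200L, n_seqids = 2L,
                       seq_length = 500000L, noncoding_frac = 0.15,
                       exon_len = c(120L, 400L), intron_len = c(60L, 400L),
                       gap_len = c(200L, 800L)) {
  stopifnot(n_genes >= 1L)
  set.seed(seed)
  seqids <- sprintf("chrS%d", seq_len(n_seqids))
  per_seq <- rep(n_genes %/% n_seqids, n_seqids)
  per_seq[seq_len(n_genes %% n_seqids)] <- per_seq[seq_len(n_genes %% n_seqids)] + 1L
  rows <- list()
  gi <- 0L
  for (s in seq_len(n_seqids)) {
    cursor <- 0L
    for (g in seq_len(per_seq[s])) {
      gi <- gi + 1L
      gene_id <- sprintf("G%04d", gi)
      n_ex <- sample.int(5L, 1L)
      widths <- sample(seq.int(exon_len[1L], exon_len[2L]), n_ex, replace = TRUE)
      introns <- if (n_ex > 1L)
        sample(seq.int(intron_len[1L], intron_len[2L]), n_ex - 1L, replace = TRUE)
      else integer(0)
      gap <- sample(seq.int(gap_len[1L], gap_len[2L]), 1L)
      gstart <- cursor + gap
      span <- sum(widths) + sum(introns)
      if (gstart + span > seq_length) {
        stop("infeasible packing: gene ", gene_id, " would end at ",
             gstart + span, " on ", seqids[s], " (length ", seq_length, ")")
      }
      ex_start <- gstart + c(0L, cumsum(widths[-n_ex] + introns))
      strand <- sample(c("+", "-"), 1L)
      coding <- stats::runif(1) >= noncoding_frac
      ex <- data.frame(
        gene_id = gene_id, gene_name = paste0("SYN", gene_id),
        biotype = if (coding) "coding" else "noncoding",
        transcript_id = paste0(gene_id, ".t1"), feature = "exon",
        seqid = seqids[s], start = ex_start, end = ex_start + widths,
        strand = strand, stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- ex
      if (coding) {
        txlen <- sum(widths)
        utr5 <- sample.int(max(1L, txlen %/% 5L), 1L)
        utr3 <- sample.int(max(1L, txlen %/% 5L), 1L)
        cds_tx <- c(utr5, txlen - utr3)
        blocks <- project_to_genome(cds_tx[1L], cds_tx[2L],
                                    ex[c("seqid", "start", "end", "strand")],
                                    ex$transcript_id[1L])
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = gene_id, gene_name = paste0("SYN", gene_id),
          biotype = "coding", transcript_id = paste0(gene_id, ".t1"),
          feature = "CDS", seqid = seqids[s],
          start = min(blocks$start), end = max(blocks$end),
          strand = strand, stringsAsFactors = FALSE)
      }
      cursor <- gstart + span
    }
  }
  model <- gene_model(do.call(rbind, rows))
  list(model = model,
       seq_lengths = stats::setNames(rep(as.integer(seq_length), n_seqids), seqids))
}

#' Generate chimera-derived interaction records
#'
#' Records are placed inside transcripts (lengths from a truncated normal
#' with the configured moments), projected to genome blocks; a configurable
#' fraction of records on multi-exon transcripts is placed across a splice
#' junction so the chimera splits into two genomic blocks. Per-miRNA record
#' counts may be fixed exactly via `mirna_counts`; planted sponge genes
#' receive at least `sponge_records` records each.
#'
#' @param genome a [gen_genome()] result (or a list with `model`).
#' @param mirna_vocab character vector of miRNA ids (used when
#'   `mirna_counts` is `NULL`).
#' @param n number of records when `mirna_counts` is `NULL`.
#' @param mirna_counts optional named integer vector fixing each miRNA's
#'   record count (`n` is then `sum(mirna_counts)`).
#' @param length_mean,length_sd,length_range interaction length model (nt).
#' @param multi_exon_frac fraction of records placed across an exon
#'   junction (when the chosen transcript allows it).
#' @param sponge_genes gene ids to overload; `sponge_records` records each.
#' @param sponge_records minimum records per sponge gene.
#' @param dataset,cell_line provenance labels.
#' @param seed RNG seed.
#' @return list with `interactions` (genome-space table, one row per
#'   block) and `manifest` (one row per record: transcript placement and
#'   block count).
#' @export
gen_interactions <- function(genome, mirna_vocab, n = 2000L,
                             mirna_counts = NULL,
                             length_mean = 37.2, length_sd = 19.4,
                             length_range = c(8L, 200L),
                             multi_exon_frac = 0.19,
                             sponge_genes = NULL, sponge_records = 55L,
                             dataset = "SIMCHIM_A", cell_line = "HEK293",
                             seed = 1L) {
  model <- genome$model
  set.seed(seed)
  if (is.null(mirna_counts)) {
    mir_of_record <- if (n > 0L) sample(mirna_vocab, n, replace = TRUE) else character(0)
  } else {
    mir_of_record <- sample(rep(names(mirna_counts), mirna_counts))
    n <- length(mir_of_record)
  }
  empty <- data.frame(seqid = character(), start = integer(), end = integer(),
                      strand = character(), mirna = character(),
                      dataset = character(), chimera = character(),
                      cell_line = character(), stringsAsFactors = FALSE)
  if (!n) return(list(interactions = empty,
                      manifest = data.frame(chimera = character(),
                                            transcript_id = character(),
                                            tx_start = integer(),
                                            tx_end = integer(),
                                            n_blocks = integer())))
  tx <- model$transcripts
  # transcript choice: sponge quota first, then length-weighted
  tx_of_record <- character(n)
  quota <- 0L
  if (!is.null(sponge_genes)) {
    for (g in sponge_genes) {
      gtx <- tx$transcript_id[tx$gene_id == g]
      if (!length(gtx)) stop("sponge gene ", g, " not in the gene model")
      take <- min(sponge_records, n - quota)
      tx_of_record[quota + seq_len(take)] <- gtx[1L]
      quota <- quota + take
    }
  }
  if (quota < n) {
    free <- seq.int(quota + 1L, n)
    tx_of_record[free] <- tx$transcript_id[
      sample.int(nrow(tx), length(free), replace = TRUE, prob = tx$length)]
  }
  lens <- .rtrunc_len(n, length_mean, length_sd, length_range[1L], length_range[2L])
  cross <- stats::runif(n) < multi_exon_frac

  blocks <- vector("list", n)
  manifest <- data.frame(chimera = sprintf("chim%05d", seq_len(n)),
                         transcript_id = tx_of_record,
                         tx_start = NA_integer_, tx_end = NA_integer_,
                         n_blocks = NA_integer_, mirna = mir_of_record,
                         stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    txid <- tx_of_record[i]
    ex <- .tx_exons(model, txid)
    txlen <- tx[txid, "length"]
    l <- min(lens[i], txlen)
    minus <- ex$strand[1L] == "-"
    ord <- if (minus) rev(seq_len(nrow(ex))) else seq_len(nrow(ex))
    w <- (ex$end - ex$start)[ord]
    offs <- c(0L, cumsum(w))
    if (cross[i] && nrow(ex) > 1L && l >= 2L) {
      j <- sample.int(nrow(ex) - 1L, 1L) # junction after transcription-order exon j
      cpos <- offs[j + 1L]
      lo <- max(0L, cpos - l + 1L)
      hi <- min(cpos - 1L, txlen - l)
      s <- if (hi < lo) max(0L, min(cpos - 1L, txlen - l)) else
        as.integer(sample(seq.int(lo, hi), 1L))
    } else {
      # wholly inside one exon
      ok <- which(w >= l)
      if (!length(ok)) { ok <- which.max(w); l <- w[ok] }
      j <- if (length(ok) > 1L) sample(ok, 1L, prob = w[ok] - l + 1L) else ok
      s <- offs[j] + as.integer(sample.int(w[j] - l + 1L, 1L) - 1L)
    }
    b <- project_to_genome(s, s + l, ex, txid)
    b$mirna <- mir_of_record[i]
    b$dataset <- dataset
    b$chimera <- manifest$chimera[i]
    b$cell_line <- cell_line
    blocks[[i]] <- b
    manifest$tx_start[i] <- s; manifest$tx_end[i] <- s + l
    manifest$n_blocks[i] <- nrow(b)
  }
  interactions <- do.call(rbind, blocks)
  rownames(interactions) <- NULL
  list(interactions = interactions, manifest = manifest)
}

#' Generate planted true binding regions
#'
#' Non-overlapping intervals inside exons, separated by at least `min_gap`
#' nt on their strand, with truncated-normal lengths. These are the ground
#' truth that [gen_clip_peaks()] replicates across datasets.
#'
#' @param genome a [gen_genome()] result.
#' @param n_regions number of regions to place.
#' @param min_gap minimum separation in nt between regions on one strand.
#' @param length_mean,length_sd,length_range length model (nt).
#' @param seed RNG seed.
#' @return data frame `region, seqid, start, end, strand, length`.
#' @export
gen_true_regions <- function(genome, n_regions = 120L, min_gap = 30L,
                             length_mean = 37.2, length_sd = 19.4,
                             length_range = c(8L, 80L), seed = 1L) {
  set.seed(seed)
  ex <- genome$model$exons
  placed <- list()
  tries <- 0L
  while (length(placed) < n_regions && tries < n_regions * 50L) {
    tries <- tries + 1L
    i <- sample.int(nrow(ex), 1L)
    l <- .rtrunc_len(1L, length_mean, length_sd, length_range[1L], length_range[2L])
    w <- ex$end[i] - ex$start[i]
    if (l > w) next
    s <- ex$start[i] + sample.int(w - l + 1L, 1L) - 1L
    cand <- c(seqid = ex$seqid[i], strand = ex$strand[i])
    clash <- any(vapply(placed, function(p) {
      p$seqid == cand["seqid"] && p$strand == cand["strand"] &&
        (s - min_gap) < p$end && p$start < (s + l + min_gap)
    }, logical(1)))
    if (clash) next
    placed[[length(placed) + 1L]] <- data.frame(
      seqid = ex$seqid[i], start = s, end = s + l, strand = ex$strand[i],
      stringsAsFactors = FALSE)
  }
  if (length(placed) < n_regions) {
    stop("could not place ", n_regions, " separated regions; reduce n_regions")
  }
  df <- do.call(rbind, placed)
  df <- df[order(df$seqid, df$start), , drop = FALSE]
  df <- cbind(region = sprintf("true%04d", seq_len(nrow(df))), df,
              length = df$end - df$start)
  rownames(df) <- NULL
  df
}

#' Generate replicate CLIP peak datasets around true regions
#'
#' Each of `n_datasets` datasets covers each true region independently with
#' probability `p`, with boundaries jittered by a rounded normal of sd
#' `jitter_sd`; `fp_per_dataset` additional false-positive peaks per
#' dataset are placed uniformly. With noise-free settings (`p = 1`,
#' `jitter_sd = 0`, `fp_per_dataset = 0`) and at least two datasets, the
#' consensus caller at (L = 10, n = 2) recovers exactly the true regions of
#' length >= 10, which the manifest records as the expected truth set.
#'
#' @param true_regions a [gen_true_regions()] table.
#' @param seq_lengths named integer vector of sequence lengths.
#' @param n_datasets number of datasets (>= 2 to exercise the n = 2 rule).
#' @param p per-dataset probability of covering a true region.
#' @param jitter_sd boundary jitter sd in nt.
#' @param fp_per_dataset false-positive peaks per dataset.
#' @param fp_len false-positive peak length in nt.
#' @param cell_line_map optional character vector assigning a cell line to
#'   each dataset (recycled from the 9-name vocabulary by default).
#' @param method method tag for all peaks.
#' @param seed RNG seed.
#' @return list with `peaks` (one table, `dataset` column distinguishes
#'   datasets) and `manifest` (`expected_mibrs`: truth regions of length >=
#'   10 under noise-free settings, else `NULL`; per-dataset coverage
#'   matrix).
#' @export
gen_clip_peaks <- function(true_regions, seq_lengths, n_datasets = 5L,
                           p = 1, jitter_sd = 0, fp_per_dataset = 0L,
                           fp_len = 30L, cell_line_map = NULL,
                           method = "HITS-CLIP", seed = 1L) {
  stopifnot(n_datasets >= 1L)
  set.seed(seed)
  datasets <- sprintf("GSMSIM%02d", seq_len(n_datasets))
  if (is.null(cell_line_map)) {
    cell_line_map <- rep_len(.CELL_LINES, n_datasets)
  }
  names(cell_line_map) <- datasets
  covers <- matrix(FALSE, nrow(true_regions), n_datasets,
                   dimnames = list(true_regions$region, datasets))
  rows <- list()
  for (d in seq_len(n_datasets)) {
    take <- stats::runif(nrow(true_regions)) < p
    covers[, d] <- take
    if (any(take)) {
      tr <- true_regions[take, , drop = FALSE]
      js <- as.integer(round(stats::rnorm(nrow(tr), 0, jitter_sd)))
      je <- as.integer(round(stats::rnorm(nrow(tr), 0, jitter_sd)))
      st <- pmax(0L, tr$start + js)
      en <- unname(pmin(seq_lengths[tr$seqid], pmax(st + 1L, tr$end + je)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = tr$seqid, start = st, end = as.integer(en), strand = tr$strand,
        dataset = datasets[d], cell_line = unname(cell_line_map[d]), method = method,
        stringsAsFactors = FALSE)
    }
    if (fp_per_dataset > 0L) {
      sq <- sample(names(seq_lengths), fp_per_dataset, replace = TRUE)
      st <- unname(vapply(sq, function(q) sample.int(seq_lengths[q] - fp_len, 1L) - 1L,
                          integer(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        seqid = sq, start = st, end = st + fp_len,
        strand = sample(c("+", "-"), fp_per_dataset, replace = TRUE),
        dataset = datasets[d], cell_line = unname(cell_line_map[d]), method = method,
        stringsAsFactors = FALSE)
    }
  }
  peaks <- do.call(rbind, rows)
  rownames(peaks) <- NULL
  noise_free <- p == 1 && jitter_sd == 0 && fp_per_dataset == 0L
  expected <- if (noise_free) {
    tr <- true_regions[true_regions$length >= 10L, , drop = FALSE]
    rownames(tr) <- NULL
    tr
  } else NULL
  list(peaks = peaks,
       manifest = list(datasets = datasets, cell_line_map = cell_line_map,
                       covers = covers, noise_free = noise_free,
                       expected_mibrs = expected))
}

#' Generate expression tables with planted classification extremes
#'
#' Builds transcript-level TPM tables (replicates) and a miRNA count matrix
#' whose background cohort has expression exactly proportional to its
#' interaction count (constant expression-to-interaction ratio), with
#' planted type-1 miRNAs (top expression, one interaction) and type-2
#' miRNAs (top interaction count, expression chosen so the ratio falls in
#' the bottom decile). Replicate counts are identical, so median-of-ratios
#' size factors are exactly 1 and the planted sets are recovered exactly by
#' strict nearest-rank percentile cutoffs.
#'
#' @param genome a [gen_genome()] result.
#' @param mirna_vocab miRNA ids (>= 10).
#' @param planted_type1,planted_type2 disjoint subsets of `mirna_vocab`.
#' @param sponge_genes gene ids guaranteed an expression call.
#' @param frac_nonexpressed fraction of genes given zero TPM.
#' @param ratio_c background expression-to-interaction ratio (counts per
#'   record).
#' @param bg_k integer range of background per-miRNA record counts.
#' @param type2_k record count of type-2 miRNAs.
#' @param n_replicates mRNA replicates; `n_samples` miRNA samples.
#' @param seed RNG seed.
#' @return list with `tx_tpm` (data frame `transcript_id` + replicates),
#'   `mirna_counts_table` (data frame `mirna` + samples),
#'   `mirna_record_counts` (named vector for [gen_interactions()]),
#'   `manifest` (planted ids and parameters).
#' @export
gen_expression <- function(genome, mirna_vocab, planted_type1 = character(),
                           planted_type2 = character(),
                           sponge_genes = character(),
                           frac_nonexpressed = 0.1, ratio_c = 20L,
                           bg_k = c(2L, 13L), type2_k = 150L,
                           n_replicates = 2L, n_samples = 2L, seed = 1L) {
  if (length(mirna_vocab) < 10L) stop("planting infeasible: need >= 10 miRNAs")
  if (length(intersect(planted_type1, planted_type2))) {
    stop("planted type1 and type2 sets must be disjoint")
  }
  set.seed(seed)
  model <- genome$model
  tx <- model$transcripts
  genes <- model$genes$gene_id
  nonexp <- sample(setdiff(genes, sponge_genes),
                   round(frac_nonexpressed * length(genes)))
  base <- stats::rlnorm(length(genes), meanlog = 3, sdlog = 1) + 1.5
  names(base) <- genes
  base[nonexp] <- 0
  tpm <- data.frame(transcript_id = tx$transcript_id, stringsAsFactors = FALSE)
  for (r in seq_len(n_replicates)) {
    noise <- stats::runif(nrow(tx), 0.9, 1.1)
    tpm[[paste0("rep", r)]] <- round(base[tx$gene_id] * noise, 3)
  }

  bg <- setdiff(mirna_vocab, c(planted_type1, planted_type2))
  k <- stats::setNames(integer(length(mirna_vocab)), mirna_vocab)
  k[bg] <- sample(seq.int(bg_k[1L], bg_k[2L]), length(bg), replace = TRUE)
  k[planted_type1] <- 1L
  k[planted_type2] <- as.integer(type2_k)
  expr <- stats::setNames(numeric(length(mirna_vocab)), mirna_vocab)
  expr[bg] <- ratio_c * k[bg]
  expr[planted_type1] <- max(expr[bg]) * 10 + seq_along(planted_type1)
  expr[planted_type2] <- 10
  counts <- data.frame(mirna = mirna_vocab, stringsAsFactors = FALSE)
  for (s in seq_len(n_samples)) counts[[paste0("s", s)]] <- as.integer(expr)
  list(tx_tpm = tpm,
       mirna_counts_table = counts,
       mirna_record_counts = k,
       manifest = list(type1 = planted_type1, type2 = planted_type2,
                       sponge_genes = sponge_genes,
                       nonexpressed_genes = nonexp, ratio_c = ratio_c))
}

#' Generate a conservation track for synthetic mature miRNAs
#'
#' Places a 22-nt mature span per miRNA on a dedicated sequence and emits
#' per-base scores.
#'
#' @param mirna_vocab miRNA ids.
#' @param seqid sequence name for the spans.
#' @param score_mean,score_sd per-base score model.
#' @param seed RNG seed.
#' @return list `mirna_coords` (`mirna, seqid, start, end, strand`) and
#'   `phylop` (`seqid, pos, score`).
#' @export
gen_conservation <- function(mirna_vocab, seqid = "chrSmir",
                             score_mean = 0.5, score_sd = 0.2, seed = 1L) {
  set.seed(seed)
  n <- length(mirna_vocab)
  starts <- (seq_len(n) - 1L) * 30L
  coords <- data.frame(mirna = mirna_vocab, seqid = seqid, start = starts,
                       end = starts + 22L, strand = "+", stringsAsFactors = FALSE)
  pos <- unlist(lapply(starts, function(s) seq.int(s, s + 21L)))
  phylop <- data.frame(seqid = seqid, pos = pos,
                       score = round(stats::rnorm(length(pos), score_mean,
                                                  score_sd), 4),
                       stringsAsFactors = FALSE)
  list(mirna_coords = coords, phylop = phylop)
}

#' Generate a full synthetic study with a truth manifest
#'
#' Orchestrates all generators under one master seed: a genome, two
#' chimera interaction datasets with a planted number of common
#' interactions, replicate CLIP peak sets around planted true binding
#' regions, expression tables with planted sponge genes and type-1/type-2
#' miRNAs, and a conservation track. When `out_dir` is given, every input
#' format plus `truth.json` (the manifest) is written there.
#'
#' @param seed master seed; all generator seeds derive from it.
#' @param out_dir optional output directory.
#' @param n_genes,n_seqids,seq_length genome scale.
#' @param n_mirnas miRNA vocabulary size.
#' @param n_datasets CLIP datasets.
#' @param n_type1,n_type2,n_sponges planted set sizes.
#' @param sponge_records records planted per sponge gene.
#' @param n_true_regions planted binding regions.
#' @param n_common interaction records of dataset B copied from dataset A
#'   coordinates (the planted common-interaction count).
#' @param n_b independently placed records of dataset B.
#' @param peak_p,peak_jitter_sd,peak_fp CLIP noise knobs (defaults are the
#'   noise-free study conditions).
#' @return list of class `sim_study` with `genome`, `interactions_a`,
#'   `interactions_b`, `peaks`, `expression`, `conservation` and `truth`
#'   (the manifest).
#' @export
sim_all <- function(seed = 17L, out_dir = NULL, n_genes = 200L,
                    n_seqids = 2L, seq_length = 500000L, n_mirnas = 200L,
                    n_datasets = 5L, n_type1 = 3L, n_type2 = 3L,
                    n_sponges = 2L, sponge_records = 55L,
                    n_true_regions = 120L, n_common = 25L, n_b = 400L,
                    peak_p = 1, peak_jitter_sd = 0, peak_fp = 0L) {
  set.seed(seed)
  sub <- sample.int(2^30, 8L)
  genome <- gen_genome(sub[1L], n_genes = n_genes, n_seqids = n_seqids,
                       seq_length = seq_length)
  mirna_vocab <- sprintf("sim-miR-%03d", seq_len(n_mirnas))
  set.seed(sub[2L])
  planted_type1 <- sample(mirna_vocab, n_type1)
  planted_type2 <- sample(setdiff(mirna_vocab, planted_type1), n_type2)
  coding <- genome$model$genes$gene_id[genome$model$genes$biotype == "coding"]
  sponge_genes <- sample(coding, n_sponges)

  expression <- gen_expression(genome, mirna_vocab,
                               planted_type1 = planted_type1,
                               planted_type2 = planted_type2,
                               sponge_genes = sponge_genes, seed = sub[3L])
  ia <- gen_interactions(genome, mirna_vocab,
                         mirna_counts = expression$mirna_record_counts,
                         sponge_genes = sponge_genes,
                         sponge_records = sponge_records,
                         dataset = "SIMCHIM_A", cell_line = "HEK293",
                         seed = sub[4L])
  ib <- gen_interactions(genome, mirna_vocab, n = n_b,
                         dataset = "SIMCHIM_B", cell_line = "Huh7.5",
                         seed = sub[5L])
  # plant common interactions: copy coordinates of n_common A records into B
  set.seed(sub[6L])
  a_recs <- unique(ia$interactions$chimera)
  common_src <- sample(a_recs, min(n_common, length(a_recs)))
  copies <- ia$interactions[ia$interactions$chimera %in% common_src, , drop = FALSE]
  copies$dataset <- "SIMCHIM_B"
  copies$cell_line <- "Huh7.5"
  copies$chimera <- paste0("cp_", copies$chimera)
  ib$interactions <- rbind(ib$interactions, copies)

  true_regions <- gen_true_regions(genome, n_regions = n_true_regions,
                                   seed = sub[7L])
  clip <- gen_clip_peaks(true_regions, genome$seq_lengths,
                         n_datasets = n_datasets, p = peak_p,
                         jitter_sd = peak_jitter_sd,
                         fp_per_dataset = peak_fp, seed = sub[8L])
  conservation <- gen_conservation(mirna_vocab, seed = sub[1L])

  truth <- list(seed = seed,
                true_regions = true_regions,
                expected_mibrs = clip$manifest$expected_mibrs,
                sponge_genes = sponge_genes,
                sponge_records = sponge_records,
                type1 = planted_type1, type2 = planted_type2,
                mirna_record_counts = as.list(expression$mirna_record_counts),
                n_common = length(common_src),
                common_chimeras = common_src,
                nonexpressed_genes = expression$manifest$nonexpressed_genes,
                fp_per_dataset = peak_fp)
  study <- structure(list(genome = genome, interactions_a = ia,
                          interactions_b = ib, peaks = clip,
                          expression = expression,
                          conservation = conservation, truth = truth),
                     class = "sim_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_gene_model(genome$model, file.path(out_dir, "genome.tsv"))
    write_interactions(ia$interactions, file.path(out_dir, "interactions_a.tsv"))
    write_interactions(ib$interactions, file.path(out_dir, "interactions_b.tsv"))
    write_peaks(clip$peaks, file.path(out_dir, "peaks.tsv"))
    utils::write.table(expression$tx_tpm, file.path(out_dir, "tx_tpm.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(expression$mirna_counts_table,
                       file.path(out_dir, "mirna_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(conservation$phylop, file.path(out_dir, "phylop.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(conservation$mirna_coords,
                       file.path(out_dir, "mirna_coords.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth, file.path(out_dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  study
}

#' @export
print.sim_study <- function(x, ...) {
  cat("synthetic study (seed ", x$truth$seed, "):\n", sep = "")
  cat("  genes:", nrow(x$genome$model$genes),
      "| miRNAs:", length(x$truth$mirna_record_counts),
      "| true regions:", nrow(x$truth$true_regions), "\n")
  cat("  planted: ", length(x$truth$sponge_genes), " sponge gene(s), ",
      length(x$truth$type1), " type1, ", length(x$truth$type2),
      " type2, ", x$truth$n_common, " common interaction(s)\n", sep = "")
  invisible(x)
}
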