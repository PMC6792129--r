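# Cross-dataset common-interaction detection and its random-placement null.

# split an interaction table into record keys; returns integer record index
# per row plus a per-record metadata frame
.record_index <- function(interactions) {
  key <- paste(interactions$dataset, interactions$chimera, sep = "\r")
  idx <- match(key, unique(key))
  meta <- interactions[!duplicated(key), c("dataset", "chimera", "mirna"), drop = FALSE]
  meta$record_id <- paste(meta$dataset, meta$chimera, sep = ":")
  rownames(meta) <- NULL
  list(idx = idx, meta = meta)
}

#' Find common interactions between two datasets
#'
#' Two interaction records — one from each dataset — are "common" when some
#' genomic block of one overlaps some block of the other on the same seqid
#' and strand by at least `min_overlap` nt. Pairing is many-to-many: one
#' record may take part in several pairs, which is why the number of common
#' pairs can exceed the number of distinct records on either side.
#'
#' @param setA,setB interaction tables in genome coordinates (rows are
#'   blocks; blocks of one chimera share a `chimera` id).
#' @param min_overlap minimum per-block overlap in nt (default 1).
#' @param require_same_mirna if `TRUE`, only records carrying the same
#'   miRNA id can pair.
#' @param overlap_mode how the overlap length of a record pair with several
#'   overlapping block pairs is aggregated: `"sum"` (shared footprint,
#'   default) or `"max"`.
#' @return list with `pairs` (data frame `id_a, id_b, mirna_a, mirna_b,
#'   overlap, same_mirna`) and `summary` (`n_pairs`, `n_distinct_a`,
#'   `n_distinct_b`, `mean_overlap`, `sd_overlap`, `n_pairs_over_20nt`).
#' @examples
#' a <- data.frame(seqid = "chr1", start = 0L, end = 50L, strand = "+",
#'                 mirna = "miR-1", dataset = "A", chimera = "c1",
#'                 cell_line = "HEK293")
#' b <- data.frame(seqid = "chr1", start = c(40L, 45L), end = c(90L, 60L),
#'                 strand = "+", mirna = c("miR-2", "miR-1"), dataset = "B",
#'                 chimera = c("d1", "d2"), cell_line = "Huh7.5")
#' find_common(a, b)$summary
#' @export
find_common <- function(setA, setB, min_overlap = 1L,
                        require_same_mirna = FALSE,
                        overlap_mode = c("sum", "max")) {
  overlap_mode <- match.arg(overlap_mode)
  ra <- .record_index(setA); rb <- .record_index(setB)
  empty <- data.frame(id_a = character(), id_b = character(),
                      mirna_a = character(), mirna_b = character(),
                      overlap = integer(), same_mirna = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(setA) || !nrow(setB)) {
    return(list(pairs = empty, summary = .pair_summary(empty)))
  }
  gra <- .df_to_gr(setA); grb <- .df_to_gr(setB)
  # the two sets legitimately cover different seqid subsets
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gra, grb, minoverlap = as.integer(min_overlap),
                                ignore.strand = FALSE))
  if (!length(hits)) return(list(pairs = empty, summary = .pair_summary(empty)))
  qa <- S4Vectors::queryHits(hits); qb <- S4Vectors::subjectHits(hits)
  ov <- IRanges::width(IRanges::pintersect(GenomicRanges::ranges(gra)[qa],
                                           GenomicRanges::ranges(grb)[qb]))
  pair_key <- paste(ra$idx[qa], rb$idx[qb])
  agg_fun <- if (overlap_mode == "sum") sum else max
  ov_by_pair <- tapply(ov, pair_key, agg_fun)
  uniq <- !duplicated(pair_key)
  ia <- ra$idx[qa][uniq]; ib <- rb$idx[qb][uniq]
  pairs <- data.frame(
    id_a = ra$meta$record_id[ia], id_b = rb$meta$record_id[ib],
    mirna_a = ra$meta$mirna[ia], mirna_b = rb$meta$mirna[ib],
    overlap = as.integer(ov_by_pair[pair_key[uniq]]),
    stringsAsFactors = FALSE
  )
  pairs$same_mirna <- pairs$mirna_a == pairs$mirna_b
  if (require_same_mirna) pairs <- pairs[pairs$same_mirna, , drop = FALSE]
  pairs <- pairs[order(pairs$id_a, pairs$id_b), , drop = FALSE]
  rownames(pairs) <- NULL
  list(pairs = pairs, summary = .pair_summary(pairs))
}

.pair_summary <- function(pairs) {
  list(n_pairs = nrow(pairs),
       n_distinct_a = length(unique(pairs$id_a)),
       n_distinct_b = length(unique(pairs$id_b)),
       mean_overlap = if (nrow(pairs)) mean(pairs$overlap) else NA_real_,
       sd_overlap = if (nrow(pairs) > 1L) stats::sd(pairs$overlap) else NA_real_,
       n_pairs_over_20nt = sum(pairs$overlap > 20L))
}

# place n fragments in transcripts: lengths from sampler, transcript chosen
# with probability proportional to its length, start uniform so the fragment
# lies wholly inside. Returns a transcript-space interaction table.
.place_fragments <- function(n, tx_ids, tx_len, length_sampler,
                             dataset, retry_cap = 100L) {
  if (!n) {
    return(data.frame(seqid = character(), start = integer(), end = integer(),
                      strand = character(), mirna = character(),
                      dataset = character(), chimera = character(),
                      cell_line = character(), stringsAsFactors = FALSE))
  }
  tx_pick <- sample.int(length(tx_ids), n, replace = TRUE, prob = tx_len)
  lens <- integer(n)
  for (i in seq_len(n)) {
    l <- as.integer(round(length_sampler(1L)))
    tries <- 0L
    while (l > tx_len[tx_pick[i]] || l < 1L) {
      tries <- tries + 1L
      if (tries > retry_cap) {
        stop("could not sample a fragment fitting transcript ",
             tx_ids[tx_pick[i]], " (length ", tx_len[tx_pick[i]], ")")
      }
      l <- as.integer(round(length_sampler(1L)))
    }
    lens[i] <- l
  }
  starts <- vapply(seq_len(n), function(i) {
    as.integer(sample.int(tx_len[tx_pick[i]] - lens[i] + 1L, 1L) - 1L)
  }, integer(1))
  data.frame(seqid = tx_ids[tx_pick], start = starts, end = starts + lens,
             strand = "+", mirna = "sim", dataset = dataset,
             chimera = sprintf("f%06d", seq_len(n)),
             cell_line = "sim", stringsAsFactors = FALSE)
}

#' Random-placement null for cross-dataset interaction overlap
#'
#' Emulates the size-matched simulation used to judge whether the observed
#' number of common interactions between two chimera datasets exceeds
#' chance: in each replicate, `nA` and `nB` fragments with lengths drawn
#' from the two datasets' empirical length distributions are placed at
#' uniform-random positions within a shared set of expressed transcripts
#' (transcripts chosen with probability proportional to length, fragments
#' wholly inside one transcript), and the two synthetic sets are scored with
#' [find_common()]. Fragments may overlap each other within a set; no
#' exclusion is applied, which keeps the closed-form expectation
#' `nA * nB * (2L - 1) / T` valid on a single transcript of length `T` with
#' fixed fragment length `L`.
#'
#' @param transcripts named integer vector of transcript lengths (the shared
#'   expressed transcript set), or a data frame with columns
#'   `transcript_id`, `length`.
#' @param nA,nB fragment counts matching the observed dataset sizes.
#' @param length_sampler_A,length_sampler_B functions `f(n)` drawing `n`
#'   fragment lengths.
#' @param replicates number of independent runs (default 5).
#' @param seed master seed; per-replicate seeds are derived from it.
#' @param observed optionally, the observed common-pair count; when given,
#'   an add-one empirical p-value `(1 + #\{replicates >= observed\}) /
#'   (1 + replicates)` and a z-score against the replicate distribution are
#'   reported. With few replicates the empirical p-value is floored at
#'   `1 / (1 + replicates)`.
#' @param min_overlap passed to [find_common()].
#' @param model optional [gene_model]; when supplied, fragments are
#'   projected to genome space before scoring, otherwise they are scored in
#'   transcript space directly.
#' @return list of class `null_result`: `counts`, `mean_overlap`,
#'   `n_over_20`, per-replicate vectors; `mean_count`, `sd_count`;
#'   `p_empirical`, `z_score` (if `observed` given); `seed`.
#' @export
simulate_null <- function(transcripts, nA, nB, length_sampler_A,
                          length_sampler_B, replicates = 5L, seed = 1L,
                          observed = NULL, min_overlap = 1L, model = NULL) {
  if (is.data.frame(transcripts)) {
    tx_len <- transcripts$length
    tx_ids <- transcripts$transcript_id
  } else {
    tx_len <- as.integer(transcripts)
    tx_ids <- names(transcripts)
    if (is.null(tx_ids)) tx_ids <- sprintf("tx%05d", seq_along(tx_len))
  }
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max - 1L, replicates)
  counts <- integer(replicates)
  mean_ov <- numeric(replicates)
  over20 <- integer(replicates)
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    a <- .place_fragments(nA, tx_ids, tx_len, length_sampler_A, "nullA")
    b <- .place_fragments(nB, tx_ids, tx_len, length_sampler_B, "nullB")
    if (!is.null(model)) {
      a <- project_interactions(a, model)$interactions
      b <- project_interactions(b, model)$interactions
    }
    fc <- find_common(a, b, min_overlap = min_overlap)
    counts[r] <- fc$summary$n_pairs
    mean_ov[r] <- if (fc$summary$n_pairs) fc$summary$mean_overlap else NA_real_
    over20[r] <- fc$summary$n_pairs_over_20nt
  }
  res <- list(counts = counts, mean_overlap = mean_ov, n_over_20 = over20,
              mean_count = mean(counts), sd_count = stats::sd(counts),
              replicates = replicates, seed = seed)
  if (!is.null(observed)) {
    res$observed <- observed
    res$p_empirical <- (1 + sum(counts >= observed)) / (1 + replicates)
    res$z_score <- if (res$sd_count > 0) (observed - res$mean_count) / res$sd_count else Inf
  }
  structure(res, class = "null_result")
}

#' @export
print.null_result <- function(x, ...) {
  cat("random-placement null:", x$replicates, "replicate(s)\n")
  cat("  common pairs: mean", format(x$mean_count), "+/-", format(x$sd_count), "\n")
  if (!is.null(x$observed)) {
    cat("  observed", x$observed, "-> empirical p =", format(x$p_empirical),
        "(add-one estimator), z =", format(x$z_score), "\n")
  }
  invisible(x)
}
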