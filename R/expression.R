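# Expression summarization, interaction counting, gene and miRNA
# classification, conservation means and per-transcript interaction profiles.

#' Summarize transcript-level TPM to gene level
#'
#' Gene expression is the sum of its transcripts' TPM within each replicate;
#' the reported level is the mean across replicates. A gene is retained only
#' if BOTH filters pass: mean across replicates >= `min_tpm` and at least
#' one replicate >= `min_tpm`.
#'
#' @param tpm data frame with a `transcript_id` column and one numeric
#'   column per replicate.
#' @param tx2gene data frame `transcript_id`, `gene_id`. Transcripts absent
#'   from the mapping are excluded with a message.
#' @param min_tpm expression call threshold in TPM (default 1).
#' @return data frame `gene_id`, per-replicate sums, `mean_tpm`,
#'   `expressed` (always `TRUE` for retained rows); genes failing the
#'   filters are dropped.
#' @export
summarize_gene_expression <- function(tpm, tx2gene, min_tpm = 1) {
  rep_cols <- setdiff(names(tpm), "transcript_id")
  if (!length(rep_cols)) stop("no replicate columns in tpm table")
  known <- tpm$transcript_id %in% tx2gene$transcript_id
  if (any(!known)) {
    message("summarize_gene_expression: ", sum(!known),
            " transcript(s) absent from the mapping, excluded")
  }
  tpm <- tpm[known, , drop = FALSE]
  if (!nrow(tpm)) {
    out <- data.frame(gene_id = character(), mean_tpm = numeric(),
                      expressed = logical(), stringsAsFactors = FALSE)
    return(out)
  }
  gene <- tx2gene$gene_id[match(tpm$transcript_id, tx2gene$transcript_id)]
  sums <- stats::aggregate(tpm[rep_cols], by = list(gene_id = gene), FUN = sum)
  mean_tpm <- rowMeans(sums[, rep_cols, drop = FALSE])
  keep <- mean_tpm >= min_tpm &
    apply(sums[, rep_cols, drop = FALSE] >= min_tpm, 1L, any)
  out <- cbind(sums[keep, , drop = FALSE],
               mean_tpm = mean_tpm[keep],
               expressed = rep(TRUE, sum(keep)))
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Median-of-ratios normalization of miRNA counts
#'
#' Size factors follow the median-of-ratios construction: for each miRNA
#' with a nonzero geometric mean across samples, each sample's ratio of
#' count to that geometric mean is formed, and the sample's size factor is
#' the median of its ratios. Normalized values are counts divided by the
#' size factor; the reported expression level is their mean across samples.
#' A miRNA is called expressed when that mean is at least `expressed_cutoff`
#' counts.
#'
#' If every miRNA contains a zero (no row has a finite log geometric mean),
#' size factors fall back to 1 with a warning.
#'
#' @param counts integer matrix (miRNAs x samples) or data frame with a
#'   `mirna` column plus count columns.
#' @param expressed_cutoff normalized-count threshold for the expressed
#'   call (default 3).
#' @return list with `table` (data frame `mirna`, `norm_mean`, `expressed`),
#'   `normalized` (matrix), `size_factors`.
#' @export
normalize_mirna_counts <- function(counts, expressed_cutoff = 3) {
  if (is.data.frame(counts)) {
    mirna <- counts$mirna
    mat <- as.matrix(counts[setdiff(names(counts), "mirna")])
  } else {
    mat <- as.matrix(counts)
    mirna <- rownames(mat)
    if (is.null(mirna)) mirna <- sprintf("mir%04d", seq_len(nrow(mat)))
  }
  storage.mode(mat) <- "double"
  if (ncol(mat) < 2L) stop("need at least two samples to normalize")
  loggeo <- rowMeans(log(mat))
  usable <- is.finite(loggeo)
  if (!any(usable)) {
    warning("every miRNA contains a zero count; size factors set to 1")
    sf <- rep(1, ncol(mat))
  } else {
    # median taken on the log-ratio scale (the canonical DESeq construction;
    # identical to the plain ratio median for odd cohort sizes)
    sf <- apply(mat[usable, , drop = FALSE], 2L, function(col) {
      exp(stats::median(log(col) - loggeo[usable]))
    })
  }
  names(sf) <- colnames(mat)
  normalized <- sweep(mat, 2L, sf, "/")
  norm_mean <- rowMeans(normalized)
  list(table = data.frame(mirna = mirna, norm_mean = norm_mean,
                          expressed = norm_mean >= expressed_cutoff,
                          stringsAsFactors = FALSE, row.names = NULL),
       normalized = normalized,
       size_factors = sf)
}

#' Count interactions per gene or per miRNA
#'
#' Counts are record-level: every chimera counts once, so repeated
#' observations of the same miRNA on the same gene accumulate. The number of
#' distinct partners (miRNAs for genes, genes for miRNAs) is reported
#' alongside.
#'
#' @param interactions genome-space interaction table carrying a `gene_id`
#'   column (e.g. from [assign_genes()]) and a `mirna` column.
#' @param level `"gene"` or `"mirna"`.
#' @return data frame `gene_id` (or `mirna`), `n_interactions`,
#'   `n_distinct_partners`.
#' @export
count_interactions <- function(interactions, level = c("gene", "mirna")) {
  level <- match.arg(level)
  df <- as.data.frame(interactions)
  rec_key <- paste(df$dataset, df$chimera, sep = "\r")
  rec <- df[!duplicated(rec_key), , drop = FALSE]
  if (level == "gene") {
    rec <- rec[!is.na(rec$gene_id), , drop = FALSE]
    by <- rec$gene_id; partner <- rec$mirna; id_col <- "gene_id"
  } else {
    by <- rec$mirna
    partner <- if (!is.null(rec$gene_id)) rec$gene_id else rec$seqid
    id_col <- "mirna"
  }
  if (!length(by)) {
    out <- data.frame(id = character(), n_interactions = integer(),
                      n_distinct_partners = integer(), stringsAsFactors = FALSE)
    names(out)[1L] <- id_col
    return(out)
  }
  n <- tapply(partner, by, length)
  d <- tapply(partner, by, function(x) length(unique(x[!is.na(x)])))
  out <- data.frame(id = names(n), n_interactions = as.integer(n),
                    n_distinct_partners = as.integer(d),
                    stringsAsFactors = FALSE, row.names = NULL)
  names(out)[1L] <- id_col
  out[order(out[[id_col]]), , drop = FALSE]
}

#' Assign interaction records to genes
#'
#' Annotates each record's combined genomic footprint against the gene
#' model (precedence rules of [annotate_interval()]) and attaches `gene_id`
#' and `part` columns to every row of the record.
#'
#' @param interactions genome-space interaction table.
#' @param model a [gene_model].
#' @return the interaction table with `gene_id`, `gene_name`, `part`.
#' @export
assign_genes <- function(interactions, model) {
  df <- as.data.frame(interactions)
  ann <- annotate_interval(df[c("seqid", "start", "end", "strand")], model)
  rec_key <- paste(df$dataset, df$chimera, sep = "\r")
  # a multi-block record takes the highest-precedence annotation of its blocks
  prec <- c(CDS = 1, UTR3 = 2, UTR5 = 3, ncRNA_exonic = 4, intronic = 5,
            intergenic = 6)
  best <- tapply(seq_len(nrow(df)), rec_key, function(ix) {
    ix[which.min(prec[ann$part[ix]])]
  })
  pick <- unlist(best)[match(rec_key, names(best))]
  df$gene_id <- ann$gene_id[pick]
  df$gene_name <- ann$gene_name[pick]
  df$part <- ann$part[pick]
  df
}

#' Categorize genes by interaction load
#'
#' Expressed genes are split by record-level interaction count into
#' `expressed_0`, `expressed_1_8`, `high_interacting` (>= `high_cutoff`,
#' default 9) and `sponge_like` (>= `sponge_cutoff`, default 50; these also
#' meet the high-interacting threshold). Genes with interactions but no
#' expression call are flagged `non_expressed_interacting`.
#'
#' @param gene_expression data frame with `gene_id` and `mean_tpm` for
#'   expressed genes (e.g. [summarize_gene_expression()] output).
#' @param interaction_counts data frame `gene_id`, `n_interactions`,
#'   `n_distinct_partners` from [count_interactions()].
#' @param high_cutoff,sponge_cutoff category thresholds (records).
#' @return data frame `gene_id`, `mean_tpm`, `n_interactions`,
#'   `n_distinct_mirnas`, `category`.
#' @export
categorize_genes <- function(gene_expression, interaction_counts,
                             high_cutoff = 9L, sponge_cutoff = 50L) {
  genes <- union(gene_expression$gene_id, interaction_counts$gene_id)
  tpm <- gene_expression$mean_tpm[match(genes, gene_expression$gene_id)]
  n <- interaction_counts$n_interactions[match(genes, interaction_counts$gene_id)]
  d <- interaction_counts$n_distinct_partners[match(genes, interaction_counts$gene_id)]
  n[is.na(n)] <- 0L; d[is.na(d)] <- 0L
  expressed <- !is.na(tpm)
  category <- ifelse(!expressed, "non_expressed_interacting",
              ifelse(n >= sponge_cutoff, "sponge_like",
              ifelse(n >= high_cutoff, "high_interacting",
              ifelse(n >= 1L, "expressed_1_8", "expressed_0"))))
  out <- data.frame(gene_id = genes, mean_tpm = tpm, n_interactions = n,
                    n_distinct_mirnas = d, category = category,
                    stringsAsFactors = FALSE)
  # non-expressed genes with zero interactions are unobserved; drop them
  out <- out[expressed | out$n_interactions > 0L, , drop = FALSE]
  out <- out[order(out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# nearest-rank percentile: value at rank ceil(q/100 * n) of the sorted vector
nearest_rank_percentile <- function(x, q) {
  s <- sort(x)
  s[max(1L, ceiling(q / 100 * length(s)))]
}

#' Classify miRNAs into expression/interaction ratio types
#'
#' For each miRNA the ratio `R = expression / n_interactions` captures how
#' its abundance relates to its detected target repertoire. On the cohort of
#' miRNAs that are both expressed and interacting, nearest-rank percentile
#' cutoffs define two extreme classes with strict inequalities:
#' * **type 1** — expression above the 90th percentile AND `R` above the
#'   90th percentile (abundant, few targets: dedicated regulators);
#' * **type 2** — `R` below the 10th percentile AND interaction count above
#'   the 90th percentile (scarce relative to a large target repertoire).
#'
#' @param summaries data frame with `mirna`, `expression` (normalized mean
#'   counts), `n_interactions`, and optionally `expressed` (logical; rows
#'   with `expressed == FALSE` or zero interactions are removed before the
#'   percentiles are computed).
#' @param pct_hi,pct_lo percentile cutoffs (default 90 / 10).
#' @return data frame with `mirna`, `expression`, `n_interactions`,
#'   `ratio_R`, `type` (`type1` / `type2` / `none`), plus a `cutoffs`
#'   attribute listing the percentile values used. With fewer than 10
#'   eligible miRNAs a warning is raised and no type is assigned.
#' @export
classify_mirna_types <- function(summaries, pct_hi = 90, pct_lo = 10) {
  df <- as.data.frame(summaries)
  if (!is.null(df$expressed)) df <- df[df$expressed, , drop = FALSE]
  df <- df[df$n_interactions > 0L, , drop = FALSE]
  df$ratio_R <- df$expression / df$n_interactions
  cutoffs <- list(expression_hi = NA_real_, ratio_hi = NA_real_,
                  ratio_lo = NA_real_, interactions_hi = NA_real_)
  if (nrow(df) < 10L) {
    warning("fewer than 10 eligible miRNAs; no types assigned")
    df$type <- rep("none", nrow(df))
  } else {
    cutoffs$expression_hi <- nearest_rank_percentile(df$expression, pct_hi)
    cutoffs$ratio_hi <- nearest_rank_percentile(df$ratio_R, pct_hi)
    cutoffs$ratio_lo <- nearest_rank_percentile(df$ratio_R, pct_lo)
    cutoffs$interactions_hi <- nearest_rank_percentile(df$n_interactions, pct_hi)
    type1 <- df$expression > cutoffs$expression_hi & df$ratio_R > cutoffs$ratio_hi
    type2 <- df$ratio_R < cutoffs$ratio_lo &
      df$n_interactions > cutoffs$interactions_hi
    df$type <- ifelse(type1, "type1", ifelse(type2, "type2", "none"))
  }
  rownames(df) <- NULL
  structure(df, cutoffs = cutoffs)
}

#' Mean conservation score per miRNA group
#'
#' Each miRNA's conservation is the mean of per-base scores over its mature
#' coordinates; a group's value is the mean of its members' means. Bases
#' absent from the score table are skipped and counted; miRNAs with no
#' scored base at all are excluded with a message.
#'
#' @param groups named list of character vectors of miRNA ids.
#' @param phylop data frame `seqid`, `pos` (0-based), `score`.
#' @param mirna_coords data frame `mirna`, `seqid`, `start`, `end`,
#'   `strand` (mature spans, 0-based half-open).
#' @return data frame `group`, `mean_phylop`, `n_mirnas`,
#'   `n_missing_bases`.
#' @export
conservation_means <- function(groups, phylop, mirna_coords) {
  score_key <- paste(phylop$seqid, phylop$pos)
  per_mirna <- function(id) {
    row <- mirna_coords[mirna_coords$mirna == id, , drop = FALSE]
    if (!nrow(row)) return(c(mean = NA_real_, missing = NA_real_))
    pos <- seq.int(row$start[1L], row$end[1L] - 1L)
    sc <- phylop$score[match(paste(row$seqid[1L], pos), score_key)]
    c(mean = if (all(is.na(sc))) NA_real_ else mean(sc, na.rm = TRUE),
      missing = sum(is.na(sc)))
  }
  out <- lapply(names(groups), function(g) {
    ids <- groups[[g]]
    if (!length(ids)) stop("group '", g, "' is empty")
    vals <- vapply(ids, per_mirna, numeric(2))
    drop <- is.na(vals["mean", ])
    if (any(drop)) {
      message("conservation_means: excluding ", sum(drop),
              " miRNA(s) with no scored bases in group ", g)
    }
    data.frame(group = g,
               mean_phylop = mean(vals["mean", !drop]),
               n_mirnas = sum(!drop),
               n_missing_bases = sum(vals["missing", ], na.rm = TRUE),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Per-bin interaction profile along a transcript
#'
#' Segments a transcript into fixed-width bins (default 50 nt, last bin
#' possibly partial) and counts, per bin, the interaction records whose
#' transcript-space interval overlaps it; a record spanning a bin boundary
#' increments both bins.
#'
#' @param tx_intervals data frame of interaction intervals in transcript
#'   coordinates (`start`, `end`, 0-based half-open).
#' @param tx_length transcript length in nt.
#' @param bin bin width in nt (default 50).
#' @return data frame `bin` (0-based index), `start`, `end`, `count`.
#' @export
interaction_profile <- function(tx_intervals, tx_length, bin = 50L) {
  n_bins <- as.integer(ceiling(tx_length / bin))
  counts <- integer(n_bins)
  for (i in seq_len(nrow(tx_intervals))) {
    b0 <- tx_intervals$start[i] %/% bin
    b1 <- (tx_intervals$end[i] - 1L) %/% bin
    ix <- seq.int(b0, min(b1, n_bins - 1L)) + 1L
    counts[ix] <- counts[ix] + 1L
  }
  data.frame(bin = seq_len(n_bins) - 1L,
             start = (seq_len(n_bins) - 1L) * bin,
             end = pmin(seq_len(n_bins) * bin, as.integer(tx_length)),
             count = counts)
}
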