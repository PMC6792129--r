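# Exp-MiBR consensus calling: per-position evidence profiles over merged
# CLIP peaks and chimera blocks, (L, n) run extraction, parameter grid,
# region characterization, tissue and sequence-coverage summaries.

#' Build a per-position evidence profile
#'
#' An evidence unit is either a whole non-chimeric CLIP dataset (GSM) or an
#' individual chimeric read: a dataset contributes at most one unit to any
#' position however many of its peaks cover it (its intervals are unioned
#' first, making the profile idempotent under duplicated peak rows), and
#' each chimera contributes at most one unit per position through its
#' blocks. A chimera's parent dataset does not additionally count as a
#' non-chimeric unit.
#'
#' Profiles are strand-resolved; unstranded peaks (strand `.`) contribute to
#' both strands and are flagged `unstranded` in the unit metadata.
#'
#' @param peaks CLIP peak table (`seqid, start, end, strand, dataset,
#'   cell_line, method`) or `NULL`.
#' @param interactions genome-space chimera interaction table or `NULL`.
#' @return object of class `support_profile` wrapping a unit-level
#'   [GenomicRanges::GRanges] (intervals unioned within each unit) with
#'   metadata columns `unit`, `kind` (`dataset`/`chimera`), `dataset`,
#'   `cell_line`, `mirna`, `unstranded`.
#' @export
build_support_profile <- function(peaks = NULL, interactions = NULL) {
  parts <- list()
  if (!is.null(peaks) && nrow(peaks)) {
    pk <- as.data.frame(peaks)
    uns <- pk$strand == "."
    if (any(uns)) {
      both <- rbind(transform(pk[uns, ], strand = "+"),
                    transform(pk[uns, ], strand = "-"))
      both$unstranded <- TRUE
      pk <- pk[!uns, , drop = FALSE]
      if (nrow(pk)) pk$unstranded <- FALSE
      pk <- rbind(pk, both)
    } else {
      pk$unstranded <- FALSE
    }
    pk$unit <- pk$dataset
    pk$kind <- "dataset"
    pk$mirna <- NA_character_
    parts[[length(parts) + 1L]] <-
      pk[c("seqid", "start", "end", "strand", "unit", "kind", "dataset",
           "cell_line", "mirna", "unstranded")]
  }
  if (!is.null(interactions) && nrow(interactions)) {
    ch <- as.data.frame(interactions)
    ch$unit <- paste(ch$dataset, ch$chimera, sep = ":")
    ch$kind <- "chimera"
    ch$unstranded <- FALSE
    parts[[length(parts) + 1L]] <-
      ch[c("seqid", "start", "end", "strand", "unit", "kind", "dataset",
           "cell_line", "mirna", "unstranded")]
  }
  if (!length(parts)) {
    units <- GenomicRanges::GRanges()
    return(structure(list(units = units), class = "support_profile"))
  }
  df <- do.call(rbind, parts)
  validate_intervals(df, "evidence interval")
  gr <- .df_to_gr(df)
  # union intervals within each unit so a unit counts once per position
  key <- paste(df$unit, df$kind, sep = "\r")
  red <- lapply(split(seq_along(gr), key), function(ix) {
    r <- GenomicRanges::reduce(gr[ix])
    mc <- S4Vectors::mcols(gr)[ix[1L], , drop = FALSE]
    mirnas <- unique(df$mirna[ix])
    mc$mirna <- if (all(is.na(mirnas))) NA_character_ else
      paste(stats::na.omit(mirnas), collapse = ",")
    S4Vectors::mcols(r) <- mc[rep(1L, length(r)), , drop = FALSE]
    r
  })
  units <- sort(do.call(c, unname(red)))
  structure(list(units = units), class = "support_profile")
}

#' @export
print.support_profile <- function(x, ...) {
  u <- S4Vectors::mcols(x$units)$unit
  cat("support_profile:", length(unique(u)), "evidence unit(s),",
      length(x$units), "unioned interval(s)\n")
  invisible(x)
}

# per-(seqid, strand) coverage RleLists of a profile
.profile_coverage <- function(profile, strand) {
  gr <- profile$units[as.character(GenomicRanges::strand(profile$units)) == strand]
  GenomicRanges::coverage(gr)
}

#' Extract consensus miRNA-binding regions from an evidence profile
#'
#' A region is a maximal run of consecutive positions each supported by at
#' least `n` evidence units, kept when the run is at least `L` nt long
#' (defaults L = 10, n = 2: every base confirmed by two independent
#' datasets or two chimeric reads). Runs are maximal: the positions
#' immediately flanking a reported region have support below `n`.
#'
#' With `mode = "merged"` each qualifying run is expanded to the merged
#' evidence footprint containing it (the union of covered positions around
#' the run), an alternative reading of a consensus region as "the merged
#' region containing a qualifying subsequence".
#'
#' @param profile a [build_support_profile()] result.
#' @param L minimum run length in nt.
#' @param n minimum per-position evidence count.
#' @param mode `"run"` (default, trimmed maximal run) or `"merged"`.
#' @return data frame of class `exp_mibr`: `region_id, seqid, start, end,
#'   strand, length, min_support, max_support`.
#' @export
extract_regions <- function(profile, L = 10L, n = 2L, mode = c("run", "merged")) {
  mode <- match.arg(mode)
  stopifnot(L >= 1L, n >= 1L)
  out <- list()
  for (s in c("+", "-")) {
    cov <- .profile_coverage(profile, s)
    if (!length(cov)) next
    sl <- IRanges::slice(cov, lower = n, rangesOnly = FALSE)
    for (sq in names(sl)) {
      v <- sl[[sq]]
      if (!length(v)) next
      w <- IRanges::width(v)
      keep <- w >= L
      if (!any(keep)) next
      st <- IRanges::start(v)[keep] - 1L
      en <- IRanges::end(v)[keep]
      mn <- as.integer(IRanges::viewMins(v)[keep])
      mx <- as.integer(IRanges::viewMaxs(v)[keep])
      if (mode == "merged") {
        foot <- IRanges::slice(cov[[sq]], lower = 1L, rangesOnly = TRUE)
        run_ir <- IRanges::IRanges(st + 1L, en)
        hit <- IRanges::findOverlaps(run_ir, foot, select = "first")
        # one merged region per footprint; support stats aggregated over
        # its qualifying runs
        mn <- as.integer(tapply(mn, hit, min)[as.character(unique(hit))])
        mx <- as.integer(tapply(mx, hit, max)[as.character(unique(hit))])
        st <- IRanges::start(foot)[unique(hit)] - 1L
        en <- IRanges::end(foot)[unique(hit)]
      }
      out[[length(out) + 1L]] <- data.frame(
        seqid = sq, start = st, end = en, strand = s,
        length = en - st, min_support = mn, max_support = mx,
        stringsAsFactors = FALSE)
    }
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(seqid = character(), start = integer(), end = integer(),
               strand = character(), length = integer(),
               min_support = integer(), max_support = integer(),
               stringsAsFactors = FALSE)
  res <- res[order(res$seqid, res$start, res$strand), , drop = FALSE]
  res <- cbind(region_id = if (nrow(res)) sprintf("MiBR%05d", seq_len(nrow(res)))
               else character(), res)
  rownames(res) <- NULL
  class(res) <- c("exp_mibr", "data.frame")
  res
}

#' Region counts over a grid of (L, n) stringency parameters
#'
#' Counts, for every combination in the two ranges (defaults L = 1..25,
#' n = 1..10), the merged evidence regions containing a subsequence of
#' length >= `L` whose every position is supported by >= `n` units — i.e.
#' `|extract_regions(profile, L, n, mode = "merged")|`. Counting merged
#' regions (rather than trimmed runs, which can split as `n` rises) makes
#' the grid non-increasing in `n` at fixed `L` and non-increasing in `L` at
#' fixed `n`.
#'
#' @param profile a [build_support_profile()] result.
#' @param L_range,n_range integer vectors of parameter values.
#' @return integer matrix with rows `L` and columns `n` (dimnames set).
#' @export
parameter_grid <- function(profile, L_range = 1:25, n_range = 1:10) {
  stopifnot(length(L_range) > 0L, length(n_range) > 0L)
  m <- matrix(0L, length(L_range), length(n_range),
              dimnames = list(L = L_range, n = n_range))
  for (j in seq_along(n_range)) {
    # per merged footprint, the longest run at support >= n
    best <- integer(0)
    for (s in c("+", "-")) {
      cov <- .profile_coverage(profile, s)
      if (!length(cov)) next
      for (sq in names(cov)) {
        runs <- IRanges::slice(cov[[sq]], lower = n_range[j], rangesOnly = TRUE)
        if (!length(runs)) next
        foot <- IRanges::slice(cov[[sq]], lower = 1L, rangesOnly = TRUE)
        hit <- IRanges::findOverlaps(runs, foot, select = "first")
        best <- c(best, as.integer(tapply(IRanges::width(runs), hit, max)))
      }
    }
    for (i in seq_along(L_range)) m[i, j] <- sum(best >= L_range[i])
  }
  m
}

#' Attach annotation and evidence metadata to consensus regions
#'
#' Each region gains its gene and mRNA-part annotation (precedence rules of
#' [annotate_interval()]), the list of supporting dataset ids and cell
#' lines, and the deduplicated list of interacting miRNAs contributed by
#' overlapping chimeras (empty when only non-chimeric peaks support the
#' region).
#'
#' @param regions [extract_regions()] output.
#' @param model a [gene_model] (or `NULL` to skip annotation).
#' @param profile the [build_support_profile()] the regions came from.
#' @return the region table with columns `gene_id, gene_name, part,
#'   n_datasets, datasets, cell_lines, mirnas` added (list columns
#'   serialized as comma-joined strings).
#' @export
characterize_regions <- function(regions, model, profile) {
  df <- as.data.frame(regions)
  if (!nrow(df)) {
    df[c("gene_id", "gene_name", "part", "n_datasets", "datasets",
         "cell_lines", "mirnas")] <-
      list(character(), character(), character(), integer(), character(),
           character(), character())
    return(df)
  }
  if (!is.null(model)) {
    ann <- annotate_interval(df[c("seqid", "start", "end", "strand")], model)
    df$gene_id <- ann$gene_id
    df$gene_name <- ann$gene_name
    df$part <- ann$part
  } else {
    df$gene_id <- NA_character_; df$gene_name <- NA_character_
    df$part <- NA_character_
  }
  gr <- .df_to_gr(df[c("seqid", "start", "end", "strand")])
  units <- profile$units
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(gr, units, ignore.strand = FALSE))
  mc <- S4Vectors::mcols(units)
  ds <- ch_mir <- cl <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    u <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    ds[[i]] <- sort(unique(mc$dataset[u]))
    cl[[i]] <- sort(unique(mc$cell_line[u]))
    mir <- mc$mirna[u][mc$kind[u] == "chimera"]
    mir <- unlist(strsplit(mir[!is.na(mir)], ",", fixed = TRUE))
    ch_mir[[i]] <- if (is.null(mir)) character(0) else sort(unique(mir))
  }
  df$n_datasets <- lengths(ds)
  df$datasets <- vapply(ds, paste, character(1), collapse = ",")
  df$cell_lines <- vapply(cl, paste, character(1), collapse = ",")
  df$mirnas <- vapply(ch_mir, paste, character(1), collapse = ",")
  df
}

#' Tissue specificity of consensus regions
#'
#' Splits regions by the cell lines their evidence comes from: exclusive
#' (one cell line), shared, and ubiquitous (at least `k` cell lines,
#' default 7).
#'
#' @param regions characterized region table (needs a `cell_lines`
#'   comma-joined column).
#' @param k ubiquity threshold in cell lines.
#' @param groups optional named list mapping group labels to cell-line
#'   vectors (e.g. `list(HEK293 = "HEK293", other = c("HeLa", ...))`); when
#'   given, per-group exclusive/shared counts are reported for that
#'   partition instead of per single cell line.
#' @return list with `per_region` (`region_id`, `n_cell_lines`,
#'   `ubiquitous`), `per_class` (class label, `n_exclusive`), `n_shared`,
#'   `n_ubiquitous`.
#' @export
tissue_summary <- function(regions, k = 7L, groups = NULL) {
  df <- as.data.frame(regions)
  if (!nrow(df)) {
    return(list(per_region = data.frame(region_id = character(),
                                        n_cell_lines = integer(),
                                        ubiquitous = logical()),
                per_class = data.frame(class = character(),
                                       n_exclusive = integer()),
                n_shared = 0L, n_ubiquitous = 0L))
  }
  cls <- strsplit(df$cell_lines, ",", fixed = TRUE)
  if (!is.null(groups)) {
    cls <- lapply(cls, function(x) {
      g <- vapply(x, function(cl) {
        hit <- names(groups)[vapply(groups, function(v) cl %in% v, logical(1))]
        if (length(hit)) hit[1L] else "other"
      }, character(1))
      unique(g)
    })
  }
  n_cl <- lengths(lapply(strsplit(df$cell_lines, ",", fixed = TRUE), unique))
  per_region <- data.frame(region_id = df$region_id, n_cell_lines = n_cl,
                           ubiquitous = n_cl >= k, stringsAsFactors = FALSE)
  exclusive <- lengths(cls) == 1L
  tab <- table(unlist(cls[exclusive]))
  per_class <- data.frame(class = names(tab), n_exclusive = as.integer(tab),
                          stringsAsFactors = FALSE, row.names = NULL)
  list(per_region = per_region, per_class = per_class,
       n_shared = sum(!exclusive), n_ubiquitous = sum(per_region$ubiquitous))
}

#' Fraction of a sequence covered by consensus regions
#'
#' Computes the covered fraction of one sequence (union of region positions
#' on either strand over the sequence length) and how many of the
#' sequence's genes are touched by at least one exonic overlap — the
#' summary used for dense targets such as the mitochondrial genome.
#'
#' @param regions region table.
#' @param seqid sequence to summarize.
#' @param seq_length its length in nt.
#' @param model optional [gene_model] for the gene tally.
#' @return list `fraction_covered`, `n_genes_touched`, `n_genes_total`.
#' @export
sequence_coverage <- function(regions, seqid, seq_length, model = NULL) {
  df <- as.data.frame(regions)
  df <- df[df$seqid == seqid, , drop = FALSE]
  frac <- .union_width(df$start, df$end) / seq_length
  n_touched <- NA_integer_; n_total <- NA_integer_
  if (!is.null(model)) {
    if (!seqid %in% model$genes$seqid) stop("seqid ", seqid, " not in gene model")
    g_here <- model$genes$gene_id[model$genes$seqid == seqid]
    n_total <- length(g_here)
    if (nrow(df)) {
      ex <- model$exons[model$exons$gene_id %in% g_here, , drop = FALSE]
      ex_gr <- .df_to_gr(ex)
      r_gr <- .df_to_gr(df[c("seqid", "start", "end", "strand")])
      hit <- GenomicRanges::findOverlaps(ex_gr, r_gr, ignore.strand = TRUE)
      n_touched <- length(unique(ex$gene_id[S4Vectors::queryHits(hit)]))
    } else n_touched <- 0L
  }
  list(fraction_covered = frac, n_genes_touched = n_touched,
       n_genes_total = n_total)
}

#' Write a characterized region table
#'
#' Writes the TSV region catalogue and, optionally, a BED6 companion.
#'
#' @param regions characterized region table.
#' @param path output TSV path.
#' @param bed_path optional BED6 output path (`name` = region id,
#'   `score` = `n_datasets`).
#' @export
write_mibr_table <- function(regions, path, bed_path = NULL) {
  utils::write.table(as.data.frame(regions), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(bed_path)) {
    df <- as.data.frame(regions)
    write_bed(data.frame(seqid = df$seqid, start = df$start, end = df$end,
                         name = df$region_id,
                         score = if (!is.null(df$n_datasets)) df$n_datasets else 0L,
                         strand = df$strand), bed_path)
  }
  invisible(path)
}

#' Read a region table written by [write_mibr_table()]
#' @param path TSV path.
#' @return region data frame.
#' @export
read_mibr_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_intervals(df, "Exp-MiBR region")
  df
}
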