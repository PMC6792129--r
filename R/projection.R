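#' Project a transcript-space interval to genome coordinates
#'
#' Chimera-derived interaction records aligned to the mature transcriptome
#' carry transcript coordinates; comparison with genome-space data requires
#' projecting them through the transcript's exon structure. Position 0 of a
#' transcript is its 5' end: the leftmost base of the exon union on the plus
#' strand and the rightmost base on the minus strand. An interval that spans
#' one or more splice junctions yields one genomic block per touched exon.
#'
#' @param start,end transcript-space interval, 0-based half-open.
#' @param exons data frame of the transcript's exons (`seqid`, `start`,
#'   `end`, `strand`), sorted by genomic start, one seqid/strand.
#' @param transcript_id label used in error messages.
#' @return data frame of genomic blocks (`seqid`, `start`, `end`, `strand`),
#'   sorted by genomic start; block widths sum to `end - start`.
#' @examples
#' ex <- data.frame(seqid = "chr1", start = 1000L, end = 1100L, strand = "+")
#' project_to_genome(10, 20, ex) # [1010, 1020)
#' @seealso [project_to_transcript()] for the inverse.
#' @export
project_to_genome <- function(start, end, exons, transcript_id = "<tx>") {
  start <- as.integer(start); end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 0L || start >= end) {
    stop("invalid transcript interval [", start, ", ", end, ")")
  }
  exons <- exons[order(exons$start), , drop = FALSE]
  widths <- exons$end - exons$start
  txlen <- sum(widths)
  if (end > txlen) {
    stop("interval [", start, ", ", end, ") exceeds length ", txlen,
         " of transcript ", transcript_id)
  }
  minus <- exons$strand[1L] == "-"
  ord <- if (minus) rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  offs <- c(0L, cumsum(widths[ord]))[seq_along(ord)]

  out <- vector("list", length(ord))
  for (i in seq_along(ord)) {
    j <- ord[i]
    s <- max(start, offs[i])
    t <- min(end, offs[i] + widths[j])
    if (s >= t) next
    if (minus) {
      gs <- exons$end[j] - (t - offs[i])
      ge <- exons$end[j] - (s - offs[i])
    } else {
      gs <- exons$start[j] + (s - offs[i])
      ge <- exons$start[j] + (t - offs[i])
    }
    out[[i]] <- data.frame(seqid = exons$seqid[j], start = gs, end = ge,
                           strand = exons$strand[j], stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Project genomic blocks back to transcript coordinates
#'
#' Inverse of [project_to_genome()]: maps a set of genomic blocks lying
#' within a transcript's exons to the single contiguous transcript-space
#' interval they cover. Used for round-trip validation and for building
#' per-transcript interaction profiles.
#'
#' @param blocks data frame of genomic blocks (`seqid`, `start`, `end`,
#'   `strand`); every block must lie wholly inside one exon.
#' @param exons the transcript's exons as in [project_to_genome()].
#' @param transcript_id label used in error messages.
#' @return named numeric vector `c(start =, end =)` in transcript
#'   coordinates, 0-based half-open.
#' @export
project_to_transcript <- function(blocks, exons, transcript_id = "<tx>") {
  if (is.null(blocks) || !nrow(blocks)) stop("no blocks to project for ", transcript_id)
  exons <- exons[order(exons$start), , drop = FALSE]
  widths <- exons$end - exons$start
  minus <- exons$strand[1L] == "-"
  ord <- if (minus) rev(seq_len(nrow(exons))) else seq_len(nrow(exons))
  offs <- integer(nrow(exons)) # transcript offset of each exon (genomic order index)
  offs[ord] <- c(0L, cumsum(widths[ord]))[seq_along(ord)]

  ivs <- matrix(NA_integer_, nrow(blocks), 2L)
  for (b in seq_len(nrow(blocks))) {
    j <- which(exons$seqid == blocks$seqid[b] &
               exons$start <= blocks$start[b] & blocks$end[b] <= exons$end)
    if (!length(j)) {
      stop("block [", blocks$start[b], ", ", blocks$end[b],
           ") does not lie within a single exon of ", transcript_id)
    }
    j <- j[1L]
    if (minus) {
      ts <- offs[j] + (exons$end[j] - blocks$end[b])
      te <- offs[j] + (exons$end[j] - blocks$start[b])
    } else {
      ts <- offs[j] + (blocks$start[b] - exons$start[j])
      te <- offs[j] + (blocks$end[b] - exons$start[j])
    }
    ivs[b, ] <- c(ts, te)
  }
  ivs <- ivs[order(ivs[, 1L]), , drop = FALSE]
  if (nrow(ivs) > 1L && any(ivs[-1L, 1L] != ivs[-nrow(ivs), 2L])) {
    stop("blocks are not contiguous in transcript space for ", transcript_id)
  }
  c(start = ivs[1L, 1L], end = ivs[nrow(ivs), 2L])
}

#' Batch-project transcript-space interaction records to genome space
#'
#' Applies [project_to_genome()] to every record of a transcript-space
#' interaction table (see [read_interactions()]) and reports bookkeeping:
#' records whose interval exceeds the transcript length (or whose transcript
#' is absent from the model) are dropped and counted, mirroring the way
#' transcript-to-genome conversion failures reduce a dataset's retained
#' interaction count.
#'
#' @param interactions transcript-space interaction table; the `seqid`
#'   column holds transcript ids.
#' @param model a [gene_model].
#' @return list with `interactions` (genome-space table, one row per block,
#'   blocks of one chimera sharing its `chimera` id), `n_input` /
#'   `n_failed` / `n_retained` record counts, and `failed` (record keys).
#' @export
project_interactions <- function(interactions, model) {
  key <- paste(interactions$dataset, interactions$chimera, sep = "\r")
  n_input <- length(unique(key))
  tx <- model$transcripts
  known <- interactions$seqid %in% tx$transcript_id
  lens <- rep(NA_integer_, nrow(interactions))
  lens[known] <- tx[interactions$seqid[known], "length"]
  bad_row <- !known | interactions$end > lens
  failed_keys <- unique(key[bad_row])

  keep <- !(key %in% failed_keys)
  ints <- interactions[keep, , drop = FALSE]
  out <- vector("list", nrow(ints))
  if (nrow(ints)) {
    # fast path: rows fitting inside a single-exon transcript are pure offsets
    n_ex <- table(model$exons$transcript_id)
    single <- ints$seqid %in% names(n_ex)[n_ex == 1L]
    if (any(single)) {
      ex1 <- model$exons[model$exons$transcript_id %in% ints$seqid[single], ]
      rownames(ex1) <- ex1$transcript_id
      e <- ex1[ints$seqid[single], ]
      minus <- e$strand == "-"
      gs <- ifelse(minus, e$end - ints$end[single], e$start + ints$start[single])
      ge <- ifelse(minus, e$end - ints$start[single], e$start + ints$end[single])
      proj1 <- data.frame(seqid = e$seqid, start = gs, end = ge, strand = e$strand,
                          stringsAsFactors = FALSE)
      idx1 <- which(single)
      for (k in seq_along(idx1)) out[[idx1[k]]] <- proj1[k, , drop = FALSE]
    }
    for (i in which(!single)) {
      out[[i]] <- project_to_genome(ints$start[i], ints$end[i],
                                    .tx_exons(model, ints$seqid[i]), ints$seqid[i])
    }
  }
  nb <- vapply(out, function(x) if (is.null(x)) 0L else nrow(x), integer(1))
  meta <- ints[rep(seq_len(nrow(ints)), nb),
               setdiff(names(ints), c("seqid", "start", "end", "strand")),
               drop = FALSE]
  res <- cbind(do.call(rbind, out), meta)
  rownames(res) <- NULL
  list(interactions = res,
       n_input = n_input,
       n_failed = length(failed_keys),
       n_retained = n_input - length(failed_keys),
       failed = sub("\r", ":", failed_keys))
}
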