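#' Annotate a genomic interval against gene models
#'
#' Assigns every interval exactly one part label with the fixed precedence
#' `CDS > UTR3 > UTR5 > ncRNA_exonic > intronic > intergenic`: an interval
#' overlapping several parts (e.g. spanning a CDS/3'UTR junction) takes the
#' highest-precedence one, and when several transcripts overlap the interval
#' the transcript yielding the highest-precedence part wins. The result is
#' total and deterministic; intervals with no gene overlap are `intergenic`
#' with gene `NA`.
#'
#' Strand handling: an interval with strand `+` or `-` only annotates against
#' transcripts on that strand; strand `.` matches both.
#'
#' @param intervals data frame of 0-based half-open intervals (`seqid`,
#'   `start`, `end`, `strand`).
#' @param model a [gene_model].
#' @param precedence character vector ordering the part labels, highest
#'   first. The default is the package's fixed order.
#' @return data frame with one row per input interval: `gene_id`,
#'   `gene_name`, `part`.
#' @examples
#' gm <- gene_model(data.frame(
#'   gene_id = "g1", gene_name = "G1", biotype = "coding",
#'   transcript_id = "g1.t1", feature = c("exon", "CDS"),
#'   seqid = "chr1", start = c(0L, 100L), end = c(1000L, 700L), strand = "+"
#' ))
#' annotate_interval(data.frame(seqid = "chr1", start = 650, end = 720,
#'                              strand = "+"), gm)$part # "CDS"
#' @export
annotate_interval <- function(intervals, model,
                              precedence = c("CDS", "UTR3", "UTR5",
                                             "ncRNA_exonic", "intronic",
                                             "intergenic")) {
  validate_intervals(intervals, "query interval")
  n <- nrow(intervals)
  out <- data.frame(gene_id = rep(NA_character_, n),
                    gene_name = rep(NA_character_, n),
                    part = rep("intergenic", n),
                    stringsAsFactors = FALSE)
  if (!n) return(out)

  rank <- stats::setNames(seq_along(precedence), precedence)
  tx <- model$transcripts
  # transcript genomic spans for intron detection
  span <- do.call(rbind, lapply(seq_len(nrow(tx)), function(i) {
    ex <- model$exons[model$exons$transcript_id == tx$transcript_id[i], ]
    data.frame(transcript_id = tx$transcript_id[i], seqid = tx$seqid[i],
               start = min(ex$start), end = max(ex$end), strand = tx$strand[i],
               stringsAsFactors = FALSE)
  }))
  span_gr <- .df_to_gr(span)
  q_gr <- .df_to_gr(intervals)
  # disjoint seqid sets are a legitimate no-overlap case, not a warning
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(q_gr, span_gr, ignore.strand = FALSE))

  for (i in seq_len(n)) {
    tx_idx <- S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]
    if (!length(tx_idx)) next
    best_rank <- rank["intergenic"]; best_gene <- NA_character_
    for (j in tx_idx) {
      txid <- span$transcript_id[j]
      part <- .part_for_tx(intervals$start[i], intervals$end[i], model, txid)
      if (rank[part] < best_rank) {
        best_rank <- rank[part]
        best_gene <- tx[txid, "gene_id"]
      }
    }
    if (!is.na(best_gene)) {
      out$gene_id[i] <- best_gene
      out$gene_name[i] <- model$genes[best_gene, "gene_name"]
      out$part[i] <- names(rank)[best_rank]
    }
  }
  out
}

# highest-precedence part of [start,end) within one transcript
.part_for_tx <- function(start, end, model, txid) {
  ex <- model$exons[model$exons$transcript_id == txid, , drop = FALSE]
  ov <- ex$start < end & start < ex$end
  if (!any(ov)) return("intronic")
  info <- model$transcripts[txid, ]
  coding <- model$genes[info$gene_id, "biotype"] == "coding" && !is.na(info$cds_start)
  if (!coding) return("ncRNA_exonic")
  cs <- info$cds_start; ce <- info$cds_end
  # exonic sub-segments of the query, classified against the CDS genomic span
  segs <- cbind(pmax(start, ex$start[ov]), pmin(end, ex$end[ov]))
  in_cds <- any(segs[, 1L] < ce & cs < segs[, 2L])
  if (in_cds) return("CDS")
  right <- any(segs[, 2L] > ce) # exonic sequence genomically right of the CDS
  left <- any(segs[, 1L] < cs)
  if (info$strand == "+") {
    if (right) return("UTR3")
    if (left) return("UTR5")
  } else {
    if (left) return("UTR3")
    if (right) return("UTR5")
  }
  "intronic" # unreachable for well-formed models; defensive
}
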