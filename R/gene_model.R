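#' Gene models from a GTF-lite table
#'
#' The package consumes a flat, tab-separated gene model ("GTF-lite") with one
#' row per exon or CDS feature and columns
#' `gene_id, gene_name, biotype, transcript_id, feature, seqid, start, end,
#' strand`, coordinates 0-based half-open. `biotype` is `coding` or
#' `noncoding`; `feature` is `exon` or `CDS`. A `gene_model` object indexes
#' this table for coordinate projection and annotation.
#'
#' @section Invariants:
#' Exons of one transcript are non-overlapping, sorted, and share seqid and
#' strand; a transcript's CDS span lies within its exon union. Both are
#' checked at construction time.
#'
#' @param features data frame in GTF-lite layout (see above).
#' @return an object of class `gene_model` with components
#'   `genes` (one row per gene), `transcripts` (one row per transcript, with
#'   the transcript length and optional CDS span), and `exons` (exon rows,
#'   sorted by transcript and genomic start).
#' @examples
#' gm <- gene_model(data.frame(
#'   gene_id = "g1", gene_name = "G1", biotype = "coding",
#'   transcript_id = "g1.t1", feature = c("exon", "CDS"),
#'   seqid = "chr1", start = c(100L, 130L), end = c(400L, 370L), strand = "+"
#' ))
#' transcript_length(gm, "g1.t1")
#' @export
gene_model <- function(features) {
  req <- c("gene_id", "gene_name", "biotype", "transcript_id", "feature",
           "seqid", "start", "end", "strand")
  miss <- setdiff(req, names(features))
  if (length(miss)) stop("gene model lacks column(s): ", paste(miss, collapse = ", "))
  features$start <- as.integer(features$start)
  features$end <- as.integer(features$end)
  validate_intervals(features, "gene model feature")
  if (!all(features$feature %in% c("exon", "CDS"))) {
    stop("gene model feature column must be 'exon' or 'CDS'")
  }

  exons <- features[features$feature == "exon", , drop = FALSE]
  cds <- features[features$feature == "CDS", , drop = FALSE]
  if (!nrow(exons)) stop("gene model contains no exon rows")
  exons <- exons[order(exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL

  # per-transcript invariant checks
  for (tx in unique(exons$transcript_id)) {
    ex <- exons[exons$transcript_id == tx, , drop = FALSE]
    if (length(unique(ex$seqid)) != 1L || length(unique(ex$strand)) != 1L) {
      stop("transcript ", tx, ": exons span multiple seqids or strands")
    }
    if (nrow(ex) > 1L && any(ex$start[-1L] < ex$end[-nrow(ex)])) {
      stop("transcript ", tx, ": overlapping exons")
    }
  }

  tx_ids <- unique(exons$transcript_id)
  tx_len <- vapply(tx_ids, function(tx) {
    ex <- exons[exons$transcript_id == tx, ]
    sum(ex$end - ex$start)
  }, integer(1))
  first <- exons[!duplicated(exons$transcript_id), ]
  rownames(first) <- first$transcript_id
  transcripts <- data.frame(
    transcript_id = tx_ids,
    gene_id = first[tx_ids, "gene_id"],
    seqid = first[tx_ids, "seqid"],
    strand = first[tx_ids, "strand"],
    length = tx_len,
    cds_start = NA_integer_,
    cds_end = NA_integer_,
    stringsAsFactors = FALSE
  )
  rownames(transcripts) <- transcripts$transcript_id
  if (nrow(cds)) {
    for (tx in unique(cds$transcript_id)) {
      if (!tx %in% tx_ids) stop("CDS row for unknown transcript ", tx)
      cs <- min(cds$start[cds$transcript_id == tx])
      ce <- max(cds$end[cds$transcript_id == tx])
      ex <- exons[exons$transcript_id == tx, ]
      ok <- any(ex$start <= cs & cs < ex$end) && any(ex$start < ce & ce <= ex$end)
      if (!ok) stop("transcript ", tx, ": CDS span outside exon union")
      transcripts[tx, "cds_start"] <- cs
      transcripts[tx, "cds_end"] <- ce
    }
  }

  gfirst <- features[!duplicated(features$gene_id), ]
  genes <- data.frame(
    gene_id = gfirst$gene_id, gene_name = gfirst$gene_name,
    biotype = gfirst$biotype, seqid = gfirst$seqid, strand = gfirst$strand,
    stringsAsFactors = FALSE
  )
  rownames(genes) <- genes$gene_id

  structure(
    list(genes = genes, transcripts = transcripts,
         exons = exons[c("transcript_id", "gene_id", "seqid", "start", "end", "strand")]),
    class = "gene_model"
  )
}

#' @export
print.gene_model <- function(x, ...) {
  cat("gene_model:", nrow(x$genes), "genes,", nrow(x$transcripts),
      "transcripts,", nrow(x$exons), "exons\n")
  invisible(x)
}

#' Read / write a GTF-lite gene model
#'
#' @param path path to a tab-separated GTF-lite file with a header row.
#' @return `read_gene_model`: a [gene_model]. `write_gene_model`: the path,
#'   invisibly.
#' @export
read_gene_model <- function(path) {
  gene_model(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' @param model a [gene_model].
#' @rdname read_gene_model
#' @export
write_gene_model <- function(model, path) {
  ex <- model$exons
  g <- model$genes[ex$gene_id, ]
  rows <- data.frame(
    gene_id = ex$gene_id, gene_name = g$gene_name, biotype = g$biotype,
    transcript_id = ex$transcript_id, feature = "exon",
    seqid = ex$seqid, start = ex$start, end = ex$end, strand = ex$strand,
    stringsAsFactors = FALSE
  )
  tx <- model$transcripts[!is.na(model$transcripts$cds_start), , drop = FALSE]
  if (nrow(tx)) {
    g2 <- model$genes[tx$gene_id, ]
    rows <- rbind(rows, data.frame(
      gene_id = tx$gene_id, gene_name = g2$gene_name, biotype = g2$biotype,
      transcript_id = tx$transcript_id, feature = "CDS",
      seqid = tx$seqid, start = tx$cds_start, end = tx$cds_end,
      strand = tx$strand, stringsAsFactors = FALSE
    ))
  }
  rows <- rows[order(rows$gene_id, rows$transcript_id, rows$feature, rows$start), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Transcript length (sum of exon widths)
#'
#' @param model a [gene_model].
#' @param transcript_id transcript identifier(s).
#' @return integer vector of lengths in nt.
#' @export
transcript_length <- function(model, transcript_id) {
  unknown <- setdiff(transcript_id, model$transcripts$transcript_id)
  if (length(unknown)) stop("unknown transcript(s): ", paste(unknown, collapse = ", "))
  model$transcripts[transcript_id, "length"]
}

# exon rows of one transcript, sorted by genomic start
.tx_exons <- function(model, transcript_id) {
  ex <- model$exons[model$exons$transcript_id == transcript_id, , drop = FALSE]
  if (!nrow(ex)) stop("unknown transcript: ", transcript_id)
  ex[order(ex$start), , drop = FALSE]
}
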