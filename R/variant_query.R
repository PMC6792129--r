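# Desk-side equivalent of the region-lookup web tool: intersect a VCF or a
# single genome coordinate with the consensus region table.

#' Query a single genome position against a region table
#'
#' @param seqid sequence name.
#' @param position_1based 1-based position (as a user or a VCF would state
#'   it); internally position - 1 is tested against each region's 0-based
#'   half-open interval.
#' @param mibr_table region table (from [extract_regions()] /
#'   [characterize_regions()] or [read_mibr_table()]).
#' @return data frame of hits: matched region rows plus `offset` (0-based
#'   offset of the position within the region). Zero rows when nothing
#'   overlaps.
#' @examples
#' tab <- data.frame(region_id = "r1", seqid = "chr1", start = 100L,
#'                   end = 120L, strand = "+")
#' nrow(query_point("chr1", 101, tab)) # first base -> 1 hit
#' nrow(query_point("chr1", 121, tab)) # end is exclusive -> 0 hits
#' @export
query_point <- function(seqid, position_1based, mibr_table) {
  pos <- suppressWarnings(as.integer(position_1based))
  if (is.na(pos) || pos < 1L) {
    stop("malformed coordinate '", position_1based,
         "'; expected a 1-based position, e.g. query_point(\"chr2\", 216499, table)")
  }
  p0 <- pos - 1L
  hit <- mibr_table$seqid == seqid & mibr_table$start <= p0 & p0 < mibr_table$end
  out <- as.data.frame(mibr_table)[hit, , drop = FALSE]
  out$offset <- p0 - out$start
  rownames(out) <- NULL
  out
}

# INFO keys added by annotate_vcf
.mibr_info_keys <- c("MIBR", "MIBR_GENE", "MIBR_PART", "MIBR_NDS", "MIBR_MIR")

.mibr_info_header <- function() {
  c('##INFO=<ID=MIBR,Number=.,Type=String,Description="Overlapping consensus miRNA-binding region id(s)">',
    '##INFO=<ID=MIBR_GENE,Number=.,Type=String,Description="Gene of each overlapping region">',
    '##INFO=<ID=MIBR_PART,Number=.,Type=String,Description="mRNA part of each overlapping region">',
    '##INFO=<ID=MIBR_NDS,Number=.,Type=String,Description="Supporting dataset count of each overlapping region">',
    '##INFO=<ID=MIBR_MIR,Number=.,Type=String,Description="Interacting miRNAs of each overlapping region (| separated)">')
}

#' Annotate a VCF against the consensus region table
#'
#' Each variant overlapping a region gains INFO fields `MIBR` (region ids),
#' `MIBR_GENE`, `MIBR_PART`, `MIBR_NDS` (dataset counts) and `MIBR_MIR`
#' (miRNA lists, `|`-separated within a region); values for several
#' overlapping regions are comma-joined in matching order. Variants outside
#' every region pass through untouched, record order is preserved, and
#' removing the added INFO fields restores the input body byte-for-byte.
#'
#' By default indels are matched by their anchor position only
#' (`span_aware = FALSE`); with `span_aware = TRUE` the REF span
#' `[POS-1, POS-1+nchar(REF))` is intersected instead.
#'
#' @param vcf_path input VCF (v4.0/4.1) path.
#' @param mibr_table region table.
#' @param out_path optional path for the annotated VCF.
#' @param size_limit passed to [read_vcf()] (default 20 MB).
#' @param span_aware match the full REF span instead of the anchor base.
#' @return list with `lines` (annotated VCF lines), `hits` (data frame
#'   variant row index, position, matched region id), `n_annotated`.
#' @export
annotate_vcf <- function(vcf_path, mibr_table, out_path = NULL,
                         size_limit = 20 * 1024^2, span_aware = FALSE) {
  vcf <- read_vcf(vcf_path, size_limit = size_limit)
  body <- vcf$body
  lines <- vcf$lines
  hits_list <- list()
  n_annotated <- 0L
  for (i in seq_len(nrow(body))) {
    if (span_aware) {
      s0 <- body$start[i]; e0 <- body$start[i] + nchar(body$ref[i])
      hit <- mibr_table$seqid == body$seqid[i] &
        mibr_table$start < e0 & s0 < mibr_table$end
      regions <- as.data.frame(mibr_table)[hit, , drop = FALSE]
    } else {
      regions <- query_point(body$seqid[i], body$pos[i], mibr_table)
    }
    if (!nrow(regions)) next
    n_annotated <- n_annotated + 1L
    hits_list[[length(hits_list) + 1L]] <-
      data.frame(row = i, seqid = body$seqid[i], pos = body$pos[i],
                 region_id = regions$region_id, stringsAsFactors = FALSE)
    gv <- function(col, default) {
      if (!is.null(regions[[col]])) {
        v <- as.character(regions[[col]])
        v[is.na(v) | !nzchar(v)] <- default
        v
      } else rep(default, nrow(regions))
    }
    add <- paste0(
      "MIBR=", paste(regions$region_id, collapse = ","),
      ";MIBR_GENE=", paste(gv("gene_name", "NA"), collapse = ","),
      ";MIBR_PART=", paste(gv("part", "NA"), collapse = ","),
      ";MIBR_NDS=", paste(gv("n_datasets", "0"), collapse = ","),
      ";MIBR_MIR=", paste(gsub(",", "|", gv("mirnas", "NA"), fixed = TRUE),
                          collapse = ",")
    )
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    fields[8L] <- if (fields[8L] == ".") add else paste0(fields[8L], ";", add)
    lines[i] <- paste(fields, collapse = "\t")
  }
  header <- vcf$header
  chrom_ix <- grep("^#CHROM", header)
  ins <- if (length(chrom_ix)) chrom_ix[1L] else length(header) + 1L
  header <- append(header, .mibr_info_header(), after = ins - 1L)
  out_lines <- c(header, lines)
  if (!is.null(out_path)) writeLines(out_lines, out_path)
  hits <- if (length(hits_list)) do.call(rbind, hits_list) else
    data.frame(row = integer(), seqid = character(), pos = integer(),
               region_id = character(), stringsAsFactors = FALSE)
  list(lines = out_lines, hits = hits, n_annotated = n_annotated)
}

#' Strip the INFO fields added by [annotate_vcf()]
#'
#' @param lines character vector of VCF lines (header + body).
#' @return the lines with every `MIBR*` INFO entry and the added `##INFO`
#'   header lines removed; annotating and stripping reproduces the input.
#' @export
strip_mibr_info <- function(lines) {
  keep_hdr <- !(lines %in% .mibr_info_header())
  lines <- lines[keep_hdr]
  body <- !grepl("^#", lines)
  fix <- function(line) {
    fields <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 8L) return(line)
    entries <- strsplit(fields[8L], ";", fixed = TRUE)[[1L]]
    keys <- sub("=.*$", "", entries)
    entries <- entries[!keys %in% .mibr_info_keys]
    fields[8L] <- if (length(entries)) paste(entries, collapse = ";") else "."
    paste(fields, collapse = "\t")
  }
  lines[body] <- vapply(lines[body], fix, character(1), USE.NAMES = FALSE)
  lines
}
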