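# Internal coordinate conventions and small interval helpers.
#
# All coordinates inside the package are 0-based half-open [start, end) on a
# single assembly. VCF (1-based) and BED (0-based half-open) are converted at
# the I/O boundary. GRanges objects used internally for overlap/coverage work
# are 1-based closed; the two helpers below are the only place the shift
# happens.

#' Convert a 0-based half-open interval data frame to a GRanges
#'
#' @param df data frame with columns `seqid`, `start`, `end`, `strand` and
#'   optionally further metadata columns, coordinates 0-based half-open.
#' @return a [GenomicRanges::GRanges] with the extra columns as mcols.
#' @keywords internal
#' @noRd
.df_to_gr <- function(df) {
  stopifnot(all(c("seqid", "start", "end", "strand") %in% names(df)))
  gr <- GenomicRanges::GRanges(
    seqnames = as.character(df$seqid),
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand %in% c("+", "-"), df$strand, "*")
  )
  extra <- setdiff(names(df), c("seqid", "start", "end", "strand"))
  if (length(extra)) {
    S4Vectors::mcols(gr) <- S4Vectors::DataFrame(df[extra], check.names = FALSE)
  }
  gr
}

#' @keywords internal
#' @noRd
.gr_to_df <- function(gr) {
  df <- data.frame(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    strand = {
      s <- as.character(GenomicRanges::strand(gr))
      ifelse(s == "*", ".", s)
    },
    stringsAsFactors = FALSE
  )
  mc <- S4Vectors::mcols(gr)
  if (ncol(mc)) df <- cbind(df, as.data.frame(mc), row.names = NULL)
  rownames(df) <- NULL
  df
}

#' Validate a 0-based half-open interval table
#'
#' Checks the invariants every interval in the package must satisfy:
#' non-empty seqid, `0 <= start < end`, strand one of `+`, `-`, `.`.
#'
#' @param df interval data frame (`seqid`, `start`, `end`, `strand`).
#' @param what label used in error messages.
#' @return `df`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_intervals <- function(df, what = "interval") {
  if (!all(c("seqid", "start", "end", "strand") %in% names(df))) {
    stop(what, " table lacks required columns seqid/start/end/strand")
  }
  bad <- which(is.na(df$seqid) | !nzchar(as.character(df$seqid)))
  if (length(bad)) stop(what, ": empty seqid at row(s) ", paste(utils::head(bad), collapse = ", "))
  bad <- which(!(df$start >= 0 & df$start < df$end))
  if (length(bad)) stop(what, ": need 0 <= start < end at row(s) ", paste(utils::head(bad), collapse = ", "))
  bad <- which(!df$strand %in% c("+", "-", "."))
  if (length(bad)) stop(what, ": strand must be one of +, -, . at row(s) ", paste(utils::head(bad), collapse = ", "))
  invisible(df)
}

# Length of the union of a set of 0-based half-open intervals on one seqid.
.union_width <- function(start, end) {
  if (!length(start)) return(0L)
  ir <- IRanges::reduce(IRanges::IRanges(start + 1L, end))
  sum(IRanges::width(ir))
}
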