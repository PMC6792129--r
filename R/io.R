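#' Read chimera-derived interaction records
#'
#' Interactions are supplied as a tab-separated table with header columns
#' `seqid, start, end, strand, mirna, dataset, chimera, cell_line`
#' (coordinates 0-based half-open; in transcript space the `seqid` column
#' holds transcript ids). One chimeric read is one record; a chimera whose
#' target region crosses splice junctions occupies several rows sharing its
#' `chimera` id, each row one genomic block.
#'
#' Malformed rows (`start >= end`, negative `start`) are rejected
#' individually and reported with their line numbers; a missing required
#' column is a hard error.
#'
#' @param path path to the TSV file.
#' @param coordinate_space `"genome"` or `"transcript"`; stored as an
#'   attribute, coordinates are not changed.
#' @return data frame of interaction rows (class `interactions`) with
#'   attributes `coordinate_space`, `n_records` (distinct chimera count) and
#'   `rejected` (data frame `line`, `reason`).
#' @export
read_interactions <- function(path, coordinate_space = c("genome", "transcript")) {
  coordinate_space <- match.arg(coordinate_space)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  req <- c("seqid", "start", "end", "strand", "mirna", "dataset", "chimera", "cell_line")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("interactions file ", path, " lacks column(s): ",
                         paste(miss, collapse = ", "))
  df$start <- as.integer(df$start); df$end <- as.integer(df$end)
  bad <- is.na(df$start) | is.na(df$end) | df$start < 0L | df$start >= df$end
  bad_lines <- which(bad) + 1L # +1 for the header line
  rejected <- data.frame(line = bad_lines,
                         reason = rep("start >= end or negative coordinate",
                                      length(bad_lines)),
                         stringsAsFactors = FALSE)
  if (nrow(rejected)) {
    message("read_interactions: rejected ", nrow(rejected), " row(s) at line(s) ",
            paste(utils::head(rejected$line, 10L), collapse = ", "))
  }
  df <- df[!bad, , drop = FALSE]
  df <- df[order(df$dataset, df$chimera, df$seqid, df$start), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            coordinate_space = coordinate_space,
            n_records = length(unique(paste(df$dataset, df$chimera))),
            rejected = rejected,
            class = c("interactions", "data.frame"))
}

#' Write an interaction table
#' @param interactions interaction data frame.
#' @param path output path.
#' @rdname read_interactions
#' @export
write_interactions <- function(interactions, path) {
  cols <- c("seqid", "start", "end", "strand", "mirna", "dataset", "chimera", "cell_line")
  utils::write.table(as.data.frame(interactions)[cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a CLIP peak table
#'
#' One file per dataset is the usual layout; columns
#' `seqid, start, end, strand, dataset, cell_line, method` (TSV with header,
#' 0-based half-open). `method` is free text such as `PAR-CLIP` or
#' `HITS-CLIP`.
#'
#' @param path path, or a character vector of paths whose tables are
#'   concatenated.
#' @return data frame of peak rows.
#' @export
read_peaks <- function(path) {
  tabs <- lapply(path, function(p) {
    df <- utils::read.delim(p, stringsAsFactors = FALSE)
    req <- c("seqid", "start", "end", "strand", "dataset", "cell_line", "method")
    miss <- setdiff(req, names(df))
    if (length(miss)) stop("peaks file ", p, " lacks column(s): ",
                           paste(miss, collapse = ", "))
    if (any(!nzchar(df$dataset))) stop("peaks file ", p, ": empty dataset id")
    df$start <- as.integer(df$start); df$end <- as.integer(df$end)
    validate_intervals(df, paste0("peak (", p, ")"))
    df
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  out
}

#' @rdname read_peaks
#' @param peaks peak data frame.
#' @export
write_peaks <- function(peaks, path) {
  cols <- c("seqid", "start", "end", "strand", "dataset", "cell_line", "method")
  utils::write.table(peaks[cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write BED6
#'
#' BED is 0-based half-open, matching the package's internal convention, so
#' coordinates pass through unchanged and a read/write round trip is
#' lossless.
#'
#' @param path file path.
#' @return `read_bed`: data frame `seqid, start, end, name, score, strand`.
#' @export
read_bed <- function(path) {
  df <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                          col.names = c("seqid", "start", "end", "name",
                                        "score", "strand"),
                          colClasses = c("character", "integer", "integer",
                                         "character", "character", "character"))
  validate_intervals(df, "BED record")
  df
}

#' @rdname read_bed
#' @param regions data frame with at least `seqid, start, end, name, score,
#'   strand` (missing `name`/`score` filled with `.`/`0`).
#' @export
write_bed <- function(regions, path) {
  if (is.null(regions$name)) regions$name <- "."
  if (is.null(regions$score)) regions$score <- 0L
  df <- regions[c("seqid", "start", "end", "name", "score", "strand")]
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a VCF (v4.0/4.1) file
#'
#' Parses the standard 8 fixed columns of a VCF body and converts the
#' 1-based `POS` to the internal 0-based convention (`start = POS - 1`,
#' `end = POS`, a point interval at the anchor base). The raw header and
#' body lines are kept verbatim so downstream annotation can preserve the
#' input byte-for-byte.
#'
#' @param path VCF file path.
#' @param size_limit refuse files larger than this many bytes (default
#'   20 MB, matching the published tool's input cap).
#' @return list of class `vcf` with `header` (character), `body` (data
#'   frame `seqid, pos, id, ref, alt, qual, filter, info, start, end`),
#'   `lines` (verbatim body lines), `version`.
#' @export
read_vcf <- function(path, size_limit = 20 * 1024^2) {
  sz <- file.info(path)$size
  if (!is.na(sz) && sz > size_limit) {
    stop("VCF file ", path, " is ", sz, " bytes, over the ", size_limit,
         "-byte limit; refusing to read")
  }
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  header <- lines[hdr]
  ff <- grep("^##fileformat=VCFv", header, value = TRUE)
  if (!length(ff)) stop("unparseable VCF header in ", path,
                        ": no ##fileformat=VCFv line")
  version <- sub("^##fileformat=VCFv", "", ff[1L])
  body_lines <- lines[!hdr]
  body_lines <- body_lines[nzchar(body_lines)]
  if (length(body_lines)) {
    fields <- strsplit(body_lines, "\t", fixed = TRUE)
    if (any(lengths(fields) < 8L)) stop("VCF body row with fewer than 8 columns in ", path)
    m <- t(vapply(fields, function(x) x[1:8], character(8)))
    pos <- as.integer(m[, 2L])
    body <- data.frame(seqid = m[, 1L], pos = pos, id = m[, 3L], ref = m[, 4L],
                       alt = m[, 5L], qual = m[, 6L], filter = m[, 7L],
                       info = m[, 8L],
                       start = pos - 1L, end = pos,
                       stringsAsFactors = FALSE)
  } else {
    body <- data.frame(seqid = character(), pos = integer(), id = character(),
                       ref = character(), alt = character(), qual = character(),
                       filter = character(), info = character(),
                       start = integer(), end = integer(),
                       stringsAsFactors = FALSE)
  }
  structure(list(header = header, body = body, lines = body_lines,
                 version = version, path = path),
            class = "vcf")
}

#' @export
print.vcf <- function(x, ...) {
  cat("VCF v", x$version, ": ", nrow(x$body), " record(s)\n", sep = "")
  invisible(x)
}
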