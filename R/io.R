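# Delimited-text I/O: recordings (samples x channels on disk, with a
# sample-rate declaration), cohort manifests and tidy result tables.

#' Write a multichannel recording as delimited text
#'
#' On disk the layout is samples in rows and channels in columns, with a
#' header row of channel labels and a leading comment line declaring the
#' sampling rate (`# sample_rate_hz: 1200`). Values are written with 10
#' significant digits, so write-read round trips are lossless at that
#' precision and byte-stable for identical input.
#'
#' @param recording Numeric matrix, channels in rows, samples in columns;
#'   row names are the channel labels.
#' @param path Output file path.
#' @param sample_rate_hz Sampling rate to declare in the header.
#' @return `path`, invisibly.
#' @export
write_recording <- function(recording, path, sample_rate_hz) {
  stopifnot(is.matrix(recording), is.numeric(recording))
  fs <- .check_fs(sample_rate_hz)
  if (is.null(rownames(recording)))
    rownames(recording) <- sprintf("ch%03d", seq_len(nrow(recording)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# sample_rate_hz: %.10g", fs), con)
  writeLines(paste(rownames(recording), collapse = "\t"), con)
  body <- apply(t(recording), 1L, function(row)
    paste(sprintf("%.10g", row), collapse = "\t"))
  writeLines(body, con)
  invisible(path)
}

#' Read a multichannel recording written by [write_recording()]
#'
#' @param path Input file path.
#' @return Numeric matrix (channels x samples) with channel labels as row
#'   names and the declared rate as `attr(, "sample_rate_hz")`.
#' @export
read_recording <- function(path) {
  if (!file.exists(path))
    stop("recording file not found: ", path)
  first <- readLines(path, n = 1L)
  fs <- NA_real_
  if (grepl("^#\\s*sample_rate_hz:", first))
    fs <- as.numeric(sub("^#\\s*sample_rate_hz:\\s*", "", first))
  tab <- utils::read.delim(path, comment.char = "#", header = TRUE,
                           check.names = FALSE)
  if (ncol(tab) < 1L || nrow(tab) < 1L)
    stop("malformed recording file (no data rows): ", path)
  mat <- t(as.matrix(tab))
  if (!is.numeric(mat))
    stop("malformed recording file (non-numeric values): ", path)
  colnames(mat) <- NULL
  attr(mat, "sample_rate_hz") <- fs
  mat
}

#' Write / read a cohort manifest table
#'
#' The manifest lists one recording per row: `subject_id`, `group`, `mix`
#' (generator weight, `NA` for real data) and `file` (path relative to the
#' manifest's directory or absolute).
#'
#' @param manifest Data frame as produced by [gen_cohort()].
#' @param path File path (tab-separated).
#' @return `path` (write) or the manifest data frame with an additional
#'   attribute `dir`, the manifest's directory (read).
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "file")
  if (!all(need %in% names(out)))
    stop("manifest ", path, " must have columns: ", paste(need, collapse = ", "))
  attr(out, "dir") <- dirname(path)
  out
}

#' Write / read a tidy long-format table (tab-separated)
#'
#' Shared writer/reader for profile and statistics tables. Numeric columns
#' are written with 10 significant digits for byte-stable reruns.
#'
#' @param table Data frame.
#' @param path File path.
#' @return `path` (write) or the data frame (read).
#' @export
write_table_tsv <- function(table, path) {
  out <- table
  num <- vapply(out, is.numeric, logical(1))
  out[num] <- lapply(out[num], function(v) sprintf("%.10g", v))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_tsv
#' @export
read_table_tsv <- function(path) {
  if (!file.exists(path)) stop("table not found: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Serialize a pattern distribution to JSON
#'
#' Writes the forward pattern counts keyed by rank tuple, plus `n_vectors`,
#' `m`, `tau`, `U` and `V` -- a compact debuggable record.
#'
#' @param dist A [pattern_distribution()].
#' @param path Optional path; when omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
pattern_distribution_json <- function(dist, path = NULL) {
  stopifnot(inherits(dist, "pattern_distribution"))
  obj <- list(m = dist$m, tau = dist$tau, n_vectors = dist$n_vectors,
              U = dist$U, V = dist$V, counts = as.list(dist$counts))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
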