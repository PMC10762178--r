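#' Multichannel signal matrix
#'
#' The universal input container of the package: `p` mixed channels in rows,
#' `n` time samples in columns.  All downstream selectors
#' ([cw_ica()], [dw_determination()], [ica_corr_y()], [ica_by_blocks()])
#' accept a `signal_matrix` or any plain numeric matrix with the same
#' row-per-channel convention.
#'
#' @param data numeric matrix, one row per channel.
#' @param channel_labels optional character vector of length `nrow(data)`.
#' @return An object of class `signal_matrix`: a list with elements `data`,
#'   `channel_labels`, `p` (channels) and `n` (samples).
#' @examples
#' x <- signal_matrix(matrix(rnorm(4 * 100), 4))
#' x$p
#' @export
signal_matrix <- function(data, channel_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("'data' must be a numeric matrix")
  if (!all(is.finite(data))) stop("'data' must not contain NA/NaN/Inf entries")
  p <- nrow(data)
  n <- ncol(data)
  if (p < 2L) stop("need at least 2 channels (rows), got ", p)
  if (n < 4L) stop("need at least 4 samples per channel, got ", n)
  if (n < 10L * p) {
    warning("signal length n = ", n, " is short relative to p = ", p,
            " channels (n < 10*p); ICA estimates may be unstable")
  }
  if (!is.null(channel_labels)) {
    channel_labels <- as.character(channel_labels)
    if (length(channel_labels) != p) {
      stop("'channel_labels' must have one entry per row")
    }
  }
  structure(list(data = data, channel_labels = channel_labels, p = p, n = n),
            class = "signal_matrix")
}

# Coerce a signal_matrix or bare matrix to the underlying numeric matrix.
signal_data <- function(x) {
  if (inherits(x, "signal_matrix")) return(x$data)
  if (is.matrix(x) && is.numeric(x)) return(x)
  stop("expected a 'signal_matrix' or a numeric matrix")
}

#' @export
print.signal_matrix <- function(x, ...) {
  cat("signal_matrix:", x$p, "channels x", x$n, "samples\n")
  if (!is.null(x$channel_labels)) {
    cat("channels:", paste(utils::head(x$channel_labels, 8), collapse = ", "),
        if (x$p > 8) "...\n" else "\n")
  }
  invisible(x)
}

#' Read and write delimited signal matrices
#'
#' Plain-text matrix I/O with the row-per-channel convention.  Values are
#' written with 17 significant digits so that a write/read round trip
#' reproduces every double bit-for-bit.
#'
#' @param path file path.
#' @param delimiter single-character field separator.
#' @param header if `TRUE` the first line holds channel labels (one label per
#'   row of the matrix, i.e. the file is transposed-header style: labels name
#'   the rows that follow).
#' @return `read_matrix()` returns a [signal_matrix()]; `write_matrix()`
#'   returns `invisible(NULL)`.
#' @export
read_matrix <- function(path, delimiter = ",", header = FALSE) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("file '", path, "' is empty")
  labels <- NULL
  if (header) {
    labels <- trimws(strsplit(lines[[1]], delimiter, fixed = TRUE)[[1]])
    lines <- lines[-1]
  }
  fields <- strsplit(lines, delimiter, fixed = TRUE)
  widths <- lengths(fields)
  if (length(unique(widths)) != 1L) {
    bad <- which(widths != widths[[1]])[[1]]
    stop("ragged input: row ", bad + as.integer(header), " of '", path,
         "' has ", widths[[bad]], " fields, expected ", widths[[1]])
  }
  rows <- lapply(seq_along(fields), function(i) {
    raw <- trimws(fields[[i]])
    val <- suppressWarnings(as.numeric(raw))
    if (anyNA(val)) {
      j <- which(is.na(val))[[1]]
      stop("non-numeric value '", raw[[j]], "' at row ",
           i + as.integer(header), ", column ", j, " of '", path, "'")
    }
    val
  })
  signal_matrix(do.call(rbind, rows), channel_labels = labels)
}

#' @param x a [signal_matrix()] or numeric matrix to write.
#' @rdname read_matrix
#' @export
write_matrix <- function(x, path, delimiter = ",", header = FALSE) {
  labels <- if (inherits(x, "signal_matrix")) x$channel_labels else NULL
  m <- signal_data(x)
  con <- file(path, "w")
  on.exit(close(con))
  if (header) {
    if (is.null(labels)) labels <- paste0("ch", seq_len(nrow(m)))
    writeLines(paste(labels, collapse = delimiter), con)
  }
  txt <- apply(m, 1L, function(r) paste(sprintf("%.17g", r), collapse = delimiter))
  writeLines(txt, con)
  invisible(NULL)
}
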