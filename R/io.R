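# atomic write: write to a temp file in the target directory, then rename,
# so interrupted runs never leave truncated files behind
atomic_write <- function(path, writer) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  on.exit(if (file.exists(tmp)) unlink(tmp), add = TRUE)
  writer(tmp)
  if (!file.rename(tmp, path)) stop("could not move temporary file to ", path)
  invisible(path)
}

#' Read and write time-series files
#'
#' The single supported dialect: comma-separated text, one header row, '.'
#' decimal separator, two numeric columns (`time`, value) or three for
#' planar data.  Times must be strictly increasing with a fixed step
#' (relative jitter above 1e-6 is rejected).  Values are written with full
#' double precision so a write-then-read round trip is exact.
#'
#' @param path File path.
#' @return `read_timeseries()` returns a list with `times`, `values` and,
#'   for three-column files, `values2`.
#' @export
read_timeseries <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 3L) stop("time-series file needs a header and >= 2 rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  ncol <- length(header)
  if (!ncol %in% c(2L, 3L))
    stop("expected 2 or 3 comma-separated columns, found ", ncol)
  n <- length(lines) - 1L
  mat <- matrix(NA_real_, n, ncol)
  for (i in seq_len(n)) {
    cells <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(cells) != ncol)
      stop("malformed row at line ", i + 1L, ": expected ", ncol,
           " cells, found ", length(cells))
    vals <- suppressWarnings(as.numeric(cells))
    if (any(is.na(vals)))
      stop("malformed row at line ", i + 1L, ": non-numeric cell")
    mat[i, ] <- vals
  }
  times <- mat[, 1]
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  dts <- diff(times)
  if ((max(dts) - min(dts)) > 1e-6 * stats::median(dts))
    stop("irregular sampling: time steps vary by more than 1e-6 relative")
  out <- list(times = times, values = mat[, 2])
  if (ncol == 3L) out$values2 <- mat[, 3]
  out
}

#' @rdname read_timeseries
#' @param times,values,values2 Columns to write (`values2` optional).
#' @param value_name,value2_name Header names of the value columns.
#' @export
write_timeseries <- function(path, times, values, values2 = NULL,
                             value_name = "y", value2_name = "y2") {
  fmt <- function(x) sprintf("%.17g", x)
  header <- if (is.null(values2)) paste("time", value_name, sep = ",")
  else paste("time", value_name, value2_name, sep = ",")
  rows <- if (is.null(values2)) paste(fmt(times), fmt(values), sep = ",")
  else paste(fmt(times), fmt(values), fmt(values2), sep = ",")
  atomic_write(path, function(tmp)
    writeLines(c(header, rows), tmp))
  invisible(path)
}

#' Write a run manifest
#'
#' Every command-line run records one JSON manifest: the command, the full
#' configuration snapshot, the seed, md5 hashes of the input and output
#' files, a timestamp and the package version.  Re-running with the
#' configuration and seed in a manifest reproduces stochastic outputs
#' bit-identically (the timestamp and hashes are the only run-specific
#' fields).
#'
#' @param path Manifest path (JSON).
#' @param command Subcommand name.
#' @param config Configuration list (flags, parameters).
#' @param seed Integer seed or `NULL`.
#' @param inputs,outputs Character vectors of file paths to hash.
#' @return The manifest list, invisibly.
#' @export
write_manifest <- function(path, command, config, seed = NULL,
                           inputs = character(), outputs = character()) {
  hash <- function(files) {
    files <- files[file.exists(files)]
    if (length(files) == 0L) return(NULL)
    as.list(stats::setNames(unname(tools::md5sum(files)), basename(files)))
  }
  manifest <- list(command = command, config = config, seed = seed,
                   input_hashes = hash(inputs), output_hashes = hash(outputs),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"),
                   package = "scalesym",
                   version = as.character(utils::packageVersion("scalesym")))
  atomic_write(path, function(tmp)
    jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA,
                         null = "null"))
  invisible(manifest)
}
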