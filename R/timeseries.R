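#' Collective-variable time series
#'
#' A uniformly sampled scalar collective-variable trace: times in ps and
#' values in angstrom, with a uniform stride. The container for all
#' trajectory data in the package, whether read from Colvars-style files or
#' generated by [simulate_bd()].
#'
#' @param times Numeric vector of times in ps, strictly increasing, uniform
#'   spacing (within 1e-9 ps).
#' @param values Numeric vector of the collective variable in angstrom, same
#'   length as `times`.
#' @param label Short text label.
#' @param metadata Free-form provenance list (seed, generator settings, wrap
#'   counts, ...).
#' @return An object of class `cv_series` with fields `times`, `values`,
#'   `stride`, `label`, `metadata`.
#' @export
cv_series <- function(times, values, label = "cv", metadata = list()) {
  if (length(times) != length(values))
    stop("times and values must have the same length")
  if (length(times) < 2L)
    stop("a cv_series needs at least 2 records")
  dt <- diff(times)
  stride <- dt[1L]
  if (any(dt <= 0)) stop("times must be strictly increasing")
  bad <- which(abs(dt - stride) > 1e-9)
  if (length(bad))
    stop(sprintf("non-uniform stride at record %d: spacing %.9g vs stride %.9g ps",
                 bad[1L] + 1L, dt[bad[1L]], stride))
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 stride = stride, label = label, metadata = metadata),
            class = "cv_series")
}

#' @export
print.cv_series <- function(x, ...) {
  cat(sprintf("<cv_series> '%s': %d records, stride %g ps, t = [%g, %g] ps, z in [%.3f, %.3f] A\n",
              x$label, length(x$times), x$stride, x$times[1L],
              x$times[length(x$times)], min(x$values), max(x$values)))
  invisible(x)
}

#' @export
length.cv_series <- function(x) length(x$times)

#' Read a Colvars-style collective-variable file
#'
#' Whitespace-delimited numeric columns; lines starting with `#` are headers
#' or comments and blank lines are ignored. Column 1 is time in ps; `column`
#' selects the value column (1-based among the remaining columns, so the
#' default `column = 1` reads the second file column). Scientific notation is
#' accepted. The stride is inferred from the first two records and enforced
#' on the rest.
#'
#' @param path File path.
#' @param column Value column index (1 = first column after time).
#' @param label Label for the series; defaults to the file name.
#' @return A [cv_series()].
#' @export
read_cv_series <- function(path, column = 1L, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", raw)
  lines <- raw[keep]
  if (!length(lines)) stop("empty input: no data lines in ", path)
  lineno <- which(keep)
  toks <- strsplit(trimws(lines), "\\s+")
  ncols <- lengths(toks)
  if (any(ncols < column + 1L)) {
    i <- which(ncols < column + 1L)[1L]
    stop(sprintf("line %d: expected at least %d columns, found %d",
                 lineno[i], column + 1L, ncols[i]))
  }
  parse_col <- function(j) {
    v <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", j)))
    if (anyNA(v)) {
      i <- which(is.na(v))[1L]
      stop(sprintf("line %d: malformed numeric field '%s'",
                   lineno[i], vapply(toks, `[[`, "", j)[i]))
    }
    v
  }
  times <- parse_col(1L)
  values <- parse_col(column + 1L)
  if (length(times) < 2L) stop("empty input: fewer than 2 records in ", path)
  dt <- diff(times)
  stride <- dt[1L]
  bad <- which(abs(dt - stride) > 1e-9)
  if (length(bad))
    stop(sprintf("format error at line %d: stride %.9g ps does not match inferred stride %.9g ps",
                 lineno[bad[1L] + 1L], dt[bad[1L]], stride))
  cv_series(times, values, label = label %||% basename(path),
            metadata = list(path = path, column = column))
}

#' Write a collective-variable series to a Colvars-style file
#'
#' Emits `#` metadata lines (label, stride, any scalar metadata entries) and
#' two whitespace-delimited columns (time, value) at 10 significant digits,
#' so that [read_cv_series()] round-trips exactly.
#'
#' @param ts A [cv_series()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cv_series <- function(ts, path) {
  stopifnot(inherits(ts, "cv_series"))
  hdr <- c(sprintf("# label %s", ts$label),
           sprintf("# stride %.10g", ts$stride))
  sc <- ts$metadata[vapply(ts$metadata, function(x)
    is.atomic(x) && length(x) == 1L, logical(1))]
  if (length(sc))
    hdr <- c(hdr, sprintf("# %s %s", names(sc), vapply(sc, format, "")))
  body <- sprintf("%.10g %.10g", ts$times, ts$values)
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Subsample a series by an integer factor
#'
#' Keeps every `factor`-th record starting at the first; the stride is
#' multiplied by `factor`. Emulates a coarser output frequency of the
#' collective variable, which is what makes milestoning MFPTs stride-sensitive.
#'
#' @param ts A [cv_series()].
#' @param factor Positive integer.
#' @return A [cv_series()].
#' @export
subsample <- function(ts, factor) {
  stopifnot(inherits(ts, "cv_series"))
  if (!is.numeric(factor) || length(factor) != 1L || factor < 1 ||
      factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  if (factor == 1L) return(ts)
  idx <- seq(1L, length(ts$times), by = factor)
  cv_series(ts$times[idx], ts$values[idx], label = ts$label,
            metadata = c(ts$metadata, list(subsample_factor = factor)))
}

#' Split a series into contiguous equal-length blocks
#'
#' Remainder records are dropped from the end, preserving stationarity of
#' each block for block-error analysis.
#'
#' @param ts A [cv_series()].
#' @param n_blocks Number of blocks (>= 2).
#' @return List of [cv_series()].
#' @export
split_blocks <- function(ts, n_blocks) {
  stopifnot(inherits(ts, "cv_series"))
  if (!is.numeric(n_blocks) || length(n_blocks) != 1L || n_blocks < 2 ||
      n_blocks != round(n_blocks))
    stop("n_blocks must be an integer >= 2")
  n <- length(ts$times)
  len <- n %/% n_blocks
  if (len < 2L)
    stop(sprintf("cannot split %d records into %d blocks of length >= 2", n, n_blocks))
  lapply(seq_len(n_blocks), function(b) {
    idx <- ((b - 1L) * len + 1L):(b * len)
    cv_series(ts$times[idx], ts$values[idx],
              label = sprintf("%s[block %d/%d]", ts$label, b, n_blocks),
              metadata = c(ts$metadata, list(block = b, n_blocks = n_blocks)))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
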