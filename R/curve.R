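#' Construct a scattering curve
#'
#' A scattering curve is the lingua franca of SAXS analysis: a tibble with
#' columns `q` (scattering-vector magnitude, nm^-1, strictly increasing),
#' `I` (intensity, arbitrary normalized units) and optionally `sigma`
#' (1-sigma uncertainty on `I`). All analysis functions in the package take
#' and return this representation, so calls chain with the pipe.
#'
#' @param q Numeric vector of scattering-vector magnitudes in inverse
#'   nanometres. Must be non-negative, strictly increasing and NaN-free.
#' @param I Numeric vector of intensities, same length as `q`.
#' @param sigma Optional numeric vector of 1-sigma uncertainties (same units
#'   as `I`). `NULL` is allowed only for synthetic noiseless curves.
#' @param metadata Named list of free-text metadata (sample name,
#'   concentration, buffer description, comment header lines ...).
#'
#' @return A tibble of class `sas_curve` with columns `q`, `I` and, when
#'   given, `sigma`; metadata is kept in the `"metadata"` attribute.
#' @examples
#' sas_curve(c(0.1, 0.2, 0.3), c(10, 5, 2), c(1, 1, 1))
#' @export
sas_curve <- function(q, I, sigma = NULL, metadata = list()) {
  q <- as.double(q); I <- as.double(I)
  if (length(q) != length(I)) {
    stop("`q` and `I` must have the same length", call. = FALSE)
  }
  if (anyNA(q)) stop("NaN/NA forbidden in `q`", call. = FALSE)
  if (length(q) && any(q < 0)) stop("`q` must be non-negative", call. = FALSE)
  if (length(q) > 1 && any(diff(q) <= 0)) {
    stop("`q` must be strictly increasing", call. = FALSE)
  }
  if (!is.null(sigma)) {
    sigma <- as.double(sigma)
    if (length(sigma) != length(q)) {
      stop("`sigma` must have the same length as `q`", call. = FALSE)
    }
    bad <- which(!is.na(sigma) & sigma < 0)
    if (length(bad)) {
      stop(sprintf("negative sigma at position %d", bad[1]), call. = FALSE)
    }
    out <- tibble::tibble(q = q, I = I, sigma = sigma)
  } else {
    out <- tibble::tibble(q = q, I = I)
  }
  attr(out, "metadata") <- metadata
  class(out) <- c("sas_curve", class(out))
  out
}

#' @export
print.sas_curve <- function(x, ...) {
  md <- attr(x, "metadata")
  cat(sprintf("<sas_curve> %d points, q in [%.4g, %.4g] nm^-1%s\n",
              nrow(x),
              if (nrow(x)) min(x$q) else NA, if (nrow(x)) max(x$q) else NA,
              if (has_sigma(x)) "" else " (no sigma)"))
  if (!is.null(md$sample)) cat("  sample:", md$sample, "\n")
  NextMethod()
}

has_sigma <- function(curve) "sigma" %in% names(curve)

curve_metadata <- function(curve) {
  md <- attr(curve, "metadata")
  if (is.null(md)) list() else md
}

#' Read a three-column ASCII scattering file
#'
#' Reads the classic `.dat` exchange format: comment lines starting with `#`
#' followed by 2 or 3 numeric columns (`q`, `I` and optionally `sigma`).
#' The comment header is preserved as metadata. A declared q unit in the
#' header (`nm^-1` or `angstrom^-1` / `A^-1`) is honoured; angstrom input is
#' converted to the package-internal inverse nanometres on load.
#'
#' @param path Path to an existing `.dat` file.
#' @param q_unit Unit of the q column when the header does not declare one:
#'   `"nm^-1"` (default) or `"angstrom^-1"`.
#' @return A [sas_curve()].
#' @export
read_dat <- function(path, q_unit = c("nm^-1", "angstrom^-1")) {
  q_unit <- match.arg(q_unit)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  is_comment <- grepl("^\\s*#", lines)
  is_blank <- grepl("^\\s*$", lines)
  header <- sub("^\\s*#\\s?", "", lines[is_comment])
  data_lines <- which(!is_comment & !is_blank)

  unit_line <- grep("q_unit\\s*[:=]", header, value = TRUE)
  if (length(unit_line)) {
    u <- trimws(sub(".*q_unit\\s*[:=]\\s*", "", unit_line[1]))
    q_unit <- if (grepl("^(a|angstrom|Å)", tolower(u))) "angstrom^-1" else "nm^-1"
  }

  if (!length(data_lines)) {
    return(sas_curve(numeric(0), numeric(0), numeric(0),
                     metadata = list(header = header, path = path)))
  }
  fields <- strsplit(trimws(lines[data_lines]), "\\s+")
  ncol <- lengths(fields)
  if (any(ncol < 2 | ncol > 3)) {
    bad <- data_lines[which(ncol < 2 | ncol > 3)[1]]
    stop(sprintf("line %d: expected 2 or 3 numeric columns", bad), call. = FALSE)
  }
  num <- suppressWarnings(lapply(fields, as.numeric))
  if (anyNA(unlist(num))) {
    bad <- data_lines[which(vapply(num, anyNA, logical(1)))[1]]
    stop(sprintf("line %d: non-numeric value", bad), call. = FALSE)
  }
  q <- vapply(num, `[`, numeric(1), 1)
  I <- vapply(num, `[`, numeric(1), 2)
  sigma <- if (all(ncol == 3)) vapply(num, `[`, numeric(1), 3) else NULL
  if (!is.null(sigma)) {
    neg <- which(sigma < 0)
    if (length(neg)) {
      stop(sprintf("negative sigma on line %d", data_lines[neg[1]]), call. = FALSE)
    }
  }
  if (length(q) > 1 && any(diff(q) <= 0)) {
    stop("q column is not strictly increasing", call. = FALSE)
  }
  if (q_unit == "angstrom^-1") q <- q * 10
  sas_curve(q, I, sigma, metadata = list(header = header, path = path))
}

#' Write a scattering curve as three-column ASCII
#'
#' Writes `#`-prefixed header lines (sample metadata and the q unit) followed
#' by the numeric payload in scientific notation at full double precision, so
#' that a read/write roundtrip is lossless to 1 ulp.
#'
#' @param curve A [sas_curve()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dat <- function(curve, path) {
  stopifnot(inherits(curve, "sas_curve"))
  md <- curve_metadata(curve)
  header <- c(
    if (!is.null(md$sample)) paste0("# sample: ", md$sample),
    if (!is.null(md$concentration)) paste0("# concentration_mg_ml: ", md$concentration),
    if (!is.null(md$buffer)) paste0("# buffer: ", md$buffer),
    "# q_unit: nm^-1",
    if (has_sigma(curve)) "# columns: q I sigma" else "# columns: q I"
  )
  fmt <- function(x) sprintf("%.17e", x)
  if (has_sigma(curve)) {
    body <- paste(fmt(curve$q), fmt(curve$I), fmt(curve$sigma))
  } else {
    body <- paste(fmt(curve$q), fmt(curve$I))
  }
  con <- file(path, open = "wb")  # binary mode: deterministic LF line endings
  on.exit(close(con))
  writeLines(c(header, body), con, sep = "\n")
  invisible(path)
}
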