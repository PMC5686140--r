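# Format readers and report writers.

#' Read a 1-D SAXS curve from a text file
#'
#' Accepts whitespace- or comma-separated 2- or 3-column files (q, I and
#' optionally sigma), skipping \code{#} comment and non-numeric header
#' lines. Momentum-transfer units are Angstrom^-1 internally; with
#' \code{units = "auto"} a curve whose q extends beyond 1.5 is taken to be
#' in nm^-1 and converted (divided by 10), with a message.
#'
#' @param path File path.
#' @param units "auto", "A" or "nm".
#' @return A [scattering_curve()].
#' @export
read_saxs_dat <- function(path, units = c("auto", "A", "nm")) {
  units <- match.arg(units)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  rows <- lapply(lines, function(ln) {
    f <- strsplit(ln, "[,[:space:]]+")[[1]]
    suppressWarnings(as.numeric(f))
  })
  ok <- vapply(rows, function(r) length(r) >= 2 && !anyNA(r[1:2]), logical(1))
  rows <- rows[ok]
  if (length(rows) < 2L) stop("fewer than 2 numeric data rows in ", path)
  ncol <- min(vapply(rows, length, integer(1)))
  if (ncol < 2L) stop("fewer than 2 numeric columns in ", path)
  mat <- do.call(rbind, lapply(rows, function(r) r[seq_len(min(ncol, 3L))]))
  q <- mat[, 1]
  if (any(diff(q) <= 0)) stop("q values are not strictly increasing in ", path)
  if (units == "nm" || (units == "auto" && max(q) > 1.5)) {
    if (units == "auto")
      message("q extends beyond 1.5; interpreting as nm^-1 and converting")
    q <- q / 10
  }
  sigma <- if (ncol(mat) >= 3L) mat[, 3] else NULL
  scattering_curve(q, mat[, 2], sigma)
}

#' Write a scattering curve or P(r) table as whitespace-delimited text
#'
#' @param obj A [scattering_curve()] or [ift_pr()] result.
#' @param path Output path.
#' @return Invisibly, \code{path}.
#' @export
write_saxs_dat <- function(obj, path) {
  if (inherits(obj, "scattering_curve")) {
    df <- data.frame(q = obj$q, I = obj$I, sigma = obj$sigma)
    header <- "# q(A^-1) I sigma"
  } else if (inherits(obj, "pofr")) {
    df <- data.frame(r = obj$r, P = obj$pr)
    header <- sprintf("# r(A) P(r)  Dmax=%.2f Rg=%.3f", obj$Dmax, obj$Rg)
  } else stop("unsupported object")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(format(df, digits = 8), con, quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an analysis report as JSON or CSV
#'
#' data.frames go to CSV or JSON rows; lists go to JSON with stable key
#' order and the package version embedded.
#'
#' @param obj data.frame or list.
#' @param path Output path; format follows the extension unless given.
#' @param format "json" or "csv".
#' @return Invisibly, \code{path}.
#' @export
write_report <- function(obj, path, format = c("auto", "json", "csv")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "json"
  if (format == "csv") {
    if (!is.data.frame(obj)) stop("CSV output requires a data.frame")
    utils::write.csv(obj, path, row.names = FALSE)
  } else {
    payload <- list(package = "idpchar",
                    version = as.character(utils::packageVersion("idpchar")),
                    report = obj)
    jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}
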