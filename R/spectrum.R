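#' Construct a field-swept first-derivative EPR spectrum
#'
#' @param field strictly increasing magnetic-field axis, mT.
#' @param intensity first-derivative amplitude (arbitrary units), same
#'   length as `field`.
#' @param frequency_GHz microwave frequency in GHz (required by g-value
#'   analysis and quantification).
#' @param meta named list of free-form labels.
#' @return An object of class `epr_spectrum`.
#' @export
epr_spectrum <- function(field, intensity, frequency_GHz = NULL, meta = list()) {
  field <- as.numeric(field); intensity <- as.numeric(intensity)
  if (length(field) != length(intensity))
    stop("'field' and 'intensity' must have equal length")
  if (length(field) < 2L || any(!is.finite(field)) || any(diff(field) <= 0))
    stop("'field' must be a strictly increasing finite axis (mT)")
  if (any(!is.finite(intensity)))
    stop("non-finite intensities")
  if (!is.null(frequency_GHz)) {
    frequency_GHz <- as.numeric(frequency_GHz)
    if (length(frequency_GHz) != 1L || !is.finite(frequency_GHz) || frequency_GHz <= 0)
      stop("'frequency_GHz' must be a single positive number")
  }
  structure(list(field = field, intensity = intensity,
                 frequency_GHz = frequency_GHz, meta = meta),
            class = "epr_spectrum")
}

#' @export
print.epr_spectrum <- function(x, ...) {
  cat("EPR spectrum (first derivative)\n")
  cat(sprintf("  %d points, field %.4g-%.4g mT\n",
              length(x$field), min(x$field), max(x$field)))
  if (!is.null(x$frequency_GHz))
    cat(sprintf("  microwave frequency: %.4g GHz\n", x$frequency_GHz))
  for (nm in names(x$meta)) cat("  ", nm, ": ", format(x$meta[[nm]]), "\n", sep = "")
  invisible(x)
}

#' @export
plot.epr_spectrum <- function(x, ...) {
  graphics::plot(x$field, x$intensity, type = "l",
                 xlab = "Field (mT)", ylab = "dA/dB (a.u.)", ...)
  graphics::abline(h = 0, col = "grey70", lty = 3)
  invisible(x)
}

#' Read or write a spectrum as two-column CSV
#'
#' The format is `field_mT,intensity` preceded by `#`-prefixed header lines
#' of the form `# key: value`; `frequency_GHz` is the key the analysis modes
#' require. CRLF line endings and scientific-notation numbers are accepted.
#'
#' @param path file path.
#' @param require_frequency error if the `frequency_GHz` header is absent
#'   (the analysis functions need it).
#' @return `read_spectrum()` returns an `epr_spectrum`; `write_spectrum()`
#'   invisibly returns `path`.
#' @export
read_spectrum <- function(path, require_frequency = FALSE) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+?)\\s*:\\s*(.*)$", h))[[1]]
    if (length(m) == 3L) meta[[m[2]]] <- m[3]
  }
  body <- lines[!grepl("^#", lines) & nzchar(lines)]
  if (!length(body)) stop("no data rows in spectrum file: ", path)
  df <- utils::read.csv(text = body, header = grepl("[A-Za-z]", body[1]))
  if (ncol(df) < 2L) stop("spectrum file must have two numeric columns: ", path)
  freq <- meta[["frequency_GHz"]]
  if (is.null(freq) && require_frequency)
    stop("spectrum file lacks the required '# frequency_GHz: <value>' header: ",
         path)
  meta[["frequency_GHz"]] <- NULL
  epr_spectrum(df[[1]], df[[2]],
               frequency_GHz = if (is.null(freq)) NULL else as.numeric(freq),
               meta = meta)
}

#' @param spectrum an `epr_spectrum`.
#' @rdname read_spectrum
#' @export
write_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "epr_spectrum"))
  con <- file(path, "w"); on.exit(close(con))
  if (!is.null(spectrum$frequency_GHz))
    writeLines(sprintf("# frequency_GHz: %.15g", spectrum$frequency_GHz), con)
  for (nm in names(spectrum$meta))
    writeLines(paste0("# ", nm, ": ", format(spectrum$meta[[nm]])), con)
  writeLines("field_mT,intensity", con)
  writeLines(sprintf("%.15g,%.15g", spectrum$field, spectrum$intensity), con)
  invisible(path)
}
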