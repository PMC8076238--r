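#' Construct a spectrum object
#'
#' A spectrum is a two-column data.frame (`wavelength` in nm, `value`) with a
#' `kind` tag (`"reflectance"`, `"absorption"` or `"scattering"`) and a units
#' string.  Wavelengths must be strictly increasing and unique.
#'
#' @param wavelength wavelengths, nm.
#' @param value values (reflectance, mu_a in mm^-1, or mu_s' in mm^-1).
#' @param kind kind tag.
#' @param units units string.
#' @return An object of classes `spectrum` and `data.frame`.
#' @export
spectrum <- function(wavelength, value,
                     kind = c("absorption", "reflectance", "scattering"),
                     units = "mm^-1") {
  kind <- match.arg(kind)
  stopifnot(length(wavelength) == length(value))
  if (anyDuplicated(wavelength))
    stop("duplicate wavelengths in spectrum")
  if (is.unsorted(wavelength, strictly = TRUE)) {
    o <- order(wavelength)
    wavelength <- wavelength[o]; value <- value[o]
  }
  structure(data.frame(wavelength = as.numeric(wavelength),
                       value = as.numeric(value)),
            kind = kind, units = units,
            class = c("spectrum", "data.frame"))
}

#' Read a spectrum from two-column delimited text
#'
#' Files carry `#` comment headers with `kind:` and `units:` entries and two
#' whitespace- or tab-delimited numeric columns (wavelength nm, value).
#' Non-numeric rows and duplicated wavelengths are parse errors naming the
#' offending line; unsorted wavelengths are sorted with a warning.
#'
#' @param path file path.
#' @return A [spectrum()].
#' @export
read_spectrum <- function(path) {
  lines <- readLines(path)
  is_hdr <- startsWith(trimws(lines), "#")
  hdr <- lines[is_hdr]
  body_idx <- which(!is_hdr & nzchar(trimws(lines)))
  get <- function(key) {
    ln <- grep(paste0("^#\\s*", key, ":"), hdr, value = TRUE)
    if (!length(ln)) return(NA_character_)
    trimws(sub(paste0("^#\\s*", key, ":"), "", ln[1]))
  }
  wl <- val <- numeric(length(body_idx))
  for (i in seq_along(body_idx)) {
    parts <- strsplit(trimws(lines[body_idx[i]]), "[\t ,]+")[[1]]
    v <- suppressWarnings(as.numeric(parts))
    if (length(v) < 2 || any(is.na(v[1:2])))
      stop("parse error at line ", body_idx[i], " of ", path,
           ": non-numeric row '", lines[body_idx[i]], "'")
    wl[i] <- v[1]; val[i] <- v[2]
  }
  if (anyDuplicated(wl)) {
    dup <- body_idx[which(duplicated(wl))[1]]
    stop("parse error at line ", dup, " of ", path,
         ": duplicate wavelength ", wl[duplicated(wl)][1])
  }
  if (is.unsorted(wl, strictly = TRUE))
    warning("wavelengths not sorted in ", path, "; sorting")
  kind <- get("kind")
  if (is.na(kind)) kind <- "absorption"
  units <- get("units")
  if (is.na(units)) units <- "mm^-1"
  spectrum(wl, val, kind = kind, units = units)
}

#' Write a spectrum as two-column delimited text
#'
#' @param x a [spectrum()].
#' @param path file path.
#' @export
write_spectrum <- function(x, path) {
  stopifnot(inherits(x, "spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(paste0("# kind: ", attr(x, "kind")),
               paste0("# units: ", attr(x, "units"))), con)
  write.table(data.frame(format(x$wavelength, digits = 17, trim = TRUE),
                         format(x$value, digits = 17, trim = TRUE)),
              con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
}

#' Report a spectrum's coverage of an analysis band
#'
#' Counts in-band points, lists gaps larger than `max_gap` nm, and flags
#' spectra extending beyond 1380 nm, where strong water absorption makes
#' measured reflectance unreliable.
#'
#' @param x a [spectrum()].
#' @param band a [band()].
#' @param max_gap largest tolerated spacing between consecutive in-band
#'   points, nm.
#' @return A list with `n_points`, `full_coverage`, `gaps` (data.frame with
#'   `from`/`to`), and `beyond_1380`.
#' @export
validate_band_coverage <- function(x, band, max_gap = 5) {
  stopifnot(inherits(x, "spectrum"))
  wl <- x$wavelength
  inb <- wl[wl >= band$range[1] & wl <= band$range[2]]
  gaps <- data.frame(from = numeric(0), to = numeric(0))
  if (length(inb) >= 2) {
    d <- diff(inb)
    big <- which(d > max_gap)
    gaps <- data.frame(from = inb[big], to = inb[big + 1])
  }
  edge_gap <- length(inb) == 0 ||
    (inb[1] - band$range[1]) > max_gap ||
    (band$range[2] - inb[length(inb)]) > max_gap
  list(n_points = length(inb),
       full_coverage = !edge_gap && nrow(gaps) == 0 && length(inb) >= 2,
       gaps = gaps,
       beyond_1380 = max(wl) > 1380)
}
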