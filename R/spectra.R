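#' Construct an FTIR absorbance spectrum
#'
#' A spectrum is a paired series of wavenumbers (cm^-1) and absorbances
#' (dimensionless absorbance units). Wavenumbers are stored in descending
#' order (the 4000 -> 650 cm^-1 mid-IR plotting convention); constructors
#' and readers accept either direction and normalize.
#'
#' @param wavenumbers numeric vector of wavenumbers in cm^-1, strictly
#'   monotone in either direction.
#' @param absorbance numeric vector of absorbance values, same length.
#' @param meta named list of free-form metadata (sample id, cell line,
#'   concentration label, mixing fraction `phi`, ...).
#' @return An object of class `"ftir_spectrum"`: a list with elements
#'   `wavenumbers`, `absorbance` (both descending-ordered) and `meta`.
#' @examples
#' s <- ftir_spectrum(c(4000, 3999, 3998), c(0.1, 0.2, 0.1))
#' s$wavenumbers
#' @export
ftir_spectrum <- function(wavenumbers, absorbance, meta = list()) {
  wavenumbers <- as.numeric(wavenumbers)
  absorbance <- as.numeric(absorbance)
  if (length(wavenumbers) != length(absorbance)) {
    stop("wavenumbers and absorbance must have equal length", call. = FALSE)
  }
  if (length(wavenumbers) < 2) {
    stop("a spectrum needs at least 2 points", call. = FALSE)
  }
  if (any(!is.finite(wavenumbers)) || any(!is.finite(absorbance))) {
    stop("spectrum contains non-finite values (NaN/Inf/NA)", call. = FALSE)
  }
  dw <- diff(wavenumbers)
  if (all(dw > 0)) {
    # ascending input: flip to the canonical descending order
    wavenumbers <- rev(wavenumbers)
    absorbance <- rev(absorbance)
  } else if (!all(dw < 0)) {
    stop("wavenumbers must be strictly monotone", call. = FALSE)
  }
  structure(list(wavenumbers = wavenumbers, absorbance = absorbance,
                 meta = as.list(meta)),
            class = "ftir_spectrum")
}

#' @export
print.ftir_spectrum <- function(x, ...) {
  cat(sprintf("FTIR spectrum: %d points, %.1f-%.1f cm^-1, absorbance [%.4g, %.4g]\n",
              length(x$wavenumbers),
              max(x$wavenumbers), min(x$wavenumbers),
              min(x$absorbance), max(x$absorbance)))
  if (length(x$meta)) {
    cat("meta:", paste(names(x$meta), unlist(lapply(x$meta, format)),
                       sep = "=", collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
length.ftir_spectrum <- function(x) length(x$wavenumbers)

#' Read a spectrum from disk
#'
#' Supports two plain-text formats: a two-column CSV
#' (`wavenumber,absorbance`, optional `# key=value` header lines carrying
#' metadata) and a single-block JCAMP-DX subset (AFFN-encoded
#' `##XYDATA=(X++(Y..Y))` or `##XYDATA=(XY..XY)`; compressed dialects such
#' as DIFDUP are not supported).
#'
#' @param path path to the file.
#' @param format `"csv"` or `"jcamp-dx"`; `"auto"` guesses from the file
#'   extension (`.jdx`/`.dx` -> JCAMP, otherwise CSV).
#' @return An [ftir_spectrum] in canonical descending wavenumber order.
#' @export
read_spectrum <- function(path, format = c("auto", "csv", "jcamp-dx")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("jdx", "dx", "jcm")) "jcamp-dx" else "csv"
  }
  switch(format,
         "csv" = read_spectrum_csv(path),
         "jcamp-dx" = read_spectrum_jcamp(path))
}

read_spectrum_csv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  meta_lines <- grep("^\\s*#", lines, value = TRUE)
  data_lines <- grep("^\\s*#", lines, invert = TRUE, value = TRUE)
  meta <- list()
  for (ml in meta_lines) {
    kv <- sub("^\\s*#\\s*", "", ml)
    if (grepl("=", kv, fixed = TRUE)) {
      key <- trimws(sub("=.*$", "", kv))
      val <- trimws(sub("^[^=]*=", "", kv))
      num <- suppressWarnings(as.numeric(val))
      meta[[key]] <- if (!is.na(num)) num else val
    }
  }
  # tolerate a non-numeric header row such as "wavenumber,absorbance"
  if (length(data_lines) &&
      is.na(suppressWarnings(as.numeric(strsplit(data_lines[1], ",")[[1]][1])))) {
    data_lines <- data_lines[-1]
  }
  if (!length(data_lines)) stop("no data rows in ", path, call. = FALSE)
  parts <- strsplit(data_lines, "[,\t]")
  if (any(lengths(parts) < 2)) {
    stop("expected two comma-separated numeric columns in ", path,
         call. = FALSE)
  }
  w <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 1L)))
  a <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 2L)))
  if (anyNA(w) || anyNA(a)) {
    stop("non-numeric or NaN entries in spectrum columns of ", path,
         call. = FALSE)
  }
  ftir_spectrum(w, a, meta)
}

# Minimal JCAMP-DX reader: one data block, AFFN numbers only.
read_spectrum_jcamp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ldr <- function(name) {
    hit <- grep(paste0("^##", name, "="), lines, ignore.case = TRUE,
                value = TRUE)
    if (!length(hit)) return(NA_character_)
    trimws(sub("^##[^=]*=", "", hit[[1]]))
  }
  start <- grep("^##XYDATA=", lines, ignore.case = TRUE)
  if (!length(start)) stop("no ##XYDATA block in ", path, call. = FALSE)
  variant <- toupper(gsub("\\s", "", sub("^##XYDATA=", "", lines[start[1]],
                                         ignore.case = TRUE)))
  stop_idx <- grep("^##", lines)
  stop_idx <- stop_idx[stop_idx > start[1]]
  end <- if (length(stop_idx)) min(stop_idx) - 1L else length(lines)
  body <- lines[seq(start[1] + 1L, end)]
  body <- body[nzchar(trimws(body))]
  xfac <- suppressWarnings(as.numeric(ldr("XFACTOR"))); if (is.na(xfac)) xfac <- 1
  yfac <- suppressWarnings(as.numeric(ldr("YFACTOR"))); if (is.na(yfac)) yfac <- 1
  meta <- list()
  ttl <- ldr("TITLE")
  if (!is.na(ttl) && nzchar(ttl)) meta$title <- ttl
  if (variant %in% c("(X++(Y..Y))", "(X++(Y...Y))")) {
    w <- numeric(0); a <- numeric(0)
    for (ln in body) {
      vals <- suppressWarnings(as.numeric(strsplit(trimws(ln),
                                                   "[\\s,;]+", perl = TRUE)[[1]]))
      if (anyNA(vals) || length(vals) < 2) {
        stop("unparseable AFFN line in ", path, ": ", ln, call. = FALSE)
      }
      x0 <- vals[1] * xfac
      ys <- vals[-1] * yfac
      nline <- length(ys)
      # per-line X is the first abscissa; spacing from DELTAX or global grid
      dx <- suppressWarnings(as.numeric(ldr("DELTAX")))
      if (is.na(dx)) {
        firstx <- suppressWarnings(as.numeric(ldr("FIRSTX")))
        lastx <- suppressWarnings(as.numeric(ldr("LASTX")))
        npt <- suppressWarnings(as.numeric(ldr("NPOINTS")))
        if (anyNA(c(firstx, lastx, npt)) || npt < 2) {
          stop("JCAMP block lacks DELTAX and FIRSTX/LASTX/NPOINTS",
               call. = FALSE)
        }
        dx <- (lastx - firstx) / (npt - 1)
      }
      w <- c(w, x0 + dx * (seq_len(nline) - 1))
      a <- c(a, ys)
    }
    ftir_spectrum(w, a, meta)
  } else if (variant == "(XY..XY)") {
    vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body),
                                                        "[\\s,;]+", perl = TRUE))))
    vals <- vals[!is.na(vals)]
    if (length(vals) < 4 || length(vals) %% 2 != 0) {
      stop("malformed (XY..XY) block in ", path, call. = FALSE)
    }
    ftir_spectrum(vals[c(TRUE, FALSE)] * xfac, vals[c(FALSE, TRUE)] * yfac,
                  meta)
  } else {
    stop("unsupported JCAMP XYDATA variant: ", variant,
         " (only AFFN (X++(Y..Y)) and (XY..XY) are read)", call. = FALSE)
  }
}

#' Crop a spectrum to a wavenumber window
#'
#' @param s an [ftir_spectrum].
#' @param wmin,wmax window bounds in cm^-1, `wmin < wmax`. The standard
#'   mid-IR acquisition window is 650-4000 cm^-1.
#' @return The cropped [ftir_spectrum].
#' @export
crop_to_range <- function(s, wmin, wmax) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (!(wmin < wmax)) stop("wmin must be < wmax", call. = FALSE)
  keep <- s$wavenumbers >= wmin & s$wavenumbers <= wmax
  if (sum(keep) < 2) {
    stop(sprintf("crop window [%g, %g] retains fewer than 2 points",
                 wmin, wmax), call. = FALSE)
  }
  ftir_spectrum(s$wavenumbers[keep], s$absorbance[keep], s$meta)
}

#' Resample a spectrum onto a uniform wavenumber grid
#'
#' Linear interpolation onto `n_points` equally spaced wavenumbers
#' spanning the spectrum's range; endpoints are preserved exactly. One
#' wavenumber per raster column is the downstream use.
#'
#' @param s an [ftir_spectrum].
#' @param n_points number of output points, at least 2.
#' @return The resampled [ftir_spectrum].
#' @export
resample_uniform <- function(s, n_points) {
  stopifnot(inherits(s, "ftir_spectrum"))
  if (n_points < 2) stop("n_points must be >= 2", call. = FALSE)
  grid <- seq(max(s$wavenumbers), min(s$wavenumbers), length.out = n_points)
  a <- stats::approx(x = s$wavenumbers, y = s$absorbance, xout = grid,
                     method = "linear", rule = 2)$y
  ftir_spectrum(grid, a, s$meta)
}

#' Write a spectrum to CSV
#'
#' Metadata are serialized as `# key=value` header lines so that
#' `read_spectrum(write_spectrum(s))` round-trips both data and meta.
#'
#' @param s an [ftir_spectrum].
#' @param path output path.
#' @param format only `"csv"` is supported for writing.
#' @return `path`, invisibly.
#' @export
write_spectrum <- function(s, path, format = "csv") {
  stopifnot(inherits(s, "ftir_spectrum"))
  format <- match.arg(format, "csv")
  hdr <- character(0)
  if (length(s$meta)) {
    hdr <- sprintf("# %s=%s", names(s$meta),
                   vapply(s$meta, function(v) format(v, digits = 15), ""))
  }
  rows <- sprintf("%.12g,%.12g", s$wavenumbers, s$absorbance)
  ok <- tryCatch({
    writeLines(c(hdr, "wavenumber,absorbance", rows), path)
    TRUE
  }, error = function(e) e, warning = function(w) w)
  if (!isTRUE(ok)) stop("cannot write spectrum to ", path, call. = FALSE)
  invisible(path)
}
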