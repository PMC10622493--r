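#' Rasterization settings for the spectrum-to-image step
#'
#' The analysis operates on an axis-free plot of the spectrum: the trace
#' alone, no grids, ticks or margins, exported as an 8-bit grayscale image
#' and thresholded to binary. The default canvas is 1024 x 128 px: the
#' amplitude axis follows the 128-px (7-bit) quantization of the original
#' protocol, and 1024 columns give roughly three spectral points per
#' column at a typical 4 cm^-1 instrument resolution.
#'
#' @param width,height canvas size in pixels (`width >= 64`,
#'   `height >= 16`).
#' @param line_thickness trace thickness in pixels (vertical), `>= 1`.
#' @param threshold binarization cut in 0-255; pixels darker than this
#'   become foreground.
#' @param connect_columns join consecutive column samples with vertical
#'   runs so the trace is a connected polyline (every column covered).
#' @return A list of class `"raster_config"`.
#' @export
raster_config <- function(width = 1024L, height = 128L, line_thickness = 1L,
                          threshold = 128L, connect_columns = TRUE) {
  width <- as.integer(width); height <- as.integer(height)
  line_thickness <- as.integer(line_thickness)
  threshold <- as.integer(threshold)
  if (width < 64L) stop("width must be >= 64 px", call. = FALSE)
  if (height < 16L) stop("height must be >= 16 px", call. = FALSE)
  if (line_thickness < 1L) stop("line_thickness must be >= 1", call. = FALSE)
  if (threshold <= 0L || threshold >= 255L) {
    stop("threshold must lie strictly between 0 and 255", call. = FALSE)
  }
  structure(list(width = width, height = height,
                 line_thickness = line_thickness, threshold = threshold,
                 connect_columns = isTRUE(connect_columns)),
            class = "raster_config")
}

#' Normalize spectrum amplitude to [0, 1]
#'
#' Min-max normalization is the mechanism that makes the downstream
#' multifractal number independent of overall signal amplitude (and hence
#' of the cell concentration placed on the ATR crystal): any positive
#' rescaling of the absorbance yields a byte-identical trace image.
#'
#' @param s an [ftir_spectrum].
#' @param mode `"minmax"` maps the observed range onto `[0, 1]`;
#'   `"fixed"` maps the interval `[lo, hi]` affinely onto `[0, 1]`,
#'   clipping outside values.
#' @param lo,hi fixed-mode reference range (required for `mode="fixed"`).
#' @return The normalized [ftir_spectrum].
#' @export
normalize_amplitude <- function(s, mode = c("minmax", "fixed"),
                                lo = NULL, hi = NULL) {
  stopifnot(inherits(s, "ftir_spectrum"))
  mode <- match.arg(mode)
  a <- s$absorbance
  if (mode == "minmax") {
    rng <- range(a)
    if (diff(rng) <= 0) {
      stop("constant spectrum cannot be minmax-normalized; use mode='fixed'",
           call. = FALSE)
    }
    a <- (a - rng[1]) / diff(rng)
  } else {
    if (is.null(lo) || is.null(hi) || !(lo < hi)) {
      stop("fixed mode needs lo < hi", call. = FALSE)
    }
    a <- pmin(pmax((a - lo) / (hi - lo), 0), 1)
  }
  ftir_spectrum(s$wavenumbers, a, s$meta)
}

#' Render a spectrum as an axis-free grayscale trace image
#'
#' The spectrum (amplitude already in `[0, 1]`) is resampled to one point
#' per column; descending wavenumber runs left to right, absorbance 0 maps
#' to the bottom row and 1 to the top. Absorbance `a` lands on (0-based)
#' row `floor((1 - a) * (height - 1) + 0.5)`, ties breaking toward the
#' top. With `connect_columns`, consecutive samples are joined by vertical
#' runs so the trace is a connected polyline. Background is 255, trace 0;
#' no anti-aliasing (grey edge pixels would corrupt the binary mass).
#'
#' @param s a normalized [ftir_spectrum] (see [normalize_amplitude]).
#' @param cfg a [raster_config].
#' @return A `height x width` integer matrix of class `"gray_image"`
#'   (row 1 = top row).
#' @export
render_trace <- function(s, cfg = raster_config()) {
  stopifnot(inherits(s, "ftir_spectrum"), inherits(cfg, "raster_config"))
  a <- s$absorbance
  if (min(a) < -1e-9 || max(a) > 1 + 1e-9) {
    stop("spectrum must be normalized to [0,1] before rendering; ",
         "see normalize_amplitude()", call. = FALSE)
  }
  a <- pmin(pmax(a, 0), 1)
  w <- cfg$width; h <- cfg$height
  av <- if (length(a) == w) a else {
    stats::approx(seq(0, 1, length.out = length(a)), a,
                  xout = seq(0, 1, length.out = w), rule = 2)$y
  }
  rows <- floor((1 - av) * (h - 1) + 0.5) + 1L  # 1-based, row 1 = top
  img <- matrix(255L, nrow = h, ncol = w)
  thick <- seq_len(cfg$line_thickness) - 1L
  prev <- rows[1]
  for (j in seq_len(w)) {
    r <- rows[j]
    cells <- r
    if (cfg$connect_columns && j > 1L && prev != r) {
      run <- seq(prev, r)
      cells <- run[-1]  # exclude the previous column's row: no double count
    }
    rr <- unique(pmin(rep(cells, each = length(thick)) + thick, h))
    img[rr, j] <- 0L
    prev <- r
  }
  structure(img, class = c("gray_image", "matrix", "array"))
}

#' Threshold a grayscale image to a binary trace mask
#'
#' Foreground (mask = 1) is the dark trace: pixels with value strictly
#' below `threshold`.
#'
#' @param g a `"gray_image"` matrix (values 0-255).
#' @param threshold cut in (0, 255); default 128.
#' @return A `"binary_image"` 0/1 integer matrix with at least one
#'   foreground pixel.
#' @export
binarize <- function(g, threshold = 128L) {
  if (!is.matrix(g)) stop("g must be a matrix image", call. = FALSE)
  if (threshold <= 0 || threshold >= 256) {
    stop("threshold must be in (0, 255]", call. = FALSE)
  }
  mask <- matrix(as.integer(g < threshold), nrow = nrow(g))
  if (!any(mask == 1L)) {
    stop("binarization produced an empty trace (no foreground pixels)",
         call. = FALSE)
  }
  structure(mask, class = c("binary_image", "matrix", "array"))
}

#' Spectrum to binary trace image in one call
#'
#' Convenience composition: [normalize_amplitude] (minmax by default),
#' [render_trace], [binarize].
#'
#' @param s an [ftir_spectrum].
#' @param cfg a [raster_config].
#' @param normalize `"minmax"`, `"fixed"` or `"none"` (input already in
#'   `[0, 1]`).
#' @param lo,hi fixed-mode range, see [normalize_amplitude].
#' @return A `"binary_image"` matrix.
#' @export
spectrum_to_binary <- function(s, cfg = raster_config(),
                               normalize = c("minmax", "fixed", "none"),
                               lo = NULL, hi = NULL) {
  normalize <- match.arg(normalize)
  if (normalize != "none") {
    s <- normalize_amplitude(s, mode = normalize, lo = lo, hi = hi)
  }
  binarize(render_trace(s, cfg), cfg$threshold)
}

#' Write an image as PNG or BMP
#'
#' 8-bit grayscale for `"gray_image"`, 0/1 mask rendered as black trace on
#' white for `"binary_image"`. The BMP writer emits an uncompressed 8-bit
#' palettized file.
#'
#' @param img a `"gray_image"` or `"binary_image"` matrix.
#' @param path output path; format from extension unless given.
#' @param format `"png"`, `"bmp"` or `"auto"`.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path, format = c("auto", "png", "bmp")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (tolower(tools::file_ext(path)) == "bmp") "bmp" else "png"
  }
  vals <- if (inherits(img, "binary_image")) {
    (1L - unclass(img)) * 255L
  } else {
    unclass(img)
  }
  if (format == "png") {
    png::writePNG(vals / 255, target = path)
  } else {
    write_bmp8(vals, path)
  }
  invisible(path)
}

# Minimal uncompressed 8-bit grayscale-palette BMP writer.
write_bmp8 <- function(vals, path) {
  h <- nrow(vals); w <- ncol(vals)
  row_bytes <- ceiling(w / 4) * 4  # rows padded to 4-byte boundaries
  palette <- as.raw(rep(0:255, each = 4) * c(1, 1, 1, 0))
  data_offset <- 14 + 40 + 1024
  file_size <- data_offset + row_bytes * h
  u16 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  u32 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("BM"), con)
  u32(file_size); u16(0); u16(0); u32(data_offset)
  u32(40); u32(w); u32(h); u16(1); u16(8)
  u32(0); u32(row_bytes * h); u32(2835); u32(2835); u32(256); u32(0)
  writeBin(palette, con)
  pad <- as.raw(rep(0, row_bytes - w))
  for (r in seq(h, 1)) {  # BMP stores rows bottom-up
    writeBin(c(as.raw(vals[r, ]), pad), con)
  }
  invisible(path)
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("8-bit grayscale image %d x %d px (w x h), %d trace px\n",
              ncol(x), nrow(x), sum(x < 128)))
  invisible(x)
}

#' @export
print.binary_image <- function(x, ...) {
  cat(sprintf("binary image %d x %d px (w x h), %d foreground px\n",
              ncol(x), nrow(x), sum(x == 1L)))
  invisible(x)
}
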