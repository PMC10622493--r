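# Multiplicative cascades: exact multifractal measures with closed-form
# spectra, used to verify the box-counting estimator, plus synthetic
# FTIR-like spectra whose fine-structure roughness is driven by the same
# cascade construction.

#' Deterministic or shuffled 1-D binomial cascade measure
#'
#' Recursive mass splitting on dyadic intervals: at each of `depth`
#' levels every cell's mass is divided between its two children with
#' weights `p` and `1 - p`. With `shuffle = FALSE` the `p` share always
#' goes left (deterministic); with `shuffle = TRUE` the assignment is
#' randomized per split (seeded), which leaves the multifractal spectrum
#' unchanged in theory.
#'
#' @param p left-child weight in (0, 1).
#' @param depth number of splitting levels (`>= 1`); the field has
#'   `2^depth` cells.
#' @param shuffle randomize the sub-cell assignment per split.
#' @param seed RNG seed used when `shuffle = TRUE`.
#' @return A 1-D [mass_field] with total mass 1.
#' @export
binomial_measure_1d <- function(p, depth, shuffle = FALSE, seed = 1L) {
  if (p <= 0 || p >= 1) stop("p must be in (0, 1)", call. = FALSE)
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  build <- function() {
    m <- 1
    for (lev in seq_len(depth)) {
      n <- length(m)
      w <- if (shuffle) {
        flip <- stats::runif(n) < 0.5
        rbind(ifelse(flip, 1 - p, p), ifelse(flip, p, 1 - p))
      } else {
        matrix(c(p, 1 - p), nrow = 2, ncol = n)
      }
      m <- as.vector(w * rep(m, each = 2))
    }
    m
  }
  m <- if (shuffle) with_seed(seed, build()) else build()
  mass_field(m)
}

#' Deterministic or shuffled 2-D multinomial cascade measure
#'
#' Quadrant splitting: each cell's mass is divided among its four
#' children with the given weights; with `shuffle = TRUE` the
#' weight-to-quadrant assignment is permuted per split. Without shuffle,
#' `weights[1]` goes to the top-left quadrant, then top-right,
#' bottom-left, bottom-right.
#'
#' @param weights four positive weights summing to 1 (within 1e-12).
#' @param depth splitting levels; the field is `2^depth x 2^depth`.
#' @param shuffle randomize quadrant assignment per split.
#' @param seed RNG seed used when `shuffle = TRUE`.
#' @return A 2-D [mass_field] with total mass 1.
#' @export
multinomial_measure_2d <- function(weights, depth, shuffle = FALSE,
                                   seed = 1L) {
  weights <- as.numeric(weights)
  if (length(weights) != 4 || any(weights <= 0) ||
      abs(sum(weights) - 1) > 1e-12) {
    stop("weights must be 4 positive values summing to 1", call. = FALSE)
  }
  if (depth < 1) stop("depth must be >= 1", call. = FALSE)
  build <- function() {
    m <- matrix(1, 1, 1)
    for (lev in seq_len(depth)) {
      n <- nrow(m)
      out <- matrix(0, 2 * n, 2 * n)
      tl <- seq_len(n)
      for (i in tl) for (j in tl) {
        w <- if (shuffle) sample(weights) else weights
        r <- 2 * i - 1; cc <- 2 * j - 1
        out[r, cc] <- m[i, j] * w[1]       # top-left
        out[r, cc + 1] <- m[i, j] * w[2]   # top-right
        out[r + 1, cc] <- m[i, j] * w[3]   # bottom-left
        out[r + 1, cc + 1] <- m[i, j] * w[4]
      }
      m <- out
    }
    m
  }
  m <- if (shuffle) with_seed(seed, build()) else build()
  mass_field(m)
}

#' Closed-form mass exponents of a multiplicative cascade
#'
#' For a cascade with branch weights `w` and scale ratio 1/2 per level
#' (binomial pairs in 1-D, quadruples in 2-D),
#' `tau(q) = -log2(sum(w^q))`. The uniform pair gives `tau = q - 1`
#' (D = 1); the uniform quadruple gives `tau = 2(q - 1)` (D = 2).
#'
#' @param weights positive branch weights summing to 1.
#' @param q moment order(s).
#' @return `tau(q)`, vectorized over `q`.
#' @export
theory_tau <- function(weights, q) {
  stopifnot(all(weights > 0), abs(sum(weights) - 1) < 1e-9)
  vapply(q, function(qq) -log2(sum(weights^qq)), 0)
}

#' Closed-form generalized dimensions of a cascade
#'
#' `D(q) = tau(q)/(q - 1)` with the entropy limit
#' `D(1) = -sum(w * log2(w))` at q = 1.
#'
#' @inheritParams theory_tau
#' @return `D(q)`, vectorized over `q`.
#' @export
theory_dimension <- function(weights, q) {
  vapply(q, function(qq) {
    if (abs(qq - 1) < 1e-12) {
      -sum(weights * log2(weights))
    } else {
      theory_tau(weights, qq) / (qq - 1)
    }
  }, 0)
}

#' Closed-form singularity spectrum of a cascade
#'
#' `alpha(q) = -sum(w^q log w) / (log 2 * sum(w^q))` and
#' `f = q * alpha - tau`. As `q -> +Inf`, `alpha -> -log2(max w)`
#' (`alpha_min`); as `q -> -Inf`, `alpha -> -log2(min w)` (`alpha_max`).
#'
#' @inheritParams theory_tau
#' @return List with vectors `alpha` and `f`.
#' @export
theory_alpha_f <- function(weights, q) {
  alpha <- vapply(q, function(qq) {
    wq <- weights^qq
    -sum(wq * log(weights)) / (log(2) * sum(wq))
  }, 0)
  list(alpha = alpha, f = q * alpha - theory_tau(weights, q))
}

#' Synthetic FTIR-like cell spectrum with cascade roughness
#'
#' Emulates a mid-IR absorbance spectrum of a cell suspension over
#' 4000-650 cm^-1: a sum of Gaussian absorption bands (default placements
#' are amide-I/II, OH/NH stretch, CH stretch and phosphate-like bands —
#' fixture conventions, not measured values), a zero-mean fine-structure
#' texture, and a small white detector-noise floor.
#'
#' The texture is the centered logarithm of a shuffled binomial cascade
#' measure — a long-range-correlated field whose fluctuations live on
#' every dyadic scale of the wavenumber axis. Its standard deviation is
#' set by the cascade itself: per level the log-multipliers are
#' `log(2p)` and `log(2(1-p))`, so a more skewed cascade (smaller
#' `roughness_p`) yields an intrinsically rougher, more intermittent
#' texture with no per-realization rescaling. This makes `roughness_p`
#' the fixture's stand-in for metastatic phenotype: smaller p, rougher
#' fine structure, larger downstream multifractal number;
#' `roughness_p = 0.5` gives a flat texture (noise floor only).
#'
#' @param bands matrix or data.frame with columns center (cm^-1), width
#'   (Gaussian sigma, cm^-1) and amplitude (AU).
#' @param roughness_p cascade parameter in (0, 0.5].
#' @param roughness_amp texture gain in AU per unit of centered log-mass
#'   (the realized texture SD is `roughness_amp` times the cascade's
#'   log-mass SD, roughly 2.3 at p = 0.2 and 0.33 at p = 0.45 for depth
#'   11).
#' @param noise_amp SD of the additive white noise floor in AU,
#'   emulating detector noise.
#' @param n_points number of spectral points.
#' @param wmin,wmax spectral range in cm^-1.
#' @param seed RNG seed (cascade shuffling and noise).
#' @param meta extra metadata stored on the spectrum.
#' @return An [ftir_spectrum] with nonnegative absorbance.
#' @export
synth_ftir_spectrum <- function(bands = default_bands(),
                                roughness_p = 0.3, roughness_amp = 0.05,
                                noise_amp = 0.008,
                                n_points = 2048L, wmin = 650, wmax = 4000,
                                seed = 1L, meta = list()) {
  if (roughness_p <= 0 || roughness_p > 0.5) {
    stop("roughness_p must be in (0, 0.5]", call. = FALSE)
  }
  bands <- as.matrix(bands)
  if (ncol(bands) != 3) stop("bands needs 3 columns", call. = FALSE)
  if (any(bands[, 1] < wmin | bands[, 1] > wmax)) {
    stop("band centers must lie within the spectral range", call. = FALSE)
  }
  if (any(bands[, 3] < 0)) stop("band amplitudes must be >= 0", call. = FALSE)
  w <- seq(wmax, wmin, length.out = n_points)
  base <- rep(0, n_points)
  for (b in seq_len(nrow(bands))) {
    base <- base + bands[b, 3] * exp(-(w - bands[b, 1])^2 /
                                       (2 * bands[b, 2]^2))
  }
  if (roughness_amp > 0 && roughness_p < 0.5) {
    depth <- ceiling(log2(n_points))
    fld <- binomial_measure_1d(roughness_p, depth, shuffle = TRUE,
                               seed = seed)
    lm <- log(fld$mass[seq_len(n_points)])
    base <- base + roughness_amp * (lm - mean(lm))
  }
  if (noise_amp > 0) {
    base <- base + with_seed(seed + 1L, stats::rnorm(n_points,
                                                     sd = noise_amp))
  }
  meta <- utils::modifyList(list(roughness_p = roughness_p,
                                 roughness_amp = roughness_amp,
                                 noise_amp = noise_amp,
                                 seed = seed), as.list(meta))
  ftir_spectrum(w, pmax(base, 0), meta)
}

#' Default synthetic band placements
#'
#' Five Gaussian bands loosely following cell-suspension mid-IR features:
#' OH/NH stretch (3300), CH stretch (2925), amide I (1650), amide II
#' (1545) and a phosphate/carbohydrate band (1080). Columns: center
#' (cm^-1), sigma (cm^-1), amplitude (AU).
#'
#' @return A 5 x 3 numeric matrix.
#' @export
default_bands <- function() {
  matrix(c(3300, 200, 0.6,
           2925, 60, 0.3,
           1650, 40, 0.9,
           1545, 40, 0.6,
           1080, 60, 0.4),
         ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("center", "width", "amplitude")))
}

#' Mix two spectra at a cancer-cell fraction
#'
#' Pointwise convex combination `(1 - phi) * healthy + phi * cancer` on a
#' shared wavenumber grid, emulating a suspension in which a fraction
#' `phi` of the cells is cancerous. `phi` is recorded in the result's
#' metadata.
#'
#' @param healthy,cancer [ftir_spectrum] objects on identical grids
#'   (resample first if needed).
#' @param phi cancer-cell fraction in `[0, 1]`.
#' @return The mixed [ftir_spectrum].
#' @export
mix_spectra <- function(healthy, cancer, phi) {
  stopifnot(inherits(healthy, "ftir_spectrum"),
            inherits(cancer, "ftir_spectrum"))
  if (phi < 0 || phi > 1) stop("phi must be in [0, 1]", call. = FALSE)
  if (length(healthy$wavenumbers) != length(cancer$wavenumbers) ||
      max(abs(healthy$wavenumbers - cancer$wavenumbers)) > 1e-6) {
    stop("wavenumber grids differ; resample_uniform() both spectra first",
         call. = FALSE)
  }
  meta <- utils::modifyList(healthy$meta, list(phi = phi))
  ftir_spectrum(healthy$wavenumbers,
                (1 - phi) * healthy$absorbance + phi * cancer$absorbance,
                meta)
}
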