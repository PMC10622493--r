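#' Box-counting configuration for multifractal estimation
#'
#' Defaults mirror the FracLac-style protocol used for spectrum trace
#' images: moment orders Q from -10 to 10, 100 box sizes, smallest box
#' edge 10 px, largest box edge 60% of the smaller image dimension.
#'
#' @param q_min,q_max bounds of the moment-order grid (dimensionless).
#' @param q_step grid spacing; the grid is `seq(q_min, q_max, q_step)`.
#' @param n_sizes number of box sizes requested (duplicates after integer
#'   rounding are dropped).
#' @param min_box_px smallest box edge in pixels.
#' @param max_image_frac largest box edge as a fraction of the smaller
#'   image dimension (0 < frac <= 1).
#' @param n_grid_origins number of grid origins; 1 uses the fixed origin
#'   (0,0), more than 1 averages log-moments over seeded random offsets.
#' @param fit_min_r2 minimum per-Q regression R^2 for a Q value to enter
#'   summary quantities such as `alpha_min`/`alpha_max`.
#' @param sizes optional explicit integer box sizes, overriding
#'   generation (e.g. exact dyadic sizes for cascade verification).
#' @param include_partial include partial boxes at the far image edge
#'   (their mass counts); set `FALSE` to discard them.
#' @param regression `"anchored"` (default) constrains every scaling fit
#'   through the whole-image point `(log L, 0)` where `L = max(dims)` and
#'   all moment sums vanish exactly — the ratio form
#'   `log Z / log(eps/L)` of the scaling definition, under which D(Q) is
#'   a positive mixture of per-scale Renyi entropies and the ordering
#'   D(0) >= D(1) >= D(2), the single f(alpha) hump and the Q = 1
#'   tangency hold exactly on any input. `"free"` is the unconstrained
#'   least-squares slope.
#' @param seed RNG seed for random grid origins.
#' @return A list of class `"mfa_config"`.
#' @export
mfa_config <- function(q_min = -10, q_max = 10, q_step = 0.25,
                       n_sizes = 100L, min_box_px = 10L,
                       max_image_frac = 0.60, n_grid_origins = 1L,
                       fit_min_r2 = 0.90, sizes = NULL,
                       include_partial = TRUE,
                       regression = c("anchored", "free"), seed = 1L) {
  regression <- match.arg(regression)
  if (!(q_min < q_max)) stop("q_min must be < q_max", call. = FALSE)
  if (q_step <= 0) stop("q_step must be positive", call. = FALSE)
  if (n_sizes < 3) stop("n_sizes must be >= 3", call. = FALSE)
  if (min_box_px < 1) stop("min_box_px must be >= 1", call. = FALSE)
  if (max_image_frac <= 0 || max_image_frac > 1) {
    stop("max_image_frac must be in (0, 1]", call. = FALSE)
  }
  if (!is.null(sizes)) {
    sizes <- sort(unique(as.integer(sizes)))
    if (any(sizes < 1)) stop("explicit sizes must be >= 1", call. = FALSE)
    if (length(sizes) < 3) stop("need >= 3 box sizes", call. = FALSE)
  }
  structure(list(q_min = q_min, q_max = q_max, q_step = q_step,
                 n_sizes = as.integer(n_sizes),
                 min_box_px = as.integer(min_box_px),
                 max_image_frac = max_image_frac,
                 n_grid_origins = as.integer(n_grid_origins),
                 fit_min_r2 = fit_min_r2, sizes = sizes,
                 include_partial = isTRUE(include_partial),
                 regression = regression,
                 seed = as.integer(seed)),
            class = "mfa_config")
}

#' @keywords internal
#' @noRd
q_grid <- function(cfg) seq(cfg$q_min, cfg$q_max, by = cfg$q_step)

#' Construct a mass field
#'
#' A mass field is a nonnegative per-cell mass array (1-D vector or 2-D
#' matrix) with positive total mass: the common currency of the
#' box-counting estimator. Binary images are the special case with mass
#' in {0, 1}; exact cascade measures feed the same estimator.
#'
#' @param mass nonnegative numeric vector (1-D field) or matrix (2-D).
#' @return An object of class `"mass_field"` with elements `mass`, `dims`
#'   and `total_mass`.
#' @export
mass_field <- function(mass) {
  if (!(is.numeric(mass) || is.integer(mass))) {
    stop("mass must be numeric", call. = FALSE)
  }
  if (any(!is.finite(mass))) stop("mass must be finite", call. = FALSE)
  if (any(mass < 0)) stop("mass must be nonnegative", call. = FALSE)
  total <- sum(mass)
  if (total <= 0) stop("total mass must be positive", call. = FALSE)
  dims <- if (is.matrix(mass)) dim(mass) else length(mass)
  structure(list(mass = mass, dims = dims, total_mass = total),
            class = "mass_field")
}

#' @export
print.mass_field <- function(x, ...) {
  cat(sprintf("mass field: %s cells, total mass %.6g, %d nonzero\n",
              paste(x$dims, collapse = " x "), x$total_mass,
              sum(x$mass > 0)))
  invisible(x)
}

#' Convert a binary image to a mass field
#'
#' Each foreground pixel carries unit mass; total mass is the foreground
#' pixel count.
#'
#' @param img a `"binary_image"` (or any 0/1 matrix with >= 1 foreground
#'   pixel).
#' @return A 2-D [mass_field].
#' @export
image_to_mass_field <- function(img) {
  m <- unclass(img)
  if (!is.matrix(m)) stop("img must be a matrix", call. = FALSE)
  if (!all(m %in% c(0L, 1L))) stop("img must be a 0/1 mask", call. = FALSE)
  if (!any(m == 1L)) stop("image has no foreground pixels", call. = FALSE)
  mass_field(m)
}

#' Generate box sizes for the grid scan
#'
#' Up to `n_sizes` distinct integer edge lengths, approximately
#' geometrically spaced over `[min_box_px, floor(max_image_frac *
#' min(dims))]`, endpoints included.
#'
#' @param dims integer cell counts per axis (length 1 or 2).
#' @param cfg an [mfa_config].
#' @return Strictly increasing integer vector of box edges.
#' @export
make_box_sizes <- function(dims, cfg = mfa_config()) {
  lo <- cfg$min_box_px
  hi <- as.integer(floor(cfg$max_image_frac * min(dims)))
  if (hi <= lo) {
    stop(sprintf(paste0("no feasible box sizes: min_box_px=%d, ",
                        "max edge floor(%.2f * %d)=%d"),
                 lo, cfg$max_image_frac, min(dims), hi), call. = FALSE)
  }
  s <- unique(as.integer(round(exp(seq(log(lo), log(hi),
                                       length.out = cfg$n_sizes)))))
  s <- s[s >= lo & s <= hi]
  sort(unique(c(lo, s, hi)))
}

#' Normalized box probabilities at one scale
#'
#' Tiles the field from a grid origin into boxes of the given edge
#' (partial boxes at the edges included by default, their mass counting)
#' and returns the normalized masses of occupied boxes.
#'
#' @param field a [mass_field].
#' @param size box edge in cells.
#' @param origin integer grid offset per axis, each in `[0, size)`. Cells
#'   before the origin fall in a partial box at the near edge.
#' @param include_partial drop boxes not fully inside the field if
#'   `FALSE`.
#' @return Numeric vector of occupied-box probabilities summing to 1.
#' @export
box_probabilities <- function(field, size, origin = c(0L, 0L),
                              include_partial = TRUE) {
  stopifnot(inherits(field, "mass_field"))
  size <- as.integer(size)
  if (size < 1) stop("size must be >= 1", call. = FALSE)
  origin <- as.integer(origin)
  if (any(origin < 0) || any(origin >= size)) {
    stop("origin components must lie in [0, size)", call. = FALSE)
  }
  m <- field$mass
  if (is.matrix(m)) {
    nr <- nrow(m); nc <- ncol(m)
    ri <- (seq_len(nr) - 1L + size - origin[1]) %/% size
    ci <- (seq_len(nc) - 1L + size - origin[2]) %/% size
    if (!include_partial) {
      # a box is complete iff all `size` of its cells exist on each axis
      rfull <- tabulate(ri + 1L)
      cfull <- tabulate(ci + 1L)
      keep_r <- rfull[ri + 1L] == size
      keep_c <- cfull[ci + 1L] == size
      sel <- outer(keep_r, keep_c, "&")
      m <- m * sel
    }
    ids <- outer(ri, ci, function(a, b) a * (max(ci) + 1L) + b)
    tot <- as.vector(rowsum(as.vector(m), as.vector(ids)))
  } else {
    n <- length(m)
    ids <- (seq_len(n) - 1L + size - origin[1]) %/% size
    if (!include_partial) {
      full <- tabulate(ids + 1L)
      m <- m * (full[ids + 1L] == size)
    }
    tot <- as.vector(rowsum(m, ids))
  }
  tot <- tot[tot > 0]
  if (!length(tot)) stop("no occupied boxes at this scale", call. = FALSE)
  tot / sum(tot)
}

# Per-scale moment statistics over the Q grid, averaged across grid
# origins. For each size and q this yields
#   logZ  = log sum_i P_i^q                     (partition function)
#   s_num = sum_i mu_i log P_i,  mu_i = P_i^q / Z   (Chhabra-Jensen)
#   s_den = sum_i mu_i log mu_i = q*s_num - logZ
# all computed in log-space so |q| = 10 on P_i as small as 1/total_mass
# cannot overflow.
#' @keywords internal
#' @noRd
scale_moments <- function(field, sizes, q, cfg) {
  nd <- length(field$dims)
  origins <- list(rep(0L, max(nd, 1L)))
  # random origins are drawn once as uniform fractions and scaled per
  # size, so origin < size holds at every scale
  extra <- if (cfg$n_grid_origins > 1L) {
    with_seed(cfg$seed,
              lapply(seq_len(cfg$n_grid_origins - 1L),
                     function(i) stats::runif(nd)))
  } else {
    list()
  }
  nq <- length(q)
  logZ <- matrix(NA_real_, length(sizes), nq)
  s_num <- matrix(NA_real_, length(sizes), nq)
  n_boxes <- integer(length(sizes))
  for (k in seq_along(sizes)) {
    sz <- sizes[k]
    ors <- c(list(rep(0L, nd)),
             lapply(extra, function(f) as.integer(floor(f * sz))))
    acc_z <- matrix(NA_real_, length(ors), nq)
    acc_n <- matrix(NA_real_, length(ors), nq)
    nb <- 0L
    for (oi in seq_along(ors)) {
      # an offset grid can capture no complete occupied box when partial
      # boxes are discarded; such origins are skipped, not fatal
      P <- tryCatch(box_probabilities(field, sz, ors[[oi]],
                                      include_partial = cfg$include_partial),
                    error = function(e) NULL)
      if (is.null(P)) next
      if (nb == 0L) nb <- length(P)
      L <- log(P)
      for (iq in seq_len(nq)) {
        a <- q[iq] * L
        lz <- log_sum_exp(a)
        mu <- exp(a - lz)
        acc_z[oi, iq] <- lz
        acc_n[oi, iq] <- sum(mu * L)
      }
    }
    if (all(is.na(acc_z[, 1]))) {
      stop("no grid origin yields occupied boxes at size ", sz,
           call. = FALSE)
    }
    logZ[k, ] <- colMeans(acc_z, na.rm = TRUE)
    s_num[k, ] <- colMeans(acc_n, na.rm = TRUE)
    n_boxes[k] <- nb
  }
  qmat <- matrix(q, nrow = length(sizes), ncol = nq, byrow = TRUE)
  list(sizes = sizes, q = q, logZ = logZ, s_num = s_num,
       s_den = qmat * s_num - logZ, n_boxes = n_boxes,
       anchor = if (cfg$regression == "anchored") log(max(field$dims))
                else NULL)
}

#' Partition-function moments of one probability vector
#'
#' For occupied-box probabilities `P` and moment order `q`, returns
#' `Z = sum(P^q)`, `s_num = sum(mu * log(P))` and
#' `s_den = sum(mu * log(mu))` with `mu = P^q / Z` — the per-scale sums
#' underlying the mass exponents and the direct singularity-spectrum
#' estimator. Computed in log-space.
#'
#' @param P positive probabilities summing to 1.
#' @param q moment order.
#' @return List with `Z`, `s_num`, `s_den`, `log_Z`.
#' @export
partition_moments <- function(P, q) {
  if (any(P <= 0)) stop("all P must be > 0 (occupied boxes only)",
                        call. = FALSE)
  L <- log(P)
  a <- q * L
  lz <- log_sum_exp(a)
  mu <- exp(a - lz)
  s_num <- sum(mu * L)
  list(Z = exp(lz), s_num = s_num, s_den = q * s_num - lz, log_Z = lz)
}

#' Mass exponents tau(Q) by scaling regression
#'
#' `tau(Q)` is the least-squares slope of `log Z(Q, eps)` against
#' `log eps` over the box-size range (log-moments already averaged over
#' grid origins). Sign convention: the uniform plane measure has
#' `tau(Q) = 2(Q - 1)`, so `D = tau / (Q - 1)` is positive.
#'
#' @param moments output of the internal per-scale moment pass (a list
#'   with `sizes`, `q`, `logZ`, and `anchor` when the anchored ratio-form
#'   fit is in use).
#' @return List with `tau` and per-Q `r2`.
#' @export
mass_exponents <- function(moments) {
  x <- log(moments$sizes)
  if (length(x) < 3) stop("need >= 3 scales", call. = FALSE)
  nq <- length(moments$q)
  tau <- numeric(nq); r2 <- numeric(nq)
  for (iq in seq_len(nq)) {
    ft <- scaling_fit(x, moments$logZ[, iq], moments$anchor)
    tau[iq] <- ft$slope
    r2[iq] <- ft$r2
  }
  list(tau = tau, r2 = r2)
}

#' @keywords internal
#' @noRd
scaling_fit <- function(x, y, anchor = NULL) {
  if (is.null(anchor)) fit_line(x, y) else fit_anchored(x, y, anchor)
}

#' Generalized (Renyi) dimensions D(Q)
#'
#' `D(Q) = tau(Q) / (Q - 1)` away from Q = 1; at Q = 1 the information
#' dimension is taken as the slope of `sum(P log P)` against `log eps`
#' (the entropy limit), never by division.
#'
#' @param tau mass exponents on the Q grid.
#' @param moments per-scale moments (for the Q = 1 entropy path).
#' @param q the Q grid.
#' @return List with `d` and `r2_d1` (R^2 of the entropy regression, NA
#'   when 1 is not on the grid).
#' @export
generalized_dimensions <- function(tau, moments, q) {
  d <- rep(NA_real_, length(q))
  at1 <- abs(q - 1) < 1e-12
  d[!at1] <- tau[!at1] / (q[!at1] - 1)
  r2_d1 <- NA_real_
  if (any(at1)) {
    iq <- which(at1)[1]
    ft <- scaling_fit(log(moments$sizes), moments$s_num[, iq],
                      moments$anchor)
    d[at1] <- ft$slope
    r2_d1 <- ft$r2
  }
  list(d = d, r2_d1 = r2_d1)
}

#' Direct (Chhabra-Jensen) singularity spectrum
#'
#' `alpha(Q)` is the slope of `sum(mu log P)` and `f(Q)` the slope of
#' `sum(mu log mu)` against `log eps`, with `mu = P^Q / sum(P^Q)` — the
#' direct estimator that avoids numerically differentiating tau(Q).
#'
#' @param moments per-scale moments.
#' @return List with `alpha`, `f`, `r2_alpha`, `r2_f`.
#' @export
chhabra_jensen <- function(moments) {
  x <- log(moments$sizes)
  if (length(x) < 3) stop("need >= 3 scales", call. = FALSE)
  nq <- length(moments$q)
  alpha <- numeric(nq); f <- numeric(nq)
  r2a <- numeric(nq); r2f <- numeric(nq)
  for (iq in seq_len(nq)) {
    fa <- scaling_fit(x, moments$s_num[, iq], moments$anchor)
    ff <- scaling_fit(x, moments$s_den[, iq], moments$anchor)
    alpha[iq] <- fa$slope; r2a[iq] <- fa$r2
    f[iq] <- ff$slope; r2f[iq] <- ff$r2
  }
  list(alpha = alpha, f = f, r2_alpha = r2a, r2_f = r2f)
}

#' Legendre-transform singularity spectrum
#'
#' `alpha = d tau / dQ` by central finite differences on the Q grid
#' (one-sided at the ends), then `f = Q * alpha - tau`. Retained as a
#' cross-check channel against the direct estimator.
#'
#' @param tau mass exponents on the grid.
#' @param q the Q grid.
#' @return List with `alpha` and `f`.
#' @export
legendre_spectrum <- function(tau, q) {
  n <- length(q)
  stopifnot(length(tau) == n, n >= 3)
  alpha <- numeric(n)
  alpha[1] <- (tau[2] - tau[1]) / (q[2] - q[1])
  alpha[n] <- (tau[n] - tau[n - 1]) / (q[n] - q[n - 1])
  if (n > 2) {
    alpha[2:(n - 1)] <- (tau[3:n] - tau[1:(n - 2)]) / (q[3:n] - q[1:(n - 2)])
  }
  list(alpha = alpha, f = q * alpha - tau)
}

#' Full multifractal analysis of an image or mass field
#'
#' Runs the whole estimation pipeline: mass field, box sizes, per-scale
#' occupied-box probabilities (averaged over grid origins), mass
#' exponents tau(Q), generalized dimensions D(Q) with the entropy-limit
#' path at Q = 1, the direct (Chhabra-Jensen) singularity spectrum
#' (primary) and the Legendre transform (cross-check). Summary scalars
#' (`alpha_min`, `alpha_max`, `delta_alpha`, `alpha0`, `f_max`, D(0..2))
#' are taken over Q values whose fits pass `fit_min_r2`; violations of
#' the expected spectrum geometry are reported as warnings, never
#' silently dropped.
#'
#' @param x a `"binary_image"`, a [mass_field], a 0/1 matrix, or a
#'   nonnegative numeric vector/matrix.
#' @param cfg an [mfa_config].
#' @param check emit warnings when spectrum invariants (D(0) >= D(1) >=
#'   D(2), single hump, Q = 1 tangency, alpha monotone) fail beyond
#'   `check_tol`.
#' @param check_tol tolerance for the invariant checks.
#' @return An object of class `"multifractal_spectrum"`: per-Q `q`,
#'   `tau`, `d`, `alpha`, `f`, `alpha_legendre`, `f_legendre`, `h`
#'   (= (tau + D0)/Q, Q != 0), fit diagnostics `r2_tau`, `r2_alpha`,
#'   `r2_f`, summary scalars, the config, and `diagnostics` (invariant
#'   flags).
#' @examples
#' fld <- multinomial_measure_2d(c(0.4, 0.3, 0.2, 0.1), depth = 6)
#' ms <- analyze(fld, mfa_config(sizes = 2^(0:5)))
#' ms$d0; ms$delta_alpha
#' @export
analyze <- function(x, cfg = mfa_config(), check = TRUE, check_tol = 0.05) {
  field <- if (inherits(x, "mass_field")) {
    x
  } else if (inherits(x, "binary_image")) {
    image_to_mass_field(x)
  } else if (is.matrix(x) && all(x %in% c(0, 1))) {
    image_to_mass_field(x)
  } else {
    mass_field(x)
  }
  sizes <- if (!is.null(cfg$sizes)) {
    s <- cfg$sizes[cfg$sizes <= min(field$dims)]
    if (length(s) < 3) stop("fewer than 3 explicit sizes fit the field",
                            call. = FALSE)
    s
  } else {
    make_box_sizes(field$dims, cfg)
  }
  if (length(sizes) < 3) stop("need >= 3 box sizes", call. = FALSE)
  q <- q_grid(cfg)
  mom <- scale_moments(field, sizes, q, cfg)
  me <- mass_exponents(mom)
  gd <- generalized_dimensions(me$tau, mom, q)
  cj <- chhabra_jensen(mom)
  lg <- legendre_spectrum(me$tau, q)

  ok <- cj$r2_alpha >= cfg$fit_min_r2 & me$r2 >= cfg$fit_min_r2
  if (!any(ok)) ok <- rep(TRUE, length(q))  # fall back to full grid
  at <- function(v, qq) {
    i <- which(abs(q - qq) < 1e-9)
    if (length(i)) v[i[1]] else stats::approx(q, v, xout = qq, rule = 2)$y
  }
  d0 <- at(gd$d, 0); d1 <- at(gd$d, 1); d2 <- at(gd$d, 2)
  alpha_min <- min(cj$alpha[ok]); alpha_max <- max(cj$alpha[ok])
  h <- ifelse(abs(q) < 1e-12, NA_real_, (me$tau + d0) / q)

  res <- structure(list(
    q = q, tau = me$tau, d = gd$d, alpha = cj$alpha, f = cj$f,
    alpha_legendre = lg$alpha, f_legendre = lg$f, h = h,
    r2_tau = me$r2, r2_alpha = cj$r2_alpha, r2_f = cj$r2_f,
    fit_ok = ok,
    alpha_min = alpha_min, alpha_max = alpha_max,
    delta_alpha = alpha_max - alpha_min,
    alpha0 = at(cj$alpha, 0), f_max = max(cj$f[ok]),
    d0 = d0, d1 = d1, d2 = d2,
    sizes = sizes, n_boxes = mom$n_boxes,
    config = cfg, config_hash = config_hash(cfg)
  ), class = "multifractal_spectrum")

  diag <- list(
    ordering = (d0 >= d1 - check_tol) && (d1 >= d2 - check_tol),
    hump_at_q0 = abs(at(cj$f, 0) - max(cj$f[ok])) <= check_tol,
    q1_tangency = abs(at(cj$f, 1) - at(cj$alpha, 1)) <= check_tol,
    alpha_monotone = all(diff(cj$alpha[ok]) <= check_tol),
    all_fits_pass = all(cj$r2_alpha >= cfg$fit_min_r2 &
                          me$r2 >= cfg$fit_min_r2)
  )
  res$diagnostics <- diag
  if (check) {
    bad <- names(diag)[!vapply(diag[1:4], isTRUE, TRUE)]
    if (length(bad)) {
      warning("multifractal spectrum invariant(s) violated beyond tol ",
              check_tol, ": ", paste(bad, collapse = ", "),
              " (D0=", signif(d0, 4), ", D1=", signif(d1, 4),
              ", D2=", signif(d2, 4), ")", call. = FALSE)
    }
  }
  res
}

#' @export
print.multifractal_spectrum <- function(x, ...) {
  cat("Multifractal spectrum (box counting)\n")
  cat(sprintf("  Q in [%g, %g] step %g; %d box sizes in [%d, %d]\n",
              min(x$q), max(x$q), x$q[2] - x$q[1], length(x$sizes),
              min(x$sizes), max(x$sizes)))
  cat(sprintf("  D(0)=%.4f  D(1)=%.4f  D(2)=%.4f\n", x$d0, x$d1, x$d2))
  cat(sprintf("  alpha in [%.4f, %.4f]  delta_alpha=%.4f  f_max=%.4f\n",
              x$alpha_min, x$alpha_max, x$delta_alpha, x$f_max))
  if (!all(x$fit_ok)) {
    cat(sprintf("  %d/%d Q values failed the R^2 >= %.2f fit gate\n",
                sum(!x$fit_ok), length(x$q), x$config$fit_min_r2))
  }
  invisible(x)
}

#' @export
as.data.frame.multifractal_spectrum <- function(x, ...) {
  data.frame(q = x$q, tau = x$tau, d = x$d, alpha = x$alpha, f = x$f,
             alpha_legendre = x$alpha_legendre, f_legendre = x$f_legendre,
             h = x$h, r2_tau = x$r2_tau, r2_alpha = x$r2_alpha,
             r2_f = x$r2_f, fit_ok = x$fit_ok)
}

#' Write a multifractal spectrum as CSV and/or a JSON summary
#'
#' @param ms a `"multifractal_spectrum"`.
#' @param csv_path,json_path output paths (either may be `NULL` to skip).
#' @return Invisibly, the written paths.
#' @export
write_mfa <- function(ms, csv_path = NULL, json_path = NULL) {
  stopifnot(inherits(ms, "multifractal_spectrum"))
  if (!is.null(csv_path)) {
    utils::write.csv(as.data.frame(ms), csv_path, row.names = FALSE)
  }
  if (!is.null(json_path)) {
    summ <- list(alpha_min = ms$alpha_min, alpha_max = ms$alpha_max,
                 delta_alpha = ms$delta_alpha, alpha0 = ms$alpha0,
                 d0 = ms$d0, d1 = ms$d1, d2 = ms$d2, f_max = ms$f_max,
                 diagnostics = ms$diagnostics,
                 config = unclass(ms$config)[!vapply(unclass(ms$config),
                                                     is.null, TRUE)],
                 config_hash = ms$config_hash, seed = ms$config$seed)
    jsonlite::write_json(summ, json_path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(c(csv = csv_path, json = json_path))
}
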