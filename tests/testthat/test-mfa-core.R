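test_that("mass fields validate their invariants", {
  f <- mass_field(matrix(1, 4, 4))
  expect_equal(f$total_mass, 16)
  expect_equal(image_to_mass_field(matrix(c(0L, 1L, 0L, 0L), 2))$total_mass, 1)
  expect_error(mass_field(matrix(0, 2, 2)), "positive")
  expect_error(mass_field(c(1, -1)), "nonnegative")
  expect_error(image_to_mass_field(matrix(0L, 2, 2)), "foreground")
  expect_error(image_to_mass_field(matrix(0.5, 2, 2)), "0/1")

  s <- ftir_spectrum(seq(4000, 650, length.out = 300), rep(0.5, 300))
  img <- binarize(render_trace(s, raster_config(width = 256, height = 128)))
  expect_equal(image_to_mass_field(img)$total_mass, 256)
})

test_that("box sizes follow the grid-scan protocol bounds", {
  cfg <- mfa_config()
  sz <- make_box_sizes(c(128, 1024), cfg)
  expect_equal(min(sz), 10)
  expect_equal(max(sz), 76)          # floor(0.60 * 128)
  expect_true(all(diff(sz) > 0))
  expect_lte(length(sz), 100)

  expect_equal(make_box_sizes(c(100, 100), mfa_config(n_sizes = 3,
                                                      max_image_frac = 0.4)),
               c(10, 20, 40))
  expect_error(make_box_sizes(c(16, 16), cfg), "no feasible")
})

test_that("box probabilities tile correctly, partial boxes included", {
  f <- mass_field(matrix(1, 4, 4))
  expect_equal(sort(box_probabilities(f, 2)), rep(0.25, 4))
  expect_equal(box_probabilities(f, 4), 1)
  # offset origin splits the 4x4 field into partial strips: 3x3 grid
  p <- box_probabilities(f, 2, origin = c(1, 1))
  expect_length(p, 9)
  expect_equal(sum(p), 1)
  expect_error(box_probabilities(f, 2, origin = c(2, 0)), "origin")

  # 1-D binomial cascade aggregates match the direct construction
  fld <- binomial_measure_1d(0.25, 6)
  for (k in c(1, 2, 4)) {
    p <- box_probabilities(fld, 2^k)
    direct <- as.vector(tapply(fld$mass, (seq_along(fld$mass) - 1) %/% 2^k,
                               sum))
    expect_equal(p, direct[direct > 0], tolerance = 1e-12)
  }
})

test_that("partition moments match hand arithmetic and survive extreme Q", {
  pm <- partition_moments(rep(0.25, 4), 2)
  expect_equal(pm$Z, 0.25)
  expect_equal(partition_moments(c(0.625, 0.375), 2)$Z, 0.53125)
  expect_equal(partition_moments(runif(7, 0.05, 0.2), 0)$Z, 7)

  # log-space survives |q| = 20 on probabilities ~ 1/total_mass
  tiny <- rep(1e-4, 1e4)
  pm2 <- partition_moments(tiny, 20)
  expect_true(is.finite(pm2$log_Z))
  pm3 <- partition_moments(tiny, -20)
  expect_true(is.finite(pm3$log_Z))
  expect_error(partition_moments(c(0.5, 0), 2), "> 0")
})

test_that("mass exponents recover closed forms on exact cascades", {
  ms <- analyze(binomial_measure_1d(0.25, 10), dyadic_cfg(10), check = FALSE)
  expect_equal(ms$tau[ms$q == 2], BIN25$tau2, tolerance = 1e-6)
  expect_equal(ms$tau[ms$q == 0], -1, tolerance = 1e-6)  # full 1-D support
  expect_equal(ms$tau[ms$q == 1], 0, tolerance = 1e-9)

  # uniform 2-D plane: tau(Q) = 2(Q - 1)
  msu <- analyze(mass_field(matrix(1, 64, 64)), dyadic_cfg(6), check = FALSE)
  expect_equal(msu$tau, 2 * (msu$q - 1), tolerance = 1e-9)
})

test_that("generalized dimensions use the entropy limit at Q = 1", {
  ms <- analyze(binomial_measure_1d(0.25, 10), dyadic_cfg(10), check = FALSE)
  expect_equal(ms$d1, BIN25$d1, tolerance = 1e-6)
  # the entropy-limit value splices continuously into the tau/(Q-1) curve
  d_near <- ms$d[abs(ms$q - 1) <= 0.25 + 1e-9]
  expect_equal(d_near, theory_dimension(BIN25$w, c(0.75, 1, 1.25)),
               tolerance = 1e-6)

  # p = 0.5 collapses to the uniform line: D(Q) = 1, f = alpha = D
  ms5 <- analyze(binomial_measure_1d(0.5, 10), dyadic_cfg(10), check = FALSE)
  expect_lt(max(abs(ms5$d - 1)), 1e-9)
  expect_lt(max(abs(ms5$alpha - 1)), 1e-9)
  expect_lt(max(abs(ms5$f - 1)), 1e-9)

  msu <- analyze(mass_field(matrix(1, 64, 64)), dyadic_cfg(6), check = FALSE)
  expect_lt(max(abs(msu$d - 2)), 1e-9)
})

test_that("direct estimator reaches the closed-form alpha limits", {
  ms <- analyze(binomial_measure_1d(0.25, 12), dyadic_cfg(12), check = FALSE)
  th <- theory_alpha_f(BIN25$w, ms$q)
  expect_lt(max(abs(ms$alpha - th$alpha)), 1e-9)
  expect_lt(max(abs(ms$f - th$f)), 1e-9)
  expect_equal(ms$alpha[ms$q == 10], BIN25$alpha_min, tolerance = 1e-3)
  expect_equal(ms$alpha[ms$q == -10], BIN25$alpha_max, tolerance = 1e-3)
})

test_that("Legendre transform inverts linear and cascade mass exponents", {
  q <- seq(-5, 5, 0.25)
  lg <- legendre_spectrum(2 * (q - 1), q)
  expect_equal(lg$alpha, rep(2, length(q)), tolerance = 1e-12)
  expect_equal(lg$f, rep(2, length(q)), tolerance = 1e-12)

  tau <- theory_tau(BIN25$w, q)
  th <- theory_alpha_f(BIN25$w, q)
  lg2 <- legendre_spectrum(tau, q)
  inner <- seq(2, length(q) - 1)
  expect_lt(max(abs(lg2$alpha[inner] - th$alpha[inner])), 0.01)  # O(step^2)
  # f at Q = 0 equals -tau(0) = D(0)
  expect_equal(lg2$f[q == 0], -tau[q == 0], tolerance = 1e-9)
})

test_that("analyze is deterministic and reports geometry diagnostics", {
  fld <- multinomial_measure_2d(c(0.4, 0.3, 0.2, 0.1), 6)
  a <- analyze(fld, dyadic_cfg(6), check = FALSE)
  b <- analyze(fld, dyadic_cfg(6), check = FALSE)
  expect_identical(a[setdiff(names(a), "config")],
                   b[setdiff(names(b), "config")])
  expect_true(all(unlist(a$diagnostics[1:4])))
  expect_s3_class(a, "multifractal_spectrum")

  df <- as.data.frame(a)
  expect_named(df, c("q", "tau", "d", "alpha", "f", "alpha_legendre",
                     "f_legendre", "h", "r2_tau", "r2_alpha", "r2_f",
                     "fit_ok"))
  # H(Q) = (tau + D0)/Q is finite off Q = 0 and NA at Q = 0
  expect_true(is.na(df$h[df$q == 0]))
  expect_true(all(is.finite(df$h[df$q != 0])))
})

test_that("grid-origin averaging keeps cascade recovery within tolerance", {
  fld <- binomial_measure_1d(0.25, 10)
  ms <- analyze(fld, dyadic_cfg(10, n_grid_origins = 4, seed = 11),
                check = FALSE)
  expect_equal(ms$d1, BIN25$d1, tolerance = 0.03)
  expect_equal(ms$tau[ms$q == 2], BIN25$tau2, tolerance = 0.03)
  # same seed, same result
  ms2 <- analyze(fld, dyadic_cfg(10, n_grid_origins = 4, seed = 11),
                 check = FALSE)
  expect_identical(ms$alpha, ms2$alpha)
})

test_that("analyze of a rendered trace lies between line and plane", {
  s <- synth_ftir_spectrum(seed = 4)
  ms <- analyze(spectrum_to_binary(s), mfa_config(), check = FALSE)
  expect_gte(ms$d0, 1)
  expect_lte(ms$d0, 2)
})

test_that("degenerate inputs are rejected with clear errors", {
  expect_error(analyze(mass_field(rep(1, 8)), mfa_config(sizes = c(16, 32, 64))),
               "fewer than 3")
  expect_error(mfa_config(q_min = 5, q_max = -5), "q_min")
  expect_error(mfa_config(n_sizes = 2), "n_sizes")
  expect_error(mfa_config(max_image_frac = 1.5), "max_image_frac")
})
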