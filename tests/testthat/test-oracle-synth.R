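test_that("binomial cascades conserve mass and hit exact cell values", {
  f <- binomial_measure_1d(0.25, 3)
  expect_length(f$mass, 8)
  expect_equal(f$total_mass, 1, tolerance = 1e-12)
  expect_equal(max(f$mass), 0.75^3)          # 0.421875
  expect_equal(min(f$mass), 0.25^3)

  expect_true(all(binomial_measure_1d(0.5, 7)$mass == 2^-7))

  # shuffling preserves the multiset of masses and conservation
  fs <- binomial_measure_1d(0.25, 6, shuffle = TRUE, seed = 3)
  expect_equal(sum(fs$mass), 1, tolerance = 1e-12)
  expect_equal(sort(fs$mass), sort(binomial_measure_1d(0.25, 6)$mass),
               tolerance = 1e-12)
  expect_identical(fs$mass,
                   binomial_measure_1d(0.25, 6, shuffle = TRUE, seed = 3)$mass)
  expect_error(binomial_measure_1d(1.2, 3), "p must be")
})

test_that("multinomial cascades split quadrants as constructed", {
  w <- c(0.4, 0.3, 0.2, 0.1)
  f <- multinomial_measure_2d(w, 2)
  expect_equal(dim(f$mass), c(4, 4))
  expect_equal(sum(f$mass), 1, tolerance = 1e-12)
  expect_equal(f$mass[1, 1], 0.16)           # top-left twice: 0.4 * 0.4
  expect_equal(f$mass[4, 4], 0.01)           # bottom-right twice

  u <- multinomial_measure_2d(rep(0.25, 4), 2)
  expect_true(all(abs(u$mass - 1 / 16) < 1e-12))
  expect_equal(sum(multinomial_measure_2d(w, 5, shuffle = TRUE,
                                          seed = 2)$mass), 1,
               tolerance = 1e-12)
  expect_error(multinomial_measure_2d(c(0.5, 0.5), 2), "4 positive")
})

test_that("theory curves match hand-computed constants", {
  expect_equal(theory_tau(rep(0.25, 4), c(-1, 0, 2)), 2 * c(-1, 0, 2) - 2)
  expect_equal(theory_tau(BIN25$w, 2), BIN25$tau2)
  expect_equal(theory_tau(BIN25$w, 1), 0)
  expect_equal(theory_dimension(BIN25$w, 1), BIN25$d1)
  expect_equal(theory_dimension(rep(0.25, 4), seq(-3, 3)), rep(2, 7))

  th <- theory_alpha_f(BIN25$w, c(0, 1, 50, -50))
  expect_equal(th$f[1], 1)                   # f(q=0) = support dimension
  expect_equal(th$f[2], th$alpha[2])         # tangency at q = 1
  expect_equal(th$alpha[3], BIN25$alpha_min, tolerance = 1e-6)
  expect_equal(th$alpha[4], BIN25$alpha_max, tolerance = 1e-6)
})

test_that("shuffled and unshuffled cascades have matching estimated spectra", {
  a <- analyze(binomial_measure_1d(0.3, 10), dyadic_cfg(10), check = FALSE)
  b <- analyze(binomial_measure_1d(0.3, 10, shuffle = TRUE, seed = 5),
               dyadic_cfg(10), check = FALSE)
  sel <- abs(a$q) <= 5
  expect_lt(max(abs(a$tau[sel] - b$tau[sel])), 0.05)
  expect_lt(max(abs(a$alpha[sel] - b$alpha[sel])), 0.05)
})

test_that("synthetic spectra are reproducible, nonnegative and band-accurate", {
  s1 <- synth_ftir_spectrum(seed = 9)
  s2 <- synth_ftir_spectrum(seed = 9)
  expect_identical(s1$absorbance, s2$absorbance)
  expect_true(all(s1$absorbance >= 0))
  expect_length(s1, 2048)
  expect_equal(max(s1$wavenumbers), 4000)
  expect_equal(min(s1$wavenumbers), 650)

  # noise-free, texture-free spectrum is the exact Gaussian mixture
  clean <- synth_ftir_spectrum(roughness_amp = 0, noise_amp = 0, seed = 1)
  b <- default_bands()
  at <- function(w0) clean$absorbance[which.min(abs(clean$wavenumbers - w0))]
  for (i in seq_len(nrow(b))) {
    others <- sum(b[-i, 3] * exp(-(b[i, 1] - b[-i, 1])^2 / (2 * b[-i, 2]^2)))
    expect_equal(at(b[i, 1]), unname(b[i, 3] + others), tolerance = 1e-3)
  }
  expect_error(synth_ftir_spectrum(roughness_p = 0.7), "roughness_p")
})

test_that("lower roughness_p yields rougher texture and wider spectra", {
  # texture SD grows as the cascade skews (log-multiplier variance)
  sd_at <- function(p) {
    s <- synth_ftir_spectrum(roughness_p = p, noise_amp = 0, seed = 21)
    clean <- synth_ftir_spectrum(roughness_p = p, roughness_amp = 0,
                                 noise_amp = 0, seed = 21)
    sd(s$absorbance - clean$absorbance)
  }
  expect_gt(sd_at(0.20), sd_at(0.30))
  expect_gt(sd_at(0.30), sd_at(0.45))

  # downstream contract: majority of seeds give wider delta_alpha at
  # p = 0.20 than p = 0.45 after the full render-and-analyze pipeline
  votes <- vapply(1:5, function(sd) {
    lo <- analyze(spectrum_to_binary(synth_ftir_spectrum(roughness_p = 0.20,
                                                         seed = sd)),
                  mfa_config(), check = FALSE)$delta_alpha
    hi <- analyze(spectrum_to_binary(synth_ftir_spectrum(roughness_p = 0.45,
                                                         seed = sd)),
                  mfa_config(), check = FALSE)$delta_alpha
    lo > hi
  }, TRUE)
  expect_gte(sum(votes), 3)
})

test_that("mixing is the exact convex combination with phi recorded", {
  w <- seq(4000, 650, length.out = 32)
  h <- ftir_spectrum(w, rep(0.2, 32))
  cz <- ftir_spectrum(w, rep(0.6, 32))
  expect_equal(mix_spectra(h, cz, 0)$absorbance, h$absorbance)
  expect_equal(mix_spectra(h, cz, 1)$absorbance, cz$absorbance)
  m <- mix_spectra(h, cz, 0.5)
  expect_true(all(m$absorbance == 0.4))
  expect_equal(m$meta$phi, 0.5)
  expect_error(mix_spectra(h, ftir_spectrum(w[-1], rep(1, 31)), 0.5),
               "grids differ|resample")
  expect_error(mix_spectra(h, cz, 1.5), "phi")
})
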