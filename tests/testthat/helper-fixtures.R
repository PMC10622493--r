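# Shared fixtures, all built in code at test time.

tiny_spectrum <- function() {
  ftir_spectrum(c(4000, 3999, 3998), c(0.1, 0.2, 0.1))
}

ramp_spectrum <- function(n = 64) {
  # absorbance affine in wavenumber: 0 at 650, 1 at 4000
  w <- seq(4000, 650, length.out = n)
  ftir_spectrum(w, (w - 650) / (4000 - 650))
}

write_tmp_csv <- function(lines) {
  path <- withr::local_tempfile(fileext = ".csv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# dyadic configuration for exact cascade verification
dyadic_cfg <- function(depth, ...) {
  mfa_config(sizes = 2^(0:(depth - 1)), ...)
}

# canonical closed-form constants for the (0.25, 0.75) binomial pair
BIN25 <- list(
  w = c(0.25, 0.75),
  tau2 = -log2(0.25^2 + 0.75^2),          # 0.6780719
  d1 = -(0.25 * log2(0.25) + 0.75 * log2(0.75)),  # 0.8112781
  alpha_min = -log2(0.75),                 # 0.4150375
  alpha_max = -log2(0.25),                 # 2
  delta_alpha = log2(3)                    # 1.5849625
)
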