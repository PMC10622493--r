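# Internal numerical helpers shared across modules.

#' @keywords internal
#' @noRd
log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Least-squares line fit returning slope, intercept and R^2.
# Degenerate cases: constant y is reported as a perfect flat fit
# (slope 0, R^2 1); constant x is a usage error upstream.
#' @keywords internal
#' @noRd
fit_line <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (diff(range(x)) < .Machine$double.eps) {
    stop("degenerate regression: all abscissae equal", call. = FALSE)
  }
  mx <- mean(x)
  my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  intercept <- my - slope * mx
  ss_tot <- sum((y - my)^2)
  ss_res <- sum((y - intercept - slope * x)^2)
  r2 <- if (ss_tot < 1e-20) {
    if (ss_res < 1e-20) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  list(slope = slope, intercept = intercept, r2 = r2)
}

# Least-squares line constrained through the anchor point (x0, 0): the
# ratio-form scaling estimator log Z / log(eps/L) in regression clothing.
# With all x < x0 the slope is a positive mixture of the per-scale ratios
# y_k / (x_k - x0), which is what makes the Renyi ordering of D(Q) exact.
#' @keywords internal
#' @noRd
fit_anchored <- function(x, y, x0) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  dx <- x - x0
  if (all(abs(dx) < .Machine$double.eps)) {
    stop("degenerate regression: all scales at the anchor", call. = FALSE)
  }
  slope <- sum(dx * y) / sum(dx^2)
  fitted <- slope * dx
  my <- mean(y)
  ss_tot <- sum((y - my)^2)
  ss_res <- sum((y - fitted)^2)
  r2 <- if (ss_tot < 1e-20) {
    if (ss_res < 1e-20) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  list(slope = slope, intercept = -slope * x0, r2 = r2)
}

# FNV-1a 32-bit hash of a character scalar, returned as 8 hex digits.
# Used only to stamp outputs with a short configuration fingerprint.
#' @keywords internal
#' @noRd
fnv1a_hash <- function(s) {
  bytes <- utf8ToInt(enc2utf8(paste(s, collapse = "\n")))
  h <- 2166136261
  for (b in bytes) {
    # xor on the low 16 bits only (b < 2^16; bitwXor needs < 2^31 inputs)
    h <- (h %/% 65536) * 65536 + bitwXor(h %% 65536, b %% 65536)
    # 32-bit modular multiply by the FNV prime 16777619 = 16777216 + 403,
    # split so intermediates stay exact below 2^53
    h <- (h * 403 + (h * 16777216) %% 4294967296) %% 4294967296
  }
  # format as 8 hex digits; h may exceed .Machine$integer.max, so split
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' @keywords internal
#' @noRd
config_hash <- function(cfg) {
  flat <- unlist(cfg)
  fnv1a_hash(paste(names(flat), format(flat, digits = 15), sep = "=",
                   collapse = ";"))
}

# Evaluate code with a private RNG stream, restoring the caller's state.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
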