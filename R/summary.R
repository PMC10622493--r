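# Scalar reduction of a multifractal spectrum and the three experiment
# templates built on it: group separation, concentration invariance and
# cancer-fraction dose response.

#' Reduce a multifractal spectrum to a scalar multifractal number
#'
#' The default reduction is the singularity-spectrum width
#' `delta_alpha = alpha_max - alpha_min`, taken over the Q values whose
#' fits pass the configured R^2 gate: the wider the spectrum, the
#' stronger the multifractality. Alternatives hedge the ambiguity of
#' which scalar a practitioner plots: `alpha0` (alpha at Q = 0), `d1`
#' (information dimension), `f_at_q` (f at a chosen Q), and the
#' experimental `aperture` reading `|f(Q=1) - f(Q=-1)|`.
#'
#' @param ms a `"multifractal_spectrum"` from [analyze()].
#' @param method one of `"delta_alpha"`, `"alpha0"`, `"d1"`, `"f_at_q"`,
#'   `"aperture"`.
#' @param q_star the Q at which `f` is read for `method = "f_at_q"`.
#' @param source optional sample identifier recorded on the result.
#' @return An object of class `"multifractal_number"`: list with `value`,
#'   `method`, `q_star` (if relevant), `source` and `config_hash`.
#' @export
multifractal_number <- function(ms,
                                method = c("delta_alpha", "alpha0", "d1",
                                           "f_at_q", "aperture"),
                                q_star = 2, source = NULL) {
  stopifnot(inherits(ms, "multifractal_spectrum"))
  method <- match.arg(method)
  ok <- ms$fit_ok
  if (!any(ok)) {
    stop("no Q value passes the fit-quality gate; cannot summarize",
         call. = FALSE)
  }
  at <- function(v, qq) {
    i <- which(abs(ms$q - qq) < 1e-9)
    if (length(i)) v[i[1]] else stats::approx(ms$q, v, xout = qq, rule = 2)$y
  }
  value <- switch(method,
    delta_alpha = max(ms$alpha[ok]) - min(ms$alpha[ok]),
    alpha0 = at(ms$alpha, 0),
    d1 = at(ms$d, 1),
    f_at_q = at(ms$f, q_star),
    aperture = abs(at(ms$f, 1) - at(ms$f, -1))
  )
  if (!is.finite(value)) stop("non-finite multifractal number", call. = FALSE)
  structure(list(value = value, method = method,
                 q_star = if (method == "f_at_q") q_star else NULL,
                 source = source, config_hash = ms$config_hash),
            class = "multifractal_number")
}

#' @export
print.multifractal_number <- function(x, ...) {
  cat(sprintf("multifractal number (%s%s): %.5f\n", x$method,
              if (!is.null(x$q_star)) sprintf(", q*=%g", x$q_star) else "",
              x$value))
  invisible(x)
}

#' @keywords internal
#' @noRd
mf_values <- function(xs) {
  if (inherits(xs, "multifractal_number")) xs <- list(xs)
  if (is.numeric(xs)) return(list(values = as.numeric(xs), method = NA))
  stopifnot(is.list(xs))
  if (all(vapply(xs, inherits, TRUE, "multifractal_number"))) {
    meth <- unique(vapply(xs, `[[`, "", "method"))
    if (length(meth) != 1) {
      stop("mixed multifractal-number methods: ",
           paste(meth, collapse = ", "), call. = FALSE)
    }
    list(values = vapply(xs, `[[`, 0, "value"), method = meth)
  } else {
    list(values = as.numeric(unlist(xs)), method = NA)
  }
}

#' Compare groups of multifractal numbers
#'
#' Per-group mean, standard deviation and n, plus a two-sample Welch
#' (unequal-variance) t-test for two groups or a one-way ANOVA for more.
#' Replicate counts of 3 per group are typical for triplicate spectra.
#'
#' @param groups named list; each element a numeric vector or a list of
#'   `"multifractal_number"` objects (all with the same method label).
#' @param test `"auto"` (Welch t for 2 groups, ANOVA otherwise),
#'   `"welch_t"` or `"anova"`.
#' @return An object of class `"mf_group_comparison"`: a list with a
#'   per-group `summary` data.frame, `test`, `statistic`, `p_value`.
#' @export
compare_groups <- function(groups, test = c("auto", "welch_t", "anova")) {
  test <- match.arg(test)
  if (!is.list(groups) || length(groups) < 2) {
    stop("need a list of >= 2 groups", call. = FALSE)
  }
  parsed <- lapply(groups, mf_values)
  meths <- unique(stats::na.omit(vapply(parsed, function(p)
    as.character(p$method), "")))
  meths <- meths[meths != "NA"]
  if (length(meths) > 1) {
    stop("groups mix multifractal-number methods: ",
         paste(meths, collapse = ", "), call. = FALSE)
  }
  vals <- lapply(parsed, `[[`, "values")
  if (any(lengths(vals) < 2)) {
    stop("each group needs >= 2 replicates for an SD", call. = FALSE)
  }
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("group", seq_along(groups))
  summ <- data.frame(group = nm,
                     n = lengths(vals),
                     mean = vapply(vals, mean, 0),
                     sd = vapply(vals, stats::sd, 0),
                     row.names = NULL)
  if (test == "auto") test <- if (length(vals) == 2) "welch_t" else "anova"
  degenerate <- all(vapply(vals, stats::sd, 0) == 0)
  if (test == "welch_t") {
    if (length(vals) != 2) stop("welch_t needs exactly 2 groups",
                                call. = FALSE)
    if (degenerate) {
      # no within-group variability: any mean difference is deterministic
      same <- mean(vals[[1]]) == mean(vals[[2]])
      statistic <- if (same) 0 else Inf
      p <- if (same) 1 else 0
    } else {
      ht <- stats::t.test(vals[[1]], vals[[2]], var.equal = FALSE)
      statistic <- unname(ht$statistic)
      p <- ht$p.value
    }
  } else {
    if (degenerate) {
      same <- length(unique(vapply(vals, mean, 0))) == 1
      statistic <- if (same) 0 else Inf
      p <- if (same) 1 else 0
    } else {
      df <- data.frame(value = unlist(vals),
                       group = factor(rep(nm, lengths(vals))))
      av <- stats::anova(stats::aov(value ~ group, data = df))
      statistic <- av$`F value`[1]
      p <- av$`Pr(>F)`[1]
    }
  }
  structure(list(summary = summ, test = test, statistic = statistic,
                 p_value = p,
                 method = if (length(meths)) meths else NA_character_),
            class = "mf_group_comparison")
}

#' @export
print.mf_group_comparison <- function(x, ...) {
  cat("Group comparison of multifractal numbers\n")
  print(x$summary, row.names = FALSE)
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n", x$test, x$statistic,
              x$p_value))
  invisible(x)
}

#' Concentration-invariance report
#'
#' Given multifractal numbers computed from amplitude-scaled copies of
#' one base spectrum (e.g. scalings x1, x2, x4, x10 mirroring 1e5-1e6
#' cells/ml), reports the maximum absolute pairwise difference. With
#' min-max normalization in the raster stage the scaled copies produce
#' byte-identical binary images, so the spread is exactly 0; without
#' normalization the observed spread is reported and flagged.
#'
#' @param numbers list of `"multifractal_number"` objects or a numeric
#'   vector.
#' @param tol spread above which the result is flagged as variant.
#' @return List with `spread`, `invariant` (logical), `values`.
#' @export
invariance_report <- function(numbers, tol = 0) {
  v <- mf_values(numbers)$values
  spread <- if (length(v) < 2) 0 else max(v) - min(v)
  list(spread = spread, invariant = spread <= tol, values = v)
}

#' Dose-response monotonicity between cancer fraction and MF number
#'
#' Spearman rank correlation between the mixing fraction `phi` and the
#' multifractal number, with a direction label. Ties across all values
#' make rho undefined; this is reported rather than erroring.
#'
#' @param phis cancer-cell fractions, length >= 3.
#' @param numbers matching multifractal numbers (list or numeric).
#' @return List with `rho`, `direction` (`"increasing"`, `"decreasing"`,
#'   `"flat"`, `"undefined"`), `phis`, `values`.
#' @export
dose_response <- function(phis, numbers) {
  v <- mf_values(numbers)$values
  if (length(phis) != length(v)) stop("length mismatch", call. = FALSE)
  if (length(phis) < 3) stop("need >= 3 doses", call. = FALSE)
  if (stats::sd(v) == 0 || stats::sd(phis) == 0) {
    return(list(rho = NA_real_, direction = "undefined", phis = phis,
                values = v))
  }
  rho <- suppressWarnings(stats::cor(phis, v, method = "spearman"))
  direction <- if (!is.finite(rho)) "undefined"
  else if (rho > 0) "increasing"
  else if (rho < 0) "decreasing"
  else "flat"
  list(rho = rho, direction = direction, phis = phis, values = v)
}

#' End-to-end multifractal number of a spectrum
#'
#' Convenience wrapper: normalize, rasterize, binarize, analyze, reduce.
#'
#' @param s an [ftir_spectrum].
#' @param raster a [raster_config].
#' @param mfa an [mfa_config].
#' @param method,q_star passed to [multifractal_number()].
#' @param normalize amplitude normalization mode for the raster stage.
#' @return A `"multifractal_number"`.
#' @export
spectrum_mf_number <- function(s, raster = raster_config(),
                               mfa = mfa_config(),
                               method = "delta_alpha", q_star = 2,
                               normalize = "minmax") {
  img <- spectrum_to_binary(s, raster, normalize = normalize)
  ms <- analyze(img, mfa, check = FALSE)
  multifractal_number(ms, method = method, q_star = q_star,
                      source = s$meta$sample_id)
}
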