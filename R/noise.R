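# Uniform-noise mixing and the noise-tolerance simulation: how much
# random (uniform over categories) answering can be added to a perfect
# binomial response pattern before the chi-square test rejects the
# binomial fit, and the inverse problem of reading a noise level off an
# observed misfit summary.

#' Mix uniform noise into a category distribution
#'
#' A fraction `kappa` of responses is assumed to be given at random, each
#' category equally likely; the rest follow `probs`. The noisy
#' distribution is the convex combination
#' `(1 - kappa) probs + kappa / m`.
#'
#' @param probs Probability vector of length m.
#' @param kappa Noise fraction in \[0, 1\] (`kappa = 0.12` is "12% noise").
#' @return A `"category_probs"` vector; `model_tag` is `"uniform"` when
#'   `kappa = 1`, otherwise the input's tag (or `"binomial"` for plain
#'   vectors).
#' @examples
#' apply_noise(category_probabilities(0.8), 0.12)
#' @export
apply_noise <- function(probs, kappa) {
  check_prob(kappa, "kappa")
  p <- as.numeric(probs)
  m <- length(p)
  tag <- attr(probs, "model_tag")
  if (is.null(tag)) tag <- "binomial"
  out <- (1 - kappa) * p + kappa / m
  cat_probs(out, if (kappa >= 1) "uniform" else tag)
}

#' Noise-tolerance curve of the binomial fit
#'
#' For each noise percentage, every item's binomial category distribution
#' is contaminated with that much uniform noise, converted to counts
#' (exact expected counts `N * probs` in `"expected"` mode, one
#' multinomial draw per item in `"sampled"` mode), and refitted with the
#' 1PBM; the curve records the proportion of items whose refitted
#' chi-square exceeds the critical value (default: the upper 5% quantile
#' at the configured df, 9.4877 for df = 4). In expected mode the curve is
#' deterministic — at zero noise every item fits perfectly — and the
#' misfit proportion is nondecreasing in the noise level.
#'
#' @param p_values Vector of item endorsement probabilities in (0, 1).
#' @param N Respondents per item (default 1731).
#' @param noise_pcts Noise percentages to evaluate (default 0:15).
#' @param mode `"expected"` (deterministic) or `"sampled"`.
#' @param seed Optional seed for `"sampled"` mode; ignored in expected
#'   mode.
#' @param alpha Significance level of the misfit test (default 0.05).
#' @param m Number of response categories (default 5).
#' @param df_mode Degrees-of-freedom convention, see [fit_binomial()].
#' @param grid_step,guard Passed to [fit_binomial()].
#' @return A `"noise_curve"`: list with `curve` (data.frame of
#'   `noise_pct`, `misfit_prop`, `pass_prop`, `mean_chi2`,
#'   `median_chi2`), `chi2` (items x levels matrix), `critical`, and
#'   `config`.
#' @export
noise_misfit_curve <- function(p_values, N = 1731, noise_pcts = 0:15,
                               mode = c("expected", "sampled"),
                               seed = NULL, alpha = 0.05, m = 5,
                               df_mode = c("paper", "corrected"),
                               grid_step = 1e-4, guard = 1e-3) {
  mode <- match.arg(mode)
  df_mode <- match.arg(df_mode)
  if (length(p_values) == 0) stop("`p_values` must be non-empty")
  if (any(p_values <= 0) || any(p_values >= 1)) {
    stop("all `p_values` must lie strictly inside (0, 1)")
  }
  if (any(noise_pcts < 0) || any(noise_pcts > 100)) {
    stop("`noise_pcts` must lie in [0, 100]")
  }
  df <- df_for(m, 1, df_mode)
  critical <- qchisq(1 - alpha, df)
  if (mode == "sampled" && !is.null(seed)) set.seed(seed)
  base <- lapply(p_values, category_probabilities, m = m)
  chi2 <- matrix(NA_real_, length(p_values), length(noise_pcts),
                 dimnames = list(NULL, paste0("noise", noise_pcts)))
  for (j in seq_along(noise_pcts)) {
    kappa <- noise_pcts[j] / 100
    for (i in seq_along(p_values)) {
      probs <- apply_noise(base[[i]], kappa)
      cnt <- if (mode == "expected") N * as.numeric(probs) else
        as.numeric(rmultinom(1, N, as.numeric(probs)))
      fit <- fit_binomial(response_counts(cnt), grid_step = grid_step,
                          guard = guard, df_mode = df_mode)
      chi2[i, j] <- fit$chi2
    }
  }
  misfit <- colMeans(chi2 > critical)
  curve <- data.frame(
    noise_pct = noise_pcts,
    misfit_prop = misfit,
    pass_prop = 1 - misfit,
    mean_chi2 = colMeans(chi2),
    median_chi2 = apply(chi2, 2, median),
    row.names = NULL
  )
  structure(
    list(curve = curve, chi2 = chi2, critical = critical,
         config = list(N = N, n_items = length(p_values), mode = mode,
                       alpha = alpha, m = m, df = df, seed = seed)),
    class = "noise_curve"
  )
}

#' @export
print.noise_curve <- function(x, ...) {
  cat(sprintf(
    "Noise-tolerance curve: %d items, N = %d, %s mode, crit = %.4f\n",
    x$config$n_items, x$config$N, x$config$mode, x$critical))
  print(x$curve, digits = 4)
  invisible(x)
}

#' Back-estimate the noise level from an observed misfit summary
#'
#' Inverts the simulated noise-to-misfit mapping: a deterministic
#' (expected-mode) noise curve is computed on a 1% grid for the supplied
#' item endorsement probabilities and sample size, and the noise
#' percentage whose simulated summary matches the observed one is found
#' by monotone linear interpolation. Two summaries are supported:
#' `"mean_chi2"` matches the mean item chi-square, `"pass_rate"` matches
#' the proportion of items passing the chi-square test at the configured
#' level. The mapping is conditioned on N (chi-square scales with N at a
#' fixed mixing distance), so the same summary at a larger N maps to a
#' smaller noise percentage.
#'
#' @param summary_value The observed summary: a mean chi-square
#'   (`method = "mean_chi2"`) or a pass proportion in \[0, 1\]
#'   (`method = "pass_rate"`).
#' @param p_values Item endorsement probabilities defining the simulated
#'   bank.
#' @param N Respondents per item.
#' @param method Which summary to invert.
#' @param max_pct Upper end of the simulated noise grid (default 30).
#' @param ... Passed to [noise_misfit_curve()] (e.g. `alpha`, `m`,
#'   `df_mode`).
#' @return The estimated noise percentage. If the observed summary lies
#'   beyond the simulated range the grid maximum is returned with
#'   attribute `censored = TRUE` (read "at least this much noise").
#' @export
estimate_noise_level <- function(summary_value, p_values, N = 1731,
                                 method = c("mean_chi2", "pass_rate"),
                                 max_pct = 30, ...) {
  method <- match.arg(method)
  nc <- noise_misfit_curve(p_values, N = N, noise_pcts = 0:max_pct,
                           mode = "expected", ...)
  cv <- nc$curve
  if (method == "mean_chi2") {
    if (summary_value < 0) stop("a chi-square summary must be >= 0")
    x <- cv$mean_chi2                       # increasing in noise
    if (summary_value > max(x)) {
      return(structure(max_pct, censored = TRUE, method = method))
    }
    if (summary_value <= x[1]) {
      est <- cv$noise_pct[1]
    } else {
      est <- approx(x, cv$noise_pct, xout = summary_value,
                    ties = "ordered")$y
    }
  } else {
    if (summary_value < 0 || summary_value > 1) {
      stop("a pass rate must lie in [0, 1]")
    }
    pass <- cv$pass_prop                    # nonincreasing in noise
    if (summary_value < min(pass)) {
      return(structure(max_pct, censored = TRUE, method = method))
    }
    # first noise level at which the simulated pass rate drops to the
    # observed value, interpolating across the bracketing grid points
    below <- which(pass <= summary_value)
    if (length(below) == 0) return(structure(0, censored = FALSE,
                                             method = method))
    j <- below[1]
    if (j == 1 || pass[j] == summary_value) {
      est <- cv$noise_pct[j]
    } else {
      est <- approx(pass[c(j - 1, j)], cv$noise_pct[c(j - 1, j)],
                    xout = summary_value)$y
    }
  }
  structure(est, censored = FALSE, method = method)
}
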