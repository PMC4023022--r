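# Exhaustive chi-square-minimising fitters for the one-parameter binomial
# model (1PBM), the two-parameter discretised-normal benchmark (2PNM) and
# the three-parameter binomial mixture (3PBM).
#
# Grid expected-probability tables are cached per (m, guard, step): the
# chi-square over a whole grid reduces to
#   chi2(theta) = sum_k O_k^2 / (N e_k) - 2 N + N sum_k e_k
# which is one matrix-vector product against the cached reciprocal table,
# so refitting thousands of items (noise curves, recovery studies) stays
# cheap.

.fit_cache <- new.env(parent = emptyenv())

# Floor applied to expected probabilities before division; parameter grids
# stop `guard` short of 0 and 1 so expected counts stay positive.
PROB_FLOOR <- 1e-9

# Cached 1PBM grid: p values and reciprocal expected-probability table.
binom_grid <- function(m, guard, step) {
  key <- sprintf("b|%d|%.10g|%.10g", m, guard, step)
  hit <- .fit_cache[[key]]
  if (!is.null(hit)) return(hit)
  p <- seq(guard, 1 - guard, by = step)
  E <- vapply(0:(m - 1), function(k) dbinom(k, m - 1, p), numeric(length(p)))
  E <- pmax(E, PROB_FLOOR)
  g <- list(p = p, inv = 1 / E, esum = rowSums(E))
  .fit_cache[[key]] <- g
  g
}

# Cached 3PBM grid. p_B and q_B run over {guard, step, 2*step, ...,
# 1-step, 1-guard}; w over seq(0.5, 1, by = step) (dominant-component
# convention). Stores the flattened (p, q, w) design and the reciprocal
# expected-probability table.
mixed_grid <- function(m, guard, step) {
  key <- sprintf("m|%d|%.10g|%.10g", m, guard, step)
  hit <- .fit_cache[[key]]
  if (!is.null(hit)) return(hit)
  pq <- unique(c(guard, seq(step, 1 - step, by = step), 1 - guard))
  w <- seq(0.5, 1, by = step)
  B <- vapply(0:(m - 1), function(k) dbinom(k, m - 1, pq),
              numeric(length(pq)))
  np <- length(pq)
  ip <- rep(seq_len(np), times = np)   # p index varies fastest
  iq <- rep(seq_len(np), each = np)
  PB <- B[ip, , drop = FALSE]
  QB <- B[iq, , drop = FALSE]
  nw <- length(w)
  ncell <- np * np
  E <- matrix(0, ncell * nw, m)
  for (j in seq_len(nw)) {
    rows <- (j - 1L) * ncell + seq_len(ncell)
    E[rows, ] <- w[j] * PB + (1 - w[j]) * QB
  }
  E <- pmax(E, PROB_FLOOR)
  g <- list(p = rep(pq[ip], times = nw),
            q = rep(pq[iq], times = nw),
            w = rep(w, each = ncell),
            inv = 1 / E, esum = rowSums(E))
  .fit_cache[[key]] <- g
  g
}

# chi2 over every grid row, given observed counts O (sum N).
grid_chi2 <- function(g, O, N) {
  as.vector(g$inv %*% (O * O)) / N - 2 * N + N * g$esum
}

# Deterministic argmin with ties broken by larger w then smaller p then
# smaller q (mixture grids) or smaller p (single grids).
pick_best <- function(chi2, w = NULL, p = NULL, q = NULL, tol = 1e-9) {
  cand <- which(chi2 <= min(chi2) + tol)
  if (length(cand) > 1L) {
    ord <- order(if (is.null(w)) rep(0, length(cand)) else -w[cand],
                 if (is.null(p)) rep(0, length(cand)) else p[cand],
                 if (is.null(q)) rep(0, length(cand)) else q[cand])
    cand <- cand[ord]
  }
  cand[1L]
}

df_for <- function(m, k, df_mode) {
  df_mode <- match.arg(df_mode, c("paper", "corrected"))
  if (df_mode == "paper") m - 1 else m - 1 - k
}

#' Pearson chi-square between observed counts and model probabilities
#'
#' `sum_k (O_k - N e_k)^2 / (N e_k)` over the m categories, the
#' goodness-of-fit statistic every fitter minimises. Expected
#' probabilities are floored at 1e-9 before division so the statistic
#' stays finite near the parameter boundary; with `guard_zero = FALSE` a
#' category with expected probability below the floor but positive
#' observed count raises an error instead.
#'
#' @param observed A [response_counts] object or numeric counts vector.
#' @param expected Probability vector of length m (e.g. from
#'   [category_probabilities()]).
#' @param guard_zero Floor near-zero expected probabilities (default TRUE).
#' @return The chi-square statistic (non-negative scalar).
#' @examples
#' pearson_chi2(c(100, 200, 400, 200, 100),
#'              category_probabilities(0.5))  # 66.67
#' @export
pearson_chi2 <- function(observed, expected, guard_zero = TRUE) {
  obs <- as_counts(observed)
  e <- as.numeric(expected)
  if (length(e) != obs$m) stop("expected probabilities must have length m")
  if (!guard_zero && any(e < PROB_FLOOR & obs$counts > 0)) {
    stop("degenerate expected probability with positive observed count")
  }
  e <- pmax(e, PROB_FLOOR)
  Ne <- obs$N * e
  sum((obs$counts - Ne)^2 / Ne)
}

new_fit <- function(class, fields, m, N, k, df_mode) {
  df <- df_for(m, k, df_mode)
  fields$df <- df
  fields$p_value <- pchisq(fields$chi2, df, lower.tail = FALSE)
  fields$aic <- fields$chi2 + 2 * k
  fields$k <- k
  fields$m <- m
  fields$N <- N
  structure(fields, class = c(class, "likertbin_fit"))
}

#' Fit the one-parameter binomial model (1PBM)
#'
#' Exhaustive search for the endorsement probability `p_B` minimising the
#' Pearson chi-square between observed category counts and the binomial
#' category probabilities: every p on a grid over
#' \[guard, 1-guard\] is evaluated, then the winner is polished by a local
#' continuous refinement pass within one grid step.
#'
#' @param counts A [response_counts] object or numeric counts vector.
#' @param grid_step Grid resolution for the p sweep (default 1e-4).
#' @param guard Distance kept from the 0/1 boundary (default 1e-3).
#' @param df_mode `"paper"` uses df = m-1 for every model, matching the
#'   convention under which the reference chi-square quantiles and
#'   p-values were computed; `"corrected"` uses df = m-1-k.
#' @return A `"binomial_fit"`: list with `p_B`, `chi2`, `df`, `p_value`,
#'   `aic` (chi2 + 2k, k = 1), `k`, `m`, `N`.
#' @examples
#' cnt <- response_counts(1731 * category_probabilities(0.3))
#' fit_binomial(cnt)$p_B  # 0.3
#' @export
fit_binomial <- function(counts, grid_step = 1e-4, guard = 1e-3,
                         df_mode = c("paper", "corrected")) {
  obs <- as_counts(counts)
  df_mode <- match.arg(df_mode)
  g <- binom_grid(obs$m, guard, grid_step)
  chi2v <- grid_chi2(g, obs$counts, obs$N)
  i <- pick_best(chi2v, p = g$p)
  p0 <- g$p[i]
  best_chi2 <- chi2v[i]
  # local refinement within one grid step of the discrete winner
  f <- function(p) pearson_chi2(obs, dbinom(0:(obs$m - 1), obs$m - 1, p))
  lo <- max(guard, p0 - grid_step)
  hi <- min(1 - guard, p0 + grid_step)
  opt <- optimize(f, c(lo, hi), tol = 1e-10)
  if (opt$objective < best_chi2) {
    p0 <- opt$minimum
    best_chi2 <- opt$objective
  }
  new_fit("binomial_fit", list(p_B = p0, chi2 = best_chi2),
          obs$m, obs$N, k = 1, df_mode)
}

#' Normal (discretised) category probabilities
#'
#' Category probabilities for the two-parameter normal benchmark: a latent
#' normal(mu, sigma) is cut at the half-integer boundaries between
#' category values 1..m, with open outer bins, so
#' `P(Rk) = Phi((k+0.5 - mu)/sigma) - Phi((k-0.5 - mu)/sigma)` for interior
#' k. With `renormalize = TRUE` the normal mass is instead truncated to
#' \[0.5, m+0.5\] and rescaled to sum to 1.
#'
#' @param mu Latent mean on the 1..m scale.
#' @param sigma Latent standard deviation (> 0).
#' @param m Number of response categories (default 5).
#' @param renormalize Use the truncate-and-renormalise convention.
#' @return A `"category_probs"` vector with `model_tag = "normal"`.
#' @export
normal_probs <- function(mu, sigma, m = 5, renormalize = FALSE) {
  if (sigma <= 0) stop("`sigma` must be positive")
  cuts <- seq(1.5, m - 0.5, by = 1)
  if (renormalize) {
    edges <- c(0.5, cuts, m + 0.5)
    mass <- diff(pnorm(edges, mu, sigma))
    probs <- mass / sum(mass)
  } else {
    probs <- diff(pnorm(c(-Inf, cuts, Inf), mu, sigma))
  }
  cat_probs(probs, "normal")
}

#' Fit the two-parameter normal model (2PNM)
#'
#' Minimises the Pearson chi-square over (mu, sigma) for the discretised
#' normal category probabilities of [normal_probs()]: a coarse grid sweep
#' followed by box-constrained quasi-Newton refinement. Serves as the
#' continuous-latent-variable benchmark against which the binomial models
#' are compared.
#'
#' @inheritParams fit_binomial
#' @param sigma_floor Lower bound for sigma; a fit pinned at the floor
#'   (all mass effectively in one category) is flagged `degenerate`.
#' @param renormalize Passed to [normal_probs()].
#' @return A `"normal_fit"`: list with `mu`, `sigma`, `degenerate`,
#'   `chi2`, `df`, `p_value`, `aic` (k = 2), `k`, `m`, `N`.
#' @export
fit_normal <- function(counts, sigma_floor = 0.05, renormalize = FALSE,
                       df_mode = c("paper", "corrected")) {
  obs <- as_counts(counts)
  df_mode <- match.arg(df_mode)
  m <- obs$m
  f <- function(par) {
    pearson_chi2(obs, normal_probs(par[1], par[2], m, renormalize))
  }
  # coarse sweep, then refine from the best cell
  mus <- seq(0.5, m + 0.5, by = 0.1)
  sigmas <- seq(sigma_floor, m - 1, by = 0.1)
  grid <- expand.grid(mu = mus, sigma = sigmas)
  chi2v <- mapply(function(mu, s) f(c(mu, s)), grid$mu, grid$sigma)
  start <- as.numeric(grid[which.min(chi2v), ])
  opt <- optim(start, f, method = "L-BFGS-B",
               lower = c(0, sigma_floor), upper = c(m + 1, 2 * m))
  mu <- opt$par[1]; sigma <- opt$par[2]; chi2 <- opt$value
  if (min(chi2v) < chi2) {           # guard against a failed line search
    mu <- start[1]; sigma <- start[2]; chi2 <- min(chi2v)
  }
  new_fit("normal_fit",
          list(mu = mu, sigma = sigma,
               degenerate = sigma <= sigma_floor * (1 + 1e-8),
               chi2 = chi2),
          m, obs$N, k = 2, df_mode)
}

#' Fit the mixed-binomial model (3PBM)
#'
#' Exhaustive grid search over all combinations of the two component
#' endorsement probabilities `p_B`, `q_B` and the dominant-component
#' weight `w` (w >= 0.5 by convention), minimising the Pearson
#' chi-square; the coarse winner is refined on a local fine grid. The
#' mixture contains the single binomial as the boundary case w = 1, so
#' its chi-square never exceeds the 1PBM chi-square: whenever the finer
#' 1PBM search finds a lower chi-square than the mixture grids, the fit
#' collapses to that boundary solution.
#'
#' The fit is compared with [fit_binomial()] on the same counts:
#' `improvement_pct = 100 (1 - chi2_mixed / chi2_single)`, and the mixture
#' is `selected` when the improvement reaches at least 5%. Perfect single
#' fits (chi2 = 0) are assigned improvement 0.
#'
#' @inheritParams fit_binomial
#' @param coarse_step Coarse grid resolution (default 0.01, two decimals).
#' @param refine_step Local refinement resolution (default 1e-3).
#' @param single Optional precomputed `"binomial_fit"` for the same
#'   counts; computed if missing.
#' @return A `"mixed_fit"`: list with `p_B`, `q_B`, `w`, `chi2`, `df`,
#'   `p_value`, `aic` (k = 3), `improvement_pct`, `selected`, and the
#'   comparison `single` fit.
#' @examples
#' cnt <- response_counts(1731 * mixed_category_probabilities(0.08, 0.8, 0.66))
#' fit_mixed_binomial(cnt)[c("p_B", "q_B", "w")]
#' @export
fit_mixed_binomial <- function(counts, coarse_step = 0.01,
                               refine_step = 1e-3, guard = 1e-3,
                               df_mode = c("paper", "corrected"),
                               single = NULL) {
  obs <- as_counts(counts)
  df_mode <- match.arg(df_mode)
  m <- obs$m
  g <- mixed_grid(m, guard, coarse_step)
  chi2v <- grid_chi2(g, obs$counts, obs$N)
  i <- pick_best(chi2v, w = g$w, p = g$p, q = g$q)
  best <- list(p = g$p[i], q = g$q[i], w = g$w[i], chi2 = chi2v[i])

  # local fine grid around the coarse winner
  pr <- refine_seq(best$p, coarse_step, refine_step, guard, 1 - guard)
  qr <- refine_seq(best$q, coarse_step, refine_step, guard, 1 - guard)
  wr <- refine_seq(best$w, coarse_step, refine_step, 0.5, 1)
  BP <- vapply(0:(m - 1), function(k) dbinom(k, m - 1, pr),
               numeric(length(pr)))
  BQ <- vapply(0:(m - 1), function(k) dbinom(k, m - 1, qr),
               numeric(length(qr)))
  ncell <- length(pr) * length(qr)
  ip <- rep(seq_along(pr), times = length(qr))
  iq <- rep(seq_along(qr), each = length(pr))
  PB <- BP[ip, , drop = FALSE]
  QB <- BQ[iq, , drop = FALSE]
  O2 <- obs$counts^2
  N <- obs$N
  for (w in rev(wr)) {   # descending w: ties resolve to the larger weight
    E <- pmax(w * PB + (1 - w) * QB, PROB_FLOOR)
    c2 <- as.vector((1 / E) %*% O2) / N - 2 * N + N * rowSums(E)
    j <- pick_best(c2, w = rep(w, ncell), p = pr[ip], q = qr[iq])
    if (c2[j] < best$chi2 - 1e-12) {
      best <- list(p = pr[ip[j]], q = qr[iq[j]], w = w, chi2 = c2[j])
    }
  }

  if (is.null(single)) {
    single <- fit_binomial(obs, guard = guard, df_mode = df_mode)
  }
  if (single$chi2 < best$chi2) {
    # boundary case of the mixture: the finer single-model search won
    best <- list(p = single$p_B, q = single$p_B, w = 1, chi2 = single$chi2)
  }
  improvement <- if (single$chi2 <= 1e-12) 0 else
    100 * (1 - best$chi2 / single$chi2)
  fit <- new_fit("mixed_fit",
                 list(p_B = best$p, q_B = best$q, w = best$w,
                      chi2 = best$chi2),
                 m, N, k = 3, df_mode)
  fit$improvement_pct <- improvement
  fit$selected <- improvement >= 5
  fit$single <- single
  fit
}

refine_seq <- function(center, halfwidth, step, lo, hi) {
  s <- seq(max(lo, center - halfwidth), min(hi, center + halfwidth),
           by = step)
  sort(unique(c(s, center)))
}

#' Model selection between single, mixed and normal fits
#'
#' Applies the improvement rule: the mixture replaces the single binomial
#' when it reduces the chi-square by at least 5%; otherwise the single
#' model is retained. AIC = chi2 + 2k is reported for all supplied models
#' (k = 1, 3, 2 for binomial, mixed, normal) but does not override the
#' improvement rule.
#'
#' @param single A `"binomial_fit"`.
#' @param mixed A `"mixed_fit"` on the same counts.
#' @param normal Optional `"normal_fit"` on the same counts.
#' @return A `"model_selection"` list: `selected` (`"mixed"` or
#'   `"binomial"`), `improvement_pct`, `aic` (named vector), and the fits.
#' @export
select_model <- function(single, mixed, normal = NULL) {
  improvement <- if (single$chi2 <= 1e-12) 0 else
    100 * (1 - mixed$chi2 / single$chi2)
  aic <- c(binomial = single$aic, mixed = mixed$aic)
  if (!is.null(normal)) aic <- c(aic, normal = normal$aic)
  structure(
    list(selected = if (improvement >= 5) "mixed" else "binomial",
         improvement_pct = improvement,
         aic = aic,
         single = single, mixed = mixed, normal = normal),
    class = "model_selection"
  )
}

#' @export
print.likertbin_fit <- function(x, digits = 4, ...) {
  cat(class(x)[1], ": ", sep = "")
  pars <- switch(class(x)[1],
    binomial_fit = sprintf("p_B = %.4f", x$p_B),
    normal_fit = sprintf("mu = %.3f, sigma = %.3f%s", x$mu, x$sigma,
                         if (isTRUE(x$degenerate)) " (degenerate)" else ""),
    mixed_fit = sprintf("p_B = %.3f, q_B = %.3f, w = %.3f", x$p_B,
                        x$q_B, x$w),
    "")
  cat(pars, "\n", sep = "")
  cat(sprintf("  chi2(%d) = %.4g, p = %.4g, AIC = %.4g\n",
              x$df, x$chi2, x$p_value, x$aic))
  if (!is.null(x$improvement_pct)) {
    cat(sprintf("  improvement over 1PBM: %.1f%% (%sselected)\n",
                x$improvement_pct, if (x$selected) "" else "not "))
  }
  invisible(x)
}

# Expected probability vector of a fit object.
#' Model-implied category probabilities of a fit
#'
#' @param fit A fit returned by [fit_binomial()], [fit_normal()] or
#'   [fit_mixed_binomial()].
#' @return The fitted `"category_probs"` vector.
#' @export
fitted_probs <- function(fit) {
  switch(class(fit)[1],
    binomial_fit = category_probabilities(fit$p_B, fit$m),
    normal_fit = normal_probs(fit$mu, fit$sigma, fit$m),
    mixed_fit = mixed_category_probabilities(fit$p_B, fit$q_B, fit$w,
                                             fit$m),
    stop("not a likertbin fit object"))
}
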