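test_that("pearson_chi2 matches hand arithmetic", {
  # perfect fit
  cnt <- expected_binomial_counts(0.42, 500)
  expect_lt(pearson_chi2(cnt, category_probabilities(0.42)), 1e-18)
  # hand-computed example: N = 1000 against the symmetric binomial
  got <- pearson_chi2(c(100, 200, 400, 200, 100),
                      category_probabilities(0.5))
  expect_equal(got, 22.5 + 10 + 5 / 3 + 10 + 22.5, tolerance = 1e-12)
  # linear in N at fixed expected probabilities
  expect_equal(pearson_chi2(2 * c(100, 200, 400, 200, 100),
                            category_probabilities(0.5)),
               2 * got, tolerance = 1e-12)
  # degenerate expected probability with guarding disabled
  expect_error(
    pearson_chi2(c(5, 0, 0, 0, 5), c(1, 0, 0, 0, 0), guard_zero = FALSE),
    "degenerate")
})

test_that("fit_binomial recovers generating probabilities", {
  # noiseless recovery from exact expected counts
  fit <- fit_binomial(expected_binomial_counts(0.3, 1731))
  expect_equal(fit$p_B, 0.3, tolerance = 1e-6)
  expect_lt(fit$chi2, 1e-10)
  # all mass in the lowest category pins p at the grid boundary
  deg <- fit_binomial(response_counts(c(50, 0, 0, 0, 0)))
  expect_equal(deg$p_B, 0.001, tolerance = 1e-9)
  expect_lt(deg$chi2, qchisq(0.95, 4))
  # multinomial sampling at the reference N stays within sampling error
  set.seed(20)
  cnt <- sample_item_counts(category_probabilities(0.6), 1731)
  fit <- fit_binomial(cnt)
  expect_lt(abs(fit$p_B - 0.6), 0.02)
})

test_that("fit_binomial equals a fine brute-force scan", {
  set.seed(99)
  for (i in 1:20) {
    probs <- rexp(5); probs <- probs / sum(probs)
    counts <- as.numeric(rmultinom(1, 500, probs))
    counts <- counts + 0.5  # keep every category populated
    fit <- fit_binomial(response_counts(counts))
    ora <- oracle_best_binomial(counts)
    expect_lt(abs(fit$chi2 - ora$chi2), 1e-6 * max(1, ora$chi2))
    expect_lte(fit$chi2, ora$chi2 + 1e-9)
  }
})

test_that("fit statistics follow the df and AIC conventions", {
  cnt <- response_counts(c(100, 150, 400, 250, 100))
  fit <- fit_binomial(cnt)
  expect_equal(fit$df, 4)
  expect_equal(fit$aic, fit$chi2 + 2)
  expect_equal(fit$p_value, pchisq(fit$chi2, 4, lower.tail = FALSE))
  corrected <- fit_binomial(cnt, df_mode = "corrected")
  expect_equal(corrected$df, 3)
  expect_equal(fit_normal(cnt, df_mode = "corrected")$df, 2)
  expect_equal(fit_mixed_binomial(cnt, df_mode = "corrected")$df, 1)
  expect_equal(fit_normal(cnt)$df, 4)
  expect_equal(fit_mixed_binomial(cnt)$df, 4)
})

test_that("fit_normal behaves on symmetric, degenerate and binomial data", {
  # symmetric counts centre the latent normal on the midpoint
  sym <- fit_normal(response_counts(c(50, 200, 500, 200, 50)))
  expect_equal(sym$mu, 3, tolerance = 1e-3)
  expect_false(sym$degenerate)
  # single-category counts pin sigma at the floor
  deg <- fit_normal(response_counts(c(0, 0, 300, 0, 0)))
  expect_true(deg$degenerate)
  # a binomial distribution is never matched exactly by the
  # discretised normal: compare against an independent grid oracle
  cnt <- expected_binomial_counts(0.5, 1000)
  fit <- fit_normal(cnt)
  expect_gt(fit$chi2, 0.5)
  mus <- seq(2, 4, by = 0.02)
  sigmas <- seq(0.3, 2, by = 0.02)
  oracle_min <- min(sapply(mus, function(mu) {
    sapply(sigmas, function(s) {
      cuts <- c(-Inf, 1.5, 2.5, 3.5, 4.5, Inf)
      oracle_chi2(cnt$counts, diff(pnorm(cuts, mu, s)))
    })
  }))
  expect_lte(fit$chi2, oracle_min + 1e-6)
  # renormalised convention gives a different but valid distribution
  pr <- normal_probs(3, 1, renormalize = TRUE)
  expect_equal(sum(pr), 1, tolerance = 1e-12)
})

test_that("fit_mixed_binomial recovers on-grid triples exactly", {
  probs <- mixed_category_probabilities(0.25, 0.75, 0.6)
  fit <- fit_mixed_binomial(response_counts(1000 * as.numeric(probs)))
  expect_equal(fit$p_B, 0.25)
  expect_equal(fit$q_B, 0.75)
  expect_equal(fit$w, 0.6)
  expect_lt(fit$chi2, 1e-8)
  expect_equal(fit$improvement_pct, 100, tolerance = 1e-6)
  expect_true(fit$selected)
})

test_that("pure binomial data give the mixture no advantage", {
  cnt <- expected_binomial_counts(0.55, 1731)
  fit <- fit_mixed_binomial(cnt)
  expect_lt(fit$chi2, 1e-8)
  expect_equal(fit$improvement_pct, 0)
  expect_false(fit$selected)
  expect_equal(fit$w, 1)
})

test_that("the mixture never fits worse than the single binomial", {
  set.seed(12)
  for (i in 1:15) {
    probs <- rexp(5); probs <- probs / sum(probs)
    counts <- as.numeric(rmultinom(1, 800, probs))
    counts[counts == 0] <- 0.5
    fit <- fit_mixed_binomial(response_counts(counts))
    expect_lte(fit$chi2, fit$single$chi2 + 1e-9)
    expect_gte(fit$improvement_pct, 0)
    expect_lte(fit$improvement_pct, 100)
    expect_equal(fit$selected, fit$improvement_pct >= 5)
  }
})

test_that("select_model applies the 5% improvement rule and AIC", {
  fake_fit <- function(chi2, k, class) {
    structure(list(chi2 = chi2, aic = chi2 + 2 * k, k = k),
              class = c(class, "likertbin_fit"))
  }
  single <- fake_fit(100, 1, "binomial_fit")
  expect_equal(single$aic, 102)
  expect_equal(fake_fit(10, 1, "binomial_fit")$aic, 12)
  sel6 <- select_model(single, fake_fit(94, 3, "mixed_fit"))
  expect_equal(sel6$selected, "mixed")
  expect_equal(sel6$improvement_pct, 6)
  sel4 <- select_model(single, fake_fit(96, 3, "mixed_fit"),
                       fake_fit(95, 2, "normal_fit"))
  expect_equal(sel4$selected, "binomial")
  expect_equal(sel4$improvement_pct, 4)
  expect_equal(unname(sel4$aic), c(102, 102, 99))
})

test_that("fitted p_B tracks the item mean across a binomial bank", {
  bank <- generate_item_bank(n_items = 60, N = 1731, seed = 31)
  p_hat <- vapply(bank$counts, function(cc) fit_binomial(cc)$p_B,
                  numeric(1))
  means <- vapply(bank$counts, mean_score, numeric(1))
  expect_gt(cor(means, p_hat), 0.999)
  # the link is the affine map (mean - 1) / (m - 1)
  expect_lt(max(abs(p_hat - (means - 1) / 4)), 0.01)
})

test_that("fitted_probs reproduces each model family", {
  cnt <- response_counts(c(100, 150, 300, 250, 200))
  fb <- fit_binomial(cnt)
  expect_equal(as.numeric(fitted_probs(fb)),
               dbinom(0:4, 4, fb$p_B))
  fm <- fit_mixed_binomial(cnt)
  expect_equal(sum(fitted_probs(fm)), 1, tolerance = 1e-12)
  fn <- fit_normal(cnt)
  expect_equal(sum(fitted_probs(fn)), 1, tolerance = 1e-12)
})
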