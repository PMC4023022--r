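test_that("sample_item_counts conserves totals in both modes", {
  probs <- category_probabilities(0.4)
  s <- sample_item_counts(probs, 10, seed = 1)
  expect_equal(sum(s$counts), 10)
  expect_true(all(s$counts >= 0 & s$counts == round(s$counts)))
  # degenerate distribution puts everything in one category
  deg <- sample_item_counts(c(0, 0, 0, 0, 1), 50, seed = 2)
  expect_equal(unname(deg$counts), c(0, 0, 0, 0, 50))
  # expected mode returns exact real-valued expected counts
  e <- sample_item_counts(probs, 1731, mode = "expected")
  expect_equal(unname(e$counts), 1731 * as.numeric(probs))
  # at large N sampled frequencies approach the generating probabilities
  big <- sample_item_counts(probs, 1e5, seed = 3)
  se <- sqrt(as.numeric(probs) * (1 - as.numeric(probs)) / 1e5)
  expect_true(all(abs(big$counts / 1e5 - as.numeric(probs)) <= 3 * se))
})

test_that("inject_bias shifts mass onto one category and renormalises", {
  probs <- category_probabilities(0.5)
  out <- inject_bias(probs, 3, 0.2)
  expect_equal(sum(out), 1, tolerance = 1e-12)
  expect_equal(out[[3]], 0.375 + 0.2)
  # the other categories keep their relative proportions
  expect_equal(out[[1]] / out[[2]], probs[[1]] / probs[[2]],
               tolerance = 1e-12)
  # negative delta models category avoidance
  avoid <- inject_bias(probs, 3, -0.2)
  expect_equal(avoid[[3]], 0.175)
  expect_error(inject_bias(probs, 3, 0.7), "outside")
})

test_that("the default bank reproduces the reference study conditions", {
  bank <- generate_item_bank(seed = 100)
  expect_equal(length(bank$counts), 240)
  expect_equal(nrow(bank$truth), 240)
  expect_true(all(vapply(bank$counts, function(x) sum(x$counts),
                         numeric(1)) == 1731))
  expect_true(all(bank$truth$p_B >= 0.05 & bank$truth$p_B <= 0.95))
  # the drawn probabilities track the surrogate distribution's moments
  expect_lt(abs(mean(bank$truth$p_B) - 0.56), 0.03)
  expect_lt(abs(sd(bank$truth$p_B) - 0.13), 0.03)
})

test_that("generation is reproducible under a seed", {
  a <- generate_item_bank(n_items = 15, N = 300, seed = 7)
  b <- generate_item_bank(n_items = 15, N = 300, seed = 7)
  expect_identical(a$truth, b$truth)
  expect_identical(lapply(a$counts, `[[`, "counts"),
                   lapply(b$counts, `[[`, "counts"))
  c <- generate_item_bank(n_items = 15, N = 300, seed = 8)
  expect_false(identical(a$truth$p_B, c$truth$p_B))
})

test_that("the truth log round-trips losslessly through JSON", {
  bank <- generate_item_bank(n_items = 8, N = 200,
                             mixture_fraction = 0.5,
                             bias_items = 3, bias_category = 5,
                             bias_delta = 0.15, seed = 21)
  path <- withr::local_tempfile(fileext = ".json")
  write_truth_log(bank$truth, path)
  back <- read_truth_log(path)
  expect_equal(back, bank$truth)
  expect_equal(attr(back, "seed"), 21)
  expect_equal(attr(back, "mode"), "sampled")
})

test_that("a pure mixture bank records and recovers its fixed triple", {
  bank <- generate_item_bank(n_items = 5, N = 1731,
                             mixture_fraction = 1,
                             mixture_params = list(p_B = 0.08, q_B = 0.80,
                                                   w = 0.66),
                             mode = "expected", seed = 9)
  expect_true(all(bank$truth$model == "mixed"))
  expect_true(all(bank$truth$p_B == 0.08 & bank$truth$q_B == 0.80 &
                    bank$truth$w == 0.66))
  fit <- fit_mixed_binomial(bank$counts[[1]])
  expect_equal(c(fit$p_B, fit$q_B, fit$w), c(0.08, 0.80, 0.66))
})

test_that("expected-mode binomial banks are recovered end to end", {
  bank <- generate_item_bank(n_items = 30, N = 1731, mode = "expected",
                             seed = 44)
  p_hat <- vapply(bank$counts, function(cc) fit_binomial(cc)$p_B,
                  numeric(1))
  expect_lt(max(abs(p_hat - bank$truth$p_B)), 1e-4)
})

test_that("a 12% noise bank leaves no item fitting at the 5% level", {
  bank <- generate_item_bank(n_items = 60, N = 1731,
                             noise_fraction = 0.12, mode = "expected",
                             seed = 55)
  chi2 <- vapply(bank$counts, function(cc) fit_binomial(cc)$chi2,
                 numeric(1))
  expect_true(all(chi2 > qchisq(0.95, 4)))
})

test_that("inconsistent configurations are rejected", {
  expect_error(generate_item_bank(n_items = 5, mixture_fraction = 1.2),
               "mixture_fraction")
  expect_error(generate_item_bank(n_items = 5, noise_fraction = -0.1),
               "noise_fraction")
  expect_error(generate_item_bank(n_items = 5, bias_items = 2),
               "bias_category")
})
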