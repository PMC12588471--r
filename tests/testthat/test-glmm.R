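# Random-intercept logistic regression and the frequentist decision rules.

test_that("participant aggregation conserves counts and pools REG trials", {
  trials <- dplyr::bind_rows(
    fake_trials(rep(c(TRUE, FALSE), 18), "X", participants = 2L),
    fake_trials(rep(TRUE, 10), "X", arm = "reg")
  )
  counts <- aggregate_by_participant(trials, "X")
  expect_equal(nrow(counts), 3)  # two participants + one REG pseudo-group
  expect_equal(sum(counts$k), sum(trials$hit))
  expect_equal(sum(counts$n), nrow(trials))
  expect_equal(counts$n[counts$participant_id != "reg"], c(18, 18))
  expect_error(aggregate_by_participant(trials, "O"), "absent")
})

test_that("homogeneous data reduce to the pooled binomial fit", {
  # between-participant spread at or below the binomial expectation drives
  # the variance component to its boundary, where the fit is exactly the
  # pooled logit
  k <- rep(c(8, 9, 10), length.out = 42)
  fit <- fit_random_intercept_logit(tibble::tibble(k = k, n = 18))
  p_pool <- sum(k) / (42 * 18)
  expect_equal(fit$beta0, qlogis(p_pool), tolerance = 1e-6)
  expect_equal(fit$sigma_u, 0)
  se_binom <- 1 / sqrt(42 * 18 * p_pool * (1 - p_pool))
  expect_equal(fit$se_beta0, se_binom, tolerance = 0.01)
  expect_true(fit$converged)
})

test_that("GH quadrature matches direct integration of participant likelihoods", {
  counts <- tibble::tibble(k = c(3, 10, 7, 15, 0), n = c(10, 18, 18, 18, 5))
  direct_ll <- function(beta0, sigma) {
    sum(vapply(seq_len(nrow(counts)), function(i) {
      log(stats::integrate(
        function(u) dbinom(counts$k[i], counts$n[i], plogis(beta0 + u)) *
          dnorm(u, 0, sigma),
        -Inf, Inf, rel.tol = 1e-12, abs.tol = 0)$value)
    }, numeric(1)))
  }
  gh <- function(beta0, sigma, q) {
    metapsi:::gh_loglik(beta0, sigma, counts$k, counts$n,
                        pracma::gaussHermite(q))
  }
  for (par in list(c(0, 0.3), c(-0.4, 0.8))) {
    expect_equal(gh(par[1], par[2], 50), direct_ll(par[1], par[2]),
                 tolerance = 1e-8)
  }
  # heavier heterogeneity spreads the integrand and needs more nodes
  expect_equal(gh(0.25, 1.5, 150), direct_ll(0.25, 1.5), tolerance = 1e-8)
})

test_that("the GH-ML fit agrees with lme4 on heterogeneous data", {
  skip_if_not_installed("lme4")
  withr::local_seed(22)
  u <- rnorm(60, 0, 0.5)
  counts <- tibble::tibble(id = seq_len(60),
                           k = rbinom(60, 30, plogis(0.1 + u)), n = 30)
  fit <- fit_random_intercept_logit(counts, n_quad = 25)
  ref <- lme4::glmer(cbind(k, n - k) ~ 1 + (1 | id), data = counts,
                     family = stats::binomial(), nAGQ = 25)
  expect_equal(fit$beta0, unname(lme4::fixef(ref)), tolerance = 1e-3)
  expect_equal(fit$sigma_u,
               sqrt(unname(lme4::VarCorr(ref)$id[1])), tolerance = 0.02)
  expect_equal(fit$se_beta0,
               unname(sqrt(stats::vcov(ref)[1, 1])), tolerance = 0.02)
})

test_that("probability-scale intervals reproduce the published reporting", {
  # pure-session erotic condition: 49.48% of 37,836 -> SE 0.26 points
  fit1 <- fit_random_intercept_logit(
    tibble::tibble(k = round(0.4948 * 37836), n = 37836))
  int1 <- wald_interval(fit1, 0.95)
  expect_equal(round(int1$se_pct, 2), 0.26)
  # delta-method SE equals the binomial SE near 0.5
  expect_equal(int1$se_pct, 100 * sqrt(int1$p_hat * (1 - int1$p_hat) / 37836),
               tolerance = 0.01)
})

test_that("Wald intervals are symmetric at chance and widen with the level", {
  fit <- fit_random_intercept_logit(tibble::tibble(k = 500, n = 1000))
  int <- wald_interval(fit, 0.95)
  expect_equal(int$p_hat, 0.5)
  expect_equal(int$ci_high - 0.5, 0.5 - int$ci_low, tolerance = 1e-10)
  widths <- vapply(c(0.8, 0.95, 0.995, 0.9975, 0.99875), function(l) {
    i <- wald_interval(fit, l); i$ci_high - i$ci_low
  }, numeric(1))
  expect_true(all(diff(widths) > 0))
  expect_error(wald_interval(fit, 1.2), "\\(0, 1\\)")
})

test_that("the preregistered decision rules follow the CI bounds", {
  mk <- function(lo, hi, level = 0.995) {
    tibble::tibble(p_hat = (lo + hi) / 2, se_pct = 1, ci_low = lo,
                   ci_high = hi, level = level, p_value = 0.5)
  }
  expect_equal(decide_frequentist(mk(0.494, 0.505)), "M0")
  expect_equal(decide_frequentist(mk(0.501, 0.515)), "M1")
  expect_equal(decide_frequentist(mk(0.499, 0.512)), "inconclusive")
  expect_true(confirm_bidirectional(mk(0.501, 0.515, 0.95)))
  expect_false(confirm_bidirectional(mk(0.499, 0.512, 0.95)))
  expect_false(confirm_bidirectional(mk(0.5, 0.512, 0.95)))  # touching
  expect_error(confirm_bidirectional(mk(0.4, 0.6, 0.99)), "95%")
})

test_that("two-sided confirmation discriminates the published replications", {
  # confirmed below-chance replication: 49.65% of 127,000
  fit2 <- fit_random_intercept_logit(
    tibble::tibble(k = round(0.4965 * 127000), n = 127000))
  expect_true(confirm_bidirectional(wald_interval(fit2, 0.95)))
  # failed second replication: 50.07% of 217,800
  fit3 <- fit_random_intercept_logit(
    tibble::tibble(k = round(0.5007 * 217800), n = 217800))
  expect_false(confirm_bidirectional(wald_interval(fit3, 0.95)))
})

test_that("sequential looks use the Bonferroni-adjusted CI levels", {
  expect_equal(vapply(1:3, ci_level_for_point, numeric(1)),
               c(0.995, 0.9975, 0.99875))
  expect_error(ci_level_for_point(4), "1, 2 or 3")
  expect_error(ci_level_for_point(0), "1, 2 or 3")
})

test_that("degenerate counts are rejected rather than silently fitted", {
  expect_error(fit_random_intercept_logit(tibble::tibble(k = 5, n = 5)),
               "degenerate")
  expect_error(fit_random_intercept_logit(tibble::tibble(k = 6, n = 5)),
               "invalid")
})
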