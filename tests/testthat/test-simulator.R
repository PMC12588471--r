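# Trial-level simulator of the guessing paradigm.

test_that("session plans exhaust the image pool with the designed composition", {
  withr::local_seed(1)
  pure <- build_session_plan("pure")
  expect_equal(nrow(pure), 36)
  expect_equal(sort(unique(pure$trial_index)), 1:36)
  expect_equal(as.list(table(pure$condition)), list(O = 18L, X = 18L))
  expect_equal(sort(pure$image_id),
               sort(c(sprintf("e%02d", 1:18), sprintf("n%02d", 1:18))))

  mixed <- build_session_plan("mixed")
  tab <- table(mixed$condition)
  expect_equal(as.integer(tab[c("X", "O", "SX", "SO")]), rep(9L, 4))
  expect_equal(sum(mixed$condition %in% c("SX", "SO")), 18)
  expect_equal(anyDuplicated(mixed$image_id), 0)
  # erotic images back erotic-condition trials only
  expect_true(all(startsWith(
    mixed$image_id[mixed$condition %in% c("X", "SX")], "e")))
})

test_that("identical seeds give byte-identical studies", {
  cfg <- study_config(8, "mixed", heterogeneity_sd = 0.2,
                      incomplete_session_prob = 0.3, seed = 99)
  expect_identical(simulate_study(cfg), simulate_study(cfg))
  set.seed(5); a <- build_session_plan("pure")
  set.seed(5); b <- build_session_plan("pure")
  expect_identical(a, b)
})

test_that("sham trials never display the reward; rewards imply hits", {
  trials <- simulate_study(study_config(40, "mixed", seed = 2))
  expect_false(any(trials$reward_shown & trials$condition %in% c("SX", "SO")))
  expect_true(all(trials$hit[trials$reward_shown]))
  expect_false(any(trials$reward_shown & !trials$hit))
  expect_equal(trials$hit, trials$guess_side == trials$target_side)
})

test_that("a null pure study has the designed trial bookkeeping", {
  trials <- simulate_study(study_config(10, "pure", seed = 3))
  expect_equal(nrow(trials), 360)
  expect_equal(as.list(table(trials$condition)), list(O = 180L, X = 180L))
  expect_equal(dplyr::n_distinct(trials$participant_id), 10)
})

test_that("human-arm hit rates track the configured base rate", {
  # Bem-sized erotic effect: 0.531 over ~1,560 erotic trials
  cfg <- study_config(87, "pure", base_rates = c(X = 0.531, O = 0.5),
                      seed = 4)
  trials <- simulate_study(cfg)
  x <- trials[trials$condition == "X", ]
  expect_gte(nrow(x), 1560)
  se <- sqrt(0.531 * 0.469 / nrow(x))
  expect_lt(abs(mean(x$hit) - 0.531), 3 * se)
})

test_that("the all-zero bias, zero-heterogeneity simulator is exactly null", {
  cfg <- study_config(700, "mixed", seed = 5)
  trials <- simulate_study(cfg)
  props <- tapply(trials$hit, trials$condition, mean)
  ns <- tapply(trials$hit, trials$condition, length)
  expect_true(all(ns >= 6000))
  expect_true(all(abs(props - 0.5) < 4 * sqrt(0.25 / ns)))
  # rejection-rate calibration of a two-sided 5% test over repeated nulls
  withr::local_seed(6)
  reject <- replicate(200, {
    tr <- simulate_study(study_config(15, "pure"))
    k <- sum(tr$hit[tr$condition == "X"]); n <- sum(tr$condition == "X")
    abs((k / n - 0.5) / sqrt(0.25 / n)) > qnorm(0.975)
  })
  expect_lt(abs(mean(reject) - 0.05), 3 * sqrt(0.05 * 0.95 / 200))
})

test_that("REG-arm agreement and side channels follow the injected class-A bias", {
  cfg <- study_config(1, "pure", arm = "reg",
                      bias = bias_spec(side_delta = 0.05))
  withr::local_seed(7)
  rec <- draw_trial_outcome(big_plan(1e6), 0, cfg)
  # two independent channels at P(left) = 0.55 agree w.p. 0.55^2 + 0.45^2
  p_hit <- 0.5 + 2 * 0.05^2
  expect_lt(abs(mean(rec$hit) - p_hit), 3 * sqrt(p_hit * (1 - p_hit) / 1e6))
  expect_lt(abs(mean(rec$target_side == "left") - 0.55),
            3 * sqrt(0.55 * 0.45 / 1e6))
  expect_lt(abs(mean(rec$guess_side == "left") - 0.55),
            3 * sqrt(0.55 * 0.45 / 1e6))
})

test_that("counterfactual arm switch leaves the null hit process unchanged", {
  # human arm at base rate 0.5 and the REG arm generate exchangeable
  # Bernoulli(0.5) hit sequences: compare large-sample hit counts
  withr::local_seed(8)
  human <- simulate_study(study_config(400, "pure", arm = "human"))
  reg <- simulate_study(study_config(400, "pure", arm = "reg"))
  tst <- prop.test(c(sum(human$hit), sum(reg$hit)),
                   c(nrow(human), nrow(reg)))
  expect_gt(tst$p.value, 0.001)
  expect_equal(nrow(human), nrow(reg))
})

test_that("incomplete sessions truncate and overruns stay within the cap", {
  short <- simulate_study(study_config(50, "pure", overrun_prob = 0,
                                       incomplete_session_prob = 0.9,
                                       seed = 9))
  per <- dplyr::count(short, session_id)
  expect_true(all(per$n >= 1 & per$n <= 36))
  expect_gt(mean(per$n < 36), 0.5)
  cfg <- study_config(50, "pure", overrun_prob = 0.9, overrun_max = 40L,
                      seed = 10)
  over <- simulate_study(cfg)
  per <- dplyr::count(over, session_id)
  expect_true(all(per$n >= 36 & per$n <= 40))
  expect_gt(mean(per$n > 36), 0.5)
  expect_error(study_config(1, "pure", incomplete_session_prob = 1))
  expect_error(study_config(1, "pure", overrun_prob = 1))
})

test_that("heterogeneity inflates between-participant spread", {
  withr::local_seed(12)
  flat <- simulate_study(study_config(150, "pure", heterogeneity_sd = 0))
  wide <- simulate_study(study_config(150, "pure", heterogeneity_sd = 1.5))
  spread <- function(tr) {
    var(tapply(tr$hit, tr$participant_id, mean))
  }
  expect_gt(spread(wide), 2 * spread(flat))
})

test_that("invalid conditions and configs are rejected", {
  cfg <- study_config(1, "pure")
  bad <- tibble::tibble(condition = "Z", trial_index = 1L, image_id = "e01")
  expect_error(draw_trial_outcome(bad, 0, cfg), "invalid condition")
  expect_error(study_config(1, "pure", base_rates = c(X = 0.5)),
               "exactly the conditions")
  expect_error(study_config(1, "pure", base_rates = c(X = 1, O = 0.5)),
               "\\(0, 1\\)")
  expect_error(study_config(1, "pure", overrun_max = 50L))
  expect_error(bias_spec(side_delta = 0.6), "inside")
  expect_warning(study_config(1, "pure", arm = "reg",
                              base_rates = c(X = 0.5, O = 0.5)), "ignored")
})

test_that("trial tables round-trip losslessly through CSV", {
  path <- withr::local_tempfile(fileext = ".csv")
  trials <- simulate_study(study_config(5, "mixed", seed = 13))
  write_trials(trials, path)
  back <- read_trials(path)
  expect_equal(as.data.frame(back), as.data.frame(trials[names(back)]))

  empty <- trials[0, ]
  write_trials(empty, path)
  expect_equal(nrow(read_trials(path)), 0)

  bad <- trials
  bad$condition[3] <- "Q"
  write_trials(bad, path)
  expect_error(read_trials(path), "condition.*Q")

  utils::write.csv(trials[-1], path, row.names = FALSE)
  expect_error(read_trials(path), "participant_id")
})
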