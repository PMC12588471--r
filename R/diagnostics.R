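# The advanced meta-experimental protocol (AMP) layer: the full test
# battery across conditions and arms, class-A error detection on
# counterfactual REG arms, side-bias checks, and whole-pipeline error-rate
# calibration.

#' Run the full test battery across every condition and arm
#'
#' For each (condition, arm) present in the table: hit percentage with
#' delta-method SE, two-sided Wald p-value from the intercept-only
#' random-intercept fit (pooled fit on the REG arm, which has no participant
#' grouping), BF01 under each prior, and the preregistered frequentist
#' decision at `level`.
#'
#' @param trials A trial tibble.
#' @param priors Named list of priors for the Bayes tests (default
#'   [tpp_priors()]); set to `NULL` to skip the Bayes columns.
#' @param level Confidence level for the frequentist decision (default
#'   0.995, the first-look preregistered level).
#' @return A `condition_battery` tibble, one row per (condition, arm).
#' @export
condition_battery <- function(trials, priors = tpp_priors(), level = 0.995) {
  check_trials(trials)
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  groups <- trials |>
    dplyr::distinct(.data$condition, .data$arm) |>
    dplyr::arrange(match(.data$condition, condition_levels), .data$arm)
  rows <- purrr::pmap(groups, function(condition, arm) {
    sub <- trials[trials$condition == condition & trials$arm == arm, ]
    counts <- aggregate_by_participant(sub, condition)
    fit <- fit_random_intercept_logit(counts)
    interval <- wald_interval(fit, level)
    row <- tibble::tibble(
      condition = condition, arm = arm,
      n = nrow(sub), hits = sum(sub$hit),
      hit_pct = 100 * interval$p_hat, se_pct = interval$se_pct,
      p_value = interval$p_value, decision = decide_frequentist(interval)
    )
    if (!is.null(priors)) {
      bf <- purrr::map_dbl(priors,
                           ~ bf01_one_sided(sum(sub$hit), nrow(sub), .x)$bf01)
      row <- dplyr::bind_cols(row, tibble::as_tibble(as.list(
        stats::setNames(bf, paste0("bf01_", names(priors))))))
    }
    row
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("condition_battery", class(out))
  out
}

#' Plot a condition battery as a Table-1-style bar chart
#'
#' Hit percentages per condition and arm with standard-error whiskers and a
#' dashed chance line at 50%.
#'
#' @param object A `condition_battery` tibble.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.condition_battery <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(x = .data$condition, y = .data$hit_pct,
                               fill = .data$arm)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9), width = 0.8) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$hit_pct - .data$se_pct,
                   ymax = .data$hit_pct + .data$se_pct),
      position = ggplot2::position_dodge(0.9), width = 0.25) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::coord_cartesian(
      ylim = c(min(48, min(object$hit_pct) - 1),
               max(52, max(object$hit_pct) + 1))) +
    ggplot2::labs(x = "condition", y = "hit rate (%)", fill = "arm")
}

#' Class-A systematic-error check on a counterfactual arm
#'
#' Trials on the REG arm are produced without participants, so any
#' deviation of their hit rate from 50% indicates systematic bias in the
#' measurement process itself (class-A error). Runs a two-sided Wald
#' proportion test of the hit rate against 0.5 for each REG condition.
#'
#' @param reg_trials A trial tibble containing only `arm == "reg"` rows.
#' @param alpha Two-sided significance level (default 0.05).
#' @return A `class_a_report`: a tibble with per-condition estimates, CIs
#'   and rejection flags, carrying attribute `verdict` (`"no_evidence"` or
#'   `"class_a_detected"` when any condition rejects).
#' @export
class_a_check <- function(reg_trials, alpha = 0.05) {
  check_trials(reg_trials)
  if (nrow(reg_trials) == 0) stop("empty trial table", call. = FALSE)
  if (any(reg_trials$arm != "reg")) {
    stop("class-A check is defined on the REG arm only; human-arm rows present",
         call. = FALSE)
  }
  z <- stats::qnorm(1 - alpha / 2)
  out <- reg_trials |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n = dplyr::n(), hits = sum(.data$hit),
                     .groups = "drop") |>
    dplyr::mutate(
      hit_rate = .data$hits / .data$n,
      se = sqrt(.data$hit_rate * (1 - .data$hit_rate) / .data$n),
      bias_hat = .data$hit_rate - 0.5,
      ci_low = .data$hit_rate - z * .data$se,
      ci_high = .data$hit_rate + z * .data$se,
      p_value = 2 * stats::pnorm(-abs(.data$bias_hat / .data$se)),
      reject = .data$p_value < alpha
    )
  verdict <- if (any(out$reject)) "class_a_detected" else "no_evidence"
  structure(out, verdict = verdict,
            class = c("class_a_report", class(out)))
}

#' Side-bias check on targets and guesses
#'
#' 95% Wald confidence intervals for P(left target) and P(left guess) per
#' condition, flagging whether each contains the theoretically expected 0.5.
#'
#' @param trials A trial tibble.
#' @return A tibble, one row per condition and channel (`target`/`guess`):
#'   `p_left`, `ci_low`, `ci_high`, `contains_half`.
#' @export
side_bias_check <- function(trials) {
  check_trials(trials)
  if (nrow(trials) == 0) stop("empty trial table", call. = FALSE)
  z <- stats::qnorm(0.975)
  trials |>
    tidyr::pivot_longer(c("target_side", "guess_side"),
                        names_to = "channel", values_to = "side") |>
    dplyr::mutate(channel = sub("_side$", "", .data$channel)) |>
    dplyr::group_by(.data$condition, .data$channel) |>
    dplyr::summarise(n = dplyr::n(), p_left = mean(.data$side == "left"),
                     .groups = "drop") |>
    dplyr::mutate(
      se = sqrt(.data$p_left * (1 - .data$p_left) / .data$n),
      ci_low = .data$p_left - z * .data$se,
      ci_high = .data$p_left + z * .data$se,
      contains_half = .data$ci_low <= 0.5 & 0.5 <= .data$ci_high
    )
}

#' Calibrate whole-pipeline error rates over a scenario grid
#'
#' For each scenario (true rate, heterogeneity, class-A bias, arm) runs
#' `reps` count-level sequential studies through the four-test battery and
#' tabulates the fraction reaching each joint decision. REG-arm scenarios
#' apply the dual-channel class-A agreement rate 0.5 + 2 delta^2.
#'
#' @param scenarios A data frame with columns `name`, `p_true`,
#'   `heterogeneity_sd`, `side_delta`, `arm` (missing columns default to
#'   the null: 0.5, 0, 0, "human").
#' @param reps Replicates per scenario (>= 500).
#' @param seed Optional seed.
#' @param design A [design_spec()].
#' @return A tibble, one row per scenario: fractions `stop_m0`, `stop_m1`,
#'   `inconclusive`.
#' @export
estimate_error_rates <- function(scenarios, reps = 1000, seed = NULL,
                                 design = design_spec()) {
  stopifnot(is.data.frame(scenarios), nrow(scenarios) >= 1, reps >= 500)
  maybe_set_seed(seed)
  defaults <- list(name = NA_character_, p_true = 0.5, heterogeneity_sd = 0,
                   side_delta = 0, arm = "human")
  for (col in names(defaults)) {
    if (!col %in% names(scenarios)) scenarios[[col]] <- defaults[[col]]
  }
  purrr::pmap_dfr(
    scenarios[names(defaults)],
    function(name, p_true, heterogeneity_sd, side_delta, arm) {
      p_eff <- if (arm == "reg") 0.5 + 2 * side_delta^2 else p_true
      K <- simulate_look_counts(p_eff, heterogeneity_sd, design, reps)
      decision <- sequential_decide_counts(K, design)
      tibble::tibble(name = name, arm = arm, p_effective = p_eff,
                     stop_m0 = mean(decision == "M0"),
                     stop_m1 = mean(decision == "M1"),
                     inconclusive = mean(decision == "inconclusive"))
    })
}
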