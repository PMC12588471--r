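# Trial-level simulator of the forced-choice guessing paradigm: 36-trial
# sessions drawing 18 erotic + 18 neutral reward images without replacement,
# the target side drawn with replacement after the guess, sham trials that
# never display the reward, REG-substituted counterfactual arms, participant
# heterogeneity on the log-odds scale, and injectable systematic biases.

#' Injectable systematic-error parameters
#'
#' Parameterises the three classes of systematic error the simulator can
#' inject. `side_delta` (class A) shifts P(left) of *both* random binary
#' channels — the target-side draw and, on REG arms, the substituted guess —
#' by the same signed offset, emulating a biased random event generator;
#' on REG arms a shared offset delta on both channels raises the agreement
#' (hit) probability to 0.5 + 2 delta^2. `session_drift` (class B) adds a
#' per-repeated-session log-odds drift to a participant's hit probability.
#' `control_delta` (class C) adds a log-odds offset only in the neutral
#' control conditions (O, SO). With all three at zero the simulator is
#' exactly null: every condition's hit probability equals its base rate.
#'
#' @param side_delta Signed offset on P(left) of the target and REG-guess
#'   channels; `0.5 + side_delta` must stay in (0, 1).
#' @param session_drift Additive log-odds drift per repeated session index.
#' @param control_delta Additive log-odds offset for control conditions.
#' @return A `bias_spec` object.
#' @examples
#' bias_spec(side_delta = 0.05)
#' @export
bias_spec <- function(side_delta = 0, session_drift = 0, control_delta = 0) {
  stopifnot(is.numeric(side_delta), is.numeric(session_drift),
            is.numeric(control_delta))
  if (0.5 + side_delta <= 0 || 0.5 + side_delta >= 1) {
    stop("`side_delta` must keep 0.5 + side_delta inside (0, 1)",
         call. = FALSE)
  }
  structure(list(side_delta = side_delta, session_drift = session_drift,
                 control_delta = control_delta),
            class = "bias_spec")
}

#' Study configuration for the paradigm simulator
#'
#' Describes one simulated study arm. Pure sessions contain 18 true-erotic
#' (X) and 18 true-neutral (O) trials; mixed sessions contain 18 true trials
#' (9 X + 9 O) interleaved with 18 sham trials (9 SX + 9 SO) on which the
#' reward image is never displayed. The `human` arm draws each hit at the
#' condition's base rate (plus participant effect and bias terms) on the
#' log-odds scale; the `reg` arm replaces the participant with a random
#' event generator, so hits arise purely from the agreement of two
#' independent binary channels and base rates are not used.
#'
#' @param n_participants Number of participants (or pseudo-sessions on the
#'   REG arm).
#' @param session_type `"pure"` or `"mixed"`.
#' @param arm `"human"` or `"reg"`.
#' @param base_rates Named vector of true hit probabilities per condition.
#'   Must cover exactly the conditions implied by `session_type`; defaults
#'   to 0.5 everywhere (the null). Ignored with a warning on the REG arm.
#' @param heterogeneity_sd SD (>= 0) of participant random intercepts on the
#'   log-odds scale.
#' @param bias A [bias_spec()].
#' @param n_trials_target Pre-specified analysis sample size per condition,
#'   carried for downstream inclusion/truncation (default 37836).
#' @param incomplete_session_prob Probability a session is abandoned early
#'   (truncated uniformly to 1-35 trials).
#' @param overrun_prob Probability a session over-runs with 1-6 extra
#'   trials (to at most `overrun_max`); the default mirrors the rare
#'   (< 0.05% of trials) connection-latency overruns seen in practice.
#' @param overrun_max Hard per-session cap, between 36 and 42 trials.
#' @param sessions_per_participant Repeated sessions per participant; the
#'   class-B drift acts on the repeat index.
#' @param seed Optional integer seed making [simulate_study()] fully
#'   reproducible.
#' @return A `study_config` object.
#' @examples
#' study_config(n_participants = 10, session_type = "pure")
#' @export
study_config <- function(n_participants,
                         session_type = c("pure", "mixed"),
                         arm = c("human", "reg"),
                         base_rates = NULL,
                         heterogeneity_sd = 0,
                         bias = bias_spec(),
                         n_trials_target = 37836L,
                         incomplete_session_prob = 0,
                         overrun_prob = 0.0005,
                         overrun_max = 42L,
                         sessions_per_participant = 1L,
                         seed = NULL) {
  session_type <- match.arg(session_type)
  arm <- match.arg(arm)
  stopifnot(is.numeric(n_participants), n_participants >= 1,
            is.numeric(heterogeneity_sd), heterogeneity_sd >= 0,
            inherits(bias, "bias_spec"),
            incomplete_session_prob >= 0, incomplete_session_prob < 1,
            overrun_prob >= 0, overrun_prob < 1,
            overrun_max >= 36, overrun_max <= 42,
            sessions_per_participant >= 1)
  conds <- session_conditions(session_type)
  if (arm == "reg") {
    if (!is.null(base_rates)) {
      warning("base_rates are ignored on the REG arm: hits arise from ",
              "channel agreement", call. = FALSE)
    }
    base_rates <- NULL
  } else {
    if (is.null(base_rates)) {
      base_rates <- stats::setNames(rep(0.5, length(conds)), conds)
    }
    if (!setequal(names(base_rates), conds)) {
      stop(sprintf("base_rates must name exactly the conditions %s",
                   paste(conds, collapse = ", ")), call. = FALSE)
    }
    if (any(base_rates <= 0) || any(base_rates >= 1)) {
      stop("all base rates must lie in (0, 1)", call. = FALSE)
    }
  }
  structure(
    list(n_participants = as.integer(n_participants),
         session_type = session_type, arm = arm, base_rates = base_rates,
         heterogeneity_sd = heterogeneity_sd, bias = bias,
         n_trials_target = as.integer(n_trials_target),
         incomplete_session_prob = incomplete_session_prob,
         overrun_prob = overrun_prob, overrun_max = as.integer(overrun_max),
         sessions_per_participant = as.integer(sessions_per_participant),
         seed = seed),
    class = "study_config"
  )
}

session_conditions <- function(session_type) {
  if (session_type == "pure") c("X", "O") else c("X", "O", "SX", "SO")
}

#' Plan one 36-trial session
#'
#' Draws the per-trial conditions and reward-image assignment for a single
#' session. The 36-image pool (18 erotic `e01`-`e18`, 18 neutral
#' `n01`-`n18`) is exhausted exactly once: erotic images back X and SX
#' trials, neutral images back O and SO trials. A pure session holds 18 X
#' and 18 O trials; a mixed session holds 18 true trials (9 X + 9 O)
#' interleaved with 18 sham trials (9 SX + 9 SO). Trial order and the
#' image-to-trial assignment are randomised from the ambient RNG stream.
#'
#' @param session_type `"pure"` or `"mixed"`.
#' @return A tibble with 36 rows: `condition`, `trial_index`, `image_id`.
#' @examples
#' set.seed(1)
#' build_session_plan("mixed")
#' @export
build_session_plan <- function(session_type = c("pure", "mixed")) {
  session_type <- match.arg(session_type)
  conds <- if (session_type == "pure") {
    rep(c("X", "O"), each = 18L)
  } else {
    rep(c("X", "O", "SX", "SO"), each = 9L)
  }
  conds <- sample(conds)
  erotic <- sample(sprintf("e%02d", 1:18))
  neutral <- sample(sprintf("n%02d", 1:18))
  image_id <- character(36L)
  is_erotic <- conds %in% c("X", "SX")
  image_id[is_erotic] <- erotic
  image_id[!is_erotic] <- neutral
  tibble::tibble(condition = conds, trial_index = 1:36, image_id = image_id)
}

# hit probability on the human arm for a block of planned trials
human_hit_prob <- function(condition, base_rates, participant_effect,
                           session_repeat, bias) {
  eta <- logit(unname(base_rates[condition])) + participant_effect +
    bias$session_drift * (session_repeat - 1)
  eta <- eta + ifelse(condition %in% c("O", "SO"), bias$control_delta, 0)
  inv_logit(eta)
}

#' Draw the outcome of planned trials
#'
#' Completes a session plan into trial records. On the human arm the hit
#' indicator is drawn directly at the configured probability — only the hit
#' process is statistically identified, so the guess side is back-filled to
#' agree with the independently drawn target side exactly when the trial is
#' a hit. On the REG arm the guess is itself a (possibly class-A-biased)
#' random binary channel, and the hit is the agreement of guess and target.
#' The target side is always drawn with replacement, after the guess, with
#' P(left) = 0.5 + `side_delta`. Sham trials never display the reward.
#'
#' @param spec A session-plan tibble from [build_session_plan()] (any subset
#'   of rows).
#' @param participant_effect Log-odds offset of this participant (0 for REG).
#' @param config A [study_config()].
#' @param session_repeat Repeat index of this session for the participant.
#' @return `spec` extended with `guess_side`, `target_side`, `hit`,
#'   `reward_shown`.
#' @export
draw_trial_outcome <- function(spec, participant_effect, config,
                               session_repeat = 1L) {
  stopifnot(inherits(config, "study_config"))
  if (!all(spec$condition %in% condition_levels)) {
    stop("invalid condition in trial plan", call. = FALSE)
  }
  m <- nrow(spec)
  delta_a <- config$bias$side_delta
  target_left <- stats::runif(m) < 0.5 + delta_a
  if (config$arm == "reg") {
    guess_left <- stats::runif(m) < 0.5 + delta_a
    hit <- guess_left == target_left
  } else {
    if (!all(spec$condition %in% names(config$base_rates))) {
      stop("no base rate defined for some condition in the plan",
           call. = FALSE)
    }
    p_hit <- human_hit_prob(spec$condition, config$base_rates,
                            participant_effect, session_repeat, config$bias)
    hit <- stats::runif(m) < p_hit
    guess_left <- ifelse(hit, target_left, !target_left)
  }
  spec |>
    dplyr::mutate(
      guess_side = ifelse(guess_left, "left", "right"),
      target_side = ifelse(target_left, "left", "right"),
      hit = hit,
      reward_shown = hit & .data$condition %in% c("X", "O")
    )
}

#' Simulate a full study arm
#'
#' Generates trial records for `n_participants * sessions_per_participant`
#' sessions. Participant effects are drawn from Normal(0, heterogeneity_sd^2)
#' on the log-odds scale; incomplete sessions (truncated uniformly to 1-35
#' trials) and over-run sessions (1-6 extra trials, capped at
#' `overrun_max`) occur at the configured probabilities. Fully reproducible
#' from `config$seed`.
#'
#' @param config A [study_config()].
#' @return A tibble of trial records with columns `participant_id`,
#'   `session_id`, `session_type`, `arm`, `condition`, `trial_index`,
#'   `guess_side`, `target_side`, `hit`, `reward_shown`.
#' @examples
#' trials <- simulate_study(study_config(10, "pure", seed = 1))
#' dplyr::count(trials, condition)
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  maybe_set_seed(config$seed)
  n_part <- config$n_participants
  reps <- config$sessions_per_participant
  effects <- if (config$arm == "reg") {
    rep(0, n_part)
  } else {
    stats::rnorm(n_part, 0, config$heterogeneity_sd)
  }
  sessions <- tidyr::expand_grid(part = seq_len(n_part),
                                 rep = seq_len(reps))
  records <- purrr::pmap(sessions, function(part, rep) {
    plan <- build_session_plan(config$session_type)
    if (stats::runif(1) < config$incomplete_session_prob) {
      plan <- plan[seq_len(sample.int(35L, 1L)), , drop = FALSE]
    } else if (stats::runif(1) < config$overrun_prob) {
      extra_n <- min(sample.int(6L, 1L), config$overrun_max - 36L)
      if (extra_n > 0) {
        extra <- plan[sample.int(36L, extra_n), , drop = FALSE]
        extra$trial_index <- 36L + seq_len(extra_n)
        plan <- dplyr::bind_rows(plan, extra)
      }
    }
    out <- draw_trial_outcome(plan, effects[[part]], config,
                              session_repeat = rep)
    out$participant_id <- sprintf("p%05d", part)
    out$session_id <- sprintf("p%05d_s%02d", part, rep)
    out
  })
  dplyr::bind_rows(records) |>
    dplyr::mutate(session_type = config$session_type, arm = config$arm) |>
    dplyr::select(dplyr::all_of(trial_columns), "image_id")
}

#' Write / read a trial table as CSV
#'
#' Lossless round-trip of a trial table with a fixed, documented column
#' order (`participant_id`, `session_id`, `session_type`, `arm`,
#' `condition`, `trial_index`, `guess_side`, `target_side`, `hit`,
#' `reward_shown`, optionally `image_id`). `read_trials()` validates the
#' header and every enum column, naming the offending column and rows on
#' failure.
#'
#' @param trials A trial tibble.
#' @param path File path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()`
#'   returns the trial tibble.
#' @export
write_trials <- function(trials, path) {
  check_trials(trials)
  cols <- c(trial_columns, intersect("image_id", names(trials)))
  readr::write_csv(trials[cols], path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  header <- names(readr::read_csv(path, n_max = 0,
                                  col_types = readr::cols(
                                    .default = readr::col_character()),
                                  progress = FALSE, show_col_types = FALSE))
  missing <- setdiff(trial_columns, header)
  if (length(missing)) {
    stop("trial file is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials <- readr::read_csv(
    path,
    col_types = readr::cols(
      participant_id = readr::col_character(),
      session_id = readr::col_character(),
      session_type = readr::col_character(),
      arm = readr::col_character(),
      condition = readr::col_character(),
      trial_index = readr::col_integer(),
      guess_side = readr::col_character(),
      target_side = readr::col_character(),
      hit = readr::col_logical(),
      reward_shown = readr::col_logical(),
      .default = readr::col_character()
    ),
    progress = FALSE, show_col_types = FALSE
  )
  checks <- list(condition = condition_levels,
                 guess_side = side_levels, target_side = side_levels,
                 session_type = c("pure", "mixed"), arm = c("human", "reg"))
  if (nrow(trials) > 0) {
    for (col in names(checks)) {
      bad <- which(!trials[[col]] %in% checks[[col]])
      if (length(bad)) {
        stop(sprintf("column `%s` has invalid value(s) %s at row(s) %s",
                     col,
                     paste(unique(trials[[col]][bad]), collapse = ", "),
                     paste(utils::head(bad, 5), collapse = ", ")),
             call. = FALSE)
      }
    }
  }
  trials
}
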