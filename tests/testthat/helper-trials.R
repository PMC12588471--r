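# Build a minimal valid trial tibble from a vector of hit indicators, for
# tests that exercise the analysis layer without the full simulator.
fake_trials <- function(hits, condition = "X", arm = "human",
                        participants = 1L, session_type = "pure") {
  n <- length(hits)
  target_left <- stats::runif(n) < 0.5
  guess_left <- ifelse(hits, target_left, !target_left)
  pid <- sprintf("p%05d", rep_len(seq_len(participants), n))
  tibble::tibble(
    participant_id = pid,
    session_id = paste0(pid, "_s01"),
    session_type = session_type,
    arm = arm,
    condition = condition,
    trial_index = as.integer(stats::ave(seq_len(n), pid, FUN = seq_along)),
    guess_side = ifelse(guess_left, "left", "right"),
    target_side = ifelse(target_left, "left", "right"),
    hit = as.logical(hits),
    reward_shown = as.logical(hits) & condition %in% c("X", "O")
  )
}

# Large block of planned trials of one condition, for vectorised
# draw_trial_outcome() calls.
big_plan <- function(n, condition = "X") {
  tibble::tibble(condition = condition, trial_index = seq_len(n),
                 image_id = "e01")
}
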