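# Rendering of study reports and the command-line entry point. A thin
# Rscript wrapper around amp_main() is installed at inst/cli/metapsi.

fmt_result <- function(hit_pct, se_pct, p_value) {
  sprintf("%.2f ± %.2f; p = %.3f", hit_pct, se_pct, p_value)
}

#' Render condition reports as a study table
#'
#' Deterministic, publication-style rendering of a [condition_battery()]
#' result: percentages and standard errors to two decimals, p-values to
#' three, the `Result (%)` cell in the conventional
#' `"49.65 +/- 0.14; p = 0.013"` form. Bayes-factor columns that are absent
#' render as blank cells.
#'
#' @param reports A `condition_battery` tibble (or any data frame with
#'   `condition`, `arm`, `n`, `hit_pct`, `se_pct`, `p_value`).
#' @param style `"markdown"` (pipe table) or `"plain"` (aligned text).
#' @return A single character string.
#' @export
render_study_table <- function(reports, style = c("markdown", "plain")) {
  style <- match.arg(style)
  stopifnot(is.data.frame(reports), nrow(reports) >= 1)
  bf_cols <- grep("^bf01_", names(reports), value = TRUE)
  cells <- tibble::tibble(
    Condition = as.character(reports$condition),
    Arm = as.character(reports$arm),
    `Result (%)` = fmt_result(reports$hit_pct, reports$se_pct,
                              reports$p_value),
    `No. Trials` = format(reports$n, big.mark = ",", trim = TRUE)
  )
  for (col in bf_cols) {
    label <- paste0("BF01 (", sub("^bf01_", "", col), ")")
    v <- reports[[col]]
    cells[[label]] <- ifelse(is.na(v), "", sprintf("%.3g", v))
  }
  header <- names(cells)
  mat <- as.matrix(cells)
  if (style == "markdown") {
    lines <- c(paste0("| ", paste(header, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(header)),
                                 collapse = "|"), "|"),
               apply(mat, 1, function(r)
                 paste0("| ", paste(r, collapse = " | "), " |")))
  } else {
    widths <- pmax(nchar(header), apply(nchar(mat), 2, max))
    pad <- function(r) paste(mapply(formatC, r, width = widths,
                                    flag = "-"), collapse = "  ")
    lines <- c(pad(header), pad(strrep("-", widths)), apply(mat, 1, pad))
  }
  paste(lines, collapse = "\n")
}

# --- minimal subcommand argument parsing -----------------------------------

parse_cli_args <- function(args) {
  out <- list()
  i <- 1
  while (i <= length(args)) {
    a <- args[[i]]
    if (!startsWith(a, "--")) {
      stop("unexpected argument: ", a, call. = FALSE)
    }
    key <- gsub("-", "_", substring(a, 3))
    if (i == length(args) || startsWith(args[[i + 1]], "--")) {
      out[[key]] <- TRUE
      i <- i + 1
    } else {
      out[[key]] <- args[[i + 1]]
      i <- i + 2
    }
  }
  out
}

read_config_file <- function(path) {
  if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
}

config_from_list <- function(cfg) {
  cfg$bias <- do.call(bias_spec, as.list(cfg$bias %||% list()))
  if (!is.null(cfg$base_rates)) cfg$base_rates <- unlist(cfg$base_rates)
  do.call(study_config, cfg)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

cli_log <- function(...) message("[metapsi] ", sprintf(...))

cli_usage <- function() {
  cat("usage: metapsi <simulate|analyze|bayes|sequential|power|diagnose|report> [--flags]\n",
      "  simulate   --config c.yaml [--seed S] --out trials.csv\n",
      "  analyze    --trials t.csv --condition X [--level 0.95] [--json]\n",
      "  bayes      --k K --n N [--prior uniform|buj|replication]\n",
      "  sequential --trials t.csv [--condition X] [--json]\n",
      "  power      --n N --p-true P [--alpha A] [--reps R] [--seed S] [--sequential]\n",
      "  diagnose   --trials t.csv [--alpha A]\n",
      "  report     --trials t.csv [--style markdown|plain]\n", sep = "")
}

#' Command-line entry point
#'
#' Dispatches the `simulate`, `analyze`, `bayes`, `sequential`, `power`,
#' `diagnose` and `report` subcommands. Intended to be called by the
#' installed `metapsi` Rscript wrapper (`system.file("cli", "metapsi",
#' package = "metapsi")`), but callable directly with a character vector of
#' arguments. Every run logs the seed and package version it used; JSON
#' output embeds them.
#'
#' @param args Character vector of command-line arguments (subcommand
#'   first); defaults to the process arguments.
#' @return Integer exit status, invisibly (0 on success, 2 on usage error).
#' @export
amp_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (length(args) == 0 ||
      !args[[1]] %in% c("simulate", "analyze", "bayes", "sequential",
                        "power", "diagnose", "report")) {
    cli_usage()
    return(invisible(2L))
  }
  sub <- args[[1]]
  opts <- tryCatch(parse_cli_args(args[-1]), error = function(e) e)
  if (inherits(opts, "error")) {
    message(conditionMessage(opts))
    cli_usage()
    return(invisible(2L))
  }
  version <- as.character(utils::packageVersion("metapsi"))
  status <- tryCatch({
    switch(sub,
      simulate = {
        cfg <- config_from_list(read_config_file(opts$config))
        if (!is.null(opts$seed)) cfg$seed <- as.integer(opts$seed)
        cli_log("simulate: seed=%s version=%s", cfg$seed %||% "NULL", version)
        trials <- simulate_study(cfg)
        write_trials(trials, opts$out)
        cli_log("wrote %d trials to %s", nrow(trials), opts$out)
      },
      analyze = {
        trials <- read_trials(opts$trials)
        level <- as.numeric(opts$level %||% 0.95)
        counts <- aggregate_by_participant(trials, opts$condition %||% "X")
        fit <- fit_random_intercept_logit(counts)
        interval <- wald_interval(fit, level)
        interval$decision <- decide_frequentist(interval)
        if (isTRUE(opts$json)) {
          cat(jsonlite::toJSON(c(as.list(interval), version = version),
                               auto_unbox = TRUE, digits = NA), "\n")
        } else {
          print(fit); print(interval)
        }
      },
      bayes = {
        prior <- prior_spec(opts$prior %||% "buj")
        res <- bf01_one_sided(as.integer(opts$k), as.integer(opts$n), prior)
        if (isTRUE(opts$json)) {
          cat(jsonlite::toJSON(c(as.list(res), version = version),
                               auto_unbox = TRUE, digits = NA), "\n")
        } else {
          cat(sprintf("BF01 (%s prior) = %.4g -> %s\n", prior$name,
                      res$bf01, res$support))
        }
      },
      sequential = {
        trials <- read_trials(opts$trials)
        outcome <- run_sequential(trials, design_spec(),
                                  opts$condition %||% "X")
        if (isTRUE(opts$json)) {
          cat(jsonlite::toJSON(c(glance(outcome), version = version),
                               auto_unbox = TRUE, digits = NA), "\n")
        } else {
          print(outcome)
        }
      },
      power = {
        seed <- if (!is.null(opts$seed)) as.integer(opts$seed)
        cli_log("power: seed=%s version=%s", seed %||% "NULL", version)
        res <- if (isTRUE(opts$sequential)) {
          sequential_power_tpp(as.numeric(opts$p_true),
                               reps = as.numeric(opts$reps %||% 1e4),
                               seed = seed)
        } else if (!is.null(opts$reps)) {
          mc_power(as.numeric(opts$n), as.numeric(opts$p_true),
                   as.numeric(opts$alpha %||% 0.05),
                   reps = as.numeric(opts$reps), seed = seed)
        } else {
          analytic_power(as.numeric(opts$n), as.numeric(opts$p_true),
                         as.numeric(opts$alpha %||% 0.05))
        }
        print(res)
      },
      diagnose = {
        trials <- read_trials(opts$trials)
        reg <- dplyr::filter(trials, .data$arm == "reg")
        if (nrow(reg) > 0) {
          rep_a <- class_a_check(reg, as.numeric(opts$alpha %||% 0.05))
          cat("class-A verdict:", attr(rep_a, "verdict"), "\n")
          print(tibble::as_tibble(rep_a))
        }
        print(side_bias_check(trials))
      },
      report = {
        trials <- read_trials(opts$trials)
        battery <- condition_battery(trials)
        cat(render_study_table(battery, opts$style %||% "markdown"), "\n")
      }
    )
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
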