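# The adaptive screening protocol: per-ear descent 40 -> 30 -> 20 dB HL with
# a 2-of-3 forced-choice criterion, timeout failure, and duration bookkeeping.

#' Protocol configuration
#'
#' Parameters of the adaptive picture-pointing screen. Defaults reproduce the
#' standard protocol: start at 40 dB HL in the right ear, present up to three
#' 6-picture sets per level, pass on 2 correct, fail the level outright on any
#' timeout (no answer within 10 s), then descend to 30 and 20 dB HL.
#'
#' @param levels Ordered, strictly decreasing presentation levels (dB HL).
#' @param sets_per_level Picture sets offered per level.
#' @param pass_criterion Correct responses needed to pass a level
#'   (`<= sets_per_level`).
#' @param pictures_per_set Alternatives per set (fixes the 1/6 chance floor).
#' @param timeout Response window, seconds.
#' @param ear_order Order in which ears are tested.
#' @param early_stop Stop presenting sets once the level's pass/fail is
#'   decided (on by default; the always-`sets_per_level` variant is kept as a
#'   flag because published protocol descriptions leave it open).
#' @param response_median_s Median simulated response time per presentation
#'   (lognormal, truncated at `timeout`).
#' @param response_sdlog Lognormal sdlog of the response-time draw.
#' @param inter_trial_s Fixed per-presentation overhead (picture loading,
#'   word playback), seconds.
#' @return Object of class `protocol_config`.
#' @export
protocol_config <- function(levels = c(40, 30, 20), sets_per_level = 3,
                            pass_criterion = 2, pictures_per_set = 6,
                            timeout = 10, ear_order = c("right", "left"),
                            early_stop = TRUE, response_median_s = 5,
                            response_sdlog = 0.5, inter_trial_s = 2) {
  if (length(levels) < 1L || any(diff(levels) >= 0)) {
    stop("`levels` must be strictly decreasing", call. = FALSE)
  }
  if (pass_criterion > sets_per_level || pass_criterion < 1) {
    stop("`pass_criterion` must be in 1..sets_per_level", call. = FALSE)
  }
  if (pictures_per_set < 2) stop("`pictures_per_set` must be >= 2", call. = FALSE)
  if (timeout <= 0) stop("`timeout` must be positive", call. = FALSE)
  if (!all(ear_order %in% c("right", "left"))) {
    stop("`ear_order` entries must be 'right'/'left'", call. = FALSE)
  }
  structure(list(levels = levels, sets_per_level = sets_per_level,
                 pass_criterion = pass_criterion,
                 pictures_per_set = pictures_per_set, timeout = timeout,
                 ear_order = ear_order, early_stop = isTRUE(early_stop),
                 response_median_s = response_median_s,
                 response_sdlog = response_sdlog,
                 inter_trial_s = inter_trial_s),
            class = "protocol_config")
}

#' Test conditions: headphone, room and calibration context
#'
#' Bundles the acoustic context a screen runs in. The defaults describe a
#' standard quiet hospital room (35 dBA ambient) with a calibrated system:
#' residual ambient noise is fully blocked by 20-30 dB of passive isolation
#' plus the 10 dB masking margin, so the effective level equals the nominal
#' level (see [effective_level()]).
#'
#' @param headphone A [headphone_spec()], typically from [headphone_preset()].
#' @param ambient_dBA Room noise, dBA.
#' @param cal_error Fixed residual calibration error, dB.
#' @param cal_error_sd SD of an additional zero-mean per-level calibration
#'   error draw, dB (0 = perfectly repeatable calibration).
#' @param masking_offset Masking margin passed to [effective_level()].
#' @return Object of class `test_conditions`.
#' @export
test_conditions <- function(headphone = headphone_preset("tdh39"),
                            ambient_dBA = 35, cal_error = 0, cal_error_sd = 0,
                            masking_offset = 10) {
  stopifnot(inherits(headphone, "headphone_spec"))
  if (cal_error_sd < 0) stop("`cal_error_sd` must be >= 0", call. = FALSE)
  structure(list(headphone = headphone, ambient_dBA = ambient_dBA,
                 cal_error = cal_error, cal_error_sd = cal_error_sd,
                 masking_offset = masking_offset), class = "test_conditions")
}

# Threshold the spondee task works against: the ear's pure-tone average.
ear_threshold <- function(child, ear) pure_tone_average(child[[ear]])

#' Run one protocol level for one ear
#'
#' Presents up to `sets_per_level` picture sets at one level. Any timeout
#' fails the level immediately. Otherwise the level is passed on reaching
#' `pass_criterion` correct responses; with `early_stop`, presentation stops
#' as soon as the outcome is decided either way.
#'
#' @param level Presentation level, dB HL (must be one of `config$levels`).
#' @param child A [child_profile()].
#' @param ear `"right"` or `"left"`.
#' @param conditions A [test_conditions()].
#' @param config A [protocol_config()].
#' @return List with `passed` (logical) and `log`, a data frame of one row
#'   per presentation (`level, set, effective_level, outcome, response_s`).
#' @export
run_level <- function(level, child, ear, conditions = test_conditions(),
                      config = protocol_config()) {
  if (!level %in% config$levels) {
    stop("`level` is not one of the configured protocol levels", call. = FALSE)
  }
  theta <- ear_threshold(child, ear)
  cal <- conditions$cal_error +
    if (conditions$cal_error_sd > 0) rnorm(1, 0, conditions$cal_error_sd) else 0
  eff <- effective_level(level, conditions$headphone, cal_error = cal,
                         ambient_dBA = conditions$ambient_dBA,
                         masking_offset = conditions$masking_offset)
  n_max <- config$sets_per_level
  max_wrong <- n_max - config$pass_criterion   # one more wrong makes pass unreachable
  outcomes <- character(0)
  times <- numeric(0)
  n_ok <- 0L; n_bad <- 0L; passed <- FALSE
  for (set in seq_len(n_max)) {
    out <- respond(eff, theta, child$behavior, n = 1)
    rt <- if (out == "timeout") config$timeout else {
      min(rlnorm(1, log(config$response_median_s), config$response_sdlog),
          config$timeout)
    }
    outcomes <- c(outcomes, out)
    times <- c(times, rt + config$inter_trial_s)
    if (out == "timeout") { passed <- FALSE; break }
    if (out == "correct") n_ok <- n_ok + 1L else n_bad <- n_bad + 1L
    if (config$early_stop) {
      if (n_ok >= config$pass_criterion) { passed <- TRUE; break }
      if (n_bad > max_wrong) { passed <- FALSE; break }
    } else if (set == n_max) {
      passed <- n_ok >= config$pass_criterion
    }
  }
  list(passed = passed,
       log = data.frame(level = level, set = seq_along(outcomes),
                        effective_level = eff, outcome = outcomes,
                        response_s = times))
}

#' Screen one ear with the full descent protocol
#'
#' Traverses the configured levels in order (40, 30, 20 dB HL by default),
#' stopping at the first failed level. The screened category follows from
#' the lowest passed level via [screened_category()].
#'
#' @inheritParams run_level
#' @return Object of class `screening_result`: `child_id`, `ear`,
#'   `lowest_passed_level` (`NA` if none), `category`, `presentations` log,
#'   and `duration_s`.
#' @export
run_ear <- function(child, ear, conditions = test_conditions(),
                    config = protocol_config()) {
  ear <- match.arg(ear, c("right", "left"))
  lowest <- NA_real_
  logs <- list()
  for (lv in config$levels) {
    res <- run_level(lv, child, ear, conditions, config)
    logs[[length(logs) + 1L]] <- res$log
    if (!res$passed) break
    lowest <- lv
  }
  log <- do.call(rbind, logs)
  structure(list(child_id = child$child_id, ear = ear,
                 lowest_passed_level = lowest,
                 category = screened_category(lowest),
                 presentations = log,
                 duration_s = sum(log$response_s)),
            class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result>", x$child_id, x$ear, "ear:",
      as.character(x$category),
      if (is.na(x$lowest_passed_level)) "(no level passed)" else
        sprintf("(lowest pass %g dB HL)", x$lowest_passed_level),
      sprintf("in %.1f s, %d presentations\n", x$duration_s,
              nrow(x$presentations)))
  invisible(x)
}

#' Screen both ears of one child
#'
#' Runs [run_ear()] for each ear in `config$ear_order` (right then left by
#' default). When `seed` is given, an independent substream is derived for
#' each ear so the two ears' randomness does not interleave.
#'
#' @inheritParams run_level
#' @param seed Optional integer seed for reproducibility.
#' @return Named list of [run_ear()] results, one per ear.
#' @export
run_screening <- function(child, conditions = test_conditions(),
                          config = protocol_config(), seed = NULL) {
  ears <- config$ear_order
  if (!is.null(seed)) {
    sub <- derive_seeds(seed, length(ears))
  }
  out <- list()
  for (i in seq_along(ears)) {
    if (!is.null(seed)) set.seed(sub[i])
    out[[ears[i]]] <- run_ear(child, ears[i], conditions, config)
  }
  out
}

#' Screen a whole cohort
#'
#' @param cohort List of [child_profile()] objects (see [generate_cohort()]).
#' @inheritParams run_screening
#' @return Data frame with one row per ear: `child_id, ear, headphone,
#'   lowest_passed_level, category, n_presentations, duration_s`.
#' @export
screen_cohort <- function(cohort, conditions = test_conditions(),
                          config = protocol_config(), seed = NULL) {
  child_seeds <- if (!is.null(seed)) derive_seeds(seed, length(cohort))
  rows <- lapply(seq_along(cohort), function(i) {
    res <- run_screening(cohort[[i]], conditions, config,
                         seed = if (!is.null(seed)) child_seeds[i])
    do.call(rbind, lapply(res, function(r) {
      data.frame(child_id = r$child_id, ear = r$ear,
                 headphone = conditions$headphone$name,
                 lowest_passed_level = r$lowest_passed_level,
                 category = as.character(r$category),
                 n_presentations = nrow(r$presentations),
                 duration_s = r$duration_s)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
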