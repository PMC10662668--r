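# Probabilistic response model of a child performing the 6-picture
# forced-choice word identification task.

#' Psychometric response parameters
#'
#' Parameters of the m-alternative forced-choice psychometric function used
#' by the virtual child: chance floor `guess` (1/6 for six pictures), upper
#' asymptote shortfall `lapse` (attention slips), logistic `slope` in dB, and
#' a per-presentation `timeout_prob` of failing to answer within the allowed
#' response window.
#'
#' `slope = 0` is allowed and denotes the deterministic step-function limit:
#' the child answers correctly exactly when the presentation level is at or
#' above the ear threshold.
#'
#' @param guess Guess rate, in \[0, 1). Default `1/6`.
#' @param lapse Lapse rate, in \[0, 0.2\]. Default 0.02.
#' @param slope Logistic slope parameter, dB, >= 0. Default 4.
#' @param timeout_prob Probability a presentation ends in a timeout,
#'   in \[0, 1). Default 0.01.
#' @return Object of class `psychometric_params`.
#' @export
psychometric_params <- function(guess = 1 / 6, lapse = 0.02, slope = 4,
                                timeout_prob = 0.01) {
  for (nm in c("guess", "lapse", "slope", "timeout_prob")) {
    stop_if_not_scalar_number(get(nm), nm)
  }
  if (guess < 0 || guess >= 1) stop("`guess` must be in [0, 1)", call. = FALSE)
  if (lapse < 0 || lapse > 0.2) stop("`lapse` must be in [0, 0.2]", call. = FALSE)
  if (slope < 0) stop("`slope` must be >= 0", call. = FALSE)
  if (timeout_prob < 0 || timeout_prob >= 1) {
    stop("`timeout_prob` must be in [0, 1)", call. = FALSE)
  }
  if (guess + lapse >= 1) stop("`guess + lapse` must be < 1", call. = FALSE)
  structure(list(guess = guess, lapse = lapse, slope = slope,
                 timeout_prob = timeout_prob), class = "psychometric_params")
}

#' Probability of a correct picture choice
#'
#' The standard m-AFC psychometric function
#' `psi(x) = guess + (1 - guess - lapse) * F((x - threshold) / slope)`
#' with a logistic `F`, evaluated at presentation level `x` (dB HL) for an
#' ear with the given threshold. Far below threshold the child is reduced to
#' guessing among the six pictures (`psi -> guess`); far above, `psi ->
#' 1 - lapse`. With `slope = 0`, `F` degenerates to a step at the threshold.
#'
#' @param level Presentation level(s), dB HL.
#' @param threshold Ear threshold(s), dB HL.
#' @param params A [psychometric_params()].
#' @return Probability of a correct response (vectorized).
#' @examples
#' p_correct(30, 30, psychometric_params(lapse = 0))  # 1/6 + (5/6)/2
#' @export
p_correct <- function(level, threshold, params = psychometric_params()) {
  stopifnot(inherits(params, "psychometric_params"))
  if (any(!is.finite(level)) || any(!is.finite(threshold))) {
    stop("levels and thresholds must be finite", call. = FALSE)
  }
  f <- if (params$slope == 0) {
    as.numeric(level >= threshold)
  } else {
    stats::plogis((level - threshold) / params$slope)
  }
  params$guess + (1 - params$guess - params$lapse) * f
}

#' Simulate one or more forced-choice responses
#'
#' Each presentation first times out with probability `timeout_prob`;
#' otherwise the child answers correctly with probability
#' [p_correct()]. Draws come from R's global random stream, so results are
#' reproducible under `set.seed()`.
#'
#' @inheritParams p_correct
#' @param n Number of independent presentations to simulate.
#' @return Character vector in `{"correct", "incorrect", "timeout"}`.
#' @export
respond <- function(level, threshold, params = psychometric_params(), n = 1) {
  p <- p_correct(level, threshold, params)
  u_t <- runif(n)
  u_c <- runif(n)
  ifelse(u_t < params$timeout_prob, "timeout",
         ifelse(u_c < p, "correct", "incorrect"))
}

#' Construct a virtual child
#'
#' Ground truth for simulation: per-ear audiograms plus the behavioral
#' response parameters.
#'
#' @param child_id Identifier.
#' @param right,left [ear_audiogram()] objects for the two ears.
#' @param behavior A [psychometric_params()].
#' @return Object of class `child_profile`.
#' @examples
#' ch <- child_profile("c1",
#'   ear_audiogram("right", rep(10, 5)),
#'   ear_audiogram("left", rep(35, 5)))
#' @export
child_profile <- function(child_id, right, left,
                          behavior = psychometric_params()) {
  if (!inherits(right, "ear_audiogram") || !inherits(left, "ear_audiogram")) {
    stop("`right` and `left` must be ear_audiogram objects", call. = FALSE)
  }
  if (right$ear != "right" || left$ear != "left") {
    stop("audiograms supplied to the wrong ear slots", call. = FALSE)
  }
  stopifnot(inherits(behavior, "psychometric_params"))
  structure(list(child_id = as.character(child_id), right = right, left = left,
                 behavior = behavior), class = "child_profile")
}

#' @export
print.child_profile <- function(x, ...) {
  cat("<child_profile>", x$child_id, "\n")
  cat(sprintf("  right PTA %5.1f dB HL (%s)\n", pure_tone_average(x$right),
              ear_category(x$right)))
  cat(sprintf("  left  PTA %5.1f dB HL (%s)\n", pure_tone_average(x$left),
              ear_category(x$left)))
  invisible(x)
}

#' Read / write child profiles
#'
#' Profiles travel as a wide CSV (one row per child: `child_id`,
#' `right_f0_5 .. right_f4`, `left_f0_5 .. left_f4`, `guess`, `lapse`,
#' `slope`, `timeout_prob`) or as JSON via [jsonlite::toJSON()].
#'
#' @param cohort A list of [child_profile()] objects.
#' @param path File path.
#' @return `read_children()` returns a list of `child_profile`s;
#'   the writers return `path` invisibly.
#' @export
write_children <- function(cohort, path) {
  write.csv(children_to_df(cohort), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_children
#' @export
read_children <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  df_to_children(df)
}

#' @rdname write_children
#' @export
write_children_json <- function(cohort, path) {
  jsonlite::write_json(children_to_df(cohort), path, digits = NA)
  invisible(path)
}

#' @rdname write_children
#' @export
read_children_json <- function(path) {
  df_to_children(jsonlite::fromJSON(path))
}

children_to_df <- function(cohort) {
  do.call(rbind, lapply(cohort, function(ch) {
    r <- ch$right$thresholds; l <- ch$left$thresholds; b <- ch$behavior
    data.frame(child_id = ch$child_id,
               right_f0_5 = r[["0.5"]], right_f1 = r[["1"]], right_f2 = r[["2"]],
               right_f3 = r[["3"]], right_f4 = r[["4"]],
               left_f0_5 = l[["0.5"]], left_f1 = l[["1"]], left_f2 = l[["2"]],
               left_f3 = l[["3"]], left_f4 = l[["4"]],
               guess = b$guess, lapse = b$lapse, slope = b$slope,
               timeout_prob = b$timeout_prob)
  }))
}

df_to_children <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    child_profile(
      row$child_id,
      ear_audiogram("right", as.numeric(row[paste0("right_f", c("0_5", 1:4))])),
      ear_audiogram("left", as.numeric(row[paste0("left_f", c("0_5", 1:4))])),
      psychometric_params(row$guess, row$lapse, row$slope, row$timeout_prob)
    )
  })
}
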