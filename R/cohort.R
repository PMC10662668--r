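# Synthetic cohort generation with a configurable prevalence structure, and a
# simulated conditioned-play-audiometry reference classifier.

#' Cohort configuration
#'
#' Generative model for a cohort of 4-5-year-old children. Each child is
#' assigned a hearing status multinomially — bilaterally normal, unilateral
#' loss, or bilateral loss — with default prevalences 70% / 21% / 9%. Loss
#' ears are moderate with probability `severity_mix` (default 0.2) and mild
#' otherwise. Per-ear thresholds are drawn flat across frequency (optionally
#' jittered) from:
#' \itemize{
#'   \item normal ears: Normal(10, 5) truncated to \[-10, 20\] dB HL,
#'   \item mild ears: Uniform(25, 40) dB HL,
#'   \item moderate ears: Uniform(45, 70) dB HL.
#' }
#'
#' @param n_children Number of children.
#' @param p_bilateral_normal,p_unilateral_loss,p_bilateral_loss Status
#'   prevalences; must sum to 1.
#' @param severity_mix Probability a loss ear is moderate (vs mild).
#' @param normal_mean,normal_sd,normal_range Truncated-normal parameters for
#'   normal-ear thresholds.
#' @param mild_range,moderate_range Uniform threshold ranges for loss ears.
#' @param jitter_sd SD (dB) of optional per-frequency jitter around the flat
#'   ear level; 0 keeps audiograms flat.
#' @param behavior Default [psychometric_params()] assigned to every child.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(n_children = 44, p_bilateral_normal = 0.70,
                          p_unilateral_loss = 0.21, p_bilateral_loss = 0.09,
                          severity_mix = 0.2, normal_mean = 10, normal_sd = 5,
                          normal_range = c(-10, 20), mild_range = c(25, 40),
                          moderate_range = c(45, 70), jitter_sd = 0,
                          behavior = psychometric_params()) {
  p <- c(p_bilateral_normal, p_unilateral_loss, p_bilateral_loss)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
    stop("status prevalences must be non-negative and sum to 1", call. = FALSE)
  }
  if (severity_mix < 0 || severity_mix > 1) {
    stop("`severity_mix` must be a probability", call. = FALSE)
  }
  if (n_children < 1) stop("`n_children` must be >= 1", call. = FALSE)
  if (mild_range[1] <= 20 || mild_range[2] > 40) {
    stop("`mild_range` must lie within (20, 40]", call. = FALSE)
  }
  if (moderate_range[1] <= 40) {
    stop("`moderate_range` must lie above 40 dB HL", call. = FALSE)
  }
  structure(list(n_children = n_children,
                 p_bilateral_normal = p_bilateral_normal,
                 p_unilateral_loss = p_unilateral_loss,
                 p_bilateral_loss = p_bilateral_loss,
                 severity_mix = severity_mix, normal_mean = normal_mean,
                 normal_sd = normal_sd, normal_range = normal_range,
                 mild_range = mild_range, moderate_range = moderate_range,
                 jitter_sd = jitter_sd, behavior = behavior),
            class = "cohort_config")
}

# One ear's flat threshold given its severity label.
draw_ear_threshold <- function(severity, cfg) {
  switch(severity,
    normal = rtruncnorm(1, cfg$normal_mean, cfg$normal_sd,
                        cfg$normal_range[1], cfg$normal_range[2]),
    mild = runif(1, cfg$mild_range[1], cfg$mild_range[2]),
    moderate = runif(1, cfg$moderate_range[1], cfg$moderate_range[2]))
}

draw_audiogram <- function(ear, severity, cfg) {
  base <- draw_ear_threshold(severity, cfg)
  th <- rep(base, 5)
  if (cfg$jitter_sd > 0) th <- th + rnorm(5, 0, cfg$jitter_sd)
  ear_audiogram(ear, pmin(120, pmax(-10, th)))
}

#' Generate a synthetic cohort
#'
#' @param config A [cohort_config()].
#' @param seed Optional integer seed; the same seed reproduces the cohort
#'   exactly.
#' @return A list of [child_profile()] objects (class `cohort`), with the
#'   config and seed stored as attributes and each child's true status in
#'   `attr(., "status")`.
#' @examples
#' co <- generate_cohort(cohort_config(n_children = 10), seed = 1)
#' table(vapply(co, function(ch) as.character(ear_category(ch$left)), ""))
#' @export
generate_cohort <- function(config = cohort_config(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_children
  status <- sample(c("bilateral_normal", "unilateral_loss", "bilateral_loss"),
                   n, replace = TRUE,
                   prob = c(config$p_bilateral_normal,
                            config$p_unilateral_loss,
                            config$p_bilateral_loss))
  loss_side <- sample(c("right", "left"), n, replace = TRUE)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    sev <- c(right = "normal", left = "normal")
    if (status[i] == "unilateral_loss") {
      sev[loss_side[i]] <-
        if (runif(1) < config$severity_mix) "moderate" else "mild"
    } else if (status[i] == "bilateral_loss") {
      sev["right"] <- if (runif(1) < config$severity_mix) "moderate" else "mild"
      sev["left"] <- if (runif(1) < config$severity_mix) "moderate" else "mild"
    }
    children[[i]] <- child_profile(
      sprintf("child_%03d", i),
      draw_audiogram("right", sev[["right"]], config),
      draw_audiogram("left", sev[["left"]], config),
      config$behavior)
  }
  structure(children, class = c("cohort", "list"), status = status,
            config = config, seed = seed)
}

#' Simulated conditioned-play audiometry of one child
#'
#' Measures each ear at 0.5, 1, 2, 3 and 4 kHz: the true threshold plus
#' zero-mean Gaussian measurement noise, quantized to the audiometer's 5 dB
#' step, averaged to the PTA and classified with [classify_hearing_level()].
#' Test duration is drawn per ear from a lognormal chosen so that two-ear
#' totals land in the several-hundred-second range typical of play
#' audiometry in this age group.
#'
#' @param child A [child_profile()].
#' @param noise_sd Measurement noise SD, dB (default 2.5).
#' @param step Quantization step, dB.
#' @param duration_meanlog,duration_sdlog Lognormal parameters of the per-ear
#'   duration draw, seconds.
#' @param seed Optional integer seed.
#' @return Data frame with one row per ear: measured thresholds `f0_5..f4`,
#'   `pta`, `category`, `duration_s`.
#' @export
reference_test <- function(child, noise_sd = 2.5, step = 5,
                           duration_meanlog = log(275),
                           duration_sdlog = 0.25, seed = NULL) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(c("right", "left"), function(e) {
    true <- child[[e]]$thresholds
    meas <- true + if (noise_sd > 0) rnorm(5, 0, noise_sd) else 0
    meas <- pmin(120, pmax(-10, quantize_db(meas, step)))
    pta <- mean(meas)
    data.frame(child_id = child$child_id, ear = e,
               f0_5 = meas[[1]], f1 = meas[[2]], f2 = meas[[3]],
               f3 = meas[[4]], f4 = meas[[5]],
               pta = pta,
               category = as.character(classify_hearing_level(pta)),
               duration_s = rlnorm(1, duration_meanlog, duration_sdlog))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Reference-test a whole cohort
#'
#' @param cohort A cohort from [generate_cohort()].
#' @inheritParams reference_test
#' @return Data frame of [reference_test()] rows for every child.
#' @export
reference_cohort <- function(cohort, noise_sd = 2.5, step = 5,
                             duration_meanlog = log(275),
                             duration_sdlog = 0.25, seed = NULL) {
  child_seeds <- if (!is.null(seed)) derive_seeds(seed, length(cohort))
  rows <- lapply(seq_along(cohort), function(i) {
    reference_test(cohort[[i]], noise_sd = noise_sd, step = step,
                   duration_meanlog = duration_meanlog,
                   duration_sdlog = duration_sdlog,
                   seed = if (!is.null(seed)) child_seeds[i])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
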