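# Hearing-level semantics: categories, audiograms, pure-tone averages and the
# mapping from a screening outcome to a category.

#' Hearing screening categories
#'
#' The three-category scale used throughout the package, ordered
#' `normal < mild < moderate`. Cutoffs follow pediatric screening guidelines:
#' a hearing level of 20 dB HL or better is normal, above 20 up to and
#' including 40 dB HL is mild hearing loss, and above 40 dB HL is moderate.
#'
#' @format A character vector of the three category labels in order.
#' @export
hearing_categories <- c("normal", "mild", "moderate")

# Audiometric test frequencies, kHz.
audiogram_frequencies <- c(0.5, 1, 2, 3, 4)

#' Classify a hearing level in dB HL into a screening category
#'
#' @param level Numeric vector of hearing levels (dB HL). Must be finite.
#' @return Ordered factor with levels `normal < mild < moderate`.
#'   `level <= 20` is normal, `20 < level <= 40` mild, `level > 40` moderate;
#'   boundaries are inclusive as printed and no rounding is applied first.
#' @examples
#' classify_hearing_level(c(20, 40, 40.1))
#' @export
classify_hearing_level <- function(level) {
  if (!is.numeric(level) || length(level) == 0L || any(!is.finite(level))) {
    stop("`level` must be finite numeric (dB HL)", call. = FALSE)
  }
  lab <- ifelse(level <= 20, "normal", ifelse(level <= 40, "mild", "moderate"))
  factor(lab, levels = hearing_categories, ordered = TRUE)
}

#' Construct a per-ear audiogram
#'
#' @param ear `"right"` or `"left"`.
#' @param thresholds Numeric vector of five air-conduction thresholds (dB HL)
#'   at 0.5, 1, 2, 3 and 4 kHz, in that order or named by frequency.
#' @return An object of class `ear_audiogram`: list with `ear` and a named
#'   `thresholds` vector.
#' @examples
#' ear_audiogram("right", c(10, 10, 15, 20, 20))
#' @export
ear_audiogram <- function(ear, thresholds) {
  ear <- match.arg(ear, c("right", "left"))
  fq <- as.character(audiogram_frequencies)
  if (!is.numeric(thresholds) || length(thresholds) != 5L) {
    stop("`thresholds` must hold the five frequencies ",
         paste(fq, collapse = ", "), " kHz", call. = FALSE)
  }
  if (!is.null(names(thresholds))) {
    if (!setequal(names(thresholds), fq)) {
      stop("threshold names must be ", paste(fq, collapse = ", "), call. = FALSE)
    }
    thresholds <- thresholds[fq]
  } else {
    names(thresholds) <- fq
  }
  if (any(!is.finite(thresholds)) || any(thresholds < -10) || any(thresholds > 120)) {
    stop("thresholds must be finite and within [-10, 120] dB HL", call. = FALSE)
  }
  structure(list(ear = ear, thresholds = thresholds), class = "ear_audiogram")
}

#' Pure-tone average of an audiogram
#'
#' Arithmetic mean of the thresholds at the requested frequencies.
#'
#' @param audiogram An [ear_audiogram()] (or a named numeric threshold vector).
#' @param frequencies Frequencies (kHz) to average over; defaults to all five
#'   tested frequencies (0.5, 1, 2, 3, 4 kHz).
#' @return Pure-tone average in dB HL.
#' @examples
#' a <- ear_audiogram("left", c(0, 0, 0, 60, 60))
#' pure_tone_average(a)              # 24
#' pure_tone_average(a, c(0.5, 1, 2))
#' @export
pure_tone_average <- function(audiogram, frequencies = audiogram_frequencies) {
  thr <- if (inherits(audiogram, "ear_audiogram")) audiogram$thresholds else audiogram
  if (is.null(names(thr))) stop("audiogram thresholds must be named by frequency",
                                call. = FALSE)
  if (length(frequencies) == 0L) stop("empty frequency set", call. = FALSE)
  fq <- as.character(frequencies)
  if (!all(fq %in% names(thr))) {
    stop("requested frequencies not all present in the audiogram", call. = FALSE)
  }
  mean(thr[fq])
}

#' Screening category implied by the lowest passed protocol level
#'
#' The descent protocol presents 40, then 30, then 20 dB HL. Passing 20 dB HL
#' demonstrates normal hearing; a lowest pass of 30 or 40 dB HL places the
#' screened threshold in the mild band; failing even 40 dB HL implies a level
#' above 40, i.e. moderate loss.
#'
#' @param lowest_passed_level Lowest level passed (20, 30 or 40 dB HL), or
#'   `NA` if no level was passed. Vectorized.
#' @return Ordered factor of screening categories.
#' @examples
#' screened_category(c(20, 30, 40, NA))
#' @export
screened_category <- function(lowest_passed_level) {
  lv <- lowest_passed_level
  if (length(lv) == 0L) stop("no level supplied", call. = FALSE)
  bad <- !is.na(lv) & !(lv %in% c(20, 30, 40))
  if (any(bad)) {
    stop("lowest_passed_level must be 20, 30, 40 or NA (none passed)",
         call. = FALSE)
  }
  lab <- ifelse(is.na(lv), "moderate",
                ifelse(lv <= 20, "normal", "mild"))
  factor(lab, levels = hearing_categories, ordered = TRUE)
}

#' Reference category of an ear
#'
#' Assigns the reference (audiometric) category of an ear, by default from the
#' five-frequency pure-tone average; `method = "worst"` instead classifies the
#' worst single threshold, for sensitivity analyses.
#'
#' @inheritParams pure_tone_average
#' @param method `"pta"` (default) or `"worst"`.
#' @return A single ordered-factor category.
#' @export
ear_category <- function(audiogram, method = c("pta", "worst"),
                         frequencies = audiogram_frequencies) {
  method <- match.arg(method)
  thr <- if (inherits(audiogram, "ear_audiogram")) audiogram$thresholds else audiogram
  level <- switch(method,
    pta   = pure_tone_average(audiogram, frequencies),
    worst = max(thr[as.character(frequencies)])
  )
  classify_hearing_level(level)
}

#' @export
print.ear_audiogram <- function(x, ...) {
  cat("<ear_audiogram>", x$ear, "ear\n")
  print(x$thresholds)
  cat("PTA:", round(pure_tone_average(x), 1), "dB HL,",
      as.character(ear_category(x)), "\n")
  invisible(x)
}

#' Read / write audiogram tables
#'
#' Audiograms travel as CSV with columns `child_id, ear, f0_5, f1, f2, f3, f4`
#' (thresholds in dB HL). Lines starting with `#` are treated as comments.
#'
#' @param path File path.
#' @param x A data frame in that layout, or a cohort (list of
#'   [child_profile()] objects) which is flattened to one row per ear.
#' @return `read_audiograms()` returns the data frame; `write_audiograms()`
#'   returns `path` invisibly.
#' @export
read_audiograms <- function(path) {
  df <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("child_id", "ear", "f0_5", "f1", "f2", "f3", "f4")
  if (!all(need %in% names(df))) {
    stop("audiogram CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df
}

#' @rdname read_audiograms
#' @export
write_audiograms <- function(x, path) {
  if (is.list(x) && !is.data.frame(x)) x <- cohort_audiograms(x)
  write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# Flatten a cohort to the audiogram CSV layout (one row per ear).
cohort_audiograms <- function(cohort) {
  rows <- lapply(cohort, function(ch) {
    do.call(rbind, lapply(c("right", "left"), function(e) {
      th <- ch[[e]]$thresholds
      data.frame(child_id = ch$child_id, ear = e,
                 f0_5 = th[["0.5"]], f1 = th[["1"]], f2 = th[["2"]],
                 f3 = th[["3"]], f4 = th[["4"]])
    }))
  })
  do.call(rbind, rows)
}
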