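# Diagnostic-accuracy statistics: 2x2 tables, percent agreement, Cohen's
# kappa, exact binomial confidence intervals, exact McNemar, paired t on
# durations, reconstruction of tables from printed summaries, and a
# kappa-paradox diagnostic.

#' A 2x2 diagnostic cross-classification
#'
#' Counts of ears cross-classified screener-vs-reference for one dichotomy:
#' `a` = both positive, `b` = screener positive only, `c` = reference
#' positive only, `d` = both negative.
#'
#' @param a,b,c,d Non-negative integer counts; at least one must be positive.
#' @return Object of class `two_by_two`.
#' @examples
#' two_by_two(1, 7, 0, 80)
#' @export
two_by_two <- function(a, b, c, d) {
  cells <- c(a = a, b = b, c = c, d = d)
  if (any(!is.finite(cells)) || any(cells < 0) ||
      any(cells != round(cells))) {
    stop("cell counts must be non-negative integers", call. = FALSE)
  }
  if (sum(cells) == 0) stop("table must contain at least one observation",
                            call. = FALSE)
  structure(as.list(cells), class = "two_by_two")
}

#' @export
print.two_by_two <- function(x, ...) {
  m <- matrix(c(x$a, x$c, x$b, x$d), 2, 2,
              dimnames = list(test = c("positive", "negative"),
                              reference = c("positive", "negative")))
  cat("<two_by_two> N =", x$a + x$b + x$c + x$d, "\n")
  print(t(m))
  invisible(x)
}

#' Cross-classify paired categories under a one-vs-rest dichotomy
#'
#' Dichotomizes both category sequences as `== positive` versus the rest and
#' counts the four screener-vs-reference combinations.
#'
#' @param test,ref Equal-length paired per-ear category vectors (factor or
#'   character).
#' @param positive The category treated as positive (e.g. `"moderate"`).
#' @return A [two_by_two()].
#' @export
confusion <- function(test, ref, positive) {
  if (length(test) != length(ref)) {
    stop("`test` and `ref` must be paired (equal length)", call. = FALSE)
  }
  tp <- as.character(test) == positive
  rp <- as.character(ref) == positive
  two_by_two(sum(tp & rp), sum(tp & !rp), sum(!tp & rp), sum(!tp & !rp))
}

#' Percent agreement of a 2x2 table
#'
#' @param t A [two_by_two()].
#' @return `100 * (a + d) / N`, the percentage of concordant pairs.
#' @examples
#' percent_agreement(two_by_two(1, 7, 0, 80))  # 92.05
#' @export
percent_agreement <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  100 * (t$a + t$d) / (t$a + t$b + t$c + t$d)
}

#' Cohen's kappa for a 2x2 table
#'
#' Chance-corrected agreement `kappa = (po - pe) / (1 - pe)`, with observed
#' agreement `po = (a + d)/N` and expected agreement `pe` from the product of
#' the marginal proportions. The p-value is the large-sample z test of
#' `kappa = 0`, using the standard error of kappa under the null
#' (Fleiss-style, computed from the margins).
#'
#' @param t A [two_by_two()].
#' @return Object of class `kappa_result`: `po`, `pe`, `kappa`, `se0`, `z`,
#'   `p_value`, `n`.
#' @examples
#' cohens_kappa(two_by_two(1, 7, 0, 80))$kappa  # 0.206
#' @export
cohens_kappa <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  n <- t$a + t$b + t$c + t$d
  po <- (t$a + t$d) / n
  p1r <- (t$a + t$b) / n; p2r <- (t$c + t$d) / n   # screener margins
  p1c <- (t$a + t$c) / n; p2c <- (t$b + t$d) / n   # reference margins
  pe <- p1r * p1c + p2r * p2c
  if (pe >= 1 - 1e-12) {
    stop("degenerate table: both raters use a single category (pe = 1), ",
         "kappa is undefined", call. = FALSE)
  }
  kappa <- (po - pe) / (1 - pe)
  # null variance vanishes (up to floating error) when one rater is
  # constant; the z test is undefined there, the kappa itself is not
  v0 <- max(0, pe + pe^2 -
              (p1r * p1c * (p1r + p1c) + p2r * p2c * (p2r + p2c)))
  se0 <- sqrt(v0) / ((1 - pe) * sqrt(n))
  z <- if (se0 > 0) kappa / se0 else NA_real_
  structure(list(po = po, pe = pe, kappa = kappa, se0 = se0, z = z,
                 p_value = if (is.na(z)) NA_real_ else 2 * pnorm(-abs(z)),
                 n = n),
            class = "kappa_result")
}

#' @export
print.kappa_result <- function(x, ...) {
  cat(sprintf("Cohen's kappa = %.3f (po = %.4f, pe = %.4f), z = %.2f, p = %.3g\n",
              x$kappa, x$po, x$pe, x$z, x$p_value))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' The exact interval from binomial tail probabilities, in the usual
#' beta-quantile form: the lower bound is 0 when `x = 0` and the upper bound
#' 100 when `x = n`.
#'
#' @param x Number of successes.
#' @param n Number of trials, >= 1.
#' @param conf Confidence level (default 0.95).
#' @return Named numeric `c(lo, hi)` on the percentage scale.
#' @examples
#' clopper_pearson(1, 1)   # 2.5, 100
#' clopper_pearson(2, 4)   # 6.76, 93.24
#' @export
clopper_pearson <- function(x, n, conf = 0.95) {
  if (!is.finite(x) || !is.finite(n) || n < 1 || x < 0 || x > n ||
      x != round(x) || n != round(n)) {
    stop("need integer counts with 0 <= x <= n, n >= 1", call. = FALSE)
  }
  if (conf <= 0 || conf >= 1) stop("`conf` must be in (0, 1)", call. = FALSE)
  alpha <- (1 - conf) / 2
  lo <- if (x == 0) 0 else qbeta(alpha, x, n - x + 1)
  hi <- if (x == n) 1 else qbeta(1 - alpha, x + 1, n - x)
  c(lo = 100 * lo, hi = 100 * hi)
}

#' Sensitivity and specificity with exact confidence intervals
#'
#' Point estimates `100 a/(a+c)` and `100 d/(b+d)` with [clopper_pearson()]
#' intervals. An empty margin leaves the corresponding estimate undefined:
#' it is returned as `NA` with a warning.
#'
#' @param t A [two_by_two()].
#' @param conf Confidence level.
#' @return Object of class `diagnostic_summary`: `sensitivity`,
#'   `specificity` (each a list with `estimate`, `lo`, `hi`), `agreement`,
#'   and the input `table`.
#' @examples
#' sens_spec(two_by_two(1, 7, 0, 80))
#' @export
sens_spec <- function(t, conf = 0.95) {
  stopifnot(inherits(t, "two_by_two"))
  est <- function(x, n, what) {
    if (n == 0) {
      warning("no ", what, " margin: estimate undefined", call. = FALSE)
      return(list(estimate = NA_real_, lo = NA_real_, hi = NA_real_))
    }
    ci <- clopper_pearson(x, n, conf)
    list(estimate = 100 * x / n, lo = ci[["lo"]], hi = ci[["hi"]])
  }
  structure(list(sensitivity = est(t$a, t$a + t$c, "reference-positive"),
                 specificity = est(t$d, t$b + t$d, "reference-negative"),
                 agreement = percent_agreement(t),
                 conf = conf, table = t),
            class = "diagnostic_summary")
}

#' @export
print.diagnostic_summary <- function(x, ...) {
  fmt <- function(e, lab) {
    if (is.na(e$estimate)) cat(sprintf("  %-12s undefined (empty margin)\n", lab))
    else cat(sprintf("  %-12s %5.1f%% (%.3g-%.3g)\n", lab, e$estimate, e$lo, e$hi))
  }
  cat(sprintf("<diagnostic_summary> N = %d, agreement %.2f%%\n",
              x$table$a + x$table$b + x$table$c + x$table$d, x$agreement))
  fmt(x$sensitivity, "sensitivity")
  fmt(x$specificity, "specificity")
  invisible(x)
}

#' Exact McNemar test on discordant pairs
#'
#' Exact two-sided binomial test of whether the two discordant cell counts
#' are symmetric: under the null each discordant pair falls either way with
#' probability 1/2. Equal-tail doubling, capped at 1; `p = 1` when there are
#' no discordant pairs.
#'
#' @param b,c The two discordant counts (screener-only positives and
#'   reference-only positives, or any paired disagreement split).
#' @return The exact two-sided p-value.
#' @examples
#' mcnemar_exact(5, 0)  # 2 * 0.5^5 = 0.0625
#' @export
mcnemar_exact <- function(b, c) {
  if (b < 0 || c < 0 || b != round(b) || c != round(c)) {
    stop("discordant counts must be non-negative integers", call. = FALSE)
  }
  n <- b + c
  if (n == 0) return(1)
  k <- min(b, c)
  p <- 2 * pbinom(k, n, 0.5)
  if (b == c) p <- p - dbinom(k, n, 0.5)  # avoid double-counting the center
  min(1, p)
}

#' Paired t test on per-child test durations
#'
#' Standard paired t test comparing two duration series measured on the same
#' children (e.g. app screen vs reference audiometry).
#'
#' @param durations_a,durations_b Equal-length numeric vectors, seconds.
#' @return List with `t`, `df`, `p_value`, `mean_diff` (a minus b).
#' @export
duration_t_test <- function(durations_a, durations_b) {
  if (length(durations_a) != length(durations_b) || length(durations_a) < 2) {
    stop("need two paired series of equal length >= 2", call. = FALSE)
  }
  d <- durations_a - durations_b
  if (stats::sd(d) <= 1e-10 * (abs(mean(d)) + 1)) {
    stop("degenerate comparison: all paired differences identical", call. = FALSE)
  }
  tt <- t.test(durations_a, durations_b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, mean_diff = unname(tt$estimate))
}

#' Reconstruct a 2x2 table from printed summary statistics
#'
#' Inverts a published sensitivity point estimate with its exact
#' (Clopper-Pearson) confidence interval, together with the screener-positive
#' row count and the total, back into the unique integer table that produced
#' them. The exact CI is a fingerprint of the integer pair (successes,
#' trials): the search enumerates every reference-positive margin `m <= N`
#' and success count `x`, keeps those whose sensitivity and CI round (half
#' up) to the printed values at their printed precision, and fails loudly
#' unless exactly one table remains.
#'
#' @param sens_pct Printed sensitivity, percent.
#' @param sens_ci Printed 95% CI as `c(lo, hi)`, percent.
#' @param test_positive_n Screener-positive row count (a + b).
#' @param n_total Total number of paired observations N.
#' @param conf Confidence level of the printed interval.
#' @param tol Optional absolute matching tolerance (percentage points)
#'   overriding the printed-precision rule; used mainly to probe how coarse
#'   printing must get before the inversion stops being unique.
#' @return The unique [two_by_two()] with `a + c = m`, `a = x`,
#'   `b = test_positive_n - x`, `d = N - m - b`.
#' @examples
#' reconstruct_from_summaries(100, c(2.5, 100), 8, 88)  # (1, 7, 0, 80)
#' @export
reconstruct_from_summaries <- function(sens_pct, sens_ci, test_positive_n,
                                       n_total, conf = 0.95, tol = NULL) {
  if (n_total < test_positive_n) {
    stop("`n_total` must be at least `test_positive_n`", call. = FALSE)
  }
  matches <- function(candidate, printed) {
    eps <- if (is.null(tol)) 0.5 * 10^(-printed_decimals(printed)) else tol
    abs(candidate - printed) <= eps + 1e-9
  }
  sols <- list()
  for (m in 1:n_total) {
    for (x in 0:min(m, test_positive_n)) {
      b <- test_positive_n - x
      d <- n_total - m - b
      if (d < 0) next
      if (!matches(100 * x / m, sens_pct)) next
      ci <- clopper_pearson(x, m, conf)
      if (!matches(ci[["lo"]], sens_ci[1]) || !matches(ci[["hi"]], sens_ci[2])) next
      sols[[length(sols) + 1L]] <- two_by_two(x, b, m - x, d)
    }
  }
  if (length(sols) == 0L) {
    stop("no 2x2 table is consistent with the printed summaries", call. = FALSE)
  }
  if (length(sols) > 1L) {
    stop("multiple 2x2 tables (", length(sols),
         ") are consistent with the printed summaries; ",
         "the inversion is not unique at this precision", call. = FALSE)
  }
  sols[[1L]]
}

#' Kappa-paradox diagnostic for a 2x2 table
#'
#' High percent agreement can coexist with low kappa when one category
#' dominates: skewed margins push the expected agreement `pe` toward 1, so
#' the chance-corrected numerator shrinks. This report quantifies that:
#' the prevalence index `(a - d)/N`, the bias index `(b - c)/N`, and the
#' prevalence-adjusted bias-adjusted kappa `PABAK = 2 po - 1`, which is what
#' kappa would be with balanced margins and symmetric errors. The paradox is
#' flagged when agreement is high (po >= 0.75) yet kappa is below 0.4.
#'
#' @param t A [two_by_two()].
#' @return List: `po`, `pe`, `kappa` (`NA` for the single-category
#'   degenerate table), `prevalence_index`, `bias_index`, `pabak`,
#'   `paradox` flag, and `degenerate` flag.
#' @examples
#' kappa_paradox_report(two_by_two(1, 7, 0, 80))  # agreement 92%, kappa 0.21
#' @export
kappa_paradox_report <- function(t) {
  stopifnot(inherits(t, "two_by_two"))
  n <- t$a + t$b + t$c + t$d
  po <- (t$a + t$d) / n
  kr <- tryCatch(cohens_kappa(t), error = function(e) NULL)
  degenerate <- is.null(kr)
  kappa <- if (degenerate) NA_real_ else kr$kappa
  pe <- if (degenerate) 1 else kr$pe
  pabak <- 2 * po - 1
  list(po = po, pe = pe, kappa = kappa,
       prevalence_index = (t$a - t$d) / n,
       bias_index = (t$b - t$c) / n,
       pabak = pabak,
       paradox = !degenerate && po >= 0.75 && kappa < 0.4,
       degenerate = degenerate)
}

#' Evaluate a screening run against the reference
#'
#' Joins per-ear screener and reference categories and, for each category's
#' one-vs-rest dichotomy, computes the 2x2 table, percent agreement, Cohen's
#' kappa with its p-value, and sensitivity/specificity with exact CIs.
#' Degenerate dichotomies (a category absent from both raters) yield `NA`
#' kappa; empty margins yield `NA` estimates.
#'
#' @param app Data frame from [screen_cohort()] (needs `child_id`, `ear`,
#'   `category`).
#' @param ref Data frame from [reference_cohort()] (same key columns).
#' @param conf Confidence level for the exact intervals.
#' @return Data frame with one row per category: `category`,
#'   `n_test_positive`, `n_ref_positive`, `agreement`, `kappa`, `kappa_p`,
#'   `sensitivity`, `sens_lo`, `sens_hi`, `specificity`, `spec_lo`,
#'   `spec_hi`. The underlying tables are attached as `attr(., "tables")`.
#' @export
evaluate_screening <- function(app, ref, conf = 0.95) {
  key <- c("child_id", "ear")
  m <- merge(app[, c(key, "category")], ref[, c(key, "category")],
             by = key, suffixes = c("_app", "_ref"))
  if (nrow(m) != nrow(app) || nrow(m) != nrow(ref)) {
    stop("app and reference results do not pair one-to-one on child_id/ear",
         call. = FALSE)
  }
  tables <- list()
  rows <- lapply(hearing_categories, function(cat) {
    t <- confusion(m$category_app, m$category_ref, positive = cat)
    tables[[cat]] <<- t
    kr <- tryCatch(cohens_kappa(t), error = function(e) NULL)
    ss <- suppressWarnings(sens_spec(t, conf))
    data.frame(category = cat,
               n_test_positive = t$a + t$b,
               n_ref_positive = t$a + t$c,
               agreement = percent_agreement(t),
               kappa = if (is.null(kr)) NA_real_ else kr$kappa,
               kappa_p = if (is.null(kr)) NA_real_ else kr$p_value,
               sensitivity = ss$sensitivity$estimate,
               sens_lo = ss$sensitivity$lo, sens_hi = ss$sensitivity$hi,
               specificity = ss$specificity$estimate,
               spec_lo = ss$specificity$lo, spec_hi = ss$specificity$hi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "tables") <- tables
  out
}
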