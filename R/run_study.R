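# Full simulated diagnostic study: cohort -> three headphone screens +
# reference audiometry in randomized order -> per-headphone evaluation ->
# duration and McNemar comparisons.

#' Run a complete simulated diagnostic accuracy study
#'
#' One seeded end-to-end study: generate a cohort, screen every child with
#' each configured headphone, run the simulated conditioned-play-audiometry
#' reference, evaluate every headphone against the reference per hearing
#' category, compare each non-reference headphone to the first (reference)
#' headphone with exact McNemar tests on the paired dichotomous calls, and
#' compare per-child test durations with paired t tests. The per-child order
#' of the four tests is randomized and logged (it does not influence the
#' simulated outcomes — the virtual children do not learn — but mirrors the
#' blinded randomized design such a study uses).
#'
#' @param seed Integer master seed; every random component derives its
#'   substream from it.
#' @param n_children Cohort size (default 44).
#' @param headphones Character vector of [headphone_preset()] names; the
#'   first is the reference headphone for McNemar comparisons.
#' @param cohort Optional [cohort_config()] (its `n_children` is overridden
#'   by the `n_children` argument).
#' @param protocol A [protocol_config()].
#' @param ambient_dBA Quiet-room ambient noise for all app screens.
#' @param noise_sd Reference audiometry measurement noise, dB.
#' @param out_dir Optional directory: when given, cohort, per-headphone
#'   results, reference results, evaluation reports and comparisons are
#'   written as CSV, each stamped with a header comment carrying the package
#'   version, seed and a configuration hash.
#' @return List of class `study_report`: `seed`, `cohort`, `test_order`,
#'   `screenings` (named list of data frames), `reference`, `reports`
#'   (named list from [evaluate_screening()]), `mcnemar`, `durations`,
#'   `duration_tests`.
#' @examples
#' \donttest{
#' st <- run_study(seed = 1, n_children = 44)
#' st$reports$tdh39
#' }
#' @export
run_study <- function(seed, n_children = 44,
                      headphones = c("tdh39", "dt770", "generic"),
                      cohort = cohort_config(), protocol = protocol_config(),
                      ambient_dBA = 35, noise_sd = 2.5, out_dir = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cohort$n_children <- n_children
  n_tests <- length(headphones) + 1L
  seeds <- derive_seeds(seed, 2L + length(headphones) + 1L)

  children <- generate_cohort(cohort, seed = seeds[1])

  # Randomized per-child order of the 3 app screens + reference (logged).
  set.seed(seeds[2])
  test_names <- c(headphones, "reference")
  order_df <- do.call(rbind, lapply(seq_along(children), function(i) {
    data.frame(child_id = children[[i]]$child_id,
               position = seq_len(n_tests),
               test = sample(test_names))
  }))

  screenings <- list()
  for (i in seq_along(headphones)) {
    cond <- test_conditions(headphone_preset(headphones[i]),
                            ambient_dBA = ambient_dBA)
    screenings[[headphones[i]]] <-
      screen_cohort(children, cond, protocol, seed = seeds[2 + i])
  }
  reference <- reference_cohort(children, noise_sd = noise_sd,
                                seed = seeds[2 + length(headphones) + 1])

  reports <- lapply(screenings, evaluate_screening, ref = reference)

  # Exact McNemar: each headphone's dichotomous calls vs the reference
  # headphone's, paired over ears.
  ref_hp <- headphones[1]
  mcn <- NULL
  if (length(headphones) > 1) {
    base <- screenings[[ref_hp]]
    mcn <- do.call(rbind, lapply(headphones[-1], function(hp) {
      other <- screenings[[hp]]
      stopifnot(identical(base$child_id, other$child_id),
                identical(base$ear, other$ear))
      do.call(rbind, lapply(hearing_categories, function(cat) {
        p_base <- base$category == cat
        p_other <- other$category == cat
        b <- sum(p_other & !p_base)
        c <- sum(!p_other & p_base)
        data.frame(headphone = hp, reference_headphone = ref_hp,
                   category = cat, b = b, c = c,
                   p_value = mcnemar_exact(b, c))
      }))
    }))
    rownames(mcn) <- NULL
  }

  # Per-child durations: both ears summed for the app, both ears for the
  # reference.
  agg <- function(df) {
    s <- tapply(df$duration_s, df$child_id, sum)
    s[order(names(s))]
  }
  durations <- data.frame(child_id = sort(unique(reference$child_id)),
                          reference = as.numeric(agg(reference)))
  for (hp in headphones) durations[[hp]] <- as.numeric(agg(screenings[[hp]]))
  duration_tests <- lapply(setNames(headphones, headphones), function(hp) {
    duration_t_test(durations[[hp]], durations$reference)
  })

  report <- structure(list(seed = seed, cohort = children,
                           test_order = order_df, screenings = screenings,
                           reference = reference, reports = reports,
                           mcnemar = mcn, durations = durations,
                           duration_tests = duration_tests),
                      class = "study_report")
  if (!is.null(out_dir)) write_study_outputs(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report> seed", x$seed, "-", length(x$cohort), "children,",
      nrow(x$reference), "ears\n")
  for (hp in names(x$reports)) {
    r <- x$reports[[hp]]
    cat(sprintf("  %-8s agreement %s | kappa %s\n", hp,
                paste(sprintf("%.2f", r$agreement), collapse = "/"),
                paste(sprintf("%.3f", r$kappa), collapse = "/")))
  }
  cat(sprintf("  mean duration: reference %.0f s, app %s s\n",
              mean(x$durations$reference),
              paste(sprintf("%.0f", colMeans(
                x$durations[, !(names(x$durations) %in%
                                  c("child_id", "reference")), drop = FALSE])),
                collapse = "/")))
  invisible(x)
}

# Write every table of a study report as CSV with a traceability header.
write_study_outputs <- function(report, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(seed = report$seed, n = length(report$cohort),
                           headphones = names(report$screenings)))
  stamp <- sprintf("# hearscreen %s seed=%s config=%s",
                   as.character(packageVersion("hearscreen")),
                   report$seed, hash)
  emit <- function(df, name) {
    path <- file.path(out_dir, paste0(name, ".csv"))
    con <- file(path, "w")
    writeLines(stamp, con)
    write.csv(df, con, row.names = FALSE, quote = FALSE)
    close(con)
  }
  emit(cohort_audiograms(report$cohort), "cohort_audiograms")
  emit(report$test_order, "test_order")
  emit(report$reference, "reference_results")
  for (hp in names(report$screenings)) {
    emit(report$screenings[[hp]], paste0("screening_", hp))
    emit(report$reports[[hp]], paste0("report_", hp))
  }
  if (!is.null(report$mcnemar)) emit(report$mcnemar, "mcnemar")
  emit(report$durations, "durations")
  invisible(out_dir)
}
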