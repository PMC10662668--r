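quiet <- function(hp = "tdh39") test_conditions(headphone_preset(hp))

test_that("a level is decided by the 2-of-3 criterion with early stopping", {
  cfg <- protocol_config()
  # deterministic passer: threshold far below every level
  ch <- flat_child("pass", 5, 5, noiseless_behavior())
  res <- run_level(40, ch, "right", quiet(), cfg)
  expect_true(res$passed)
  expect_equal(nrow(res$log), 2)  # stopped after 2 correct
  # deterministic failer
  ch2 <- flat_child("fail", 60, 60, noiseless_behavior())
  res2 <- run_level(40, ch2, "right", quiet(), cfg)
  expect_false(res2$passed)
  expect_equal(nrow(res2$log), 2)  # two wrong make 2-of-3 unreachable
  expect_error(run_level(25, ch, "right", quiet(), cfg), "protocol levels")
})

test_that("without early stopping all sets are presented", {
  cfg <- protocol_config(early_stop = FALSE)
  ch <- flat_child("pass", 5, 5, noiseless_behavior())
  res <- run_level(40, ch, "right", quiet(), cfg)
  expect_true(res$passed)
  expect_equal(nrow(res$log), 3)
})

test_that("any timeout fails the level immediately", {
  ch <- flat_child("t", 5, 5,
                   psychometric_params(guess = 0, lapse = 0, slope = 0,
                                       timeout_prob = 0.999999))
  res <- run_level(40, ch, "right", quiet(), protocol_config())
  expect_false(res$passed)
  expect_equal(nrow(res$log), 1)
  expect_equal(res$log$outcome, "timeout")
  expect_equal(res$log$response_s, 10 + 2)  # full window + overhead
})

test_that("noiseless ears land in the category forced by their threshold", {
  cases <- list(list(th = 5, cat = "normal", lowest = 20),
                list(th = 35, cat = "mild", lowest = 40),
                list(th = 60, cat = "moderate", lowest = NA_real_))
  for (cs in cases) {
    ch <- flat_child("x", cs$th, cs$th, noiseless_behavior())
    r <- run_ear(ch, "right", quiet(), protocol_config())
    expect_equal(as.character(r$category), cs$cat)
    expect_equal(r$lowest_passed_level, cs$lowest)
  }
})

test_that("descent stops at the first failed level and never passes below it", {
  cfg <- protocol_config()
  set.seed(33)
  for (i in 1:100) {
    ch <- flat_child("x", runif(1, 0, 80), runif(1, 0, 80))
    r <- run_ear(ch, "right", quiet(), cfg)
    lv <- r$presentations$level
    expect_true(all(diff(match(unique(lv), cfg$levels)) == 1))  # in order
    if (!is.na(r$lowest_passed_level)) {
      passed_levels <- cfg$levels[cfg$levels >= r$lowest_passed_level]
      expect_true(all(passed_levels %in% lv))
    }
    expect_lte(nrow(r$presentations), cfg$sets_per_level * length(cfg$levels))
    expect_equal(r$category, screened_category(r$lowest_passed_level))
    expect_equal(r$duration_s, sum(r$presentations$response_s))
  }
})

test_that("both-ear screening is deterministic under a seed and symmetric", {
  ch <- flat_child("sym", 10, 10, noiseless_behavior())
  a <- run_screening(ch, quiet(), seed = 99)
  b <- run_screening(ch, quiet(), seed = 99)
  expect_identical(a, b)
  expect_equal(a$right$category, a$left$category)
  expect_equal(names(a), c("right", "left"))

  asym <- flat_child("asym", 5, 60, noiseless_behavior())
  r <- run_screening(asym, quiet(), seed = 1)
  expect_equal(as.character(r$right$category), "normal")
  expect_equal(as.character(r$left$category), "moderate")
})

test_that("ambient noise above the isolation budget degrades screening", {
  # 20 dB ear, 30 dB isolation. At 55 dBA the levels play effectively at
  # 25/15/5 dB: the ear passes 40 but not 30, so it screens mild; at 65 dBA
  # (15/5/-5 effective) even the 40 dB level is inaudible and it screens
  # moderate.
  ch <- flat_child("noisy", 20, 20, noiseless_behavior())
  noisy <- test_conditions(headphone_preset("tdh39"), ambient_dBA = 55)
  r <- run_ear(ch, "right", noisy, protocol_config())
  expect_equal(as.character(r$category), "mild")
  louder <- test_conditions(headphone_preset("tdh39"), ambient_dBA = 65)
  r2 <- run_ear(ch, "right", louder, protocol_config())
  expect_equal(as.character(r2$category), "moderate")
  quiet_r <- run_ear(ch, "right", quiet(), protocol_config())
  expect_equal(as.character(quiet_r$category), "normal")
})

test_that("cohort screening yields one tidy row per ear, reproducibly", {
  co <- generate_cohort(cohort_config(n_children = 6), seed = 2)
  a <- screen_cohort(co, quiet(), seed = 10)
  b <- screen_cohort(co, quiet(), seed = 10)
  expect_identical(a, b)
  expect_equal(nrow(a), 12)
  expect_equal(unique(a$headphone), "tdh39")
  expect_true(all(a$n_presentations <= 9))
  expect_true(all(a$duration_s > 0))
})

test_that("simulated two-ear app durations are in a plausible clinic range", {
  co <- generate_cohort(cohort_config(n_children = 40), seed = 4)
  res <- screen_cohort(co, quiet(), seed = 8)
  per_child <- tapply(res$duration_s, res$child_id, sum)
  expect_gt(mean(per_child), 40)
  expect_lt(mean(per_child), 160)
})
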