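test_that("2x2 construction and confusion counting are exact", {
  t <- two_by_two(1, 7, 0, 80)
  expect_equal(t$a + t$b + t$c + t$d, 88)
  expect_error(two_by_two(-1, 0, 0, 5), "non-negative")
  expect_error(two_by_two(0, 0, 0, 0), "at least one")

  test <- c(rep("moderate", 3), rep("normal", 7))
  t2 <- confusion(test, test, positive = "moderate")
  expect_equal(unlist(t2[c("a", "b", "c", "d")]), c(a = 3, b = 0, c = 0, d = 7))
  t3 <- confusion(rep("normal", 10), test, positive = "moderate")
  expect_equal(t3$a + t3$b, 0)
  expect_error(confusion(test[1:5], test, "moderate"), "equal length")
})

test_that("percent agreement reproduces the published moderate-row values", {
  expect_equal(round(percent_agreement(two_by_two(1, 7, 0, 80)), 2), 92.05)
  expect_equal(round(percent_agreement(two_by_two(1, 5, 0, 82)), 2), 94.32)
  expect_equal(percent_agreement(two_by_two(0, 0, 0, 10)), 100)
})

test_that("Cohen's kappa matches its landmarks and the enumeration oracle", {
  k <- cohens_kappa(two_by_two(1, 7, 0, 80))
  expect_equal(round(k$kappa, 3), 0.206)
  expect_equal(k$po, 81 / 88)

  perfect <- cohens_kappa(two_by_two(5, 0, 0, 5))
  expect_equal(perfect$kappa, 1)
  independent <- cohens_kappa(two_by_two(4, 16, 16, 64))
  expect_equal(independent$kappa, 0)
  expect_error(cohens_kappa(two_by_two(0, 0, 0, 9)), "degenerate")

  set.seed(5)
  for (i in 1:50) {
    t <- do.call(two_by_two, as.list(rmultinom(1, 120, runif(4, 0.05, 1))[, 1] + 1))
    expect_equal(cohens_kappa(t)$kappa, kappa_oracle(t), tolerance = 1e-12)
  }
})

test_that("kappa and agreement are invariant under positive/negative relabeling", {
  set.seed(8)
  for (i in 1:25) {
    cells <- rmultinom(1, 90, runif(4, 0.05, 1))[, 1] + 1
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    swapped <- two_by_two(cells[4], cells[3], cells[2], cells[1])
    expect_equal(cohens_kappa(t)$kappa, cohens_kappa(swapped)$kappa)
    expect_equal(percent_agreement(t), percent_agreement(swapped))
  }
})

test_that("kappa p-value behaves like a null z test", {
  # strong association at decent n: small p
  expect_lt(cohens_kappa(two_by_two(30, 5, 5, 30))$p_value, 1e-6)
  # independent margins: kappa 0, p = 1
  expect_equal(cohens_kappa(two_by_two(4, 16, 16, 64))$p_value, 1)
})

test_that("Clopper-Pearson reproduces printed intervals and boundary rules", {
  expect_equal(round(clopper_pearson(1, 1), 1), c(lo = 2.5, hi = 100))
  expect_equal(round(clopper_pearson(2, 4), 2), c(lo = 6.76, hi = 93.24))
  expect_equal(clopper_pearson(0, 10)[["lo"]], 0)
  expect_equal(clopper_pearson(10, 10)[["hi"]], 100)
  expect_error(clopper_pearson(5, 4), "x <= n")
  # cross-check against the independent exact implementation in binom.test
  for (case in list(c(3, 17), c(0, 5), c(12, 12), c(40, 87))) {
    bt <- 100 * as.numeric(stats::binom.test(case[1], case[2])$conf.int)
    expect_equal(unname(clopper_pearson(case[1], case[2])), bt,
                 tolerance = 1e-8)
  }
})

test_that("sensitivity/specificity summaries match the published moderate rows", {
  s <- sens_spec(two_by_two(1, 7, 0, 80))
  expect_equal(s$sensitivity$estimate, 100)
  expect_equal(round(c(s$sensitivity$lo, s$sensitivity$hi), 1), c(2.5, 100))
  expect_equal(round(s$specificity$estimate, 0), 92)
  expect_equal(round(s$specificity$lo, 1), 84.1)

  s2 <- sens_spec(two_by_two(1, 5, 0, 82))
  expect_equal(round(s2$specificity$estimate, 1), 94.3)

  s3 <- sens_spec(two_by_two(0, 0, 5, 5))
  expect_equal(s3$sensitivity$estimate, 0)
  expect_equal(s3$specificity$estimate, 100)

  expect_warning(sens_spec(two_by_two(0, 3, 0, 5)), "reference-positive")
})

test_that("CI bounds always bracket the point estimates", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(1:60, 1)
    x <- sample(0:n, 1)
    ci <- clopper_pearson(x, n)
    expect_lte(ci[["lo"]], 100 * x / n + 1e-9)
    expect_gte(ci[["hi"]], 100 * x / n - 1e-9)
  }
})

test_that("exact McNemar matches closed-form binomial tails", {
  expect_equal(mcnemar_exact(3, 3), 1)
  expect_equal(mcnemar_exact(0, 0), 1)
  expect_equal(mcnemar_exact(5, 0), 2 * 0.5^5)
  # equal-tail doubling agrees with binom.test under p = 1/2 symmetry
  for (bc in list(c(7, 2), c(1, 9), c(4, 4), c(0, 6))) {
    expect_equal(mcnemar_exact(bc[1], bc[2]),
                 stats::binom.test(bc[1], sum(bc), 0.5)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("paired duration comparison detects shifts and rejects degeneracy", {
  set.seed(21)
  a <- rlnorm(44, log(85), 0.2)
  expect_error(duration_t_test(a, a), "degenerate")
  expect_error(duration_t_test(a + 10, a), "degenerate")  # zero-variance shift
  res <- duration_t_test(a + 10 + rnorm(44, 0, 0.5), a)
  expect_equal(res$mean_diff, 10, tolerance = 0.1)
  expect_lt(res$p_value, 1e-20)
  expect_error(duration_t_test(a, a[1:10]), "equal length")

  # simulated app vs reference durations separate decisively at n = 44
  co <- generate_cohort(cohort_config(n_children = 44), seed = 30)
  app <- screen_cohort(co, test_conditions(), seed = 31)
  ref <- reference_cohort(co, seed = 32)
  cmp <- duration_t_test(tapply(app$duration_s, app$child_id, sum),
                         tapply(ref$duration_s, ref$child_id, sum))
  expect_lt(cmp$p_value, 0.001)
  expect_lt(cmp$mean_diff, 0)
})

test_that("table reconstruction inverts printed summaries uniquely", {
  t <- reconstruct_from_summaries(100, c(2.5, 100), 8, 88)
  expect_equal(unlist(t[c("a", "b", "c", "d")]), c(a = 1, b = 7, c = 0, d = 80))
  # 50 (6.76-93.2) is the exact-CI fingerprint of 2 of 4
  t2 <- reconstruct_from_summaries(50, c(6.76, 93.2), 11, 88)
  expect_equal(t2$a + t2$c, 4)
  expect_equal(t2$a, 2)
  expect_error(reconstruct_from_summaries(100, c(50, 100), 8, 88),
               "no 2x2 table")
  expect_error(reconstruct_from_summaries(100, c(2.5, 100), 8, 88, tol = 30),
               "multiple")
  expect_error(reconstruct_from_summaries(100, c(2.5, 100), 90, 88),
               "at least")
})

test_that("reconstruction is the left inverse of sens_spec at printed precision", {
  set.seed(17)
  tried <- 0
  for (i in 1:40) {
    m <- sample(1:12, 1)            # reference-positive margin
    x <- sample(0:m, 1)             # true positives
    b <- sample(0:10, 1)
    d <- sample(20:80, 1)
    t <- two_by_two(x, b, m - x, d)
    n <- x + b + (m - x) + d
    ss <- suppressWarnings(sens_spec(t))
    if (is.na(ss$sensitivity$estimate)) next
    printed_sens <- round(ss$sensitivity$estimate, 1)
    printed_ci <- round(c(ss$sensitivity$lo, ss$sensitivity$hi), 2)
    back <- tryCatch(
      reconstruct_from_summaries(printed_sens, printed_ci, x + b, n),
      error = function(e) e)
    if (inherits(back, "error")) {
      # only the documented non-uniqueness escape is acceptable
      expect_match(conditionMessage(back), "multiple")
    } else {
      tried <- tried + 1
      expect_equal(unlist(back[c("a", "b", "c", "d")]),
                   unlist(t[c("a", "b", "c", "d")]))
    }
  }
  expect_gt(tried, 20)  # the identity actually got exercised
})

test_that("kappa paradox report quantifies prevalence-driven disagreement", {
  rep1 <- kappa_paradox_report(two_by_two(1, 7, 0, 80))
  expect_true(rep1$paradox)
  expect_equal(rep1$pabak, 2 * (81 / 88) - 1)  # 0.841
  expect_equal(round(rep1$pabak, 3), 0.841)
  expect_lt(rep1$prevalence_index, 0)

  balanced <- kappa_paradox_report(two_by_two(20, 5, 5, 20))
  expect_false(balanced$paradox)
  expect_equal(balanced$kappa, balanced$pabak)
  expect_equal(balanced$kappa, 0.6)

  degen <- kappa_paradox_report(two_by_two(0, 0, 0, 12))
  expect_true(degen$degenerate)
  expect_true(is.na(degen$kappa))
  expect_equal(degen$pabak, 1)
})

test_that("evaluate_screening assembles per-category reports with NA degeneracies", {
  app <- data.frame(child_id = rep(sprintf("c%02d", 1:5), each = 2),
                    ear = rep(c("right", "left"), 5),
                    category = c(rep("normal", 9), "mild"))
  ref <- app
  ref$category <- c(rep("normal", 9), "mild")
  rep <- evaluate_screening(app, ref)
  expect_equal(nrow(rep), 3)
  expect_equal(rep$agreement, rep(100, 3))
  expect_true(is.na(rep$kappa[rep$category == "moderate"]))  # absent category
  expect_equal(rep$kappa[rep$category == "mild"], 1)
  expect_error(evaluate_screening(app[1:9, ], ref), "one-to-one")
})
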