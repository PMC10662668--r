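test_that("cohort generation is seeded, validated, and respects degenerate mixtures", {
  cfg <- cohort_config(n_children = 30)
  a <- generate_cohort(cfg, seed = 7)
  b <- generate_cohort(cfg, seed = 7)
  expect_equal(children_ids <- vapply(a, `[[`, "", "child_id"),
               vapply(b, `[[`, "", "child_id"))
  expect_identical(lapply(a, `[[`, "right"), lapply(b, `[[`, "right"))

  all_normal <- generate_cohort(
    cohort_config(n_children = 50, p_bilateral_normal = 1,
                  p_unilateral_loss = 0, p_bilateral_loss = 0), seed = 3)
  cats <- unlist(lapply(all_normal, function(ch) {
    c(as.character(ear_category(ch$right)), as.character(ear_category(ch$left)))
  }))
  expect_true(all(cats == "normal"))

  expect_error(cohort_config(p_bilateral_normal = 0.5, p_unilateral_loss = 0.5,
                             p_bilateral_loss = 0.5), "sum to 1")
})

test_that("expected status composition at n = 44 matches the prevalence structure", {
  cfg <- cohort_config(n_children = 44)
  expected <- 44 * c(cfg$p_bilateral_normal, cfg$p_unilateral_loss,
                     cfg$p_bilateral_loss)
  expect_equal(expected, c(30.8, 9.24, 3.96))
  # and the realized composition at a fixed seed is within binomial scatter
  co <- generate_cohort(cfg, seed = 20)
  counts <- table(factor(attr(co, "status"),
                         levels = c("bilateral_normal", "unilateral_loss",
                                    "bilateral_loss")))
  expect_gt(suppressWarnings(chisq.test(counts, p = c(0.70, 0.21, 0.09))$p.value),
            0.01)
})

test_that("threshold draws respect the category bands", {
  co <- generate_cohort(cohort_config(n_children = 300), seed = 9)
  for (ch in co) {
    for (ear in c("right", "left")) {
      th <- ch[[ear]]$thresholds
      expect_equal(length(unique(th)), 1)  # flat by default
      cat <- as.character(ear_category(ch[[ear]]))
      t0 <- th[[1]]
      if (cat == "normal") expect_true(t0 >= -10 && t0 <= 20)
      if (cat == "mild") expect_true(t0 > 25 - 1e-9 && t0 <= 40)
      if (cat == "moderate") expect_true(t0 > 45 - 1e-9 && t0 <= 70)
    }
  }
})

test_that("noiseless reference audiometry reproduces the true category exactly", {
  for (th in seq(0, 80, by = 5)) {
    ch <- flat_child("x", th, th)
    ref <- reference_test(ch, noise_sd = 0, seed = 1)
    expect_equal(ref$pta, rep(th, 2))
    expect_equal(ref$category,
                 rep(as.character(classify_hearing_level(th)), 2))
  }
})

test_that("reference measurements are quantized to the audiometer step", {
  ch <- flat_child("q", 12, 33)
  ref <- reference_test(ch, noise_sd = 4, seed = 5)
  vals <- unlist(ref[, c("f0_5", "f1", "f2", "f3", "f4")])
  expect_true(all(vals %% 5 == 0))
})

test_that("noisy reference misclassification rate matches the analytic model", {
  # 20 dB flat ear, noise sd 5, 5 dB quantization: each frequency reads
  # 20 + 5k with P(k) = pnorm((5k+2.5)/5) - pnorm((5k-2.5)/5); the ear is
  # called mild iff the PTA exceeds 20, i.e. the five k's sum to >= 1.
  ks <- -10:10
  pk <- pnorm((5 * ks + 2.5) / 5) - pnorm((5 * ks - 2.5) / 5)
  dist <- setNames(pk, ks)
  conv <- function(p1, p2) {
    out <- list()
    for (i in names(p1)) for (j in names(p2)) {
      k <- as.character(as.numeric(i) + as.numeric(j))
      out[[k]] <- (out[[k]] %||% 0) + p1[[i]] * p2[[j]]
    }
    unlist(out)
  }
  total <- Reduce(conv, rep(list(as.list(dist)), 5))
  p_mild_analytic <- sum(total[as.numeric(names(total)) >= 1])

  ch <- flat_child("b", 20, 20)
  set.seed(77)
  hits <- replicate(5000, {
    ref <- reference_test(ch, noise_sd = 5)
    sum(ref$category == "mild")
  })
  p_hat <- sum(hits) / 10000  # 2 ears x 5000 draws
  se <- sqrt(p_mild_analytic * (1 - p_mild_analytic) / 10000)
  expect_lt(abs(p_hat - p_mild_analytic), 4 * se)
})

test_that("reference durations sit in the several-hundred-second band", {
  co <- generate_cohort(cohort_config(n_children = 40), seed = 13)
  ref <- reference_cohort(co, seed = 14)
  per_child <- tapply(ref$duration_s, ref$child_id, sum)
  expect_gt(mean(per_child), 400)
  expect_lt(mean(per_child), 800)
})
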