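test_that("the linear fit collapses to OLS when annotators are exchangeable", {
  set.seed(14)
  # every annotator sees identical data, so the between-annotator variance
  # is estimated at exactly zero and the fit must match plain OLS
  x0 <- rnorm(30)
  y0 <- 1.5 + 2 * x0 + rnorm(30, 0, 0.5)
  d <- data.frame(
    annotator_id = rep(sprintf("A%02d", 1:10), each = 30),
    x = rep(x0, 10), y = rep(y0, 10)
  )
  fit <- suppressMessages(
    fit_random_intercept(d, "x", "y", family = "linear"))
  ols <- lm(y ~ x, data = d)
  expect_equal(fit$estimate, unname(coef(ols)["x"]), tolerance = 1e-6)
  expect_lt(fit$p, 1e-10)
  expect_true(fit$ci_low < fit$estimate && fit$estimate < fit$ci_high)
})

test_that("a planted uncertainty-duration effect is recovered with significance", {
  cfg <- sim_config(seed = 202)
  trip <- bare_triplets(30)
  set.seed(55)
  u <- runif(30, 0.15, 0.95)
  ev <- simulate_annotators(trip, u, cfg)
  fit <- fit_random_intercept(ev[ev$triplet_id > 3, ], "stated_u",
                              "duration_s", adjust = "triplet_id",
                              family = "linear")
  expect_lt(fit$p, 0.05)
  expect_equal(fit$estimate, cfg$duration_per_u_s, tolerance = 0.25)
})

test_that("degenerate inputs raise informative errors", {
  d <- data.frame(annotator_id = rep(c("a", "b"), each = 5),
                  x = rnorm(10), y = rep(1, 10))
  expect_error(fit_random_intercept(d, "x", "y"), "constant")
  d1 <- data.frame(annotator_id = "a", x = rnorm(5), y = rnorm(5))
  expect_error(fit_random_intercept(d1, "x", "y"), "2 annotators")
  expect_error(fit_random_intercept(d, "x", "z"), "lack column")
  d$y <- rnorm(10)
  expect_error(fit_random_intercept(d, "x", "y", family = "logistic"),
               "0/1")
})

test_that("the association grid mirrors the study's table structure", {
  cfg <- sim_config(seed = 77)
  trip <- bare_triplets(30)
  set.seed(3)
  u <- runif(30, 0.2, 0.95)
  ev <- simulate_annotators(trip, u, cfg)
  eda <- simulate_eda(ev, cfg)
  ev$eda_mean <- NA_real_
  for (a in names(eda)) {
    sel <- ev$annotator_id == a
    d <- ev[sel, ]
    ev$eda_mean[sel][order(d$triplet_id)] <-
      eda_means(eda[[a]], d$duration_s[order(d$triplet_id)])
  }
  suite <- association_suite(ev, skip_first = 3)
  expect_equal(nrow(suite), 10)
  expect_setequal(unique(suite$block),
                  c("uncertainty", "ordinal", "correctness",
                    "uncertainty_adjusted"))
  # the planted ordinal decay in duration is recovered with its sign
  ord <- suite[suite$exposure == "triplet_id" &
                 suite$outcome == "duration_s", ]
  expect_lt(ord$estimate, 0)
  expect_lt(ord$p, 0.05)
  # logistic row reports an odds ratio with a CI around it
  logi <- suite[suite$family == "logistic", ]
  expect_equal(logi$outcome, "correct")
  expect_gt(logi$estimate, 0)
  expect_true(logi$ci_low < logi$estimate & logi$estimate < logi$ci_high)

  # without EDA the corresponding rows are skipped with a notice
  ev2 <- ev[, setdiff(names(ev), "eda_mean")]
  expect_message(suite2 <- association_suite(ev2, skip_first = 3),
                 "skipping EDA")
  expect_equal(nrow(suite2), 5)
  expect_false(any(suite2$exposure == "eda_mean" |
                     suite2$outcome == "eda_mean"))
})

test_that("acclimatization summaries quantify the early-task slowdown", {
  cfg <- sim_config(seed = 31, duration_decay_s = 1.5)
  trip <- bare_triplets(30)
  ev <- simulate_annotators(trip, rep(0.5, 30), cfg)
  ac <- acclimatization_summary(ev, k = 3)
  expect_equal(ac$k, 3)
  expect_equal(nrow(ac$triplet), 30)
  # planted decay: the first three tasks are slower than the rest
  expect_gt(median(ac$triplet$duration_median[1:3]),
            median(ac$triplet$duration_median[4:30]))
  expect_true(all(ac$annotator$ratio_all >= 0 &
                    ac$annotator$ratio_all <= 1))
  expect_equal(ac$n_improved,
               sum(ac$annotator$ratio_excl > ac$annotator$ratio_all))

  # k = 0 keeps both correctness vectors identical
  ac0 <- acclimatization_summary(ev, k = 0)
  expect_equal(ac0$annotator$ratio_all, ac0$annotator$ratio_excl)
  expect_error(acclimatization_summary(ev, k = 30), "smaller")
})
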