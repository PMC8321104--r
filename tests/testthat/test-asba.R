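test_that("heom reproduces hand-computed distances", {
  cohort <- tiny_cohort(4)
  schema <- feature_schema(cohort)
  r <- cohort[1, ]
  expect_equal(heom(r, r, schema), 0)

  # differing only in two nominal variables -> sqrt(2)
  r2 <- r
  r2$sex <- 1 - r$sex
  r2$diabetes <- 1 - r$diabetes
  expect_equal(heom(r, r2, schema), sqrt(2))

  # age 30 vs 60 under range [20, 80] -> (60 - 30) / (80 - 20) = 0.5
  ref <- data.frame(age = c(20, 80), sex = c(0, 1))
  s <- feature_schema(ref, continuous = "age", nominal = character())
  expect_equal(heom(list(age = 30), list(age = 60), s), 0.5)
})

test_that("heom clips out-of-range differences and ignores constants", {
  ref <- data.frame(age = c(20, 80), crp_hs = c(1, 1))
  s <- feature_schema(ref, continuous = c("age", "crp_hs"),
                      nominal = character())
  # difference of 90 years exceeds the 60-year range -> clipped to 1
  expect_equal(heom(list(age = 0, crp_hs = 5), list(age = 90, crp_hs = 2),
                    s), 1)
  # zero-width range contributes 0
  expect_equal(heom(list(age = 20, crp_hs = 5), list(age = 20, crp_hs = 9),
                    s), 0)
  expect_error(heom(list(age = 1), list(age = 2), s), "crp_hs")
})

test_that("heom is a bounded semimetric on the feature space", {
  cohort <- generate_cohort(sim_config(seed = 21, cohort_size = 40))
  schema <- feature_schema(cohort)
  set.seed(77)
  for (k in 1:25) {
    i <- sample(nrow(cohort), 2)
    a <- cohort[i[1], ]
    b <- cohort[i[2], ]
    d <- heom(a, b, schema)
    expect_gte(d, 0)
    expect_lte(d, sqrt(10))
    expect_equal(heom(b, a, schema), d)
  }
  expect_equal(heom(cohort[3, ], cohort[3, ], schema), 0)
})

test_that("the machine annotator chooses the nearest anchor with Eq-5 uncertainty", {
  ref <- data.frame(age = seq(0, 10, length.out = 3), sex = c(0, 1, 0))
  schema <- feature_schema(ref, continuous = "age", nominal = "sex")
  cohort <- data.frame(id = c("a", "b", "c"),
                       age = c(0, 6, 12.633249), sex = c(0, 0, 1),
                       stringsAsFactors = FALSE)
  trip <- data.frame(triplet_id = 1, id_A = "a", id_B = "b", id_C = "c",
                     true_label = "A", stringsAsFactors = FALSE)
  res <- asba_annotate(trip, cohort, schema = schema)
  # dist(A,B) = 0.6; dist(C,B) = sqrt(0.6633^2 + 1) = 1.2
  expect_equal(res$dist_AB, 0.6)
  expect_equal(res$dist_CB, 1.2, tolerance = 1e-6)
  expect_equal(res$choice, "A")
  expect_equal(res$asba_u, 0.5, tolerance = 1e-6)
  expect_equal(res$correct, 1L)

  # B identical to A -> certain choice of A
  cohort2 <- cohort
  cohort2$age[2] <- 0
  res2 <- asba_annotate(trip, cohort2, schema = schema)
  expect_equal(res2$choice, "A")
  expect_equal(res2$asba_u, 0)

  # equidistant anchors -> tie resolves to C with maximal uncertainty
  cohort3 <- data.frame(id = c("a", "b", "c"), age = c(2, 6, 10),
                        sex = c(0, 0, 0), stringsAsFactors = FALSE)
  expect_warning(res3 <- asba_annotate(trip, cohort3, schema = schema),
                 "equidistant")
  expect_equal(res3$choice, "C")
  expect_equal(res3$asba_u, 1)
})

test_that("uncertainty is invariant under swapping the anchors", {
  cohort <- generate_cohort(sim_config(seed = 31))
  groups <- sample_and_group(cohort, seed = 2)
  trip <- build_triplets(groups)
  res <- asba_annotate(trip, cohort)
  swapped <- trip
  swapped$id_A <- trip$id_C
  swapped$id_C <- trip$id_A
  res_sw <- suppressWarnings(asba_annotate(swapped, cohort))
  expect_equal(res_sw$asba_u, res$asba_u)
  ties <- res$dist_AB == res$dist_CB
  expect_equal(res_sw$choice[!ties],
               ifelse(res$choice[!ties] == "A", "C", "A"))
  expect_true(all(res$asba_u >= 0 & res$asba_u <= 1))
})

test_that("Eq-6/Eq-7 discretization rounds half-up and thresholds at tau", {
  d <- discretize_asba_u(c(0, 0.19, 0.5, 1))
  expect_equal(d$aggregated, c(0L, 1L, 2L, 3L))
  expect_equal(d$binary, c(0L, 0L, 1L, 1L))
  expect_error(discretize_asba_u(1.2), "\\[0, 1\\]")
  expect_error(discretize_asba_u(0.5, tau_asba = 0), "tau_asba")
})

test_that("correctness rises as the planted signal sharpens and falls with uncertainty", {
  # planted signal: B is its true anchor plus feature noise
  make_planted <- function(noise_sd, n_t = 150, seed = 99) {
    set.seed(seed)
    anchor_a <- runif(n_t, 60, 100)
    anchor_c <- runif(n_t, 0, 40)
    truth <- sample(c("A", "C"), n_t, replace = TRUE)
    b <- ifelse(truth == "A", anchor_a, anchor_c) + rnorm(n_t, 0, noise_sd)
    ldl_a <- runif(n_t, 4, 6)
    ldl_c <- runif(n_t, 1, 3)
    ldl_b <- ifelse(truth == "A", ldl_a, ldl_c) + rnorm(n_t, 0,
                                                        noise_sd / 20)
    cohort <- data.frame(
      id = c(sprintf("a%d", 1:n_t), sprintf("b%d", 1:n_t),
             sprintf("c%d", 1:n_t)),
      age = c(anchor_a, b, anchor_c),
      ldlch = c(ldl_a, ldl_b, ldl_c), stringsAsFactors = FALSE)
    trip <- data.frame(triplet_id = 1:n_t, id_A = sprintf("a%d", 1:n_t),
                       id_B = sprintf("b%d", 1:n_t),
                       id_C = sprintf("c%d", 1:n_t), true_label = truth,
                       stringsAsFactors = FALSE)
    schema <- feature_schema(cohort, continuous = c("age", "ldlch"),
                             nominal = character())
    asba_annotate(trip, cohort, schema = schema)
  }
  res_lo <- make_planted(5)
  res_mid <- make_planted(25)
  res_hi <- make_planted(60)
  expect_gt(mean(res_lo$correct), 0.5)
  expect_gt(mean(res_mid$correct), 0.5)
  expect_gt(mean(res_lo$correct), mean(res_mid$correct))
  expect_gt(mean(res_mid$correct), mean(res_hi$correct))

  # within one run, correctness decreases across uncertainty terciles
  res <- make_planted(30, n_t = 300)
  bins <- cut(res$asba_u, breaks = quantile(res$asba_u, c(0, 1/3, 2/3, 1)),
              include.lowest = TRUE)
  rates <- tapply(res$correct, bins, mean)
  expect_gt(rates[1], rates[3])
})
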