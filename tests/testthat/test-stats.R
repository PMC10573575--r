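test_that("change scores difference the right visits and drop incomplete eyes", {
  rec <- records_with_visit_means(200.7, 213.4, 10, "thickness_um", "circle5",
                                  "pretreatment", "exudation", seed = 60)
  ch <- change_scores(rec, "pretreatment", "exudation")
  expect_equal(nrow(ch), 10)
  expect_equal(mean(ch$change), 213.4 - 200.7, tolerance = 1e-9)
  ## identical visits give all-zero changes
  rec0 <- rec
  rec0$value[rec0$visit == "exudation"] <-
    rec0$value[rec0$visit == "pretreatment"]
  ch0 <- change_scores(rec0, "pretreatment", "exudation")
  expect_true(all(ch0$change == 0))
  ## an eye missing the target visit is dropped, with its id recorded
  rec_miss <- rec[!(rec$eye_id == "E03" & rec$visit == "exudation"), ]
  expect_message(ch2 <- change_scores(rec_miss, "pretreatment", "exudation"),
                 "E03")
  expect_equal(nrow(ch2), 9)
  expect_identical(attr(ch2, "dropped"), "E03")
})

test_that("mean of paired changes equals the difference of visit means", {
  set.seed(61)
  rec <- records_with_visit_means(180, 195.3, 23, "thickness_um", "circle5",
                                  "exudation", "post_treatment", seed = 61,
                                  spread = 30)
  ch <- change_scores(rec, "exudation", "post_treatment")
  a <- mean(rec$value[rec$visit == "exudation"])
  b <- mean(rec$value[rec$visit == "post_treatment"])
  expect_equal(mean(ch$change), b - a, tolerance = 1e-12)
})

test_that("zero residuals give zero cluster-robust standard errors", {
  y <- rep(5, 12)
  cl <- rep(1:4, each = 3)
  fit <- cluster_robust_fit(y, cluster = cl)
  expect_equal(fit$coefficients[1, "estimate"], 5)
  expect_equal(fit$coefficients[1, "se"], 0)
})

test_that("CR0 with singleton clusters equals the HC0 sandwich", {
  set.seed(62)
  n <- 40
  X <- cbind(1, stats::rnorm(n), stats::rnorm(n))
  y <- X %*% c(1, 2, -0.5) + stats::rnorm(n)
  fit <- cluster_robust_fit(y, X, cluster = seq_len(n), correction = "CR0")
  bread <- solve(t(X) %*% X)
  e <- as.numeric(y - X %*% solve(t(X) %*% X, t(X) %*% y))
  meat <- t(X) %*% diag(e^2) %*% X
  hc0 <- bread %*% meat %*% bread
  expect_equal(unname(fit$vcov), unname(hc0), tolerance = 1e-10)
})

test_that("sandwich covariance matches a brute-force per-cluster loop", {
  set.seed(63)
  for (rep in 1:50) {
    G <- sample(5:15, 1)
    n <- G * sample(2:5, 1)
    cl <- sample(rep(seq_len(G), length.out = n))
    k <- sample(1:3, 1)
    X <- cbind(1, matrix(stats::rnorm(n * (k - 1)), n))
    y <- X %*% stats::rnorm(k) + stats::rnorm(n) + stats::rnorm(G)[cl]
    for (corr in c("CR0", "CR1")) {
      fit <- cluster_robust_fit(y, X, cl, correction = corr)
      V <- brute_force_sandwich(y, X, cl, corr)
      expect_equal(unname(fit$vcov), unname(V), tolerance = 1e-10)
    }
  }
})

test_that("the estimator agrees with an independent implementation", {
  skip_if_not_installed("sandwich")
  set.seed(64)
  n <- 60; G <- 12
  cl <- sample(rep(seq_len(G), length.out = n))
  X <- cbind(1, stats::rnorm(n), stats::rnorm(n))
  y <- X %*% c(1, 2, -1) + stats::rnorm(n) + stats::rnorm(G)[cl]
  lmf <- stats::lm(y ~ X - 1)
  expect_equal(unname(cluster_robust_fit(y, X, cl, "CR1")$vcov),
               unname(sandwich::vcovCL(lmf, cluster = cl, type = "HC1")),
               tolerance = 1e-10)
  expect_equal(unname(cluster_robust_fit(y, X, cl, "CR0")$vcov),
               unname(sandwich::vcovCL(lmf, cluster = cl, type = "HC0",
                                       cadjust = FALSE)),
               tolerance = 1e-10)
})

test_that("degenerate designs are rejected", {
  y <- stats::rnorm(10)
  X <- cbind(1, rep(2, 10))   # collinear with the intercept
  expect_error(cluster_robust_fit(y, X, cluster = rep(1:5, 2)), "singular")
  expect_error(cluster_robust_fit(y, cluster = rep(1, 10)),
               "at least 2 clusters")
  expect_error(cluster_robust_fit(stats::rnorm(2),
                                  X = matrix(stats::rnorm(4), 2),
                                  cluster = 1:2),
               "more observations")
})

test_that("type-difference test targets the type-3 indicator", {
  set.seed(65)
  n <- 30
  mnv <- rep(c(1, 2, 3), each = 10)
  ch <- stats::rnorm(n) + ifelse(mnv == 3, 4, 0)
  fit <- type_difference_test(ch, mnv, cluster = seq_len(n))
  expect_equal(fit$coefficients["type3", "estimate"],
               mean(ch[mnv == 3]) - mean(ch[mnv != 3]), tolerance = 1e-9)
  expect_error(type_difference_test(ch[mnv == 3], mnv[mnv == 3],
                                    cluster = 1:10),
               "both MNV groups")
})

test_that("summary tables carry visit means, signed changes and p-values", {
  cp <- cohort_params(seed = 66)
  rec <- cohort_to_records(generate_cohort(cp))
  tabs <- summarize_tables(rec)
  expect_named(tabs, c("pre_to_exudation", "exudation_to_post", "pre_to_post"))
  t3 <- tabs$exudation_to_post$all_eyes
  th <- t3[t3$metric == "thickness_um", ]
  ## "decrease" rows are positive when the measurement fell
  expect_identical(th$direction, "decrease")
  expect_equal(th$change_mean, th$mean_from - th$mean_to, tolerance = 1e-9)
  expect_gt(th$change_mean, 0)
  expect_true(all(tabs$pre_to_exudation$all_eyes$p_value >= 0))
  expect_true(all(tabs$pre_to_exudation$all_eyes$p_value <= 1))
  bt <- tabs$pre_to_exudation$by_type
  expect_setequal(unique(bt$group), c("type_1_or_2", "type_3"))
})

test_that("constant records summarize to zero change with zero SD", {
  cp <- cohort_params(
    n_patients = 6,
    thickness = list(baseline_mean = 200, between_patient_sd = 0,
                     between_eye_sd = 0, residual_sd = 0,
                     delta_exudation = 0, delta_treatment = 0),
    cvi = list(baseline_mean = 0.6, between_patient_sd = 0,
               between_eye_sd = 0, residual_sd = 0,
               delta_exudation = 0, delta_treatment = 0),
    seed = 67)
  rec <- cohort_to_records(generate_cohort(cp))
  tabs <- summarize_tables(rec, comparisons = "pre_to_exudation")
  tab <- tabs$pre_to_exudation$all_eyes
  expect_true(all(tab$change_mean == 0))
  expect_true(all(tab$change_sd == 0))
})

test_that("null cohorts rarely show spurious mean changes", {
  null_params <- function(s) cohort_params(
    thickness = list(baseline_mean = 200, between_patient_sd = 60,
                     between_eye_sd = 20, residual_sd = 16,
                     delta_exudation = 0, delta_treatment = 0),
    cvi = list(baseline_mean = 0.6, between_patient_sd = 0.03,
               between_eye_sd = 0.01, residual_sd = 0.016,
               delta_exudation = 0, delta_treatment = 0),
    seed = s)
  hits <- 0L
  for (s in 1:40) {
    rec <- cohort_to_records(generate_cohort(null_params(s)))
    ch <- suppressMessages(change_scores(rec, "pretreatment", "exudation",
                                         metric = "thickness_um"))
    se <- stats::sd(ch$change) / sqrt(nrow(ch))
    if (abs(mean(ch$change)) <= 3 * se) hits <- hits + 1L
  }
  expect_gte(hits, 38L)
})

test_that("a cohort at the observed effect size recovers the mean change", {
  cp <- cohort_params(n_patients = 27, p_fellow_eye = 0, seed = 68)
  rec <- cohort_to_records(generate_cohort(cp))
  ch <- suppressMessages(change_scores(rec, "pretreatment", "exudation",
                                       metric = "thickness_um"))
  se <- stats::sd(ch$change) / sqrt(nrow(ch))
  expect_lt(abs(mean(ch$change) - 12.7), 3 * se)
})
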