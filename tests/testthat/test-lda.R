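make_toy <- function(n = 30, p = 4, shift = 2, seed = 5) {
  set.seed(seed)
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  X[seq_len(n), 1] <- X[seq_len(n), 1] + shift
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- paste0("x", seq_len(p))
  d$label <- rep(c("active", "inactive"), each = n)
  d$id <- sprintf("m%03d", seq_len(2 * n))
  d
}

test_that("evaluate_df is the linear form with sign-coded classes", {
  m <- discriminant_model(c("x", "y"), c(1, -1), 0)
  expect_equal(evaluate_df(c(x = 2, y = 2), m), 0)        # boundary
  expect_equal(evaluate_df(c(x = 0, y = 0), m), 0)
  m2 <- discriminant_model(c("x", "y"), c(2, 0.5), intercept = 1.5)
  expect_equal(evaluate_df(c(x = 0, y = 0), m2), 1.5)     # intercept only
  # linearity: changing one input changes DF by coefficient * increment
  base <- evaluate_df(c(x = 1, y = 3), m2)
  expect_equal(evaluate_df(c(x = 1, y = 5), m2) - base, 0.5 * 2)
  # data frame in, tibble out
  out <- evaluate_df(tibble::tibble(x = c(0, 1), y = c(0, 0)), m2)
  expect_s3_class(out, "tbl_df")
  expect_equal(out$df, c(1.5, 3.5))
  expect_error(evaluate_df(c(x = 1), m2), "missing descriptor")
})

test_that("wilks_lambda equals the det-ratio oracle and hits its bounds", {
  # equal class means: no between-group scatter
  d <- tibble::tibble(x = rep(c(1, 2, 3), 2),
                      label = rep(c("active", "inactive"), each = 3))
  expect_equal(wilks_lambda(d, "x"), 1)
  # zero within-class variance, distinct means: perfect separation
  d2 <- tibble::tibble(x = c(1, 1, 1, 5, 5, 5),
                       label = rep(c("active", "inactive"), each = 3))
  expect_equal(wilks_lambda(d2, "x"), 0)
  # 6-point 2-descriptor toy vs oracle
  d3 <- tibble::tibble(x = c(0.1, 0.5, 0.2, 1.4, 1.1, 1.9),
                       y = c(1.0, 0.4, 0.7, 0.2, 0.9, 0.1),
                       label = rep(c("active", "inactive"), each = 3))
  expect_equal(wilks_lambda(d3, c("x", "y")),
               wilks_oracle(cbind(d3$x, d3$y), d3$label),
               tolerance = 1e-12)
  # random small instances to 1e-10
  set.seed(99)
  for (r in 1:20) {
    n <- sample(3:5, 1)
    p <- sample(1:3, 1)
    X <- matrix(rnorm(2 * n * p), 2 * n, p)
    d4 <- tibble::as_tibble(as.data.frame(X))
    names(d4) <- paste0("v", seq_len(p))
    d4$label <- rep(c("active", "inactive"), each = n)
    expect_equal(wilks_lambda(d4, paste0("v", seq_len(p))),
                 wilks_oracle(X, d4$label), tolerance = 1e-10)
  }
  expect_error(
    wilks_lambda(tibble::tibble(x = rep(1, 6),
                                label = rep(c("active", "inactive"), 3)),
                 "x"), "singular")
})

test_that("adding a descriptor never increases Wilks' lambda", {
  d <- make_toy(n = 25, p = 5)
  set.seed(3)
  for (r in 1:10) {
    sub <- sample(paste0("x", 1:5), 3)
    lam_small <- wilks_lambda(d, sub[1:2])
    lam_big <- wilks_lambda(d, sub)
    expect_lte(lam_big, lam_small + 1e-12)
  }
})

test_that("wilks_to_f follows the exact two-group transformation", {
  expect_equal(wilks_to_f(1, 20, 2)$F, 0)
  expect_equal(wilks_to_f(1, 20, 2)$p_value, 1)
  expect_equal(wilks_to_f(0, 20, 2)$F, Inf)
  expect_equal(wilks_to_f(0.5, 12, 1)$F, 10)  # direct substitution
  # inversion: lambda = df2 / (df2 + p F)
  for (lam in c(0.1, 0.462, 0.686, 0.9)) {
    ft <- wilks_to_f(lam, 101, 3)
    lam_back <- ft$df2 / (ft$df2 + ft$df1 * ft$F)
    expect_equal(lam_back, lam, tolerance = 1e-12)
  }
})

test_that("fitted discriminant agrees with the reference LDA implementation", {
  d <- make_toy(n = 40, p = 4, shift = 1.5, seed = 8)
  m <- fit_discriminant(d, paste0("x", 1:4))
  scored <- evaluate_df(d, m)
  ref <- MASS::lda(as.matrix(d[paste0("x", 1:4)]),
                   grouping = d$label, prior = c(0.5, 0.5))
  ref_pred <- predict(ref)$class
  expect_equal(scored$df > 0, ref_pred == "active")
  # boundary at 0: class centroids score symmetrically
  mu_a <- colMeans(d[d$label == "active", paste0("x", 1:4)])
  mu_i <- colMeans(d[d$label == "inactive", paste0("x", 1:4)])
  expect_equal(evaluate_df(c(mu_a), m), -evaluate_df(c(mu_i), m))
})

test_that("stepwise selection recovers planted signal descriptors", {
  set.seed(20240101)
  n <- 60; p <- 50
  X <- matrix(rnorm(2 * n * p), 2 * n, p)
  planted <- c(7, 21, 38)
  for (j in planted) X[seq_len(n), j] <- X[seq_len(n), j] + 1.4
  d <- tibble::as_tibble(as.data.frame(X))
  names(d) <- sprintf("d%02d", seq_len(p))
  d$label <- rep(c("active", "inactive"), each = n)
  m <- stepwise_select(d)
  expect_true(all(sprintf("d%02d", planted) %in% m$descriptors))
  # noise descriptors stay mostly out
  expect_lte(length(m$descriptors), 10)
})

test_that("stepwise picks a perfect separator first and honors max_terms", {
  d <- make_toy(n = 20, p = 3, shift = 0.5, seed = 4)
  d$sep <- ifelse(d$label == "active", 10, -10) + rnorm(nrow(d), 0, 0.01)
  m <- stepwise_select(d)
  expect_equal(m$descriptors[1], "sep")
  m1 <- stepwise_select(d, max_terms = 1)
  expect_length(m1$descriptors, 1)
  # nothing informative: intercept-only with warning
  dnull <- make_toy(n = 15, p = 3, shift = 0, seed = 10)
  expect_warning(m0 <- stepwise_select(dnull, p_enter = 1e-8),
                 "intercept-only")
  expect_length(m0$descriptors, 0)
})

test_that("confusion_summary rounds percentages like published tables", {
  # counts mirroring the published training table: 33/42 actives, 45/59
  # inactives correct
  d <- tibble::tibble(
    x = c(rep(1, 33), rep(-1, 9), rep(1, 14), rep(-1, 45)),
    label = rep(c("active", "inactive"), c(42, 59)))
  m <- discriminant_model("x", 1, 0)
  cs <- confusion_summary(d, m)
  expect_equal(cs$pct_correct, c(79, 76, 77))
  expect_equal(cs$n_active, c(33, 14, 47))
  expect_equal(cs$n_inactive, c(9, 45, 54))
  # perfect classifier
  dp <- tibble::tibble(x = c(1, 1, -1, -1),
                       label = c("active", "active", "inactive", "inactive"))
  expect_equal(confusion_summary(dp, m)$pct_correct, c(100, 100, 100))
})

test_that("lsocv is seed-deterministic and exact on separable data", {
  d <- make_toy(n = 30, p = 3, shift = 12, seed = 2)  # fully separated
  m <- fit_discriminant(d, paste0("x", 1:3))
  cv1 <- lsocv(d, m, seed = 7)
  cv2 <- lsocv(d, m, seed = 7)
  expect_identical(cv1, cv2)
  expect_equal(cv1$summary$mean_pct_correct, 100)
  expect_equal(cv1$summary$n_folds_used, 10)
  expect_equal(unique(cv1$folds$n_holdout), 12)  # ceiling(0.2 * 30) per class
})

test_that("tidy and glance expose model terms and statistics", {
  d <- make_toy()
  m <- fit_discriminant(d, c("x1", "x2"), name = "DF_test")
  td <- generics::tidy(m)
  expect_equal(td$term, c("(Intercept)", "x1", "x2"))
  expect_equal(nrow(td), 3)
  gl <- generics::glance(m)
  expect_equal(gl$N, nrow(d))
  expect_equal(gl$name, "DF_test")
  expect_true(gl$wilks_lambda > 0 && gl$wilks_lambda < 1)
})

test_that("models round-trip through JSON including NA-coefficient registry entries", {
  d <- make_toy()
  m <- fit_discriminant(d, c("x1", "x3"), name = "DF_rt")
  path <- withr::local_tempfile(fileext = ".json")
  write_model(m, path)
  back <- read_model(path)
  expect_equal(back$descriptors, m$descriptors)
  expect_equal(back$coefficients, m$coefficients)
  expect_equal(back$intercept, m$intercept)
  expect_equal(back$stats$wilks_lambda, m$stats$wilks_lambda)

  pub <- published_models()
  expect_named(pub, c("DF_gen", "DF_1", "DF_2", "DF_3"))
  expect_equal(pub$DF_gen$descriptors, c("SRW05", "CIC2", "GATS6m"))
  expect_equal(pub$DF_gen$stats$N, 101)
  expect_error(evaluate_df(c(SRW05 = 1, CIC2 = 1, GATS6m = 1), pub$DF_gen),
               "no usable coefficients")
})

test_that("evaluate_df is invariant to row order and batching", {
  d <- make_toy(n = 20)
  m <- fit_discriminant(d, paste0("x", 1:3))
  full <- evaluate_df(d, m)
  perm <- sample(nrow(d))
  shuffled <- evaluate_df(d[perm, ], m)
  expect_equal(shuffled$df, full$df[perm])
  halves <- c(evaluate_df(d[1:10, ], m)$df,
              evaluate_df(d[-(1:10), ], m)$df)
  expect_equal(halves, full$df)
})
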