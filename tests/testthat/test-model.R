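## small synthetic feature tables, no signal synthesis needed
make_fm <- function(n = 14, n_noise = 10, seed = 1) {
  withr::with_seed(seed, {
    fas <- sample(10:50, n, replace = TRUE)
    fm <- tibble::tibble(subject_id = sprintf("S%02d", 1:n), fas = fas)
    fm$planted <- 100 - 2 * fas
    for (j in seq_len(n_noise)) fm[[paste0("noise_", j)]] <- rnorm(n)
    fm
  })
}

test_that("feature assembly excludes incomplete subjects and NA columns", {
  f <- make_fm()
  f$incomplete <- c(rep(TRUE, 3), rep(FALSE, 11))
  f$broken <- c(rnorm(13), NA)        # missing value on a complete subject
  expect_message(fm <- assemble_feature_matrix(f), "missing values")
  expect_equal(nrow(fm), 11)
  expect_false("broken" %in% attr(fm, "feature_cols"))
  expect_equal(attr(fm, "excluded_subjects"), sprintf("S%02d", 1:3))
  f2 <- make_fm()
  names(f2)[names(f2) == "noise_2"] <- "noise_1"
  expect_error(assemble_feature_matrix(f2), "duplicate")
  expect_error(assemble_feature_matrix(make_fm(n = 2)), "3 complete subjects")
})

test_that("a noiseless linear feature is ranked first with a vanishing p-value", {
  sel <- select_features(make_fm())
  expect_equal(sel$feature[1], "planted")
  expect_lt(sel$p[1], 1e-6)
  expect_true(all(sel$p < 0.05))
  expect_true(!is.unsorted(sel$p))
})

test_that("correlation statistics match the t-distribution closed form", {
  withr::with_seed(8, {
    for (i in 1:20) {
      m <- sample(5:20, 1)
      fm <- tibble::tibble(subject_id = as.character(1:m), fas = rnorm(m),
                           x = rnorm(m))
      sel <- select_features(fm, alpha = Inf)
      ct <- cor.test(fm$x, fm$fas)
      expect_equal(sel$r, unname(ct$estimate), tolerance = 1e-10)
      expect_equal(sel$p, ct$p.value, tolerance = 1e-10)
    }
  })
})

test_that("zero-variance columns are never selected", {
  fm <- make_fm()
  fm$flat <- 1
  sel <- select_features(fm, alpha = Inf)
  expect_equal(sel$p[sel$feature == "flat"], 1)
  sel05 <- select_features(fm, alpha = 0.05)
  expect_false("flat" %in% sel05$feature)
})

test_that("redundancy pruning keeps the better member of reciprocal pairs", {
  sel <- structure(
    tibble::tibble(
      feature = c("ratio_alpha_theta_O2", "ratio_theta_alpha_O2",
                  "np_alpha_C3", "ratio_beta_theta_C3"),
      r = c(-0.9, 0.89, 0.5, -0.6),
      p = c(0.0011, 0.0012, 0.02, 0.01)),
    class = c("nf_selection", class(tibble::tibble())), alpha = 0.05, m = 14)
  out <- drop_redundant(sel)
  expect_true("ratio_alpha_theta_O2" %in% out$feature)
  expect_false("ratio_theta_alpha_O2" %in% out$feature)
  expect_true(all(c("np_alpha_C3", "ratio_beta_theta_C3") %in% out$feature))
  ## no reciprocal pair: untouched
  expect_identical(drop_redundant(out)$feature, out$feature)
  ## brute-force property: output never contains both members of a pair
  withr::with_seed(12, {
    for (i in 1:20) {
      nm <- sample(ratio_feature_names(), 30)
      s <- tibble::tibble(feature = nm, r = runif(30, -1, 1), p = runif(30))
      s <- s[order(s$p), ]
      class(s) <- c("nf_selection", class(tibble::tibble()))
      pruned <- drop_redundant(s)
      parts <- stringr::str_match(pruned$feature, "^ratio_([a-z]+)_([a-z]+)_(.+)$")
      key <- paste(pmin(parts[, 2], parts[, 3]), pmax(parts[, 2], parts[, 3]),
                   parts[, 4])
      expect_false(anyDuplicated(key) > 0)
    }
  })
})

test_that("the normal-equation fit recovers exact linear structure", {
  withr::with_seed(2, {
    X <- matrix(rnorm(12 * 3), 12, 3, dimnames = list(NULL, c("a", "b", "c")))
    w_true <- c(5, 1.5, -2, 0.5)
    y <- cbind(1, X) %*% w_true
    fit <- fit_mlr(X, drop(y))
    expect_equal(unname(fit$coefficients), w_true, tolerance = 1e-9)
    expect_lt(max(abs(fit$residuals)), 1e-9)
  })
  ## intercept-only model predicts the mean
  fit0 <- fit_mlr(matrix(numeric(0), 5, 0), c(1, 2, 3, 4, 10))
  expect_equal(unname(fit0$coefficients), 4)
})

test_that("the normal equation agrees with a QR least-squares oracle", {
  withr::with_seed(13, {
    for (i in 1:20) {
      n <- sample(8:25, 1); k <- sample(1:5, 1)
      X <- matrix(rnorm(n * k), n, k,
                  dimnames = list(NULL, paste0("f", 1:k)))
      y <- rnorm(n)
      fit <- fit_mlr(X, y)
      oracle <- unname(coef(lm(y ~ X)))
      expect_equal(unname(fit$coefficients), oracle, tolerance = 1e-8)
    }
  })
})

test_that("rank-deficient designs fall back to the minimum-norm solution", {
  withr::with_seed(14, {
    X <- matrix(rnorm(4 * 6), 4, 6, dimnames = list(NULL, paste0("f", 1:6)))
    y <- rnorm(4)
    expect_message(fit <- fit_mlr(X, y), "rank-deficient")
    expect_true(fit$rank_deficient)
    expect_lt(max(abs(fit$residuals)), 1e-8)   # interpolates the training data
  })
})

test_that("prediction and broom-style accessors are consistent", {
  fm <- make_fm()
  fit <- fit_mlr(fm[, c("planted", "noise_1")], fm$fas)
  newd <- fm[1:3, ]
  expect_equal(predict(fit, newd), fit$fitted[1:3], tolerance = 1e-10)
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "planted", "noise_1"))
  gl <- glance(fit)
  expect_equal(gl$nobs, 14)
  expect_equal(gl$rmse, rmse_value(fm$fas, fit$fitted), tolerance = 1e-12)
  expect_gt(gl$r.squared, 0.999)
})

test_that("RMSE follows its definition", {
  expect_equal(rmse_value(c(20, 30), c(22, 28)), 2)
  expect_equal(rmse_value(1:5, 1:5), 0)
  withr::with_seed(15, {
    y <- rnorm(40); yh <- rnorm(40)
    expect_equal(rmse_value(y, yh), sqrt(sum((y - yh)^2) / 40), tolerance = 1e-12)
  })
  expect_error(rmse_value(1:3, 1:4), "equal length")
})
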