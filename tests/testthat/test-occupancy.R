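mk_wide_profiles <- function(X, chrom = "chrI") {
  feats <- colnames(X)
  dplyr::bind_rows(lapply(feats, function(f) {
    tibble::tibble(chrom = chrom, feature = f,
                   pos = 50 + (seq_len(nrow(X)) - 1) * 10,
                   value = X[, f])
  }))
}

test_that("track alignment intersects bins and fixes the feature order", {
  withr::local_seed(1)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, c("b", "a", "c")))
  p <- mk_wide_profiles(X)
  w <- align_tracks(p)
  expect_equal(names(w), c("chrom", "pos", "a", "b", "c"))
  expect_equal(nrow(w), 20)
  # missing leading bins in one profile drop those bins everywhere
  p2 <- p[!(p$feature == "a" & p$pos < 100), ]
  expect_equal(nrow(align_tracks(p2)), 15)
  # shuffled input order yields the identical matrix
  w2 <- align_tracks(p[sample(nrow(p)), ])
  expect_equal(w2, w)
  occ <- tibble::tibble(chrom = "chrI", pos = w$pos, value = 1)
  expect_equal(names(align_tracks(p, occ))[6], "occupancy")
  expect_error(align_tracks(p, tibble::tibble(chrom = "chrX", pos = 1,
                                              value = 1)), "shared")
})

test_that("LARS recovers an exact sparse combination and matches OLS on the support", {
  withr::local_seed(31)
  n <- 300
  X <- matrix(rnorm(n * 12), n, 12,
              dimnames = list(NULL, sprintf("f%02d", 1:12)))
  beta_true <- setNames(rep(0, 12), colnames(X))
  beta_true[c("f03", "f07", "f11")] <- c(2, -1.5, 0.8)
  y <- drop(X %*% beta_true) + 5
  p <- mk_wide_profiles(X)
  occ <- tibble::tibble(chrom = "chrI", pos = 50 + (seq_len(n) - 1) * 10,
                        value = y)
  fit <- fit_occupancy(p, occ)
  expect_setequal(fit$entry_order[1:3], c("f03", "f07", "f11"))
  expect_equal(unname(fit$coefficients[c("f03", "f07", "f11")]),
               c(2, -1.5, 0.8), tolerance = 1e-6)
  expect_lt(max(abs(fit$coefficients[setdiff(names(beta_true),
                                             c("f03", "f07", "f11"))])),
            1e-6)
  # OLS on the true support agrees
  ols <- lm(y ~ X[, c("f03", "f07", "f11")])
  expect_equal(unname(fit$intercept), unname(coef(ols)[1]), tolerance = 1e-6)
})

test_that("pure-noise response selects (almost) nothing", {
  withr::local_seed(55)
  X <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  y <- rnorm(200)
  fit <- fit_occupancy(mk_wide_profiles(X),
                       tibble::tibble(chrom = "chrI",
                                      pos = 50 + (0:199) * 10, value = y))
  expect_lt(fit$r_squared, 0.06)
})

test_that("a single feature reduces to the simple regression slope", {
  withr::local_seed(2)
  x <- rnorm(100)
  y <- 3 * x + rnorm(100, 0, 0.1)
  X <- matrix(x, dimnames = list(NULL, "only"))
  fit <- fit_occupancy(mk_wide_profiles(X),
                       tibble::tibble(chrom = "chrI", pos = 50 + (0:99) * 10,
                                      value = y), stop = "full")
  expect_equal(unname(fit$coefficients["only"]),
               unname(coef(lm(y ~ x))[2]), tolerance = 1e-8)
})

test_that("active features share the same absolute correlation along the path", {
  withr::local_seed(9)
  n <- 150
  X <- matrix(rnorm(n * 5), n, 5, dimnames = list(NULL, paste0("f", 1:5)))
  y <- X[, 1] - 0.5 * X[, 3] + rnorm(n, 0, 0.5)
  Xs <- scale(X)
  fit <- nucstruct:::lars_path(X, y)
  yc <- y - mean(y)
  for (k in 2:nrow(fit$beta)) {
    resid <- yc - Xs %*% fit$beta[k, ]
    cors <- abs(drop(crossprod(Xs, resid)))
    active <- match(fit$entry_order[seq_len(k - 1)], colnames(X))
    if (k <= nrow(fit$beta) - 0 && length(active) > 1) {
      expect_lt(diff(range(cors[active])), 1e-8 * max(1, max(cors)))
    }
  }
})

test_that("constant features are dropped with a warning; duplicates end the path early", {
  withr::local_seed(12)
  X <- cbind(a = rnorm(50), b = rep(1, 50), c = rnorm(50))
  y <- X[, "a"] + rnorm(50, 0, 0.1)
  p <- mk_wide_profiles(X)
  occ <- tibble::tibble(chrom = "chrI", pos = 50 + (0:49) * 10, value = y)
  expect_warning(fit <- fit_occupancy(p, occ), "constant")
  expect_equal(unname(fit$coefficients["b"]), 0)
  X2 <- cbind(a = rnorm(60), dup = 0, c = rnorm(60))
  X2[, "dup"] <- X2[, "a"]
  y2 <- X2[, "a"] + rnorm(60, 0, 0.1)
  expect_warning(
    fit2 <- fit_occupancy(mk_wide_profiles(X2),
                          tibble::tibble(chrom = "chrI",
                                         pos = 50 + (0:59) * 10, value = y2)),
    "rank deficient")
  expect_lte(sum(fit2$coefficients != 0), 2)
})

test_that("prediction is affine, masks propagate, and fitting never sees test chromosomes", {
  withr::local_seed(21)
  X <- matrix(rnorm(80 * 3), 80, 3, dimnames = list(NULL, paste0("f", 1:3)))
  y <- X[, 1] + rnorm(80, 0, 0.05)
  pA <- mk_wide_profiles(X[1:40, , drop = FALSE], chrom = "chrA")
  pB <- mk_wide_profiles(X[41:80, , drop = FALSE], chrom = "chrB")
  occA <- tibble::tibble(chrom = "chrA", pos = 50 + (0:39) * 10, value = y[1:40])
  occB_good <- tibble::tibble(chrom = "chrB", pos = 50 + (0:39) * 10,
                              value = y[41:80])
  occB_junk <- dplyr::mutate(occB_good, value = rnorm(40, 100, 50))
  f1 <- fit_occupancy(dplyr::bind_rows(pA, pB),
                      dplyr::bind_rows(occA, occB_good), train_chroms = "chrA")
  f2 <- fit_occupancy(dplyr::bind_rows(pA, pB),
                      dplyr::bind_rows(occA, occB_junk), train_chroms = "chrA")
  expect_equal(f1$coefficients, f2$coefficients)
  expect_equal(f1$intercept, f2$intercept)
  # zero-coefficient model predicts the constant intercept
  f0 <- f1
  f0$coefficients[] <- 0
  pred0 <- predict_occupancy(f0, pB)
  expect_true(all(pred0$value == f0$intercept))
  # masked input bins are masked in the prediction
  pB_na <- pB
  pB_na$value[pB_na$feature == "f1" & pB_na$pos == 50] <- NA
  predna <- predict_occupancy(f1, pB_na)
  expect_true(is.na(predna$value[predna$pos == 50]))
})

test_that("held-out prediction is near-perfect without noise and attenuates as expected with noise", {
  withr::local_seed(77)
  n <- 400
  X <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("f", 1:4)))
  chrom <- rep(c("tr", "te"), each = n / 2)
  yhat <- drop(X %*% c(1, -2, 0.5, 0))
  p <- dplyr::bind_rows(
    mk_wide_profiles(X[chrom == "tr", ], chrom = "tr"),
    mk_wide_profiles(X[chrom == "te", ], chrom = "te"))
  pos <- 50 + (seq_len(n / 2) - 1) * 10
  mk_occ <- function(vals) tibble::tibble(
    chrom = rep(c("tr", "te"), each = n / 2), pos = rep(pos, 2), value = vals)
  # noiseless: held-out r >= 0.99
  fit <- fit_occupancy(p, mk_occ(yhat), train_chroms = "tr")
  pred <- predict_occupancy(fit, p[p$chrom == "te", ])
  r_clean <- cor(pred$value, yhat[chrom == "te"])
  expect_gte(r_clean, 0.99)
  # noise at sigma = sd(yhat): r should fall to about r_clean / sqrt(2)
  sigma <- sd(yhat)
  y_noisy <- yhat + rnorm(n, 0, sigma)
  fitn <- fit_occupancy(p, mk_occ(y_noisy), train_chroms = "tr")
  predn <- predict_occupancy(fitn, p[p$chrom == "te", ])
  r_noisy <- cor(predn$value, y_noisy[chrom == "te"])
  expect_equal(r_noisy, r_clean / sqrt(2), tolerance = 0.12)
})

test_that("tidy and glance summarise the fitted occupancy model", {
  withr::local_seed(4)
  X <- matrix(rnorm(200), 50, 4, dimnames = list(NULL, paste0("f", 1:4)))
  y <- X[, 2] + rnorm(50, 0, 0.1)
  fit <- fit_occupancy(mk_wide_profiles(X),
                       tibble::tibble(chrom = "chrI", pos = 50 + (0:49) * 10,
                                      value = y))
  td <- tidy(fit)
  expect_equal(td$term[1], "(Intercept)")
  expect_equal(nrow(td), 5)
  gl <- glance(fit)
  expect_equal(gl$n, 50)
  expect_gte(gl$r_squared, 0.9)
})
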