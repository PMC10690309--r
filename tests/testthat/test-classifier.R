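test_that("gaussian moment fit: closed forms, Monte-Carlo, degenerate input", {
  f <- fit_gaussian(c(1, 3), "two")
  expect_equal(f$mean, 2)
  expect_equal(f$sd, sqrt(2))
  expect_equal(f$n, 2L)

  set.seed(123)
  f2 <- fit_gaussian(rnorm(1e5, 5, 0.8))
  expect_lt(abs(f2$mean - 5), 0.01)
  expect_lt(abs(f2$sd - 0.8), 0.01)

  expect_error(fit_gaussian(c(2, 2, 2)), "zero variance")
  expect_error(fit_gaussian(3), "at least 2")
  expect_error(fit_gaussian(c(1, NA, Inf)), "at least 2")
})

test_that("equal-variance crossing is the midpoint of the means", {
  expect_equal(intersection_threshold(gm(1, 0.5), gm(3, 0.5)), 2)
  expect_equal(intersection_threshold(gm(0, 1), gm(4, 1)), 2)
  expect_equal(intersection_threshold(gm(4, 1), gm(0, 1)), 2)  # symmetric
  expect_error(intersection_threshold(gm(2, 1), gm(2, 1)), "identical")
  expect_error(intersection_threshold(gm(2, 1), gm(2, 3)), "equal means")
})

test_that("unequal-variance crossing matches dense numeric root-finding", {
  cases <- list(c(0, 1, 2, 2), c(1, 0.3, 3, 0.8), c(-2, 2, 5, 0.5),
                c(0.5, 0.2, 0.9, 0.35))
  for (cs in cases) {
    a <- gm(cs[1], cs[2]); b <- gm(cs[3], cs[4])
    thr <- intersection_threshold(a, b)
    # oracle: sign change of the density difference on a fine bracket
    f <- function(x) dnorm(x, a$mean, a$sd) - dnorm(x, b$mean, b$sd)
    root <- uniroot(f, lower = min(a$mean, b$mean) + 1e-9,
                    upper = max(a$mean, b$mean) - 1e-9, tol = 1e-14)$root
    expect_equal(thr, root, tolerance = 1e-7)
    # density equality at the returned threshold
    expect_lt(abs(f(thr)), 1e-10)
    expect_gt(thr, min(a$mean, b$mean))
    expect_lt(thr, max(a$mean, b$mean))
  }
})

test_that("population balanced accuracy peaks at the crossing threshold", {
  a <- gm(1.8, 0.4); b <- gm(3.1, 0.7)
  thr <- intersection_threshold(a, b)
  ba <- function(t) (pnorm(t, a$mean, a$sd) + 1 - pnorm(t, b$mean, b$sd)) / 2
  sweep <- seq(a$mean, b$mean, length.out = 2001)
  expect_gte(ba(thr), max(ba(sweep)) - 1e-8)
})

test_that("the fitted classifier exposes the standard modelling surface", {
  set.seed(5)
  d <- data.frame(mu = c(rnorm(200, 2.2, 0.3), rnorm(200, 8, 0.5)),
                  label = rep(c("cortex", "tumor"), each = 200))
  fit <- atten_classifier(mu ~ label, d, positive = "tumor")

  cf <- coef(fit)
  expect_lt(abs(cf[["cortex.mean"]] - 2.2), 0.1)
  expect_true(cf[["threshold"]] > 2.2 && cf[["threshold"]] < 8)
  expect_output(print(fit), "threshold")
  s <- summary(fit)
  expect_equal(s$training_auc, 1)

  res <- residuals(fit)
  expect_equal(length(res), 400)
  expect_lt(abs(mean(res)), 0.05)

  sim <- simulate(fit, nsim = 50, seed = 1)
  expect_equal(nrow(sim), 100)
  expect_setequal(unique(sim$label), c("cortex", "tumor"))

  path <- withr::local_tempfile(fileext = ".png")
  grDevices::png(path); plot(fit); grDevices::dev.off()
  expect_true(file.exists(path))
})

test_that("threshold classification: sides, exact-tie rule, abstention", {
  d <- data.frame(mu = c(1, 1.2, 0.8, 3, 3.2, 2.8),
                  label = rep(c("rest_cls", "tumor"), each = 3))
  fit <- atten_classifier(mu ~ label, d, positive = "tumor")
  fit$threshold <- 2; fit$positive_high <- TRUE   # pin for the contract check
  calls <- predict(fit, c(2.5, 2.0, 1.1, NA))
  expect_equal(calls[1], "tumor")
  expect_equal(calls[2], "tumor")   # exactly at threshold -> higher-mean class
  expect_equal(calls[3], "rest")
  expect_true(is.na(calls[4]))      # abstain, reported not dropped
  expect_equal(attr(calls, "n_abstain"), 1L)
})

test_that("multi-class likelihood rule picks the nearest class in sd units", {
  set.seed(8)
  d <- data.frame(mu = c(rnorm(100, 1.5, 0.2), rnorm(100, 3, 0.2),
                         rnorm(100, 8, 0.4)),
                  label = rep(c("medulla", "calyx", "tumor"), each = 100))
  fit <- atten_classifier(mu ~ label, d)
  calls <- predict(fit, c(1.4, 3.1, 7.5))
  expect_equal(calls[1:3], c("medulla", "calyx", "tumor"))
})

test_that("ROC endpoints, monotonicity and the trivial AUC values", {
  r <- roc_auc(c(5, 6, 7), c(1, 2, 3))
  expect_equal(r$auc, 1)
  expect_equal(c(r$fpr[1], r$tpr[1]), c(0, 0))
  expect_equal(c(r$fpr[length(r$fpr)], r$tpr[length(r$tpr)]), c(1, 1))
  expect_true(all(diff(r$tpr) >= 0) && all(diff(r$fpr) >= 0))

  x <- c(1, 2, 2, 3, 4)
  expect_equal(roc_auc(x, x)$auc, 0.5)   # exchangeable, ties counted 1/2
  expect_error(roc_auc(numeric(0), 1:3), "nonempty")
})

test_that("empirical AUC matches the binormal closed form and pROC", {
  set.seed(99)
  pos <- rnorm(1e4, 5, 1); neg <- rnorm(1e4, 3, 1)
  r <- roc_auc(pos, neg)
  expect_lt(abs(r$auc - pnorm(2 / sqrt(2))), 0.01)
  # independent implementation cross-check
  expect_equal(r$auc,
               as.numeric(pROC::auc(pROC::roc(
                 response = rep(c(1, 0), each = 1e4),
                 predictor = c(pos, neg), quiet = TRUE, direction = "<"))),
               tolerance = 1e-12)
})

test_that("binormal agreement across a (delta, sd1, sd2) grid, 3 MC SEs", {
  grid <- expand.grid(delta = c(0.5, 1.5, 3), s1 = c(0.5, 1), s2 = c(1, 2))
  set.seed(17)
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    reps <- vapply(1:20, function(k)
      roc_auc(rnorm(800, g$delta, g$s1), rnorm(800, 0, g$s2))$auc, numeric(1))
    truth <- pnorm(g$delta / sqrt(g$s1^2 + g$s2^2))
    se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - truth), 3 * se + 1e-4)
  }
})

test_that("AUC never decreases when the mean separation grows, matched seeds", {
  aucs <- vapply(c(0.5, 1, 2, 3, 5), function(delta) {
    set.seed(31)  # matched draws across separations
    roc_auc(rnorm(500, delta, 1), rnorm(500, 0, 1))$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= 0))
})

test_that("balanced pooling draws equal counts per normal class per subject", {
  mt <- synthetic_mu_table(c("K1", "K2", "K3"),
                           list(tumor = 8, cortex = 2.5, medulla = 1.5,
                                calyx = 3, fat = 2),
                           n_per = 10)
  pool <- one_vs_rest_pool(mt, "tumor", per_class_subsample = 5, seed = 2)
  expect_equal(length(pool$negatives), 5 * 4 * 3)  # subsample x classes x subjects
  expect_equal(length(pool$positives), 30)
  pool2 <- one_vs_rest_pool(mt, "tumor", per_class_subsample = 5, seed = 2)
  expect_identical(pool, pool2)
  expect_error(one_vs_rest_pool(mt, "tumor", 0), ">= 1")
  expect_error(one_vs_rest_pool(mt, "tumor", 11), "insufficient")
})
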