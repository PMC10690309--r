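test_that("confusion matrix counting, abstentions and label checks", {
  cm <- confusion_from_calls(c("t", "t", "c"), c("t", "c", "c"),
                             labels = c("t", "c"))
  expect_equal(unclass(cm)[, ],
               matrix(c(1L, 0L, 1L, 1L), 2,
                      dimnames = list(truth = c("t", "c"),
                                      predicted = c("t", "c")))[, ])

  cm2 <- confusion_from_calls(c("a", "b"), c("a", "b"))
  expect_equal(diag(unclass(cm2)), c(a = 1L, b = 1L))

  cm3 <- confusion_from_calls(c("a", "b", "a"), c("a", NA, "b"))
  expect_equal(attr(cm3, "abstain"), c(0L, 1L))

  expect_error(confusion_from_calls(character(0), character(0)), "empty")
  expect_error(confusion_from_calls("a", "z", labels = "a"), "unknown label")
})

test_that("one-vs-rest counts reproduce the published tumor and pelvis cells", {
  t1 <- oct_table_fixture("table1a")
  bc <- one_vs_rest(t1, "tumor")
  expect_equal(unclass(bc)[c("tp", "fn", "fp", "tn")],
               list(tp = 9983L, fn = 17L, fp = 886L, tn = 39114L))

  t2a <- oct_table_fixture("table2a")
  bp <- one_vs_rest(t2a, "pelvis")
  expect_equal(unclass(bp)[c("tp", "fn", "fp", "tn")],
               list(tp = 9969L, fn = 31L, fp = 2L, tn = 49998L))

  d <- as_confusion_matrix(matrix(c(5, 0, 0, 5), 2,
                                  dimnames = list(c("x", "y"), c("x", "y"))))
  expect_equal(unclass(one_vs_rest(d, "x"))[c("tp", "fp", "fn", "tn")],
               list(tp = 5L, fp = 0L, fn = 0L, tn = 5L))
})

test_that("count conservation: one-vs-rest sums and trace identity", {
  for (nm in c("table1a", "table2a", "table2b")) {
    cm <- oct_table_fixture(nm)
    m <- unclass(cm)
    expect_true(all(rowSums(m) == 10000))
    tps <- 0
    for (cl in rownames(m)) {
      bc <- one_vs_rest(cm, cl)
      expect_equal(bc$tp + bc$fp + bc$tn + bc$fn, sum(m))
      tps <- tps + bc$tp
    }
    expect_equal(tps, sum(diag(m)))
  }
})

test_that("metric formulas on the published binary counts", {
  met <- binary_metrics(list(tp = 9983L, fp = 886L, fn = 17L, tn = 39114L))
  expect_equal(unname(met["accuracy"]), 49097 / 50000)
  expect_equal(unname(met["precision"]), 9983 / 10869)
  expect_equal(unname(met["recall"]), 9983 / 10000)
  expect_equal(unname(met["f1"]), 19966 / 20869)

  met2 <- binary_metrics(list(tp = 1947L, fp = 2562L, fn = 8053L, tn = 37438L))
  expect_equal(unname(met2["accuracy"]), 39385 / 50000)
  expect_equal(unname(met2["recall"]), 1947 / 10000)

  und <- binary_metrics(list(tp = 0L, fp = 0L, fn = 3L, tn = 7L))
  expect_true(is.na(und["precision"]))   # undefined, not 0
  expect_equal(unname(und["recall"]), 0)
  expect_error(binary_metrics(list(tp = 0L, fp = 0L, fn = 0L, tn = 0L)),
               "all-zero")
})

test_that("every published per-class metric reproduces at printed precision", {
  chk <- reproduce_printed_metrics()
  expect_equal(nrow(chk), 21)
  expect_true(all(chk$match))
  expect_lt(max(abs(chk$diff)), 0.005 + 1e-9)
})

test_that("the CNN matrices yield the published headline accuracies", {
  r2a <- metrics_report(oct_table_fixture("table2a"))
  expect_equal(r2a$accuracy[r2a$class == "tumor"], 59708 / 60000)
  r2b <- metrics_report(oct_table_fixture("table2b"))
  expect_equal(r2b$accuracy[r2b$class == "tumor"], 59687 / 60000)
  m <- unclass(oct_table_fixture("table2a"))
  expect_equal(m["calyx", "tumor"] / sum(m["calyx", ]), 0.0148)
})

test_that("split plan rotates every subject through every role correctly", {
  plan <- make_split_plan(paste0("K", 1:5))
  expect_equal(nrow(plan), 20)                      # 5 test x 4 validation
  expect_equal(sort(unique(plan$test)), paste0("K", 1:5))
  expect_true(all(table(plan$test) == 4))
  for (i in seq_len(nrow(plan))) {
    roles <- c(plan$test[i], plan$validation[i], plan$train[[i]])
    expect_equal(sort(roles), paste0("K", 1:5))     # partition, no overlap
    expect_equal(length(roles), length(unique(roles)))
    expect_equal(length(plan$train[[i]]), 3)
  }
  plan3 <- make_split_plan(c("a", "b", "c"))
  expect_equal(nrow(plan3), 6)                      # 3 test x 2 rotations
  expect_error(make_split_plan(c("a", "b")), "at least 3")
  # seeded plans cover the same folds in a permuted order
  p1 <- make_split_plan(paste0("K", 1:5), seed = 4)
  expect_identical(p1, make_split_plan(paste0("K", 1:5), seed = 4))
  expect_setequal(paste(p1$test, p1$validation),
                  paste(plan$test, plan$validation))
})

test_that("cross-testing trains per fold and recalls well-separated tumor", {
  mt <- synthetic_mu_table(paste0("K", 1:5),
                           list(tumor = 8, cortex = 2.5, medulla = 1.5,
                                calyx = 3, fat = 2),
                           n_per = 20, sd = 0.3, seed = 3)
  plan <- make_split_plan(paste0("K", 1:5))
  ct <- cross_test_attenuation(mt, plan, positive = "tumor")
  bm <- binary_metrics(one_vs_rest(ct$pooled, "tumor"))
  expect_gte(bm[["recall"]], 0.99)
  expect_equal(sum(unclass(ct$pooled)), nrow(mt))
  expect_equal(length(ct$per_fold), 5)
})

test_that("cross-testing errors when a training fold lacks a class", {
  mt <- synthetic_mu_table(paste0("K", 1:3),
                           list(tumor = 8, cortex = 2.5), n_per = 6)
  mt <- mt[!(mt$label == "tumor" & mt$subject_id != "K1"), ]  # tumor only in K1
  plan <- make_split_plan(paste0("K", 1:3))
  expect_error(cross_test_attenuation(mt, plan, positive = "tumor"),
               "missing from training")
  expect_error(cross_test_attenuation(mt[mt$subject_id != "K3", ], plan),
               "subjects in plan but not in table")
})

test_that("classes with identical generative mu are exchangeable: accuracy ~ 0.5", {
  mt <- synthetic_mu_table(paste0("K", 1:4), list(a = 3, b = 3), n_per = 50,
                           sd = 0.4, seed = 9)
  plan <- make_split_plan(paste0("K", 1:4))
  ct <- cross_test_attenuation(mt, plan)
  acc <- sum(diag(unclass(ct$pooled))) / sum(unclass(ct$pooled))
  expect_lt(abs(acc - 0.5), 0.05)
})

test_that("pelvis-style abstentions are tallied, not dropped", {
  mt <- synthetic_mu_table(paste0("K", 1:3),
                           list(tumor = 8, cortex = 2.5), n_per = 10)
  pel <- data.frame(scan_id = sprintf("K%d_pelvis_%d", rep(1:3, each = 4), 1:4),
                    subject_id = rep(paste0("K", 1:3), each = 4),
                    label = "pelvis", mu = NA_real_,
                    n_valid_columns = 0L, valid = FALSE)
  mt <- rbind(mt, pel)
  plan <- make_split_plan(paste0("K", 1:3))
  ct <- cross_test_attenuation(mt, plan, positive = "tumor")
  expect_equal(unname(ct$abstentions["pelvis"]), 12L)
  expect_equal(sum(unclass(ct$pooled)), 60)  # pelvis rows stay out of the matrix
})
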