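test_that("AUC equals Mann-Whitney pair counting", {
  expect_equal(roc_auc(c(.9, .8, .3, .2), c(1, 1, 0, 0)), 1)
  expect_equal(roc_auc(rep(0.4, 10), rep(c(0, 1), 5)), 0.5)
  # 8-patient hand set with a tie across classes
  s <- c(0.9, 0.7, 0.5, 0.5, 0.5, 0.4, 0.2, 0.1)
  l <- c(1, 1, 1, 0, 0, 0, 0, 1)
  expect_equal(roc_auc(s, l), auc_pair_counting(s, l))
  # fuzz against the brute-force oracle
  set.seed(50)
  for (rep in 1:200) {
    n <- sample(4:12, 1)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(roc_auc(s, l), auc_pair_counting(s, l))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "single class")
})

test_that("AUC respects complement symmetry and monotone invariance", {
  set.seed(51)
  for (rep in 1:20) {
    n <- sample(10:40, 1)
    l <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    s <- rnorm(n)
    expect_equal(roc_auc(s, l) + roc_auc(-s, l), 1)
    expect_equal(roc_auc(plogis(3 * s + 2), l), roc_auc(s, l))
    expect_equal(roc_auc(exp(s), l), roc_auc(s, l))
  }
})

test_that("AUC agrees with pROC", {
  skip_if_not_installed("pROC")
  set.seed(52)
  s <- runif(60)
  l <- rbinom(60, 1, 0.35)
  expect_equal(roc_auc(s, l),
               as.numeric(pROC::auc(pROC::roc(l, s, quiet = TRUE,
                                              direction = "<"))))
})

test_that("BCa intervals are deterministic, bracketing and reduce to
           percentile in the symmetric case", {
  set.seed(53)
  n <- 62
  l <- rep(c(1, 0), c(11, 51))
  s <- c(rnorm(11, 1.2), rnorm(51))
  ci1 <- bca_ci(s, l, n_boot = 1000, seed = 99)
  ci2 <- bca_ci(s, l, n_boot = 1000, seed = 99)
  expect_identical(ci1[c("ci_low", "ci_high")], ci2[c("ci_low", "ci_high")])
  expect_false(ci1$degenerate)
  expect_lte(ci1$ci_low, ci1$auc)
  expect_gte(ci1$ci_high, ci1$auc)
  expect_gte(ci1$ci_low, 0)
  expect_lte(ci1$ci_high, 1)

  # zero bias-correction and acceleration degenerate to pure percentile
  boot <- rnorm(2000, 0.8, 0.05)
  expect_equal(hemopred:::.bca_endpoints(boot, z0 = 0, a = 0),
               unname(quantile(boot, c(0.025, 0.975))))
})

test_that("single-class bootstrap replicates are redrawn and counted", {
  set.seed(54)
  l <- rep(c(1, 0), c(2, 10))  # replicates frequently lose both cases
  s <- c(0.9, 0.8, runif(10, 0, 0.7))
  ci <- bca_ci(s, l, n_boot = 500, seed = 7)
  expect_gt(ci$n_redrawn, 0)
  expect_true(is.finite(ci$ci_low) && is.finite(ci$ci_high))
})

test_that("DeLong variance matches enumeration of placement values", {
  set.seed(55)
  for (rep in 1:10) {
    n <- sample(8:12, 1)
    l <- c(0, 0, 1, 1, sample(0:1, n - 4, replace = TRUE))
    s <- round(runif(n), 2)
    # direct enumeration of the structural components
    cases <- s[l == 1]
    ctrls <- s[l == 0]
    n1 <- length(cases)
    n0 <- length(ctrls)
    v10 <- sapply(cases, function(a) {
      mean((a > ctrls) + 0.5 * (a == ctrls))
    })
    v01 <- sapply(ctrls, function(b) {
      mean((cases > b) + 0.5 * (cases == b))
    })
    expect_equal(delong_auc_variance(s, l),
                 var(v10) / n1 + var(v01) / n0)
  }
})

test_that("DeLong test agrees with pROC and is degenerate on itself", {
  skip_if_not_installed("pROC")
  set.seed(56)
  n <- 50
  l <- rbinom(n, 1, 0.4)
  l[1:2] <- c(0, 1)
  sa <- rnorm(n) + l
  sb <- rnorm(n) + 0.5 * l
  dt <- delong_test(sa, sb, l)
  ref <- pROC::roc.test(pROC::roc(l, sa, quiet = TRUE, direction = "<"),
                        pROC::roc(l, sb, quiet = TRUE, direction = "<"),
                        method = "delong", paired = TRUE)
  expect_equal(dt$p_value, as.numeric(ref$p.value), tolerance = 1e-8)
  expect_equal(dt$auc_a, roc_auc(sa, l))

  self <- delong_test(sa, sa, l)
  expect_true(self$degenerate)
  expect_equal(self$p_value, 1)
  expect_equal(self$delta, 0)
})

test_that("inclusion frequency summarizes significant high performers", {
  set.seed(57)
  n <- 120
  x <- cbind(strong = rnorm(n, 5), noise1 = rnorm(n, 3), noise2 = rexp(n))
  rownames(x) <- sprintf("p%03d", 1:n)
  y <- rbinom(n, 1, plogis(-3 + 2.5 * (x[, "strong"] - 5)))
  task <- run_task(x, y)
  freq <- inclusion_frequency(task, auc_threshold = 0.7)
  expect_identical(freq$feature[1], "strong")
  expect_gt(freq$n_high_performers[1], 0)
  # positive-effect feature: bar is monotone with OR > 1 throughout
  expect_equal(freq$frac_or_gt_1[1], 1)
  expect_equal(freq$frac_or_lt_1[1], 0)
  ok <- freq$n_high_performers > 0
  expect_equal(freq$frac_or_gt_1[ok] + freq$frac_or_lt_1[ok],
               rep(1, sum(ok)))
  # impossible threshold yields an empty table with a warning
  expect_warning(empty <- inclusion_frequency(task, auc_threshold = 1.01),
                 "no classifier")
  expect_equal(nrow(empty), 0L)
})

test_that("pairwise task comparison is complete and validated", {
  set.seed(58)
  n <- 40
  ids <- sprintf("p%02d", 1:n)
  l <- setNames(rbinom(n, 1, 0.4), ids)
  l[1:2] <- c(0, 1)
  sc <- list(t1 = setNames(rnorm(n) + l, ids),
             t2 = setNames(rnorm(n) + 0.5 * l, ids),
             t3 = setNames(rnorm(n), ids))
  cmp <- compare_tasks(sc, l)
  expect_equal(nrow(cmp), 3L)  # C(3, 2)
  # comparing a task with itself gives P = 1
  cmp_self <- compare_tasks(list(a = sc$t1, b = sc$t1), l)
  expect_equal(cmp_self$p_value, 1)
  # scrambled patient names still align by id
  sc2 <- sc
  sc2$t2 <- sc2$t2[rev(ids)]
  expect_equal(compare_tasks(sc2, l)$p_value, cmp$p_value)
  # mismatched patient sets are an error
  sc_bad <- sc
  names(sc_bad$t3)[1] <- "zz"
  expect_error(compare_tasks(sc_bad, l), "different patient set")
})
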