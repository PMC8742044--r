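# Confusion counts, SE/SP/ACC, ROC/AUC and model comparison.

test_that("confusion counts match hand enumeration and a brute-force tally", {
  cc <- confusion(c(1, 1, 0, 0), c(1, 0, 0, 1))
  expect_identical(cc[c("TP", "FN", "TN", "FP")],
                   list(TP = 1L, FN = 1L, TN = 1L, FP = 1L))
  ident <- confusion(c(1, 0, 1), c(1, 0, 1))
  expect_identical(ident$FP + ident$FN, 0L)

  set.seed(10)
  y <- rbinom(1000, 1, 0.4)
  p <- rbinom(1000, 1, 0.5)
  cc <- confusion(y, p)
  # independent per-element tally oracle
  tally <- c(TP = 0L, FP = 0L, TN = 0L, FN = 0L)
  for (i in seq_along(y)) {
    k <- if (y[i] == 1 && p[i] == 1) "TP" else if (y[i] == 0 && p[i] == 1) "FP"
         else if (y[i] == 0 && p[i] == 0) "TN" else "FN"
    tally[k] <- tally[k] + 1L
  }
  expect_identical(unlist(cc[names(tally)]), tally)
  expect_identical(cc$TP + cc$FP + cc$TN + cc$FN, 1000L)

  expect_error(confusion(c(1, 0), c(1, 0, 1)), "length")
  expect_error(confusion(c(1, 2), c(1, 0)), "binary")
})

test_that("SE/SP/ACC evaluate their defining formulas exactly", {
  mk <- function(tp, fp, tn, fn)
    structure(list(TP = tp, FP = fp, TN = tn, FN = fn),
              class = "confusion_counts")
  expect_identical(classification_metrics(mk(5, 2, 3, 0))[["se"]], 1)
  expect_identical(classification_metrics(mk(1, 1, 1, 1))[["acc"]], 0.5)
  set.seed(11)
  for (i in 1:25) {
    v <- rpois(4, 10) + 1
    m <- classification_metrics(mk(v[1], v[2], v[3], v[4]))
    expect_identical(m[["se"]], v[1] / (v[1] + v[4]))
    expect_identical(m[["sp"]], v[3] / (v[3] + v[2]))
    expect_identical(m[["acc"]], (v[1] + v[3]) / sum(v))
    # ACC = (SE*P + SP*N) / (P + N)
    P <- v[1] + v[4]; N <- v[2] + v[3]
    expect_equal(m[["acc"]], (m[["se"]] * P + m[["sp"]] * N) / (P + N),
                 tolerance = 1e-12)
  }
  expect_warning(m0 <- classification_metrics(mk(0, 1, 1, 0)), "SE undefined")
  expect_true(is.na(m0[["se"]]))
  expect_error(classification_metrics(mk(0, 0, 0, 0)), "all counts are zero")
})

test_that("ROC endpoints, monotonicity and degenerate cases", {
  r <- roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))
  expect_identical(r$auc, 1)
  r_tie <- roc_auc(rep(0.5, 10), rep(c(0, 1), 5))
  expect_identical(r_tie$auc, 0.5)
  set.seed(12)
  r3 <- roc_auc(runif(40), rbinom(40, 1, 0.5))
  expect_identical(r3$roc$fpr[1], 0)
  expect_identical(r3$roc$tpr[1], 0)
  expect_identical(utils::tail(r3$roc$fpr, 1), 1)
  expect_identical(utils::tail(r3$roc$tpr, 1), 1)
  expect_true(all(diff(r3$roc$fpr) >= 0))
  expect_true(all(diff(r3$roc$tpr) >= 0))
  expect_error(roc_auc(runif(5), rep(1, 5)), "one category")
})

test_that("trapezoidal AUC equals the rank-statistic pair oracle", {
  pair_auc <- function(s, y) {
    pos <- s[y == 1]; neg <- s[y == 0]
    tot <- 0
    for (a in pos) for (b in neg)
      tot <- tot + (a > b) + 0.5 * (a == b)
    tot / (length(pos) * length(neg))
  }
  set.seed(13)
  for (i in 1:5) {
    y <- c(0, 1, rbinom(48, 1, 0.5))
    s <- round(runif(50), 2)   # rounding forces ties
    r <- roc_auc(s, y)
    expect_equal(r$auc, pair_auc(s, y), tolerance = 1e-12)
    # AUC is invariant under strictly increasing transforms
    expect_equal(roc_auc(exp(3 * s), y)$auc, r$auc, tolerance = 1e-12)
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  set.seed(14)
  y <- c(0, 1, rbinom(60, 1, 0.5))
  s <- runif(62)
  r <- roc_auc(s, y)
  ref <- as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE,
                                        direction = "<")))
  expect_equal(r$auc, ref, tolerance = 1e-10)
})

test_that("metrics reports are internally consistent", {
  set.seed(15)
  y <- c(0, 1, rbinom(30, 1, 0.5))
  s <- runif(32)
  rep <- metrics_report(s, y, threshold = 0.5)
  cc <- rep$counts
  expect_identical(cc$TP + cc$FN, sum(y == 1))
  expect_identical(cc$TN + cc$FP, sum(y == 0))
  expect_equal(rep$se + cc$FN / (cc$TP + cc$FN), 1, tolerance = 1e-12)
  expect_equal(rep$sp + cc$FP / (cc$TN + cc$FP), 1, tolerance = 1e-12)
  p <- tempfile(fileext = ".csv")
  write_metrics_report(rep, p)
  back <- utils::read.csv(p)
  expect_equal(back$value[back$metric == "AUC"], rep$auc, tolerance = 1e-12)
})

test_that("model comparison aggregates folds and rejects mismatched plans", {
  mk_report <- function(acc) {
    set.seed(round(1000 * acc))
    y <- rep(c(0, 1), 10)
    s <- ifelse(y == 1, acc, 1 - acc) + runif(20, -0.05, 0.05)
    metrics_report(s, y)
  }
  mk_cv <- function(fp, accs) {
    reports <- lapply(accs, mk_report)
    vals <- sapply(reports, function(r) unlist(r[c("se", "sp", "acc", "auc")]))
    structure(list(fold_reports = reports, mean = rowMeans(vals),
                   sd = apply(vals, 1, sd), k = length(accs),
                   plan_fingerprint = fp), class = "cv_result")
  }
  a <- mk_cv("5/subject/1/100", c(0.7, 0.8, 0.9))
  b <- mk_cv("5/subject/1/100", c(0.6, 0.7, 0.8))
  tab <- compare_models(list(modelA = a, modelB = b))
  expect_identical(nrow(tab), 2L)
  expect_equal(tab$auc[1], mean(vapply(a$fold_reports, function(r) r$auc,
                                       numeric(1))), tolerance = 1e-12)
  expect_identical(nrow(compare_models(list(solo = a))), 1L)
  c_other <- mk_cv("5/subject/2/99", c(0.7, 0.8, 0.9))
  expect_error(compare_models(list(a = a, c = c_other)), "mismatch")
})
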