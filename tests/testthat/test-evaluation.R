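test_that("confusion metrics reproduce hand-worked values", {
  perfect <- confusion_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unname(perfect), rep(1, 6))

  m <- confusion_metrics(c(TP = 40, TN = 45, FP = 5, FN = 10))
  expect_equal(unname(m[c("sensitivity", "specificity", "accuracy")]),
               c(0.8, 0.9, 0.85))
  expect_equal(unname(m), unname(oracle_metrics(40, 45, 5, 10)))
  expect_error(confusion_metrics(c(TP = 0, TN = 0, FP = 0, FN = 0)), "zero")
})

test_that("confusion metrics agree with the scalar oracle on random matrices", {
  set.seed(31)
  for (i in 1:1000) {
    cts <- as.numeric(rmultinom(1, 200, runif(4, 0.01, 1)))
    got <- confusion_metrics(c(TP = cts[1], TN = cts[2], FP = cts[3], FN = cts[4]))
    expect_equal(as.numeric(got), as.numeric(oracle_metrics(cts[1], cts[2], cts[3], cts[4])))
  }
})

test_that("label swap exchanges sensitivity and specificity, preserving accuracy and |MCC|", {
  set.seed(5)
  for (i in 1:50) {
    cts <- as.numeric(rmultinom(1, 150, runif(4, 0.05, 1)))
    a <- confusion_metrics(c(TP = cts[1], TN = cts[2], FP = cts[3], FN = cts[4]))
    b <- confusion_metrics(c(TP = cts[2], TN = cts[1], FP = cts[4], FN = cts[3]))
    expect_equal(a[["sensitivity"]], b[["specificity"]])
    expect_equal(a[["specificity"]], b[["sensitivity"]])
    expect_equal(a[["accuracy"]], b[["accuracy"]])
    expect_equal(abs(a[["mcc"]]), abs(b[["mcc"]]))
  }
})

test_that("degenerate denominators report zero with a flag instead of crashing", {
  m <- confusion_metrics(c(TP = 0, TN = 10, FP = 0, FN = 0))
  expect_equal(unname(m[c("sensitivity", "precision", "f1", "mcc")]),
               c(0, 0, 0, 0))
  expect_true(all(c("sensitivity", "precision") %in% attr(m, "degenerate")))
  expect_equal(m[["accuracy"]], 1)
})

test_that("accuracy identity holds exactly", {
  set.seed(8)
  for (i in 1:50) {
    cts <- as.numeric(rmultinom(1, 99, runif(4, 0.05, 1)))
    m <- confusion_metrics(c(TP = cts[1], TN = cts[2], FP = cts[3], FN = cts[4]))
    expect_equal(m[["accuracy"]], 1 - (cts[3] + cts[4]) / sum(cts),
                 tolerance = 1e-15)
  }
})

test_that("ROC AUC matches the exhaustive pairwise oracle and handles ties", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$auc, 1)
  set.seed(12)
  for (i in 1:50) {
    n <- 30 + i
    scores <- round(runif(n), 2)       # rounding forces ties
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) next
    expect_equal(roc_auc(scores, labels)$auc, oracle_auc(scores, labels))
  }
  expect_error(roc_auc(runif(5), rep(1, 5)), "both classes")
})

test_that("AUC of label-independent scores concentrates near one half", {
  set.seed(99)
  n <- 4000
  scores <- runif(n)
  labels <- rbinom(n, 1, 0.5)
  n1 <- sum(labels); n0 <- n - n1
  se <- sqrt((n + 1) / (12 * n1 * n0))
  expect_lt(abs(roc_auc(scores, labels)$auc - 0.5), 3 * se)
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(21)
  scores <- runif(60); labels <- rbinom(60, 1, 0.5)
  a0 <- roc_auc(scores, labels)$auc
  expect_equal(roc_auc(qlogis(scores), labels)$auc, a0)
  expect_equal(roc_auc(scores^3, labels)$auc, a0)
})

test_that("AUC agrees with an established independent implementation", {
  skip_if_not_installed("pROC")
  set.seed(14)
  scores <- round(runif(200), 2)
  labels <- rbinom(200, 1, 0.3)
  ref <- as.numeric(suppressMessages(pROC::auc(labels, scores)))
  expect_equal(roc_auc(scores, labels)$auc, ref)
})

test_that("PR curve and step-rule area match the brute-force sweep", {
  expect_equal(pr_aupr(c(0.9, 0.8, 0.2, 0.1), c(1, 1, 0, 0))$aupr, 1)
  all_pos <- pr_aupr(runif(10), rep(1, 10))
  expect_true(all(all_pos$curve$precision == 1))
  expect_equal(all_pos$aupr, 1)
  set.seed(17)
  for (i in 1:30) {
    scores <- round(runif(40), 2)
    labels <- rbinom(40, 1, 0.3)
    if (!sum(labels)) next
    expect_equal(pr_aupr(scores, labels)$aupr, oracle_aupr(scores, labels))
  }
  expect_error(pr_aupr(runif(4), rep(0, 4)), "positive")
})

test_that("top-u precision uses stable tie order and matches the oracle", {
  expect_equal(top_u_precision(c(0.9, 0.8, 0.7, 0.1), c(1, 1, 1, 0), 3), 1)
  scores <- c(0.5, 0.5, 0.5, 0.4)
  labels <- c(1, 0, 1, 1)
  expect_equal(top_u_precision(scores, labels, 2), 0.5)  # first two in input order
  set.seed(23)
  for (i in 1:30) {
    s <- round(runif(50), 1)
    l <- rbinom(50, 1, 0.4)
    u <- sample(c(10, 25, 50), 1)
    expect_equal(top_u_precision(s, l, u), oracle_top_u(s, l, u))
  }
  expect_equal(top_u_precision(runif(20), rep(c(1, 0), 10), 20), 0.5)
  expect_error(top_u_precision(runif(5), rep(1, 5), 10), "u = 10")
})

test_that("network prediction thresholds produce nested edge sets", {
  set.seed(44)
  n <- 200
  pairs <- data.frame(id_a = paste0("x", 1:n), id_b = paste0("y", 1:n))
  scores <- runif(n)
  prev <- NULL
  for (th in c(0.5, 0.8, 0.9, 0.95, 0.98)) {
    edges <- network_predict(scores, pairs, th, "interaction")
    expect_true(all(edges$score > th))
    if (!is.null(prev)) expect_true(all(edges$id_a %in% prev$id_a))
    prev <- edges
  }
  prev <- NULL
  for (th in c(0.5, 0.2, 0.1, 0.05, 0.01)) {
    edges <- network_predict(scores, pairs, th, "non_interaction")
    expect_true(all(edges$score < th))
    if (!is.null(prev)) expect_true(all(edges$id_a %in% prev$id_a))
    prev <- edges
  }
  default_pos <- network_predict(scores, pairs, 0.5, "interaction")
  expect_equal(nrow(default_pos), sum(scores > 0.5))
})

test_that("evaluation reports summarize members with mean, sd and variance", {
  set.seed(55)
  labels <- rbinom(80, 1, 0.5)
  probs <- sapply(1:5, function(j) plogis(2 * labels - 1 + rnorm(80, 0, 0.8)))
  rep <- evaluation_report(probs, labels)
  expect_named(rep$ensemble,
               c("sensitivity", "specificity", "precision", "f1", "mcc", "accuracy"))
  expect_equal(rep$member_var, rep$member_sd^2)
  expect_true(rep$auc > 0.5)
  expect_equal(sum(rep$counts), 80)
})
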