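test_that("the normality gate passes normal samples at its nominal level", {
  pass_norm <- pass_exp <- logical(200)
  for (i in 1:200) {
    set.seed(1000 + i)
    pass_norm[i] <- normality_gate(rnorm(40))
    pass_exp[i] <- normality_gate(rexp(40))
  }
  expect_gt(mean(pass_norm), 0.90)    # nominal 0.95
  expect_lt(mean(pass_exp), 0.25)     # power against a skewed alternative
  expect_error(normality_gate(rep(1, 10)), "degenerate sample",
               class = "dopplerperf_error_stats")
})

test_that("group comparison gates the test and matches the exact rank oracle", {
  # identical groups: no separation
  cmp0 <- compare_groups(c(1:5, 1:5), rep(c("malignant", "inflammatory"),
                                          each = 5))
  expect_equal(cmp0$p, 1.0)

  # complete separation {1..5} vs {10..14}: exact two-sided p for U = 0,
  # verified by full enumeration of all C(10,5) rank assignments
  vals <- c(1:5, 10:14)
  labs <- rep(c("malignant", "inflammatory"), each = 5)
  cmp <- compare_groups(vals, labs, test = "mann-whitney")
  expect_equal(cmp$test, "mann-whitney")
  combos <- utils::combn(10, 5)
  u_of <- function(ix) {
    r <- rank(vals)
    sum(r[ix]) - 5 * 6 / 2
  }
  u_obs <- u_of(1:5)
  us <- apply(combos, 2, u_of)
  p_exact <- mean(abs(us - 12.5) >= abs(u_obs - 12.5))
  expect_equal(cmp$p, p_exact)
  expect_equal(round(p_exact, 4), 0.0079)

  # normal separated groups: the gate picks the t-test in the large majority
  # of draws and the separation is overwhelmingly significant
  l <- rep(c("malignant", "inflammatory"), c(40, 29))
  picks <- character(100); ps <- numeric(100)
  for (i in 1:100) {
    set.seed(600 + i)
    v <- c(rnorm(40, 1.422, 0.742), rnorm(29, 2.653, 0.733))
    cmpn <- compare_groups(v, l)
    picks[i] <- cmpn$test; ps[i] <- cmpn$p
  }
  expect_gte(mean(picks == "t"), 0.85)   # two Shapiro gates at level 0.05
  expect_gte(mean(ps < 0.001), 0.95)
  expect_match(cmpn$groups$summary[1], "±|\\(")

  expect_error(compare_groups(c(1, 2, 1, 2), rep(c("a", "b"), 2)),
               "insufficient group size", class = "dopplerperf_error_stats")
})

test_that("ROC AUC equals the brute-force pairwise concordance, with ties", {
  set.seed(29)
  for (rep in 1:30) {
    n1 <- sample(5:25, 1); n2 <- sample(5:25, 1)
    vals <- c(sample(1:8, n1, TRUE) + 0.5 * rbinom(n1, 1, 0.5),
              sample(3:10, n2, TRUE))
    labs <- rep(c("malignant", "inflammatory"), c(n1, n2))
    res <- roc_analysis(vals, labs)
    pos <- labs == "malignant"
    auc_bf <- auc_bruteforce(vals, pos)
    expect_equal(res$auc, max(auc_bf, 1 - auc_bf))
  }
  expect_equal(roc_analysis(c(1, 2, 3, 4),
                            rep(c("malignant", "inflammatory"), each = 2))$auc, 1)
  expect_equal(roc_analysis(rep(2, 6),
                            rep(c("malignant", "inflammatory"), 3))$auc, 0.5)
  expect_error(roc_analysis(1:4, rep("malignant", 4)), "single-class input",
               class = "dopplerperf_error_stats")
})

test_that("the nadir decision rule is consistent and deterministic", {
  set.seed(31)
  for (rep in 1:20) {
    vals <- c(rnorm(20, 1), rnorm(15, 2.5))
    labs <- rep(c("malignant", "inflammatory"), c(20, 15))
    res <- roc_analysis(vals, labs)
    pos <- labs == "malignant"
    # confusion matrix at the nadir under the oriented rule
    if (res$direction == "lower-is-malignant") {
      sens <- mean(vals[pos] <= res$nadir)
      spec <- mean(vals[!pos] > res$nadir)
    } else {
      sens <- mean(vals[pos] >= res$nadir)
      spec <- mean(vals[!pos] < res$nadir)
    }
    expect_equal(res$sensitivity, sens)
    expect_equal(res$specificity, spec)
    expect_equal(res$acc, (sens * sum(pos) + spec * sum(!pos)) / length(vals))
    # the nadir maximizes Youden's J over observed thresholds
    j_all <- res$curve$sensitivity + res$curve$specificity - 1
    expect_equal(res$sensitivity + res$specificity - 1, max(j_all))
  }
})

test_that("AUC is invariant under monotone maps and flips with labels", {
  set.seed(37)
  vals <- rnorm(40)
  labs <- rep(c("malignant", "inflammatory"), 20)
  a <- roc_analysis(vals, labs)$auc
  expect_equal(roc_analysis(exp(vals), labs)$auc, a)
  pos <- labs == "malignant"
  raw <- auc_bruteforce(vals, pos)
  expect_equal(auc_bruteforce(vals, !pos), 1 - raw)
})

test_that("paired AUC comparison: self gives p = 1, and matches pROC DeLong", {
  set.seed(41)
  vals <- c(rnorm(30, 0), rnorm(25, 1))
  labs <- rep(c("malignant", "inflammatory"), c(30, 25))
  self <- compare_auc(vals, vals, labs)
  expect_equal(self$p, 1)
  expect_equal(self$delta, 0)
  # monotone transform: identical ROC, p = 1
  expect_equal(compare_auc(vals, exp(vals), labs)$p, 1)

  skip_if_not_installed("pROC")
  for (i in 1:10) {
    set.seed(500 + i)
    a <- c(rnorm(30, 0), rnorm(25, 1.2))
    b <- 0.6 * a + sqrt(1 - 0.36) * rnorm(55)
    res <- compare_auc(a, b, labs)
    ref <- pROC::roc.test(
      pROC::roc(labs, a, levels = c("inflammatory", "malignant"),
                direction = "<", quiet = TRUE),
      pROC::roc(labs, b, levels = c("inflammatory", "malignant"),
                direction = "<", quiet = TRUE),
      method = "delong", paired = TRUE)
    expect_equal(res$p, as.numeric(ref$p.value), tolerance = 1e-8)
  }
})

test_that("every calibrated parameter discriminates the groups across seeds", {
  # all six parameters stay clearly informative (AUC well above chance) on
  # calibrated cohorts; the published exact AUC ordering is not reproducible
  # from the group quartiles alone and is not asserted
  params <- c("tfv", "tpi", "fv", "volf", "tri", "ri")
  ok <- logical(20)
  for (s in 1:20) {
    co <- draw_cohort_params(40, 29, seed = 40000 + s)
    aucs <- vapply(params, function(p)
      roc_analysis(co[[p]], co$label, parameter = p)$auc, numeric(1))
    ok[s] <- all(aucs >= 0.65)
  }
  expect_gte(mean(ok), 0.9)
})

test_that("the cohort report produces one row per parameter and tolerates missing blocks", {
  set.seed(43)
  n <- 30
  cohort <- tibble::tibble(
    case_id = sprintf("c%02d", 1:n),
    label = rep(c("malignant", "inflammatory"), c(16, 14)),
    tfv = c(rnorm(16, 1.4, 0.5), rnorm(14, 2.6, 0.5)),
    tri = c(runif(16, 0.9, 1), runif(14, 0.5, 0.9)),
    tpi = c(rlnorm(16, -5.5, 1), rlnorm(14, -4.1, 0.6)),
    fv = c(rlnorm(16, 0.5, 0.8), rlnorm(14, 1.2, 0.3)),
    ri = c(runif(16, 0.9, 1), runif(14, 0.5, 1)),
    volf = c(rlnorm(16, -4.6, 1), rlnorm(14, -3.4, 0.6))
  )
  rep1 <- cohort_report(cohort)
  expect_equal(nrow(rep1$comparisons), 6)
  expect_equal(nrow(rep1$roc), 6)
  expect_equal(nrow(rep1$auc_comparisons), 9)   # 3 tissue x 3 single-vessel
  expect_true(all(rep1$roc$auc >= 0.5))

  # single-vessel block entirely missing: rows present but NA
  cohort2 <- cohort
  cohort2$fv <- cohort2$ri <- cohort2$volf <- NA_real_
  rep2 <- cohort_report(cohort2)
  expect_equal(nrow(rep2$roc), 6)
  expect_true(all(is.na(rep2$roc$auc[rep2$roc$parameter %in%
                                       c("fv", "ri", "volf")])))
})
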