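#' Normality gate for choosing between parametric and rank tests
#'
#' Shapiro–Wilk at the 0.05 level: a sample "passes" (returns `TRUE`) when
#' there is no evidence against normality.
#'
#' @param x Numeric vector, `n >= 3`, non-constant.
#' @param alpha Test level (default 0.05).
#' @return Logical scalar.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[is.finite(x)]
  if (length(x) < 3) abort("insufficient group size",
                           class = "dopplerperf_error_stats")
  if (diff(range(x)) == 0) abort("degenerate sample",
                                 class = "dopplerperf_error_stats")
  shapiro.test(x)$p.value >= alpha
}

#' Two-group comparison with a normality gate
#'
#' When both groups pass the normality gate the groups are compared with an
#' unequal-variance two-sample t-test and summarized as mean ± SD; otherwise
#' with a two-sided Mann–Whitney U test and summarized as median (Q1–Q3).
#' A constant group cannot pass the gate and falls to the rank test.
#'
#' @param values Numeric vector.
#' @param labels Vector of group labels with exactly two levels, conventionally
#'   `"malignant"` / `"inflammatory"`. Pairs with missing values are dropped.
#' @param parameter Optional parameter name carried into the output.
#' @param alpha Normality-gate level.
#' @param test `"auto"` (the normality gate decides, the default) or force
#'   `"t"` / `"mann-whitney"`.
#' @return An object of class `group_comparison` with fields `parameter`,
#'   `test` (`"t"` or `"mann-whitney"`), `p`, and a `groups` tibble
#'   (`label`, `n`, `center`, `spread_lo`, `spread_hi`, `summary`).
#' @export
compare_groups <- function(values, labels, parameter = NULL, alpha = 0.05,
                           test = c("auto", "t", "mann-whitney")) {
  test <- match.arg(test)
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels)[keep]
  lev <- unique(labels)
  if (length(lev) != 2) abort("labels must have exactly two levels",
                              class = "dopplerperf_error_stats")
  lev <- if (all(c("malignant", "inflammatory") %in% lev))
    c("malignant", "inflammatory") else sort(lev)
  g1 <- values[labels == lev[1]]; g2 <- values[labels == lev[2]]
  if (length(g1) < 3 || length(g2) < 3) {
    abort("insufficient group size", class = "dopplerperf_error_stats")
  }
  gate <- function(g) tryCatch(normality_gate(g, alpha),
                               dopplerperf_error_stats = function(e) FALSE)
  normal <- switch(test, auto = gate(g1) && gate(g2), t = TRUE,
                   `mann-whitney` = FALSE)
  if (normal) {
    ht <- t.test(g1, g2, var.equal = FALSE)
    summarize <- function(g) {
      tibble(n = length(g), center = mean(g), spread_lo = mean(g) - sd(g),
             spread_hi = mean(g) + sd(g),
             summary = sprintf("%.3f ±%.3f", mean(g), sd(g)))
    }
    test <- "t"
  } else {
    ht <- suppressWarnings(wilcox.test(g1, g2))
    summarize <- function(g) {
      q <- quantile(g, c(.25, .5, .75), names = FALSE, type = 7)
      tibble(n = length(g), center = q[2], spread_lo = q[1], spread_hi = q[3],
             summary = sprintf("%.3f (%.3f–%.3f)", q[2], q[1], q[3]))
    }
    test <- "mann-whitney"
  }
  groups <- dplyr::bind_rows(
    dplyr::mutate(summarize(g1), label = lev[1], .before = 1),
    dplyr::mutate(summarize(g2), label = lev[2], .before = 1)
  )
  structure(
    list(parameter = parameter %||% "value", test = test,
         p = as.numeric(ht$p.value), groups = groups),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s (%s test): p = %.4g\n",
              x$parameter, x$test, x$p))
  print(x$groups)
  invisible(x)
}

#' @export
tidy.group_comparison <- function(x, ...) {
  tibble(parameter = x$parameter, test = x$test,
         !!x$groups$label[1] := x$groups$summary[1],
         !!x$groups$label[2] := x$groups$summary[2],
         p = x$p)
}

# concordance AUC for "higher score => positive class" with ties counted 1/2
auc_concordance_ <- function(score, positive) {
  n1 <- sum(positive); n2 <- sum(!positive)
  r <- rank(score)
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

# two-sided normal-approximation p for the Mann-Whitney statistic, tie-corrected
mw_p_normal_ <- function(score, positive) {
  n1 <- sum(positive); n2 <- sum(!positive); n <- n1 + n2
  u <- auc_concordance_(score, positive) * n1 * n2
  ties <- table(score)
  v <- n1 * n2 / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  if (v <= 0) return(1)
  2 * pnorm(-abs(u - n1 * n2 / 2) / sqrt(v))
}

#' ROC analysis with a Youden-optimal cut-off
#'
#' The AUC is the Mann–Whitney concordance estimator (ties count 1/2), with
#' the decision direction chosen automatically so that `auc >= 0.5`: for the
#' flow parameters of hypovascular malignant lesions the oriented rule is
#' "value below the cut-off indicates malignancy". The reported cut-off (the
#' "nadir value") is the observed value maximizing Youden's
#' `J = sensitivity + specificity - 1`; ties resolve towards higher
#' specificity, then towards the smaller threshold, so the cut-off is
#' deterministic. Significance of the AUC against 0.5 uses the tie-corrected
#' normal approximation to the Mann–Whitney statistic.
#'
#' @param values Numeric marker values; missing values are dropped with their
#'   labels.
#' @param labels Two-level labels; `positive` names the positive class.
#' @param positive Positive class (default `"malignant"`).
#' @param parameter Optional parameter name carried into the output.
#' @return An object of class `roc_result` with fields `parameter`,
#'   `direction` (`"lower-is-malignant"` or `"higher-is-malignant"`, with the
#'   positive class name substituted), `auc`, `nadir`, `sensitivity`,
#'   `specificity`, `acc`, `p`, `n_pos`, `n_neg` and a `curve` tibble of ROC
#'   coordinates.
#' @export
roc_analysis <- function(values, labels, positive = "malignant",
                         parameter = NULL) {
  keep <- is.finite(values) & !is.na(labels)
  values <- values[keep]; labels <- as.character(labels)[keep]
  pos <- labels == positive
  if (!any(pos) || all(pos)) abort("single-class input",
                                   class = "dopplerperf_error_stats")
  auc_high <- auc_concordance_(values, pos)      # higher value => positive
  # direction auto-chosen so auc >= 0.5; at exactly 0.5 keep the
  # lower-is-positive convention of hypovascular lesions
  lower_is_pos <- auc_high <= 0.5
  direction <- if (lower_is_pos) paste0("lower-is-", positive)
               else paste0("higher-is-", positive)
  auc <- if (lower_is_pos) 1 - auc_high else auc_high
  n_pos <- sum(pos); n_neg <- sum(!pos)
  thr <- sort(unique(values))
  if (lower_is_pos) {
    sens <- vapply(thr, function(c) mean(values[pos] <= c), numeric(1))
    spec <- vapply(thr, function(c) mean(values[!pos] > c), numeric(1))
  } else {
    sens <- vapply(thr, function(c) mean(values[pos] >= c), numeric(1))
    spec <- vapply(thr, function(c) mean(values[!pos] < c), numeric(1))
  }
  j <- sens + spec - 1
  best <- which(j == max(j))
  best <- best[spec[best] == max(spec[best])]
  best <- best[which.min(thr[best])]
  acc <- (sens[best] * n_pos + spec[best] * n_neg) / (n_pos + n_neg)
  structure(
    list(parameter = parameter %||% "value", direction = direction,
         auc = auc, nadir = thr[best],
         sensitivity = sens[best], specificity = spec[best], acc = acc,
         p = mw_p_normal_(values, pos), n_pos = n_pos, n_neg = n_neg,
         curve = tibble(threshold = thr, sensitivity = sens,
                        specificity = spec)),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf(
    "<roc_result> %s: AUC %.3f (%s), nadir %.4g, sens %.3f, spec %.3f, ACC %.3f, p %.4g\n",
    x$parameter, x$auc, x$direction, x$nadir, x$sensitivity, x$specificity,
    x$acc, x$p))
  invisible(x)
}

#' @export
tidy.roc_result <- function(x, ...) {
  tibble(parameter = x$parameter, direction = x$direction, nadir = x$nadir,
         sensitivity = x$sensitivity, specificity = x$specificity,
         acc = x$acc, auc = x$auc, p = x$p)
}

#' @export
glance.roc_result <- function(x, ...) {
  tibble(auc = x$auc, p = x$p, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' ROC curve plot
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot of the ROC curve with the nadir point marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  cv <- dplyr::arrange(object$curve, 1 - .data$specificity, .data$sensitivity)
  cv <- dplyr::bind_rows(tibble(threshold = NA, sensitivity = 0, specificity = 1),
                         cv,
                         tibble(threshold = NA, sensitivity = 1, specificity = 0))
  at <- object$curve[object$curve$threshold == object$nadir, ]
  ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3) +
    ggplot2::geom_point(data = at, colour = "red", size = 2) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "1 - specificity", y = "sensitivity",
      title = sprintf("%s: AUC %.3f, nadir %.4g", object$parameter,
                      object$auc, object$nadir))
}

# DeLong placement components for one marker (higher score => positive)
delong_components_ <- function(score, pos) {
  x <- score[pos]; y <- score[!pos]
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), theta = mean(psi))
}

#' Paired comparison of two correlated AUCs (DeLong)
#'
#' Tests whether two markers measured on the same cases discriminate the
#' classes equally well, accounting for the correlation induced by the shared
#' cases. Each marker is first oriented so its AUC is at least 0.5 (the AUC of
#' a marker and of its sign-flip describe the same discriminative ability).
#' When the variance of the AUC difference is zero — e.g. a marker compared
#' with itself or with a strictly monotone transform of itself — the two ROC
#' curves are identical and `p = 1`.
#'
#' @param values_a,values_b Numeric marker values on the same cases.
#' @param labels Two-level labels; cases with a missing value in either marker
#'   are dropped (pairwise-complete).
#' @param positive Positive class.
#' @return An object of class `auc_comparison` with fields `auc_a`, `auc_b`,
#'   `delta`, `z`, `p`, `n_pos`, `n_neg`.
#' @export
compare_auc <- function(values_a, values_b, labels, positive = "malignant") {
  keep <- is.finite(values_a) & is.finite(values_b) & !is.na(labels)
  values_a <- values_a[keep]; values_b <- values_b[keep]
  labels <- as.character(labels)[keep]
  pos <- labels == positive
  if (sum(pos) < 2 || sum(!pos) < 2) {
    abort("insufficient pairs", class = "dopplerperf_error_stats")
  }
  orient <- function(v) if (auc_concordance_(v, pos) < 0.5) -v else v
  a <- delong_components_(orient(values_a), pos)
  b <- delong_components_(orient(values_b), pos)
  m <- sum(pos); n <- sum(!pos)
  s10 <- stats::cov(cbind(a$v10, b$v10))
  s01 <- stats::cov(cbind(a$v01, b$v01))
  v <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
       (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  delta <- a$theta - b$theta
  if (v <= .Machine$double.eps) {
    z <- 0; p <- 1
  } else {
    z <- delta / sqrt(v)
    p <- 2 * pnorm(-abs(z))
  }
  structure(
    list(auc_a = a$theta, auc_b = b$theta, delta = delta, z = z, p = p,
         n_pos = m, n_neg = n),
    class = "auc_comparison"
  )
}

#' @export
print.auc_comparison <- function(x, ...) {
  cat(sprintf("<auc_comparison> AUC %.3f vs %.3f, delta %.3f, z %.3f, p %.4g\n",
              x$auc_a, x$auc_b, x$delta, x$z, x$p))
  invisible(x)
}

#' @export
tidy.auc_comparison <- function(x, ...) {
  tibble(auc_a = x$auc_a, auc_b = x$auc_b, delta = x$delta, z = x$z, p = x$p)
}

#' Group-comparison and ROC report for a cohort of per-case results
#'
#' Builds the two canonical summary tables for a labeled cohort: per-parameter
#' group comparisons (normality-gated test, group summaries, p), and
#' per-parameter ROC results (AUC, nadir cut-off, sensitivity, specificity,
#' accuracy, significance), plus the ROC curve coordinates and the paired
#' DeLong comparisons between every tissue-perfusion parameter and every
#' single-vessel parameter.
#'
#' @param cohort A data frame with a `label` column (`malignant` /
#'   `inflammatory`) and the parameter columns; missing values allowed (e.g.
#'   cases excluded from single-vessel analysis).
#' @param parameters Character vector of parameter columns to analyze.
#' @param dtpm_parameters,svfm_parameters Parameter groups used for the paired
#'   AUC comparison block.
#' @return A list of class `cohort_report`: `comparisons` (tibble, one row per
#'   parameter), `roc` (tibble), `auc_comparisons` (tibble), `curves` (tibble
#'   of ROC coordinates), and the underlying result objects in
#'   `roc_objects`.
#' @export
cohort_report <- function(cohort,
                          parameters = c("tfv", "tri", "tpi", "fv", "ri", "volf"),
                          dtpm_parameters = intersect(c("tfv", "tri", "tpi"),
                                                      parameters),
                          svfm_parameters = intersect(c("fv", "ri", "volf"),
                                                      parameters)) {
  stopifnot("label" %in% names(cohort))
  parameters <- intersect(parameters, names(cohort))
  comp <- purrr::map(parameters, function(p) {
    res <- tryCatch(
      tidy(compare_groups(cohort[[p]], cohort$label, parameter = p)),
      dopplerperf_error_stats = function(e)
        tibble(parameter = p, test = NA_character_, malignant = NA_character_,
               inflammatory = NA_character_, p = NA_real_)
    )
    res
  })
  comp <- dplyr::bind_rows(comp)
  roc_obj <- purrr::map(parameters, function(p) {
    tryCatch(roc_analysis(cohort[[p]], cohort$label, parameter = p),
             dopplerperf_error_stats = function(e) NULL)
  })
  names(roc_obj) <- parameters
  roc_tbl <- dplyr::bind_rows(purrr::map(parameters, function(p) {
    if (is.null(roc_obj[[p]])) {
      tibble(parameter = p, direction = NA_character_, nadir = NA_real_,
             sensitivity = NA_real_, specificity = NA_real_, acc = NA_real_,
             auc = NA_real_, p = NA_real_)
    } else tidy(roc_obj[[p]])
  }))
  curves <- dplyr::bind_rows(purrr::map(parameters, function(p) {
    if (is.null(roc_obj[[p]])) return(NULL)
    dplyr::mutate(roc_obj[[p]]$curve, parameter = p, .before = 1)
  }))
  pairs <- tidyr::expand_grid(param_a = dtpm_parameters,
                              param_b = svfm_parameters)
  auc_cmp <- dplyr::bind_rows(purrr::pmap(pairs, function(param_a, param_b) {
    res <- tryCatch(
      compare_auc(cohort[[param_a]], cohort[[param_b]], cohort$label),
      dopplerperf_error_stats = function(e) NULL
    )
    if (is.null(res)) {
      tibble(param_a = param_a, param_b = param_b, auc_a = NA_real_,
             auc_b = NA_real_, delta = NA_real_, z = NA_real_, p = NA_real_)
    } else {
      dplyr::mutate(tidy(res), param_a = param_a, param_b = param_b,
                    .before = 1)
    }
  }))
  structure(
    list(comparisons = comp, roc = roc_tbl, auc_comparisons = auc_cmp,
         curves = curves, roc_objects = roc_obj),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\nGroup comparisons:\n")
  print(x$comparisons)
  cat("\nROC analysis:\n")
  print(x$roc)
  cat("\nPaired AUC comparisons (tissue vs single-vessel):\n")
  print(x$auc_comparisons)
  invisible(x)
}
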