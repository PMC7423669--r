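# Inferential layer: t-tests on mismatch statistics, per-axis ANOVA,
# MANOVA and LDA posterior classification on retained PC scores.
# Standard tests are delegated to stats:: / MASS:: and wrapped in a uniform
# result type.

#' Uniform hypothesis-test result
#'
#' @param statistic Test statistic value.
#' @param df Degrees of freedom (length 1 or 2).
#' @param p_value Two-sided p-value in [0, 1].
#' @param test_name Human-readable test label.
#' @param group_labels Labels of the groups compared.
#' @param extra Optional named list of auxiliary quantities (e.g. Wilks'
#'   lambda alongside Pillai's trace).
#' @return Object of class `test_result`.
#' @export
test_result <- function(statistic, df, p_value, test_name,
                        group_labels = character(), extra = list()) {
  structure(
    list(statistic = unname(statistic), df = unname(df),
         p_value = unname(p_value), test_name = test_name,
         group_labels = group_labels, extra = extra),
    class = "test_result"
  )
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$test_name, x$statistic,
              paste(signif(x$df, 6), collapse = ", "), x$p_value))
  invisible(x)
}

#' One-sample t-test
#'
#' Classic one-sample t against `mu0` with two-sided p from Student's t on
#' n - 1 degrees of freedom. Used on per-sample absolute-mismatch values to
#' test whether co-mimic populations differ in pattern beyond zero.
#'
#' @param values Numeric vector, n >= 2 with nonzero variance.
#' @param mu0 Null mean (default 0).
#' @return `test_result`.
#' @export
one_sample_t <- function(values, mu0 = 0) {
  values <- as.numeric(values)
  if (length(values) < 2L) {
    wm_stop("wm_degenerate_sample_error", "one-sample t needs n >= 2")
  }
  if (stats::sd(values) == 0) {
    wm_stop("wm_degenerate_sample_error", "zero variance: t statistic undefined")
  }
  tt <- stats::t.test(values, mu = mu0)
  test_result(tt$statistic, tt$parameter, tt$p.value, "one-sample t-test")
}

#' Two-sample t-test
#'
#' Welch's t-test by default (no equal-variance assumption); set
#' `equal_var = TRUE` for the pooled-variance test. Used on per-sample
#' relative pattern areas between co-mimics.
#'
#' @param a,b Numeric vectors, each n >= 2.
#' @param equal_var Pool variances (default `FALSE`, Welch).
#' @return `test_result`.
#' @export
two_sample_t <- function(a, b, equal_var = FALSE) {
  a <- as.numeric(a); b <- as.numeric(b)
  if (length(a) < 2L || length(b) < 2L) {
    wm_stop("wm_degenerate_sample_error", "two-sample t needs n >= 2 per group")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    wm_stop("wm_degenerate_sample_error",
            "zero variance in both groups: t statistic undefined")
  }
  tt <- stats::t.test(a, b, var.equal = equal_var)
  test_result(tt$statistic, tt$parameter, tt$p.value,
              if (equal_var) "two-sample t-test (pooled)" else "Welch two-sample t-test")
}

.check_groups <- function(labels, min_per_group = 2L) {
  labels <- factor(labels)
  tab <- table(labels)
  if (length(tab) < 2L) {
    wm_stop("wm_sample_size_error", "at least 2 groups are required")
  }
  if (any(tab < min_per_group)) {
    wm_stop("wm_sample_size_error",
            sprintf("every group needs >= %d samples (smallest has %d)",
                    min_per_group, min(tab)))
  }
  labels
}

#' One-way ANOVA on a single PC axis
#'
#' Fixed-effects one-way F test of group differences in the scores of one
#' PC axis. When within-group variance is exactly zero but groups differ,
#' the F statistic is unbounded and the result is reported as degenerate
#' (statistic `Inf`, p 0) rather than a numeric artefact.
#'
#' @param scores Score matrix (samples x axes) or numeric vector.
#' @param labels Group labels, one per sample.
#' @param axis Axis (column) to test; ignored for vector input.
#' @return `test_result` with `df = c(df_between, df_within)`.
#' @export
per_axis_anova <- function(scores, labels, axis = 1L) {
  y <- if (is.matrix(scores)) scores[, axis] else as.numeric(scores)
  g <- .check_groups(labels)
  if (length(y) != length(g)) {
    wm_stop("wm_config_error", "scores and labels differ in length")
  }
  fit <- stats::aov(y ~ g)
  tab <- summary(fit)[[1L]]
  ss_within <- tab["Residuals", "Sum Sq"]
  if (ss_within <= .Machine$double.eps * sum(y^2)) {
    if (tab[1L, "Sum Sq"] <= .Machine$double.eps * max(sum(y^2), 1)) {
      return(test_result(0, tab[, "Df"], 1, "one-way ANOVA",
                         levels(g)))
    }
    return(test_result(Inf, tab[, "Df"], 0,
                       "one-way ANOVA (degenerate: zero within-group variance)",
                       levels(g)))
  }
  test_result(tab[1L, "F value"], tab[, "Df"], tab[1L, "Pr(>F)"],
              "one-way ANOVA", levels(g))
}

#' MANOVA on retained PC scores
#'
#' Multivariate analysis of variance of group membership on the retained
#' PC axes. Pillai's trace (with its standard F approximation) is the
#' reported statistic for robustness; Wilks' lambda is returned alongside
#' in `extra`. A single retained axis reduces to the one-way ANOVA on that
#' axis.
#'
#' @param scores Samples x retained-axes score matrix.
#' @param labels Group labels, one per sample.
#' @return `test_result`; `df` is the (df1, df2) pair of the Pillai F
#'   approximation.
#' @export
manova_scores <- function(scores, labels) {
  scores <- as.matrix(scores)
  g <- .check_groups(labels)
  if (nrow(scores) != length(g)) {
    wm_stop("wm_config_error", "scores and labels differ in length")
  }
  p <- ncol(scores)
  if (p == 1L) {
    res <- per_axis_anova(scores, g, 1L)
    res$test_name <- "MANOVA (1 axis: one-way ANOVA)"
    return(res)
  }
  if (nrow(scores) <= p + nlevels(g)) {
    wm_stop("wm_sample_size_error",
            "too few samples for the number of axes and groups")
  }
  fit <- tryCatch(
    stats::manova(scores ~ g),
    error = function(e) wm_stop("wm_rank_error", conditionMessage(e))
  )
  sp <- tryCatch(
    summary(fit, test = "Pillai")$stats,
    error = function(e) {
      wm_stop("wm_rank_error",
              "singular within-group covariance: retain fewer PC axes")
    }
  )
  sw <- summary(fit, test = "Wilks")$stats
  test_result(
    sp["g", "Pillai"], sp["g", c("num Df", "den Df")], sp["g", "Pr(>F)"],
    "MANOVA (Pillai)", levels(g),
    extra = list(
      approx_f = unname(sp["g", "approx F"]),
      wilks = unname(sw["g", "Wilks"]),
      wilks_p = unname(sw["g", "Pr(>F)"])
    )
  )
}

#' LDA posterior classification of groups
#'
#' Linear discriminant analysis with pooled covariance and proportional
#' priors on retained PC scores. Reports, per group, the mean posterior
#' probability assigned to a sample's true group (as a percentage), plus
#' confusion counts. The default scheme is leave-one-out cross-validation;
#' `resubstitution` scores the training data directly and inflates
#' posteriors.
#'
#' @param scores Samples x retained-axes score matrix (a vector is treated
#'   as one axis).
#' @param labels Group labels, one per sample.
#' @param scheme `"loo"` (default) or `"resubstitution"`.
#' @return Object of class `classification_report`: `posterior_pct` (named
#'   per-group mean posterior for the true group, in %), `confusion`
#'   (true x predicted counts), `scheme`.
#' @export
lda_classify <- function(scores, labels, scheme = c("loo", "resubstitution")) {
  scheme <- match.arg(scheme)
  scores <- as.matrix(scores)
  g <- .check_groups(labels, min_per_group = 3L)
  if (nrow(scores) != length(g)) {
    wm_stop("wm_config_error", "scores and labels differ in length")
  }
  res <- tryCatch({
    if (scheme == "loo") {
      fit <- MASS::lda(scores, grouping = g, CV = TRUE)
      list(class = fit$class, posterior = fit$posterior)
    } else {
      fit <- MASS::lda(scores, grouping = g)
      pred <- stats::predict(fit, scores)
      list(class = pred$class, posterior = pred$posterior)
    }
  }, error = function(e) {
    wm_stop("wm_rank_error",
            sprintf("LDA failed (singular pooled covariance?): %s",
                    conditionMessage(e)))
  })
  true_post <- res$posterior[cbind(seq_along(g), match(as.character(g),
                                                       colnames(res$posterior)))]
  posterior_pct <- stats::setNames(
    as.numeric(tapply(true_post, g, mean)) * 100, levels(g)
  )
  confusion <- table(true = g, predicted = factor(res$class, levels = levels(g)))
  structure(
    list(posterior_pct = posterior_pct, confusion = confusion, scheme = scheme),
    class = "classification_report"
  )
}

#' @export
print.classification_report <- function(x, ...) {
  cat(sprintf("<classification_report> scheme = %s\n", x$scheme))
  for (grp in names(x$posterior_pct)) {
    cat(sprintf("  %s: mean posterior for true group %.1f%%\n",
                grp, x$posterior_pct[[grp]]))
  }
  invisible(x)
}
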