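#' Correlate per-fly sleep with peak responsiveness
#'
#' Pearson correlation with a two-tailed p-value between per-fly sleep
#' duration (min/hr) and per-fly fitted peak responsiveness (mm/s) within one
#' circadian window. Flies missing either value are excluded listwise.
#'
#' @param sleep Per-fly sleep values (min/hr).
#' @param responsiveness Per-fly peak responsiveness (mm/s), same order.
#' @param window `"day"` or `"night"` (annotation only).
#' @return List of class `correlation_result`: `R`, `p`, `n`, `window`,
#'   `n_excluded`.
#' @export
correlate_sleep_vs_responsiveness <- function(sleep, responsiveness,
                                              window = c("day", "night")) {
  window <- match.arg(window)
  if (length(sleep) != length(responsiveness)) {
    stop_contract("sleep and responsiveness must be paired per fly")
  }
  ok <- is.finite(sleep) & is.finite(responsiveness)
  if (sum(ok) < 3) stop_insufficient("need >= 3 complete pairs")
  ct <- cor.test(sleep[ok], responsiveness[ok], method = "pearson",
                 alternative = "two.sided")
  structure(list(R = unname(ct$estimate), p = ct$p.value, n = sum(ok),
                 window = window, n_excluded = sum(!ok)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("<correlation_result> %s: R = %.3f, p = %.3g, n = %d\n",
              x$window, x$R, x$p, x$n))
  invisible(x)
}

#' Dunn's post hoc comparisons after a Friedman test
#'
#' Within-block ranks; each condition is compared to the declared reference
#' with `z = (meanrank - meanrank_ref) / sqrt(k (k + 1) / (6 n))` and the
#' two-tailed normal p-value is Bonferroni-adjusted over the family of
#' contrasts.
#' @noRd
dunn_posthoc <- function(mat, reference) {
  k <- ncol(mat); n <- nrow(mat)
  ranks <- t(apply(mat, 1, rank))
  mean_rank <- colMeans(ranks)
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(colnames(mat), reference)
  z <- (mean_rank[others] - mean_rank[reference]) / se
  p_unadj <- 2 * pnorm(-abs(z))
  data.frame(contrast = paste(others, "vs", reference),
             statistic = unname(z), p_unadjusted = unname(p_unadj),
             p_adjusted = pmin(1, unname(p_unadj) * length(others)))
}

#' Group-level comparison with the study's test battery
#'
#' Dispatches to the test declared by the design: Friedman with Dunn's post
#' hoc against a reference condition (within-cell pre/stim/post designs),
#' Wilcoxon signed rank against zero (baseline-zeroed power ratios),
#' Mann-Whitney (two independent groups), paired/unpaired t-tests (screened
#' with Shapiro-Wilk at p < 0.05 and demoted to the matching nonparametric
#' test on failure, as the analysis plan prescribes), or two-way ANOVA with
#' Dunnett contrasts against a control group. All tests are two-tailed at
#' alpha = 0.05 and any post hoc adjustment is recorded in the result.
#'
#' @param values The data, shaped per test: a subjects x conditions matrix or
#'   data frame (`friedman_dunn`, `paired_t`), a numeric vector
#'   (`wilcoxon_signed_rank_vs_zero`), a list of two vectors (`mann_whitney`,
#'   `unpaired_t`), or a data frame with `value`, `group` and a second factor
#'   column (`two_way_anova_dunnett`).
#' @param design List with `test` (one of the names above), optional
#'   `reference` (reference condition/group label), optional
#'   `normality_screen` (default TRUE for t-tests), and for the ANOVA design
#'   `factor2` (name of the second factor column).
#' @return List of class `group_comparison`: `test_requested`, `test_used`,
#'   `statistic`, `p`, `contrasts` (data frame or NULL), `n`, `adjustment`,
#'   `normality` (screen results or NULL).
#' @export
compare_conditions <- function(values, design) {
  test <- design$test
  if (is.null(test)) stop_contract("design must declare a test")
  out <- switch(
    test,
    friedman_dunn = {
      mat <- as.matrix(values)
      if (is.null(colnames(mat))) colnames(mat) <- paste0("c", seq_len(ncol(mat)))
      if (ncol(mat) < 3) stop_contract("friedman_dunn needs >= 3 conditions")
      ref <- design$reference %||% colnames(mat)[1]
      ft <- friedman.test(mat)
      # fully tied ranks (no variation across conditions): null result
      stat <- unname(ft$statistic)
      pval <- ft$p.value
      if (!is.finite(pval)) { stat <- 0; pval <- 1 }
      list(test_used = "friedman_dunn", statistic = stat,
           p = pval, contrasts = dunn_posthoc(mat, ref),
           n = nrow(mat), adjustment = "bonferroni (Dunn)", normality = NULL)
    },
    wilcoxon_signed_rank_vs_zero = {
      x <- as.numeric(values)
      wt <- suppressWarnings(wilcox.test(x, mu = 0, alternative = "two.sided"))
      list(test_used = "wilcoxon_signed_rank_vs_zero",
           statistic = unname(wt$statistic), p = wt$p.value,
           contrasts = NULL, n = length(x), adjustment = "none",
           normality = NULL)
    },
    mann_whitney = {
      if (!is.list(values) || length(values) != 2) {
        stop_contract("mann_whitney needs a list of two groups")
      }
      wt <- suppressWarnings(wilcox.test(values[[1]], values[[2]],
                                         alternative = "two.sided"))
      list(test_used = "mann_whitney", statistic = unname(wt$statistic),
           p = wt$p.value, contrasts = NULL,
           n = lengths(values), adjustment = "none", normality = NULL)
    },
    paired_t = {
      mat <- as.matrix(values)
      if (ncol(mat) != 2) stop_contract("paired_t needs two paired columns")
      d <- mat[, 1] - mat[, 2]
      screen <- !isFALSE(design$normality_screen)
      sw <- if (screen && length(d) >= 3 && sd(d) > 0) shapiro.test(d) else NULL
      if (!is.null(sw) && sw$p.value < 0.05) {
        wt <- suppressWarnings(wilcox.test(mat[, 1], mat[, 2], paired = TRUE))
        list(test_used = "wilcoxon_signed_rank_paired",
             statistic = unname(wt$statistic), p = wt$p.value,
             contrasts = NULL, n = nrow(mat), adjustment = "none",
             normality = data.frame(target = "differences", p = sw$p.value))
      } else {
        tt <- t.test(mat[, 1], mat[, 2], paired = TRUE)
        list(test_used = "paired_t", statistic = unname(tt$statistic),
             p = tt$p.value, contrasts = NULL, n = nrow(mat),
             adjustment = "none",
             normality = if (is.null(sw)) NULL else
               data.frame(target = "differences", p = sw$p.value))
      }
    },
    unpaired_t = {
      if (!is.list(values) || length(values) != 2) {
        stop_contract("unpaired_t needs a list of two groups")
      }
      screen <- !isFALSE(design$normality_screen)
      sws <- if (screen) lapply(values, function(v) {
        if (length(v) >= 3 && sd(v) > 0) shapiro.test(v)$p.value else NA_real_
      }) else NULL
      fails <- !is.null(sws) && any(unlist(sws) < 0.05, na.rm = TRUE)
      if (fails) {
        wt <- suppressWarnings(wilcox.test(values[[1]], values[[2]]))
        list(test_used = "mann_whitney", statistic = unname(wt$statistic),
             p = wt$p.value, contrasts = NULL, n = lengths(values),
             adjustment = "none",
             normality = data.frame(target = c("group1", "group2"),
                                    p = unlist(sws)))
      } else {
        tt <- t.test(values[[1]], values[[2]])
        list(test_used = "unpaired_t", statistic = unname(tt$statistic),
             p = tt$p.value, contrasts = NULL, n = lengths(values),
             adjustment = "none",
             normality = if (is.null(sws)) NULL else
               data.frame(target = c("group1", "group2"), p = unlist(sws)))
      }
    },
    two_way_anova_dunnett = {
      df <- as.data.frame(values)
      f2 <- design$factor2 %||% setdiff(names(df), c("value", "group"))[1]
      if (!all(c("value", "group", f2) %in% names(df))) {
        stop_contract("two_way_anova_dunnett needs value, group and ", f2)
      }
      ref <- design$reference %||% levels(factor(df$group))[1]
      df$group <- stats::relevel(factor(df$group), ref = ref)
      df$.f2 <- factor(df[[f2]])
      fit <- aov(value ~ group + .f2, data = df)
      an <- summary(fit)[[1]]
      glht <- multcomp::glht(fit, linfct = multcomp::mcp(group = "Dunnett"))
      sm <- summary(glht)
      list(test_used = "two_way_anova_dunnett",
           statistic = an["group", "F value"],
           p = an["group", "Pr(>F)"],
           contrasts = data.frame(
             contrast = names(sm$test$coefficients),
             statistic = unname(sm$test$tstat),
             p_unadjusted = 2 * stats::pt(-abs(unname(sm$test$tstat)),
                                          df = fit$df.residual),
             p_adjusted = unname(as.numeric(sm$test$pvalues))),
           n = nrow(df), adjustment = "dunnett (single-step)",
           normality = NULL)
    },
    stop_contract("unknown test: ", test)
  )
  out$test_requested <- test
  class(out) <- "group_comparison"
  out
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s: statistic = %.3f, p = %.3g\n",
              x$test_used, x$statistic, x$p))
  if (!is.null(x$contrasts)) {
    print(x$contrasts, row.names = FALSE)
  }
  invisible(x)
}
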