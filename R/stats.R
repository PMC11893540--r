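#' Check the assumptions gating the test choice
#'
#' Normality is assessed by a Shapiro-Wilk test on the pair differences
#' (alpha = .05); outliers by the 3 x IQR rule (any difference outside
#' `[Q1 - 3 IQR, Q3 + 3 IQR]`); sphericity by Mauchly's test when `x` is a
#' subjects x levels matrix with at least 3 levels (otherwise not
#' applicable). Constant differences make the Shapiro test undefined; this
#' degenerate case is flagged and normality reported as NA.
#'
#' @param x Numeric vector of first-condition values, paired differences
#'   (when `y` is NULL), or a subjects x levels matrix.
#' @param y Optional second-condition values (same length as `x`).
#' @param alpha Significance level for the Shapiro-Wilk test.
#' @return List with logical elements `normality` (TRUE = assumption met,
#'   NA when degenerate), `outliers` (TRUE = outliers present), `sphericity`
#'   (NA unless a >= 3 level matrix is supplied), and `degenerate`.
#' @export
check_assumptions <- function(x, y = NULL, alpha = 0.05) {
  if (is.matrix(x)) {
    if (ncol(x) < 3) stop("sphericity needs at least 3 levels")
    if (nrow(x) < 3) stop("need at least 3 subjects")
    norm <- vapply(seq_len(ncol(x)), function(j) col_normality(x[, j], alpha),
                   NA)
    outl <- vapply(seq_len(ncol(x)), function(j) has_outliers_3iqr(x[, j]),
                   NA)
    sph <- tryCatch({
      fit <- lm(x ~ 1)
      mauchly.test(fit, X = ~1)$p.value >= alpha
    }, error = function(e) NA)
    return(list(normality = if (anyNA(norm)) NA else all(norm),
                outliers = any(outl), sphericity = sph,
                degenerate = anyNA(norm)))
  }
  d <- if (is.null(y)) x else x - y
  if (length(d) < 3) stop("need at least 3 pairs")
  list(normality = col_normality(d, alpha),
       outliers = has_outliers_3iqr(d),
       sphericity = NA, degenerate = is.na(col_normality(d, alpha)))
}

col_normality <- function(d, alpha = 0.05) {
  if (stats::sd(d) == 0) return(NA)
  shapiro.test(d)$p.value >= alpha
}

has_outliers_3iqr <- function(d) {
  q <- quantile(d, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  any(d < q[1] - 3 * iqr | d > q[2] + 3 * iqr)
}

#' Assumption-gated paired comparison
#'
#' Runs a paired t-test (with Cohen's dz and a noncentral-t 95% CI) when the
#' differences pass the normality check and carry no 3 x IQR outliers, and a
#' Wilcoxon signed-rank test (with matched-pairs rank-biserial r and a
#' normal-approximation 95% CI) otherwise. All-zero differences yield the
#' degenerate result p = 1 with a zero effect.
#'
#' @param x,y Paired numeric vectors (condition A, condition B).
#' @param tail `"two.sided"`, `"greater"` (x > y) or `"less"`.
#' @param alpha Significance level used for the assumption checks.
#' @param force Optionally force the `"t"` or `"wilcoxon"` branch,
#'   bypassing the gate. Default `"auto"`.
#' @return Object of class `test_result`: `test`, `statistic`, `p_raw`,
#'   `p_adjusted` (NA until a family correction fills it), `tail`, `effect`
#'   (list with `kind`, `value`, `ci95`), `n`, `assumptions`.
#' @export
paired_compare <- function(x, y, tail = c("two.sided", "greater", "less"),
                           alpha = 0.05, force = c("auto", "t", "wilcoxon")) {
  tail <- match.arg(tail)
  force <- match.arg(force)
  if (length(x) != length(y)) stop("x and y must be paired (equal length)")
  if (length(x) < 3) stop("need at least 3 pairs")
  d <- x - y
  assum <- check_assumptions(d)
  if (all(d == 0)) {
    return(new_test_result(
      test = "degenerate (all differences zero)", statistic = 0, p_raw = 1,
      tail = tail, effect = list(kind = "cohen_dz", value = 0,
                                 ci95 = c(0, 0)),
      n = length(d), assumptions = assum, flags = "all_zero_differences"))
  }
  use_t <- if (force == "auto")
    isTRUE(assum$normality) && !assum$outliers else force == "t"
  if (use_t) {
    ht <- t.test(x, y, paired = TRUE, alternative = tail)
    n <- length(d)
    dz <- mean(d) / stats::sd(d)
    ci <- dz_ci(dz, n)
    new_test_result(test = "paired t-test",
                    statistic = unname(ht$statistic), p_raw = ht$p.value,
                    tail = tail,
                    effect = list(kind = "cohen_dz", value = dz, ci95 = ci),
                    n = n, assumptions = assum)
  } else {
    ht <- suppressWarnings(wilcox.test(x, y, paired = TRUE,
                                       alternative = tail))
    eff <- rank_biserial(d)
    new_test_result(test = "Wilcoxon signed-rank",
                    statistic = unname(ht$statistic), p_raw = ht$p.value,
                    tail = tail, effect = eff, n = length(d),
                    assumptions = assum)
  }
}

# 95% CI for Cohen's dz by inverting the noncentral t distribution.
dz_ci <- function(dz, n) {
  t_obs <- dz * sqrt(n)
  df <- n - 1
  bound <- function(target) {
    # pt() is decreasing in ncp, so f is decreasing; extreme-tail pt()
    # precision warnings are irrelevant at CI accuracy
    f <- function(ncp) suppressWarnings(pt(t_obs, df, ncp)) - target
    lo <- t_obs - 10 - abs(t_obs); hi <- t_obs + 10 + abs(t_obs)
    tryCatch(uniroot(f, c(lo, hi), extendInt = "downX")$root,
             error = function(e) NA_real_)
  }
  c(bound(0.975), bound(0.025)) / sqrt(n)
}

# Matched-pairs rank-biserial correlation with a 95% CI from the normal
# approximation of the signed-rank statistic.
rank_biserial <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) return(list(kind = "rank_biserial_r", value = 0,
                          ci95 = c(0, 0)))
  r_abs <- rank(abs(d))
  w_pos <- sum(r_abs[d > 0])
  s <- n * (n + 1) / 2
  r <- (2 * w_pos - s) / s
  se_w <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
  ci_w <- w_pos + c(-1, 1) * 1.96 * se_w
  ci <- pmin(pmax((2 * ci_w - s) / s, -1), 1)
  list(kind = "rank_biserial_r", value = r, ci95 = ci)
}

new_test_result <- function(test, statistic, p_raw, tail, effect, n,
                            assumptions, flags = character(),
                            posthoc = NULL) {
  structure(list(test = test, statistic = statistic, p_raw = p_raw,
                 p_adjusted = NA_real_, tail = tail, effect = effect,
                 n = n, assumptions = assumptions, flags = flags,
                 posthoc = posthoc),
            class = "test_result")
}

#' @export
print.test_result <- function(x, digits = 4, ...) {
  cat("<test_result> ", x$test, " (", x$tail, "), n = ", x$n, "\n",
      "  statistic = ", signif(x$statistic, digits), ", p = ",
      signif(x$p_raw, digits), sep = "")
  if (!is.na(x$p_adjusted))
    cat(", p(adj) = ", signif(x$p_adjusted, digits), sep = "")
  cat("\n  effect ", x$effect$kind, " = ", signif(x$effect$value, digits),
      " [", signif(x$effect$ci95[1], digits), ", ",
      signif(x$effect$ci95[2], digits), "]\n", sep = "")
  if (length(x$flags)) cat("  flags:", paste(x$flags, collapse = ", "), "\n")
  if (!is.null(x$posthoc)) {
    cat("  post-hoc (", attr(x$posthoc, "method"), "):\n", sep = "")
    print(x$posthoc, digits = digits)
  }
  invisible(x)
}

#' Assumption-gated multilevel comparison across stages
#'
#' For a complete subjects x levels matrix (typically the four stages W, N2,
#' N3, REM): a one-way repeated-measures ANOVA with partial eta-squared and
#' Tukey post-hoc contrasts when per-level normality, the 3 x IQR outlier
#' rule and Mauchly sphericity all pass; otherwise a Friedman test with
#' Kendall's W (bootstrap 95% CI) and pairwise Wilcoxon signed-rank
#' post-hocs, Bonferroni-Holm corrected.
#'
#' @param values Numeric matrix, one row per subject, one column per level;
#'   missing cells are an error (complete cases are required).
#' @param alpha Assumption-check significance level.
#' @param seed Seed for the Kendall's W bootstrap CI.
#' @param n_boot Bootstrap resamples for the Kendall's W CI. Default 2000.
#' @param force Force `"anova"` or `"friedman"`; default `"auto"`.
#' @return A `test_result`; the post-hoc table (columns `contrast`,
#'   `p_raw`, `p_adjusted`) is attached as `$posthoc`.
#' @export
multilevel_compare <- function(values, alpha = 0.05, seed = 1,
                               n_boot = 2000,
                               force = c("auto", "anova", "friedman")) {
  force <- match.arg(force)
  values <- as.matrix(values)
  if (anyNA(values))
    stop("missing cells; multilevel comparison needs complete cases")
  n <- nrow(values); k <- ncol(values)
  if (k < 3) stop("need at least 3 levels")
  if (is.null(colnames(values))) colnames(values) <- paste0("L", seq_len(k))
  if (all(apply(values, 1, function(r) max(r) - min(r)) == 0)) {
    ph <- posthoc_frame(colnames(values), rep(1, k * (k - 1) / 2), "none")
    return(new_test_result(
      test = "degenerate (all levels identical)", statistic = 0, p_raw = 1,
      tail = "two.sided",
      effect = list(kind = "kendall_w", value = 0, ci95 = c(0, 0)),
      n = n, assumptions = list(), flags = "all_levels_identical",
      posthoc = ph))
  }
  assum <- check_assumptions(values, alpha = alpha)
  use_anova <- if (force == "auto")
    isTRUE(assum$normality) && !assum$outliers && isTRUE(assum$sphericity)
  else force == "anova"
  if (use_anova) {
    grand <- mean(values)
    ss_subj <- k * sum((rowMeans(values) - grand)^2)
    ss_treat <- n * sum((colMeans(values) - grand)^2)
    ss_tot <- sum((values - grand)^2)
    ss_err <- ss_tot - ss_subj - ss_treat
    df1 <- k - 1; df2 <- (k - 1) * (n - 1)
    ms_treat <- ss_treat / df1; ms_err <- ss_err / df2
    f <- ms_treat / ms_err
    p <- pf(f, df1, df2, lower.tail = FALSE)
    eta2 <- ss_treat / (ss_treat + ss_err)
    ci <- eta2_ci(f, df1, df2)
    ## Tukey HSD on the repeated-measures error term
    se <- sqrt(ms_err / n)
    cmb <- utils::combn(k, 2)
    q <- abs(colMeans(values)[cmb[1, ]] - colMeans(values)[cmb[2, ]]) / se
    p_ph <- ptukey(q, nmeans = k, df = df2, lower.tail = FALSE)
    ph <- posthoc_frame(colnames(values), p_ph, "tukey")
    new_test_result(test = "repeated-measures ANOVA", statistic = f,
                    p_raw = p, tail = "two.sided",
                    effect = list(kind = "eta_squared", value = eta2,
                                  ci95 = ci),
                    n = n, assumptions = assum, posthoc = ph)
  } else {
    ht <- friedman.test(values)
    w <- unname(ht$statistic) / (n * (k - 1))
    ci <- kendall_w_boot_ci(values, n_boot, seed)
    cmb <- utils::combn(k, 2)
    p_ph <- vapply(seq_len(ncol(cmb)), function(j)
      suppressWarnings(wilcox.test(values[, cmb[1, j]], values[, cmb[2, j]],
                                   paired = TRUE)$p.value), 0)
    ph <- posthoc_frame(colnames(values), holm_adjust(p_ph),
                        "wilcoxon + holm", p_raw = p_ph)
    new_test_result(test = "Friedman rank-sum", statistic = ht$statistic,
                    p_raw = ht$p.value, tail = "two.sided",
                    effect = list(kind = "kendall_w", value = w, ci95 = ci),
                    n = n, assumptions = assum, posthoc = ph)
  }
}

posthoc_frame <- function(levels_, p_adj, method, p_raw = p_adj) {
  cmb <- utils::combn(length(levels_), 2)
  df <- data.frame(
    contrast = paste(levels_[cmb[1, ]], levels_[cmb[2, ]], sep = "-"),
    p_raw = p_raw, p_adjusted = pmin(p_adj, 1))
  attr(df, "method") <- method
  df
}

# 95% CI for partial eta-squared by inverting the noncentral F distribution.
eta2_ci <- function(f, df1, df2) {
  bound <- function(target) {
    if (suppressWarnings(pf(f, df1, df2, 0)) < target) return(0)
    g <- function(ncp) suppressWarnings(pf(f, df1, df2, ncp)) - target
    tryCatch(uniroot(g, c(0, 10 * (f * df1 + df1 + df2)),
                     extendInt = "downX")$root,
             error = function(e) NA_real_)
  }
  lam <- c(bound(0.975), bound(0.025))
  lam <- pmax(lam, 0)
  lam / (lam + df1 + df2 + 1)
}

kendall_w_boot_ci <- function(values, n_boot, seed) {
  set.seed(seed)
  n <- nrow(values); k <- ncol(values)
  ws <- vapply(seq_len(n_boot), function(b) {
    v <- values[sample.int(n, replace = TRUE), , drop = FALSE]
    ht <- suppressWarnings(friedman.test(v))
    s <- unname(ht$statistic) / (n * (k - 1))
    if (is.finite(s)) s else 0
  }, 0)
  unname(quantile(ws, c(0.025, 0.975)))
}

#' Bonferroni-Holm step-down adjustment
#'
#' Thin wrapper around `p.adjust(..., method = "holm")`: monotone, capped at
#' 1, invariant to input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values in the input order.
#' @export
holm_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "holm")
}

#' Monte-Carlo power of the paired comparison
#'
#' Simulates normally distributed paired differences with standardized mean
#' `effect_d` and estimates the rejection rate at each sample size in
#' `n_grid`. The test family is a parameter: the plain paired t-test, the
#' Wilcoxon signed-rank test, or the full assumption-gated branch used by
#' [paired_compare()].
#'
#' @param effect_d Standardized effect size (Cohen's dz) of the simulated
#'   differences; 0 simulates the null.
#' @param alpha Significance level. Default 0.05.
#' @param n_grid Integer vector of sample sizes.
#' @param n_sims Simulations per sample size.
#' @param seed Integer seed.
#' @param tail `"two.sided"` or `"greater"`.
#' @param test `"t"`, `"wilcoxon"` or `"gated"`.
#' @return `data.frame(n, power)`.
#' @export
power_simulation <- function(effect_d, alpha = 0.05, n_grid = 30,
                             n_sims = 10000, seed = 1,
                             tail = c("two.sided", "greater"),
                             test = c("t", "wilcoxon", "gated")) {
  tail <- match.arg(tail); test <- match.arg(test)
  if (effect_d < 0) stop("effect_d must be non-negative")
  set.seed(seed)
  power <- vapply(n_grid, function(n) {
    if (test == "t") {
      d <- matrix(rnorm(n * n_sims, mean = effect_d), nrow = n)
      m <- colMeans(d)
      s <- sqrt((colSums(d^2) - n * m^2) / (n - 1))
      tstat <- m / (s / sqrt(n))
      p <- if (tail == "two.sided")
        2 * pt(abs(tstat), n - 1, lower.tail = FALSE)
      else pt(tstat, n - 1, lower.tail = FALSE)
      mean(p < alpha)
    } else {
      hits <- 0L
      for (b in seq_len(n_sims)) {
        d <- rnorm(n, mean = effect_d)
        p <- if (test == "wilcoxon")
          suppressWarnings(wilcox.test(d, alternative = tail)$p.value)
        else paired_compare(d, rep(0, n), tail = tail)$p_raw
        if (p < alpha) hits <- hits + 1L
      }
      hits / n_sims
    }
  }, 0)
  data.frame(n = n_grid, power = power)
}
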