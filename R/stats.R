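#' Statistical test result container
#'
#' @param test_name label of the test.
#' @param statistic test statistic (H for Kruskal-Wallis, F for factorial
#'   ANOVA on ranks, W/V for rank-sum).
#' @param df degrees of freedom (scalar or pair).
#' @param p_value raw p value.
#' @param p_adjusted multiplicity-adjusted p (defaults to the raw value).
#' @param alpha significance level.
#' @param comparison optional label, e.g. "A-B" for a pairwise contrast.
#' @return An object of class `stat_result`.
#' @export
stat_result <- function(test_name, statistic, df, p_value,
                        p_adjusted = p_value, alpha = 0.05,
                        comparison = NA_character_) {
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value out of [0, 1]")
  }
  structure(list(test_name = test_name, statistic = statistic, df = df,
                 p_value = p_value, p_adjusted = p_adjusted, alpha = alpha,
                 comparison = comparison),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  dfs <- paste(x$df, collapse = ",")
  pshow <- function(p) if (!is.na(p) && p < 1e-3) "<0.001" else sprintf("%.4g", p)
  cmp <- if (!is.na(x$comparison)) sprintf(" [%s]", x$comparison) else ""
  cat(sprintf("%s%s: statistic = %.4g, df = %s, p = %s (adj. %s)\n",
              x$test_name, cmp, x$statistic, dfs, pshow(x$p_value),
              pshow(x$p_adjusted)))
  invisible(x)
}

# tie-corrected Kruskal-Wallis H on midranks (used by the permutation path)
kw_statistic <- function(values, g) {
  r <- rank(values)
  n <- length(values)
  sums <- tapply(r, g, sum)
  ns <- tapply(r, g, length)
  h <- 12 / (n * (n + 1)) * sum(sums^2 / ns) - 3 * (n + 1)
  ties <- table(values)
  corr <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (corr <= 0) return(0)  # all values tied
  h / corr
}

#' Kruskal-Wallis omnibus test
#'
#' Nonparametric one-way omnibus test on midranks with tie correction.
#' The p value comes from the chi-square approximation (df = k - 1) or,
#' optionally, from a label-permutation null of the same H statistic.
#' If every observation is identical, H = 0 and p = 1 by convention.
#'
#' @param groups list of two or more numeric vectors (each n >= 2).
#' @param p_method `"chisq"` (default) or `"permutation"`.
#' @param n_perm permutations when `p_method = "permutation"`.
#' @param alpha significance level recorded in the result.
#' @return A `stat_result` with statistic H and df = k - 1.
#' @export
kruskal_wallis <- function(groups, p_method = c("chisq", "permutation"),
                           n_perm = 10000L, alpha = 0.05) {
  p_method <- match.arg(p_method)
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 1L)) stop("empty group")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), lengths(groups)))
  k <- length(groups)
  if (length(unique(values)) == 1L) {
    return(stat_result("Kruskal-Wallis", 0, k - 1L, 1, alpha = alpha))
  }
  h <- kw_statistic(values, g)
  p <- if (p_method == "chisq") {
    stats::pchisq(h, df = k - 1L, lower.tail = FALSE)
  } else {
    ge <- 0L
    for (b in seq_len(n_perm)) {
      hp <- kw_statistic(values, sample(g))
      if (hp >= h - 1e-12) ge <- ge + 1L
    }
    (ge + 1) / (n_perm + 1)
  }
  stat_result("Kruskal-Wallis", h, k - 1L, p, alpha = alpha)
}

#' Pairwise post hoc comparisons after an omnibus test
#'
#' Either Tukey's HSD applied to the rank-transformed data (studentized-range
#' p values) or pairwise two-sided rank-sum tests; in both cases the p values
#' are then Bonferroni-adjusted across the k(k-1)/2 comparisons.
#'
#' @param groups named (or unnamed) list of numeric samples.
#' @param method `"tukey_on_ranks"` or `"rank_sum"`.
#' @param alpha significance level recorded in the results.
#' @return A list of `stat_result`, one per pair, each carrying `p_adjusted`.
#' @export
posthoc_pairwise <- function(groups, method = c("tukey_on_ranks", "rank_sum"),
                             alpha = 0.05) {
  method <- match.arg(method)
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  nm <- names(groups)
  if (is.null(nm)) nm <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(nm, lengths(groups)), levels = nm)
  pairs <- utils::combn(nm, 2)
  if (method == "tukey_on_ranks") {
    if (length(unique(values)) == 1L) {
      res <- lapply(seq_len(ncol(pairs)), function(j) {
        stat_result("Tukey HSD on ranks", 0, NA, 1, 1, alpha,
                    paste(pairs[2, j], pairs[1, j], sep = "-"))
      })
      return(res)
    }
    r <- rank(values)
    fit <- stats::aov(r ~ g)
    tk <- stats::TukeyHSD(fit)$g
    praw <- tk[, "p adj"]
    padj <- adjust_bonferroni(pmin(1, praw))
    res <- lapply(seq_len(nrow(tk)), function(j) {
      stat_result("Tukey HSD on ranks", tk[j, "diff"],
                  c(length(nm) - 1L, length(values) - length(nm)),
                  praw[j], padj[j], alpha, rownames(tk)[j])
    })
  } else {
    praw <- numeric(ncol(pairs))
    stats_w <- numeric(ncol(pairs))
    for (j in seq_len(ncol(pairs))) {
      rs <- rank_sum(groups[[pairs[1, j]]], groups[[pairs[2, j]]])
      praw[j] <- rs$p_value
      stats_w[j] <- rs$statistic
    }
    padj <- adjust_bonferroni(praw)
    res <- lapply(seq_len(ncol(pairs)), function(j) {
      stat_result("rank-sum", stats_w[j], NA, praw[j], padj[j], alpha,
                  paste(pairs[2, j], pairs[1, j], sep = "-"))
    })
  }
  res
}

#' Align responses for one effect of a two-factor design
#'
#' Aligned-rank-transform alignment: the cell-mean residual plus the
#' estimated effect of interest only. After aligning for effect X, a
#' standard two-way ANOVA on the (unranked) aligned data has sums of squares
#' ~0 for every effect other than X in a balanced design.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced).
#' @param effect `"A"`, `"B"`, or `"AB"`.
#' @return Numeric vector of aligned responses.
#' @export
art_align <- function(values, factor_a, factor_b,
                      effect = c("A", "B", "AB")) {
  effect <- match.arg(effect)
  fa <- factor(factor_a); fb <- factor(factor_b)
  grand <- mean(values)
  cellm <- stats::ave(values, fa, fb, FUN = mean)
  am <- stats::ave(values, fa, FUN = mean)
  bm <- stats::ave(values, fb, FUN = mean)
  resid <- values - cellm
  switch(effect,
         A = resid + am - grand,
         B = resid + bm - grand,
         AB = resid + cellm - am - bm + grand)
}

#' Aligned-rank-transform two-way factorial analysis
#'
#' Nonparametric factorial omnibus: for each effect (A, B, and the A x B
#' interaction) the response is aligned for that effect, midranked, and a
#' two-way fixed-effects factorial ANOVA is run on the ranks; only the row
#' for the aligned effect is interpreted. Requires a complete crossed layout
#' with at least 2 replicates per cell.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factors (coerced).
#' @param alpha significance level recorded in the results.
#' @return A named list of three `stat_result` objects (`A`, `B`, `AB`) with
#'   F statistics and (numerator, denominator) df.
#' @export
art_anova_2way <- function(values, factor_a, factor_b, alpha = 0.05) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  tab <- table(fa, fb)
  if (any(tab < 2L)) {
    bad <- which(tab < 2L, arr.ind = TRUE)
    stop("incomplete design: cell(s) ",
         paste(sprintf("(%s, %s)", rownames(tab)[bad[, 1]],
                       colnames(tab)[bad[, 2]]), collapse = ", "),
         " have fewer than 2 replicates")
  }
  effects <- c(A = "A", B = "B", AB = "AB")
  rows <- c(A = 1L, B = 2L, AB = 3L)
  out <- lapply(names(effects), function(ef) {
    if (stats::var(values) == 0) {
      df1 <- switch(ef, A = nlevels(fa) - 1L, B = nlevels(fb) - 1L,
                    AB = (nlevels(fa) - 1L) * (nlevels(fb) - 1L))
      return(stat_result(paste0("ART ", ef), 0,
                         c(df1, length(values) - nlevels(fa) * nlevels(fb)),
                         1, alpha = alpha))
    }
    al <- art_align(values, fa, fb, ef)
    r <- rank(al)
    an <- stats::anova(stats::lm(r ~ fa * fb))
    i <- rows[[ef]]
    fstat <- an[i, "F value"]
    if (!is.finite(fstat)) fstat <- 0
    p <- an[i, "Pr(>F)"]
    if (!is.finite(p)) p <- 1
    stat_result(paste0("ART ", ef), fstat,
                c(an[i, "Df"], an[4, "Df"]), p, alpha = alpha)
  })
  names(out) <- names(effects)
  out
}

#' Two-sided rank-sum test
#'
#' Wilcoxon rank-sum (unpaired) or signed-rank (paired), two-sided, midranks
#' with tie correction; the exact null distribution is used for combined
#' n <= 12 without ties, otherwise the normal approximation with continuity
#' correction. Identical paired samples return p = 1.
#'
#' @param x,y numeric samples (each n >= 2; equal length when paired).
#' @param paired logical.
#' @param alpha significance level recorded in the result.
#' @return A `stat_result` with statistic W (or V when paired).
#' @export
rank_sum <- function(x, y, paired = FALSE, alpha = 0.05) {
  if (length(x) < 2L || length(y) < 2L) stop("need n >= 2 per sample")
  if (paired && length(x) != length(y)) {
    stop("paired samples must have equal length")
  }
  if (paired && all(x == y)) {
    return(stat_result("Wilcoxon signed-rank", 0, NA, 1, alpha = alpha))
  }
  nn <- length(x) + length(y)
  exact <- if (paired) {
    d <- x - y
    nn <= 12L && !any(d == 0) && !any(duplicated(abs(d)))
  } else {
    nn <= 12L && !any(duplicated(c(x, y)))
  }
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, paired = paired, exact = exact, correct = TRUE)
  )
  stat_result(if (paired) "Wilcoxon signed-rank" else "Wilcoxon rank-sum",
              unname(wt$statistic), NA, wt$p.value, alpha = alpha)
}

#' Bonferroni correction
#'
#' Each p value is multiplied by the number of comparisons and capped at 1;
#' order is preserved.
#'
#' @param p_values numeric vector in [0, 1].
#' @return Adjusted p values, same length and order.
#' @export
adjust_bonferroni <- function(p_values) {
  p_values <- as.numeric(p_values)
  if (any(is.na(p_values)) || any(p_values < 0 | p_values > 1)) {
    stop("p values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Agreement result container
#'
#' @param icc intraclass correlation (may be NA when only Bland-Altman
#'   quantities are computed).
#' @param bias mean difference a - b.
#' @param loa_low,loa_high 95% limits of agreement (bias -/+ 1.96 SD of the
#'   differences).
#' @param n_pairs number of pairs.
#' @param ... further fields (e.g. `slope`, `means`, `differences`,
#'   `icc_consistency`).
#' @return An object of class `agreement_result`.
#' @export
agreement_result <- function(icc, bias, loa_low, loa_high, n_pairs, ...) {
  if (loa_low > bias + 1e-12 || loa_high < bias - 1e-12) {
    stop("limits of agreement must bracket the bias")
  }
  structure(c(list(icc = icc, bias = bias, loa_low = loa_low,
                   loa_high = loa_high, n_pairs = n_pairs), list(...)),
            class = "agreement_result")
}

#' @export
print.agreement_result <- function(x, ...) {
  if (!is.na(x$icc)) cat(sprintf("ICC(A,1) = %.3f  ", x$icc))
  cat(sprintf("bias = %.4g, 95%% LoA [%.4g, %.4g], n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n_pairs))
  invisible(x)
}

#' Two-way single-score agreement ICC
#'
#' ICC(A,1): two-way (subjects x raters), absolute-agreement, single-rater
#' intraclass correlation, from the mean squares of the two-way layout:
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with k = 2 raters.
#' The consistency form ICC(C,1) is also returned for reference.
#'
#' @param rater1,rater2 paired numeric scores (n >= 3).
#' @param alpha significance level (unused, carried for reporting symmetry).
#' @return An `agreement_result` with `icc`, `icc_consistency`, and the
#'   Bland-Altman quantities for the same pairs.
#' @export
icc_agreement <- function(rater1, rater2, alpha = 0.05) {
  if (length(rater1) != length(rater2)) stop("paired scores required")
  n <- length(rater1)
  if (n < 3L) stop("need at least 3 subjects")
  y <- c(rater1, rater2)
  if (stats::var(y) == 0) stop("constant scores: ICC undefined")
  subj <- factor(rep(seq_len(n), 2))
  rater <- factor(rep(1:2, each = n))
  # identical raters give a perfect fit; the mean squares remain valid
  an <- suppressWarnings(stats::anova(stats::lm(y ~ subj + rater)))
  msr <- an["subj", "Mean Sq"]
  msc <- an["rater", "Mean Sq"]
  mse <- an["Residuals", "Mean Sq"]
  k <- 2
  icc_a <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  icc_c <- (msr - mse) / (msr + (k - 1) * mse)
  ba <- bland_altman(rater1, rater2)
  agreement_result(icc = icc_a, bias = ba$bias, loa_low = ba$loa_low,
                   loa_high = ba$loa_high, n_pairs = n,
                   icc_consistency = icc_c)
}

#' Bland-Altman agreement analysis
#'
#' Differences `d = a - b`: bias = mean(d), 95% limits of agreement
#' bias +/- 1.96 * SD(d) (sample SD), plus the proportional-bias slope (the
#' least-squares slope of d on the pairwise means) and the (mean, difference)
#' pairs for plotting.
#'
#' @param a,b paired numeric measurements (n >= 2).
#' @return An `agreement_result` with `slope`, `means` and `differences`.
#' @export
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop("paired measurements required")
  if (length(a) < 2L) stop("need at least 2 pairs")
  d <- a - b
  m <- (a + b) / 2
  bias <- mean(d)
  s <- stats::sd(d)
  slope <- if (stats::var(m) == 0) 0 else
    unname(stats::coef(stats::lm(d ~ m))[2])
  agreement_result(icc = NA_real_, bias = bias,
                   loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                   n_pairs = length(a), slope = slope, means = m,
                   differences = d)
}

#' @export
plot.agreement_result <- function(x, ...) {
  if (is.null(x$means)) stop("no plotting data stored in this result")
  graphics::plot(x$means, x$differences, xlab = "mean of pair",
                 ylab = "difference", main = "Bland-Altman", ...)
  graphics::abline(h = c(x$loa_low, x$bias, x$loa_high), lty = c(2, 1, 2))
  invisible(x)
}

#' Normality and homogeneity-of-variance gate
#'
#' Shapiro-Wilk per group and Bartlett's test pooled; emits a recommendation
#' flag (parametric vs nonparametric) at the given alpha. The pipeline logs
#' the recommendation but never switches tests automatically.
#'
#' @param groups list of numeric samples, each n >= 3.
#' @param alpha significance level for the gate (default 0.05).
#' @return A list with `shapiro_p` (per group), `bartlett_p`, and
#'   `recommendation`.
#' @export
normality_variance_gate <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2L) stop("need >= 2 groups")
  if (any(vapply(groups, length, integer(1)) < 3L)) {
    stop("each group needs n >= 3")
  }
  sw <- vapply(groups, function(g) {
    if (length(unique(g)) == 1L) return(0)  # degenerate: flag non-normal
    stats::shapiro.test(g)$p.value
  }, numeric(1))
  values <- unlist(groups, use.names = FALSE)
  gf <- factor(rep(seq_along(groups), lengths(groups)))
  bt <- stats::bartlett.test(values, gf)$p.value
  rec <- if (any(sw < alpha) || bt < alpha) "nonparametric" else "parametric"
  list(shapiro_p = sw, bartlett_p = bt, recommendation = rec, alpha = alpha)
}
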