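test_that("Kruskal-Wallis matches the exhaustive assignment oracle", {
  groups <- list(c(1, 2, 3), c(4, 5, 6), c(7, 8, 9))
  res <- kruskal_wallis(groups)
  expect_equal(res$statistic, 7.2, tolerance = 1e-10)
  expect_equal(res$df, 2L)
  # oracle: every way to assign the 9 values to groups of 3/3/3
  vals <- unlist(groups)
  h_obs <- oracle_kw_h(vals, factor(rep(1:3, each = 3)))
  count <- 0L; total <- 0L
  for (g1 in utils::combn(9, 3, simplify = FALSE)) {
    rest <- setdiff(1:9, g1)
    for (g2 in utils::combn(rest, 3, simplify = FALSE)) {
      g <- integer(9); g[g1] <- 1L; g[g2] <- 2L; g[setdiff(rest, g2)] <- 3L
      if (oracle_kw_h(vals, factor(g)) >= h_obs - 1e-12) count <- count + 1L
      total <- total + 1L
    }
  }
  p_exact <- count / total
  set.seed(5)
  p_perm <- kruskal_wallis(groups, p_method = "permutation",
                           n_perm = 20000L)$p_value
  expect_lt(abs(p_perm - p_exact), 3 * sqrt(p_exact * (1 - p_exact) / 20000) +
              1e-4)
  # chi-square approximation is within its documented small-sample slack
  expect_lt(abs(res$p_value - p_exact), 0.05)
})

test_that("Kruskal-Wallis handles degeneracy and matches rank-sum at k = 2", {
  expect_equal(kruskal_wallis(list(rep(3, 5), rep(3, 4)))$p_value, 1)
  expect_equal(kruskal_wallis(list(rep(3, 5), rep(3, 4)))$statistic, 0)
  set.seed(21)
  for (i in 1:50) {
    x <- stats::rnorm(8); y <- stats::rnorm(7, mean = stats::runif(1, 0, 2))
    pk <- kruskal_wallis(list(x, y))$p_value
    pw <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE,
                                              correct = FALSE))$p.value
    expect_lt(abs(pk - pw), 0.03)
  }
})

test_that("Kruskal-Wallis type-I error is calibrated at alpha = 0.05", {
  set.seed(1234)
  rej <- 0L
  for (i in 1:2000) {
    g <- lapply(1:4, function(j) stats::rnorm(10))
    if (kruskal_wallis(g)$p_value < 0.05) rej <- rej + 1L
  }
  expect_gte(rej / 2000, 0.03)
  expect_lte(rej / 2000, 0.07)
})

test_that("post hoc comparisons count pairs and respect separation", {
  g4 <- list(a = 1:4, b = 2:5, c = 3:6, d = 4:7)
  expect_length(posthoc_pairwise(g4, "rank_sum"), 6L)
  same <- posthoc_pairwise(list(a = rep(1, 4), b = rep(1, 4)),
                           "tukey_on_ranks")
  expect_true(all(vapply(same, function(s) s$p_adjusted, numeric(1)) == 1))
  sep <- list(a = 1:5, b = 101:105, c = 201:205)
  for (method in c("tukey_on_ranks", "rank_sum")) {
    ps <- vapply(posthoc_pairwise(sep, method),
                 function(s) s$p_adjusted, numeric(1))
    expect_true(all(ps < 0.05))
  }
})

test_that("ART alignment zeroes the other effects", {
  set.seed(31)
  d <- expand.grid(a = factor(1:2), b = factor(1:3), rep = 1:5)
  d$y <- stats::rnorm(nrow(d)) + 2 * as.numeric(d$a) + as.numeric(d$b) +
    1.5 * (d$a == 1 & d$b == 2)
  for (ef in c("A", "B", "AB")) {
    al <- art_align(d$y, d$a, d$b, ef)
    an <- stats::anova(stats::lm(al ~ d$a * d$b))
    ss <- an[1:3, "Sum Sq"]
    names(ss) <- c("A", "B", "AB")
    others <- ss[setdiff(c("A", "B", "AB"), ef)]
    expect_lt(max(others) / sum(an[, "Sum Sq"]), 1e-8)
  }
})

test_that("ART detects main effects and interactions it should", {
  # pure main effect of A: F_A large, interaction quiet on average
  set.seed(55)
  pa <- pint <- numeric(100)
  for (i in 1:100) {
    d <- expand.grid(a = factor(1:2), b = factor(1:2), rep = 1:5)
    d$y <- 2 * (d$a == 2) + stats::rnorm(nrow(d))
    res <- art_anova_2way(d$y, d$a, d$b)
    pa[i] <- res$A$p_value
    pint[i] <- res$AB$p_value
  }
  expect_gt(mean(pa < 0.01), 0.9)
  expect_gt(mean(pint), 0.1)
  # 2 x 3 with a pure 2-SD interaction contrast: detected in >= 80%
  set.seed(77)
  hit <- 0L
  for (i in 1:100) {
    d <- expand.grid(a = factor(1:2), b = factor(1:3), rep = 1:5)
    ac <- ifelse(d$a == 2, 1, -1)
    bc <- c(-1, 0, 1)[as.integer(d$b)]
    d$y <- stats::rnorm(nrow(d)) + 2 * ac * bc
    if (art_anova_2way(d$y, d$a, d$b)$AB$p_value < 0.05) hit <- hit + 1L
  }
  expect_gte(hit / 100, 0.8)
  # degenerate and incomplete designs
  d <- expand.grid(a = factor(1:2), b = factor(1:2), rep = 1:3)
  d$y <- 1
  res0 <- art_anova_2way(d$y, d$a, d$b)
  expect_true(all(vapply(res0, function(r) r$p_value, numeric(1)) == 1))
  drop <- which(d$a == 1 & d$b == 1)[1:2]  # leave that cell one replicate
  expect_error(art_anova_2way(d$y[-drop], d$a[-drop], d$b[-drop]),
               "incomplete")
})

test_that("rank-sum uses the exact small-sample distribution", {
  res <- rank_sum(c(1, 2, 3), c(10, 20, 30))
  # enumeration oracle over all C(6,3) = 20 assignments of ranks to x
  vals <- c(1, 2, 3, 10, 20, 30)
  w_obs <- sum(rank(vals)[1:3]) - 6
  ws <- vapply(utils::combn(6, 3, simplify = FALSE),
               function(ix) sum(rank(vals)[ix]) - 6, numeric(1))
  p_exact <- mean(abs(ws - 4.5) >= abs(w_obs - 4.5))
  expect_equal(res$p_value, p_exact)
  expect_equal(res$p_value, 0.1)
  expect_equal(rank_sum(c(1, 2, 3, 4), c(1, 2, 3, 4), paired = TRUE)$p_value,
               1)
  expect_error(rank_sum(1:3, 1:4, paired = TRUE), "equal length")
  set.seed(13)
  x <- stats::rnorm(20); y <- stats::rnorm(20, mean = 2)
  expect_lt(rank_sum(x, y)$p_value, 0.05)
})

test_that("Bonferroni correction is the capped multiply", {
  expect_equal(adjust_bonferroni(c(0.01, 0.02, 0.03, 0.04, 0.05)),
               c(0.05, 0.10, 0.15, 0.20, 0.25))
  expect_equal(adjust_bonferroni(c(0.5, 0.5, 0.5)), c(1, 1, 1))
  expect_equal(adjust_bonferroni(0.3), 0.3)
  set.seed(3)
  p <- stats::runif(20)
  adj <- adjust_bonferroni(p)
  expect_true(all(adj >= p))
  expect_true(all(diff(adj[order(p)]) >= 0))  # monotone in the raw p
  expect_error(adjust_bonferroni(c(0.5, 1.2)), "0, 1")
})

test_that("agreement ICC behaves as the two-way absolute-agreement form", {
  set.seed(8)
  r1 <- stats::rnorm(20, 10, 2)
  expect_equal(icc_agreement(r1, r1)$icc, 1.0)
  shifted <- icc_agreement(r1, r1 + 3)
  expect_lt(shifted$icc, shifted$icc_consistency)
  # variance-component recovery: sigma_s^2 = 4, sigma_e^2 = 1 -> 0.8
  for (seed in c(101, 202, 303)) {
    ap <- make_agreement_pairs(n = 200, subject_sd = 2, error_sd = 1,
                               seed = seed)
    est <- icc_agreement(ap$table$rater1, ap$table$rater2)$icc
    expect_lt(abs(est - 0.8), 0.05)
  }
  expect_error(icc_agreement(rep(1, 5), rep(1, 5)), "constant")
})

test_that("Bland-Altman bias, limits and slope are exact on constructions", {
  a <- c(1, 2, 3, 4, 5)
  same <- bland_altman(a, a)
  expect_equal(same$bias, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))
  expect_equal(same$slope, 0)
  off <- bland_altman(a, a + 1)
  expect_equal(off$bias, -1)
  expect_equal(off$loa_high - off$loa_low, 0)
  x <- seq(1, 10, length.out = 20)
  prop <- bland_altman(x, 1.1 * x)
  d <- x - 1.1 * x; m <- (x + 1.1 * x) / 2
  slope_ls <- unname(stats::coef(stats::lm(d ~ m))[2])
  expect_equal(prop$slope, slope_ls)
  expect_lt(prop$slope, -1e-3)  # proportional bias is detectable
})

test_that("normality and variance gating match their nominal rates", {
  set.seed(99)
  rej <- 0L
  for (i in 1:200) {
    if (stats::shapiro.test(stats::rnorm(50))$p.value < 0.05) rej <- rej + 1L
  }
  expect_gt(rej / 200, 0.005)
  expect_lt(rej / 200, 0.12)
  hits <- 0L
  for (i in 1:100) {
    g <- list(stats::rexp(50), stats::rnorm(50, 1), stats::rnorm(50, 1))
    if (normality_variance_gate(g)$recommendation == "nonparametric") {
      hits <- hits + 1L
    }
  }
  expect_gt(hits / 100, 0.9)
  bart_ok <- 0L
  for (i in 1:100) {
    g <- list(stats::rnorm(30), stats::rnorm(30), stats::rnorm(30))
    if (normality_variance_gate(g)$bartlett_p > 0.05) bart_ok <- bart_ok + 1L
  }
  expect_gt(bart_ok / 100, 0.85)
  expect_error(normality_variance_gate(list(1:2, 1:5)), "n >= 3")
})
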