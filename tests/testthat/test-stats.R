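test_that("the normality gate routes by per-group Shapiro-Wilk", {
  set.seed(52)
  v_norm <- rnorm(300)
  grp <- rep(c("A", "B", "C"), each = 100)
  expect_equal(normality_gate(v_norm, grp)$route, "parametric")

  v_skew <- v_norm
  v_skew[grp == "B"] <- rlnorm(100, 0, 1.5)
  expect_equal(normality_gate(v_skew, grp)$route, "nonparametric")

  v_const <- v_norm; v_const[grp == "C"] <- 1
  g <- normality_gate(v_const, grp)
  expect_equal(g$route, "nonparametric")
  expect_true(is.na(g$shapiro_p["C"]))

  expect_error(normality_gate(c(1, 2, 1, 2), c("A", "A", "B", "B")), "n >= 3")
})

test_that("Kruskal-Wallis H matches the rank-formula oracle", {
  # symmetric case: identical groups
  v <- rep(c(1, 2, 3), 3)
  g <- rep(c("A", "B", "C"), each = 3)
  r <- kruskal_dunn(v, g)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_overall, 1)

  set.seed(51)
  for (i in 1:5) {
    vv <- round(rnorm(24), 1)        # rounding induces occasional ties
    gg <- sample(rep(c("A", "B", "C"), each = 8))
    expect_equal(kruskal_dunn(vv, gg)$statistic, kw_h_oracle(vv, gg),
                 tolerance = 1e-10)
  }
  # fully separated groups, no ties: H from the oracle
  v2 <- 1:9; g2 <- rep(c("A", "B", "C"), each = 3)
  expect_equal(kruskal_dunn(v2, g2)$statistic, kw_h_oracle(v2, g2),
               tolerance = 1e-12)
  expect_error(kruskal_dunn(rep(1, 9), g2), "identical")
})

test_that("H is invariant under strictly monotone transforms", {
  set.seed(52)
  v <- rnorm(30); g <- sample(rep(c("A", "B", "C"), each = 10))
  h0 <- kruskal_dunn(v, g)$statistic
  expect_equal(kruskal_dunn(exp(v), g)$statistic, h0, tolerance = 1e-12)
  expect_equal(kruskal_dunn(v^3, g)$statistic, h0, tolerance = 1e-12)
})

test_that("chi-square p approximates the exact permutation p at small n", {
  cases <- list(c(4.4, 0.2, 0.6, 8.1, 7.3, 0.9, 6.3),
                c(3, 10, 6.5, 3.4, 2.5, 1.9, 2.3),
                c(5.2, 6.6, 9.2, 1.5, 9.3, 9.5, 1.1))
  for (v in cases) {
    sizes <- c(3, 2, 2)
    g <- rep(c("A", "B", "C"), sizes)
    p_pkg <- kruskal_dunn(v, g)$p_overall
    p_ex <- exact_kw_p(v, sizes)
    expect_lt(abs(p_pkg - p_ex), 0.02)
  }
})

test_that("Dunn z statistics match a hand computation with ties", {
  v <- c(1, 2, 2, 4, 5, 6, 6, 8, 9)
  g <- rep(c("A", "B", "C"), each = 3)
  r <- kruskal_dunn(v, g)
  # by hand: pooled ranks with tie averaging
  rk <- rank(v)
  N <- 9
  ties <- table(v)
  v0 <- N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1))
  z_ab <- (mean(rk[g == "A"]) - mean(rk[g == "B"])) / sqrt(v0 * (2 / 3))
  row_ab <- r$pairwise[r$pairwise$group1 == "A" & r$pairwise$group2 == "B", ]
  expect_equal(row_ab$z, z_ab, tolerance = 1e-12)
  expect_equal(row_ab$p_adj, min(1, 3 * 2 * pnorm(-abs(z_ab))),
               tolerance = 1e-12)
  expect_true(all(r$pairwise$p_adj >= r$pairwise$p_raw))
})

test_that("ANCOVA reduces to classical identities without covariates", {
  set.seed(53)
  v <- rnorm(40, mean = rep(c(0, 1), each = 20))
  g <- rep(c("A", "B"), each = 20)
  r <- ancova_bonferroni(v, g)
  tt <- t.test(v ~ g, var.equal = TRUE)
  expect_equal(r$statistic, unname(tt$statistic)^2, tolerance = 1e-10)
  # and equals one-way ANOVA F for 3 groups
  v3 <- rnorm(60); g3 <- rep(c("A", "B", "C"), each = 20)
  r3 <- ancova_bonferroni(v3, g3)
  expect_equal(r3$statistic, unname(summary(aov(v3 ~ g3))[[1]]$`F value`[1]),
               tolerance = 1e-10)
})

test_that("ANCOVA detects a planted one-SD group offset with high power", {
  set.seed(54)
  rejections <- replicate(200, {
    g <- rep(c("A", "B", "C"), each = 50)
    cov1 <- rnorm(150)
    shift <- c(A = 0, B = 1, C = 0)[g]
    y <- shift + 0.8 * cov1 + rnorm(150)
    ancova_bonferroni(y, g, data.frame(cov1 = cov1),
                      pairwise = FALSE)$p_overall < 0.05
  })
  expect_gt(mean(rejections), 0.9)
})

test_that("ANCOVA rejects rank-deficient designs naming the culprit", {
  v <- rnorm(30); g <- rep(c("A", "B", "C"), each = 10)
  cov_bad <- data.frame(dup = as.numeric(g == "B") + as.numeric(g == "C") * 2)
  cov_bad$dup2 <- cov_bad$dup
  expect_error(ancova_bonferroni(v, g, cov_bad), "collinear.*dup2")
})

test_that("partial correlation equals its closed-form matrix formula", {
  set.seed(55)
  n <- 120
  z1 <- rnorm(n); z2 <- rnorm(n)
  x <- 0.5 * z1 - 0.3 * z2 + rnorm(n)
  y <- -0.4 * z1 + 0.6 * z2 + 0.5 * x + rnorm(n)
  covs <- cbind(z1 = z1, z2 = z2)
  pc <- partial_corr(x, y, covs)
  # oracle: partial correlation from the inverse correlation matrix
  R <- cor(cbind(x, y, covs))
  P <- solve(R)
  r_oracle <- -P[1, 2] / sqrt(P[1, 1] * P[2, 2])
  expect_lt(abs(pc$r - r_oracle), 1e-10)
  expect_equal(pc$r_squared, pc$r^2)
  # symmetry in (x, y)
  expect_equal(partial_corr(y, x, covs)$r, pc$r, tolerance = 1e-12)
  # no covariates: plain Pearson
  pc0 <- partial_corr(x, y)
  expect_equal(pc0$r, cor(x, y), tolerance = 1e-12)
  expect_equal(pc0$p, cor.test(x, y)$p.value, tolerance = 1e-9)
  # y = x gives r = 1
  expect_equal(partial_corr(x, x + 0, covs)$r, 1, tolerance = 1e-12)
  expect_error(partial_corr(z1, y, cbind(z1)), "zero residual")
})

test_that("Spearman correlation equals tie-averaged rank correlation", {
  set.seed(56)
  x <- rnorm(25)
  expect_equal(spearman_corr(x, exp(x))$r, 1)
  expect_equal(spearman_corr(x, -x^3)$r, -1)
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 7, 7, 9)
  sp <- spearman_corr(xt, yt)
  expect_equal(sp$r, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_equal(sp$r, unname(cor.test(xt, yt, method = "spearman",
                                     exact = FALSE)$estimate),
               tolerance = 1e-12)
  expect_error(spearman_corr(rep(1, 5), 1:5), "constant")
})

test_that("chi-square on counts matches the direct formula", {
  prop <- rbind(c(20, 40), c(10, 20))
  r <- chi_square_counts(prop)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p, 1)

  diag2 <- rbind(c(10, 0), c(0, 10))
  expect_equal(chi_square_counts(diag2)$statistic, 20, tolerance = 1e-12)

  expect_error(chi_square_counts(rbind(c(0, 0), c(5, 5))), "margin")
  expect_error(chi_square_counts(rbind(c(1.5, 2), c(3, 4))), "integer")
})

test_that("independent sex draws give approximately uniform chi-square p", {
  set.seed(57)
  ps <- replicate(200, {
    g <- rep(c("A", "B", "C"), times = c(60, 40, 50))
    sex <- rbinom(length(g), 1, 0.45)
    tab <- table(g, sex)
    if (any(colSums(tab) == 0)) return(NA_real_)
    chi_square_counts(tab)$p
  })
  ps <- ps[!is.na(ps)]
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
  expect_gt(suppressWarnings(ks.test(ps, "punif")$p.value), 0.01)
})

test_that("the gated comparison routes variables to the right branch", {
  set.seed(58)
  g <- rep(c("A", "B", "C"), each = 40)
  v_norm <- rnorm(120) + (g == "C")
  r1 <- group_compare(v_norm, g, data.frame(age = rnorm(120)))
  expect_equal(r1$route, "parametric")
  expect_equal(r1$method, "ANCOVA")
  v_skew <- rlnorm(120, 0, 1)
  r2 <- group_compare(v_skew, g)
  expect_equal(r2$route, "nonparametric")
  expect_equal(r2$method, "Kruskal-Wallis")
})
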