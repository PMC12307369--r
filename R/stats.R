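#' Normality-gated routing of group comparisons
#'
#' Applies the Shapiro-Wilk test per group at `alpha`; the comparison of a
#' variable is routed to the parametric branch (ANCOVA) only if every group
#' passes, otherwise to the nonparametric branch (Kruskal-Wallis). Groups
#' with constant values, where the Shapiro-Wilk statistic is undefined, are
#' treated as non-normal and route to the nonparametric branch.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels.
#' @param alpha Significance level of the gate, default 0.05.
#' @return List: `route` (`"parametric"` or `"nonparametric"`) and
#'   `shapiro_p` (named per-group p-values, NA where degenerate).
#' @export
normality_gate <- function(values, groups, alpha = 0.05) {
  groups <- as.factor(groups)
  sp <- vapply(split(values, groups), function(x) {
    if (length(x) < 3) stop("normality gate needs n >= 3 per group")
    if (length(unique(x)) == 1) return(NA_real_)
    stats::shapiro.test(x)$p.value
  }, numeric(1))
  route <- if (all(!is.na(sp)) && all(sp > alpha)) "parametric" else "nonparametric"
  list(route = route, shapiro_p = sp)
}

# Tie-corrected Dunn z statistics over all group pairs, Bonferroni adjusted.
dunn_pairwise <- function(values, groups) {
  groups <- as.factor(groups)
  rk <- rank(values)
  N <- length(values)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  v0 <- N * (N + 1) / 12 - tie_term
  mean_rk <- tapply(rk, groups, mean)
  ns <- tapply(rk, groups, length)
  lv <- levels(groups)
  pairs <- utils::combn(lv, 2)
  m <- ncol(pairs)
  out <- data.frame(group1 = pairs[1, ], group2 = pairs[2, ],
                    z = NA_real_, p_raw = NA_real_, p_adj = NA_real_)
  for (j in seq_len(m)) {
    a <- pairs[1, j]; b <- pairs[2, j]
    se <- sqrt(v0 * (1 / ns[[a]] + 1 / ns[[b]]))
    z <- (mean_rk[[a]] - mean_rk[[b]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    out$z[j] <- z; out$p_raw[j] <- p; out$p_adj[j] <- min(1, m * p)
  }
  out
}

#' Kruskal-Wallis H test with Dunn's post hoc comparisons
#'
#' Overall tie-corrected Kruskal-Wallis H with chi-square p-value
#' (df = k - 1), followed by pairwise Dunn z-tests (tie-corrected,
#' two-sided) Bonferroni-adjusted over all group pairs.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector (>= 2 groups, total n >= 5).
#' @return A `group_test` list: `method`, `statistic` (H), `df`,
#'   `p_overall`, `pairwise` (data frame), `adjustment`.
#' @export
kruskal_dunn <- function(values, groups) {
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2) stop("need at least 2 groups")
  if (length(values) < 5) stop("need total n >= 5")
  if (length(unique(values)) == 1)
    stop("all values identical: H is undefined")
  kt <- stats::kruskal.test(values, groups)
  structure(list(method = "Kruskal-Wallis",
                 statistic = unname(kt$statistic),
                 df = unname(kt$parameter),
                 p_overall = kt$p.value,
                 pairwise = dunn_pairwise(values, groups),
                 adjustment = "Dunn + Bonferroni"),
            class = "group_test")
}

#' ANCOVA with Bonferroni-corrected pairwise contrasts
#'
#' Linear model `value ~ group + covariates`; the overall group effect is
#' the partial F-test of the group factor; pairwise comparisons are
#' contrasts of covariate-adjusted group means (estimated marginal means),
#' Bonferroni-corrected over all pairs. With no covariates this reduces to
#' one-way ANOVA.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector.
#' @param covariates Optional data frame of covariates (numeric columns,
#'   e.g. age, sex coded 0/1, education).
#' @param pairwise If `FALSE`, skip the post hoc contrasts (used in
#'   large-scale calibration runs).
#' @return A `group_test` list: `method`, `statistic` (F), `df`,
#'   `p_overall`, `pairwise`, `adjustment`, `model`.
#' @export
ancova_bonferroni <- function(values, groups, covariates = NULL,
                              pairwise = TRUE) {
  groups <- droplevels(as.factor(groups))
  dat <- data.frame(.y = values, .group = groups)
  cov_names <- character(0)
  if (!is.null(covariates) && ncol(as.data.frame(covariates)) > 0) {
    covariates <- as.data.frame(covariates)
    cov_names <- colnames(covariates)
    dat <- cbind(dat, covariates)
  }
  rhs_red <- if (length(cov_names)) paste(cov_names, collapse = " + ") else "1"
  f_full <- stats::as.formula(paste(".y ~ .group +", rhs_red))
  f_red <- stats::as.formula(paste(".y ~", rhs_red))
  fit <- stats::lm(f_full, data = dat)
  if (any(is.na(stats::coef(fit)))) {
    bad <- names(stats::coef(fit))[is.na(stats::coef(fit))]
    stop("rank-deficient design; collinear terms: ",
         paste(bad, collapse = ", "))
  }
  cmp <- stats::anova(stats::lm(f_red, data = dat), fit)
  Fstat <- cmp$F[2]; p <- cmp$`Pr(>F)`[2]
  pw <- NULL
  if (pairwise) {
    emm <- emmeans::emmeans(fit, ".group")
    ct <- as.data.frame(emmeans::contrast(emm, "pairwise", adjust = "bonferroni"))
    pw <- data.frame(contrast = ct$contrast, estimate = ct$estimate,
                     t = ct$t.ratio, p_adj = ct$p.value)
  }
  structure(list(method = "ANCOVA", statistic = unname(Fstat),
                 df = c(cmp$Df[2], stats::df.residual(fit)),
                 p_overall = p, pairwise = pw,
                 adjustment = "Bonferroni", model = fit),
            class = "group_test")
}

#' @export
print.group_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4f, p = %.4g\n", x$method, x$statistic,
              x$p_overall))
  if (!is.null(x$pairwise)) print(x$pairwise)
  invisible(x)
}

#' Gated group comparison
#'
#' Routes a variable through [normality_gate()] and runs
#' [ancova_bonferroni()] (parametric) or [kruskal_dunn()] (nonparametric).
#'
#' @inheritParams ancova_bonferroni
#' @param alpha Gate significance level.
#' @return A `group_test` with an added `route` element.
#' @export
group_compare <- function(values, groups, covariates = NULL, alpha = 0.05) {
  gate <- normality_gate(values, groups, alpha)
  res <- if (gate$route == "parametric")
    ancova_bonferroni(values, groups, covariates)
  else kruskal_dunn(values, groups)
  res$route <- gate$route
  res$shapiro_p <- gate$shapiro_p
  res
}

residualize <- function(y, Z) {
  stats::lm.fit(Z, y)$residuals
}

#' Partial correlation by residualization
#'
#' Residualizes `x` and `y` on the covariates (with intercept) by least
#' squares and reports the Pearson correlation of the residuals; the
#' p-value uses the t distribution with `n - 2 - k` degrees of freedom,
#' where k is the number of covariate columns. With no covariates this is
#' the plain Pearson correlation.
#'
#' @param x,y Numeric vectors.
#' @param covariates Optional data frame / matrix of covariates.
#' @return A `correlation_result`: `r`, `r_squared`, `p`, `df`,
#'   `n_effective`, `covariates`.
#' @export
partial_corr <- function(x, y, covariates = NULL) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (is.null(covariates)) {
    Z <- matrix(1, n, 1)
    k <- 0L
    cn <- character(0)
  } else {
    covariates <- as.matrix(as.data.frame(covariates))
    Z <- cbind(1, covariates)
    k <- ncol(covariates)
    cn <- colnames(covariates)
  }
  if (n <= k + 2) stop("need n > number of covariates + 2")
  rx <- residualize(x, Z); ry <- residualize(y, Z)
  if (stats::sd(rx) <= 1e-10 * (stats::sd(x) + 1e-300) ||
      stats::sd(ry) <= 1e-10 * (stats::sd(y) + 1e-300))
    stop("zero residual variance after adjusting for the covariates")
  r <- stats::cor(rx, ry)
  df <- n - 2 - k
  tval <- r * sqrt(df / (1 - r^2))
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(tval), df)
  structure(list(r = r, r_squared = r^2, p = p, df = df, n_effective = n,
                 covariates = cn), class = "correlation_result")
}

#' Spearman rank correlation
#'
#' Pearson correlation of tie-averaged ranks; p-value via the t
#' approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length (n >= 3).
#' @return A `correlation_result`.
#' @export
spearman_corr <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y lengths differ")
  if (n < 3) stop("need n >= 3")
  if (length(unique(x)) == 1 || length(unique(y)) == 1)
    stop("constant input: rank correlation undefined")
  r <- stats::cor(rank(x), rank(y))
  df <- n - 2
  p <- if (abs(r) >= 1) 0 else 2 * stats::pt(-abs(r * sqrt(df / (1 - r^2))), df)
  structure(list(r = r, r_squared = r^2, p = p, df = df, n_effective = n,
                 covariates = character(0)), class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.4f (R^2 = %.4f), p = %.4g, df = %d\n",
              x$r, x$r_squared, x$p, x$df))
  invisible(x)
}

#' Pearson chi-square test on a contingency table
#'
#' Without continuity correction; df = (rows - 1)(cols - 1). Intended for
#' sex-by-group tables.
#'
#' @param tab Matrix of nonnegative integer counts with positive margins.
#' @return List: `statistic`, `df`, `p`.
#' @export
chi_square_counts <- function(tab) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be nonnegative integers")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = ct$p.value)
}
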