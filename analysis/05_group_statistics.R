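#!/usr/bin/env Rscript
# The statistical battery on the simulated cohort: Shapiro-Wilk-gated
# group comparisons (ANCOVA with Bonferroni-corrected adjusted-mean
# contrasts, or Kruskal-Wallis with Dunn post hoc tests), chi-square for
# sex, partial correlations of imaging metrics with cognition controlling
# for age, sex, education and total brain volume, and the Spearman
# correlation between ALPS and EPVS burden.
#
# Uses the generator-level cohort table from 01_simulate_cohort.R if
# present, otherwise regenerates it.

library(glymph)

dir.create("results", showWarnings = FALSE)
path <- "results/cohort_truth.tsv"
tab <- if (file.exists(path)) read.delim(path) else
  synth_cohort_table(default_group_configs(), seed = 20260901)

covs <- tab[, c("age", "sex", "education")]
vars <- c(alps = "alps_true", epvs_volume = "epvs_volume_true_mm3",
          epvs_count = "epvs_count_true")
cat("Group comparisons (normality-gated):\n")
cmp_rows <- list()
for (nm in names(vars)) {
  r <- group_compare(tab[[vars[nm]]], tab$group, covs)
  cat(sprintf("  %-12s %-15s statistic %8.3f  p %.4g\n", nm, r$method,
              r$statistic, r$p_overall))
  if (!is.null(r$pairwise)) print(r$pairwise, row.names = FALSE)
  cmp_rows[[nm]] <- data.frame(variable = nm, method = r$method,
                               statistic = r$statistic,
                               p_overall = r$p_overall)
}
write.table(do.call(rbind, cmp_rows), "results/group_comparisons.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)

sex_tab <- table(tab$group, tab$sex)
chi <- chi_square_counts(sex_tab)
cat(sprintf("\nSex by group: chi-square %.3f (df %d), p %.3f\n",
            chi$statistic, chi$df, chi$p))

cat("\nPartial correlations with cognition (age, sex, education, TBV):\n")
pc_covs <- tab[, c("age", "sex", "education", "total_brain_volume")]
for (v in c("alps_true", "epvs_volume_true_mm3")) {
  for (sc in c("mmse", "moca")) {
    pc <- partial_corr(tab[[v]], tab[[sc]], pc_covs)
    cat(sprintf("  %-22s ~ %-5s r %+.3f (R^2 %.3f), p %.4g\n",
                v, sc, pc$r, pc$r_squared, pc$p))
  }
}

sp <- spearman_corr(tab$alps_true, tab$epvs_volume_true_mm3)
cat(sprintf("\nSpearman ALPS ~ EPVS volume: rho %+.3f, p %.4g\n", sp$r, sp$p))
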