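#!/usr/bin/env Rscript
# Stage 5: covariate-adjusted group inference.
#
# Runs the statistical chain on the subject-level metrics: cohort-table
# style tests on demographics (chi-square for sex, Kruskal-Wallis for the
# skewed lesion volumes, ANOVA for the rest), ANCOVA on module densities
# with the standard covariate set (age, sex, education, GM volume, WMH),
# BH-FDR over the nodal metrics at alpha 0.01, post-hoc pairwise contrasts
# for the module densities that survive, and regressions of cognitive
# scores on module densities within diagnostic groups.

library(fcmod)

man <- read.csv("results/cohort/manifest.csv")
metrics <- read.delim("results/metrics/subject_metrics.tsv")
out_file <- "results/inference/group_tests.tsv"
dir.create(dirname(out_file), recursive = TRUE, showWarnings = FALSE)

covs <- data.frame(age = man$age, sex = as.integer(man$sex == "male"),
                   education = man$education_years,
                   gm_volume = man$gm_volume, wmh = man$wmh)
grp <- man$group
rows <- list()
add <- function(name, r, q = NA_real_) {
  rows[[length(rows) + 1]] <<- data.frame(
    term = name, method = r$method, statistic = r$statistic,
    df = paste(r$df, collapse = ","), p = r$p, q = q, effect = r$effect)
}

## cohort-table tests
add("sex", group_compare(man$sex, grp, method = "chi_square"))
add("wmh", group_compare(man$wmh, grp, method = "kruskal_wallis"))
add("pwmh", group_compare(man$pwmh, grp, method = "kruskal_wallis"))
add("age", group_compare(man$age, grp, method = "ancova"))
add("moca", group_compare(man$moca, grp, method = "ancova"))

## module-level densities, covariate-adjusted
mvalue <- function(metric_name, unit_name) {
  sub <- metrics[metrics$metric == metric_name & metrics$unit == unit_name, ]
  sub$value[match(man$subject_id, sub$subject_id)]
}
for (m in c("1", "2", "3", "4"))
  add(paste0("intra_density_m", m), group_compare(mvalue("intra_density", m), grp, covs))
add("inter_density_m1_m2", group_compare(mvalue("inter_density", "1:2"), grp, covs))

## nodal metrics with BH-FDR at 0.01, per metric family
for (fam in c("pc", "wd")) {
  units <- unique(metrics$unit[metrics$metric == fam])
  ps <- vapply(units, function(u) group_compare(mvalue(fam, u), grp, covs)$p, 0)
  fdr <- fdr_correct(ps, q_level = 0.01)
  message(sprintf("%s: %d/%d nodes significant after BH-FDR at 0.01",
                  toupper(fam), sum(fdr$significant), length(units)))
  sig_units <- units[fdr$significant]
  for (u in sig_units[seq_len(min(5, length(sig_units)))])
    add(paste0(fam, "_", u), group_compare(mvalue(fam, u), grp, covs),
        q = fdr$adjusted[match(u, units)])
}

## post-hoc contrasts for the executive-control analogue (module 2)
d2 <- mvalue("intra_density", "2")
for (pair in list(c("HC-high", "HC-low"), c("SVD-MCI", "SVD-NCI")))
  add(paste0("intra_density_m2: ", pair[1], " vs ", pair[2]),
      posthoc_pairwise(d2, grp, pair, covs))

## cognition ~ density regressions within diagnostic groups
nci <- grp == "SVD-NCI"
add("SVD-NCI: visuospatial ~ intra_density_m1",
    regress_metric_on_cognition(man$visuospatial[nci],
                                mvalue("intra_density", "1")[nci], covs[nci, ]))

res <- do.call(rbind, rows)
write.table(res, out_file, sep = "\t", quote = FALSE, row.names = FALSE)
message("inference table written to ", out_file)
sig <- res[!is.na(res$p) & res$p < 0.05, c("term", "method", "statistic", "p")]
sig$statistic <- round(sig$statistic, 2)
sig$p <- signif(sig$p, 2)
message("tests with p < 0.05:")
message(paste(capture.output(print(sig, row.names = FALSE)), collapse = "\n"))
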