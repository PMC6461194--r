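#!/usr/bin/env Rscript
# Stage 2: per-subject connectivity networks.
#
# Reads each subject's ROI time series, applies the signal-cleaning chain
# (linear detrend, 0.01-0.08 Hz zero-phase band-pass at TR = 2 s), computes
# the Fisher-z Pearson connectivity matrix, and writes per-subject matrices
# plus group-averaged matrices for module detection.

library(fcmod)

cohort_dir <- "results/cohort"
out_dir <- "results/connectivity"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

man <- read.csv(file.path(cohort_dir, "manifest.csv"))
groups <- sort(unique(man$group))

z_by_subject <- list()
for (i in seq_len(nrow(man))) {
  ts <- read_timeseries_tsv(file.path(cohort_dir, man$timeseries_path[i]))
  ts <- clean_timeseries(ts, band = c(0.01, 0.08), tr = 2)
  z_by_subject[[man$subject_id[i]]] <- connectivity_from_timeseries(ts)
}

for (g in groups) {
  avg <- group_average(z_by_subject[man$subject_id[man$group == g]])
  write_matrix_tsv(avg, file.path(out_dir, paste0("group_mean_", gsub("[^A-Za-z]", "_", g), ".tsv")))
}
for (sid in names(z_by_subject))
  write_matrix_tsv(z_by_subject[[sid]], file.path(out_dir, paste0(sid, ".tsv")))

zr <- range(vapply(z_by_subject, function(z) max(abs(z[upper.tri(z)])), 0))
message(sprintf("connectivity written for %d subjects (%d groups) to %s",
                length(z_by_subject), length(groups), out_dir))
message(sprintf("  max |z| per subject ranges %.2f-%.2f", zr[1], zr[2]))
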