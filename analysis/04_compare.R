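#!/usr/bin/env Rscript
# Three-system comparison: wild type vs the two humanized variants.
# Generates the three ensembles, runs the full comparison pipeline
# (per-position flexibility, pairwise delta-Neq / delta-PB, flagged
# windows, PB logos, mutation audit) and writes the report.
#
# Problem size: 400 frames per system at 5 deg dihedral noise.
#
# Output: results/comparison/ (per_position.tsv, per_region.tsv,
# pairwise.tsv, logos.json, mutations.tsv, run_log.txt)

# run from the repository root
source(if (file.exists("analysis/00_systems.R")) "analysis/00_systems.R"
       else "00_systems.R")

dir.create("results", showWarnings = FALSE)
sys <- build_study_profiles()
seqs <- study_sequences()

cfg <- comparison_config(
  systems = list(
    wt = list(profiles = sys$wt, n_frames = 400, noise = 5),
    hum = list(profiles = sys$hum, n_frames = 400, noise = 5),
    hum2 = list(profiles = sys$hum2, n_frames = 400, noise = 5)),
  sequences = seqs,
  seed = 20260104)
rep_ <- run_comparison(cfg)
write_report(rep_, "results/comparison")

for (key in names(rep_$pairwise)) {
  pw <- rep_$pairwise[[key]]
  cat(sprintf("%s: max delta-PB %.2f", key, max(pw$table$delta_pb, na.rm = TRUE)))
  if (length(pw$flagged_windows)) {
    cat("; flagged windows:",
        paste(vapply(pw$flagged_windows, function(w) {
          paste0(min(w), "-", max(w))
        }, ""), collapse = ", "))
  } else cat("; no flagged windows")
  cat("\n")
}

cdr1 <- sys$cdr1_window
pw1 <- rep_$pairwise[["wt vs hum"]]$table
cat(sprintf("realized delta-PB (wt vs hum) at positions %s: %s\n",
            paste(range(cdr1), collapse = "-"),
            paste(sprintf("%.2f", pw1$delta_pb[cdr1]), collapse = ", ")))
pw3 <- rep_$pairwise[["hum vs hum2"]]$table
cat(sprintf(paste0("realized delta-PB (hum vs hum2) at position 104: %.2f ",
                   "(analytic 0.50; an isolated single-position switch is ",
                   "attenuated by the generator's overlapping-window ",
                   "averaging)\n"),
            pw3$delta_pb[104]))
print(rep_$correlations, row.names = FALSE)
cat("report written under results/comparison/\n")
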