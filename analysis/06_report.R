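#!/usr/bin/env Rscript
# Aggregate the per-field tables written by analyses 02-05 into
# per-condition summaries (mean +/- SD over replicates).

suppressMessages(library(nmjquant))

files <- c("results/marker_positivity.csv", "results/elongation_index.csv",
           "results/achr_clusters.csv", "results/myotube_coverage.csv")
missing <- files[!file.exists(files)]
if (length(missing)) {
  stop("run analyses 02-05 first; missing: ", paste(missing, collapse = ", "))
}

cat("== Summary: mean +/- SD over replicate fields ==\n")
for (f in files) {
  tbl <- read_table_results(f)
  s <- summarize_results(tbl)
  cat(sprintf("\n-- %s --\n", f))
  for (i in seq_len(nrow(s))) {
    cat(sprintf("%-12s %-26s %10.3f +/- %-8.3f (n = %d, %s)\n",
                s$condition[i], s$metric[i], s$mean[i], s$sd[i], s$n[i],
                s$units[i]))
  }
}
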