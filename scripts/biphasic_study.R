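#!/usr/bin/env Rscript
# Scaled-down biphasic study: vulnerable-window scans on 2.5 x 2.5 cm
# sheets (dx = 0.02 cm) over three fibrosis seeds, for the four fibrosis
# fractions and the intercellular-uncoupling series. Roughly an overnight
# batch on one CPU. Writes one outcome log per condition and a summary
# CSV of vulnerable-window widths.
#
#   Rscript scripts/biphasic_study.R --out results/biphasic [--seeds 3]

suppressPackageStartupMessages(library(cardiowave))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(out = "results/biphasic", seeds = 3)
i <- 1
while (i <= length(args)) {
  key <- sub("^--", "", args[i])
  opt[[key]] <- args[i + 1]
  i <- i + 2
}
opt$seeds <- as.integer(opt$seeds)
dir.create(opt$out, recursive = TRUE, showWarnings = FALSE)

conditions <- rbind(
  data.frame(tag = c("fib04", "fib145", "fib28", "fib40"),
             p_f = c(0.04, 0.145, 0.28, 0.40), dmult = 0.5),
  data.frame(tag = c("unc_base", "unc_half", "unc_tenth", "unc_hundredth"),
             p_f = 0.28, dmult = 0.5 * c(1, 0.5, 0.1, 0.01))
)

summary_rows <- list()
for (k in seq_len(nrow(conditions))) {
  for (seed in seq_len(opt$seeds)) {
    tag <- sprintf("%s_seed%d", conditions$tag[k], seed)
    mesh <- build_mesh(2.5, 2.5, 0.02)
    nm <- assign_node_types(mesh, conditions$p_f[k], seed)
    df <- build_diffusion(nm, d_myo = 0.0013 * conditions$dmult[k])
    tis <- make_tissue(nm, df, "HF")
    vw <- tryCatch(
      scan_vulnerable_window(tis, ci_min = 150, ci_max = 700, step = 10,
                             n_s1 = 3, bcl = 900, observe_ms = 800,
                             dt = 0.005, sample_dt = 5, progress = TRUE),
      error = function(e) {
        message(tag, ": ", conditionMessage(e))
        NULL
      })
    if (is.null(vw)) {
      summary_rows[[tag]] <- data.frame(tag = tag, vw_width = 0,
                                        note = "inexcitable")
      next
    }
    write_vw_csv(vw, file.path(opt$out, paste0(tag, ".csv")))
    summary_rows[[tag]] <- data.frame(
      tag = tag, vw_width = vw$vw_width,
      note = if (is.null(vw$vw_limits)) "" else
        paste0("[", vw$vw_limits[1], ";", vw$vw_limits[2], "]"))
    message(sprintf("%s: VW %g ms", tag, vw$vw_width))
  }
}
write.csv(do.call(rbind, summary_rows),
          file.path(opt$out, "summary.csv"), row.names = FALSE)
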