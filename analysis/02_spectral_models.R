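#!/usr/bin/env Rscript
# Spectra-only models: every quality parameter x pretreatment x regression
# method, reported as calibration/prediction metrics. Run 01 first.

library(berryhsi)

dataset <- readRDS("scratch/dataset.rds")
grid <- expand.grid(target = c("ssc", "ph", "vc"),
                    pretreatment = c("none", "wt", "msc"),
                    model = c("plsr", "svr", "lwr"),
                    stringsAsFactors = FALSE)
rows <- lapply(seq_len(nrow(grid)), function(i) {
  cfg <- experiment_config(grid$target[i], "spectral", grid$pretreatment[i],
                           grid$model[i], "none", seed = 1L)
  res <- run_experiment(cfg, dataset)
  message(sprintf("%-4s %-4s %-4s  Rc2 %.4f RMSEC %.4f | Rp2 %.4f RMSEP %.4f",
                  grid$target[i], grid$pretreatment[i], grid$model[i],
                  res$report$rc2, res$report$rmsec,
                  res$report$rp2, res$report$rmsep))
  report_row(res)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/spectral_models.csv", row.names = FALSE)

best <- do.call(rbind, lapply(split(tab, tab$target),
                              function(d) d[which.max(d$rp2), ]))
message("best spectra-only model per target:")
print(best[, c("target", "pretreatment", "model", "rp2", "rmsep")],
      row.names = FALSE)
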