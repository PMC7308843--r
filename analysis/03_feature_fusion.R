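#!/usr/bin/env Rscript
# Fusion experiments: spectra combined with color moments and GLGCM/Gabor
# texture blocks, per target and model. Run 01 first.

library(berryhsi)

dataset <- readRDS("scratch/dataset.rds")
combos <- list(c("spectral", "color"),
               c("spectral", "texture"),
               c("spectral", "color", "texture"))
grid <- expand.grid(target = c("ssc", "ph", "vc"),
                    model = c("plsr", "svr", "lwr"),
                    combo = seq_along(combos), stringsAsFactors = FALSE)
rows <- lapply(seq_len(nrow(grid)), function(i) {
  blocks <- combos[[grid$combo[i]]]
  cfg <- experiment_config(grid$target[i], blocks, "none",
                           grid$model[i], "none", seed = 1L)
  res <- run_experiment(cfg, dataset)
  message(sprintf("%-4s %-24s %-4s  Rp2 %.4f RMSEP %.4f",
                  grid$target[i], paste(blocks, collapse = "+"),
                  grid$model[i], res$report$rp2, res$report$rmsep))
  report_row(res)
})
tab <- do.call(rbind, rows)
write.csv(tab, "results/feature_fusion.csv", row.names = FALSE)

best <- do.call(rbind, lapply(split(tab, tab$target),
                              function(d) d[which.max(d$rp2), ]))
message("best fused model per target:")
print(best[, c("target", "features", "model", "rp2", "rmsep")],
      row.names = FALSE)
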