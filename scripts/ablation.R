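#!/usr/bin/env Rscript
# Ablation harness: toggles {residual convolution, token attention, CMIoU}
# independently over the 2^3 grid on the desk-scale phantom demo and writes
# a CSV of validation metrics.  Usage:
#   Rscript scripts/ablation.R [--epochs N] [--seed S] [--out PATH]

suppressPackageStartupMessages(library(rootvoid))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(epochs = 50L, seed = 1L, out = "results/ablation.csv")
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--epochs") { opt$epochs <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else stop("unknown argument: ", args[i])
}
dir.create(dirname(opt$out), recursive = TRUE, showWarnings = FALSE)

spec <- phantom_spec_easy()
train <- lapply(seq_len(spec$n_train), function(i) {
  generate_phantom(spec, seed = 1000L + i, id = sprintf("train_%03d", i))
})
val <- lapply(seq_len(spec$n_val), function(i) {
  generate_phantom(spec, seed = 9000L + i, id = sprintf("val_%03d", i))
})

grid <- expand.grid(resconv = c(FALSE, TRUE), tokatt = c(FALSE, TRUE),
                    cmiou = c(FALSE, TRUE))
rows <- list()
for (k in seq_len(nrow(grid))) {
  g <- grid[k, ]
  cfg <- detector_config(preset = "nano", input_size = 160L,
                         use_resconv = g$resconv, use_tokatt = g$tokatt)
  tcfg <- train_config(lr = 0.003, lr_schedule = "cosine", epochs = opt$epochs,
                       batch_size = 16L, mosaic = FALSE, eval_every = opt$epochs,
                       loss = if (g$cmiou) "cmiou" else "ciou", seed = opt$seed)
  t0 <- Sys.time()
  det <- train_detector(train, cfg, tcfg, val_data = val)
  last <- det$runlog[nrow(det$runlog), ]
  rows[[k]] <- data.frame(resconv = g$resconv, tokatt = g$tokatt, cmiou = g$cmiou,
                          val_map50 = last$val_map50,
                          val_map50_95 = last$val_map50_95,
                          val_recall = last$val_recall,
                          val_precision = last$val_precision,
                          train_loss = last$loss,
                          wall_s = round(as.numeric(Sys.time() - t0, units = "secs")))
  cat(sprintf("resconv=%d tokatt=%d cmiou=%d -> mAP50 %.3f (%.0f s)\n",
              g$resconv, g$tokatt, g$cmiou, last$val_map50, rows[[k]]$wall_s))
}
res <- do.call(rbind, rows)
utils::write.csv(res, opt$out, row.names = FALSE)
cat("wrote", opt$out, "\n")
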