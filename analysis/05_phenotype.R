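# Phenotype clustering: asinh-transformed, percentile-normalized marker
# intensities (plus cell area and nuclear stain) fitted with full-covariance
# Gaussian mixtures over a range of k (30 EM restarts each); the selection
# curve, chosen model and a 2-D t-SNE embedding are written alongside the
# per-cell assignments.

source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, stages = "phenotype")

model <- jsonlite::read_json(file.path(run_dir, "phenotype_model.json"),
                             simplifyVector = TRUE)
write.csv(model$selection_curve,
          file.path(results_dir, "model_selection_curve.csv"),
          row.names = FALSE)
cat(sprintf("selected k = %d; mixture weights: %s\n", model$k,
            paste(sprintf("%.3f", model$weights), collapse = " ")))

ct <- read_celltable(file.path(run_dir, "celltable.csv"))
gt <- read.csv(file.path(run_dir, "tiles", "ground_truth.csv"))
d2 <- outer(gt$x, ct$centroid_x, "-")^2 + outer(gt$y, ct$centroid_y, "-")^2
nn <- apply(d2, 1, which.min)
hit <- sqrt(d2[cbind(seq_len(nrow(gt)), nn)]) <= gt$radius
keep <- hit & !is.na(ct$cluster[nn])
conf <- table(true = gt$cluster[keep], assigned = ct$cluster[nn[keep]])
write.csv(as.data.frame(conf),
          file.path(results_dir, "cluster_confusion.csv"), row.names = FALSE)
cat("cluster recovery (rows = true, cols = assigned):\n")
print(conf)
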