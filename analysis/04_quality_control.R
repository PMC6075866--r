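# Cycle quality control: per-cycle nucleus counts relative to cycle 1
# (tissue integrity), mutual-nearest-neighbour retention, per-channel
# dynamic range, and nuclear-channel distribution overlap across cycles
# with concordance classes.

source("analysis/00_config.R")

cfg <- analysis_config()
run_pipeline(cfg, stages = "qc")

integ <- read.csv(file.path(run_dir, "integrity.csv"))
file.copy(file.path(run_dir, "integrity.csv"),
          file.path(results_dir, "integrity.csv"), overwrite = TRUE)
qc <- jsonlite::read_json(file.path(run_dir, "qc_report.json"),
                          simplifyVector = TRUE)
write.csv(qc$dynamic_ranges, file.path(results_dir, "dynamic_ranges.csv"),
          row.names = FALSE)
cat("integrity curve:", paste(sprintf("%.3f", integ$normalized),
                              collapse = " "), "\n")
if (!is.null(qc$overlaps))
  cat("nuclear-channel overlap vs cycle 1:",
      paste(sprintf("%.3f (%s)", qc$overlaps$score, qc$overlaps$class),
            collapse = ", "), "\n")
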