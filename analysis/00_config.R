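# Shared configuration for the analysis scripts: one default synthetic
# specimen (2x2 tile grid, 3 four-channel cycles, ~500 cells) analysed end
# to end under fixed seeds. Individual scripts source this file.

library(cycifer)

run_dir <- "results/run"
results_dir <- "results"
dir.create(results_dir, showWarnings = FALSE)

analysis_config <- function() {
  run_config(list(paths = list(output = run_dir)))
}
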