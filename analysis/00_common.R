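## Shared configuration for the analysis scripts. Run the scripts in
## order from the repository root:
##   Rscript analysis/01_simulate.R
##   Rscript analysis/02_warp.R
##   ...
## Heavy intermediates are cached under results/cache/ so each stage can
## be re-run independently; every stage is deterministic in cfg$seed.

library(craniomorph)

cfg <- pipeline_config(
  n_semilandmarks = 480,   # template surface semi-landmarks
  radius          = 1.5,   # spacing radius, mm
  cycles          = 6,     # sliding cycles, step 1.00 -> 0.05
  n_perm          = 10000, # permutation tests
  population      = population_spec(seed = 20260926),
  seed            = 20260926)

paths <- list(cache = "results/cache", tables = "results/tables")
for (p in paths) dir.create(p, recursive = TRUE, showWarnings = FALSE)

cache_file <- function(name) file.path(paths$cache, name)
table_file <- function(name) file.path(paths$tables, name)
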