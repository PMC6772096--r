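# Shared configuration for the analysis scripts. Run the scripts in order
# from the repository root:
#   Rscript analysis/01_simulate.R
#   Rscript analysis/02_allocate.R
#   ...
# All outputs land under results/.

library(neonicbirds)

MASTER_SEED <- 20140101L
BUNDLE_DIR <- file.path("results", "bundle")

analysis_config <- function() {
  pipeline_config(
    out_dir = BUNDLE_DIR, rng_seed = MASTER_SEED,
    landscape = landscape_config(rng_seed = MASTER_SEED),
    n_species = 12,
    # a spread of true exposure effects, from clear declines to clear
    # increases per TEF-adjusted kg, bracketing the no-effect case
    true_beta1 = seq(-0.008, 0.008, length.out = 12),
    sites_per_grid = 2, family = "poisson")
}
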