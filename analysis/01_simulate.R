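#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# Writes per-genome FASTA files for three conditions into results/fixtures/:
#   null/     20 no-effect genomes (calibration cohort)
#   avoider/  20 genomes with a 1.5 kcal/mol planted extrinsic depletion
#   gc_split/ 20 genomes with a strong mRNA-vs-ncRNA G+C offset (intrinsic)
# Each genome has 50 mRNA heads (21 nt) and 10 ncRNAs (60-100 nt), the
# package's standard fixture scale.

library(rnavoid)

out_root <- "results/fixtures"
params <- energy_params()

specs <- list(
  # iid heads: both tests see realistic within-genome G+C variation
  null = synthetic_spec(n_genomes = 20L, effect_delta = 0,
                        head_sampling = "iid", seed = 101L),
  avoider = synthetic_spec(n_genomes = 20L, effect_delta = 1.5,
                           n_heads = 30L, n_ncrnas = 6L,
                           ncrna_len_range = c(60L, 60L),
                           head_sampling = "iid", seed = 102L),
  gc_split = synthetic_spec(n_genomes = 20L, gc_mrna = 0.35, gc_ncrna = 0.65,
                            head_sampling = "iid", seed = 103L)
)

for (cond in names(specs)) {
  dir <- file.path(out_root, cond)
  message("simulating ", cond, " cohort -> ", dir)
  run_simulate(specs[[cond]], dir, params = params)
}
message("done: three cohorts of 20 genomes under ", out_root)
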