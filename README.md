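# rnavoid

Genome-scale analysis of **mRNA:ncRNA avoidance** in bacteria and archaea:
the depletion, under selection, of stable *stochastic* interactions between
mRNA 5' ends and the abundant core non-coding RNAs (tRNA, rRNA, RNase P,
SRP, tmRNA, 6S). Avoidance predicts — and can be used to control — protein
abundance: synonymous mRNAs that dodge chance complementarity with the
cellular ncRNA pool translate better.

The package is for computational biologists who want to (1) test whether a
genome's native mRNA 5' regions interact with core ncRNAs less than
composition predicts, (2) localise avoided regions along ncRNAs and relate
them to structural accessibility, (3) quantify how much avoidance explains
of protein-abundance variation, and (4) design synonymous coding sequences
with prescribed avoidance under tight G+C control.

## The model in brief

For a genome with mRNA heads $m_1,\dots,m_k$ (first 21 nt of each CDS) and
core ncRNAs $n_1,\dots,n_l$, the interaction energy of a pair is the
accessibility-corrected binding MFE

$$E(m,n) \;=\; \min_{\text{sites } s_m, s_n}\Big[\Delta G_{\text{open}}(m, s_m) + \Delta G_{\text{open}}(n, s_n) + \Delta G_{\text{duplex}}(s_m, s_n)\Big] \;\le\; 0,$$

computed by a simplified nearest-neighbour engine (stacks, loop penalties,
duplex initiation; oracle-verified dynamic programming in C++).

* **Extrinsic avoidance**: one-tailed Mann-Whitney U of native
  $\{E(m_i,n_j)\}$ against the pooled energies of 200
  dinucleotide-preserving shuffles of each head (uniform Euler-path
  sampling) — one p-value per genome.
* **Intrinsic avoidance**: two-tailed Mann-Whitney U of per-sequence G+C of
  ncRNAs vs mRNA heads.
* A genome is an **avoider** if either p < 0.05.
* For design, a candidate mRNA's avoidance score is
  $\sum_j E(\text{head}_{21}, n_j)$ (ncRNAs are in molar excess, sites
  saturate, energies add); constructs are selected at the extremes of CAI,
  5' folding MFE (first 37 nt) and avoidance inside a fixed G+C band.

## Worked example

```r
library(rnavoid)
params <- energy_params()
set.seed(42)

# a genome with a planted 1.5 kcal/mol avoidance effect
spec <- synthetic_spec(n_heads = 30, n_ncrnas = 6,
                       ncrna_len_range = c(60, 60), effect_delta = 1.5)
b <- synth_genome(spec, genome_id = "demo", params = params)
r <- extrinsic_avoidance_test(b, params, mode = "hybrid", n_shuffles = 50)
r
#> <avoidance_result> demo: 180 native vs 9000 null energies
#>   mean native -5.65, mean null -7.44 kcal/mol
#>   p_extrinsic = 2.05e-23, p_intrinsic = NA, avoider = NA

duplex_mfe("GGGG", "CCCC", energy_params_toy())
#> <duplex_result> -5.00 kcal/mol  a[1..4] : b[1..4]  ((((&))))
```

The planted genome's native interactions are ~1.8 kcal/mol weaker than its
dinucleotide-shuffle null, and the rank test flags it at p ≈ 2e-23: exactly
the signature the genome scan looks for. The toy duplex shows the energy
arithmetic: three G:C stacks at −3.0 plus the +4.0 initiation cost.

The `analysis/` directory is the narrative workflow — run from the package
root after installing:

```sh
Rscript analysis/01_simulate.R        # three cohorts of synthetic genomes
Rscript analysis/02_avoidance_scan.R  # per-genome tests + phylum summary
Rscript analysis/03_region_profiles.R # windowed ncRNA profile + contacts
Rscript analysis/04_expression.R      # correlations, R^2 partitioning
Rscript analysis/05_design.R          # 13 constructs with controlled avoidance
```

Each stage prints what it found and writes `#`-headed TSVs under `results/`.
The methods vignette (`vignettes/avoidance-methods.Rmd`) documents the
energy model, the shuffle null, the calibration properties of the pooled
rank test, and every tunable default.

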