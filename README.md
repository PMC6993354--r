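# spectraQTL

Genome-wide association mapping of Fourier-transform infrared (FT-IR) milk
spectra with Bayesian whole-genome regression and SNP-window variance
partitioning.

## The problem

FT-IR spectroscopy of milk measures light transmittance at ~1000
wavenumbers (cm⁻¹); because infrared light interacts with specific chemical
bonds (C–H in fatty acid tails, C=O and N–H in proteins, C–O and –OH in
sugars), a milk spectrum is a cheap, dense readout of milk composition.
Individual wavenumbers are heritable, so mapping the genomic regions that
drive them gives insight into the genetics of milk composition without
assaying each component separately. This package implements that analysis
as a tested, reusable pipeline for quantitative geneticists working with
repeated-record dairy data:

1. **Wavenumber reduction.** Water-interacting regions (above 3008 cm⁻¹
   and the 1623–1669 cm⁻¹ band) are excluded; the remaining grid is
   collapsed into contiguous blocks whose pairwise correlations — after
   correcting for parity, season, days in milk and herd — exceed 0.95, and
   each block is represented by the member with the highest within-block
   correlation sum.
2. **Hierarchical repeatability model.** For each selected wavenumber *w*,
   transmittance of record *ijkl* is modelled as

   y = μ + Parityᵢ + Seasonⱼ + β₁·DIM + β₂·e^(−0.05·DIM) + Herdₖ + CowAₗ + CowPEₗ + E,

   with DIM = dim/365, random herd / permanent-environment / residual terms,
   and the additive genetic value parameterised through SNP effects:
   CowAₗ = Σₘ gₗₘ·aₘ over centred allele dosages. All parameters are drawn
   by single-site Gibbs sampling (compiled in C++); heritability is the
   posterior mean of σ²_A / (σ²_Herd + σ²_A + σ²_PE + σ²_E), with σ²_A the
   across-cow variance of CowA per draw. Wavenumbers with h² < 0.05 are
   excluded.
3. **Window GWAS.** SNPs are grouped into 100-SNP windows tiled at five
   offsets (1, 21, 41, 61, 81; truncated groups under 80 SNPs dropped).
   Each group's share of additive genetic variance is
   %σ²_A = 100 · σ²_gEBV / σ²_A from the posterior draws. Groups explaining
   > 0.35 % are merged into QTL by transitive base-pair overlap; each QTL's
   peak is its strongest group, and QTL from two populations are compared
   by interval overlap.
4. **Synthetic data.** Because the motivating datasets are proprietary,
   a first-class generator simulates herds, parities, seasons, lactation
   stages, block-correlated spectra and genotypes with planted QTL and
   known variance components, so every stage is testable end to end.

## Worked example

```r
library(spectraQTL)

cfg  <- sim_config(n_cows = 300, n_herds = 15, records_per_cow_range = c(2, 4),
                   n_chromosomes = 2, snps_per_chromosome = 150,
                   planted_qtl = list(list(chrom = 1, snp = 75, fraction = 0.4)),
                   seed = 7)
geno <- simulate_genotypes(cfg)
sim  <- simulate_spectra(cfg, geno)
sim$spectra
#> spectra_dataset: 887 records on 300 cows, 18 wavenumbers ( 975 - 2980 cm^-1 )

sel <- select_wavenumbers(sim$spectra)
sel$selection
#>   block wavenumber grid_index corr_sum   tie
#> 1     1      975.0          1 1.000000 FALSE
#> 2     2     1067.5          3 4.962688 FALSE
#> 3     3     1500.0          7 1.000000 FALSE
#> 4     4     1727.5         11 4.962118 FALSE
#> 5     5     1966.0         13 1.000000 FALSE
#> 6     6     2952.5         17 4.964926 FALSE

des <- build_design(sim$spectra, geno, sel$selection$wavenumber[2])
fit <- fit_mcmc(des, mcmc_config(2000, 800, 5, seed = 1))
h2  <- heritability(fit)
#> posterior mean h2 = 0.289 (sd 0.050), truth 0.30

gv  <- group_variances(fit, geno, make_snp_groups(geno$map))
call_qtl(gv, threshold = 0.35)
#>   chrom bp_lower bp_upper n_groups peak_group_id peak_percent
#> 1     1    37404  5897947        4      1_21_120     35.02506
#> 2     2    38277  5816556        4      2_41_140     33.99318
```

The three five-member wavenumber blocks planted by the generator are
recovered exactly (singletons are the uncorrelated filler wavenumbers);
posterior heritability 0.289 brackets the simulated truth 0.30; and the
planted QTL (chromosome 1, bp 3 003 863, 40 % of additive variance) is
covered by the chromosome-1 QTL whose peak group `1_21_120` explains 35 %
of additive genetic variance. At this desk scale every 100-SNP window
clears the 0.35 % threshold (each carries percent-scale polygenic
variance), so windows merge chromosome-wide; at realistic SNP densities
(tens of thousands of SNPs) background windows fall well below the
threshold and QTL are isolated exceedances.

A command-line front end chains the same stages
(`simulate`, `select-wavenumbers`, `fit`, `window-gwas`, `report`,
`run-all`), e.g.:

```sh
Rscript -e 'spectraQTL::spectraqtl_cli()' simulate --out-dir sim --seed 7
```

`run_pipeline()` writes selection, heritability, group-variance, QTL,
peak-region, Manhattan and overlap tables plus a JSON manifest from which
`rerun_from_manifest()` reproduces every table bit-exactly.

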