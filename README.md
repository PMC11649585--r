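# genoscaper

Landscape genomics and seed-transfer-zone delineation for
reduced-representation SNP data, built around the restoration-genetics
workflow for patchily distributed desert plants: filtered SNP matrices in,
population structure, habitat-resistance causal models, genome scans,
turnover models, seed transfer zones and genomic offset out.

It is written for restoration geneticists and landscape ecologists who
have (i) a VCF of biallelic SNPs with sample-to-location metadata, (ii)
environmental predictors, and (iii) a habitat-probability surface from a
species distribution model, and who want the chain of analyses that turns
those into seed-sourcing guidance — with every statistical step testable
against synthetic landscapes whose truth is known.

## What is inside

| Stage | Functions | Method |
|---|---|---|
| Simulation with known truth | `sim_config`, `simulate_landscape`, `write_fixture` | logit-normal allele frequencies with covariance σ²·exp(−D/φ) on a resistance distance D; planted logistic clines logit(p) = α + β·env |
| Genotype QC | `read_vcf`, `apply_quality_filters`, `thin_one_snp_per_locus` | ≤30% individual missingness, MAC ≥ 3, 99th-percentile depth, obs. het ≤ 0.7, one SNP per RAD locus |
| Diversity & differentiation | `diversity_stats`, `pairwise_fst`, `amova_phi_st` | unbiased H_e, H_o, π; Weir–Cockerham θ (ratio of summed a, b, c components); one-level AMOVA Φ_ST |
| Structure | `impute_and_pca`, `select_k_bic`, `dapc_assign` | k-means with BIC = n·log(WSS/n) + K·log(n); LDA on PCs, CV withholding whole locations |
| Distances | `build_transition`, `least_cost_matrix`, `commute_matrix`, `geographic_distance_matrix`, `environmental_distance_matrix` | SDM as conductance; Dijkstra least-cost; Laplacian commute (circuit) distance |
| Causal modeling | `mantel`, `partial_mantel`, `causal_table` | nine-test IBD / IBR / IBE battery, partial r by residual correlation |
| Genome scan | `vif_screen`, `rda_fit`, `significant_axes`, `detect_outliers`, `merge_candidates` | RDA of dosages on predictors; permutation-significant axes; |loading z| > 3 rule |
| Turnover models | `fit_gdm`, `transform_predictors`, `genomic_offset`, `compare_models`, `fit_turnover`, `cumulative_turnover` | GDM: d = 1 − exp(−η), η = α + Σ β·\|ΔI(x)\|, monotone I-splines, non-negative IRLS; gradient-forest-style importance |
| Seed zones | `cluster_populations`, `permanova_r2`, `assign_zones`, `project_future_zones`, `zone_concordance` | Ward clustering of GDM-predicted dissimilarity; cell cost 0.6·resistance + 0.4·environment; habitat ≥ 0.2 clip |

## Worked example

Simulate a landscape with known adaptive truth, scan it, and delineate
zones:

```r
library(genoscaper)

cfg <- sim_config(nrow = 30, ncol = 30, n_populations = 25,
                  n_individuals = 10, n_neutral = 300, n_adaptive = 15,
                  seed = 7)
sim  <- simulate_landscape(cfg)
geno <- apply_quality_filters(sim$geno)

pairwise_fst(geno)$mean_pairwise      # 0.157
amova_phi_st(geno)$pct_among          # 27.47 (% variance among locations)

rda <- rda_fit(geno, sim$env_at_pops[geno$samples$location, ])
ax  <- significant_axes(rda, n_perm = 99, seed = 1)
sc  <- detect_outliers(rda, ax)       # 16 candidates on 4 significant axes
mean(sim$geno$snps$id[sim$truth$adaptive_idx] %in% sc$outliers$locus)
                                      # 1.0 — all 15 planted clines found

tr  <- build_transition(sim$habitat)
res <- least_cost_matrix(tr, sim$populations)
geo <- geographic_distance_matrix(sim$populations)
partial_mantel(pairwise_fst(geno)$theta, res, geo, seed = 1)$r
                                      # 0.481 — resistance signal after
                                      #         removing geography

freqs <- pop_allele_freqs(geno)$freq[, sc$outliers$locus]
sp    <- assemble_site_pairs(freqs, as.data.frame(sim$env_at_pops),
                             matrix_predictors = list(resistance = res))
m     <- fit_gdm(sp)                  # 88.3% deviance explained
sol   <- cluster_populations(m, as.data.frame(sim$env_at_pops),
                             matrix_predictors = list(resistance = res),
                             k_range = 2:6, n_perm = 99)
sol                                   # k = 4, silhouette 0.394,
                                      # perMANOVA R2 70.1%
zones <- assign_zones(sol, sim$habitat,
                      transform_predictors(m, sim$env), sim$populations)
```

The printed numbers above are what this exact script produces: moderate
differentiation (θ ≈ 0.16), full recovery of the planted clines, a
resistance signal that survives conditioning on geography, and four seed
transfer zones covering all suitable habitat.

## The analysis workflow

`analysis/01_simulate.R` … `analysis/07_seed_zones_offset.R` run the full
study pipeline as a numbered sequence of thin drivers over the package —
simulate, QC, structure, resistance + causal models, genome scan,
GDM/turnover, zones + offset — each writing its tables and rasters under
`results/` and printing what it found:

```sh
for f in analysis/0*.R; do Rscript "$f"; done
```

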