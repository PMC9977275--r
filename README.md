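# microdiv

Eco-evolutionary "diversity-slope" analysis for gut metagenome cohorts.

Does a diverse gut community make its member species genetically more
diverse (Diversity Begets Diversity), less diverse (Ecological Controls), or
more likely to shed genes whose functions the community supplies (Black
Queen)? `microdiv` implements the measurement and modelling stack used to
ask these questions of shotgun-metagenome cohorts profiled into MIDAS-style
merged tables:

- **Community diversity** — Shannon index H' = −Σ pᵢ ln pᵢ and richness per
  sample, at species through phylum rank, plus rarefied richness by exact
  hypergeometric subsampling of reads.
- **Within-species polymorphism** — the proportion of assayed
  fourfold-degenerate (synonymous) or onefold-degenerate (nonsynonymous)
  core-gene sites with intermediate allele frequency 0.2 ≤ f ≤ 0.8, under
  the standard filter stack (sample median depth D̄ ≥ 5; site depth within
  [0.3 D̄, 3 D̄]; core genes = prevalence ≥ 90%; shared-gene blacklist and
  copy-number ≥ 3 exclusions; species with marker coverage ≥ 10 in ≥ 10
  samples), and its change between time points within a host.
- **Gene gain/loss over time** — copy number c = gene coverage / median
  marker-gene coverage; absent when c ≤ 0.05, present when 0.6 ≤ c ≤ 1.2
  with marker coverage ≥ 20; gains and losses counted between within-host
  time-point pairs over unambiguously callable genes.
- **Strain number** — a binomial mixture over K ≤ 4 discrete strain
  genotypes with frequencies π and error rate ε, fitted to multi-allelic
  sites at ≥ 20× depth by alternating exact genotype enumeration with
  gradient-based continuous optimization, K selected by BIC.
- **Diversity-slope models** — the coefficient of standardized community
  diversity in hierarchical models of each intra-species response:
  beta-logit (optionally smoothed) models for rates, zero-truncated
  Poisson/NB mixed models for strain counts, NB models for gains/losses,
  with AIC family selection, drop-one likelihood-ratio tests, profile
  confidence intervals, and temporal diversity × time-lag interactions.
- **A synthetic cohort generator** with planted DBD / EC / neutral /
  Black-Queen ground truth, in exactly the table dialect the readers
  consume, so the entire pipeline is testable offline.

## Worked example

Simulate a cohort in which strain counts couple positively to community
Shannon diversity (`beta_dbd = 0.5`) and gene-loss hazards do too
(`gamma_bq = 0.5`), then run the pipeline and fit the slope:

```r
library(microdiv)

sim <- simulate_cohort(sim_params(n_hosts = 40, n_focal_species = 3,
                                  beta_dbd = 0.5, gamma_bq = 0.5,
                                  sites_per_species = 300, seed = 42))
cohort <- sim$tables
cohort
#> cohort_tables: 80 samples, 100 species, 3 species with SNV/gene tables

dv  <- diversity_table(cohort)
cfg <- run_config()                      # every threshold above, overridable
st  <- strain_table(cohort, cfg, seed = 1)
head(st[, c("species_id", "sample_id", "K", "pi", "n_sites")], 3)
#>   species_id sample_id K                pi n_sites
#> 1      sp001   H001_T1 2 0.991811,0.008189     155
#> 2      sp001   H001_T2 2 0.991288,0.008712     165
#> 3      sp001   H004_T1 2 0.762736,0.237264     109

cs <- cross_sectional_data(st, dv, cohort)
cs$strain_count <- cs$K
fit <- fit_cross_sectional(cs, model_spec("strain_count",
                                          random_effects = character()))
fit
#> slope_fit [trunc_poisson, ml]: slope=0.1993 (se 0.0882), logL=-155.87, AIC=317.74, n=127
drop_one_lrt(fit, "div_z")$p_value
#> [1] 0.01877039
```

The fitted diversity slope on strain counts is positive (0.199 ± 0.088 on
the standardized scale) and the drop-one LRT rejects at p ≈ 0.019 — the
planted DBD signal, recovered from raw simulated read counts through site
selection, mixture fitting, BIC model selection and the count GLM. (Fitted
strains below ~1% frequency, as in the first two rows above, absorb
clustered sequencing errors; the inferred major-strain structure is
unaffected.) The same cohort's gene-loss records, regressed on diversity at
the earlier time point with `fit_temporal()`, give a positive loss slope;
one 40-host cohort is underpowered for significance there, which is why the
verification experiments below aggregate 50 cohorts.

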