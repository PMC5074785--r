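# epiland

Does a molecular buffer such as the chaperone Hsp90 hide genetic variation —
or does it potentiate it, or merely interact with it? `epiland` is an R
package for answering that question from single-cell phenotype tables
collected under a paired control/inhibitor design, as in high-throughput
yeast morphometry (CalMorph-style output: strains × conditions × replicates ×
cell-cycle stages, with hundreds of cells per well). It is aimed at
quantitative geneticists analysing strain collections — mutation-accumulation
lines, recombinants, natural isolates — for genotype-by-condition
interaction.

## What it computes

For each phenotype (a stage-specific principal component of the
morphological traits, scaled to overall variance 1), the package fits the
bivariate hierarchical model

    y_cij = mu_c + u_ic + e_cij,   (u_i,control, u_i,inhibited)' ~ N2(0, Sigma_b),
    e_cij ~ N(0, sigma^2_w,c)

by an own conjugate Gibbs sampler, with condition-specific between-strain
SDs (sigma_1, sigma_2), their cross-condition correlation rho, and
condition-specific within-strain variances. Decisions use the 95% highest
posterior density interval of the between-strain SD difference
`delta_sigma = sigma_b,inhibited − sigma_b,control`: significantly positive
means inhibition reveals variation (buffering), negative means it hides
variation (potentiation).

Around that core:

* a likelihood-ratio test for the genotype-by-condition interaction
  (boundary-corrected chi-squared mixture reference, via `lme4`);
* the Robertson-type partition of interaction variance,
  `V_int = (sigma_1 − sigma_2)^2 / 2 + sigma_1 sigma_2 (1 − rho)`,
  into *line spreading* (variance changes: buffering/potentiation) and
  *line crossing* (rank-order changes);
* preprocessing: per-trait Box-Cox normalization (pooled across conditions,
  so condition variance differences survive), replicate-plate correction,
  stage-specific PCA;
* divergence-from-ancestor statistics for per-strain inhibitor responses
  (magnitude, direction on the unit sphere, top-divergent accumulation,
  cross-perturbation correlations);
* a stabilizing-selection truncation model showing analytically and by
  Monte-Carlo how selection in the control environment turns line-crossing
  epistasis into apparent buffering
  (`delta_sigma_post = sqrt(rho^2 k + 1 − rho^2) − sqrt(k)` with
  `k = 1 − 2c phi(c) / (2 Phi(c) − 1)`);
* a synthetic-data generator with known ground truth for all of the above,
  emulating the paired-plate design end to end.

## Worked example

```r
library(epiland)

gen <- generator_config(n_strains = 40, sigma_between = c(0.4, 0.25),
                        rho_between = 0.7, cells_per_well = c(100, 200),
                        seed = 42)
effects <- generate_strain_effects(gen)
cells   <- generate_cell_table(gen, effects)   # ~72,000 cells, 132 traits
pp      <- preprocess_cells(cells)
pp
#> Preprocessed cell-morphology dataset
#> Stage 'unbudded': 23963 cells, 6 PCs explaining 98.8% of variance
#> Stage 'small_budded': 23841 cells, 9 PCs explaining 98.4% of variance
#> Stage 'large_budded': 24107 cells, 14 PCs explaining 98.1% of variance

sc <- phenotype_scores(pp, "unbudded_PC1")
fit_interaction_lrt(sc)
#> Genotype-by-condition LRT: stat = 535.909, p = 7.32e-119 (significant at 0.01)

fit <- fit_variance_mcmc(y ~ condition, sc, n_iter = 4000, burnin = 1000,
                         thin = 3, seed = 7)
summary(fit)
#> Posterior summary (40 strains, 95% HPD intervals)
#>                    median    mean     sd hpd_lower hpd_upper       ess   rhat
#> sigma_b_control    0.4447  0.4484 0.0514    0.3616    0.5462  386.5732 0.9990
#> sigma_b_inhibited  0.2306  0.2339 0.0279    0.1856    0.2904  749.9066 0.9994
#> rho_b              0.7313  0.7195 0.0808    0.5545    0.8537  505.4710 0.9994
#> sigma_w_control    0.9335  0.9336 0.0059    0.9234    0.9463 1000.0000 1.0004
#> sigma_w_inhibited  0.9389  0.9390 0.0059    0.9273    0.9495 1000.0000 0.9991
#> mu_control         0.0238  0.0218 0.0794   -0.1368    0.1742   25.7183 1.0120
#> mu_inhibited      -0.0190 -0.0212 0.0408   -0.1112    0.0506   34.8537 1.0069

variance_difference(fit, phenotype = "unbudded_PC1")
#> Delta sigma_b (inhibited - control) [unbudded_PC1]: median -0.2138, 95% HPD [-0.3009, -0.1352]
#>   significant: potentiation-hidden

partition_interaction(estimate_strain_condition_moments(sc))
#> Interaction variance 0.04948 = spreading 0.02367 + crossing 0.02581
#>   spreading fraction 0.478, crossing fraction 0.522
```

Read: on this phenotype the generating truth had the inhibited condition
*less* variable between strains (0.25 vs 0.40 on the latent scale), and the
fit recovers exactly that — inhibition hides variation (the modifier acts as
a potentiator here), with about half of the interaction variance due to the
variance change and half due to strain rank-order changes.

`run_pipeline(pipeline_config(...))` chains all stages (simulation or a TSV
table read by `read_cell_table()`, preprocessing, per-phenotype LRT + moment
partition + MCMC + HPD test, collection summary, divergence, optional
selection comparison) and writes provenance-stamped TSV outputs.

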