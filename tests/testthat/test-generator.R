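test_that("degenerate variance settings give exact degenerate effects", {
  # zero between-strain variance: all effects exactly zero
  cfg0 <- one_pheno_config(10, sigma_b = c(0, 0), rho = 0.5)
  eff0 <- generate_strain_effects(cfg0)
  expect_true(all(eff0$control == 0) && all(eff0$inhibited == 0))

  # perfect correlation with equal SDs: identical effects in both conditions
  cfg1 <- one_pheno_config(50, sigma_b = c(0.7, 0.7), rho = 1)
  eff1 <- generate_strain_effects(cfg1)
  expect_equal(eff1$control, eff1$inhibited, tolerance = 1e-12)
})

test_that("generated effects match the configured bivariate law", {
  cfg <- one_pheno_config(5000, sigma_b = c(1, 0.5), rho = 0.8, seed = 11)
  eff <- generate_strain_effects(cfg)
  S <- cov(cbind(eff$control, eff$inhibited))
  # MC standard errors of variances ~ sqrt(2/n)*sigma^2, of covariance similar
  n <- nrow(eff)
  expect_lt(abs(S[1, 1] - 1), 3 * sqrt(2 / n) * 1)
  expect_lt(abs(S[2, 2] - 0.25), 3 * sqrt(2 / n) * 0.25)
  se_cov <- sqrt((1 * 0.25 + 0.4^2) / n)
  expect_lt(abs(S[1, 2] - 0.4), 3 * se_cov)
})

test_that("cell tables are deterministic given the seed and reflect the config", {
  cfg <- one_pheno_config(6, sigma_b = c(0.5, 0.5), rho = 0.5,
                          cells = 20, seed = 5)
  eff <- generate_strain_effects(cfg)
  t1 <- generate_cell_table(cfg, eff)
  t2 <- generate_cell_table(cfg, eff)
  expect_identical(t1, t2)
  expect_named(t1, c("strain", "condition", "replicate", "stage", "u_t001"))
  # all SDs zero + identity transform: every cell identical within its well
  cfg0 <- one_pheno_config(4, sigma_b = c(0, 0), rho = 0, sigma_w = c(0, 0),
                           cells = 10)
  t0 <- generate_cell_table(cfg0, generate_strain_effects(cfg0))
  expect_equal(length(unique(t0$u_t001)), 1L)
})

test_that("condition-specific within-strain noise is realized", {
  cfg <- one_pheno_config(20, sigma_b = c(0, 0), rho = 0,
                          sigma_w = c(1, 2), cells = 300, seed = 9)
  tab <- generate_cell_table(cfg, generate_strain_effects(cfg))
  s1 <- sd(tab$u_t001[tab$condition == "control"])
  s2 <- sd(tab$u_t001[tab$condition == "inhibited"])
  expect_lt(abs(s2 / s1 - 2), 0.1)
})

test_that("per-stage substreams are independent of later stages", {
  base <- list(n_strains = 12, traits_per_stage = c(2L, 3L),
               latent_dims_per_stage = c(1L, 2L),
               stages = c("unbudded", "small_budded"),
               sigma_between = c(0.5, 0.5), seed = 21)
  cfg2 <- do.call(generator_config, base)
  base1 <- base
  base1$stages <- "unbudded"
  base1$traits_per_stage <- 2L
  base1$latent_dims_per_stage <- 1L
  cfg1 <- do.call(generator_config, base1)
  e2 <- generate_strain_effects(cfg2)
  e1 <- generate_strain_effects(cfg1)
  expect_equal(e1$control, e2$control[e2$stage == "unbudded"])
})

test_that("marginal trait distribution is a condition mixture when noise-free", {
  # identity transform, no replicate offsets: per-condition latent moments
  # must propagate exactly through the unit loading
  cfg <- one_pheno_config(4000, sigma_b = c(0.8, 0.3), rho = 0.5,
                          sigma_w = c(0.5, 0.5), cells = 2, n_replicates = 1,
                          seed = 33)
  tab <- generate_cell_table(cfg, generate_strain_effects(cfg))
  v1 <- var(tab$u_t001[tab$condition == "control"])
  v2 <- var(tab$u_t001[tab$condition == "inhibited"])
  expect_lt(abs(v1 - (0.8^2 + 0.25)), 0.06)
  expect_lt(abs(v2 - (0.3^2 + 0.25)), 0.03)
})

test_that("the pipeline recovers the sign of the variance difference", {
  # full round trip at a potentiation-like truth (delta sigma = -0.3):
  # generate -> normalize -> replicate-correct -> PCA -> moment estimates
  correct <- vapply(1:100, function(i) {
    cfg <- generator_config(n_strains = 50, stages = "unbudded",
                            traits_per_stage = 8L, latent_dims_per_stage = 1L,
                            sigma_between = c(0.7, 0.4), rho_between = 0.7,
                            cells_per_well = c(35, 45), seed = 7000 + i)
    tab <- generate_cell_table(cfg, generate_strain_effects(cfg))
    pp <- preprocess_cells(tab, n_pcs = 1L)
    vc <- estimate_strain_condition_moments(
      phenotype_scores(pp, "unbudded_PC1"))
    vc$sigma_b[2] < vc$sigma_b[1]
  }, TRUE)
  expect_gte(sum(correct), 95L)
})

test_that("invalid configurations are rejected", {
  expect_error(one_pheno_config(10, sigma_b = c(-1, 1), rho = 0), "SD")
  expect_error(one_pheno_config(10, sigma_b = c(1, 1), rho = 1.2), "rho")
  expect_error(generator_config(strain_labels = c("a", "b", "c")), "ancestor")
  expect_error(generator_config(traits_per_stage = c(1, 2)), "stages")
})

test_that("mutation classes scale responses relative to the ancestor", {
  cfg <- one_pheno_config(400, sigma_b = c(1, 1), rho = 0.3, seed = 13)
  eff <- generate_strain_effects(cfg)

  # fractions {Syn: 1} annotates every line Syn
  ann_all <- assign_mutation_classes(cfg, class_fractions = c(Syn = 1),
                                     multipliers = c(Syn = 0))
  expect_true(all(ann_all$class[ann_all$strain != "ancestor"] == "Syn"))

  # multiplier 0 removes any response difference from the ancestor
  scaled <- apply_mutation_classes(eff, ann_all)
  resp <- scaled$inhibited - scaled$control
  anc_resp <- resp[scaled$strain == "ancestor"]
  expect_equal(resp, rep(anc_resp, length(resp)), tolerance = 1e-12)

  # non-monotone multipliers are rejected
  expect_error(assign_mutation_classes(cfg,
    multipliers = c(Syn = 1, Con = 0.5, Rad = 1, Dmg = 2)), "non-decreasing")
})
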