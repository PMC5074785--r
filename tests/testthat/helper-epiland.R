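# Shared fixtures: all synthetic, built in code at test time.

# Single-phenotype generator: one stage, one trait loaded 1:1 on one latent
# dimension, so the observed trait IS the latent phenotype.
one_pheno_config <- function(n_strains, sigma_b, rho, sigma_w = c(1, 1),
                             cells = 100L, n_replicates = 2L,
                             replicate_sd = 0, trait_noise_sd = 0, seed = 1L) {
  generator_config(
    n_strains = n_strains, stages = "unbudded", traits_per_stage = 1L,
    latent_dims_per_stage = 1L, loadings = list(matrix(1, 1, 1)),
    sigma_between = sigma_b, rho_between = rho, sigma_within = sigma_w,
    replicate_sd = replicate_sd, trait_noise_sd = trait_noise_sd,
    cells_per_well = c(cells, cells), n_replicates = n_replicates,
    seed = seed)
}

one_pheno_data <- function(...) {
  cfg <- one_pheno_config(...)
  cells <- generate_cell_table(cfg, generate_strain_effects(cfg))
  data.frame(strain = cells$strain, condition = cells$condition,
             replicate = cells$replicate, y = cells$u_t001,
             stringsAsFactors = FALSE)
}

fit_quick <- function(d, seed, n_iter = 3000L, burnin = 1000L, thin = 2L) {
  fit_variance_mcmc(y ~ condition, d, n_iter = n_iter, burnin = burnin,
                    thin = thin, seed = seed)
}

# Independent oracle: exhaustive shortest-window HPD search.
brute_hpd <- function(x, mass = 0.95) {
  x <- sort(x)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  w <- vapply(seq_len(n - m + 1), function(i) x[i + m - 1] - x[i], 0)
  i <- which(w == min(w))[1]
  c(lower = x[i], upper = x[i + m - 1])
}

# Independent oracle: grid search over the Box-Cox profile likelihood.
grid_boxcox_lambda <- function(x, lo = -2, hi = 2, step = 0.01) {
  grid <- seq(lo, hi, by = step)
  ll <- vapply(grid, function(l) epiland:::.boxcox_ll(x, l), 0)
  grid[which.max(ll)]
}

# Largest principal angle (degrees) between the column spans of A and B.
subspace_angle_deg <- function(A, B) {
  qa <- qr.Q(qr(A))
  qb <- qr.Q(qr(B))
  s <- svd(crossprod(qa, qb))$d
  acos(max(-1, min(1, min(s)))) * 180 / pi
}
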