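resp_fixture <- function() {
  m <- rbind(ancestor = c(1, 0, 2),
             s1 = c(1, 0, 2),
             s2 = c(3, 4, 0),
             s3 = c(-1, 0, -2))
  colnames(m) <- paste0("unbudded_PC", 1:3)
  m
}

test_that("response vectors have the expected geometry", {
  m <- resp_fixture()
  v2 <- response_vector(m, "s2")
  expect_equal(v2$magnitude, 5)  # 3-4-0 Pythagorean
  expect_equal(response_vector(m, "ancestor")$magnitude, sqrt(5))
  expect_error(response_vector(m, "nope"), "not observed")
})

test_that("divergence from the ancestor satisfies its exact identities", {
  m <- resp_fixture()
  anc <- response_vector(m, "ancestor")
  # identical response: all-zero record
  d1 <- divergence_from_ancestor(response_vector(m, "s1"), anc)
  expect_equal(d1$magnitude_divergence, 0)
  expect_equal(d1$direction_divergence, 0)
  expect_equal(d1$max_abs_difference, 0)
  # antipodal equal-magnitude response: direction divergence exactly 2
  d3 <- divergence_from_ancestor(response_vector(m, "s3"), anc)
  expect_equal(d3$magnitude_divergence, 0, tolerance = 1e-12)
  expect_equal(d3$direction_divergence, 2, tolerance = 1e-12)
  # orthogonal unit responses: sqrt(2)
  o <- rbind(a = c(1, 0), b = c(0, 1))
  colnames(o) <- c("u_PC1", "u_PC2")
  do <- divergence_from_ancestor(response_vector(o, "a"),
                                 response_vector(o, "b"))
  expect_equal(do$direction_divergence, sqrt(2), tolerance = 1e-12)
})

test_that("direction divergence is scale-free; magnitude is antisymmetric", {
  set.seed(21)
  m <- matrix(rnorm(10), 2, 5,
              dimnames = list(c("a", "b"), paste0("PC", 1:5)))
  va <- response_vector(m, "a"); vb <- response_vector(m, "b")
  d <- divergence_from_ancestor(va, vb)
  m2 <- m; m2["a", ] <- 7 * m2["a", ]
  d_scaled <- divergence_from_ancestor(response_vector(m2, "a"), vb)
  expect_equal(d$direction_divergence, d_scaled$direction_divergence,
               tolerance = 1e-12)
  d_rev <- divergence_from_ancestor(vb, va)
  expect_equal(d$magnitude_divergence, -d_rev$magnitude_divergence)
})

test_that("max-abs response difference picks the dominant phenotype", {
  m <- resp_fixture()
  m["s1", 2] <- 0.7  # differ only on PC2
  expect_equal(max_abs_response_difference(m, "s1"), 0.7)
  expect_equal(max_abs_response_difference(m, "ancestor"), 0)
})

test_that("top-divergent accumulation covers its combinatorial limits", {
  # one dominant strain shared by all phenotypes
  D <- matrix(0, 5, 3, dimnames = list(paste0("s", 1:5), paste0("p", 1:3)))
  D["s3", ] <- 1
  out <- top_divergent_cumulative(D, k_max = 5)
  expect_equal(out$n_unique[1], 1L)
  expect_equal(out$max_possible, c(3, 5, 5, 5, 5))
  # fully disjoint rankings: count at k=1 equals number of phenotypes
  D2 <- diag(3)
  dimnames(D2) <- list(paste0("s", 1:3), paste0("p", 1:3))
  expect_equal(top_divergent_cumulative(D2, 1)$n_unique, 3L)
  expect_warning(top_divergent_cumulative(D, k_max = 10), "capped")
})

test_that("random rankings match the occupancy formula at k = 1", {
  set.seed(22)
  n_s <- 94; n_p <- 29
  counts <- replicate(400, {
    D <- matrix(runif(n_s * n_p), n_s, n_p,
                dimnames = list(sprintf("s%02d", 1:n_s), NULL))
    colnames(D) <- paste0("p", 1:n_p)
    top_divergent_cumulative(D, 1)$n_unique
  })
  expected <- n_s * (1 - (1 - 1 / n_s)^n_p)
  expect_lt(abs(mean(counts) - expected), 3 * sd(counts) / sqrt(400))
})

test_that("perturbation correlations behave at the exact limits", {
  set.seed(23)
  A <- matrix(rnorm(60), 10, 6,
              dimnames = list(paste0("s", 1:10), paste0("PC", 1:6)))
  expect_equal(unname(perturbation_correlation(A, A)$per_phenotype),
               rep(1, 6), tolerance = 1e-12)
  expect_equal(perturbation_correlation(A, -A)$median, -1, tolerance = 1e-12)
  expect_error(perturbation_correlation(A[1:2, ], A[1:2, ]), "3 shared")
})

test_that("divergence grows with the mutation-class multiplier", {
  # Monte-Carlo: stronger GxE multipliers push more strains past a direction
  # divergence threshold
  cfg <- generator_config(n_strains = 1000, stages = "unbudded",
                          traits_per_stage = 6L, latent_dims_per_stage = 3L,
                          sigma_between = c(1, 1), rho_between = 0.4,
                          seed = 31)
  eff <- generate_strain_effects(cfg)
  frac_far <- function(mult) {
    ann <- assign_mutation_classes(cfg, class_fractions = c(Dmg = 1),
                                   multipliers = c(Dmg = mult))
    e <- apply_mutation_classes(eff, ann)
    resp <- with(e, tapply(inhibited - control, list(strain, dim), mean))
    anc <- resp["ancestor", ]
    d <- sweep(resp, 2, anc)
    mean(sqrt(rowSums(d^2)) > 0.5)
  }
  fr <- vapply(c(0.2, 1, 3), frac_far, 0)
  expect_true(all(diff(fr) > 0))
})
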