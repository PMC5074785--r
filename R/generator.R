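#' Configuration for the synthetic cell-morphology generator
#'
#' Builds and validates the parameter set from which synthetic per-cell trait
#' tables are generated.  The defaults emulate a mutation-accumulation (MA)
#' screen: 94 derived lines plus their shared ancestor, assayed side by side in
#' a control and a chaperone-inhibited condition over at least two replicate
#' plates, with 132 morphometric traits split across the three cell-cycle
#' stages (unbudded, small-budded, large-budded; 19/40/73 traits driven by
#' 6/9/14 latent dimensions) and 100-500 quantified cells per strain x
#' condition x replicate x stage.
#'
#' Strain effects live on latent (principal-component-like) dimensions and are
#' mapped to observable traits through a per-stage loading matrix, so that the
#' preprocessing PCA has low-rank structure to recover.  Between-strain SDs,
#' their cross-condition correlation, and within-strain SDs are all
#' condition-specific and may vary by latent dimension.
#'
#' @param n_strains number of strains including the ancestor.
#' @param strain_labels character vector of strain IDs; must contain
#'   `"ancestor"` exactly once.  Default: `"ancestor"` plus `MA001`, ...
#' @param conditions ordered pair of condition labels, control first.
#' @param n_replicates number of replicate plate pairs (>= 2 recommended).
#' @param stages ordered cell-cycle stage labels.
#' @param traits_per_stage integer vector, traits observed in each stage.
#' @param latent_dims_per_stage integer vector, latent dimensions per stage.
#' @param loadings optional list (one per stage) of latent-dim x trait loading
#'   matrices; by default seeded orthogonal rows with decreasing norms so
#'   eigenvalues are well separated.
#' @param sigma_between between-strain SD per condition on the latent scale:
#'   a length-2 vector `(control, inhibited)`, or a list per stage of 2 x d
#'   matrices for per-dimension control.
#' @param rho_between cross-condition correlation of strain effects in
#'   `[-1, 1]`; scalar, or list per stage of per-dimension vectors.
#' @param sigma_within within-strain (cell-to-cell) SD per condition on the
#'   latent scale; same shapes as `sigma_between`.
#' @param replicate_sd SD of additive per-trait replicate-plate offsets,
#'   shared by both conditions of a plate pair.
#' @param trait_noise_sd SD of iid per-cell per-trait measurement noise (the
#'   noise floor below the latent structure).
#' @param cells_per_well length-2 integer range; cell counts are drawn
#'   uniformly from it for every strain x condition x replicate x stage.
#' @param transform monotone per-trait map inducing non-normality:
#'   `"identity"`, `"exp"`, or a vectorized function.
#' @param ancestor_zero if `TRUE` the ancestor's latent effects are fixed at
#'   zero instead of being a typical draw.  The default keeps the ancestor a
#'   typical draw, since a real ancestor responds to the inhibitor too.
#' @param seed integer seed governing all draws.  Per-stage substreams are
#'   derived deterministically, so adding a stage does not shift the draws of
#'   the other stages.
#' @return an object of class `generator_config` (a validated list).
#' @seealso [generate_strain_effects()], [generate_cell_table()]
#' @export
generator_config <- function(n_strains = 95L,
                             strain_labels = NULL,
                             conditions = c("control", "inhibited"),
                             n_replicates = 2L,
                             stages = c("unbudded", "small_budded", "large_budded"),
                             traits_per_stage = c(19L, 40L, 73L),
                             latent_dims_per_stage = c(6L, 9L, 14L),
                             loadings = NULL,
                             sigma_between = c(0.35, 0.35),
                             rho_between = 0.6,
                             sigma_within = c(1, 1),
                             replicate_sd = 0.1,
                             trait_noise_sd = 0.1,
                             cells_per_well = c(100L, 500L),
                             transform = "identity",
                             ancestor_zero = FALSE,
                             seed = 1L) {
  if (is.null(strain_labels)) {
    stopifnot(n_strains >= 2)
    strain_labels <- c("ancestor", sprintf("MA%03d", seq_len(n_strains - 1L)))
  }
  n_strains <- length(strain_labels)
  if (sum(strain_labels == "ancestor") != 1L)
    stop("'strain_labels' must contain \"ancestor\" exactly once")
  if (anyDuplicated(strain_labels))
    stop("duplicated strain labels")
  if (length(conditions) != 2L)
    stop("'conditions' must be an ordered pair (control, inhibited)")
  if (length(traits_per_stage) != length(stages) ||
      length(latent_dims_per_stage) != length(stages))
    stop("traits_per_stage and latent_dims_per_stage must match 'stages'")
  if (any(traits_per_stage < latent_dims_per_stage))
    stop("each stage needs at least as many traits as latent dimensions")
  if (length(cells_per_well) != 2L || any(cells_per_well < 1) ||
      cells_per_well[1] > cells_per_well[2])
    stop("'cells_per_well' must be an increasing positive integer range")
  if (replicate_sd < 0 || trait_noise_sd < 0)
    stop("SDs must be non-negative")

  cfg <- structure(list(
    n_strains = n_strains, strain_labels = strain_labels,
    conditions = conditions, n_replicates = as.integer(n_replicates),
    stages = stages,
    traits_per_stage = as.integer(traits_per_stage),
    latent_dims_per_stage = as.integer(latent_dims_per_stage),
    loadings = loadings,
    sigma_between = sigma_between, rho_between = rho_between,
    sigma_within = sigma_within,
    replicate_sd = replicate_sd, trait_noise_sd = trait_noise_sd,
    cells_per_well = as.integer(cells_per_well),
    transform = transform, ancestor_zero = ancestor_zero,
    seed = as.integer(seed)), class = "generator_config")

  # validate per-dimension SDs and correlations for every stage
  for (s in seq_along(stages)) {
    p <- .dim_params(cfg, s)
    if (any(c(p$sb1, p$sb2, p$sw1, p$sw2) < 0))
      stop("all latent SDs must be >= 0")
    if (any(abs(p$rho) > 1))
      stop("|rho_between| must be <= 1")
  }
  if (is.null(cfg$loadings)) {
    cfg$loadings <- lapply(seq_along(stages), function(s)
      .default_loadings(latent_dims_per_stage[s], traits_per_stage[s],
                        seed + 500L + s))
  }
  for (s in seq_along(stages)) {
    L <- cfg$loadings[[s]]
    if (!is.matrix(L) || nrow(L) != latent_dims_per_stage[s] ||
        ncol(L) != traits_per_stage[s])
      stop(sprintf("loading matrix for stage '%s' must be %d x %d",
                   stages[s], latent_dims_per_stage[s], traits_per_stage[s]))
  }
  cfg
}

#' @export
print.generator_config <- function(x, ...) {
  cat("Synthetic morphology generator configuration\n")
  cat(sprintf("  %d strains (incl. ancestor), conditions %s/%s, %d replicates\n",
              x$n_strains, x$conditions[1], x$conditions[2], x$n_replicates))
  cat(sprintf("  stages: %s\n", paste(x$stages, collapse = ", ")))
  cat(sprintf("  traits/stage: %s (latent dims %s)\n",
              paste(x$traits_per_stage, collapse = "/"),
              paste(x$latent_dims_per_stage, collapse = "/")))
  cat(sprintf("  cells per well: %d-%d, seed %d\n",
              x$cells_per_well[1], x$cells_per_well[2], x$seed))
  invisible(x)
}

# Orthogonal rows with decreasing norms: distinct eigenvalues for PCA recovery.
.default_loadings <- function(d, p, seed) {
  set.seed(seed)
  Q <- qr.Q(qr(matrix(rnorm(p * d), p, d)))
  w <- seq(2, 1, length.out = d)
  L <- t(Q) * w
  dimnames(L) <- NULL
  L
}

# Expand a (possibly scalar / length-2 / per-stage list) parameter to
# per-dimension vectors for one stage.
.expand2 <- function(x, s, d) {
  if (is.list(x)) x <- x[[s]]
  if (is.matrix(x)) {
    stopifnot(nrow(x) == 2)
    list(rep_len(x[1, ], d), rep_len(x[2, ], d))
  } else {
    x <- rep_len(x, 2)
    list(rep(x[1], d), rep(x[2], d))
  }
}

.dim_params <- function(config, s) {
  d <- config$latent_dims_per_stage[s]
  sb <- .expand2(config$sigma_between, s, d)
  sw <- .expand2(config$sigma_within, s, d)
  rho <- config$rho_between
  if (is.list(rho)) rho <- rho[[s]]
  list(sb1 = sb[[1]], sb2 = sb[[2]], rho = rep_len(rho, d),
       sw1 = sw[[1]], sw2 = sw[[2]])
}

.stage_prefixes <- function(stages) {
  pre <- substr(stages, 1L, 1L)
  if (anyDuplicated(pre)) pre <- make.unique(pre, sep = "")
  pre
}

.trait_names <- function(config) {
  pre <- .stage_prefixes(config$stages)
  lapply(seq_along(config$stages), function(s)
    sprintf("%s_t%03d", pre[s], seq_len(config$traits_per_stage[s])))
}

#' Draw condition-specific latent strain effects
#'
#' For every strain x stage x latent dimension, draws the pair of genetic
#' effects (control, inhibited) from a bivariate normal with covariance
#' \deqn{\left[\begin{array}{cc} \sigma_1^2 & \rho\sigma_1\sigma_2 \\
#'   \rho\sigma_1\sigma_2 & \sigma_2^2 \end{array}\right]}
#' where \eqn{\sigma_1,\sigma_2} are the condition-specific between-strain SDs
#' and \eqn{\rho} their cross-condition correlation.  The ancestor is a
#' typical draw unless `config$ancestor_zero`.
#'
#' @param config a [generator_config()].
#' @return a data frame of class `strain_effects` with columns `strain`,
#'   `stage`, `dim`, `control`, `inhibited`.
#' @export
generate_strain_effects <- function(config) {
  stopifnot(inherits(config, "generator_config"))
  n <- config$n_strains
  out <- vector("list", length(config$stages))
  for (s in seq_along(config$stages)) {
    set.seed(config$seed + s)
    p <- .dim_params(config, s)
    d <- config$latent_dims_per_stage[s]
    ctrl <- inh <- matrix(0, n, d)
    for (k in seq_len(d)) {
      z1 <- rnorm(n); z2 <- rnorm(n)
      ctrl[, k] <- p$sb1[k] * z1
      inh[, k] <- p$sb2[k] * (p$rho[k] * z1 + sqrt(1 - p$rho[k]^2) * z2)
    }
    if (config$ancestor_zero) {
      i <- match("ancestor", config$strain_labels)
      ctrl[i, ] <- 0; inh[i, ] <- 0
    }
    out[[s]] <- data.frame(
      strain = rep(config$strain_labels, times = d),
      stage = config$stages[s],
      dim = rep(seq_len(d), each = n),
      control = as.vector(ctrl),
      inhibited = as.vector(inh),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  class(res) <- c("strain_effects", "data.frame")
  res
}

#' Annotate strains with mutation-severity classes
#'
#' Assigns each non-ancestor strain a mutation class (by default `Syn`, `Con`,
#' `Rad`, `Dmg`: synonymous, conservative, radical, damaging) together with a
#' class-specific genotype-by-condition effect multiplier, non-decreasing with
#' severity.  The ancestor is annotated `none` with multiplier 1.
#'
#' @param config a [generator_config()].
#' @param class_fractions named fractions summing to 1.
#' @param multipliers named multipliers covering the classes.
#' @return data frame of class `mutation_annotation`: `strain`, `class`,
#'   `multiplier`, one row per strain.
#' @seealso [apply_mutation_classes()]
#' @export
assign_mutation_classes <- function(config,
                                    class_fractions = c(Syn = 0.25, Con = 0.25,
                                                        Rad = 0.25, Dmg = 0.25),
                                    multipliers = c(Syn = 0.1, Con = 0.5,
                                                    Rad = 1, Dmg = 2)) {
  stopifnot(inherits(config, "generator_config"))
  if (abs(sum(class_fractions) - 1) > 1e-8)
    stop("class fractions must sum to 1")
  cls <- names(class_fractions)
  if (is.null(cls) || !all(cls %in% names(multipliers)))
    stop("multipliers must be named and cover all classes")
  canon <- c("Syn", "Con", "Rad", "Dmg")
  present <- canon[canon %in% cls]
  if (length(present) > 1 && is.unsorted(multipliers[present]))
    stop("multipliers must be non-decreasing across Syn -> Con -> Rad -> Dmg")
  set.seed(config$seed + 999L)
  strains <- config$strain_labels
  lines <- strains[strains != "ancestor"]
  drawn <- sample(cls, length(lines), replace = TRUE, prob = class_fractions)
  ann <- data.frame(strain = strains, class = "none", multiplier = 1,
                    stringsAsFactors = FALSE)
  ann$class[match(lines, strains)] <- drawn
  ann$multiplier <- ifelse(ann$class == "none", 1,
                           unname(multipliers[ann$class]))
  class(ann) <- c("mutation_annotation", "data.frame")
  ann
}

#' Scale strain responses by mutation-class multipliers
#'
#' Rescales each strain's inhibitor response relative to the ancestor's:
#' writing \eqn{r_i} for a strain's latent response (inhibited minus control)
#' and \eqn{r_a} for the ancestor's, the inhibited effect becomes
#' `control + r_a + m * (r_i - r_a)` with `m` the strain's class multiplier.
#' A multiplier of 0 therefore makes the strain respond exactly like the
#' ancestor; expected divergence is ordered with class severity.
#'
#' @param effects a `strain_effects` table.
#' @param annotation a `mutation_annotation` table covering every strain.
#' @return modified `strain_effects` table.
#' @export
apply_mutation_classes <- function(effects, annotation) {
  stopifnot(inherits(effects, "strain_effects"),
            all(effects$strain %in% annotation$strain))
  m <- annotation$multiplier[match(effects$strain, annotation$strain)]
  resp <- effects$inhibited - effects$control
  anc <- effects$strain == "ancestor"
  key <- paste(effects$stage, effects$dim)
  r_anc <- resp[anc][match(key, key[anc])]
  effects$inhibited <- effects$control + r_anc + m * (resp - r_anc)
  effects
}

#' Generate a per-cell trait table
#'
#' Simulates the paired-plate assay: for every strain x condition x replicate
#' x stage well, a uniformly drawn number of cells is generated, each cell's
#' trait vector being
#' `replicate offset + loadings' (strain effect + within-strain latent noise)
#' + measurement noise`, optionally passed through a monotone per-trait
#' transform.  Replicate offsets are additive, per trait, and shared by the
#' two conditions of a plate pair, mirroring a side-by-side design.
#'
#' @param config a [generator_config()].
#' @param effects a `strain_effects` table covering all strains, stages and
#'   latent dimensions of `config` (e.g. from [generate_strain_effects()]).
#' @return a data frame (the cell trait table) with metadata columns `strain`,
#'   `condition`, `replicate`, `stage` followed by one column per trait,
#'   namespaced by stage (`u_t001`, ...).  Cells carry `NA` in the trait
#'   columns of the stages they do not belong to.
#' @export
generate_cell_table <- function(config, effects) {
  stopifnot(inherits(config, "generator_config"),
            inherits(effects, "strain_effects"))
  tn <- .trait_names(config)
  all_traits <- unlist(tn)
  blocks <- vector("list", length(config$stages))
  for (s in seq_along(config$stages)) {
    stage <- config$stages[s]
    d <- config$latent_dims_per_stage[s]
    p <- config$traits_per_stage[s]
    L <- config$loadings[[s]]
    pars <- .dim_params(config, s)
    ef <- effects[effects$stage == stage, , drop = FALSE]
    if (nrow(ef) != config$n_strains * d)
      stop(sprintf("effects table does not cover stage '%s'", stage))
    idx <- match(ef$strain, config$strain_labels)
    u <- array(0, c(config$n_strains, d, 2))
    u[cbind(idx, ef$dim, 1L)] <- ef$control
    u[cbind(idx, ef$dim, 2L)] <- ef$inhibited

    set.seed(config$seed + 100L + s)
    n_wells <- config$n_strains * 2L * config$n_replicates
    lo <- config$cells_per_well[1]; hi <- config$cells_per_well[2]
    n_cells <- lo + sample.int(hi - lo + 1L, n_wells, replace = TRUE) - 1L
    rep_off <- matrix(rnorm(config$n_replicates * p, 0, config$replicate_sd),
                      config$n_replicates, p)
    total <- sum(n_cells)
    X <- matrix(0, total, p)
    meta_strain <- character(total); meta_cond <- character(total)
    meta_rep <- integer(total)
    ptr <- 0L; well <- 0L
    for (i in seq_len(config$n_strains)) {
      for (ci in 1:2) {
        sw <- if (ci == 1L) pars$sw1 else pars$sw2
        for (r in seq_len(config$n_replicates)) {
          well <- well + 1L
          n <- n_cells[well]
          rows <- ptr + seq_len(n)
          eps <- matrix(rnorm(n * d), n, d)
          eps <- eps * rep(sw, each = n)
          lat <- eps + rep(u[i, , ci], each = n)
          blockX <- lat %*% L + rep(rep_off[r, ], each = n)
          if (config$trait_noise_sd > 0)
            blockX <- blockX + matrix(rnorm(n * p, 0, config$trait_noise_sd), n, p)
          X[rows, ] <- blockX
          meta_strain[rows] <- config$strain_labels[i]
          meta_cond[rows] <- config$conditions[ci]
          meta_rep[rows] <- r
          ptr <- ptr + n
        }
      }
    }
    X <- .apply_transform(X, config$transform)
    colnames(X) <- tn[[s]]
    blocks[[s]] <- list(meta = data.frame(strain = meta_strain,
                                          condition = meta_cond,
                                          replicate = meta_rep,
                                          stage = stage,
                                          stringsAsFactors = FALSE),
                        X = X)
  }
  n_total <- sum(vapply(blocks, function(b) nrow(b$X), 0L))
  full <- matrix(NA_real_, n_total, length(all_traits),
                 dimnames = list(NULL, all_traits))
  metas <- vector("list", length(blocks))
  ptr <- 0L
  for (s in seq_along(blocks)) {
    rows <- ptr + seq_len(nrow(blocks[[s]]$X))
    full[rows, colnames(blocks[[s]]$X)] <- blocks[[s]]$X
    metas[[s]] <- blocks[[s]]$meta
    ptr <- ptr + length(rows)
  }
  cbind(do.call(rbind, metas), as.data.frame(full))
}

.apply_transform <- function(X, transform) {
  if (is.function(transform)) return(transform(X))
  switch(match.arg(transform, c("identity", "exp")),
         identity = X,
         exp = exp(X))
}
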