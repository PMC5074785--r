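#' Extract one phenotype's strain effects as a (control, inhibited) table
#'
#' @param effects a `strain_effects` table from [generate_strain_effects()].
#' @param stage,dim stage label and latent dimension index.
#' @return data frame with columns `strain`, `control`, `inhibited`.
#' @export
effect_slice <- function(effects, stage, dim) {
  out <- effects[effects$stage == stage & effects$dim == dim,
                 c("strain", "control", "inhibited"), drop = FALSE]
  if (!nrow(out)) stop("no effects for stage ", stage, ", dim ", dim)
  rownames(out) <- NULL
  class(out) <- "data.frame"
  out
}

#' Apply a stabilizing-selection sieve
#'
#' Removes the strains whose control-condition ("natural environment")
#' genotypic value falls outside a symmetric window around the population
#' center, emulating stabilizing selection acting before the inhibitor is
#' ever applied.  The window half-width is on the latent effect scale, whose
#' unit is the generating between-strain SD; `scale = "sd"` instead
#' multiplies `width` by the sample SD of the control effects.
#' Alternatively a target retained fraction may be given, keeping the
#' strains closest to the center.
#'
#' @param effects data frame with columns `strain`, `control`, `inhibited`
#'   (one phenotype; see [effect_slice()]).
#' @param width window half-width `c`; `Inf` retains everyone.
#' @param fraction alternatively, the fraction of strains to retain.
#' @param condition column the sieve acts on (default `"control"`).
#' @param center window center; defaults to the population mean.
#' @param scale `"raw"` (default) or `"sd"`.
#' @return the surviving subset of `effects`.
#' @export
apply_stabilizing_selection <- function(effects, width = NULL, fraction = NULL,
                                        condition = "control", center = NULL,
                                        scale = c("raw", "sd")) {
  stopifnot(is.data.frame(effects), condition %in% names(effects))
  if (nrow(effects) < 10L) stop("need at least 10 strains")
  g <- effects[[condition]]
  if (is.null(center)) center <- mean(g)
  dist <- abs(g - center)
  if (!is.null(fraction)) {
    stopifnot(is.null(width), fraction > 0, fraction <= 1)
    keep <- rank(dist, ties.method = "first") <= ceiling(fraction * length(g))
  } else {
    stopifnot(!is.null(width), width >= 0)
    scale <- match.arg(scale)
    if (scale == "sd") width <- width * sd(g)
    keep <- dist <= width
  }
  if (!any(keep)) stop("selection window removes all strains")
  effects[keep, , drop = FALSE]
}

#' Closed-form variance difference after truncation selection
#'
#' For bivariate-normal strain effects with SDs `sigma`, correlation `rho`,
#' truncated to `|control| <= width * sigma[1]`, the surviving control-
#' condition variance shrinks by the truncated-normal factor
#' \deqn{k = 1 - 2c\,\phi(c) / (2\Phi(c) - 1)} while the inhibited condition
#' retains its independent component, giving a post-selection variance
#' difference
#' \deqn{\Delta\sigma_{post} = \sigma_2\sqrt{\rho^2 k + 1 - \rho^2}
#'   - \sigma_1\sqrt{k}.}
#' For any `rho < 1` this is positive when `sigma[1] = sigma[2]`: selection
#' turns crossing-type epistasis into apparent buffering.
#'
#' @param width window half-width in units of the control SD.
#' @param rho cross-condition correlation.
#' @param sigma length-2 between-strain SDs (control, inhibited).
#' @return `Delta sigma` after selection (inhibited minus control SD).
#' @export
truncation_delta_sigma <- function(width, rho, sigma = c(1, 1)) {
  k <- truncation_variance_factor(width)
  sigma[2] * sqrt(rho^2 * k + 1 - rho^2) - sigma[1] * sqrt(k)
}

#' Variance retention factor of symmetric normal truncation
#' @param width half-width of the window, in SD units.
#' @return the factor `k` by which the variance shrinks.
#' @export
truncation_variance_factor <- function(width) {
  if (!is.finite(width)) return(1)
  1 - 2 * width * dnorm(width) / (2 * pnorm(width) - 1)
}

#' Selection scenario
#'
#' Bundles the inputs of the pre/post selection comparison: a bivariate
#' strain-effect population and a truncation sieve on the control condition.
#'
#' @param n_strains strains per Monte-Carlo replicate.
#' @param sigma_between length-2 between-strain SDs (control, inhibited).
#' @param rho_between cross-condition correlation.
#' @param width sieve half-width (control-SD units on the latent scale).
#' @param fraction alternatively, target retained fraction.
#' @param n_reps Monte-Carlo replicates.
#' @param seed RNG seed.
#' @return list of class `selection_scenario`.
#' @export
selection_scenario <- function(n_strains = 1e4, sigma_between = c(1, 1),
                               rho_between = 0.5, width = 1, fraction = NULL,
                               n_reps = 20L, seed = 1L) {
  stopifnot(n_strains >= 10, all(sigma_between >= 0), abs(rho_between) <= 1)
  structure(list(n_strains = as.integer(n_strains),
                 sigma_between = sigma_between, rho_between = rho_between,
                 width = width, fraction = fraction,
                 n_reps = as.integer(n_reps), seed = as.integer(seed)),
            class = "selection_scenario")
}

#' Compare variance structure before and after selection
#'
#' Monte-Carlo over replicate populations: draws bivariate strain effects,
#' computes the sample-moment variance components, variance difference and
#' line-spreading/crossing partition, applies the stabilizing-selection
#' sieve on the control condition, and recomputes everything on the
#' survivors.
#'
#' @param scenario a [selection_scenario()].
#' @return object of class `selection_outcome`: per-replicate table plus
#'   means of pre/post `delta_sigma`, pre/post spreading fraction, retained
#'   fraction, and the closed-form reference for the post-selection
#'   `delta_sigma` (exact under the sieve of `width`).
#' @export
pre_post_comparison <- function(scenario) {
  stopifnot(inherits(scenario, "selection_scenario"))
  set.seed(scenario$seed)
  s1 <- scenario$sigma_between[1]; s2 <- scenario$sigma_between[2]
  rho <- scenario$rho_between
  rows <- vector("list", scenario$n_reps)
  for (r in seq_len(scenario$n_reps)) {
    z1 <- rnorm(scenario$n_strains); z2 <- rnorm(scenario$n_strains)
    eff <- data.frame(strain = sprintf("s%06d", seq_len(scenario$n_strains)),
                      control = s1 * z1,
                      inhibited = s2 * (rho * z1 + sqrt(1 - rho^2) * z2))
    pre_vc <- moments_from_strain_means(eff$control, eff$inhibited)
    pre_part <- partition_interaction(pre_vc)
    post <- apply_stabilizing_selection(eff, width = scenario$width,
                                        fraction = scenario$fraction,
                                        center = 0)
    post_vc <- moments_from_strain_means(post$control, post$inhibited)
    post_part <- partition_interaction(post_vc)
    rows[[r]] <- data.frame(
      rep = r,
      pre_delta_sigma = pre_vc$sigma_b[2] - pre_vc$sigma_b[1],
      post_delta_sigma = post_vc$sigma_b[2] - post_vc$sigma_b[1],
      pre_spreading = pre_part$spreading_fraction,
      post_spreading = post_part$spreading_fraction,
      retained = nrow(post) / nrow(eff))
  }
  tab <- do.call(rbind, rows)
  structure(list(
    table = tab,
    pre_delta_sigma = mean(tab$pre_delta_sigma),
    post_delta_sigma = mean(tab$post_delta_sigma),
    pre_spreading = mean(tab$pre_spreading, na.rm = TRUE),
    post_spreading = mean(tab$post_spreading, na.rm = TRUE),
    retained = mean(tab$retained),
    closed_form = if (is.null(scenario$fraction))
      truncation_delta_sigma(scenario$width, rho,
                             scenario$sigma_between) else NA_real_,
    scenario = scenario), class = "selection_outcome")
}

#' @export
print.selection_outcome <- function(x, ...) {
  cat("Stabilizing-selection truncation (control-condition sieve)\n")
  cat(sprintf("  retained fraction %.3f over %d replicates of %d strains\n",
              x$retained, x$scenario$n_reps, x$scenario$n_strains))
  cat(sprintf("  Delta sigma: pre %+.4f -> post %+.4f",
              x$pre_delta_sigma, x$post_delta_sigma))
  if (!is.na(x$closed_form))
    cat(sprintf(" (closed form %+.4f)", x$closed_form))
  cat("\n")
  cat(sprintf("  spreading fraction: pre %.3f -> post %.3f\n",
              x$pre_spreading, x$post_spreading))
  invisible(x)
}
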