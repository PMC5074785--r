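#' Likelihood-ratio test for genotype-by-condition interaction
#'
#' Compares, by maximum likelihood, a mixed model with random strain and
#' random strain:condition terms (condition fixed) against the reduced model
#' without the interaction term.  Because the interaction variance sits on
#' the boundary of its parameter space under the null, the reference
#' distribution is the 50:50 mixture of a point mass at zero and chi-squared
#' with 1 df; calibration of this choice is verified by simulation in the
#' test suite.
#'
#' @param data data frame with columns `strain`, `condition` and the response
#'   named in `response`.
#' @param response name of the response column (default `"y"`).
#' @param alpha significance level for the flag (default 0.01).
#' @param phenotype optional phenotype ID carried through to the result.
#' @return object of class `lrt_result`: log-likelihoods, statistic, df,
#'   p-value, significance flag.
#' @export
fit_interaction_lrt <- function(data, response = "y", alpha = 0.01,
                                phenotype = NA_character_) {
  stopifnot(all(c("strain", "condition", response) %in% names(data)))
  if (length(unique(data$strain)) < 2L)
    stop("need at least 2 strains")
  if (length(unique(data$condition)) != 2L)
    stop("both conditions must be present")
  d <- data.frame(y = data[[response]],
                  strain = factor(data$strain),
                  condition = factor(data$condition))
  ctrl <- lme4::lmerControl(check.conv.singular = "ignore",
                            calc.derivs = FALSE)
  full <- lme4::lmer(y ~ condition + (1 | strain) + (1 | strain:condition),
                     data = d, REML = FALSE, control = ctrl)
  red <- lme4::lmer(y ~ condition + (1 | strain),
                    data = d, REML = FALSE, control = ctrl)
  ll_full <- as.numeric(logLik(full))
  ll_red <- as.numeric(logLik(red))
  stat <- max(0, 2 * (ll_full - ll_red))
  p <- if (stat <= 1e-10) 1 else 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
  structure(list(phenotype = phenotype, ll_full = ll_full,
                 ll_reduced = ll_red, statistic = stat, df = 1L,
                 p_value = p, alpha = alpha, significant = p < alpha),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat(sprintf("Genotype-by-condition LRT%s: stat = %.3f, p = %.3g (%ssignificant at %g)\n",
              if (is.na(x$phenotype)) "" else paste0(" [", x$phenotype, "]"),
              x$statistic, x$p_value, if (x$significant) "" else "not ",
              x$alpha))
  invisible(x)
}

#' Construct condition-specific variance components
#'
#' Container for the quantities feeding the line-spreading / line-crossing
#' partition: between-strain SDs per condition, their cross-condition
#' correlation, and (optionally) within-strain SDs per condition.
#'
#' @param sigma_b length-2 non-negative vector `(control, inhibited)`.
#' @param rho_b correlation in `[-1, 1]` (may be `NA` when degenerate).
#' @param sigma_w optional length-2 within-strain SDs.
#' @param n_strains optional number of strains behind the estimates.
#' @return object of class `variance_components`.
#' @export
variance_components <- function(sigma_b, rho_b, sigma_w = c(NA, NA),
                                n_strains = NA_integer_) {
  stopifnot(length(sigma_b) == 2L, all(sigma_b >= 0, na.rm = TRUE))
  if (!is.na(rho_b) && abs(rho_b) > 1) stop("|rho_b| must be <= 1")
  structure(list(sigma_b = unname(sigma_b), rho_b = unname(rho_b),
                 sigma_w = unname(sigma_w), n_strains = n_strains,
                 clipped = character(0)),
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("Variance components: sigma_b = (%.4g, %.4g), rho_b = %.4g\n",
              x$sigma_b[1], x$sigma_b[2], x$rho_b))
  if (!all(is.na(x$sigma_w)))
    cat(sprintf("                     sigma_w = (%.4g, %.4g)\n",
                x$sigma_w[1], x$sigma_w[2]))
  if (length(x$clipped))
    cat("  clipped to valid range:", paste(x$clipped, collapse = ", "), "\n")
  invisible(x)
}

#' Method-of-moments strain/condition variance components
#'
#' Computes per-strain condition means, then estimates the between-strain SD
#' in each condition — by default corrected for the sampling noise of the
#' strain means (subtracting the average within-strain variance over cell
#' count) — and the cross-condition correlation of strain effects,
#' disattenuated through the noise-corrected SDs.  Estimates outside their
#' valid ranges are clipped and the clipping recorded in the result.
#'
#' @param data data frame with columns `strain`, `condition` and the response
#'   named in `response`.
#' @param response response column name.
#' @param conditions optional ordered pair (control first); defaults to the
#'   order of first appearance.
#' @param correct_noise subtract mean-level sampling noise (default `TRUE`).
#'   With `FALSE` the estimates are the raw sample moments of the strain
#'   means, for which the Robertson identity holds exactly.
#' @return object of class `variance_components`; strains missing one
#'   condition are excluded with a warning.
#' @export
estimate_strain_condition_moments <- function(data, response = "y",
                                              conditions = NULL,
                                              correct_noise = TRUE) {
  stopifnot(all(c("strain", "condition", response) %in% names(data)))
  if (is.null(conditions)) conditions <- unique(data$condition)
  stopifnot(length(conditions) == 2L)
  y <- data[[response]]
  s <- as.character(data$strain)
  keep <- !is.na(y)
  y <- y[keep]; s <- s[keep]; cond <- as.character(data$condition)[keep]

  stats_for <- function(cnd) {
    i <- cond == cnd
    m <- tapply(y[i], s[i], mean)
    v <- tapply(y[i], s[i], var)
    n <- tapply(y[i], s[i], length)
    list(m = m, v = v, n = n)
  }
  s1 <- stats_for(conditions[1]); s2 <- stats_for(conditions[2])
  common <- intersect(names(s1$m), names(s2$m))
  all_strains <- union(names(s1$m), names(s2$m))
  if (length(common) < length(all_strains))
    warning("excluding strain(s) missing one condition: ",
            paste(setdiff(all_strains, common), collapse = ", "))
  if (length(common) < 3L) stop("need at least 3 strains in both conditions")
  m1 <- s1$m[common]; m2 <- s2$m[common]
  n1 <- s1$n[common]; n2 <- s2$n[common]

  # pooled within-strain variances per condition
  w1 <- .pooled_within(s1$v[common], n1)
  w2 <- .pooled_within(s2$v[common], n2)

  clipped <- character(0)
  V1 <- var(m1); V2 <- var(m2)
  if (correct_noise) {
    V1 <- V1 - mean(w1 / n1)
    V2 <- V2 - mean(w2 / n2)
  }
  if (!is.na(V1) && V1 < 0) { V1 <- 0; clipped <- c(clipped, "sigma_b[control]") }
  if (!is.na(V2) && V2 < 0) { V2 <- 0; clipped <- c(clipped, "sigma_b[inhibited]") }
  cv <- cov(m1, m2)
  if (V1 > 0 && V2 > 0) {
    rho <- cv / sqrt(V1 * V2)
    if (rho > 1) { rho <- 1; clipped <- c(clipped, "rho_b") }
    if (rho < -1) { rho <- -1; clipped <- c(clipped, "rho_b") }
  } else {
    rho <- NA_real_
  }
  out <- variance_components(c(sqrt(V1), sqrt(V2)), rho,
                             sigma_w = c(sqrt(w1), sqrt(w2)),
                             n_strains = length(common))
  out$clipped <- clipped
  out$degenerate <- is.na(rho)
  out
}

.pooled_within <- function(v, n) {
  ok <- n > 1
  if (!any(ok)) return(0)
  sum(v[ok] * (n[ok] - 1)) / sum(n[ok] - 1)
}

#' Variance components from strain-mean vectors
#'
#' Raw sample-moment components (no noise correction) computed directly from
#' per-strain condition means; the partition evaluated at these moments
#' satisfies the Robertson identity
#' \eqn{V_{spread} + V_{cross} = \mathrm{Var}(g_1 - g_2)/2} exactly.
#'
#' @param m_control,m_inhibited numeric vectors of per-strain means, aligned.
#' @return object of class `variance_components`.
#' @export
moments_from_strain_means <- function(m_control, m_inhibited) {
  stopifnot(length(m_control) == length(m_inhibited), length(m_control) >= 2)
  V1 <- var(m_control); V2 <- var(m_inhibited)
  rho <- if (V1 > 0 && V2 > 0) cov(m_control, m_inhibited) / sqrt(V1 * V2)
         else NA_real_
  out <- variance_components(c(sqrt(V1), sqrt(V2)), rho)
  out$degenerate <- is.na(rho)
  out
}

#' Partition interaction variance into line spreading and line crossing
#'
#' Robertson-type decomposition of the genotype-by-condition interaction
#' variance: writing \eqn{\sigma_1,\sigma_2} for the condition-specific
#' between-strain SDs and \eqn{\rho} for the cross-condition correlation of
#' strain effects,
#' \deqn{V_{int} = \underbrace{(\sigma_1-\sigma_2)^2/2}_{V_{spread}}
#'   + \underbrace{\sigma_1\sigma_2(1-\rho)}_{V_{cross}}.}
#' Line spreading captures changes in the amount of between-strain variance
#' (buffering or potentiation); line crossing captures changes in strain
#' rank order.  When `V_int` is 0 the fractions are undefined (`NA`).
#'
#' @param vc a `variance_components` object.
#' @return object of class `interaction_partition` with `V_int`, `V_spread`,
#'   `V_cross`, `spreading_fraction`, `crossing_fraction`.
#' @export
partition_interaction <- function(vc) {
  stopifnot(inherits(vc, "variance_components"))
  s1 <- vc$sigma_b[1]; s2 <- vc$sigma_b[2]; rho <- vc$rho_b
  if (is.na(rho)) rho <- 1  # degenerate: no crossing measurable
  v_spread <- (s1 - s2)^2 / 2
  v_cross <- s1 * s2 * (1 - rho)
  v_int <- v_spread + v_cross
  if (v_int > 0) {
    fs <- v_spread / v_int
    fc <- v_cross / v_int
  } else {
    fs <- fc <- NA_real_
  }
  structure(list(V_int = v_int, V_spread = v_spread, V_cross = v_cross,
                 spreading_fraction = fs, crossing_fraction = fc),
            class = "interaction_partition")
}

#' @export
print.interaction_partition <- function(x, ...) {
  cat(sprintf("Interaction variance %.4g = spreading %.4g + crossing %.4g\n",
              x$V_int, x$V_spread, x$V_cross))
  if (is.na(x$spreading_fraction))
    cat("  fractions undefined (no interaction variance)\n")
  else
    cat(sprintf("  spreading fraction %.3f, crossing fraction %.3f\n",
                x$spreading_fraction, x$crossing_fraction))
  invisible(x)
}
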