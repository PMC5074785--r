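#' Priors for the hierarchical variance model
#'
#' Weakly informative conjugate defaults: inverse-Wishart for the 2x2
#' between-strain covariance (degrees of freedom 3, scale `psi_b * I`) and a
#' scaled inverse-chi-squared with tiny degrees of freedom for each residual
#' variance; condition means carry improper flat priors.  Phenotypes are
#' expected on the unit-variance PC scale, where these settings are
#' essentially data-dominated from a handful of strains upward.
#'
#' @param nu_b inverse-Wishart degrees of freedom (> 1 for a 2x2 matrix).
#' @param psi_b scalar multiplying the identity scale matrix.
#' @param nu_w residual degrees of freedom.
#' @param s2_w residual scale.
#' @return list of class `vc_prior`.
#' @export
vc_prior <- function(nu_b = 3, psi_b = 0.1, nu_w = 0.002, s2_w = 1) {
  stopifnot(nu_b > 1, psi_b > 0, nu_w > 0, s2_w > 0)
  structure(list(nu_b = nu_b, psi_b = psi_b, nu_w = nu_w, s2_w = s2_w),
            class = "vc_prior")
}

#' Bivariate hierarchical variance-components model by Gibbs sampling
#'
#' Fits, per phenotype, the model
#' \deqn{y_{cij} = \mu_c + u_{ic} + e_{cij}, \qquad
#'   (u_{i,\mathrm{control}}, u_{i,\mathrm{inhibited}})' \sim N_2(0, \Sigma_b),
#'   \qquad e_{cij} \sim N(0, \sigma^2_{w,c}),}
#' i.e. condition-specific means, an unstructured bivariate between-strain
#' covariance (condition-specific between-strain variances plus their
#' correlation), and *separate within-strain variances per condition* —
#' the heteroscedasticity that inhibitor treatments are known to induce.
#' All full conditionals are conjugate (normal for strain effects and means,
#' inverse-Wishart for \eqn{\Sigma_b}, scaled inverse-chi-squared for the
#' residual variances), so the sampler is a plain Gibbs scheme over
#' per-strain sufficient statistics.
#'
#' @param formula two-sided formula `response ~ condition`; the right-hand
#'   side must name a two-level condition column of `data`.
#' @param data data frame holding the response, the condition column, and the
#'   strain column.
#' @param strain name of the strain column (default `"strain"`).
#' @param conditions optional ordered pair (control first); defaults to the
#'   order of first appearance in `data`.
#' @param prior a [vc_prior()].
#' @param n_iter total iterations (default 13000).
#' @param burnin discarded iterations (default 3000).
#' @param thin thinning interval (default 10; defaults retain 1000 draws).
#' @param seed optional RNG seed; a fit is reproducible given the seed.
#' @return object of class `vc_mcmc` with the retained draws of
#'   `sigma_b_control`, `sigma_b_inhibited`, `rho_b`, `sigma_w_control`,
#'   `sigma_w_inhibited`, `mu_control`, `mu_inhibited`, plus effective sample
#'   sizes and split-chain R-hat per parameter.
#' @examples
#' d <- expand.grid(strain = paste0("s", 1:12), cell = 1:20,
#'                  condition = c("control", "inhibited"))
#' u <- matrix(rnorm(24, 0, 0.5), 12, 2)
#' d$y <- u[cbind(as.integer(d$strain), as.integer(d$condition))] + rnorm(nrow(d))
#' fit <- fit_variance_mcmc(y ~ condition, d, n_iter = 600, burnin = 100,
#'                          thin = 5, seed = 1)
#' coef(fit)
#' @export
fit_variance_mcmc <- function(formula, data, strain = "strain",
                              conditions = NULL, prior = vc_prior(),
                              n_iter = 13000L, burnin = 3000L, thin = 10L,
                              seed = NULL) {
  stopifnot(inherits(formula, "formula"), n_iter > burnin, thin >= 1)
  vars <- all.vars(formula)
  if (length(vars) != 2L) stop("formula must be 'response ~ condition'")
  if (!all(vars %in% names(data)))
    stop("formula variables not found in data")
  if (!strain %in% names(data)) stop("no strain column '", strain, "'")
  y <- data[[vars[1]]]
  cond <- as.character(data[[vars[2]]])
  s <- as.character(data[[strain]])
  ok <- !is.na(y)
  y <- y[ok]; cond <- cond[ok]; s <- s[ok]
  if (is.null(conditions)) conditions <- unique(cond)
  if (length(conditions) != 2L || !all(cond %in% conditions))
    stop("condition must have exactly two levels")

  # strains observed in both conditions
  both <- intersect(unique(s[cond == conditions[1]]),
                    unique(s[cond == conditions[2]]))
  if (length(both) < 3L) stop("need >= 3 strains observed in both conditions")
  if (length(both) < length(unique(s)))
    warning("excluding strain(s) missing one condition")
  keep <- s %in% both
  y <- y[keep]; s <- factor(s[keep], levels = both); cond <- cond[keep]
  ci <- ifelse(cond == conditions[1], 1L, 2L)

  I <- length(both)
  suff <- function(w) {
    list(n = as.numeric(tapply(y[w], s[w], length)),
         sum = as.numeric(tapply(y[w], s[w], sum)),
         ss = as.numeric(tapply(y[w], s[w], function(v) sum(v^2))))
  }
  st1 <- suff(ci == 1L); st2 <- suff(ci == 2L)
  N1 <- sum(st1$n); N2 <- sum(st2$n)
  m1 <- st1$sum / st1$n; m2 <- st2$sum / st2$n

  if (!is.null(seed)) set.seed(seed)
  # initial values from crude moments
  mu <- c(sum(st1$sum) / N1, sum(st2$sum) / N2)
  s2w <- c(max(1e-6, sum(st1$ss - st1$n * m1^2) / N1),
           max(1e-6, sum(st2$ss - st2$n * m2^2) / N2))
  Sigma <- diag(c(max(var(m1), 1e-4), max(var(m2), 1e-4)))
  u1 <- m1 - mu[1]; u2 <- m2 - mu[2]

  n_keep <- floor((n_iter - burnin) / thin)
  draws <- matrix(NA_real_, n_keep, 7L,
                  dimnames = list(NULL, c("sigma_b_control",
                                          "sigma_b_inhibited", "rho_b",
                                          "sigma_w_control",
                                          "sigma_w_inhibited",
                                          "mu_control", "mu_inhibited")))
  Psi0 <- diag(prior$psi_b, 2L)
  kept <- 0L
  for (it in seq_len(n_iter)) {
    # strain effects: vectorized 2x2 conjugate normal updates
    Sinv <- .inv2(Sigma)
    d1 <- st1$n / s2w[1]; d2 <- st2$n / s2w[2]
    A <- Sinv[1] + d1; C <- Sinv[3] + d2; B <- Sinv[2]
    det <- A * C - B^2
    b1 <- d1 * (m1 - mu[1]); b2 <- d2 * (m2 - mu[2])
    mu_u1 <- (C * b1 - B * b2) / det
    mu_u2 <- (A * b2 - B * b1) / det
    v11 <- C / det; v12 <- -B / det; v22 <- A / det
    z1 <- rnorm(I); z2 <- rnorm(I)
    sd1 <- sqrt(v11)
    u1 <- mu_u1 + sd1 * z1
    u2 <- mu_u2 + (v12 / sd1) * z1 + sqrt(pmax(v22 - v12^2 / v11, 0)) * z2

    # condition means (flat prior)
    mu[1] <- rnorm(1, sum(st1$sum - st1$n * u1) / N1, sqrt(s2w[1] / N1))
    mu[2] <- rnorm(1, sum(st2$sum - st2$n * u2) / N2, sqrt(s2w[2] / N2))

    # residual variances, condition-specific
    a1 <- mu[1] + u1; a2 <- mu[2] + u2
    sse1 <- sum(st1$ss - 2 * a1 * st1$sum + st1$n * a1^2)
    sse2 <- sum(st2$ss - 2 * a2 * st2$sum + st2$n * a2^2)
    s2w[1] <- (prior$nu_w * prior$s2_w + sse1) / rchisq(1, prior$nu_w + N1)
    s2w[2] <- (prior$nu_w * prior$s2_w + sse2) / rchisq(1, prior$nu_w + N2)

    # between-strain covariance: inverse-Wishart
    S <- matrix(c(sum(u1^2), sum(u1 * u2), sum(u1 * u2), sum(u2^2)), 2L)
    W <- rWishart(1L, prior$nu_b + I, .inv2m(Psi0 + S))[, , 1L]
    Sigma <- .inv2m(W)

    if (it > burnin && (it - burnin) %% thin == 0L) {
      kept <- kept + 1L
      draws[kept, ] <- c(sqrt(Sigma[1, 1]), sqrt(Sigma[2, 2]),
                         Sigma[1, 2] / sqrt(Sigma[1, 1] * Sigma[2, 2]),
                         sqrt(s2w[1]), sqrt(s2w[2]), mu[1], mu[2])
    }
  }
  draws <- draws[seq_len(kept), , drop = FALSE]
  structure(list(draws = draws,
                 conditions = conditions,
                 n_strains = I,
                 n_cells = c(N1, N2),
                 prior = prior,
                 settings = list(n_iter = n_iter, burnin = burnin,
                                 thin = thin, seed = seed),
                 ess = apply(draws, 2, .ess),
                 rhat = apply(draws, 2, .split_rhat),
                 call = match.call()),
            class = "vc_mcmc")
}

# 2x2 symmetric inverse; vector form c(i11, i12, i22) for speed in the loop
.inv2 <- function(M) {
  det <- M[1, 1] * M[2, 2] - M[1, 2]^2
  c(M[2, 2], -M[1, 2], M[1, 1]) / det
}
.inv2m <- function(M) {
  det <- M[1, 1] * M[2, 2] - M[1, 2]^2
  matrix(c(M[2, 2], -M[1, 2], -M[1, 2], M[1, 1]) / det, 2L)
}

# effective sample size from the initial positive autocorrelation sequence
.ess <- function(x) {
  n <- length(x)
  if (n < 4L || var(x) == 0) return(n)
  r <- as.numeric(acf(x, lag.max = min(n - 1L, 200L), plot = FALSE)$acf)[-1]
  neg <- which(r < 0)
  if (length(neg)) r <- r[seq_len(neg[1] - 1L)]
  min(n, n / (1 + 2 * sum(r)))
}

# split-chain potential scale reduction on a single chain
.split_rhat <- function(x) {
  n2 <- floor(length(x) / 2)
  if (n2 < 2L) return(NA_real_)
  m <- cbind(x[seq_len(n2)], x[seq.int(length(x) - n2 + 1L, length(x))])
  W <- mean(apply(m, 2, var))
  if (W == 0) return(1)
  B <- n2 * var(colMeans(m))
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' Multi-chain split R-hat across independently seeded fits
#' @param fits list of `vc_mcmc` objects fitted to the same data.
#' @param par parameter name (column of the draws).
#' @return the potential scale reduction factor.
#' @export
chain_rhat <- function(fits, par) {
  chains <- lapply(fits, function(f) as.matrix(f)[, par])
  n2 <- floor(min(lengths(chains)) / 2)
  halves <- do.call(cbind, lapply(chains, function(x)
    cbind(x[seq_len(n2)], x[seq.int(length(x) - n2 + 1L, length(x))])))
  W <- mean(apply(halves, 2, var))
  if (W == 0) return(1)
  B <- n2 * var(colMeans(halves))
  sqrt(((n2 - 1) / n2 * W + B / n2) / W)
}

#' @export
print.vc_mcmc <- function(x, ...) {
  cat("Hierarchical strain-by-condition variance model (Gibbs sampler)\n")
  cat(sprintf("  %d strains; %d / %d cells (%s / %s); %d retained draws\n",
              x$n_strains, x$n_cells[1], x$n_cells[2],
              x$conditions[1], x$conditions[2], nrow(x$draws)))
  med <- apply(x$draws, 2, median)
  cat(sprintf("  posterior medians: sigma_b = (%.3f, %.3f), rho_b = %.3f, sigma_w = (%.3f, %.3f)\n",
              med[1], med[2], med[3], med[4], med[5]))
  invisible(x)
}

#' @export
coef.vc_mcmc <- function(object, ...) apply(object$draws, 2, median)

#' @export
as.matrix.vc_mcmc <- function(x, ...) x$draws

#' @export
summary.vc_mcmc <- function(object, mass = 0.95, ...) {
  d <- object$draws
  hpds <- t(apply(d, 2, hpd_interval, mass = mass,
                  min_draws = min(100L, nrow(d))))
  out <- data.frame(median = apply(d, 2, median),
                    mean = colMeans(d),
                    sd = apply(d, 2, sd),
                    hpd_lower = hpds[, 1], hpd_upper = hpds[, 2],
                    ess = object$ess, rhat = object$rhat)
  structure(list(table = out, mass = mass, n_strains = object$n_strains),
            class = "summary.vc_mcmc")
}

#' @export
print.summary.vc_mcmc <- function(x, ...) {
  cat(sprintf("Posterior summary (%d strains, %.0f%% HPD intervals)\n",
              x$n_strains, 100 * x$mass))
  print(round(x$table, 4))
  invisible(x)
}

#' @export
plot.vc_mcmc <- function(x, pars = c("sigma_b_control", "sigma_b_inhibited",
                                     "rho_b"), ...) {
  old <- par(mfrow = c(length(pars), 2), mar = c(3, 4, 1.5, 1))
  on.exit(par(old))
  for (p in pars) {
    v <- x$draws[, p]
    plot(v, type = "l", xlab = "", ylab = p, main = "")
    plot(density(v), main = "", xlab = p)
  }
  invisible(x)
}

#' @export
simulate.vc_mcmc <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  idx <- sample.int(nrow(object$draws), nsim, replace = TRUE)
  lapply(idx, function(i) {
    d <- object$draws[i, ]
    z1 <- rnorm(object$n_strains); z2 <- rnorm(object$n_strains)
    rho <- d["rho_b"]
    data.frame(
      strain = paste0("sim", seq_len(object$n_strains)),
      control = d["mu_control"] + d["sigma_b_control"] * z1,
      inhibited = d["mu_inhibited"] +
        d["sigma_b_inhibited"] * (rho * z1 + sqrt(1 - rho^2) * z2))
  })
}

#' Highest posterior density interval
#'
#' The shortest contiguous interval containing `ceiling(mass * n)` of the
#' sorted draws; among tied shortest windows the one with the lowest lower
#' bound is returned.
#'
#' @param draws numeric vector of posterior draws.
#' @param mass interval mass in (0, 1), default 0.95.
#' @param min_draws minimum number of draws required (default 100).
#' @return named numeric `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95, min_draws = 100L) {
  stopifnot(mass > 0, mass < 1)
  n <- length(draws)
  if (n < min_draws)
    stop(sprintf("need at least %d draws, have %d", min_draws, n))
  x <- sort(draws)
  m <- ceiling(mass * n)
  if (m >= n) return(c(lower = x[1], upper = x[n]))
  widths <- x[m:n] - x[1:(n - m + 1L)]
  i <- which.min(widths)  # first minimum = lowest lower bound on ties
  c(lower = x[i], upper = x[i + m - 1L])
}

#' Posterior test of the between-strain variance difference
#'
#' Computes per draw the difference of between-strain SDs,
#' \eqn{\Delta\sigma = \sigma_{b,\mathrm{inhibited}} -
#' \sigma_{b,\mathrm{control}}}, its posterior median and HPD interval, and
#' calls the difference significant when the interval excludes zero.  A
#' significant positive difference means inhibition reveals variation
#' (buffering); a significant negative one means inhibition hides variation
#' (potentiation).
#'
#' @param object a `vc_mcmc` fit, or a numeric vector of \eqn{\Delta\sigma}
#'   draws.
#' @param mass HPD mass (default 0.95).
#' @param phenotype optional phenotype ID carried through.
#' @return object of class `variance_difference`: `median`, `hpd`,
#'   `significant`, `direction` (`"buffering-revealed"`,
#'   `"potentiation-hidden"` or `"none"`), and the draws.
#' @export
variance_difference <- function(object, mass = 0.95,
                                phenotype = NA_character_) {
  delta <- if (inherits(object, "vc_mcmc"))
    object$draws[, "sigma_b_inhibited"] - object$draws[, "sigma_b_control"]
  else as.numeric(object)
  hpd <- hpd_interval(delta, mass = mass,
                      min_draws = min(100L, length(delta)))
  med <- median(delta)
  sig <- hpd[1] > 0 || hpd[2] < 0
  dir <- if (!sig) "none"
         else if (med > 0) "buffering-revealed" else "potentiation-hidden"
  structure(list(phenotype = phenotype, median = med, hpd = hpd,
                 mass = mass, significant = sig, direction = dir,
                 draws = delta),
            class = "variance_difference")
}

#' @export
print.variance_difference <- function(x, ...) {
  cat(sprintf("Delta sigma_b (inhibited - control)%s: median %.4f, %.0f%% HPD [%.4f, %.4f]\n",
              if (is.na(x$phenotype)) "" else paste0(" [", x$phenotype, "]"),
              x$median, 100 * x$mass, x$hpd[1], x$hpd[2]))
  cat(sprintf("  %s\n", if (x$significant)
    paste("significant:", x$direction) else "not significant"))
  invisible(x)
}

#' Collection-level summary of variance differences
#'
#' Summarizes the per-phenotype posterior-median variance differences of a
#' strain collection by their median, IQR and the boxplot notch half-width
#' `1.58 * IQR / sqrt(n)` (roughly a 95% confidence interval around the
#' median); the collection tends toward buffering (potentiation) when the
#' notch interval lies entirely above (below) zero.
#'
#' @param deltas numeric vector of per-phenotype \eqn{\Delta\sigma} medians,
#'   or a list of [variance_difference()] results.
#' @param label collection label.
#' @return object of class `collection_summary` with `median`, `iqr`,
#'   `notch`, `tendency`, and counts of significantly increased / decreased
#'   phenotypes (when flags are available).
#' @export
collection_summary <- function(deltas, label = "collection") {
  n_up <- n_down <- NA_integer_
  if (is.list(deltas) && all(vapply(deltas, inherits, TRUE,
                                    "variance_difference"))) {
    sig <- vapply(deltas, `[[`, TRUE, "significant")
    med <- vapply(deltas, `[[`, 0, "median")
    n_up <- sum(sig & med > 0)
    n_down <- sum(sig & med < 0)
    deltas <- med
  }
  deltas <- as.numeric(deltas)
  if (length(deltas) < 3L) stop("need at least 3 phenotypes")
  m <- median(deltas)
  iqr <- IQR(deltas)
  notch <- 1.58 * iqr / sqrt(length(deltas))
  tendency <- if (m - notch > 0) "buffering"
              else if (m + notch < 0) "potentiation" else "none"
  structure(list(label = label, n = length(deltas), median = m, iqr = iqr,
                 notch = notch, tendency = tendency,
                 n_significant_up = n_up, n_significant_down = n_down,
                 deltas = deltas),
            class = "collection_summary")
}

#' @export
print.collection_summary <- function(x, ...) {
  cat(sprintf("Collection '%s' (%d phenotypes): median Delta sigma %.4f, IQR %.4f, notch %.4f\n",
              x$label, x$n, x$median, x$iqr, x$notch))
  cat(sprintf("  tendency: %s", x$tendency))
  if (!is.na(x$n_significant_up))
    cat(sprintf(" (%d significantly increased, %d decreased)",
                x$n_significant_up, x$n_significant_down))
  cat("\n")
  invisible(x)
}
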