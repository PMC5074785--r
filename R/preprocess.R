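#' @keywords internal
.META_COLS <- c("strain", "condition", "replicate", "stage")

.trait_cols <- function(table) setdiff(names(table), .META_COLS)

.check_cell_table <- function(table) {
  miss <- setdiff(.META_COLS, names(table))
  if (length(miss))
    stop("missing metadata column(s): ", paste(miss, collapse = ", "))
  invisible(table)
}

# Box-Cox profile log-likelihood for positive data x at exponent lambda.
.boxcox_ll <- function(x, lambda, slx = sum(log(x))) {
  y <- if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
  n <- length(x)
  v <- sum((y - mean(y))^2) / n
  -n / 2 * log(v) + (lambda - 1) * slx
}

#' Box-Cox exponent by golden-section search
#'
#' Maximizes the Box-Cox profile log-likelihood over `[lower, upper]` by
#' golden-section search (the profile is assumed unimodal).
#'
#' @param x positive numeric vector.
#' @param lower,upper search bounds for the exponent.
#' @param tol absolute convergence tolerance on the exponent.
#' @return the maximizing exponent.
#' @export
boxcox_lambda <- function(x, lower = -3, upper = 3, tol = 1e-4) {
  stopifnot(all(x > 0), length(x) > 1)
  slx <- sum(log(x))
  gr <- (sqrt(5) - 1) / 2
  a <- lower; b <- upper
  c1 <- b - gr * (b - a); c2 <- a + gr * (b - a)
  f1 <- .boxcox_ll(x, c1, slx); f2 <- .boxcox_ll(x, c2, slx)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- c1; c1 <- c2; f1 <- f2
      c2 <- a + gr * (b - a); f2 <- .boxcox_ll(x, c2, slx)
    } else {
      b <- c2; c2 <- c1; f2 <- f1
      c1 <- b - gr * (b - a); f1 <- .boxcox_ll(x, c1, slx)
    }
  }
  (a + b) / 2
}

#' Apply a Box-Cox transform
#' @param x positive numeric vector.
#' @param lambda exponent; `lambda == 0` means `log`.
#' @return transformed vector.
#' @export
boxcox_transform <- function(x, lambda) {
  if (abs(lambda) < 1e-8) log(x) else (x^lambda - 1) / lambda
}

#' Box-Cox transform and standardize every trait
#'
#' Per trait (pooling all cells, both conditions): shifts values positive if
#' needed, estimates the Box-Cox exponent by profile likelihood, transforms,
#' and standardizes to mean 0 and SD 1.  Standardization always uses the
#' pooled mean and SD, never per-condition ones, so differences in variance
#' between conditions survive normalization.  Constant traits are dropped
#' with a warning (the transform is undefined for them).
#'
#' @param table a cell trait table (metadata columns plus trait columns).
#' @param lower,upper search bounds for the exponent.
#' @return a list with elements `table` (transformed) and `fits` (a data
#'   frame per trait: `trait`, `lambda`, `shift`, `mean`, `sd`).
#' @export
boxcox_normalize <- function(table, lower = -3, upper = 3) {
  .check_cell_table(table)
  traits <- .trait_cols(table)
  fits <- vector("list", length(traits))
  drop <- character(0)
  for (tr in traits) {
    x <- table[[tr]]
    ok <- !is.na(x)
    v <- x[ok]
    if (length(unique(v)) < 2L) {
      drop <- c(drop, tr)
      next
    }
    shift <- 0
    if (min(v) <= 0) {
      eps <- 1e-6 * (max(v) - min(v))
      shift <- eps - min(v)
      v <- v + shift
    }
    lam <- boxcox_lambda(v, lower, upper)
    y <- boxcox_transform(v, lam)
    mu <- mean(y)
    sd1 <- sqrt(sum((y - mu)^2) / (length(y) - 1))
    table[[tr]][ok] <- (y - mu) / sd1
    fits[[tr]] <- data.frame(trait = tr, lambda = lam, shift = shift,
                             mean = mu, sd = sd1, stringsAsFactors = FALSE)
  }
  if (length(drop)) {
    warning("dropping constant trait(s): ", paste(drop, collapse = ", "))
    table <- table[, setdiff(names(table), drop), drop = FALSE]
  }
  list(table = table, fits = do.call(rbind, fits[!vapply(fits, is.null, TRUE)]))
}

#' Remove replicate-plate effects
#'
#' Per trait, estimates replicate main effects by least squares with
#' replicate as a categorical factor and condition retained in the model,
#' then subtracts the (centered) replicate component, leaving the grand mean
#' and the condition and strain contrasts unchanged in expectation.
#'
#' @param table a cell trait table, normally after [boxcox_normalize()].
#' @return corrected table.
#' @export
remove_replicate_effects <- function(table) {
  .check_cell_table(table)
  if (length(unique(table$replicate)) < 2L) {
    warning("single replicate: nothing to remove")
    return(table)
  }
  traits <- .trait_cols(table)
  for (stage in unique(table$stage)) {
    rows <- which(table$stage == stage)
    sub <- table[rows, , drop = FALSE]
    st_traits <- traits[colSums(!is.na(sub[traits])) > 0L]
    if (!length(st_traits)) next
    repf <- factor(sub$replicate)
    if (nlevels(repf) < 2L) next
    X <- model.matrix(~ repf + factor(sub$condition))
    Y <- as.matrix(sub[st_traits])
    B <- qr.coef(qr(X), Y)
    rep_cols <- grep("^repf", colnames(X))
    rep_part <- X[, rep_cols, drop = FALSE] %*% B[rep_cols, , drop = FALSE]
    rep_part <- sweep(rep_part, 2, colMeans(rep_part))
    table[rows, st_traits] <- Y - rep_part
  }
  table
}

#' Restrict to a whitelist of traits
#'
#' @param table a cell trait table.
#' @param whitelist character vector of trait IDs to keep.
#' @param quiet suppress the per-stage count message.
#' @return the filtered table.
#' @export
filter_traits <- function(table, whitelist, quiet = FALSE) {
  .check_cell_table(table)
  if (!length(whitelist)) stop("empty trait whitelist")
  traits <- .trait_cols(table)
  missing <- setdiff(whitelist, traits)
  if (length(missing))
    stop("whitelisted trait(s) absent from table: ",
         paste(missing, collapse = ", "))
  out <- table[, c(.META_COLS, whitelist), drop = FALSE]
  if (!quiet) {
    per_stage <- vapply(unique(out$stage), function(s) {
      rows <- out$stage == s
      sum(colSums(!is.na(out[rows, whitelist, drop = FALSE])) > 0L)
    }, 0L)
    message("traits retained per stage: ",
            paste(sprintf("%s=%d", names(per_stage), per_stage), collapse = ", "))
  }
  out
}

#' Stage-specific principal components
#'
#' Fits a PCA on all cells of one cell-cycle stage, pooled over strains and
#' conditions (no condition label enters centering or scaling), retains
#' either a requested number of components or the smallest number reaching a
#' variance target, and rescales each retained component so its overall score
#' variance is exactly 1.  Components are oriented so their
#' largest-magnitude loading is positive.
#'
#' @param table normalized cell trait table.
#' @param stage stage label present in `table`.
#' @param n_components number of PCs to retain.
#' @param variance_target alternatively, the cumulative variance fraction to
#'   reach; ignored when `n_components` is given.
#' @return object of class `pc_dataset`: `scores` (metadata plus `PC1`...),
#'   `loadings` (trait x PC, orthonormal), `var_explained`, `scale` (the
#'   per-PC SDs divided out), `stage`.
#' @export
compute_pcs <- function(table, stage, n_components = NULL,
                        variance_target = NULL) {
  .check_cell_table(table)
  rows <- which(table$stage == stage)
  if (!length(rows)) stop("stage not present: ", stage)
  traits <- .trait_cols(table)
  sub <- table[rows, , drop = FALSE]
  st_traits <- traits[colSums(!is.na(sub[traits])) > 0L]
  X <- as.matrix(sub[st_traits])
  if (anyNA(X)) stop("stage block contains missing trait values")
  fit <- prcomp(X, center = TRUE, scale. = FALSE)
  ve <- fit$sdev^2 / sum(fit$sdev^2)
  if (is.null(n_components)) {
    if (is.null(variance_target))
      stop("give n_components or variance_target")
    n_components <- which(cumsum(ve) >= variance_target)[1]
    if (is.na(n_components)) n_components <- length(ve)
  }
  if (n_components > ncol(X))
    stop("n_components exceeds number of traits")
  k <- seq_len(n_components)
  rot <- fit$rotation[, k, drop = FALSE]
  # deterministic sign: largest-|loading| entry positive
  flip <- vapply(k, function(j) {
    l <- rot[, j]; sign(l[which.max(abs(l))]) < 0
  }, TRUE)
  rot[, flip] <- -rot[, flip]
  scores <- fit$x[, k, drop = FALSE]
  scores[, flip] <- -scores[, flip]
  sds <- apply(scores, 2, sd)
  scores <- sweep(scores, 2, sds, "/")
  colnames(scores) <- colnames(rot) <- paste0("PC", k)
  structure(list(
    scores = cbind(sub[.META_COLS], as.data.frame(scores)),
    loadings = rot,
    var_explained = ve[k],
    scale = sds,
    stage = stage), class = "pc_dataset")
}

#' @export
print.pc_dataset <- function(x, ...) {
  cat(sprintf("Stage '%s': %d cells, %d PCs explaining %.1f%% of variance\n",
              x$stage, nrow(x$scores), ncol(x$loadings),
              100 * sum(x$var_explained)))
  invisible(x)
}

#' Full preprocessing chain
#'
#' Runs the fixed pipeline Box-Cox -> standardize -> replicate correction ->
#' optional trait filter -> per-stage PCA -> per-PC scaling, and returns the
#' per-stage PC datasets.
#'
#' @param table raw cell trait table.
#' @param whitelist optional trait whitelist (see [filter_traits()]).
#' @param n_pcs integer vector of PCs to retain, one entry per stage in the
#'   order the stages appear (defaults to 6/9/14, recycled as needed).
#' @param variance_target alternative to `n_pcs`.
#' @param quiet suppress progress messages.
#' @return a list of class `pc_pipeline`: per-stage `pc_dataset` objects
#'   (named by stage), plus `boxcox` fits.
#' @export
preprocess_cells <- function(table, whitelist = NULL,
                             n_pcs = c(6L, 9L, 14L),
                             variance_target = NULL, quiet = TRUE) {
  .check_cell_table(table)
  bc <- boxcox_normalize(table)
  tab <- remove_replicate_effects(bc$table)
  if (!is.null(whitelist)) tab <- filter_traits(tab, whitelist, quiet = quiet)
  stages <- unique(tab$stage)
  n_pcs <- rep_len(n_pcs, length(stages))
  pcs <- lapply(seq_along(stages), function(s)
    compute_pcs(tab, stages[s],
                n_components = if (is.null(variance_target)) n_pcs[s] else NULL,
                variance_target = variance_target))
  names(pcs) <- stages
  structure(list(pcs = pcs, boxcox = bc$fits), class = "pc_pipeline")
}

#' @export
print.pc_pipeline <- function(x, ...) {
  cat("Preprocessed cell-morphology dataset\n")
  for (p in x$pcs) print(p)
  invisible(x)
}

#' Per-cell scores for one phenotype
#'
#' Extracts the per-cell score column of one retained PC ("phenotype") as a
#' plain data frame ready for model fitting.
#'
#' @param x a `pc_pipeline` or a single `pc_dataset`.
#' @param phenotype phenotype ID `"<stage>_PC<k>"` (for a pipeline) or
#'   `"PC<k>"` (for a single dataset).
#' @return data frame with columns `strain`, `condition`, `replicate`, `y`.
#' @export
phenotype_scores <- function(x, phenotype) {
  if (inherits(x, "pc_pipeline")) {
    hit <- regmatches(phenotype, regexec("^(.*)_(PC\\d+)$", phenotype))[[1]]
    if (length(hit) != 3L || !hit[2] %in% names(x$pcs))
      stop("unknown phenotype: ", phenotype)
    x <- x$pcs[[hit[2]]]
    phenotype <- hit[3]
  }
  stopifnot(inherits(x, "pc_dataset"))
  if (!phenotype %in% names(x$scores)) stop("unknown phenotype: ", phenotype)
  data.frame(strain = x$scores$strain, condition = x$scores$condition,
             replicate = x$scores$replicate, y = x$scores[[phenotype]],
             stringsAsFactors = FALSE)
}

#' All phenotype IDs of a preprocessed dataset
#' @param x a `pc_pipeline`.
#' @return character vector like `"unbudded_PC1"`, ordered by stage then PC.
#' @export
phenotype_ids <- function(x) {
  stopifnot(inherits(x, "pc_pipeline"))
  unlist(lapply(names(x$pcs), function(s)
    paste0(s, "_", colnames(x$pcs[[s]]$loadings))), use.names = FALSE)
}
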