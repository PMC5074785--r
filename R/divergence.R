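#' Per-strain inhibitor-response matrix
#'
#' For every strain, the per-phenotype response is the strain's mean score in
#' the inhibited condition minus its mean in the control condition.  Accepts
#' a preprocessed dataset (all stages, phenotypes concatenated in stage/PC
#' order) or a plain score data frame.
#'
#' @param x a `pc_pipeline`, a `pc_dataset`, or a data frame with columns
#'   `strain`, `condition` and phenotype columns.
#' @param conditions ordered pair (control first); default order of first
#'   appearance.
#' @return numeric matrix, strains x phenotypes.
#' @export
response_matrix <- function(x, conditions = NULL) {
  if (inherits(x, "pc_pipeline")) {
    mats <- lapply(names(x$pcs), function(s) {
      m <- response_matrix(x$pcs[[s]]$scores, conditions)
      colnames(m) <- paste0(s, "_", colnames(m))
      m
    })
    strains <- sort(unique(unlist(lapply(mats, rownames))))
    out <- do.call(cbind, lapply(mats, function(m) m[strains, , drop = FALSE]))
    return(out)
  }
  if (inherits(x, "pc_dataset")) x <- x$scores
  stopifnot(all(c("strain", "condition") %in% names(x)))
  if (is.null(conditions)) conditions <- unique(x$condition)
  stopifnot(length(conditions) == 2L)
  phen <- setdiff(names(x), .META_COLS)
  phen <- phen[vapply(x[phen], is.numeric, TRUE)]
  agg <- function(cnd) {
    sub <- x[x$condition == cnd, , drop = FALSE]
    do.call(cbind, lapply(phen, function(p)
      tapply(sub[[p]], sub$strain, mean)))
  }
  m1 <- agg(conditions[1]); m2 <- agg(conditions[2])
  strains <- intersect(rownames(m1), rownames(m2))
  out <- m2[strains, , drop = FALSE] - m1[strains, , drop = FALSE]
  colnames(out) <- phen
  out[order(rownames(out)), , drop = FALSE]
}

#' Response vector of one strain
#'
#' @param x a response matrix (see [response_matrix()]), `pc_pipeline` or
#'   score data frame.
#' @param strain strain ID.
#' @param scope `"all"` for the concatenation of all phenotypes, or a stage
#'   label to restrict to that stage's phenotypes (matched by the
#'   `"<stage>_"` prefix of the phenotype names).
#' @param ... passed on to [response_matrix()] when `x` is not a matrix.
#' @return object of class `response_vector`: `strain`, `scope`, `response`
#'   (named numeric), `magnitude` (Euclidean norm).
#' @export
response_vector <- function(x, strain, scope = "all", ...) {
  if (!is.matrix(x)) x <- response_matrix(x, ...)
  if (!strain %in% rownames(x)) stop("strain not observed in both conditions: ", strain)
  v <- x[strain, ]
  if (scope != "all") {
    sel <- startsWith(colnames(x), paste0(scope, "_"))
    if (!any(sel)) stop("no phenotypes in scope: ", scope)
    v <- v[sel]
  }
  structure(list(strain = strain, scope = scope, response = v,
                 magnitude = sqrt(sum(v^2))),
            class = "response_vector")
}

#' @export
print.response_vector <- function(x, ...) {
  cat(sprintf("Response of '%s' (%s, %d phenotypes): |v| = %.4f\n",
              x$strain, x$scope, length(x$response), x$magnitude))
  invisible(x)
}

#' Divergence of a strain's response from the ancestor's
#'
#' Magnitude divergence is the signed difference of response-vector lengths;
#' direction divergence is the Euclidean distance between the endpoints of
#' the two unit vectors (in `[0, 2]`, with 2 for antipodal responses), and is
#' undefined (`NA`) when either response has zero magnitude.
#'
#' @param v,v_anc [response_vector()]s of the strain and the ancestor/
#'   reference, with identical scope and dimension.
#' @return object of class `divergence_record`: `magnitude_divergence`,
#'   `direction_divergence`, `max_abs_difference`.
#' @export
divergence_from_ancestor <- function(v, v_anc) {
  stopifnot(inherits(v, "response_vector"), inherits(v_anc, "response_vector"))
  if (length(v$response) != length(v_anc$response))
    stop("response vectors have different dimensions")
  dir_div <- if (v$magnitude > 0 && v_anc$magnitude > 0)
    sqrt(sum((v$response / v$magnitude - v_anc$response / v_anc$magnitude)^2))
  else NA_real_
  structure(list(strain = v$strain, scope = v$scope,
                 magnitude_divergence = v$magnitude - v_anc$magnitude,
                 direction_divergence = dir_div,
                 max_abs_difference = max(abs(v$response - v_anc$response))),
            class = "divergence_record")
}

#' @export
print.divergence_record <- function(x, ...) {
  cat(sprintf("Divergence of '%s' from ancestor (%s): magnitude %+.4f, direction %s, max |diff| %.4f\n",
              x$strain, x$scope, x$magnitude_divergence,
              ifelse(is.na(x$direction_divergence), "undefined",
                     sprintf("%.4f", x$direction_divergence)),
              x$max_abs_difference))
  invisible(x)
}

#' Maximum absolute response difference vs the ancestor
#'
#' The maximum, over all retained phenotypes (all stages), of the absolute
#' difference between a strain's response and the ancestor's.
#'
#' @param responses response matrix from [response_matrix()].
#' @param strain,ancestor row names of the two strains.
#' @return scalar.
#' @export
max_abs_response_difference <- function(responses, strain,
                                        ancestor = "ancestor") {
  stopifnot(all(c(strain, ancestor) %in% rownames(responses)))
  max(abs(responses[strain, ] - responses[ancestor, ]))
}

#' Cumulative count of distinct top-divergent strains
#'
#' For k = 1..`k_max`, counts the distinct strains appearing in the union of
#' every phenotype's k most divergent strains (per-phenotype absolute
#' response difference from the ancestor, ties broken by strain-label
#' order).  The maximum possible count `min(k * n_phenotypes, n_strains)` is
#' reported alongside.
#'
#' @param divergence numeric matrix, strains x phenotypes, of per-phenotype
#'   divergence scores (e.g. `abs(responses - ancestor responses)`); the
#'   ancestor itself should not be among the rows.
#' @param k_max largest rank to accumulate (capped at the number of strains,
#'   with a warning).
#' @return data frame with columns `k`, `n_unique`, `max_possible`.
#' @export
top_divergent_cumulative <- function(divergence, k_max = 25L) {
  stopifnot(is.matrix(divergence), !is.null(rownames(divergence)))
  n <- nrow(divergence)
  if (k_max > n) {
    warning("k_max exceeds number of strains; capped at ", n)
    k_max <- n
  }
  ranks <- apply(divergence, 2, function(d)
    rownames(divergence)[order(-d, rownames(divergence))])
  n_unique <- integer(k_max)
  seen <- character(0)
  for (k in seq_len(k_max)) {
    seen <- union(seen, ranks[k, ])
    n_unique[k] <- length(seen)
  }
  data.frame(k = seq_len(k_max), n_unique = n_unique,
             max_possible = pmin(seq_len(k_max) * ncol(divergence), n))
}

#' Correlation of responses across two perturbations
#'
#' Per phenotype, the Pearson correlation across strains between the
#' per-strain responses under perturbation A and under perturbation B, plus
#' the median across phenotypes.
#'
#' @param responses_a,responses_b response matrices over the same strains and
#'   phenotypes.
#' @return list with `per_phenotype` (named correlations) and `median`.
#' @export
perturbation_correlation <- function(responses_a, responses_b) {
  stopifnot(is.matrix(responses_a), is.matrix(responses_b))
  strains <- intersect(rownames(responses_a), rownames(responses_b))
  if (length(strains) < 3L) stop("need at least 3 shared strains")
  a <- responses_a[strains, , drop = FALSE]
  b <- responses_b[strains, colnames(responses_a), drop = FALSE]
  r <- vapply(seq_len(ncol(a)), function(j) cor(a[, j], b[, j]), 0)
  names(r) <- colnames(a)
  list(per_phenotype = r, median = median(r))
}
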