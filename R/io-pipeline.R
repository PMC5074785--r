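#' Read a per-cell trait table
#'
#' Reads a tidy TSV/CSV table with metadata columns `strain`, `condition`,
#' `replicate`, `stage` followed by trait columns.  Unknown columns are
#' preserved as traits.  Condition and stage labels can be normalized
#' through label maps (named vectors `c(raw = canonical)`).
#'
#' @param path file path; comment lines starting with `#` are skipped; the
#'   separator is comma for `.csv`, otherwise tab.
#' @param condition_map,stage_map optional named character vectors mapping
#'   raw labels to canonical ones.
#' @return validated cell trait table (data frame).
#' @export
read_cell_table <- function(path, condition_map = NULL, stage_map = NULL) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  tab <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE)
  .check_cell_table(tab)
  if (!is.null(condition_map)) {
    hit <- tab$condition %in% names(condition_map)
    tab$condition[hit] <- unname(condition_map[tab$condition[hit]])
  }
  if (!is.null(stage_map)) {
    hit <- tab$stage %in% names(stage_map)
    tab$stage[hit] <- unname(stage_map[tab$stage[hit]])
  }
  for (tr in .trait_cols(tab)) {
    if (!is.numeric(tab[[tr]])) {
      conv <- suppressWarnings(as.numeric(tab[[tr]]))
      bad <- which(is.na(conv) & !is.na(tab[[tr]]) & tab[[tr]] != "NA")
      if (length(bad))
        stop(sprintf("non-numeric value in trait '%s' at row %d", tr, bad[1]))
      tab[[tr]] <- conv
    }
  }
  tab
}

#' Write a per-cell trait table
#' @param table cell trait table.
#' @param path output path (TSV unless it ends in `.csv`).
#' @param header optional character vector of `#`-prefixed provenance lines.
#' @export
write_cell_table <- function(table, path, header = NULL) {
  .check_cell_table(table)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(table, con, sep = sep, row.names = FALSE, quote = FALSE)
}

#' Write / read the generator ground-truth sidecar
#'
#' Serializes a [generator_config()] (including loading matrices) as JSON so
#' parameter-recovery tests can reload the exact generating truth alongside
#' a written cell table.
#'
#' @param config a `generator_config`.
#' @param path JSON path.
#' @export
write_generator_config <- function(config, path) {
  stopifnot(inherits(config, "generator_config"))
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
}

#' @rdname write_generator_config
#' @return `read_generator_config` returns the reconstructed
#'   `generator_config`.
#' @export
read_generator_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lo <- raw$loadings
  if (!is.list(lo)) lo <- list(lo)
  raw$loadings <- lapply(seq_along(lo), function(s) {
    L <- lo[[s]]
    if (is.list(L)) L <- do.call(rbind, lapply(L, as.numeric))
    matrix(as.numeric(L), raw$latent_dims_per_stage[s],
           raw$traits_per_stage[s])
  })
  do.call(generator_config, raw[setdiff(names(raw), "n_strains")])
}

# tiny stable string hash (djb2) for provenance headers
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 5381
  for (ch in utf8ToInt(s)) h <- (h * 33 + ch) %% 2147483647
  sprintf("%08x", h)
}

#' Pipeline configuration
#'
#' @param generator a [generator_config()] used to simulate the input table,
#'   or `NULL` when `input` is given.
#' @param input path of a cell trait table to read instead of simulating.
#' @param whitelist optional trait whitelist.
#' @param n_pcs PCs retained per stage (default 6/9/14).
#' @param alpha LRT significance level.
#' @param hpd_mass HPD interval mass.
#' @param mcmc list of sampler settings (`n_iter`, `burnin`, `thin`).
#' @param ancestor ancestor/reference strain label, or `NA` to skip the
#'   divergence stage.
#' @param selection optional [selection_scenario()].
#' @param seed global seed; every stochastic stage derives its stream from it.
#' @param out_dir optional output directory for TSV artifacts.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(generator = NULL, input = NULL, whitelist = NULL,
                            n_pcs = c(6L, 9L, 14L), alpha = 0.01,
                            hpd_mass = 0.95,
                            mcmc = list(n_iter = 13000L, burnin = 3000L,
                                        thin = 10L),
                            ancestor = "ancestor", selection = NULL,
                            seed = 1L, out_dir = NULL) {
  if (is.null(generator) && is.null(input))
    stop("give a generator config or an input path")
  if (!is.null(input) && !file.exists(input))
    stop("input path does not exist: ", input)
  structure(list(generator = generator, input = input, whitelist = whitelist,
                 n_pcs = n_pcs, alpha = alpha, hpd_mass = hpd_mass,
                 mcmc = mcmc, ancestor = ancestor, selection = selection,
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes preprocess -> interaction tests -> variance inference ->
#' divergence (-> selection when configured) on a simulated or loaded cell
#' table, and returns a per-phenotype summary: LRT statistic and p-value,
#' moment variance components, spreading fraction (for phenotypes with a
#' significant interaction), posterior median variance difference with its
#' HPD bounds and significance call, plus the collection summary and the
#' divergence table.  With `out_dir` set, writes TSV artifacts carrying a
#' provenance header (config hash and seed); reruns with the same
#' configuration reproduce the outputs exactly.
#'
#' @param config a [pipeline_config()].
#' @param quiet suppress progress messages.
#' @return object of class `pipeline_result`.
#' @export
run_pipeline <- function(config, quiet = TRUE) {
  stopifnot(inherits(config, "pipeline_config"))
  say <- function(...) if (!quiet) message(...)

  say("loading cells")
  if (!is.null(config$input)) {
    cells <- read_cell_table(config$input)
  } else {
    gen <- config$generator
    gen$seed <- gen$seed + config$seed
    effects <- generate_strain_effects(gen)
    cells <- generate_cell_table(gen, effects)
  }

  say("preprocessing")
  pp <- preprocess_cells(cells, whitelist = config$whitelist,
                         n_pcs = config$n_pcs)
  ids <- phenotype_ids(pp)

  say("fitting per-phenotype models")
  rows <- vector("list", length(ids))
  diffs <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    ph <- ids[i]
    sc <- phenotype_scores(pp, ph)
    lrt <- fit_interaction_lrt(sc, alpha = config$alpha, phenotype = ph)
    vc <- estimate_strain_condition_moments(sc)
    part <- if (lrt$significant) partition_interaction(vc) else NULL
    fit <- fit_variance_mcmc(y ~ condition, sc,
                             n_iter = config$mcmc$n_iter,
                             burnin = config$mcmc$burnin,
                             thin = config$mcmc$thin,
                             seed = config$seed + 7919L * i)
    vd <- variance_difference(fit, mass = config$hpd_mass, phenotype = ph)
    diffs[[i]] <- vd
    rows[[i]] <- data.frame(
      phenotype = ph,
      lrt_stat = lrt$statistic, lrt_p = lrt$p_value,
      interaction_significant = lrt$significant,
      sigma_b_control = vc$sigma_b[1], sigma_b_inhibited = vc$sigma_b[2],
      rho_b = vc$rho_b,
      spreading_fraction = if (is.null(part)) NA_real_
                           else part$spreading_fraction,
      delta_sigma = vd$median,
      hpd_lower = vd$hpd[1], hpd_upper = vd$hpd[2],
      variance_significant = vd$significant,
      direction = vd$direction,
      stringsAsFactors = FALSE)
  }
  summary_tab <- do.call(rbind, rows)
  rownames(summary_tab) <- NULL
  coll <- if (length(diffs) >= 3L)
    collection_summary(diffs, label = "collection") else NULL

  div_tab <- NULL
  if (!is.na(config$ancestor)) {
    say("divergence statistics")
    resp <- response_matrix(pp)
    if (config$ancestor %in% rownames(resp)) {
      v_anc <- response_vector(resp, config$ancestor)
      others <- setdiff(rownames(resp), config$ancestor)
      div_tab <- do.call(rbind, lapply(others, function(st) {
        d <- divergence_from_ancestor(response_vector(resp, st), v_anc)
        data.frame(strain = st,
                   magnitude_divergence = d$magnitude_divergence,
                   direction_divergence = d$direction_divergence,
                   max_abs_difference = d$max_abs_difference,
                   stringsAsFactors = FALSE)
      }))
    }
  }

  sel <- NULL
  if (!is.null(config$selection)) {
    say("selection comparison")
    sel <- pre_post_comparison(config$selection)
  }

  res <- structure(list(summary = summary_tab, collection = coll,
                        divergence = div_tab, selection = sel,
                        config = config), class = "pipeline_result")
  if (!is.null(config$out_dir)) .write_pipeline_outputs(res, config)
  res
}

.write_pipeline_outputs <- function(res, config) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  # hash the analysis-relevant fields only, not the output location
  hashed <- unclass(config)[setdiff(names(config), "out_dir")]
  hdr <- c(sprintf("config_hash: %s", .config_hash(hashed)),
           sprintf("seed: %d", config$seed))
  wr <- function(df, name) {
    con <- file(file.path(config$out_dir, name), "w")
    on.exit(close(con), add = TRUE)
    writeLines(paste0("# ", hdr), con)
    utils::write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  }
  wr(res$summary, "summary.tsv")
  if (!is.null(res$divergence)) wr(res$divergence, "divergence.tsv")
  if (!is.null(res$selection)) wr(res$selection$table, "selection.tsv")
  invisible(res)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("Pipeline result: %d phenotypes\n", nrow(x$summary)))
  cat(sprintf("  significant interactions (alpha = %g): %d\n",
              x$config$alpha, sum(x$summary$interaction_significant)))
  cat(sprintf("  significant variance differences: %d decreased, %d increased\n",
              sum(x$summary$variance_significant & x$summary$delta_sigma < 0),
              sum(x$summary$variance_significant & x$summary$delta_sigma > 0)))
  if (!is.null(x$collection)) print(x$collection)
  invisible(x)
}

#' MA-like study scenario for the synthetic generator
#'
#' The default conditions the package uses when emulating the
#' mutation-accumulation collection: 94 lines plus their ancestor, two
#' replicates, 100-500 cells per well, 132 traits over three stages driven
#' by 6/9/14 latent dimensions, cross-condition correlation 0.6 (crossing
#' dominated), and potentiation injected as reduced inhibited-condition
#' between-strain SD — strong (ratio 0.5) on `n_strong` latent dimensions
#' (by default the first dimensions of each stage, 2/2/3 = 7 of 29) and
#' mild (ratio 0.9) on the rest, reflecting the weak collection-wide
#' potentiation tendency such screens report.
#'
#' @param sigma_b_control between-strain SD (control) on the latent scale.
#' @param strong_ratio,mild_ratio inhibited/control SD ratios.
#' @param n_strong integer vector per stage: how many leading latent dims get
#'   the strong ratio.
#' @param rho_between cross-condition correlation.
#' @param seed generator seed.
#' @param ... further arguments to [generator_config()].
#' @return a `generator_config`.
#' @export
ma_like_scenario <- function(sigma_b_control = 0.4, strong_ratio = 0.5,
                             mild_ratio = 0.9, n_strong = c(2L, 2L, 3L),
                             rho_between = 0.6, seed = 1L, ...) {
  dims <- c(6L, 9L, 14L)
  sb <- lapply(seq_along(dims), function(s) {
    ratio <- rep(mild_ratio, dims[s])
    ratio[seq_len(n_strong[s])] <- strong_ratio
    rbind(rep(sigma_b_control, dims[s]), sigma_b_control * ratio)
  })
  generator_config(sigma_between = sb, rho_between = rho_between,
                   seed = seed, ...)
}
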