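#' Run the full clonality-connectivity analysis pipeline
#'
#' Orchestrates the stages in dependency order: genotype input (file or
#' synthetic) -> clone detection and diversity -> pairwise F_ST ->
#' fragment dispersal (current field + patches, real or synthetic) ->
#' connectivity network -> site-table assembly -> beta regression of
#' genotypic richness on seed density and propagule inflow.  All
#' randomness flows from one integer seed; rerunning with the same config
#' and seed reproduces the outputs.
#'
#' The config is a nested list (or a path to a JSON file with the same
#' shape):
#' \describe{
#'   \item{seed}{integer, required.}
#'   \item{out_dir}{optional; when set, per-stage CSV/JSON artifacts are
#'     written there.}
#'   \item{synth}{synthetic-input block: arguments for
#'     [simulate_genotypes()] (`genotypes`), [simulate_bay()] (`bay`) and
#'     [simulate_reproduction()] (`reproduction`).  Mutually exclusive
#'     with the file inputs.}
#'   \item{inputs}{file-input block: `genepop` (+ `allele_digits`),
#'     `sites_csv`, `field_dir`, `patches_csv`.}
#'   \item{fst}{`n_perm` (default 199), `threshold` (network cutoff,
#'     default 0.04).}
#'   \item{dispersal}{arguments for [dispersal_config()].}
#'   \item{regression}{`formula` as a string; default
#'     `"r ~ log(seed_density) + log(inflow)"`.}
#' }
#'
#' @param config a list or path to a JSON config.
#' @return a list with `site_table`, `partition`, `clonal`, `diversity`,
#'   `fst`, `network`, `dispersal`, `regression` and `provenance`
#'   (seed, config hash, package version).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (is.null(config$seed)) stop("config error: `seed` is required.", call. = FALSE)
  seed <- as.integer(config$seed)
  use_synth <- !is.null(config$synth)
  if (!use_synth && is.null(config$inputs$genepop)) {
    stop("config error: need either a `synth` block or `inputs$genepop`.",
         call. = FALSE)
  }
  if (!use_synth) {
    for (f in c("genepop", "patches_csv", "field_dir", "sites_csv")) {
      pth <- config$inputs[[f]]
      if (!is.null(pth) && !file.exists(pth)) {
        stop("config error: input file not found: ", pth, call. = FALSE)
      }
    }
  }
  reg_formula <- stats::as.formula(
    config$regression$formula %||% "r ~ log(seed_density) + log(inflow)")
  needs_inflow <- "inflow" %in% all.vars(reg_formula)
  has_field <- use_synth || !is.null(config$inputs$field_dir)
  if (needs_inflow && !has_field) {
    stop("config error: regression uses `inflow` but no current field or ",
         "synth bay is configured.", call. = FALSE)
  }

  # --- stage: inputs ---------------------------------------------------
  if (use_synth) {
    gt <- do.call(simulate_genotypes,
                  c(config$synth$genotypes, list(seed = seed)))
    genotypes <- gt$genotypes
    bay <- do.call(simulate_bay, c(config$synth$bay, list(seed = seed + 1L)))
    field <- bay$field; patches <- bay$patches
  } else {
    genotypes <- read_genepop(config$inputs$genepop,
      allele_digits = config$inputs$allele_digits %||% 3)
    field <- if (has_field) read_current_field(config$inputs$field_dir)
    patches <- if (!is.null(config$inputs$patches_csv)) {
      readr::read_csv(config$inputs$patches_csv, show_col_types = FALSE)
    }
  }

  # --- stage: clones + diversity --------------------------------------
  partition <- detect_clones(genotypes)
  clonal <- clonal_summary(partition)
  diversity <- diversity_stats(genotypes, partition = partition)

  # --- stage: F_ST + network ------------------------------------------
  n_perm <- config$fst$n_perm %||% 199
  pw <- pairwise_fst(genotypes, n_perm = n_perm, seed = seed + 2L)
  threshold <- config$fst$threshold %||% 0.04
  net <- network_metrics(pw$fst, threshold = threshold)

  # --- stage: dispersal ------------------------------------------------
  dispersal <- NULL
  inflow_tbl <- NULL
  if (has_field) {
    dcfg <- do.call(dispersal_config,
                    c(config$dispersal, list(seed = seed + 3L)))
    dispersal <- run_dispersal(field, patches, dcfg)
    inflow_tbl <- dispersal$inflow
  }

  # --- stage: site table ----------------------------------------------
  site_table <- clonal |>
    dplyr::left_join(diversity, by = "site") |>
    dplyr::left_join(dplyr::rename(net, degree_net = "degree"), by = "site")
  if (use_synth) {
    # synthetic reproduction: map patch inflow onto sites round-robin
    if (!is.null(inflow_tbl)) {
      inflow_sites <- inflow_tbl$inflow[
        (seq_len(nrow(site_table)) - 1) %% nrow(inflow_tbl) + 1]
      inflow_sites <- pmax(inflow_sites, 1e-3)
    } else {
      inflow_sites <- rep(1, nrow(site_table))
    }
    rr <- pmin(pmax(site_table$r, 0.02), 0.98)
    rep_tbl <- do.call(simulate_reproduction,
      c(list(r = rr, inflow = inflow_sites),
        config$synth$reproduction, list(seed = seed + 4L)))
    site_table <- dplyr::bind_cols(site_table,
      rep_tbl[, c("inflow", "seed_density", "spathe_density")])
  } else if (!is.null(config$inputs$sites_csv)) {
    extra <- readr::read_csv(config$inputs$sites_csv, show_col_types = FALSE)
    site_table <- dplyr::left_join(site_table, extra, by = "site")
  }

  # --- stage: regression ----------------------------------------------
  regression <- NULL
  if (all(all.vars(reg_formula) %in% names(site_table))) {
    regression <- tryCatch(beta_regression(site_table, reg_formula),
      error = function(e) {
        warning("regression stage skipped: ", conditionMessage(e),
                call. = FALSE)
        NULL
      })
  }

  result <- list(
    site_table = site_table, partition = partition, clonal = clonal,
    diversity = diversity, fst = pw, network = net, dispersal = dispersal,
    regression = regression,
    provenance = list(
      # hash the analysis-relevant config only: where outputs land is not
      # part of the run's identity
      seed = seed,
      config_hash = rlang::hash(config[setdiff(names(config), "out_dir")]),
      package_version = as.character(utils::packageVersion("clonescape")))
  )
  if (!is.null(config$out_dir)) write_pipeline_outputs(result, config$out_dir)
  result
}

# Write the per-stage artifacts plus a summary JSON with provenance.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(result$site_table, file.path(out_dir, "site_table.csv"))
  write_matrix_csv(result$fst$fst, file.path(out_dir, "pairwise_fst.csv"))
  write_matrix_csv(result$fst$p_values, file.path(out_dir, "fst_p_values.csv"))
  readr::write_csv(result$network, file.path(out_dir, "network_metrics.csv"))
  if (!is.null(result$dispersal)) {
    write_matrix_csv(result$dispersal$probability,
                     file.path(out_dir, "probability.csv"))
    write_matrix_csv(result$dispersal$flow, file.path(out_dir, "flow.csv"))
    readr::write_csv(result$dispersal$inflow, file.path(out_dir, "inflow.csv"))
    readr::write_csv(result$dispersal$fates, file.path(out_dir, "fates.csv"))
  }
  summary <- list(provenance = result$provenance,
                  sites = nrow(result$site_table),
                  mean_r = mean(result$site_table$r),
                  global_fst_mean_pairwise =
                    mean(result$fst$fst[upper.tri(result$fst$fst)]))
  if (!is.null(result$regression)) {
    summary$regression <- list(
      coefficients = as.list(stats::coef(result$regression)),
      pseudo_r2 = result$regression$pseudo_r2)
  }
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
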