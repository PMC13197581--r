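#' Detect clones by multilocus genotype matching
#'
#' Samples sharing an identical multilocus genotype (MLG) within a site are
#' grouped into one genet (clone).  Matching is exact over all loci, with
#' allele order within a locus ignored.  Under the `"exact"` policy a
#' missing locus matches only another missing locus; under `"permissive"`
#' a missing locus matches anything, and samples are assigned greedily, in
#' input order, to the first matching genet.
#'
#' @param genotypes a long genotype tibble (see [read_genepop()]).
#' @param missing_policy `"exact"` (default) or `"permissive"`.
#' @return a `clone_partition`: a tibble with one row per sample —
#'   `site`, `sample_id`, `genet` (id, unique within site), `mlg` (the
#'   canonical genotype string) and `is_representative` (`TRUE` for the
#'   first-seen sample of each genet).
#' @examples
#' g <- simulate_genotypes(n_sites = 2, samples_per_site = 10, seed = 1)
#' detect_clones(g$genotypes)
#' @export
detect_clones <- function(genotypes, missing_policy = c("exact", "permissive")) {
  missing_policy <- match.arg(missing_policy)
  check_genotypes(genotypes)
  if (nrow(genotypes) == 0) stop("no samples supplied.", call. = FALSE)
  keys <- mlg_strings(genotypes)
  out <- vector("list", length(unique(keys$site)))
  sites <- unique(keys$site)
  for (si in seq_along(sites)) {
    k <- keys[keys$site == sites[si], , drop = FALSE]
    if (missing_policy == "exact") {
      genet_idx <- match(k$mlg, unique(k$mlg))
    } else {
      genet_idx <- integer(nrow(k))
      reps <- list()
      for (i in seq_len(nrow(k))) {
        hit <- 0L
        for (j in seq_along(reps)) {
          if (mlg_compatible(k$calls[[i]], reps[[j]])) { hit <- j; break }
        }
        if (hit == 0L) { reps[[length(reps) + 1L]] <- k$calls[[i]]; hit <- length(reps) }
        genet_idx[i] <- hit
      }
    }
    out[[si]] <- tibble::tibble(
      site = k$site, sample_id = k$sample_id,
      genet = sprintf("%s_g%02d", k$site, genet_idx), mlg = k$mlg,
      is_representative = !duplicated(genet_idx)
    )
  }
  structure(dplyr::bind_rows(out), class = c("clone_partition", class(tibble::tibble())))
}

# One canonical string per sample: loci in first-appearance order, each
# locus "min/max" or "?" when missing.  Also returns the per-locus call
# matrix used by the permissive matcher.
mlg_strings <- function(genotypes) {
  loci <- unique(genotypes$locus)
  g <- genotypes |>
    dplyr::mutate(
      lo = pmin(.data$allele_1, .data$allele_2),
      hi = pmax(.data$allele_1, .data$allele_2),
      call = ifelse(is.na(.data$lo), "?", paste0(.data$lo, "/", .data$hi)),
      locus = factor(.data$locus, levels = loci)
    ) |>
    dplyr::arrange(.data$locus)
  per_sample <- g |>
    dplyr::group_by(.data$site, .data$sample_id) |>
    dplyr::summarise(mlg = paste(.data$call, collapse = " "),
                     calls = list(.data$call), .groups = "drop")
  # restore input sample order within site
  ord <- match(unique(genotypes$sample_id), per_sample$sample_id)
  per_sample[ord[!is.na(ord)], , drop = FALSE]
}

mlg_compatible <- function(a, b) {
  known <- a != "?" & b != "?"
  all(a[known] == b[known])
}

#' Genotypic richness
#'
#' R = (G - 1)/(N - 1), where G is the number of distinct multilocus
#' genotypes (genets) and N the number of samples (ramets).  R is 0 for a
#' monoclonal stand and 1 when every sample is a distinct genet.
#'
#' @param g number of genets (vectorised).
#' @param n number of samples (vectorised).
#' @return genotypic richness in \[0, 1\].
#' @examples
#' genotypic_richness(9, 45)   # a highly clonal site, R = 0.18
#' genotypic_richness(41, 45)  # a highly diverse site, R = 0.91
#' @export
genotypic_richness <- function(g, n) {
  if (any(n < 2)) stop("R is undefined for fewer than 2 samples.", call. = FALSE)
  if (any(g < 1 | g > n)) stop("need 1 <= G <= N.", call. = FALSE)
  (g - 1) / (n - 1)
}

#' Per-site clonality summary
#'
#' @param partition a `clone_partition` from [detect_clones()].
#' @return a tibble with one row per site: `n` samples, `g` genets,
#'   `r` genotypic richness and `largest_clone_fraction` (ramets in the
#'   largest genet / N).
#' @export
clonal_summary <- function(partition) {
  partition |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(
      n = dplyr::n(),
      g = dplyr::n_distinct(.data$genet),
      largest_clone_fraction = max(table(.data$genet)) / dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(r = genotypic_richness(.data$g, .data$n)) |>
    dplyr::select("site", "n", "g", "r", "largest_clone_fraction")
}

#' Allele frequencies per locus
#'
#' Frequencies are computed over non-missing gene copies of the samples
#' supplied; filter to genet representatives first (e.g. with a
#' [detect_clones()] partition) when clonal replicates should not weight
#' the estimates.
#'
#' @param genotypes a long genotype tibble.
#' @return a tibble `locus`, `allele`, `freq`, `n_genes` (gene copies
#'   counted at the locus).
#' @export
allele_frequencies <- function(genotypes) {
  check_genotypes(genotypes)
  long <- genotypes |>
    tidyr::pivot_longer(c("allele_1", "allele_2"), values_to = "allele") |>
    dplyr::filter(!is.na(.data$allele))
  long |>
    dplyr::count(.data$locus, .data$allele, name = "copies") |>
    dplyr::group_by(.data$locus) |>
    dplyr::mutate(n_genes = sum(.data$copies),
                  freq = .data$copies / .data$n_genes) |>
    dplyr::ungroup() |>
    dplyr::select("locus", "allele", "freq", "n_genes")
}

#' Probability of a multilocus genotype under Hardy-Weinberg
#'
#' P_gen is the product over loci of `p_a * p_b * (2 if heterozygous)`,
#' the HWE probability of drawing the genotype from the supplied allele
#' frequencies.
#'
#' @param genotypes a long genotype tibble (one or more samples).
#' @param freqs an allele-frequency tibble from [allele_frequencies()].
#' @param skip_missing if `TRUE`, missing loci are skipped; otherwise they
#'   are an error.
#' @return a tibble `sample_id`, `p_gen`.
#' @export
pgen <- function(genotypes, freqs, skip_missing = FALSE) {
  check_genotypes(genotypes)
  g <- genotypes
  if (any(is.na(g$allele_1))) {
    if (!skip_missing) {
      stop("missing loci present; set `skip_missing = TRUE` to skip them.",
           call. = FALSE)
    }
    g <- dplyr::filter(g, !is.na(.data$allele_1))
  }
  g <- g |>
    dplyr::left_join(
      dplyr::select(freqs, "locus", "allele", p1 = "freq"),
      by = c(locus = "locus", allele_1 = "allele")) |>
    dplyr::left_join(
      dplyr::select(freqs, "locus", "allele", p2 = "freq"),
      by = c(locus = "locus", allele_2 = "allele"))
  if (any(is.na(g$p1) | any(is.na(g$p2)))) {
    bad <- g[is.na(g$p1) | is.na(g$p2), c("sample_id", "locus")]
    stop("allele(s) absent from the frequency table, e.g. sample ",
         bad$sample_id[1], " locus ", bad$locus[1], ".", call. = FALSE)
  }
  g |>
    dplyr::mutate(term = .data$p1 * .data$p2 *
                    ifelse(.data$allele_1 == .data$allele_2, 1, 2)) |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(p_gen = prod(.data$term), .groups = "drop")
}

#' Probability that repeated genotypes arose from separate sexual events
#'
#' P_sex is the binomial tail probability of observing at least `n_copies`
#' samples with a given multilocus genotype among `n` independent sexual
#' recruits, each carrying the genotype with probability `p_gen`.
#'
#' @param p_gen HWE genotype probability (from [pgen()]); vectorised.
#' @param n_copies observed copies of the genotype (>= 2).
#' @param n number of samples.
#' @return P_sex in \[0, 1\].
#' @export
psex <- function(p_gen, n_copies, n) {
  if (any(n_copies < 2)) {
    stop("P_sex is defined for repeated genotypes (n_copies >= 2).",
         call. = FALSE)
  }
  if (any(n_copies > n)) stop("need n_copies <= n.", call. = FALSE)
  if (any(p_gen < 0 | p_gen > 1)) stop("p_gen must lie in [0, 1].", call. = FALSE)
  stats::pbinom(n_copies - 1, n, p_gen, lower.tail = FALSE)
}

#' P_sex for every repeated genet at each site
#'
#' Computes P_gen for each genet representative from the site's genet-only
#' allele frequencies, then P_sex for genets sampled more than once.
#'
#' @param genotypes a long genotype tibble.
#' @param partition a `clone_partition`; computed if omitted.
#' @return a tibble `site`, `genet`, `n_copies`, `p_gen`, `p_sex`.
#' @export
site_psex <- function(genotypes, partition = NULL) {
  if (is.null(partition)) partition <- detect_clones(genotypes)
  reps <- partition[partition$is_representative, c("site", "sample_id", "genet")]
  counts <- partition |>
    dplyr::count(.data$site, .data$genet, name = "n_copies")
  n_site <- partition |> dplyr::count(.data$site, name = "n_samples")
  out <- lapply(unique(partition$site), function(s) {
    rep_ids <- reps$sample_id[reps$site == s]
    gsub <- genotypes[genotypes$sample_id %in% rep_ids, , drop = FALSE]
    pg <- pgen(gsub, allele_frequencies(gsub), skip_missing = TRUE)
    tibble::tibble(site = s, sample_id = pg$sample_id, p_gen = pg$p_gen)
  })
  dplyr::bind_rows(out) |>
    dplyr::inner_join(reps, by = c("site", "sample_id")) |>
    dplyr::inner_join(counts, by = c("site", "genet")) |>
    dplyr::inner_join(n_site, by = "site") |>
    dplyr::filter(.data$n_copies >= 2) |>
    dplyr::mutate(p_sex = psex(.data$p_gen, .data$n_copies, .data$n_samples)) |>
    dplyr::select("site", "genet", "n_copies", "p_gen", "p_sex")
}

#' Per-site genetic diversity
#'
#' Mean alleles per locus (Na), observed heterozygosity (Ho) and Nei's
#' unbiased expected heterozygosity, He = (2n/(2n-1)) (1 - sum p^2) with n
#' the number of genets called at the locus, averaged over loci.  By
#' default only unique multilocus genotypes (genet representatives) enter,
#' so clonal resampling does not weight the estimates.
#'
#' @param genotypes a long genotype tibble.
#' @param genets_only use one representative per genet (default `TRUE`).
#' @param partition optional precomputed `clone_partition`.
#' @return a tibble `site`, `n_genets`, `na`, `ho`, `he`.
#' @export
diversity_stats <- function(genotypes, genets_only = TRUE, partition = NULL) {
  check_genotypes(genotypes)
  if (genets_only) {
    if (is.null(partition)) partition <- detect_clones(genotypes)
    keep <- partition$sample_id[partition$is_representative]
    genotypes <- genotypes[genotypes$sample_id %in% keep, , drop = FALSE]
  }
  if (nrow(genotypes) == 0) stop("zero genets supplied.", call. = FALSE)
  per_locus <- genotypes |>
    dplyr::filter(!is.na(.data$allele_1)) |>
    dplyr::group_by(.data$site, .data$locus) |>
    dplyr::summarise(
      n = dplyr::n(),
      na = dplyr::n_distinct(c(.data$allele_1, .data$allele_2)),
      ho = mean(.data$allele_1 != .data$allele_2),
      sum_p2 = {
        p <- table(c(.data$allele_1, .data$allele_2)) / (2 * dplyr::n())
        sum(p^2)
      },
      .groups = "drop"
    ) |>
    dplyr::mutate(he = (2 * .data$n) / (2 * .data$n - 1) * (1 - .data$sum_p2))
  n_genets <- genotypes |>
    dplyr::distinct(.data$site, .data$sample_id) |>
    dplyr::count(.data$site, name = "n_genets")
  per_locus |>
    dplyr::group_by(.data$site) |>
    dplyr::summarise(na = mean(.data$na), ho = mean(.data$ho),
                     he = mean(.data$he), .groups = "drop") |>
    dplyr::left_join(n_genets, by = "site") |>
    dplyr::select("site", "n_genets", "na", "ho", "he")
}

#' Multilocus genotypes shared between sites
#'
#' Lists every MLG sampled at two or more sites, with P_sex computed from
#' allele frequencies pooled over the genets of the involved sites
#' (n_copies = total ramets carrying the MLG, n = total samples at the
#' involved sites).  Shared clones across sites are the genetic signature
#' of between-site dispersal of vegetative fragments.
#'
#' @param genotypes a long genotype tibble.
#' @param partition optional precomputed `clone_partition`.
#' @return a tibble `mlg`, `sites` (comma-separated), `n_sites`,
#'   `n_copies`, `p_gen`, `p_sex`; zero rows when no MLG is shared.
#' @export
shared_mlgs <- function(genotypes, partition = NULL) {
  if (is.null(partition)) partition <- detect_clones(genotypes)
  if (dplyr::n_distinct(partition$site) < 2) {
    stop("need at least two sites.", call. = FALSE)
  }
  occ <- partition |>
    dplyr::group_by(.data$mlg) |>
    dplyr::summarise(
      sites = paste(unique(.data$site), collapse = ", "),
      n_sites = dplyr::n_distinct(.data$site),
      n_copies = dplyr::n(),
      first_sample = .data$sample_id[1],
      site_list = list(unique(.data$site)),
      .groups = "drop") |>
    dplyr::filter(.data$n_sites >= 2)
  if (nrow(occ) == 0) {
    return(tibble::tibble(mlg = character(), sites = character(),
                          n_sites = integer(), n_copies = integer(),
                          p_gen = double(), p_sex = double()))
  }
  stats <- purrr::pmap_dfr(
    occ[, c("first_sample", "site_list", "n_copies")],
    function(first_sample, site_list, n_copies) {
      reps <- partition$sample_id[partition$is_representative &
                                    partition$site %in% site_list]
      pooled <- allele_frequencies(
        genotypes[genotypes$sample_id %in% reps, , drop = FALSE])
      pg <- pgen(genotypes[genotypes$sample_id == first_sample, , drop = FALSE],
                 pooled, skip_missing = TRUE)$p_gen
      n_tot <- sum(partition$site %in% site_list)
      tibble::tibble(p_gen = pg, p_sex = psex(pg, n_copies, n_tot))
    })
  dplyr::bind_cols(occ[, c("mlg", "sites", "n_sites", "n_copies")], stats)
}
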