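#' Simulate clonal multi-site microsatellite data
#'
#' Generates diploid genotypes for several sites under an island model
#' with Hardy-Weinberg equilibrium within sites: ancestral allele
#' frequencies are Dirichlet-drawn per locus, site frequencies follow the
#' Balding-Nichols model with differentiation parameter `fst`, genets are
#' drawn under HWE from the site frequencies, and ramets replicate genets
#' with a geometric clone-size law so the realized genotypic richness per
#' site equals its target.  Defaults mirror a temperate seagrass
#' microsatellite survey: 9 loci with 3-16 alleles each, 45 samples per
#' site, moderate differentiation (F_ST about 0.06) and site clonality
#' spanning highly clonal (R about 0.18) to almost fully sexual
#' (R about 0.93).
#'
#' @param n_sites number of sites.
#' @param n_loci number of microsatellite loci.
#' @param samples_per_site samples (ramets) per site; scalar or vector.
#' @param fst Balding-Nichols differentiation parameter in \[0, 1).
#' @param clonality target genotypic richness R per site, in (0, 1\];
#'   scalar or vector; default spreads targets evenly over 0.18-0.93.
#' @param alleles_per_locus allele count per locus; default drawn
#'   uniformly from 3 to 16.
#' @param dominant_clone_fraction optional fraction of ramets forced into
#'   the largest genet (e.g. 0.55 mimics a stand dominated by one clone).
#' @param missing_rate per-call missing-data probability (default 0).
#' @param site_names optional site names.
#' @param seed RNG seed.
#' @return a list: `genotypes` (long genotype tibble) and `truth`
#'   (list with per-sample genet assignments, per-site targets and the
#'   generator parameters).
#' @export
simulate_genotypes <- function(n_sites = 16, n_loci = 9,
                               samples_per_site = 45, fst = 0.06,
                               clonality = NULL, alleles_per_locus = NULL,
                               dominant_clone_fraction = NULL,
                               missing_rate = 0, site_names = NULL,
                               seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  stopifnot(n_sites >= 1, n_loci >= 1, fst >= 0, fst < 1)
  n_i <- rep_len(samples_per_site, n_sites)
  clonality <- if (is.null(clonality)) {
    if (n_sites == 1) 0.5 else seq(0.18, 0.93, length.out = n_sites)
  } else rep_len(clonality, n_sites)
  if (any(clonality <= 0 | clonality > 1)) {
    stop("clonality targets must lie in (0, 1].", call. = FALSE)
  }
  sites <- site_names %||% sprintf("site%02d", seq_len(n_sites))
  k_l <- alleles_per_locus %||% sample(3:16, n_loci, replace = TRUE)
  k_l <- rep_len(k_l, n_loci)
  loci <- sprintf("loc%02d", seq_len(n_loci))
  ancestral <- lapply(k_l, function(k) {
    g <- stats::rgamma(k, 1)
    g / sum(g)
  })
  rows <- list()
  genet_truth <- list()
  for (s in seq_len(n_sites)) {
    N <- n_i[s]
    G <- round(clonality[s] * (N - 1)) + 1
    if (G > N) stop("clonality target needs more genets than samples at ",
                    sites[s], ".", call. = FALSE)
    p_site <- lapply(ancestral, function(p) {
      if (fst == 0) return(p)
      g <- stats::rgamma(length(p), p * (1 - fst) / fst)
      if (sum(g) == 0) g[sample.int(length(p), 1)] <- 1
      g / sum(g)
    })
    # distinct genets under HWE (redraw collisions)
    draw_genet <- function() {
      lapply(p_site, function(p) sort(sample.int(length(p), 2, TRUE, prob = p)))
    }
    genets <- list()
    tries <- 0
    while (length(genets) < G && tries < 200 * G) {
      g <- draw_genet()
      key <- paste(unlist(g), collapse = ",")
      if (!key %in% names(genets)) genets[[key]] <- g
      tries <- tries + 1
    }
    if (length(genets) < G) {
      stop("could not draw ", G, " distinct genets at ", sites[s],
           "; increase loci or alleles.", call. = FALSE)
    }
    sizes <- clone_sizes(G, N,
      dominant = if (is.null(dominant_clone_fraction)) NA
                 else rep_len(dominant_clone_fraction, n_sites)[s])
    genet_of <- rep(seq_len(G), times = sizes)
    ids <- sprintf("%s_%03d", sites[s], seq_len(N))
    for (i in seq_len(N)) {
      g <- genets[[genet_of[i]]]
      a1 <- vapply(g, `[`, integer(1), 1)
      a2 <- vapply(g, `[`, integer(1), 2)
      a1 <- 100L + 2L * a1; a2 <- 100L + 2L * a2
      if (missing_rate > 0) {
        drop_loc <- stats::runif(n_loci) < missing_rate
        a1[drop_loc] <- NA_integer_; a2[drop_loc] <- NA_integer_
      }
      rows[[length(rows) + 1]] <- tibble::tibble(
        sample_id = ids[i], site = sites[s],
        quadrat = sprintf("Q%d", ((i - 1) %/% ceiling(N / 3)) + 1),
        locus = loci, allele_1 = a1, allele_2 = a2)
    }
    genet_truth[[s]] <- tibble::tibble(
      sample_id = ids, site = sites[s],
      genet = sprintf("%s_g%02d", sites[s], genet_of))
  }
  list(
    genotypes = dplyr::bind_rows(rows),
    truth = list(
      assignments = dplyr::bind_rows(genet_truth),
      sites = tibble::tibble(site = sites, n = n_i,
                             g = round(clonality * (n_i - 1)) + 1,
                             target_r = clonality),
      fst_target = fst, alleles_per_locus = k_l)
  )
}

# Partition N ramets into G genet sizes: geometric draws adjusted to sum
# exactly to N; increments go to larger genets (rich-get-richer), so a few
# dominant clones emerge naturally at low R.
clone_sizes <- function(G, N, dominant = NA) {
  if (G == N) return(rep(1L, N))
  sizes <- 1L + stats::rgeom(G, min(1, G / N))
  while (sum(sizes) > N) {
    i <- which.max(sizes)
    sizes[i] <- sizes[i] - 1L
  }
  while (sum(sizes) < N) {
    i <- sample.int(G, 1, prob = sizes)
    sizes[i] <- sizes[i] + 1L
  }
  if (!is.na(dominant)) {
    want <- max(1L, round(dominant * N))
    i <- which.max(sizes)
    excess <- want - sizes[i]
    while (excess > 0) {
      j <- which(sizes > 1 & seq_along(sizes) != i)
      if (length(j) == 0) break
      j <- j[which.max(sizes[j])]
      sizes[j] <- sizes[j] - 1L; sizes[i] <- sizes[i] + 1L
      excess <- excess - 1L
    }
  }
  sizes
}

#' Simulate an enclosed-bay current field with habitat patches
#'
#' Builds a rectangular bay with a land border and a mouth, bathymetry
#' deepening toward the centre, and an hourly velocity field composed of a
#' steady double-gyre circulation (discretely divergence-free on the
#' grid), a sinusoidal tidal oscillation and optional white noise.
#' Habitat patches are placed in shallow near-shore water with areas
#' spanning two orders of magnitude, exercising the area-weighted flow
#' matrix downstream.
#'
#' @param nx,ny grid cells in x and y (>= 20 each).
#' @param cell_size cell size (m); 400 m mirrors a high-resolution bay
#'   model.
#' @param duration_h length of the hourly time axis.
#' @param gyre_strength peak gyre speed (m/s).  The default keeps the
#'   fastest combined current below one cell per hourly step (CFL-safe
#'   for the default integrator).
#' @param tidal_amplitude tidal current amplitude (m/s).
#' @param tidal_period_h tidal period (h), default semidiurnal 12.42.
#' @param noise_sd white velocity noise s.d. (m/s), default 0.
#' @param n_patches habitat patches to place.
#' @param mouth_width cells of open water in the southern border.
#' @param seed RNG seed.
#' @return a list: `field` (a `current_field`) and `patches` (tibble
#'   `patch`, `cell_x`, `cell_y`, `area`).
#' @export
simulate_bay <- function(nx = 40, ny = 40, cell_size = 400,
                         duration_h = 24 * 58, gyre_strength = 0.03,
                         tidal_amplitude = 0.01, tidal_period_h = 12.42,
                         noise_sd = 0, n_patches = 6, mouth_width = 4,
                         seed = NULL) {
  if (nx < 20 || ny < 20) stop("grid must be at least 20 x 20.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  x <- (seq_len(nx) - 0.5) * cell_size
  y <- (seq_len(ny) - 0.5) * cell_size
  tt <- seq(0, duration_h)
  mask <- matrix(TRUE, nx, ny)
  mask[c(1, nx), ] <- FALSE
  mask[, c(1, ny)] <- FALSE
  if (mouth_width > 0) {
    m0 <- floor((nx - mouth_width) / 2)
    mask[m0 + seq_len(mouth_width), 1] <- TRUE
  }
  sx <- x / (nx * cell_size); sy <- y / (ny * cell_size)
  depth <- 2 + 18 * outer(4 * sx * (1 - sx), 4 * sy * (1 - sy))
  depth[!mask] <- NA
  # double gyre, exactly divergence-free under central differences:
  # u = A sin(a x) cos(b y); v = -A (sin(a h)/sin(b h)) cos(a x) sin(b y)
  a <- 2 * pi / (nx * cell_size); b <- pi / (ny * cell_size)
  h <- cell_size
  cvr <- sin(a * h) / sin(b * h)
  u_g <- gyre_strength * outer(sin(a * x), cos(b * y))
  v_g <- -gyre_strength * cvr * outer(cos(a * x), sin(b * y))
  u <- v <- array(0, c(nx, ny, length(tt)))
  tide <- tidal_amplitude * sin(2 * pi * tt / tidal_period_h)
  for (k in seq_along(tt)) {
    u[, , k] <- u_g + tide[k]
    v[, , k] <- v_g
    if (noise_sd > 0) {
      u[, , k] <- u[, , k] + stats::rnorm(nx * ny, 0, noise_sd)
      v[, , k] <- v[, , k] + stats::rnorm(nx * ny, 0, noise_sd)
    }
    u[, , k][!mask] <- 0
    v[, , k][!mask] <- 0
  }
  field <- current_field(x, y, tt, u, v, depth, mask)
  # patches: 2x2 blocks of shallow water cells near the shore
  shallow <- which(mask & depth < stats::quantile(depth[mask], 0.35),
                   arr.ind = TRUE)
  ok <- shallow[, 1] >= 2 & shallow[, 1] <= nx - 2 &
    shallow[, 2] >= 2 & shallow[, 2] <= ny - 2
  shallow <- shallow[ok, , drop = FALSE]
  block_ok <- apply(shallow, 1, function(ij) {
    all(mask[ij[1] + 0:1, ij[2] + 0:1])
  })
  shallow <- shallow[block_ok, , drop = FALSE]
  if (nrow(shallow) < n_patches) {
    stop("not enough shallow water cells for ", n_patches, " patches.",
         call. = FALSE)
  }
  # spread patch anchors by sampling without replacement, rejecting overlap
  anchors <- matrix(NA_integer_, 0, 2)
  cand <- shallow[sample.int(nrow(shallow)), , drop = FALSE]
  for (r in seq_len(nrow(cand))) {
    if (nrow(anchors) == n_patches) break
    if (nrow(anchors) == 0 ||
        all(abs(anchors[, 1] - cand[r, 1]) > 2 |
              abs(anchors[, 2] - cand[r, 2]) > 2)) {
      anchors <- rbind(anchors, cand[r, ])
    }
  }
  if (nrow(anchors) < n_patches) {
    stop("could not place ", n_patches, " non-overlapping patches.",
         call. = FALSE)
  }
  areas <- 10^stats::runif(n_patches, 3, 5)  # 1e3-1e5 m^2
  patches <- purrr::map_dfr(seq_len(n_patches), function(p) {
    tibble::tibble(
      patch = sprintf("patch%02d", p),
      cell_x = anchors[p, 1] + c(0L, 1L, 0L, 1L),
      cell_y = anchors[p, 2] + c(0L, 0L, 1L, 1L),
      area = areas[p])
  })
  list(field = field, patches = patches)
}

#' Simulate reproductive covariates linked to genotypic richness
#'
#' Inverts a logit-link beta-regression relationship so that, by
#' construction, each site's genotypic richness equals the regression
#' mean at its seed density and propagule inflow:
#' `logit(r) = beta0 + beta_seed * log(seed) + beta_inflow * log(inflow)`.
#' Spathe (flowering) density is seed density times lognormal noise, so
#' the two are strongly positively correlated, as in field data.  The
#' default coefficients are those recovered from fitting the same model to
#' a real 15-site survey table (log scale).
#'
#' @param r genotypic richness per site, strictly in (0, 1).
#' @param inflow relative propagule inflow per site (> 0).
#' @param beta0,beta_seed,beta_inflow true regression coefficients (logit
#'   scale, log-transformed predictors).
#' @param seed_noise_sd lognormal jitter s.d. on seed density (breaks the
#'   exact inversion; 0 keeps the relationship noise-free).
#' @param spathe_noise_sd lognormal noise s.d. for spathe density.
#' @param spathe_scale mean spathe/seed ratio.
#' @param seed RNG seed.
#' @return a tibble `r`, `inflow`, `seed_density`, `spathe_density`, with
#'   the true coefficients in `attr(, "truth")`.
#' @export
simulate_reproduction <- function(r, inflow, beta0 = -0.75,
                                  beta_seed = 0.21, beta_inflow = 0.30,
                                  seed_noise_sd = 0, spathe_noise_sd = 0.4,
                                  spathe_scale = 0.5, seed = NULL) {
  if (any(r <= 0 | r >= 1)) stop("r must lie strictly in (0, 1).", call. = FALSE)
  if (any(inflow <= 0)) stop("inflow must be positive.", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  log_seed <- (stats::qlogis(r) - beta0 - beta_inflow * log(inflow)) / beta_seed
  if (seed_noise_sd > 0) {
    log_seed <- log_seed + stats::rnorm(length(r), 0, seed_noise_sd)
  }
  seed_density <- exp(log_seed)
  spathe_density <- seed_density * spathe_scale *
    exp(stats::rnorm(length(r), 0, spathe_noise_sd))
  out <- tibble::tibble(r = r, inflow = inflow,
                        seed_density = seed_density,
                        spathe_density = spathe_density)
  attr(out, "truth") <- list(beta0 = beta0, beta_seed = beta_seed,
                             beta_inflow = beta_inflow)
  out
}
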