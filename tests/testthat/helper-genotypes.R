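# Build a long genotype tibble from compact per-sample call strings:
# `calls_of` is a named list (names = sample ids); each element is a
# character vector of "a/b" calls ("?" = missing), one per locus;
# `site_of` gives each sample's site (recycled).
make_geno <- function(site_of, calls_of, loci = NULL) {
  n_loci <- length(calls_of[[1]])
  loci <- loci %||% sprintf("L%d", seq_len(n_loci))
  ids <- names(calls_of)
  site_of <- rep_len(site_of, length(calls_of))
  purrr::map_dfr(seq_along(calls_of), function(k) {
    calls <- calls_of[[k]]
    a1 <- a2 <- rep(NA_integer_, n_loci)
    ok <- calls != "?"
    parts <- strsplit(calls[ok], "/")
    a1[ok] <- as.integer(vapply(parts, `[`, "", 1))
    a2[ok] <- as.integer(vapply(parts, `[`, "", 2))
    tibble::tibble(sample_id = ids[k], site = site_of[k],
                   quadrat = NA_character_, locus = loci,
                   allele_1 = a1, allele_2 = a2)
  })
}

# A flat current field: uniform constant currents over an all-water grid
# of constant depth, sized in cells.
flat_field <- function(nx = 20, ny = 20, cell = 400, hours = 24 * 40,
                       u0 = 0, v0 = 0, depth0 = 10) {
  x <- (seq_len(nx) - 0.5) * cell
  y <- (seq_len(ny) - 0.5) * cell
  tt <- seq(0, hours)
  u <- array(u0, c(nx, ny, length(tt)))
  v <- array(v0, c(nx, ny, length(tt)))
  current_field(x, y, tt, u, v,
                depth = matrix(depth0, nx, ny),
                mask = matrix(TRUE, nx, ny))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
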