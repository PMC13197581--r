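#' Weir-Cockerham F-statistics
#'
#' Multilocus theta from the Weir & Cockerham (1984) variance components
#' a (among populations), b (among individuals within populations) and c
#' (within individuals): theta = sum(a) / sum(a + b + c), summed over
#' alleles and loci.  By default only unique multilocus genotypes enter,
#' since clonal resampling would otherwise bias the within-site
#' components.
#'
#' @param genotypes a long genotype tibble (see [read_genepop()]) spanning
#'   two or more sites.
#' @param genets_only collapse clones to one representative per genet
#'   before estimating (default `TRUE`).
#' @param n_perm if > 0, a permutation p-value is computed by shuffling
#'   genets across sites.
#' @param seed optional RNG seed for the permutations.
#' @return an object of class `fst_result`: a list with `theta`,
#'   `per_locus` (tibble of locus-wise a, b, c and theta), `n_sites`,
#'   `n_genets`, and (when permuted) `p_value` and `n_perm`.
#' @examples
#' g <- simulate_genotypes(n_sites = 3, fst = 0.1, seed = 1)
#' wc_fst(g$genotypes)
#' @export
wc_fst <- function(genotypes, genets_only = TRUE, n_perm = 0, seed = NULL) {
  d <- fst_prepare(genotypes, genets_only)
  comp <- wc_components(d$a1, d$a2, d$pop)
  res <- structure(list(
    theta = comp$theta,
    per_locus = tibble::tibble(
      locus = d$loci, a = comp$a, b = comp$b, c = comp$c,
      theta = ifelse(comp$a + comp$b + comp$c == 0, NA_real_,
                     comp$a / (comp$a + comp$b + comp$c))),
    n_sites = nlevels(d$pop), n_genets = length(d$pop)
  ), class = "fst_result")
  if (n_perm > 0) {
    if (!is.null(seed)) set.seed(seed)
    perm <- replicate(n_perm,
      wc_components(d$a1, d$a2, sample(d$pop))$theta)
    res$p_value <- (1 + sum(perm >= comp$theta)) / (n_perm + 1)
    res$n_perm <- n_perm
  }
  res
}

#' @export
print.fst_result <- function(x, ...) {
  cat("Weir-Cockerham F_ST:", format(x$theta, digits = 4),
      sprintf("(%d sites, %d genets, %d loci)\n",
              x$n_sites, x$n_genets, nrow(x$per_locus)))
  if (!is.null(x$p_value)) {
    cat("permutation p =", format(x$p_value, digits = 3),
        sprintf("(%d permutations)\n", x$n_perm))
  }
  invisible(x)
}

#' @export
tidy.fst_result <- function(x, ...) x$per_locus

#' @export
glance.fst_result <- function(x, ...) {
  tibble::tibble(theta = x$theta, n_loci = nrow(x$per_locus),
                 n_sites = x$n_sites, n_genets = x$n_genets,
                 p_value = x$p_value %||% NA_real_,
                 n_perm = x$n_perm %||% NA_integer_)
}

# Collapse the long tibble into allele matrices (samples x loci) plus a
# site factor; optionally one representative per genet.
fst_prepare <- function(genotypes, genets_only) {
  check_genotypes(genotypes)
  if (genets_only) {
    part <- detect_clones(genotypes)
    keep <- part$sample_id[part$is_representative]
    genotypes <- genotypes[genotypes$sample_id %in% keep, , drop = FALSE]
  }
  loci <- unique(genotypes$locus)
  samples <- unique(genotypes$sample_id)
  idx <- cbind(match(genotypes$sample_id, samples),
               match(genotypes$locus, loci))
  a1 <- a2 <- matrix(NA_integer_, length(samples), length(loci))
  a1[idx] <- genotypes$allele_1
  a2[idx] <- genotypes$allele_2
  site <- genotypes$site[match(samples, genotypes$sample_id)]
  if (dplyr::n_distinct(site) < 2) stop("need >= 2 sites.", call. = FALSE)
  small <- names(which(table(site) < 2))
  if (length(small) > 0) {
    stop("site(s) with fewer than 2 genets: ",
         paste(small, collapse = ", "), call. = FALSE)
  }
  list(a1 = a1, a2 = a2, pop = factor(site), loci = loci)
}

# Variance components per locus, summed over alleles (W&C 1984 eqs 2-4).
wc_components <- function(a1, a2, pop) {
  L <- ncol(a1)
  A <- B <- C <- numeric(L)
  for (l in seq_len(L)) {
    x1 <- a1[, l]; x2 <- a2[, l]
    called <- !is.na(x1)
    if (!any(called)) next
    p <- droplevels(pop[called])
    if (nlevels(p) < 2) next
    x1 <- x1[called]; x2 <- x2[called]
    alleles <- sort(unique(c(x1, x2)))
    if (length(alleles) < 2) next  # monomorphic: zero components
    r <- nlevels(p)
    n_i <- as.vector(table(p))
    n_tot <- sum(n_i)
    nbar <- n_tot / r
    nc <- (n_tot - sum(n_i^2) / n_tot) / (r - 1)
    het <- x1 != x2
    for (u in alleles) {
      cnt <- (x1 == u) + (x2 == u)
      p_iu <- tapply(cnt, p, sum) / (2 * n_i)
      pbar <- sum(n_i * p_iu) / n_tot
      s2 <- sum(n_i * (p_iu - pbar)^2) / ((r - 1) * nbar)
      h_iu <- tapply(het & cnt == 1, p, sum) / n_i
      hbar <- sum(n_i * h_iu) / n_tot
      A[l] <- A[l] + (nbar / nc) *
        (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
      B[l] <- B[l] + (nbar / (nbar - 1)) *
        (pbar * (1 - pbar) - (r - 1) / r * s2 -
           (2 * nbar - 1) / (4 * nbar) * hbar)
      C[l] <- C[l] + hbar / 2
    }
  }
  denom <- sum(A + B + C)
  list(a = A, b = B, c = C,
       theta = if (denom == 0) 0 else sum(A) / denom)
}

#' Pairwise F_ST matrix with permutation significance
#'
#' Weir-Cockerham theta for every unordered site pair, with p-values from
#' permuting genets between the two sites and a significance mask at a
#' multiplicity-adjusted alpha (Bonferroni by default: with 16 sites and
#' 120 pairs, 0.05/120 = 0.0004).
#'
#' @inheritParams wc_fst
#' @param n_perm permutations per pair (>= 100 for a usable p-value;
#'   0 skips testing).
#' @param alpha family-wise significance level before adjustment.
#' @param correction `"bonferroni"` (default), `"BH"` or `"none"`.
#' @param seed optional RNG seed.
#' @return an object of class `pairwise_fst`: list with `fst` (labelled
#'   symmetric matrix, zero diagonal), `p_values`, `significant` (logical
#'   mask) and `alpha_adjusted`.
#' @export
pairwise_fst <- function(genotypes, n_perm = 2499, alpha = 0.05,
                         correction = c("bonferroni", "BH", "none"),
                         genets_only = TRUE, seed = NULL) {
  correction <- match.arg(correction)
  if (n_perm > 0 && n_perm < 100) stop("use n_perm >= 100 (or 0).", call. = FALSE)
  d <- fst_prepare(genotypes, genets_only)
  sites <- levels(d$pop)
  k <- length(sites)
  if (!is.null(seed)) set.seed(seed)
  fst <- p <- matrix(0, k, k, dimnames = list(sites, sites))
  p[] <- NA_real_
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    sel <- d$pop %in% sites[c(i, j)]
    pop2 <- droplevels(d$pop[sel])
    a1 <- d$a1[sel, , drop = FALSE]; a2 <- d$a2[sel, , drop = FALSE]
    obs <- wc_components(a1, a2, pop2)$theta
    fst[i, j] <- fst[j, i] <- obs
    if (n_perm > 0) {
      perm <- replicate(n_perm, wc_components(a1, a2, sample(pop2))$theta)
      p[i, j] <- p[j, i] <- (1 + sum(perm >= obs)) / (n_perm + 1)
    }
  }
  n_pairs <- k * (k - 1) / 2
  alpha_adj <- switch(correction,
    bonferroni = alpha / n_pairs, BH = NA_real_, none = alpha)
  signif_mask <- matrix(NA, k, k, dimnames = list(sites, sites))
  if (n_perm > 0) {
    pv <- p[upper.tri(p)]
    sig <- switch(correction,
      bonferroni = pv <= alpha / n_pairs,
      BH = stats::p.adjust(pv, "BH") <= alpha,
      none = pv <= alpha)
    signif_mask[upper.tri(signif_mask)] <- sig
    signif_mask[lower.tri(signif_mask)] <- t(signif_mask)[lower.tri(signif_mask)]
  }
  structure(list(fst = fst, p_values = p, significant = signif_mask,
                 alpha_adjusted = alpha_adj, n_perm = n_perm,
                 correction = correction),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  k <- nrow(x$fst)
  cat("Pairwise Weir-Cockerham F_ST:", k, "sites,", k * (k - 1) / 2,
      "pairs\n")
  if (x$n_perm > 0) {
    cat(sum(x$significant[upper.tri(x$significant)]),
        "pairs significant at adjusted alpha",
        format(x$alpha_adjusted, digits = 2),
        sprintf("(%s, %d permutations)\n", x$correction, x$n_perm))
  }
  invisible(x)
}

#' @export
tidy.pairwise_fst <- function(x, ...) {
  out <- matrix_to_tibble(x$fst) |>
    dplyr::rename(fst = "value") |>
    dplyr::filter(.data$from < .data$to)
  out$p_value <- x$p_values[cbind(out$from, out$to)]
  out$significant <- x$significant[cbind(out$from, out$to)]
  out
}

#' Linearized F_ST
#'
#' Elementwise F_ST / (1 - F_ST), the standard linearization used for
#' isolation-by-distance regressions.
#'
#' @param m a labelled F_ST matrix (entries < 1).
#' @return a labelled matrix of the same shape.
#' @export
linearize_fst <- function(m) {
  m <- as_labelled_matrix(m)
  if (any(m >= 1)) stop("F_ST = 1 linearizes to infinity.", call. = FALSE)
  m / (1 - m)
}

#' Mantel test between two distance-like matrices
#'
#' Pearson correlation of corresponding off-diagonal elements, with a
#' one-tailed (positive association) permutation p-value obtained by
#' jointly permuting the rows and columns of `b`.
#'
#' @param a,b symmetric labelled matrices over the same labels.
#' @param n_perm number of permutations (default 9999).
#' @param seed optional RNG seed (the p-value is reproducible given the
#'   seed).
#' @param log_transform natural-log both matrices elementwise first; all
#'   off-diagonal entries must then be > 0.
#' @param symmetrize how to symmetrize an asymmetric `b` (e.g. a flow
#'   matrix): `"none"` (error if asymmetric), `"sum"` (x + t(x)) or
#'   `"mean"`.
#' @param alternative `"greater"` (default; positive association, the
#'   isolation-by-distance convention), `"less"` (e.g. F_ST against
#'   dispersal flow, where more exchange means less differentiation) or
#'   `"two.sided"`.
#' @return an object of class `mantel_result`: a one-row tibble with
#'   `r`, `r_squared`, `p_value`, `n_perm`, `n_labels`.
#' @export
mantel_test <- function(a, b, n_perm = 9999, seed = NULL,
                        log_transform = FALSE,
                        symmetrize = c("none", "sum", "mean"),
                        alternative = c("greater", "less", "two.sided")) {
  symmetrize <- match.arg(symmetrize)
  alternative <- match.arg(alternative)
  if (n_perm < 99) stop("use n_perm >= 99.", call. = FALSE)
  a <- as_labelled_matrix(a)
  b <- as_labelled_matrix(b)
  b <- align_labels(a, b)
  b <- switch(symmetrize, none = b, sum = b + t(b), mean = (b + t(b)) / 2)
  check_symmetric(a, "a"); check_symmetric(b, "b")
  off <- upper.tri(a)
  if (log_transform) {
    bad <- which((a <= 0 | b <= 0) & off, arr.ind = TRUE)
    if (nrow(bad) > 0) {
      pairs <- apply(bad, 1, function(ij)
        paste(rownames(a)[ij[1]], colnames(a)[ij[2]], sep = " - "))
      stop("log transform needs positive entries; offending pair(s): ",
           paste(utils::head(pairs, 5), collapse = "; "),
           if (length(pairs) > 5) " ..." else "", call. = FALSE)
    }
    a <- log(a); b <- log(b)
  }
  r_obs <- stats::cor(a[off], b[off])
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(a)
  r_perm <- replicate(n_perm, {
    idx <- sample.int(n)
    stats::cor(a[off], b[idx, idx][off])
  })
  p <- switch(alternative,
    greater = (1 + sum(r_perm >= r_obs)) / (n_perm + 1),
    less = (1 + sum(r_perm <= r_obs)) / (n_perm + 1),
    two.sided = (1 + sum(abs(r_perm) >= abs(r_obs))) / (n_perm + 1))
  structure(tibble::tibble(
    r = r_obs, r_squared = r_obs^2, p_value = p,
    n_perm = n_perm, n_labels = n
  ), class = c("mantel_result", class(tibble::tibble())))
}
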