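# Literal, self-contained transcription of the 1984 variance-components
# estimator, organised differently from the package internals (per-pop
# data frames, explicit allele loop, no shared helpers): the oracle for
# wc_fst.
theta_oracle <- function(genotypes) {
  loci <- unique(genotypes$locus)
  num <- den <- 0
  for (loc in loci) {
    d <- genotypes[genotypes$locus == loc & !is.na(genotypes$allele_1), ]
    pops <- split(d, d$site)
    pops <- pops[vapply(pops, nrow, 0) > 0]
    r <- length(pops)
    if (r < 2) next
    alleles <- sort(unique(c(d$allele_1, d$allele_2)))
    if (length(alleles) < 2) next
    n_i <- vapply(pops, nrow, 0)
    nbar <- mean(n_i)
    nc <- (sum(n_i) - sum(n_i^2) / sum(n_i)) / (r - 1)
    for (al in alleles) {
      p_i <- vapply(pops, function(pp)
        sum(pp$allele_1 == al, pp$allele_2 == al) / (2 * nrow(pp)), 0)
      h_i <- vapply(pops, function(pp)
        mean(pp$allele_1 != pp$allele_2 &
               (pp$allele_1 == al | pp$allele_2 == al)), 0)
      pbar <- sum(n_i * p_i) / sum(n_i)
      hbar <- sum(n_i * h_i) / sum(n_i)
      s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
      a <- (nbar / nc) * (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                  hbar / 4) / (nbar - 1))
      b <- (nbar / (nbar - 1)) * (pbar * (1 - pbar) - (r - 1) / r * s2 -
                                    (2 * nbar - 1) / (4 * nbar) * hbar)
      cc <- hbar / 2
      num <- num + a
      den <- den + a + b + cc
    }
  }
  num / den
}

test_that("multilocus theta matches an independent variance-components oracle", {
  # 2-site, 2-allele toy dataset of 10 genotypes
  toy <- make_geno(rep(c("A", "B"), each = 5), list(
    a1 = "101/101", a2 = "101/103", a3 = "101/103", a4 = "103/103",
    a5 = "101/101",
    b1 = "103/103", b2 = "103/103", b3 = "101/103", b4 = "103/103",
    b5 = "101/103"))
  fit <- wc_fst(toy, genets_only = FALSE)
  expect_equal(fit$theta, theta_oracle(toy), tolerance = 1e-12)
  # and on a multi-locus simulated panel
  sim <- simulate_genotypes(n_sites = 4, samples_per_site = 25,
                            clonality = 1, fst = 0.1, seed = 11)
  fit2 <- wc_fst(sim$genotypes)
  expect_equal(fit2$theta, theta_oracle(sim$genotypes), tolerance = 1e-12)
})

test_that("theta hits its analytic limits and invariances", {
  # two sites with identical genotype composition: theta near 0
  one <- simulate_genotypes(n_sites = 1, samples_per_site = 50,
                            clonality = 1, fst = 0, seed = 21)$genotypes
  half <- unique(one$sample_id)[1:25]
  dup <- dplyr::mutate(one, site = ifelse(sample_id %in% half, "A", "B"))
  expect_lt(abs(wc_fst(dup)$theta), 0.02)
  # fixed for alternative alleles: theta = 1
  fixed <- make_geno(rep(c("A", "B"), each = 3), list(
    a1 = "101/101", a2 = "101/101", a3 = "101/101",
    b1 = "103/103", b2 = "103/103", b3 = "103/103"))
  expect_equal(wc_fst(fixed, genets_only = FALSE)$theta, 1)
  # invariant to site order and allele relabelling
  sim <- simulate_genotypes(n_sites = 3, samples_per_site = 20,
                            clonality = 1, fst = 0.08, seed = 31)$genotypes
  reordered <- dplyr::arrange(sim, dplyr::desc(site), sample_id, locus)
  relabelled <- dplyr::mutate(sim, allele_1 = 1000L - allele_1,
                              allele_2 = 1000L - allele_2)
  expect_equal(wc_fst(reordered)$theta, wc_fst(sim)$theta)
  expect_equal(wc_fst(relabelled)$theta, wc_fst(sim)$theta)
  # a site with fewer than two genets is named in the error
  tiny <- make_geno(c("A", "B", "B"), list(
    a1 = "101/101", b1 = "101/103", b2 = "103/103"))
  expect_error(wc_fst(tiny, genets_only = FALSE), "A")
})

test_that("theta is calibrated on the Balding-Nichols island model", {
  for (f_true in c(0.05, 0.10)) {
    est <- vapply(1:20, function(rep) {
      sim <- simulate_genotypes(n_sites = 2, samples_per_site = 50,
                                clonality = 1, fst = f_true,
                                seed = 1000 * f_true + rep)
      wc_fst(sim$genotypes)$theta
    }, 0)
    expect_lt(abs(mean(est) - f_true), 0.02)
  }
})

test_that("the pairwise matrix enumerates all site pairs symmetrically", {
  sim <- simulate_genotypes(n_sites = 5, samples_per_site = 15,
                            clonality = 1, fst = 0.05, seed = 41)
  pw <- pairwise_fst(sim$genotypes, n_perm = 0)
  expect_equal(nrow(tidy(pw)), choose(5, 2))
  expect_equal(pw$fst, t(pw$fst))
  expect_equal(unname(diag(pw$fst)), rep(0, 5))
})

test_that("pairwise permutation p-values are honest under the null", {
  # panmictic pairs: the rejection rate at alpha should not exceed
  # alpha + 2 s.e.
  alpha <- 0.1
  n_sim <- 120
  rej <- vapply(1:n_sim, function(rep) {
    sim <- simulate_genotypes(n_sites = 2, samples_per_site = 12,
                              n_loci = 4, clonality = 1, fst = 0,
                              seed = 5000 + rep)
    pw <- pairwise_fst(sim$genotypes, n_perm = 199, seed = rep)
    pw$p_values[1, 2] <= alpha
  }, NA)
  se <- sqrt(alpha * (1 - alpha) / n_sim)
  expect_lte(mean(rej), alpha + 2 * se)
})

test_that("F_ST linearization is elementwise x/(1-x) and rejects fixation", {
  m <- as_labelled_matrix(matrix(c(0, 0.5, 0.5, 0), 2,
    dimnames = list(c("a", "b"), c("a", "b"))))
  lin <- linearize_fst(m)
  expect_equal(lin["a", "b"], 1)
  expect_equal(lin["a", "a"], 0)
  m2 <- m; m2["a", "b"] <- 0.061; m2["b", "a"] <- 0.061
  expect_equal(linearize_fst(m2)["a", "b"], 0.061 / 0.939)
  m3 <- m; m3["a", "b"] <- 1
  expect_error(linearize_fst(m3), "infinity")
})

test_that("the Mantel statistic is the Pearson r of the upper triangles", {
  set.seed(1)
  n <- 8
  mk <- function() {
    m <- matrix(0, n, n, dimnames = list(letters[1:n], letters[1:n]))
    m[upper.tri(m)] <- runif(choose(n, 2))
    m + t(m)
  }
  a <- mk(); b <- mk()
  res <- mantel_test(a, b, n_perm = 99, seed = 1)
  expect_equal(res$r, cor(a[upper.tri(a)], b[upper.tri(b)]))
  expect_equal(res$r_squared, res$r^2)
  # self-comparison: perfect correlation at the smallest attainable p
  self <- mantel_test(a, a, n_perm = 999, seed = 2)
  expect_equal(self$r, 1)
  expect_equal(self$p_value, 1 / 1000)
  # identical seed, identical p
  expect_identical(mantel_test(a, b, n_perm = 499, seed = 7),
                   mantel_test(a, b, n_perm = 499, seed = 7))
  # log transform demands positivity and names an offending pair
  bz <- b; bz["a", "b"] <- bz["b", "a"] <- 0
  expect_error(mantel_test(a, bz, n_perm = 99, log_transform = TRUE), "a - b")
})

test_that("Mantel agrees with vegan and keeps its type-I error near alpha", {
  set.seed(3)
  n <- 9
  mk <- function() {
    m <- matrix(0, n, n)
    m[upper.tri(m)] <- runif(choose(n, 2))
    dimnames(m) <- list(letters[1:n], letters[1:n])
    m + t(m)
  }
  a <- mk(); b <- mk()
  ours <- mantel_test(a, b, n_perm = 999, seed = 1)
  ref <- vegan::mantel(as.dist(a), as.dist(b), permutations = 999)
  expect_equal(ours$r, unname(ref$statistic), tolerance = 1e-12)
  # null calibration: rejection rate 0.05 +/- 0.02 over independent pairs
  reps <- 400
  pvals <- vapply(1:reps, function(i) {
    set.seed(10000 + i)
    mantel_test(mk(), mk(), n_perm = 299, seed = i)$p_value
  }, 0)
  expect_lt(abs(mean(pvals <= 0.05) - 0.05), 0.02)
})
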