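test_that("clone detection collapses identical MLGs and hits the printed extremes", {
  # 45 samples built from 9 distinct genotype strings: G = 9, N = 45,
  # R = 0.18 -- the most clonal site pattern in the study system
  base <- lapply(1:9, function(k) c(paste0(100 + k, "/", 102 + k),
                                    paste0(200 + k, "/", 200 + k)))
  calls <- rep(base, length.out = 45)
  names(calls) <- sprintf("s%02d", 1:45)
  g <- make_geno("lonsdale", calls)
  part <- detect_clones(g)
  cs <- clonal_summary(part)
  expect_equal(cs$n, 45)
  expect_equal(cs$g, 9)
  expect_equal(round(cs$r, 2), 0.18)

  # monoclonal and fully sexual limits
  mono <- make_geno("m", setNames(rep(list(c("101/103", "205/205")), 5),
                                  paste0("m", 1:5)))
  expect_equal(clonal_summary(detect_clones(mono))$g, 1)
  uniq <- make_geno("u", setNames(lapply(1:5, function(k)
    c(paste0(100 + 2 * k, "/", 100 + 2 * k), "205/205")), paste0("u", 1:5)))
  expect_equal(clonal_summary(detect_clones(uniq))$g, 5)
})

test_that("clone partitions are true partitions, order-invariant and idempotent", {
  sim <- simulate_genotypes(n_sites = 2, samples_per_site = 30,
                            clonality = c(0.3, 0.8), seed = 7)
  part <- detect_clones(sim$genotypes)
  # disjoint and covering
  expect_equal(sort(unique(part$sample_id)),
               sort(unique(sim$genotypes$sample_id)))
  expect_equal(anyDuplicated(part$sample_id), 0)
  # one representative per genet
  expect_equal(sum(part$is_representative),
               dplyr::n_distinct(paste(part$site, part$genet)))
  # R invariant to sample order and within-locus allele swap
  shuffled <- sim$genotypes[sample.int(nrow(sim$genotypes)), ]
  swapped <- dplyr::mutate(shuffled, tmp = allele_1,
                           allele_1 = allele_2, allele_2 = tmp, tmp = NULL)
  expect_equal(
    dplyr::arrange(clonal_summary(detect_clones(swapped)), site)$r,
    dplyr::arrange(clonal_summary(part), site)$r)
  # recomputing on representatives only yields all-unique genets
  reps <- sim$genotypes[sim$genotypes$sample_id %in%
                          part$sample_id[part$is_representative], ]
  again <- clonal_summary(detect_clones(reps))
  expect_equal(again$g, again$n)
})

test_that("permissive matching lets missing loci join a genet, exact keeps them apart", {
  g <- make_geno("s", list(
    a = c("101/103", "205/205"),
    b = c("101/103", "?"),
    c = c("111/113", "205/205")))
  exact <- clonal_summary(detect_clones(g, "exact"))
  perm <- clonal_summary(detect_clones(g, "permissive"))
  expect_equal(exact$g, 3)
  expect_equal(perm$g, 2)
})

test_that("genotypic richness matches the printed table values and guards inputs", {
  expect_equal(round(genotypic_richness(9, 45), 2), 0.18)
  expect_equal(round(genotypic_richness(41, 45), 2), 0.91)
  expect_equal(round(genotypic_richness(40, 43), 2), 0.93)
  expect_equal(genotypic_richness(1, 10), 0)
  expect_equal(genotypic_richness(10, 10), 1)
  expect_error(genotypic_richness(2, 1), "fewer than 2")
  expect_error(genotypic_richness(11, 10), "G <= N")
})

test_that("P_gen multiplies HWE genotype probabilities across loci", {
  freqs <- tibble::tibble(
    locus = c("L1", "L1", "L2"),
    allele = c(101L, 103L, 205L),
    freq = c(0.5, 0.5, 1), n_genes = 10L)
  het <- make_geno("s", list(a = c("101/103", "205/205")))
  expect_equal(pgen(het, freqs)$p_gen, 0.5)
  hom <- make_geno("s", list(a = c("101/101", "205/205")))
  expect_equal(pgen(hom, freqs)$p_gen, 0.25)
  # het(0.5, 0.5) x hom(p = 0.2) = 0.5 * 0.04
  freqs2 <- tibble::tibble(
    locus = c("L1", "L1", "L2", "L2"),
    allele = c(101L, 103L, 205L, 207L),
    freq = c(0.5, 0.5, 0.2, 0.8), n_genes = 10L)
  g2 <- make_geno("s", list(a = c("101/103", "205/205")))
  expect_equal(pgen(g2, freqs2)$p_gen, 0.02)
  # unknown allele is an error; missing locus needs the skip flag
  stranger <- make_geno("s", list(a = c("101/199", "205/205")))
  expect_error(pgen(stranger, freqs2), "absent")
  holey <- make_geno("s", list(a = c("101/103", "?")))
  expect_error(pgen(holey, freqs2), "missing")
  expect_equal(pgen(holey, freqs2, skip_missing = TRUE)$p_gen, 0.5)
})

test_that("P_sex equals the explicit binomial tail and behaves monotonically", {
  # brute-force summation oracle
  psex_brute <- function(p, k, n) {
    sum(vapply(k:n, function(i) choose(n, i) * p^i * (1 - p)^(n - i), 0))
  }
  expect_equal(psex(1, 3, 45), 1)
  expect_equal(psex(0, 2, 45), 0)
  for (p in c(0.01, 0.1, 0.35)) {
    for (k in c(2, 5, 20)) {
      expect_equal(psex(p, k, 45), psex_brute(p, k, 45), tolerance = 1e-12)
    }
  }
  # non-increasing in n_copies; union bound at n_copies = 2
  p <- 0.02
  vals <- psex(p, 2:10, 45)
  expect_true(all(diff(vals) <= 0))
  expect_lte(psex(p, 2, 45), 45 * p)
  expect_error(psex(0.1, 1, 45), "n_copies >= 2")
})

test_that("diversity statistics match hand-computed unbiased formulas", {
  # one locus, 2 genets, both AB: Ho = 1, He = (4/3)(1 - 0.5) = 2/3
  g <- make_geno("s", list(a = c("101/103"), b = c("101/103")))
  d <- diversity_stats(g, genets_only = FALSE)
  expect_equal(d$ho, 1)
  expect_equal(d$he, 2 / 3)
  # monomorphic locus contributes Na = 1, Ho = He = 0
  mono <- make_geno("s", list(a = c("101/101"), b = c("101/101")))
  dm <- diversity_stats(mono, genets_only = FALSE)
  expect_equal(dm$na, 1)
  expect_equal(dm$ho, 0)
  expect_equal(dm$he, 0)
  expect_error(diversity_stats(g[0, ]), "no samples|zero genets")
})

test_that("unbiased He converges to 1 - sum(p^2) on a large HWE sample", {
  set.seed(99)
  p <- c(0.5, 0.3, 0.2)
  n <- 1e4
  a1 <- sample(101:103, n, TRUE, p)
  a2 <- sample(101:103, n, TRUE, p)
  g <- tibble::tibble(sample_id = sprintf("s%05d", 1:n), site = "big",
                      quadrat = NA_character_, locus = "L1",
                      allele_1 = pmin(a1, a2), allele_2 = pmax(a1, a2))
  d <- diversity_stats(g, genets_only = FALSE)
  expect_equal(d$he, 1 - sum(p^2), tolerance = 0.01)
})

test_that("shared MLGs across sites are found exactly when planted", {
  sim <- simulate_genotypes(n_sites = 2, samples_per_site = 20,
                            clonality = 0.9, seed = 3)
  g <- sim$genotypes
  # plant one clone shared across the two sites: copy a site01 sample's
  # genotype onto a site02 sample
  donor <- g[g$sample_id == "site01_001", ]
  g[g$sample_id == "site02_005", c("allele_1", "allele_2")] <-
    donor[, c("allele_1", "allele_2")]
  found <- shared_mlgs(g)
  expect_equal(nrow(found), 1)
  expect_equal(found$n_sites, 1 + 1)
  expect_true(found$p_sex >= 0 && found$p_sex <= 1)
  # disjoint MLG sets give an empty result
  none <- shared_mlgs(sim$genotypes)
  expect_equal(nrow(none), 0)
})

test_that("site-level P_sex covers only repeated genets and stays in range", {
  sim <- simulate_genotypes(n_sites = 2, samples_per_site = 30,
                            clonality = c(0.25, 0.95), seed = 5)
  ps <- site_psex(sim$genotypes)
  expect_true(all(ps$n_copies >= 2))
  expect_true(all(ps$p_sex >= 0 & ps$p_sex <= 1))
  expect_true(all(ps$p_gen > 0 & ps$p_gen <= 1))
})
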