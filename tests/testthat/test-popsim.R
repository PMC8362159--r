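test_that("base haplotypes segregate, skew to rare alleles and are reproducible", {
  b2 <- simulate_base_haplotypes(n_haps = 2, n_sites = 200, seed = 4)
  expect_true(all(colSums(b2$alleles) == 1))  # both alleles at every site
  b <- simulate_base_haplotypes(n_haps = 50, n_sites = 2000, seed = 4)
  f <- colMeans(b$alleles)
  expect_true(all(f > 0 & f < 1))
  # 1/k spectrum: singletons are the most common class
  counts <- colSums(b$alleles)
  expect_gt(sum(counts == 1), sum(counts > 25) / 2)
  expect_true(all(diff(b$pos) > 0))
  b_again <- simulate_base_haplotypes(n_haps = 50, n_sites = 2000, seed = 4)
  expect_identical(b$alleles, b_again$alleles)
  expect_identical(b$pos, b_again$pos)
})

test_that("meiosis has the Poisson crossover budget of a 1 Morgan map", {
  set.seed(11)
  pos <- sort(runif(500, 0, 100))
  parent <- haplotype_pair(rep(0L, 500), rep(1L, 500))
  n <- 10000
  xo <- replicate(n, sum(diff(meiosis(parent, pos)) != 0))
  # mean crossover count within 3 SE of the map length in Morgans
  expect_lt(abs(mean(xo) - 1), 3 * sqrt(1 / n) + 0.02)
  # 0 cM chromosome: the gamete is one of the two haplotypes, about 50/50
  starts <- replicate(500, meiosis(parent, rep(0, 5), length_cM = 0)[1])
  expect_true(all(starts %in% c(0L, 1L)))
  expect_gt(mean(starts), 0.35)
  expect_lt(mean(starts), 0.65)
  # fully inbred parent: the gamete is the haplotype, crossovers or not
  ip <- inbred_pair(rep(1L, 500))
  expect_equal(meiosis(ip, pos), ip$hap1)
})

test_that("panel selection honours frequency and segregation filters", {
  b <- simulate_base_haplotypes(n_haps = 200, n_sites = 1500, seed = 9)
  # site 1: MAF 0.005 in the base set, segregating in the parents -> the
  # frequency filter alone must exclude it
  b$alleles[, 1] <- 0L
  b$alleles[1, 1] <- 1L
  parents <- rbind(A = 2L * b$alleles[1, ], B = 2L * b$alleles[2, ])
  panel <- select_panels(b, parents, n_hd = 100, n_ld = 10)
  expect_equal(length(panel$marker), 100L)
  expect_equal(sum(panel$ld), 10L)
  sel <- attr(panel, "site_index")
  expect_false(1L %in% sel)  # MAF 0.005 site is never selected
  f <- colMeans(b$alleles)[sel]
  expect_true(all(pmin(f, 1 - f) >= 0.01))
  seg <- apply(parents[, sel], 2, function(g) any(g == 1L) || length(unique(g)) > 1L)
  expect_true(all(seg))
  # requesting every eligible site makes Ld equal Hd
  small <- select_panels(b, parents, n_hd = 50, n_ld = 50)
  expect_equal(sum(small$ld), 50L)
  expect_error(select_panels(b, parents, n_hd = 10^6, n_ld = 10), "eligible")
})

test_that("scenario masking matches the study design", {
  pop <- small_pop(seed = 21, n_crosses = 2L, n_hd_descendants_per_cross = 3L,
                   n_f2_per_cross = 20L)
  g <- unclass(pop$geno)
  ld <- pop$panel$ld
  f2 <- grep("^F2_", rownames(g), value = TRUE)
  full <- rowSums(g[f2, ] != 9L) == ncol(g)
  expect_equal(sum(full), 6L)             # 3 Hd descendants x 2 crosses
  focal <- f2[!full]
  expect_equal(length(focal), 34L)
  expect_true(all(g[focal, !ld] == 9L))
  expect_true(all(g[focal, ld] != 9L))
  expect_true(all(g["A", ] == 9L))        # ungenotyped parent row is all 9
  pop_ld <- small_pop(seed = 21, parentA_genotyping = "ld")
  gl <- unclass(pop_ld$geno)
  expect_true(all(gl["A", !pop_ld$panel$ld] == 9L))
  expect_true(all(gl["A", pop_ld$panel$ld] != 9L))
})

test_that("an inbred target parent has zero heterozygosity", {
  pop <- small_pop(seed = 8, parentA_inbred = TRUE)
  expect_true(all(hap_genotype(pop$truth$A) %in% c(0L, 2L)))
  pop_out <- small_pop(seed = 8, parentA_inbred = FALSE)
  expect_gt(mean(hap_genotype(pop_out$truth$A) == 1L), 0.05)
})

test_that("every offspring allele is traceable to its parents (Mendelian consistency)", {
  pop <- small_pop(seed = 33, parentA_inbred = FALSE, n_f2_per_cross = 15L)
  A <- pop$truth$A
  b <- pop$truth$B$hap1
  for (id in pop$crosses$B$hd) {
    f2 <- pop$truth[[id]]
    for (h in list(f2$hap1, f2$hap2)) {
      ok <- h == A$hap1 | h == A$hap2 | h == b
      expect_true(all(ok))
    }
  }
})

test_that("F2 genotype frequencies match the selfing expectation", {
  # A heterozygous x homozygous mate, F1 selfed: marginal F2 genotype
  # probabilities are (5/8, 1/4, 1/8) on the mate-allele side (enumeration:
  # half the F1 are homozygous, half segregate 1:2:1)
  pop <- small_pop(seed = 55, parentA_inbred = FALSE, n_f2_per_cross = 300L,
                   n_hd_snps = 200L, n_ld_snps = 10L, n_base_sites = 1600L)
  truthA <- hap_genotype(pop$truth$A)
  b <- pop$truth$B$hap1
  loci <- which(truthA == 1L & b == 0L)
  expect_gt(length(loci), 20)
  f2_ids <- c(pop$crosses$B$hd, pop$crosses$B$focal)
  g <- t(vapply(f2_ids, function(id) hap_genotype(pop$truth[[id]]),
                integer(length(truthA))))[, loci, drop = FALSE]
  props <- c(mean(g == 0L), mean(g == 1L), mean(g == 2L))
  expect_equal(props, c(5 / 8, 1 / 4, 1 / 8), tolerance = 0.08)
})

test_that("a seeded scenario reproduces bit-identically", {
  p1 <- small_pop(seed = 77)
  p2 <- small_pop(seed = 77)
  expect_identical(unclass(p1$geno), unclass(p2$geno))
  expect_identical(p1$panel$pos, p2$panel$pos)
  expect_identical(p1$truth$A$hap1, p2$truth$A$hap1)
})
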