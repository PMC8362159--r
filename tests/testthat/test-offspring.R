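# Toy panel helper: m equally spaced markers, the first `n_ld` being Ld.
toy_panel <- function(m, ld_idx) {
  marker_panel(paste0("m", seq_len(m)), seq(0, 100, length.out = m),
               ld_markers = paste0("m", ld_idx))
}

test_that("origin assignment follows the opposing-homozygote rule", {
  panel <- toy_panel(5, 1:5)
  A <- inbred_pair(rep(0L, 5))  # genotype 0 everywhere
  B <- inbred_pair(rep(1L, 5))  # genotype 2 everywhere
  # descendant genotype 2 at opposing homozygous parents: both haplotypes B
  anc <- assign_origin(c(2L, 1L, 0L, 9L, 2L), A, B, panel)
  expect_equal(anc$origin1[anc$marker == "m1"], "B")
  expect_equal(anc$origin2[anc$marker == "m1"], "B")
  # heterozygous descendant: one haplotype from each, alleles from parents
  expect_equal(anc$origin1[anc$marker == "m2"], "A")
  expect_equal(anc$origin2[anc$marker == "m2"], "B")
  expect_equal(anc$allele1[anc$marker == "m2"], 0L)
  expect_equal(anc$allele2[anc$marker == "m2"], 1L)
  # missing genotype carries no anchor
  expect_false("m4" %in% anc$marker)

  # identical homozygous parents: uninformative, no anchor; impossible
  # genotypes are flagged as conflicts, not anchors
  B0 <- inbred_pair(rep(0L, 5))
  anc2 <- assign_origin(c(0L, 2L, 0L, 0L, 0L), A, B0, panel)
  expect_equal(nrow(anc2), 0L)
  expect_equal(attr(anc2, "conflicts"), "m2")
})

test_that("heterozygote phasing extends origins by the nearest-anchor rule", {
  panel <- toy_panel(5, 1:5)
  A <- inbred_pair(c(0L, 9L, 9L, 9L, 0L))
  A$hap1 <- c(0L, 0L, 0L, 0L, 0L); A$hap2 <- A$hap1
  B <- inbred_pair(rep(1L, 5))
  # concordant flanking anchors (one from each parent), het markers between
  y <- c(1L, 1L, 1L, 1L, 1L)
  anc <- assign_origin(y, A, B, panel)
  ph <- phase_focal_heterozygotes(y, anc, panel)
  expect_true(all(ph$origin1 == "A"))
  expect_true(all(ph$origin2 == "B"))
  # single anchor (the only marker where both parents are homozygous):
  # the whole chromosome inherits its orientation
  A2 <- haplotype_pair(c(0L, 0L, 0L, 0L, 0L), c(0L, 1L, 1L, 1L, 1L))
  y2 <- c(0L, 1L, 1L, 9L, 1L)
  anc2 <- assign_origin(y2, A2, B, panel)
  expect_equal(nrow(anc2), 1L)
  expect_equal(anc2$dose_A, 2L)
  ph2 <- phase_focal_heterozygotes(y2, anc2, panel)
  expect_equal(ph2$origin1[c(2, 3, 5)], rep("A", 3))
  expect_equal(ph2$origin2[c(2, 3, 5)], rep("A", 3))
})

test_that("imputation matches the exhaustive minimum-crossover oracle on toys", {
  m <- 7
  panel <- toy_panel(m, 1:m)
  pa <- c(0L, 0L, 1L, 1L, 0L, 1L, 0L)   # parent A allele (inbred)
  qb <- c(1L, 1L, 0L, 0L, 1L, 0L, 1L)   # parent B allele (opposing)
  A <- inbred_pair(pa); B <- inbred_pair(qb)
  cases <- list(
    list(obs = c(1L, 4L, 7L), y = c(2L, 2L, 2L)),   # concordant: dose 2
    list(obs = c(1L, 7L), y = c(2L, 0L)),           # one crossover interval
    list(obs = c(1L, 4L, 7L), y = c(0L, 1L, 1L)),   # mixed doses
    list(obs = c(2L, 6L), y = c(1L, 1L))
  )
  for (cs in cases) {
    yfull <- rep(9L, m)
    yfull[cs$obs] <- cs$y
    oracle <- min_recomb_oracle(pa, qb, cs$obs, cs$y)
    res <- impute_focal_to_hd(yfull, A, B, panel)
    agree <- !is.na(oracle) & res$genotype != 9L
    expect_true(all(res$genotype[agree] == oracle[agree]),
                info = paste("case", paste(cs$y, collapse = "/")))
    # where the oracle is unique the heuristic must not stay silent
    expect_true(all(res$genotype[cs$obs] == cs$y))
  }
})

test_that("fully inbred parents with full anchors impute without missingness", {
  pop <- small_pop(seed = 101, parentA_inbred = TRUE)
  mate <- pop$truth$B
  id <- pop$crosses$B$focal[1]
  y <- unclass(pop$geno)[id, ]
  res <- impute_focal_to_hd(y, pop$truth$A, mate, pop$panel)
  expect_equal(imputation_yield(res$genotype), 1)
  # imputed genotype equals the sum of the assigned parental alleles
  hs <- hap_genotype(res$haplotypes)
  expect_true(all(hs == res$genotype))
  # observed Ld genotypes are never overwritten
  obs <- which(y != 9L)
  expect_equal(res$genotype[obs], unname(y[obs]))
})

test_that("imputed alleles are copies of an assigned parent's alleles", {
  pop <- small_pop(seed = 102, parentA_inbred = FALSE)
  A <- pop$truth$A
  b <- pop$truth$B$hap1
  for (id in pop$crosses$B$focal[1:5]) {
    res <- impute_focal_to_hd(unclass(pop$geno)[id, ], A, pop$truth$B,
                              pop$panel)
    for (h in list(res$haplotypes$hap1, res$haplotypes$hap2)) {
      k <- h != 9L
      expect_true(all(h[k] == A$hap1[k] | h[k] == A$hap2[k] | h[k] == b[k]))
    }
  }
})

test_that("spans with unknown origin stay missing", {
  panel <- toy_panel(6, 1:6)
  A <- inbred_pair(c(0L, 0L, 0L, 1L, 1L, 1L))
  B <- inbred_pair(c(0L, 0L, 0L, 0L, 0L, 0L))
  # parents identical over markers 1-3 (dose-free fill applies), opposing at
  # 4-6 but the focal is unobserved there with no anchor at all
  y <- rep(9L, 6)
  res <- impute_focal_to_hd(y, A, B, panel)
  expect_equal(res$genotype[1:3], c(0L, 0L, 0L))
  expect_true(all(res$genotype[4:6] == 9L))
  expect_lt(imputation_yield(res$genotype), 1)
})

test_that("whole-population offspring imputation locates cross parents", {
  pop <- small_pop(seed = 103)
  parents <- list(A = pop$truth$A, B = pop$truth$B)
  res <- impute_offspring(pop$geno, pop$pedigree, pop$panel, parents)
  expect_equal(length(res$skipped), 0L)
  focal <- pop$crosses$B$focal
  acc <- vapply(focal, function(id)
    imputation_accuracy(hap_genotype(pop$truth[[id]]), res$genotype[id, ]),
    numeric(1))
  # an all-heterozygous focal individual has no defined correlation
  expect_gt(mean(acc, na.rm = TRUE), 0.9)
})
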