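test_that("ancestor-only imputation calls only shared homozygotes", {
  gp1 <- c(0L, 0L, 2L, 1L, 0L, 9L)
  gp2 <- c(0L, 2L, 2L, 1L, 1L, 0L)
  res <- impute_from_ancestors(gp1, gp2)
  expect_equal(res$genotype, c(0L, 9L, 2L, 9L, 9L, 9L))
  # called markers are phased de facto
  expect_equal(res$haplotypes$hap1[1], 0L)
  expect_equal(res$haplotypes$hap2[3], 1L)
  expect_equal(res$provenance[c(1, 3)], c("ancestor", "ancestor"))
})

test_that("chi-square caller matches an exact enumeration oracle for n <= 12", {
  for (n in c(4L, 7L, 10L, 12L)) {
    for (n0 in 0:n) for (n1 in 0:(n - n0)) {
      counts <- c(n0, n1, n - n0 - n1)
      for (mate in c(0L, 1L, 2L)) {
        got <- chi2_call(counts, mate)$call
        expect_identical(got, chi2_oracle(counts, mate),
                         info = paste(c(counts, mate), collapse = ","))
      }
    }
  }
  # too few descendants
  expect_identical(chi2_call(c(1L, 1L, 1L), 0L)$call, "unknown")
  expect_identical(chi2_call(c(0L, 0L, 0L), 0L)$call, "unknown")
})

test_that("chi-square power against a heterozygous parent matches enumeration", {
  # descendants of (A het x mate hom 0), F1 selfed: genotype probabilities
  # (5/8, 1/4, 1/8); enumerate all count vectors with n = 10 exactly
  n <- 10L
  power <- 0; seg <- 0
  for (n0 in 0:n) for (n1 in 0:(n - n0)) {
    counts <- c(n0, n1, n - n0 - n1)
    pr <- dmultinom(counts, prob = c(5 / 8, 1 / 4, 1 / 8))
    if (counts[2] == 0 && (counts[1] == 0 || counts[3] == 0)) next
    seg <- seg + pr
    if (chi2_call(counts, 0L)$call == "het") power <- power + pr
  }
  # the decision function reproduces the exact enumeration value
  expect_equal(power / seg, 0.1345987, tolerance = 1e-6)
  # counts exactly at the expectation give chi-square 0, hence the opposing
  # homozygote when the mate is homozygous
  res <- chi2_call(c(4L, 8L, 4L), 0L)
  expect_equal(res$statistic, 0)
  expect_identical(res$call, "hom2")
  expect_identical(chi2_call(c(4L, 8L, 4L), 2L)$call, "hom0")
})

test_that("monomorphic-descendants rule needs fixation, compatibility and depth", {
  d10 <- function(g) matrix(g, nrow = 10, ncol = 3)
  desc <- list(d10(c(0L, 0L, 0L)))
  desc[[1]][, 2] <- 2L
  desc[[1]][1, 3] <- 1L
  mate <- list(c(0L, 0L, 0L))
  track <- infer_homozygous_from_descendants(desc, mate)
  expect_equal(track[1], 0L)   # all descendants 0, mate 0 -> hom0
  expect_equal(track[2], 9L)   # fixed for 2 but mate 0: impossible, no call
  expect_equal(track[3], 9L)   # segregating: out of scope for this rule
  # minimum total descendant count guard
  small <- list(matrix(0L, nrow = 3, ncol = 1))
  expect_equal(infer_homozygous_from_descendants(small, list(0L)), 9L)
})

test_that("consensus collapses to one haplotype in the inbred limit", {
  pop <- small_pop(seed = 31, parentA_inbred = TRUE)
  rel <- find_targets_and_relatives(pop$pedigree, pop$geno, pop$panel)[["A"]]
  desc <- list(unclass(pop$geno)[rel$crosses$B$descendants_hd, ])
  mate <- list(unclass(pop$geno)[rel$crosses$B$mate, ])
  status <- list(rep(9L, length(pop$panel$marker)))
  cons <- consensus_haplotypes_from_descendants(desc, mate, status,
                                                integer(0), pop$panel$pos)
  expect_true(cons$single)
  both <- cons$hap1 != 9L
  expect_true(all(cons$hap2[both] == cons$hap1[both]))
  truthA <- pop$truth$A$hap1
  expect_gt(mean(cons$hap1[both] == truthA[both]), 0.98)
})

test_that("a vote tie leaves the allele missing", {
  # two descendants, opposite implied gametes at the central marker
  pos <- c(0, 50, 100)
  desc <- list(rbind(c(2L, 2L, 2L), c(2L, 0L, 2L)))
  mate <- list(c(0L, 0L, 0L))
  status <- list(rep(9L, 3))
  cons <- consensus_haplotypes_from_descendants(desc, mate, status,
                                                integer(0), pos)
  # votes at marker 2 are 1 vs 0 within a single group: tie -> missing
  expect_true(cons$single)
  expect_equal(cons$hap1[2], 9L)
})

test_that("an outbred parent's haplotypes are recovered from descendants", {
  pop <- small_pop(seed = 41, parentA_inbred = FALSE, n_crosses = 2L,
                   n_f2_per_cross = 80L)
  fit <- impute_parent(pop$geno, pop$pedigree, pop$panel)
  truth <- hap_genotype(pop$truth$A)
  expect_gt(imputation_accuracy(truth, fit$genotype), 0.9)
  # per-allele error of the phased haplotypes, allowing label swaps locally,
  # is bounded by comparing the genotype instead
  expect_gt(mean(fit$genotype == truth), 0.85)
})

test_that("target discovery classifies relatives by cross and skips complete parents", {
  pop <- small_pop(seed = 51)
  targets <- find_targets_and_relatives(pop$pedigree, pop$geno, pop$panel)
  usable <- names(Filter(function(x) x$usable, targets))
  expect_equal(usable, "A")
  rel <- targets[["A"]]
  expect_equal(rel$mates_hd, "B")
  expect_equal(sort(rel$crosses$B$descendants_hd), sort(pop$crosses$B$hd))
  expect_equal(rel$ancestors_hd, character(0))
  # grandparents at Hd become ancestors
  pop5 <- small_pop(seed = 51, include_grandparents = TRUE)
  rel5 <- find_targets_and_relatives(pop5$pedigree, pop5$geno, pop5$panel)[["A"]]
  expect_equal(sort(rel5$ancestors_hd), c("GP1", "GP2"))
  # a fully genotyped parent is not a target
  g2 <- pop$geno
  g2["A", ] <- hap_genotype(pop$truth$A)
  targets2 <- find_targets_and_relatives(pop$pedigree, g2, pop$panel)
  expect_false("A" %in% names(targets2))
})

test_that("ancestor/descendant merge keeps agreement and blanks conflicts", {
  hp <- function(h1, h2) haplotype_pair(h1, h2)
  anc <- list(genotype = c(0L, 0L, 9L),
              haplotypes = hp(c(0L, 0L, 9L), c(0L, 0L, 9L)),
              provenance = c("ancestor", "ancestor", NA))
  des <- list(genotype = c(0L, 1L, 2L),
              haplotypes = hp(c(0L, 0L, 1L), c(0L, 1L, 1L)),
              provenance = c("consensus", "consensus", "consensus"))
  out <- merge_ancestor_descendant(anc, des)
  expect_equal(out$genotype, c(0L, 9L, 2L))   # agree / conflict / one-sided
  expect_equal(out$haplotypes$hap1[2], 9L)
  # ancestor unknown everywhere: output equals the descendant track
  anc0 <- list(genotype = rep(9L, 3),
               haplotypes = hp(rep(9L, 3), rep(9L, 3)),
               provenance = rep(NA_character_, 3))
  out0 <- merge_ancestor_descendant(anc0, des)
  expect_equal(out0$genotype, des$genotype)
})

test_that("observed genotypes are invariant and haplotype sums match genotypes", {
  for (inbred in c(TRUE, FALSE)) {
    pop <- small_pop(seed = 61 + inbred, parentA_inbred = inbred,
                     parentA_genotyping = "ld")
    fit <- impute_parent(pop$geno, pop$pedigree, pop$panel)
    obs <- which(unclass(pop$geno)["A", ] != 9L)
    expect_equal(unname(fit$genotype[obs]),
                 unname(unclass(pop$geno)["A", obs]))
    ph <- fit$haplotypes
    both <- ph$hap1 != 9L & ph$hap2 != 9L
    expect_true(all((ph$hap1 + ph$hap2)[both] == fit$genotype[both]))
  }
})

test_that("imputation report methods summarise the fit", {
  pop <- small_pop(seed = 71)
  fit <- impute_parent(pop$geno, pop$pedigree, pop$panel)
  expect_output(print(fit), "parent imputation for 'A'")
  s <- summary(fit)
  expect_output(print(s), "yield")
  expect_equal(s$n_crosses, 1L)
  expect_equal(s$n_hd_descendants, 10L)
})
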