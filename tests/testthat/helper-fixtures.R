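# Small simulated populations and toy objects shared across tests.

# A scaled-down scenario that still has every structural feature.
small_spec <- function(...) {
  args <- list(n_f2_per_cross = 60L, n_hd_snps = 400L, n_ld_snps = 20L,
               n_base_sites = 3000L)
  override <- list(...)
  args[names(override)] <- override
  do.call(scenario_spec, args)
}

small_pop <- function(seed = 1L, ...) {
  spec <- small_spec(...)
  spec$seed <- seed
  simulate_population(spec)
}

# Fully homozygous parent pair over n markers.
inbred_pair <- function(alleles) haplotype_pair(alleles, alleles)

# Exhaustive minimum-crossover phasing oracle for toy instances.
#
# Parents are fully inbred with alleles pa (parent A) and qb (parent B) per
# marker; the child is observed at `obs_idx` with genotypes y_obs. Enumerates
# every A-dose vector in {0,1,2}^m consistent with the observations,
# keeps those with the minimum number of crossovers (sum of |dose steps|),
# and returns the implied genotype where all minimisers agree (NA elsewhere).
min_recomb_oracle <- function(pa, qb, obs_idx, y_obs) {
  m <- length(pa)
  stopifnot(m <= 8)
  grids <- rep(list(0:2), m)
  doses <- as.matrix(expand.grid(grids))
  geno <- function(d) d * pa + (2 - d) * qb
  ok <- apply(doses, 1, function(d) all(geno(d)[obs_idx] == y_obs))
  doses <- doses[ok, , drop = FALSE]
  if (nrow(doses) == 0) return(rep(NA_integer_, m))
  xo <- apply(doses, 1, function(d) sum(abs(diff(d))))
  doses <- doses[xo == min(xo), , drop = FALSE]
  out <- rep(NA_integer_, m)
  for (j in seq_len(m)) {
    g <- unique(doses[, j] * pa[j] + (2 - doses[, j]) * qb[j])
    if (length(g) == 1) out[j] <- g
  }
  out
}

# Independent re-derivation of the chi-square genotype decision for one
# count vector (used as the enumeration oracle for chi2_call).
chi2_oracle <- function(counts, mate_gt, alpha = 0.05, min_n = 4) {
  n <- sum(counts)
  if (n < min_n || !(mate_gt %in% c(0, 2))) return("unknown")
  if (counts[2] == 0 && (counts[1] == 0 || counts[3] == 0)) return("unknown")
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  e <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - e)^2 / e)
  if (pchisq(x2, df = 1, lower.tail = FALSE) < alpha) "het"
  else if (mate_gt == 0) "hom2" else "hom0"
}
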