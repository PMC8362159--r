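#' Simulate base haplotypes for one chromosome
#'
#' Generates binary founder haplotypes over segregating sites on a single
#' 1 Morgan chromosome (positions uniform on 0-100 cM). The derived-allele
#' count of each site is drawn with probability proportional to 1/k
#' (a neutral-equilibrium-like frequency spectrum, skewed toward rare
#' variants), so every site segregates in the base set.
#'
#' @param n_haps number of base haplotypes (>= 2).
#' @param n_sites number of segregating sites.
#' @param seed optional integer seed.
#' @param length_cM chromosome length in cM.
#' @return list of class `base_haplotypes` with `alleles` (`n_haps` x
#'   `n_sites` 0/1 matrix), `pos` (sorted cM positions) and `length_cM`.
#' @export
simulate_base_haplotypes <- function(n_haps = 100L, n_sites = 80000L,
                                     seed = NULL, length_cM = 100) {
  if (n_haps < 2L) stop("n_haps must be >= 2")
  if (!is.null(seed)) set.seed(seed)
  pos <- sort(stats::runif(n_sites, 0, length_cM))
  while (any(diff(pos) <= 0))  # vanishing probability; keep positions strict
    pos <- sort(stats::runif(n_sites, 0, length_cM))
  kk <- 1:(n_haps - 1L)
  counts <- sample(kk, n_sites, replace = TRUE, prob = 1 / kk)
  alleles <- matrix(0L, n_haps, n_sites)
  for (s in seq_len(n_sites))
    alleles[sample.int(n_haps, counts[s]), s] <- 1L
  colnames(alleles) <- sprintf("s%06d", seq_len(n_sites))
  structure(list(alleles = alleles, pos = pos, length_cM = length_cM),
            class = "base_haplotypes")
}

#' @export
print.base_haplotypes <- function(x, ...) {
  cat(sprintf("base haplotype set: %d haplotypes x %d segregating sites, %.0f cM\n",
              nrow(x$alleles), ncol(x$alleles), x$length_cM))
  invisible(x)
}

#' Sample a gamete from a phased parent (one meiosis)
#'
#' Crossovers occur with 1% probability per cM: the crossover count is Poisson
#' with mean equal to the map length in Morgans and breakpoints are uniform
#' along the chromosome (no interference). The gamete is the corresponding
#' mosaic of the parent's two haplotypes.
#'
#' @param parent a fully phased [haplotype_pair()].
#' @param pos marker positions in cM.
#' @param length_cM chromosome length in cM (default 100, i.e. 1 Morgan).
#' @return integer allele vector.
#' @export
meiosis <- function(parent, pos, length_cM = 100) {
  n_xo <- stats::rpois(1L, length_cM / 100)
  start <- sample.int(2L, 1L)
  if (n_xo == 0L)
    return(if (start == 1L) parent$hap1 else parent$hap2)
  xo <- sort(stats::runif(n_xo, 0, length_cM))
  seg <- findInterval(pos, xo)
  use1 <- (seg + start) %% 2L == 1L
  ifelse(use1, parent$hap1, parent$hap2)
}

#' Select Hd and Ld marker panels from base haplotypes
#'
#' Hd markers are sites that segregate among the supplied parents, have a
#' minor allele frequency between 0.01 and 0.50 in the base set, and are
#' approximately equidistant in cM. The Ld panel is an approximately
#' equidistant subset of the Hd panel.
#'
#' @param base a [simulate_base_haplotypes()] result.
#' @param parent_geno matrix of parent genotype rows (codes 0/1/2) over all
#'   base sites; a site "segregates in the parents" when the parents are not
#'   all identically homozygous there.
#' @param n_hd,n_ld panel sizes.
#' @return a [marker_panel()] with attribute `site_index` giving, for each Hd
#'   marker, its column in the base set.
#' @export
select_panels <- function(base, parent_geno, n_hd, n_ld) {
  f <- colMeans(base$alleles)
  maf <- pmin(f, 1 - f)
  segregating <- apply(parent_geno, 2, function(g) any(g == 1L) || length(unique(g)) > 1L)
  eligible <- which(maf >= 0.01 & maf <= 0.5 & segregating)
  if (length(eligible) < n_hd)
    stop(sprintf("only %d eligible sites for an Hd panel of %d",
                 length(eligible), n_hd))
  sel <- eligible[equidistant_pick(base$pos[eligible], n_hd)]
  ld_sel <- sel[equidistant_pick(base$pos[sel], n_ld)]
  panel <- marker_panel(colnames(base$alleles)[sel], base$pos[sel],
                        ld_markers = colnames(base$alleles)[ld_sel])
  attr(panel, "site_index") <- sel
  panel
}

# Pick n indices of sorted positions p nearest to equidistant targets,
# monotone and without reuse.
equidistant_pick <- function(p, n) {
  m <- length(p)
  if (n > m) stop("not enough sites to pick from")
  if (n == m) return(seq_len(m))
  targets <- seq(p[1], p[m], length.out = n)
  sel <- integer(n)
  j <- 1L
  for (i in seq_len(n)) {
    max_j <- m - (n - i)  # leave room for the remaining picks
    while (j < max_j && abs(p[j + 1L] - targets[i]) < abs(p[j] - targets[i]))
      j <- j + 1L
    sel[i] <- j
    j <- j + 1L
  }
  sel
}

#' Simulate a biparental population under a masking scenario
#'
#' Builds the full study population for one replicate: inbred base founders
#' drawn from simulated base haplotypes, the target parent ("A", an F1 of the
#' two grandparents, fixed by selfing when inbred), `n_crosses` crosses of A
#' to founder mates ("B".."E"), and for every cross `n_f2_per_cross` F2
#' individuals (each from its own selfed F1). Marker panels are selected with
#' [select_panels()] and genotypes are masked per the scenario: parent A all
#' missing or Ld-only, Hd descendants fully genotyped, remaining (focal) F2 at
#' Ld only, mates (and grandparents, when included) at Hd.
#'
#' @param spec a [scenario_spec()].
#' @return list of class `bip_population` with elements `spec`, `panel`,
#'   `pedigree`, `truth` (named list of [haplotype_pair()] at panel markers),
#'   `geno_true`, `geno` (masked), and `crosses` (per cross: mate, Hd
#'   descendant ids, focal ids).
#' @export
simulate_population <- function(spec) {
  stopifnot(inherits(spec, "scenario_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  base <- simulate_base_haplotypes(spec$n_base_haplotypes, spec$n_base_sites)
  mates <- c("B", "C", "D", "E")[seq_len(spec$n_crosses)]

  founder_idx <- sample.int(nrow(base$alleles), 2L + spec$n_crosses)
  gp_haps <- list(GP1 = base$alleles[founder_idx[1], ],
                  GP2 = base$alleles[founder_idx[2], ])
  mate_haps <- lapply(seq_along(mates), function(j) base$alleles[founder_idx[2L + j], ])
  names(mate_haps) <- mates

  # Parent A: F1 of the grandparents; inbred = analytic fixation of one
  # recombinant F1 gamete (heterozygosity after ~100 selfing rounds is ~2^-100)
  f1A <- haplotype_pair(gp_haps$GP1, gp_haps$GP2)
  if (spec$parentA_inbred) {
    g <- meiosis(f1A, base$pos, base$length_cM)
    A_full <- haplotype_pair(g, g)
  } else {
    A_full <- f1A
  }

  parent_geno <- rbind(A = hap_genotype(A_full),
                       do.call(rbind, lapply(mate_haps, function(h) 2L * h)))
  panel <- select_panels(base, parent_geno, spec$n_hd_snps, spec$n_ld_snps)
  sites <- attr(panel, "site_index")
  pos <- panel$pos

  sub <- function(h) h[sites]
  truth <- list(
    GP1 = haplotype_pair(sub(gp_haps$GP1), sub(gp_haps$GP1)),
    GP2 = haplotype_pair(sub(gp_haps$GP2), sub(gp_haps$GP2)),
    A   = haplotype_pair(sub(A_full$hap1), sub(A_full$hap2)))
  for (m in mates)
    truth[[m]] <- haplotype_pair(sub(mate_haps[[m]]), sub(mate_haps[[m]]))

  ped_id <- c("GP1", "GP2", "A", mates)
  ped_p1 <- c(NA, NA, "GP1", rep(NA, length(mates)))
  ped_p2 <- c(NA, NA, "GP2", rep(NA, length(mates)))
  A_panel <- truth$A
  crosses <- list()
  for (m in mates) {
    f1_ids <- sprintf("F1_%s_%04d", m, seq_len(spec$n_f2_per_cross))
    f2_ids <- sprintf("F2_%s_%04d", m, seq_len(spec$n_f2_per_cross))
    ped_id <- c(ped_id, f1_ids, f2_ids)
    ped_p1 <- c(ped_p1, rep("A", length(f1_ids)), f1_ids)
    ped_p2 <- c(ped_p2, rep(m, length(f1_ids)), f1_ids)
    for (i in seq_along(f2_ids)) {
      gA <- meiosis(A_panel, pos, base$length_cM)
      f1 <- haplotype_pair(gA, truth[[m]]$hap1)
      truth[[f2_ids[i]]] <- haplotype_pair(meiosis(f1, pos, base$length_cM),
                                           meiosis(f1, pos, base$length_cM))
    }
    n_hd <- spec$n_hd_descendants_per_cross
    crosses[[m]] <- list(mate = m,
                         hd = f2_ids[seq_len(n_hd)],
                         focal = f2_ids[setdiff(seq_along(f2_ids), seq_len(n_hd))])
  }
  ped <- pedigree(ped_id, ped_p1, ped_p2)

  geno_ids <- c(if (spec$include_grandparents) c("GP1", "GP2"), "A", mates,
                unlist(lapply(crosses, function(cr) c(cr$hd, cr$focal)),
                       use.names = FALSE))
  geno_true <- genotype_matrix(
    do.call(rbind, lapply(truth[geno_ids], hap_genotype)),
    ids = geno_ids, markers = panel$marker)

  geno <- geno_true
  ld <- panel$ld
  if (spec$parentA_genotyping == "none") {
    geno["A", ] <- MISSING
  } else {
    geno["A", !ld] <- MISSING
  }
  for (cr in crosses)
    geno[cr$focal, !ld] <- MISSING

  structure(list(spec = spec, panel = panel, pedigree = ped, truth = truth,
                 geno_true = geno_true, geno = geno, crosses = crosses),
            class = "bip_population")
}

#' @export
print.bip_population <- function(x, ...) {
  cat("simulated biparental population\n")
  print(x$spec)
  cat(sprintf("  %d pedigree records, %d genotyped rows\n",
              nrow(x$pedigree), nrow(x$geno)))
  invisible(x)
}
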