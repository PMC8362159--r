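#' Assign parent of origin at informative Ld markers (anchor points)
#'
#' At each Ld marker where both parents are homozygous the parent of origin of
#' a focal individual's haplotypes can be resolved: with opposing homozygous
#' parents the number of copies of each parental allele in the focal genotype
#' says how many haplotypes each parent transmitted. Markers where both
#' parents carry the same homozygous genotype are uninformative (the genotype
#' is still imputable but carries no origin information), and focal genotypes
#' that are Mendelian-impossible given the parents void the anchor and are
#' flagged as conflicts.
#'
#' @param focal_gt focal genotype vector over the full panel (9 = missing).
#' @param parentA,parentB phased [haplotype_pair()]s of the two parents.
#' @param panel a [marker_panel()].
#' @return data.frame of class `anchor_set` with one row per anchor: `marker`,
#'   `pos`, `index` (panel column), `dose_A` (haplotype copies from parent A),
#'   `origin1`, `origin2`, `allele1`, `allele2`. Conflicting markers are
#'   returned in attribute `conflicts`.
#' @export
assign_origin <- function(focal_gt, parentA, parentB, panel) {
  ga <- hap_genotype(parentA)
  gb <- hap_genotype(parentB)
  ld <- which(panel$ld)
  y <- focal_gt[ld]
  a <- hom_allele(ga[ld])  # parent A allele where homozygous
  b <- hom_allele(gb[ld])
  usable <- y != MISSING & !is.na(a) & !is.na(b)
  opposing <- usable & a != b
  same <- usable & a == b
  conflict <- same & y != 2L * a
  dose <- abs(y - 2L * b)  # valid on `opposing`
  keep <- which(opposing)
  d <- dose[keep]
  out <- data.frame(
    marker = panel$marker[ld][keep],
    pos = panel$pos[ld][keep],
    index = ld[keep],
    dose_A = d,
    origin1 = ifelse(d >= 1L, "A", "B"),
    origin2 = ifelse(d == 2L, "A", "B"),
    allele1 = ifelse(d >= 1L, a[keep], b[keep]),
    allele2 = ifelse(d == 2L, a[keep], b[keep]),
    stringsAsFactors = FALSE)
  attr(out, "conflicts") <- panel$marker[ld][which(conflict)]
  class(out) <- c("anchor_set", "data.frame")
  out
}

#' Phase a focal individual's Ld heterozygotes from its anchors
#'
#' Extends parent-of-origin from the anchors to every observed Ld marker by
#' the nearest-anchor rule: between two anchors with the same orientation the
#' orientation is carried across; between discordant anchors (a crossover
#' interval) the switch is placed at the cM midpoint; markers outside all
#' anchors inherit the nearest anchor's orientation. Heterozygous markers with
#' a resolved one-from-each origin are phased so that haplotype 1 is the
#' parent-A copy.
#'
#' @param focal_gt focal genotype vector over the full panel.
#' @param anchors an [assign_origin()] result.
#' @param panel a [marker_panel()].
#' @return a [haplotype_pair()] over the Ld markers (attribute `ld_index`
#'   gives their panel columns), origins labelled "A"/"B", alleles 9 where
#'   the parental allele split cannot be resolved locally.
#' @export
phase_focal_heterozygotes <- function(focal_gt, anchors, panel) {
  ld <- which(panel$ld)
  pos <- panel$pos[ld]
  y <- focal_gt[ld]
  n <- length(ld)
  dose <- interp_nearest(pos, anchors$pos, anchors$dose_A)
  hap1 <- rep(MISSING, n); hap2 <- rep(MISSING, n)
  org1 <- rep(NA_character_, n); org2 <- rep(NA_character_, n)
  known <- !is.na(dose) & y != MISSING
  org1[known & dose >= 1L] <- "A"; org1[known & dose == 0L] <- "B"
  org2[known & dose == 2L] <- "A"; org2[known & dose <= 1L] <- "B"
  hom <- known & y %in% c(0L, 2L)
  hap1[hom] <- y[hom] %/% 2L
  hap2[hom] <- y[hom] %/% 2L
  # anchor markers carry their resolved alleles (and exact dose)
  at <- match(anchors$index, ld)
  hap1[at] <- anchors$allele1; hap2[at] <- anchors$allele2
  org1[at] <- anchors$origin1; org2[at] <- anchors$origin2
  hp <- haplotype_pair(hap1, hap2, org1, org2)
  attr(hp, "ld_index") <- ld
  attr(hp, "dose_A") <- dose
  hp
}

#' Impute a focal individual to Hd from phased parents
#'
#' Runs the full heuristic: anchor doses are read wherever the parents'
#' status allows it (both parents homozygous, or a heterozygous parent A with
#' the focal carrying a non-mate allele), the parent-A dose is extended by
#' the nearest-anchor/midpoint rule, and each Hd marker inherits the alleles
#' of the assigned parental haplotypes. For an outbred parent A the
#' within-parent haplotype is chosen by matching the focal's implied gamete
#' alleles to A's haplotypes, again extended by the nearest-anchor rule.
#' Spans with unknown origin stay missing; observed genotypes are never
#' overwritten.
#'
#' @param focal_gt focal genotype vector over the full panel (9 = missing at
#'   non-Ld markers).
#' @param parentA,parentB phased [haplotype_pair()]s, or [impute_parent()]
#'   results (parent B is the mate and is used only where homozygous).
#' @param panel a [marker_panel()].
#' @return list of class `focal_imputation`: `genotype` (imputed vector over
#'   the panel), `haplotypes` ([haplotype_pair()]), `dose` (parent-A dose),
#'   `n_anchors`.
#' @export
impute_focal_to_hd <- function(focal_gt, parentA, parentB, panel) {
  pa <- parent_info(parentA)
  pb <- parent_info(parentB)
  res <- phase_child(focal_gt, pa$status, pa$haps, pb$status, panel$pos)
  structure(list(genotype = res$genotype, haplotypes = res$haplotypes,
                 dose = res$dose, n_anchors = res$n_anchors),
            class = "focal_imputation")
}

#' Impute all Ld-genotyped offspring of phased parents
#'
#' For every requested focal individual the cross parents are located in the
#' pedigree (climbing through selfing generations until both parents of an
#' ancestor are available phased) and [impute_focal_to_hd()] is applied.
#'
#' @param geno a [genotype_matrix()] (focal rows Ld-masked).
#' @param ped a [pedigree()].
#' @param panel a [marker_panel()].
#' @param parents named list of phased [haplotype_pair()]s (the cross
#'   parents).
#' @param targets ids to impute; default: all genotyped individuals whose
#'   cross parents can be located and that have a missing Hd genotype.
#' @return list of class `offspring_imputation`: `genotype` (imputed matrix),
#'   `haplotypes`, `skipped`.
#' @export
impute_offspring <- function(geno, ped, panel, parents, targets = NULL) {
  if (is.null(targets)) {
    targets <- rownames(geno)[rowSums(unclass(geno) == MISSING) > 0L]
    targets <- setdiff(targets, names(parents))
  }
  imputed <- unclass(geno)[, , drop = FALSE]
  haps <- list()
  skipped <- character(0)
  for (id in targets) {
    cp <- find_cross_parents(ped, id, names(parents))
    if (is.null(cp)) { skipped <- c(skipped, id); next }
    res <- impute_focal_to_hd(geno[id, ], parents[[cp[1]]], parents[[cp[2]]],
                              panel)
    imputed[id, ] <- res$genotype
    haps[[id]] <- res$haplotypes
  }
  structure(list(genotype = genotype_matrix(imputed), haplotypes = haps,
                 skipped = skipped),
            class = "offspring_imputation")
}

# Genotype status track + haplotypes from either a phased haplotype pair or
# a parent_imputation fit (whose genotype track may be known where the
# haplotypes are not, e.g. unphased heterozygote calls).
parent_info <- function(x) {
  if (inherits(x, "parent_imputation"))
    list(status = unname(x$genotype), haps = x$haplotypes)
  else if (inherits(x, "haplotype_pair"))
    list(status = hap_genotype(x), haps = x)
  else stop("parent must be a haplotype_pair or a parent_imputation")
}

# Climb through selfing generations from `id` until an ancestor whose two
# parents are both in `available` is found; returns c(parent1, parent2) with
# the first element usable as "parent A", or NULL.
find_cross_parents <- function(ped, id, available, max_depth = 10L) {
  row <- match(id, ped$id)
  for (k in seq_len(max_depth)) {
    if (is.na(row)) return(NULL)
    p1 <- ped$parent1[row]; p2 <- ped$parent2[row]
    if (is.na(p1) || is.na(p2)) return(NULL)
    if (p1 %in% available && p2 %in% available) return(c(p1, p2))
    if (p1 == p2) { row <- match(p1, ped$id); next }  # selfing: climb
    return(NULL)
  }
  NULL
}

#' @export
print.offspring_imputation <- function(x, ...) {
  cat(sprintf("offspring imputation: %d individuals imputed, %d skipped\n",
              length(x$haplotypes), length(x$skipped)))
  invisible(x)
}
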