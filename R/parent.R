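#' Find imputation targets and their Hd relatives
#'
#' Walks the pedigree in topological order and identifies parents of
#' non-selfing crosses with missing Hd genotypes, together with the
#' high-density genotype information available on their relatives: Hd
#' ancestors (the target's own parents), Hd mates and Hd descendants grouped
#' by cross, and Hd siblings (listed, but used only through shared
#' ancestors).
#'
#' @param ped a [pedigree()].
#' @param geno a [genotype_matrix()] (rows may be Ld-masked).
#' @param panel a [marker_panel()].
#' @param hd_fraction minimum fraction of non-missing Hd markers for a row to
#'   count as Hd-genotyped.
#' @return named list (one element per target) of relative sets: `target`,
#'   `ancestors_hd`, `mates_hd`, `siblings_hd`, `crosses` (per mate: `mate`,
#'   `mate_hd`, `descendants_hd`) and `usable` (whether any imputation path
#'   exists).
#' @export
find_targets_and_relatives <- function(ped, geno, panel, hd_fraction = 0.5) {
  ids <- rownames(geno)
  hd_ok <- rowMeans(unclass(geno) != MISSING) >= hd_fraction
  is_hd <- function(x) x %in% ids[hd_ok]
  children <- split(ped$id, factor(ped$parent1, levels = ped$id))
  children2 <- split(ped$id, factor(ped$parent2, levels = ped$id))

  cross_parents <- unique(c(ped$parent1[!is.na(ped$parent1) & !is.na(ped$parent2) &
                                          ped$parent1 != ped$parent2],
                            ped$parent2[!is.na(ped$parent1) & !is.na(ped$parent2) &
                                          ped$parent1 != ped$parent2]))
  cross_parents <- ped$id[ped$id %in% cross_parents]  # topological order
  out <- list()
  for (t in cross_parents) {
    has_missing <- !(t %in% ids) || any(geno[t, ] == MISSING)
    if (!has_missing) next
    trow <- match(t, ped$id)
    anc <- stats::na.omit(c(ped$parent1[trow], ped$parent2[trow]))
    ancestors_hd <- if (length(anc) == 2L && all(is_hd(anc))) as.character(anc)
                    else character(0)
    sibs <- character(0)
    if (length(anc) == 2L) {
      sibs <- setdiff(ped$id[(!is.na(ped$parent1) & ped$parent1 %in% anc) |
                             (!is.na(ped$parent2) & ped$parent2 %in% anc)], t)
      sibs <- sibs[is_hd(sibs)]
    }
    kids <- unique(c(children[[t]], children2[[t]]))
    crosses <- list()
    for (k in kids) {
      krow <- match(k, ped$id)
      p <- c(ped$parent1[krow], ped$parent2[krow])
      mate <- setdiff(p, t)
      if (length(mate) != 1L) next  # selfing of the target itself
      desc <- collect_descendants(ped, k)
      desc_hd <- desc[is_hd(desc)]
      if (is.null(crosses[[mate]]))
        crosses[[mate]] <- list(mate = mate, mate_hd = is_hd(mate),
                                descendants_hd = character(0))
      crosses[[mate]]$descendants_hd <-
        unique(c(crosses[[mate]]$descendants_hd, desc_hd))
    }
    usable_crosses <- Filter(function(cr) cr$mate_hd &&
                               length(cr$descendants_hd) > 0L, crosses)
    usable <- length(ancestors_hd) == 2L || length(usable_crosses) > 0L
    out[[t]] <- list(target = t,
                     ancestors_hd = ancestors_hd,
                     mates_hd = names(Filter(function(cr) cr$mate_hd, crosses)),
                     siblings_hd = sibs,
                     crosses = crosses,
                     usable = usable)
  }
  out
}

# All descendants of `id` (including itself) by breadth-first walk.
collect_descendants <- function(ped, id) {
  out <- character(0)
  frontier <- id
  while (length(frontier)) {
    out <- c(out, frontier)
    frontier <- ped$id[(!is.na(ped$parent1) & ped$parent1 %in% frontier) |
                       (!is.na(ped$parent2) & ped$parent2 %in% frontier)]
    frontier <- setdiff(frontier, out)
  }
  out
}

#' Impute a parent from its two Hd ancestors only
#'
#' In selfing populations an ungenotyped offspring of a cross may be fixed
#' for either ancestral allele, so the only markers that can be confidently
#' imputed are those where both ancestors are homozygous for the same allele;
#' those markers are phased de facto.
#'
#' @param gp1_gt,gp2_gt ancestor genotype vectors over the panel.
#' @return list with `genotype` (0/2 where called, 9 elsewhere),
#'   `haplotypes` and `provenance` ("ancestor" where called).
#' @export
impute_from_ancestors <- function(gp1_gt, gp2_gt) {
  n <- length(gp1_gt)
  gt <- rep(MISSING, n)
  both0 <- gp1_gt == 0L & gp2_gt == 0L
  both2 <- gp1_gt == 2L & gp2_gt == 2L
  gt[both0] <- 0L
  gt[both2] <- 2L
  a <- rep(MISSING, n)
  a[both0] <- 0L; a[both2] <- 1L
  prov <- rep(NA_character_, n)
  prov[gt != MISSING] <- "ancestor"
  list(genotype = gt, haplotypes = haplotype_pair(a, a), provenance = prov)
}

#' Chi-square genotype call for a missing parent at one marker
#'
#' Tests observed descendant genotype counts against the counts expected from
#' the observed allele frequency (Hardy-Weinberg proportions, 1 df since the
#' frequency is estimated). Significant segregation distortion with a
#' homozygous mate means the missing parent is heterozygous; no significant
#' distortion with a homozygous mate imputes the parent to the homozygote
#' opposing the mate. A heterozygous mate, a monomorphic count vector or too
#' few descendants give no call.
#'
#' @param counts observed genotype counts `c(n0, n1, n2)` pooled over the Hd
#'   descendants of one cross.
#' @param mate_gt the mate's genotype code at the marker.
#' @param alpha significance level (default 0.05).
#' @param min_n minimum descendant count for a call.
#' @return list with `call` ("het", "hom0", "hom2" or "unknown"),
#'   `statistic` and `p_value`.
#' @export
chi2_call <- function(counts, mate_gt, alpha = 0.05, min_n = 4L) {
  n <- sum(counts)
  unknown <- list(call = "unknown", statistic = NA_real_, p_value = NA_real_)
  if (n < min_n || !(mate_gt %in% c(0L, 2L))) return(unknown)
  if (counts[2] == 0L && (counts[1] == 0L || counts[3] == 0L)) return(unknown)
  p <- (counts[2] + 2 * counts[3]) / (2 * n)
  expected <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
  x2 <- sum((counts - expected)^2 / expected)
  pval <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  call <- if (pval < alpha) "het" else if (mate_gt == 0L) "hom2" else "hom0"
  list(call = call, statistic = x2, p_value = pval)
}

#' Infer homozygous markers of a missing parent from descendant fixation
#'
#' At markers where the Hd descendants of every cross are fixed for the same
#' allele and every mate's genotype is compatible with that fixation, the
#' missing parent is called homozygous for that allele (monomorphic
#' descendants rule). A minimum total descendant count guards against chance
#' fixation when the parent is in fact heterozygous.
#'
#' @param desc_by_cross list (one element per cross) of descendant genotype
#'   matrices over the panel.
#' @param mate_gt_by_cross list of mate genotype vectors, matching crosses.
#' @param min_total minimum total Hd descendants for a call.
#' @return integer genotype track: 0/2 where called, 9 elsewhere.
#' @export
infer_homozygous_from_descendants <- function(desc_by_cross, mate_gt_by_cross,
                                              min_total = 4L) {
  stopifnot(length(desc_by_cross) == length(mate_gt_by_cross))
  n_mrk <- ncol(desc_by_cross[[1]])
  all0 <- rep(TRUE, n_mrk); all2 <- rep(TRUE, n_mrk)
  compat0 <- rep(TRUE, n_mrk); compat2 <- rep(TRUE, n_mrk)
  total <- 0L
  for (j in seq_along(desc_by_cross)) {
    d <- unclass(desc_by_cross[[j]])
    obs <- d != MISSING
    total <- total + nrow(d)
    all0 <- all0 & colSums(d == 0L) == colSums(obs) & colSums(obs) > 0L
    all2 <- all2 & colSums(d == 2L) == colSums(obs) & colSums(obs) > 0L
    m <- mate_gt_by_cross[[j]]
    compat0 <- compat0 & m != 2L  # a mate fixed for the other allele
    compat2 <- compat2 & m != 0L  # contradicts descendant fixation
  }
  gt <- rep(MISSING, n_mrk)
  if (total >= min_total) {
    gt[all0 & compat0] <- 0L
    gt[all2 & compat2] <- 2L
  }
  gt
}

# Per-cross call track over all markers: at segregating markers a vectorised
# chi-square call (1 = het, 0/2 = opposing homozygote, 9 = none); at markers
# where this cross's descendants are fixed for an allele the mate could have
# co-transmitted, a homozygote call for that allele (the per-cross view of
# the monomorphic-descendants rule, so that one cross's fixation can veto
# another cross's false distortion call when the tracks are combined).
cross_call_track <- function(desc, mate_gt, alpha = 0.05, min_n = 4L) {
  d <- unclass(desc)
  obs <- d != MISSING
  n <- colSums(obs)
  n0 <- colSums(d == 0L); n1 <- colSums(d == 1L); n2 <- colSums(d == 2L)
  segregating <- n > 0L & !(n1 == 0L & (n0 == 0L | n2 == 0L))
  p <- (n1 + 2 * n2) / pmax(2 * n, 1L)
  e0 <- n * (1 - p)^2; e1 <- 2 * n * p * (1 - p); e2 <- n * p^2
  x2 <- (n0 - e0)^2 / pmax(e0, .Machine$double.eps) +
        (n1 - e1)^2 / pmax(e1, .Machine$double.eps) +
        (n2 - e2)^2 / pmax(e2, .Machine$double.eps)
  pval <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  call <- rep(MISSING, length(n))
  ok <- segregating & n >= min_n & mate_gt %in% c(0L, 2L)
  sig <- ok & pval < alpha
  call[sig] <- 1L
  call[ok & !sig] <- 2L - mate_gt[ok & !sig]
  mono0 <- !segregating & n >= min_n & n0 == n & mate_gt != 2L
  mono2 <- !segregating & n >= min_n & n2 == n & mate_gt != 0L
  call[mono0] <- 0L
  call[mono2] <- 2L
  call
}

# Combine per-cross call tracks: unanimity wins, disagreement -> unknown.
combine_calls <- function(tracks) {
  n <- length(tracks[[1]])
  out <- rep(MISSING, n)
  for (tr in tracks) {
    new <- tr != MISSING
    conflict <- new & out != MISSING & out != tr
    take <- new & out == MISSING
    out[take] <- tr[take]
    out[conflict] <- -1L
  }
  out[out == -1L] <- MISSING
  out
}

#' Derive consensus haplotypes of a missing parent from its Hd descendants
#'
#' Each Hd descendant is phased against the anchor-worthy knowledge about the
#' parent (its observed Ld genotypes, and the alleles its cross's mate cannot
#' have transmitted); the implied parent-gamete alleles are collected at
#' every marker. Heterozygous anchor markers confirmed by the votes are
#' phased into two haplotypes by linkage between neighbouring loci; each
#' gamete then receives a per-marker haplotype label (anchored where its
#' votes match a phased heterozygote, extended by the nearest-anchor/midpoint
#' rule, since gametes are themselves recombinant), and a per-locus strict
#' majority within each label yields the two consensus haplotypes. Ties or
#' empty labels leave an allele missing; without any confirmed heterozygous
#' anchor the consensus collapses to a single haplotype (the inbred limit)
#' and the second haplotype stays missing at the heterozygous anchor markers.
#'
#' @param desc_by_cross list of descendant genotype matrices, one per cross.
#' @param mate_gt_by_cross list of mate genotype vectors.
#' @param status_by_cross list of trusted parent status tracks (observed
#'   genotypes; 9 = unknown), one per cross.
#' @param het_loci indices of the markers where the parent is observed
#'   heterozygous (used only to keep the second haplotype missing there when
#'   the consensus collapses to a single group).
#' @param pos marker positions in cM.
#' @return list with `hap1`, `hap2` (9 = missing), `single` (logical: one
#'   haplotype group), `votes` (gamete-allele matrix) and `labels`
#'   (per-gamete haplotype label tracks, `NULL` in the single-group case).
#' @export
consensus_haplotypes_from_descendants <- function(desc_by_cross,
                                                  mate_gt_by_cross,
                                                  status_by_cross,
                                                  het_loci, pos) {
  votes <- list()
  for (j in seq_along(desc_by_cross)) {
    d <- unclass(desc_by_cross[[j]])
    qa_gt <- mate_gt_by_cross[[j]]
    status <- status_by_cross[[j]]
    qa <- hom_allele(qa_gt)
    for (i in seq_len(nrow(d))) {
      y <- d[i, ]
      da <- dose_anchors(y, status, qa)
      da <- run_dose0_anchors(y, qa, da)
      a_idx <- which(!is.na(da))
      dose <- interp_nearest(pos, pos[a_idx], da[a_idx])
      dose[a_idx] <- da[a_idx]
      votes[[length(votes) + 1L]] <- implied_gamete(y, dose, qa)
    }
  }
  votes <- do.call(rbind, votes)
  n_mrk <- ncol(votes)
  conf <- confirmed_het(votes)

  if (length(conf) == 0L) {
    n1 <- colSums(votes == 1L, na.rm = TRUE)
    n0 <- colSums(votes == 0L, na.rm = TRUE)
    h1 <- rep(MISSING, n_mrk)
    h1[n1 > n0] <- 1L
    h1[n0 > n1] <- 0L
    h2 <- h1
    if (length(het_loci))
      h2[het_loci] <- MISSING  # one group cannot phase a heterozygote
    return(list(hap1 = h1, hap2 = h2, single = TRUE, votes = votes,
                labels = NULL))
  }

  hc1 <- chain_phase(votes, conf)
  nd <- nrow(votes)
  # label anchors per gamete: at phased heterozygous markers the vote picks
  # the haplotype directly; where only haplotype 1 is defined, a vote that
  # contradicts it marks the gamete as carrying the (locally unseen) second
  # haplotype -- this recovers regions where one haplotype reached a single
  # Hd descendant
  relabel <- function(a1, a2) {
    labels <- matrix(NA_integer_, nd, n_mrk)
    het <- a1 != MISSING & a2 != MISSING & a1 != a2
    only1 <- a1 != MISSING & (a2 == MISSING | a2 == a1)
    for (i in seq_len(nd)) {
      v <- votes[i, ]
      lab <- rep(NA_integer_, n_mrk)
      lab[het & !is.na(v) & v == a1] <- 1L
      lab[het & !is.na(v) & v == a2] <- 2L
      lab[only1 & !is.na(v) & v != a1] <- 2L
      a_idx <- which(!is.na(lab))
      if (length(a_idx))
        labels[i, ] <- interp_nearest(pos, pos[a_idx], lab[a_idx])
    }
    labels
  }
  h1 <- rep(MISSING, n_mrk); h2 <- rep(MISSING, n_mrk)
  h1[conf] <- hc1
  h2[conf] <- 1L - hc1
  labels <- NULL
  for (it in 1:3) {
    labels <- relabel(h1, h2)
    h1 <- label_majority(votes, labels, 1L)
    h2 <- label_majority(votes, labels, 2L)
  }
  # local repair: where one haplotype is resolved and the votes contain its
  # counter-allele but the other label group tied out (label orientation can
  # swap locally where a haplotype reaches a single descendant), the other
  # haplotype takes the counter-allele
  n1 <- colSums(votes == 1L, na.rm = TRUE)
  n0 <- colSums(votes == 0L, na.rm = TRUE)
  # dissent threshold scales with vote depth: with many gametes a single
  # stray vote (dose interpolated across an unseen crossover) is no longer
  # convincing evidence of a second allele
  thr <- pmax(1L, ceiling(0.05 * (n0 + n1)))
  counter <- function(h) ifelse(h == 1L, n0, n1)
  fix1 <- h1 == MISSING & h2 != MISSING & counter(h2) >= thr
  h1[fix1] <- 1L - h2[fix1]
  fix2 <- h2 == MISSING & h1 != MISSING & counter(h1) >= thr
  h2[fix2] <- 1L - h1[fix2]
  # attributed material showing both alleles is direct evidence of
  # heterozygosity even when the label groups collapse onto one allele
  fix3 <- h1 != MISSING & h1 == h2 & counter(h1) >= thr
  h2[fix3] <- 1L - h1[fix3]
  list(hap1 = h1, hap2 = h2, single = FALSE, votes = votes, labels = labels)
}

# Descendant-information path shared by the ungenotyped and Ld cases.
# a_obs: the target's observed genotype row (all 9 when ungenotyped).
impute_parent_from_descendants <- function(a_obs, crosses, geno, panel,
                                           alpha = 0.05) {
  pos <- panel$pos
  n_mrk <- length(pos)
  desc_by_cross <- lapply(crosses, function(cr)
    unclass(geno)[cr$descendants_hd, , drop = FALSE])
  mate_by_cross <- lapply(crosses, function(cr) unclass(geno)[cr$mate, ])
  has_obs <- any(a_obs != MISSING)

  # anchor-worthy knowledge about the parent is its observed genotypes only
  status_by_cross <- rep(list(a_obs), length(crosses))
  hom_track <- infer_homozygous_from_descendants(desc_by_cross, mate_by_cross)
  chi_tracks <- lapply(seq_along(crosses), function(j)
    cross_call_track(desc_by_cross[[j]], mate_by_cross[[j]], alpha = alpha))
  call <- combine_calls(chi_tracks)
  # the monomorphic-descendants rule pre-empts the chi-square calls
  call[hom_track != MISSING] <- hom_track[hom_track != MISSING]
  prov_call <- rep(NA_character_, n_mrk)
  prov_call[call != MISSING] <- "chi2"
  prov_call[hom_track != MISSING] <- "freq"
  het_loci <- which(a_obs == 1L)

  cons <- consensus_haplotypes_from_descendants(desc_by_cross, mate_by_cross,
                                                status_by_cross, het_loci, pos)
  cons_gt <- rep(MISSING, n_mrk)
  both <- cons$hap1 != MISSING & cons$hap2 != MISSING
  cons_gt[both] <- cons$hap1[both] + cons$hap2[both]

  gt <- rep(MISSING, n_mrk)
  prov <- rep(NA_character_, n_mrk)
  gt[cons_gt != MISSING] <- cons_gt[cons_gt != MISSING]
  prov[cons_gt != MISSING] <- "consensus"
  if (!has_obs) {
    # with a fully ungenotyped parent a significant-distortion call is the
    # primary evidence of heterozygosity and keeps the genotype even where
    # the consensus says otherwise; with Ld anchors available the haplotype
    # attribution is primary and the calls only fill gaps below
    het_call <- call == 1L
    gt[het_call] <- 1L
    prov[het_call] <- "chi2"
  }
  fill <- gt == MISSING & call != MISSING
  if (has_obs)
    # with Ld anchors the haplotype attribution is strictly more informative
    # than a distortion-only heterozygote call, which is then most likely a
    # transmission-sampling artefact; only homozygote calls fill gaps
    fill <- fill & call != 1L
  gt[fill] <- call[fill]
  prov[fill] <- prov_call[fill]
  obs <- a_obs != MISSING
  gt[obs] <- a_obs[obs]
  prov[obs] <- "ld_obs"

  hap1 <- rep(MISSING, n_mrk); hap2 <- rep(MISSING, n_mrk)
  hom <- gt %in% c(0L, 2L)
  hap1[hom] <- gt[hom] %/% 2L; hap2[hom] <- gt[hom] %/% 2L
  phased_het <- gt == 1L & both & cons$hap1 != cons$hap2
  hap1[phased_het] <- cons$hap1[phased_het]
  hap2[phased_het] <- cons$hap2[phased_het]

  list(genotype = gt, haplotypes = haplotype_pair(hap1, hap2),
       provenance = prov, call = call, consensus = cons)
}

#' Phase and impute a parent that has Ld genotypes
#'
#' The observed Ld genotypes serve as anchor points. With Hd ancestors the
#' parent is phased as a focal child of its own parents; with Hd descendants
#' and mates the Ld genotypes anchor the parent-of-origin of every Hd
#' descendant, consensus haplotypes are derived and the genotype is filled as
#' the sum of the two haplotypes. Observed genotypes are never overwritten.
#'
#' @inheritParams impute_parent
#' @param relatives one element of [find_targets_and_relatives()].
#' @return list with `genotype`, `haplotypes`, `provenance`.
#' @export
impute_parent_with_ld <- function(geno, ped, panel, relatives, alpha = 0.05) {
  impute_parent_paths(geno, ped, panel, relatives, alpha)
}

# Runs the ancestor path and/or the descendant path and merges them.
impute_parent_paths <- function(geno, ped, panel, relatives, alpha = 0.05) {
  t <- relatives$target
  n_mrk <- length(panel$marker)
  a_obs <- if (t %in% rownames(geno)) unclass(geno)[t, ] else rep(MISSING, n_mrk)

  usable_crosses <- Filter(function(cr) cr$mate_hd &&
                             length(cr$descendants_hd) > 0L, relatives$crosses)
  des <- anc <- NULL
  if (length(usable_crosses))
    des <- impute_parent_from_descendants(a_obs, usable_crosses, geno, panel,
                                          alpha = alpha)
  if (length(relatives$ancestors_hd) == 2L) {
    gp1 <- unclass(geno)[relatives$ancestors_hd[1], ]
    gp2 <- unclass(geno)[relatives$ancestors_hd[2], ]
    if (any(a_obs != MISSING)) {
      res <- phase_child(a_obs, gp1, haps_from_genotype(gp1), gp2, panel$pos)
      prov <- rep(NA_character_, n_mrk)
      prov[res$genotype != MISSING] <- "ancestor"
      anc <- list(genotype = res$genotype, haplotypes = res$haplotypes,
                  provenance = prov)
    } else {
      anc <- impute_from_ancestors(gp1, gp2)
    }
  }
  out <- if (!is.null(anc) && !is.null(des))
           merge_ancestor_descendant(anc, des, pos = panel$pos)
         else if (!is.null(des)) des
         else if (!is.null(anc)) anc
         else stop("no Hd relatives usable for target ", t)
  # observed genotypes are invariant under imputation
  obs <- a_obs != MISSING
  out$genotype[obs] <- a_obs[obs]
  out$provenance[obs] <- "ld_obs"
  hom_obs <- obs & a_obs %in% c(0L, 2L)
  out$haplotypes$hap1[hom_obs] <- a_obs[hom_obs] %/% 2L
  out$haplotypes$hap2[hom_obs] <- a_obs[hom_obs] %/% 2L
  out
}

#' Merge ancestor-derived and descendant-derived calls for the same parent
#'
#' The two information sources are used independently; this derives their
#' consensus. The phase labelings of the two tracks are first aligned where
#' both are phased heterozygous, with the orientation extended by the
#' nearest-anchor rule (the labels of either track may legitimately switch
#' along the chromosome). Per haplotype and marker: agreement keeps the
#' allele, a one-sided missing value keeps the non-missing allele, and a
#' disagreement (even on one haplotype) sets the haplotype and the genotype
#' to missing.
#'
#' @param anc,des lists with `genotype`, `haplotypes`, `provenance` from the
#'   ancestor-only and descendant-only paths.
#' @param pos marker positions in cM (defaults to marker index).
#' @return list with merged `genotype`, `haplotypes`, `provenance`.
#' @export
merge_ancestor_descendant <- function(anc, des, pos = NULL) {
  n <- length(anc$genotype)
  if (is.null(pos)) pos <- seq_len(n)
  a1 <- anc$haplotypes$hap1; a2 <- anc$haplotypes$hap2
  d1 <- des$haplotypes$hap1; d2 <- des$haplotypes$hap2
  info <- a1 != MISSING & a2 != MISSING & d1 != MISSING & d2 != MISSING &
    a1 != a2 & d1 != d2
  o <- rep(NA_integer_, n)
  o[info & a1 == d1] <- 1L
  o[info & a1 == d2] <- 2L
  idx <- which(!is.na(o))
  ori <- interp_nearest(pos, pos[idx], o[idx])
  swap <- !is.na(ori) & ori == 2L
  t1 <- ifelse(swap, d2, d1)
  t2 <- ifelse(swap, d1, d2)
  d1 <- t1; d2 <- t2
  merge_hap <- function(x, y) {
    out <- x
    out[x == MISSING] <- y[x == MISSING]
    out[x != MISSING & y != MISSING & x != y] <- -1L
    out
  }
  h1 <- merge_hap(a1, d1)
  h2 <- merge_hap(a2, d2)
  hap_conflict <- h1 == -1L | h2 == -1L
  h1[h1 == -1L] <- MISSING; h2[h2 == -1L] <- MISSING

  ga <- anc$genotype; gd <- des$genotype
  gt <- ga
  gt[ga == MISSING] <- gd[ga == MISSING]
  gt_conflict <- ga != MISSING & gd != MISSING & ga != gd
  gt[gt_conflict | hap_conflict] <- MISSING
  h1[gt == MISSING] <- MISSING
  h2[gt == MISSING] <- MISSING

  prov <- ifelse(!is.na(des$provenance), des$provenance, anc$provenance)
  prov[gt == MISSING] <- NA_character_
  list(genotype = gt, haplotypes = haplotype_pair(h1, h2), provenance = prov)
}

# Haplotypes readable off a genotype row: homozygotes split de facto,
# heterozygotes stay unphased.
haps_from_genotype <- function(gt) {
  a <- hom_allele(gt)
  h <- ifelse(is.na(a), MISSING, a)
  haplotype_pair(h, h)
}

#' Phase and impute a missing or Ld-genotyped parent from its Hd relatives
#'
#' The main entry point of the package. Identifies the target parent, gathers
#' its Hd relatives, runs the ancestor path (markers where both ancestors are
#' homozygous for the same allele, or anchored phasing when the target has Ld
#' genotypes) and the descendant path (descendant allele frequencies, the
#' segregation-distortion chi-square test and consensus haplotypes), and
#' merges the two with disagreements set to missing.
#'
#' @param geno a [genotype_matrix()].
#' @param ped a [pedigree()].
#' @param panel a [marker_panel()].
#' @param target id of the parent to impute; default: the single usable
#'   target found by [find_targets_and_relatives()].
#' @param alpha significance level of the chi-square test.
#' @return object of class `parent_imputation` with elements `target`,
#'   `genotype` (named vector over the panel), `haplotypes`, `provenance`,
#'   `relatives`, `alpha`.
#' @examples
#' spec <- scenario_spec(n_f2_per_cross = 40, n_hd_snps = 300, n_ld_snps = 20,
#'                       n_base_sites = 3000, seed = 1)
#' pop <- simulate_population(spec)
#' fit <- impute_parent(pop$geno, pop$pedigree, pop$panel)
#' summary(fit)
#' imputation_accuracy(pop$geno_true["A", ], fit$genotype)
#' @export
impute_parent <- function(geno, ped, panel, target = NULL, alpha = 0.05) {
  targets <- find_targets_and_relatives(ped, geno, panel)
  usable <- names(Filter(function(x) x$usable, targets))
  if (is.null(target)) {
    if (length(usable) != 1L)
      stop("found ", length(usable), " usable targets (",
           paste(usable, collapse = ", "), "); pass `target`")
    target <- usable
  }
  if (!target %in% names(targets))
    stop("'", target, "' is not a parent with missing Hd genotypes")
  rel <- targets[[target]]
  if (!rel$usable) stop("target '", target, "' has no usable Hd relatives")
  res <- impute_parent_paths(geno, ped, panel, rel, alpha = alpha)
  structure(list(target = target,
                 genotype = stats::setNames(res$genotype, panel$marker),
                 haplotypes = res$haplotypes,
                 provenance = res$provenance,
                 relatives = rel,
                 alpha = alpha,
                 panel = panel),
            class = "parent_imputation")
}

#' @export
print.parent_imputation <- function(x, ...) {
  n <- length(x$genotype)
  cat(sprintf("parent imputation for '%s': %d markers, yield %.1f%%\n",
              x$target, n, 100 * mean(x$genotype != MISSING)))
  invisible(x)
}

#' @export
summary.parent_imputation <- function(object, ...) {
  gt <- object$genotype
  tab <- table(factor(object$provenance,
                      levels = c("ld_obs", "ancestor", "freq", "chi2",
                                 "consensus")),
               useNA = "ifany")
  out <- list(target = object$target,
              n_markers = length(gt),
              yield = mean(gt != MISSING),
              n_het = sum(gt == 1L),
              provenance = tab,
              n_crosses = length(object$relatives$crosses),
              n_hd_descendants = sum(vapply(object$relatives$crosses,
                                            function(cr) length(cr$descendants_hd),
                                            integer(1))))
  class(out) <- "summary.parent_imputation"
  out
}

#' @export
print.summary.parent_imputation <- function(x, ...) {
  cat(sprintf("parent imputation for '%s'\n", x$target))
  cat(sprintf("  %d markers, yield %.2f%%, %d called heterozygous\n",
              x$n_markers, 100 * x$yield, x$n_het))
  cat(sprintf("  information: %d cross(es), %d Hd descendants\n",
              x$n_crosses, x$n_hd_descendants))
  cat("  call provenance:\n")
  print(x$provenance)
  invisible(x)
}
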