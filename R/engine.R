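# Shared anchor/parent-of-origin machinery.
#
# Every phasing task in the package reduces to the same primitive: along a
# chromosome, a child's two haplotypes form a mosaic of material transmitted
# by two parents.  At "anchor" markers the number of haplotype copies the
# child carries from parent P (its P-dose, 0/1/2) can be read directly off
# the genotypes; between anchors the dose is extended from the nearest anchor,
# with a crossover placed at the cM midpoint between discordant anchors.
# Given the dose and the (homozygous) mate allele, the allele of the P gamete
# the child carries is implied at every marker.

# Nearest-anchor step interpolation; switch at the midpoint between
# discordant anchors, ties going to the left anchor. NA when no anchors.
interp_nearest <- function(pos, anchor_pos, anchor_val) {
  n <- length(pos)
  if (length(anchor_pos) == 0L) return(rep(NA_integer_, n))
  K <- length(anchor_pos)
  k <- findInterval(pos, anchor_pos)
  left <- pmax(k, 1L)
  right <- pmin(k + 1L, K)
  dl <- abs(pos - anchor_pos[left])
  dr <- abs(anchor_pos[right] - pos)
  use_left <- (k >= 1L) & (k >= K | dl <= dr)
  as.integer(ifelse(use_left, anchor_val[left], anchor_val[right]))
}

# Mate allele vector from a genotype/call track: 0 or 1 where homozygous,
# NA where heterozygous or missing.
hom_allele <- function(gt) {
  a <- rep(NA_integer_, length(gt))
  a[gt == 0L] <- 0L
  a[gt == 2L] <- 1L
  a
}

# Exact P-dose at anchor-worthy markers of one child.
#
# qa is the mate allele (NA where the mate is not homozygous). Alleles the
# mate does not carry must have come from P, and all P-derived copies in the
# child trace to a single P gamete, so a child genotype y != 2*qa pins the
# P-dose to |y - 2*qa| exactly (dose 2 forces y into {0, 2}, hence y == 1
# means dose 1). A child with y == 2*qa is ambiguous on its own; there the
# dose is 0 only when P is *known* homozygous for the allele opposing the
# mate (status 0/2 = known homozygous, e.g. observed Ld genotypes; inferred
# homozygote calls are deliberately not trusted here, since they are wrong
# exactly where anchoring would mislead).
dose_anchors <- function(y, status, qa) {
  n <- length(y)
  d <- rep(NA_integer_, n)
  ok <- y != MISSING & !is.na(qa)
  nonmate <- ok & y != 2L * qa
  d[nonmate] <- abs(y[nonmate] - 2L * qa[nonmate])
  pa <- status %/% 2L  # parent allele where status is 0/2
  z <- ok & y == 2L * qa & (status == 0L | status == 2L) & pa != qa
  d[z] <- 0L
  d
}

# Allele of the P gamete implied by child genotype, P-dose and mate allele.
# NA where the dose is 0/unknown or the implied value is not a valid allele.
implied_gamete <- function(y, dose, qa) {
  g <- rep(NA_integer_, length(y))
  ok <- !is.na(dose) & dose >= 1L & y != MISSING & !is.na(qa)
  gg <- (y[ok] - (2L - dose[ok]) * qa[ok]) / dose[ok]
  gg[!(gg %in% c(0, 1))] <- NA
  g[ok] <- as.integer(gg)
  g
}

# Phase one child against parent P (possibly heterozygous, haplotypes may be
# partially known) and a mate Q assumed homozygous wherever used.
#
# y        child genotype over the panel (9 = missing; typically Ld-masked)
# p_status anchor-worthy P track (see dose_anchors)
# p_haps   haplotype_pair of P or NULL (alleles 9 where unknown)
# q_gt     mate genotype track
# pos      marker positions (cM)
#
# Returns dose, implied gamete alleles, the chosen P haplotype per marker,
# the imputed genotype and a haplotype pair.
phase_child <- function(y, p_status, p_haps, q_gt, pos) {
  qa <- hom_allele(q_gt)
  d_anchor <- dose_anchors(y, p_status, qa)
  a_idx <- which(!is.na(d_anchor))
  dose <- interp_nearest(pos, pos[a_idx], d_anchor[a_idx])
  dose[a_idx] <- d_anchor[a_idx]  # anchors keep their exact dose
  g <- implied_gamete(y, dose, qa)

  # which of P's haplotypes the transmitted gamete follows, resolved at
  # markers where the implied allele discriminates between them and extended
  # by the same nearest-anchor rule (the gamete is itself a recombinant)
  pa <- rep(NA_integer_, length(y))
  if (!is.null(p_haps)) {
    h1 <- p_haps$hap1; h2 <- p_haps$hap2
    differ <- h1 != h2 & h1 != MISSING & h2 != MISSING
    choice <- rep(NA_integer_, length(y))
    choice[differ & !is.na(g) & g == h1] <- 1L
    choice[differ & !is.na(g) & g == h2] <- 2L
    c_idx <- which(!is.na(choice))
    ch <- interp_nearest(pos, pos[c_idx], choice[c_idx])
    same <- h1 == h2 & h1 != MISSING
    pa[same] <- h1[same]
    use1 <- differ & !is.na(ch) & ch == 1L
    use2 <- differ & !is.na(ch) & ch == 2L
    pa[use1] <- h1[use1]
    pa[use2] <- h2[use2]
  }

  imp <- rep(MISSING, length(y))
  known_d <- !is.na(dose)
  i0 <- known_d & dose == 0L & !is.na(qa)
  imp[i0] <- 2L * qa[i0]
  i1 <- known_d & dose == 1L & !is.na(qa) & !is.na(pa)
  imp[i1] <- pa[i1] + qa[i1]
  i2 <- known_d & dose == 2L & !is.na(pa)
  imp[i2] <- 2L * pa[i2]
  # dose-free fill: both parents contribute the same allele
  nf <- !known_d & !is.na(pa) & !is.na(qa) & pa == qa
  imp[nf] <- 2L * pa[nf]
  # observed genotypes are never overwritten
  obs <- y != MISSING
  imp[obs] <- y[obs]

  hap1 <- rep(MISSING, length(y)); hap2 <- rep(MISSING, length(y))
  org1 <- rep(NA_character_, length(y)); org2 <- rep(NA_character_, length(y))
  d2 <- known_d & dose == 2L & !is.na(pa)
  hap1[d2] <- pa[d2]; hap2[d2] <- pa[d2]; org1[d2] <- "P"; org2[d2] <- "P"
  d1 <- known_d & dose == 1L & !is.na(pa) & !is.na(qa)
  hap1[d1] <- pa[d1]; hap2[d1] <- qa[d1]; org1[d1] <- "P"; org2[d1] <- "Q"
  d0 <- known_d & dose == 0L & !is.na(qa)
  hap1[d0] <- qa[d0]; hap2[d0] <- qa[d0]; org1[d0] <- "Q"; org2[d0] <- "Q"
  # phase must agree with an observed genotype; otherwise keep the genotype
  hsum <- hap1 + hap2
  bad <- obs & hap1 != MISSING & hap2 != MISSING & hsum != y
  hp_hom <- obs & y %in% c(0L, 2L)
  hap1[bad] <- MISSING; hap2[bad] <- MISSING
  org1[bad] <- NA; org2[bad] <- NA
  hap1[hp_hom & hap1 == MISSING] <- y[hp_hom & hap1 == MISSING] %/% 2L
  hap2[hp_hom & hap2 == MISSING] <- y[hp_hom & hap2 == MISSING] %/% 2L
  unk <- imp == MISSING
  hap1[unk] <- MISSING; hap2[unk] <- MISSING

  list(dose = dose, gamete = g, parent_allele = pa,
       genotype = imp,
       haplotypes = haplotype_pair(hap1, hap2, org1, org2),
       n_anchors = length(a_idx))
}

# Dose-0 anchors from long runs of the doubled mate allele.
#
# A child genotype equal to 2*qa over a long stretch of informative markers
# is evidence that the stretch carries no P material at all (P-dose 0): with
# the panel's allele-frequency spectrum a transmitted P gamete that merely
# mimics the mate would have to match it at every marker of the run. Runs of
# at least `min_run` informative markers get dose-0 anchors over their
# interior; `margin` markers at each end are left unanchored because a true
# dose-0 segment's run extends a few markers into the flanking segments.
run_dose0_anchors <- function(y, qa, d_anchor, min_run = 15L, margin = 3L) {
  info <- which(y != MISSING & !is.na(qa))
  if (length(info) < min_run) return(d_anchor)
  is2b <- y[info] == 2L * qa[info]
  r <- rle(is2b)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (k in which(r$values & r$lengths >= min_run)) {
    inner <- info[(starts[k] + margin):(ends[k] - margin)]
    d_anchor[inner][is.na(d_anchor[inner])] <- 0L
  }
  d_anchor
}

# Heterozygous loci confirmed by the transmission data themselves: both
# alleles must be seen among the gamete votes, the minority at least
# `min_minor` times and a minimum fraction of the votes (guards against
# dose-interpolation artefacts fabricating heterozygosity). Loci flagged
# heterozygous by a distortion test alone are NOT suitable phasing anchors:
# the test is significant exactly when transmission was lopsided, so those
# loci tend to show only one allele among the votes.
confirmed_het <- function(votes, min_minor = 2L, min_frac = 0.15) {
  n1 <- colSums(votes == 1L, na.rm = TRUE)
  n0 <- colSums(votes == 0L, na.rm = TRUE)
  lo <- pmin(n0, n1)
  which(lo >= min_minor & lo >= min_frac * (n0 + n1))
}

# Phase the confirmed heterozygous loci into two haplotypes by linkage
# between neighbouring loci: for each consecutive pair the orientation that
# is supported by more gamete vote co-occurrences is chosen. Returns, per
# confirmed locus, the allele assigned to haplotype 1 (haplotype 2 carries
# the other allele). A wrong link merely swaps the haplotype labels beyond
# it, which leaves genotypes (the haplotype sum) unaffected.
chain_phase <- function(votes, conf) {
  k <- length(conf)
  V <- votes[, conf, drop = FALSE]
  n1 <- colSums(V == 1L, na.rm = TRUE)
  n0 <- colSums(V == 0L, na.rm = TRUE)
  major <- as.integer(n1 >= n0)
  h1 <- major
  if (k >= 2L) {
    for (j in 2:k) {
      a <- V[, j - 1L]; b <- V[, j]
      same <- sum(a == h1[j - 1L] & b == major[j], na.rm = TRUE) +
              sum(a == (1L - h1[j - 1L]) & b == (1L - major[j]), na.rm = TRUE)
      cross <- sum(a == h1[j - 1L] & b == (1L - major[j]), na.rm = TRUE) +
               sum(a == (1L - h1[j - 1L]) & b == major[j], na.rm = TRUE)
      h1[j] <- if (same >= cross) major[j] else 1L - major[j]
    }
  }
  h1
}

# Per-locus strict-majority allele over the votes carrying label `g`
# (labels are a descendants x loci matrix in {1, 2, NA}); ties and empty
# columns give 9.
label_majority <- function(votes, labels, g) {
  sel <- !is.na(labels) & labels == g & !is.na(votes)
  n1 <- colSums(sel & votes == 1L)
  n0 <- colSums(sel & votes == 0L)
  out <- rep(MISSING, ncol(votes))
  out[n1 > n0] <- 1L
  out[n0 > n1] <- 0L
  out
}
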