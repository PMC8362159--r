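#' Genotype codes
#'
#' Genotypes are coded 0, 1 and 2, where 0 and 2 are the two homozygotes and 1
#' is the heterozygote. 9 marks a missing genotype. Haplotype alleles are coded
#' 0 and 1 (so that the genotype is the sum of the two alleles), with 9 again
#' marking missing.
#'
#' @name codes
#' @keywords internal
NULL

GENO_CODES <- c(0L, 1L, 2L, 9L)
MISSING <- 9L

#' Construct a genotype matrix
#'
#' An individuals-by-markers integer matrix of genotype codes (see [codes]).
#' Row names are individual identifiers, column names are marker identifiers.
#'
#' @param x matrix (or object coercible to one) of genotype codes in
#'   \{0, 1, 2, 9\}.
#' @param ids optional individual identifiers (row names).
#' @param markers optional marker identifiers (column names).
#' @return an integer matrix of class `geno_matrix`.
#' @examples
#' g <- genotype_matrix(rbind(c(0, 1, 2), c(2, 9, 0)),
#'                      ids = c("x", "y"), markers = c("m1", "m2", "m3"))
#' @export
genotype_matrix <- function(x, ids = NULL, markers = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  if (!is.null(ids)) rownames(x) <- ids
  if (!is.null(markers)) colnames(x) <- markers
  if (is.null(rownames(x))) rownames(x) <- paste0("ind", seq_len(nrow(x)))
  if (is.null(colnames(x))) colnames(x) <- paste0("m", seq_len(ncol(x)))
  bad <- which(!(x %in% GENO_CODES))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(x)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(x)) + 1L
    stop(sprintf("illegal genotype code %d for individual '%s' at marker '%s'",
                 x[bad[1]], rownames(x)[i], colnames(x)[j]), call. = FALSE)
  }
  class(x) <- c("geno_matrix", class(x))
  x
}

#' Construct a haplotype pair
#'
#' Two per-marker allele vectors in \{0, 1, 9\} with optional parent-of-origin
#' labels per marker. Where both alleles are non-missing their sum is the
#' genotype; a missing genotype has both alleles missing.
#'
#' @param hap1,hap2 integer allele vectors in \{0, 1, 9\}.
#' @param origin1,origin2 per-marker origin labels (parent identifiers),
#'   `NA` where unknown.
#' @return list of class `haplotype_pair`.
#' @export
haplotype_pair <- function(hap1, hap2, origin1 = NULL, origin2 = NULL) {
  hap1 <- as.integer(hap1); hap2 <- as.integer(hap2)
  if (length(hap1) != length(hap2)) stop("haplotypes differ in length")
  if (!all(hap1 %in% c(0L, 1L, 9L)) || !all(hap2 %in% c(0L, 1L, 9L)))
    stop("haplotype alleles must be 0, 1 or 9")
  n <- length(hap1)
  if (is.null(origin1)) origin1 <- rep(NA_character_, n)
  if (is.null(origin2)) origin2 <- rep(NA_character_, n)
  structure(list(hap1 = hap1, hap2 = hap2,
                 origin1 = as.character(origin1),
                 origin2 = as.character(origin2)),
            class = "haplotype_pair")
}

#' Genotype of a haplotype pair
#'
#' Sum of the two allele vectors; 9 wherever either allele is missing.
#'
#' @param hp a [haplotype_pair()].
#' @return integer genotype vector in \{0, 1, 2, 9\}.
#' @export
hap_genotype <- function(hp) {
  g <- hp$hap1 + hp$hap2
  g[hp$hap1 == MISSING | hp$hap2 == MISSING] <- MISSING
  g
}

#' Construct a pedigree
#'
#' Records of (individual, parent1, parent2). Founders have `NA` parents
#' (encoded 0 in files); selfing is encoded as `parent1 == parent2`. The
#' pedigree must be acyclic and every named parent must appear as a record.
#' Rows are stored in a topological order (founders first).
#'
#' @param id individual identifiers.
#' @param parent1,parent2 parent identifiers, `NA` (or "0") for founders.
#' @return data.frame of class `pedigree`, topologically sorted.
#' @export
pedigree <- function(id, parent1, parent2) {
  id <- as.character(id)
  p1 <- as.character(parent1); p2 <- as.character(parent2)
  p1[p1 %in% "0"] <- NA; p2[p2 %in% "0"] <- NA
  if (anyDuplicated(id)) stop("duplicated individual id in pedigree")
  known <- c(p1, p2)
  miss <- setdiff(known[!is.na(known)], id)
  if (length(miss))
    stop("parents absent from pedigree: ", paste(miss, collapse = ", "))
  ped <- data.frame(id = id, parent1 = p1, parent2 = p2,
                    stringsAsFactors = FALSE)
  ord <- ped_topo_order(ped)
  ped <- ped[ord, , drop = FALSE]
  rownames(ped) <- NULL
  class(ped) <- c("pedigree", "data.frame")
  ped
}

# Kahn's algorithm; errors on cycles.
ped_topo_order <- function(ped) {
  n <- nrow(ped)
  idx <- seq_len(n)
  names(idx) <- ped$id
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in idx) {
    for (p in unique(stats::na.omit(c(ped$parent1[i], ped$parent2[i])))) {
      j <- idx[[p]]
      children[[j]] <- c(children[[j]], i)
      indeg[i] <- indeg[i] + 1L
    }
  }
  queue <- integer(n)
  roots <- which(indeg == 0L)
  queue[seq_along(roots)] <- roots
  head <- 1L; tail <- length(roots)
  out <- integer(n); k <- 0L
  while (head <= tail) {
    i <- queue[head]; head <- head + 1L
    k <- k + 1L; out[k] <- i
    for (j in children[[i]]) {
      indeg[j] <- indeg[j] - 1L
      if (indeg[j] == 0L) { tail <- tail + 1L; queue[tail] <- j }
    }
  }
  if (k != n) stop("pedigree contains a cycle")
  out[seq_len(k)]
}

#' Construct a marker panel
#'
#' Ordered high-density (Hd) markers with map positions in centimorgans, plus
#' the low-density (Ld) subset.
#'
#' @param marker Hd marker identifiers, in map order.
#' @param pos positions in cM, strictly increasing within a chromosome.
#' @param ld_markers identifiers of the Ld subset.
#' @param chrom chromosome labels (single chromosome by default).
#' @return list of class `marker_panel` with elements `marker`, `chrom`,
#'   `pos`, `ld` (logical Ld membership).
#' @export
marker_panel <- function(marker, pos, ld_markers = character(0), chrom = 1L) {
  marker <- as.character(marker)
  pos <- as.numeric(pos)
  if (length(marker) != length(pos)) stop("marker and pos differ in length")
  if (anyDuplicated(marker)) stop("duplicated marker id")
  chrom <- rep_len(chrom, length(marker))
  for (ch in unique(chrom)) {
    p <- pos[chrom == ch]
    if (any(diff(p) <= 0))
      stop("positions must be strictly increasing within chromosome ", ch)
  }
  ld_markers <- as.character(ld_markers)
  if (!all(ld_markers %in% marker))
    stop("ld markers must be a subset of the Hd markers")
  structure(list(marker = marker, chrom = chrom, pos = pos,
                 ld = marker %in% ld_markers),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker panel: %d Hd markers (%d Ld), %s chromosome(s), %.1f-%.1f cM\n",
              length(x$marker), sum(x$ld), length(unique(x$chrom)),
              min(x$pos), max(x$pos)))
  invisible(x)
}

#' Validate genotype, pedigree and panel inputs against each other
#'
#' Checks that genotype codes are legal (fatal if not), and reports
#' individuals present in the genotype matrix but absent from the pedigree and
#' markers absent from the panel (warnings).
#'
#' @param geno a [genotype_matrix()].
#' @param ped a [pedigree()].
#' @param panel a [marker_panel()].
#' @return (invisibly) a list with character vectors `unknown_individuals` and
#'   `unknown_markers`; warnings are emitted for non-fatal findings.
#' @export
validate_inputs <- function(geno, ped, panel) {
  geno <- genotype_matrix(geno)  # re-validates codes, fatal on illegal ones
  unknown_ind <- setdiff(rownames(geno), ped$id)
  unknown_mrk <- setdiff(colnames(geno), panel$marker)
  if (length(unknown_ind))
    warning("individuals absent from pedigree: ",
            paste(unknown_ind, collapse = ", "), call. = FALSE)
  if (length(unknown_mrk))
    warning("markers absent from panel: ",
            paste(unknown_mrk, collapse = ", "), call. = FALSE)
  invisible(list(unknown_individuals = unknown_ind,
                 unknown_markers = unknown_mrk))
}

#' Describe one simulation scenario
#'
#' Declarative description of a biparental masking scenario: how inbred the
#' target parent is, how it was genotyped, how many crosses it appears in, how
#' many descendants per cross carry Hd genotypes, and whether its own parents
#' (the grandparents of the focal generation) are genotyped at Hd.
#'
#' Defaults follow the study conditions: one cross, 1,000 F2 of which 10 are
#' Hd descendants, 25,000 Hd and 50 Ld markers on a 1 Morgan chromosome.
#'
#' @param parentA_inbred logical; fully inbred target parent.
#' @param parentA_genotyping `"none"` or `"ld"`.
#' @param n_crosses number of crosses (1-4) the target parent appears in.
#' @param n_hd_descendants_per_cross Hd-genotyped F2 per cross.
#' @param include_grandparents logical; grandparents genotyped at Hd.
#' @param n_f2_per_cross F2 individuals per cross.
#' @param n_hd_snps,n_ld_snps Hd panel size and Ld subset size.
#' @param n_base_haplotypes base haplotypes behind the founders.
#' @param n_base_sites candidate segregating sites to simulate before panel
#'   selection.
#' @param seed optional integer seed.
#' @return list of class `scenario_spec`.
#' @export
scenario_spec <- function(parentA_inbred = TRUE,
                          parentA_genotyping = c("none", "ld"),
                          n_crosses = 1L,
                          n_hd_descendants_per_cross = 10L,
                          include_grandparents = FALSE,
                          n_f2_per_cross = 1000L,
                          n_hd_snps = 25000L,
                          n_ld_snps = 50L,
                          n_base_haplotypes = 100L,
                          n_base_sites = 8L * n_hd_snps,
                          seed = NULL) {
  parentA_genotyping <- match.arg(parentA_genotyping)
  n_crosses <- as.integer(n_crosses)
  if (n_crosses < 1L || n_crosses > 4L) stop("n_crosses must be in 1..4")
  if (n_hd_descendants_per_cross > n_f2_per_cross)
    stop("n_hd_descendants_per_cross must not exceed n_f2_per_cross")
  if (n_ld_snps > n_hd_snps) stop("n_ld_snps must not exceed n_hd_snps")
  structure(list(parentA_inbred = isTRUE(parentA_inbred),
                 parentA_genotyping = parentA_genotyping,
                 n_crosses = n_crosses,
                 n_hd_descendants_per_cross = as.integer(n_hd_descendants_per_cross),
                 include_grandparents = isTRUE(include_grandparents),
                 n_f2_per_cross = as.integer(n_f2_per_cross),
                 n_hd_snps = as.integer(n_hd_snps),
                 n_ld_snps = as.integer(n_ld_snps),
                 n_base_haplotypes = as.integer(n_base_haplotypes),
                 n_base_sites = as.integer(n_base_sites),
                 seed = if (is.null(seed)) NULL else as.integer(seed)),
            class = "scenario_spec")
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat("biparental imputation scenario:\n")
  cat(sprintf("  parent A: %s, %s genotypes\n",
              if (x$parentA_inbred) "inbred" else "outbred",
              if (x$parentA_genotyping == "ld") "Ld" else "no"))
  cat(sprintf("  %d cross(es), %d F2 each (%d Hd descendants), grandparents %s\n",
              x$n_crosses, x$n_f2_per_cross, x$n_hd_descendants_per_cross,
              if (x$include_grandparents) "at Hd" else "excluded"))
  cat(sprintf("  panel: %d Hd / %d Ld SNPs\n", x$n_hd_snps, x$n_ld_snps))
  invisible(x)
}
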