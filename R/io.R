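#' Read a genotype file
#'
#' Whitespace-separated file, one row per individual: the individual identifier
#' followed by one genotype code per Hd marker (0/1/2, 9 = missing).
#'
#' @param path file path.
#' @param markers optional marker identifiers for the columns.
#' @return a [genotype_matrix()].
#' @export
read_genotypes <- function(path, markers = NULL) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nfld <- lengths(toks)
  if (length(unique(nfld)) != 1L)
    stop(sprintf("ragged genotype file '%s': line %d has %d fields, expected %d",
                 path, which(nfld != nfld[1])[1], nfld[which(nfld != nfld[1])[1]],
                 nfld[1]))
  ids <- vapply(toks, `[[`, "", 1L)
  vals <- lapply(seq_along(toks), function(i) {
    v <- suppressWarnings(as.integer(toks[[i]][-1L]))
    if (anyNA(v))
      stop(sprintf("non-integer genotype token on line %d of '%s'", i, path))
    v
  })
  genotype_matrix(do.call(rbind, vals), ids = ids, markers = markers)
}

#' Write a genotype file
#'
#' @param geno a [genotype_matrix()].
#' @param path file path.
#' @export
write_genotypes <- function(geno, path) {
  df <- data.frame(id = rownames(geno), unclass(geno)[, , drop = FALSE])
  utils::write.table(df, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read a pedigree file
#'
#' Three whitespace-separated columns: individual, parent1, parent2
#' (0 = unknown/founder).
#'
#' @param path file path.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("id", "parent1", "parent2"),
                          colClasses = "character")
  pedigree(df$id, df$parent1, df$parent2)
}

#' Write a pedigree file
#'
#' @param ped a [pedigree()].
#' @param path file path.
#' @export
write_pedigree <- function(ped, path) {
  out <- ped
  out$parent1[is.na(out$parent1)] <- "0"
  out$parent2[is.na(out$parent2)] <- "0"
  utils::write.table(out, path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read a marker map file
#'
#' Three whitespace-separated columns: marker identifier, chromosome, position
#' in cM.
#'
#' @param path file path.
#' @param ld_markers optional Ld marker identifiers (or see [read_marker_list()]).
#' @return a [marker_panel()].
#' @export
read_map <- function(path, ld_markers = character(0)) {
  df <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          col.names = c("marker", "chrom", "pos"))
  marker_panel(df$marker, df$pos, ld_markers = ld_markers, chrom = df$chrom)
}

#' Write a marker map file
#'
#' @param panel a [marker_panel()].
#' @param path file path.
#' @export
write_map <- function(panel, path) {
  utils::write.table(data.frame(panel$marker, panel$chrom, panel$pos),
                     path, quote = FALSE, row.names = FALSE,
                     col.names = FALSE, sep = " ")
  invisible(path)
}

#' Read / write a one-column marker list (e.g. the Ld subset)
#'
#' @param path file path.
#' @return character vector of marker identifiers.
#' @export
read_marker_list <- function(path) {
  as.character(utils::read.table(path, header = FALSE,
                                 stringsAsFactors = FALSE)[[1]])
}

#' @rdname read_marker_list
#' @param markers character vector to write.
#' @export
write_marker_list <- function(markers, path) {
  writeLines(as.character(markers), path)
  invisible(path)
}

#' Read a phase file
#'
#' Two rows per individual (haplotype 1 then haplotype 2): the individual
#' identifier followed by one allele per marker (0/1, 9 = missing).
#'
#' @param path file path.
#' @return named list of [haplotype_pair()] objects.
#' @export
read_phase <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) %% 2L != 0L)
    stop("phase file must contain two rows per individual")
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  ids <- vapply(toks, `[[`, "", 1L)
  out <- list()
  for (k in seq_len(length(lines) / 2L)) {
    i <- 2L * k - 1L
    if (ids[i] != ids[i + 1L])
      stop("phase file rows ", i, " and ", i + 1L, " have different ids")
    h1 <- as.integer(toks[[i]][-1L]); h2 <- as.integer(toks[[i + 1L]][-1L])
    out[[ids[i]]] <- haplotype_pair(h1, h2)
  }
  out
}

#' Write a phase file
#'
#' @param haps named list of [haplotype_pair()] objects.
#' @param path file path.
#' @export
write_phase <- function(haps, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(haps)) {
    writeLines(paste(c(id, haps[[id]]$hap1), collapse = " "), con)
    writeLines(paste(c(id, haps[[id]]$hap2), collapse = " "), con)
  }
  invisible(path)
}
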