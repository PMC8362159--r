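Package: bipimpute
Title: Heuristic Phasing and Imputation for Biparental Plant Breeding Populations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Phases and imputes single nucleotide polymorphism genotypes in
    biparental plant breeding populations. Implements a heuristic pedigree-based
    method that imputes low-density genotyped descendants to high density, and
    its extension that phases and imputes a parent that is ungenotyped or only
    genotyped at low density from its high-density genotyped relatives
    (ancestors, mates and descendants), using descendant allele frequencies, a
    segregation-distortion chi-square test and consensus haplotypes. Includes a
    gene-drop simulator of biparental populations (base haplotypes, pedigree,
    marker panels, masking scenarios) and accuracy/yield metrics so the whole
    method can be validated on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
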