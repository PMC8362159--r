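---
title: "Phasing and imputing missing parents of biparental populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasing and imputing missing parents of biparental populations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Plant breeding programs cross a small number of parents and genotype large
numbers of selection candidates cheaply at low density (Ld, here 50 SNPs per
chromosome), imputing them to high density (Hd, here up to 25,000 SNPs) from
their parents' phased Hd genotypes. That strategy breaks down when a parent
has no usable Hd genotypes — lost or degraded DNA samples, pedigree errors,
or a deliberate decision not to genotype a parent used in only one cross.

`bipimpute` implements a heuristic, pedigree-based method for this setting.
Its core is `impute_parent()`: phase and impute a parent ("parent A") that is
ungenotyped or Ld-genotyped, using whatever Hd relatives exist — its own
parents (the grandparents of the focal generation), its mates, and Hd
descendants of its crosses. The imputed parent can then be used by
`impute_focal_to_hd()` / `impute_offspring()` to impute the Ld focal
descendants, and `simulate_population()` / `run_scenarios()` provide the
simulation harness that validates the whole pipeline.

Genotypes are coded 0/1/2 (0 and 2 the two homozygotes), 9 missing;
haplotype alleles are 0/1 so that the genotype is the sum of the two alleles.

## The shared phasing primitive

Every phasing task in the package reduces to one primitive. Consider a child
of a cross between parent P and a mate Q, where Q is homozygous wherever it
is used (mates in biparental programs are typically fully inbred). Along the
chromosome the child's two haplotypes form a mosaic of P material and Q
material; write the *P-dose* d(m) ∈ {0, 1, 2} for the number of haplotype
copies at marker m that descend from P. Because selfing generations separate
the child from the cross, all P-derived copies trace back to a *single* P
gamete g, so the child genotype obeys

y(m) = d(m) · g(m) + (2 − d(m)) · b(m),

with b the mate allele. Two consequences drive everything:

* **Anchors.** Alleles the mate does not carry must have come from P, and
  d = 2 forces y ∈ {0, 2}; hence any observed y(m) ≠ 2·b(m) pins the dose
  exactly: d(m) = |y(m) − 2·b(m)|. Where P is *known* homozygous for the
  allele opposing the mate (an observed genotype), y = 2b additionally pins
  d = 0. These markers are the anchor points.
* **Extension.** The dose is piecewise constant between crossovers
  (about one per Morgan per meiosis), so between anchors it is extended from
  the nearest anchor, with the switch placed at the cM midpoint between
  discordant anchors. Markers outside all anchors inherit the nearest
  anchor's dose.

Given the dose, the implied P-gamete allele g(m) = (y − (2 − d)·b)/d is read
off wherever d ≥ 1. Imputation of a focal individual is then allele copying:
d = 0 copies the mate, d = 2 copies P twice, d = 1 copies one allele from
each. For an outbred P the copy must choose between P's two haplotypes; the
choice is resolved where the implied gamete allele discriminates them and
extended by the same nearest-anchor rule (the gamete is itself a
recombinant).

One refinement applies when the parent is unknown: a *long* run of
y = 2b over informative markers is taken as dose 0 (`run_dose0_anchors()`,
default 15 informative markers with a 3-marker margin). Under the
linkage-equilibrium base haplotypes of the simulator a transmitted gamete
that merely mimics the mate over 15 markers is vanishingly unlikely, while
true dose-0 segments are common (a quarter of an F2 genome). On real data
with strong haplotype sharing this heuristic would be more aggressive than
ideal; see *Limitations*.

## Imputing a missing parent

`impute_parent()` runs up to two independent information paths and merges
them.

**Ancestor path.** If both of parent A's own parents are Hd-genotyped:
with no genotypes on A at all, selfing means either ancestral allele may
have fixed, so only markers where both ancestors are homozygous for the
*same* allele are imputed (and are phased de facto). With Ld genotypes on A,
A is phased as a focal child of its two parents using the primitive above.

**Descendant path.** For each cross of A with an Hd mate and Hd
descendants:

1. *Homozygote inference from fixation.* Markers where the descendants of
   every cross are fixed for one allele, with compatible mates, call A
   homozygous (`infer_homozygous_from_descendants()`). A minimum of four
   total descendants guards against chance fixation — with a heterozygous
   parent the probability that all ten Hd descendants are fixed is under
   1%.
2. *Segregation-distortion test.* At markers segregating among a cross's
   descendants with a homozygous mate, observed genotype counts are tested
   against the counts expected from the observed allele frequency
   (Hardy–Weinberg proportions; the frequency is estimated, so 1 df;
   α = 0.05). Significant distortion means A is heterozygous; no
   significant distortion imputes A to the homozygote opposing the mate
   (`chi2_call()`). Calls are made per cross — each cross has its own mate,
   so expectations are mate-specific — and combined across crosses with any
   disagreement giving "unknown". A cross whose descendants are fixed for
   an allele the mate could have co-transmitted contributes a homozygote
   call to this combination, so one cross's fixation can veto another
   cross's false distortion call.
3. *Consensus haplotypes.* Every Hd descendant is phased with the
   primitive, yielding its implied A-gamete allele ("vote") at each marker.
   Heterozygous markers *confirmed by the votes themselves* (both alleles
   seen, the minority at least twice and at least 15% of votes) are phased
   into two haplotypes by linkage between neighbouring confirmed markers;
   each gamete then receives a per-marker haplotype label — anchored where
   its votes match a phased heterozygote, extended by the nearest-anchor
   rule — and per-marker strict majorities within each label give the two
   consensus haplotypes. Three refinement passes re-anchor the labels
   against the growing haplotypes. Finally, a marker where one haplotype
   is resolved and the votes contain its counter-allele assigns the
   counter-allele to the other haplotype; the dissent threshold scales
   with vote depth (5% of votes, at least one) because with many gametes a
   single stray vote is most likely a dose-interpolation artefact.

The genotype is assembled by precedence: observed genotypes (never
overwritten), then consensus haplotype sums, then — for a fully ungenotyped
parent — heterozygote calls from step 2 (direct distortion evidence), then
remaining homozygote calls. With Ld anchors available, a distortion-only
heterozygote call at a consensus-defined marker is treated as a
transmission-sampling artefact and the haplotype attribution wins; only
homozygote calls fill remaining gaps there. Each call records its
provenance (`ld_obs`, `ancestor`, `freq`, `chi2`, `consensus`).

**Merge.** When both paths ran, they are merged marker by marker
(`merge_ancestor_descendant()`): agreement keeps the call, one-sided
missingness keeps the non-missing call, and disagreement — even on a single
haplotype — sets haplotype and genotype to missing. Phase labelings are
first aligned where both tracks are phased heterozygous, with the
orientation extended by the nearest-anchor rule, since either track's
labels may legitimately switch along the chromosome.

## Design choices at genuinely open points

* **Missing-value code 9.** The file formats code genotypes 0/1/2; a
  sentinel for missing is required and 9 is the convention of plain-text
  breeding genotype files.
* **α = 0.05, df = 1.** Conventional default; the distortion decision at
  n = 10–50 descendants is insensitive to small changes (verified against
  exact multinomial enumeration in the test suite).
* **Expected counts under Hardy–Weinberg proportions.** With an estimated
  allele frequency no other null fits "expected counts given observed
  allele frequencies".
* **Distortion calls are kept for an ungenotyped parent even where the
  consensus is unanimous.** A unanimous vote set at a distortion-flagged
  marker usually means the second allele never reached an Hd descendant;
  an unphased heterozygote call is then the only honest record of the
  distortion evidence. The cost is a false-positive rate of about 4% of
  opposing-homozygote markers (in blocks, since neighbouring markers share
  descendant counts) — this, not any per-marker noise, is the dominant
  error of the ungenotyped path, and it is what limits an inbred parent's
  accuracy to roughly 0.98 rather than 1.0.
* **Heterozygote phasing anchors are vote-confirmed markers, not
  distortion-flagged ones.** The distortion test is significant exactly
  when transmission was lopsided, so flagged markers tend to show only one
  allele among the votes and are the worst possible phasing anchors. This
  is the one place the implementation deliberately refines the obvious
  reading of the procedure; without it, phasing of an outbred parent
  collapses.
* **Consensus ties and empty groups stay missing**, consistent with the
  merge rule's preference for missingness over guessing.
* **Siblings** are accepted in the relative set but contribute only through
  shared ancestors; no sibling-specific rule exists.

## The simulator

`simulate_population()` builds one replicate of the study conditions:

* **Base haplotypes** (`simulate_base_haplotypes()`): 100 binary haplotypes
  over segregating sites on a 1 Morgan chromosome, positions uniform on
  0–100 cM, derived-allele counts drawn with probability ∝ 1/k (the
  neutral-equilibrium spectrum, skewed toward rare variants). Sites are
  independent — the generator reproduces the frequency spectrum and site
  counts of a coalescent simulation, not its linkage disequilibrium.
* **Pedigree.** Two inbred founders (the grandparents) are crossed; parent
  A is one F1, fixed by selfing when inbred. Fixation is analytic: one
  recombinant F1 gamete is doubled, equivalent in distribution to 100
  selfing rounds (residual heterozygosity 2^-100) at a fraction of the
  cost. A is crossed to one to four inbred founder mates; every F2 comes
  from its own selfed F1, so each samples an independent A gamete.
  Meiosis draws a Poisson number of crossovers (mean = map length in
  Morgans, no interference) with uniform breakpoints.
* **Panels** (`select_panels()`): Hd markers are sites segregating among
  the cross parents with base minor-allele frequency in [0.01, 0.50],
  approximately equidistant in cM; the Ld panel is an equidistant subset.
* **Masking.** Parent A is fully masked or Ld-masked per scenario; 10 (or
  50) F2 per cross keep Hd genotypes, the focal remainder keep Ld only;
  mates — and grandparents, when the scenario includes them — stay at Hd.

Scenarios 1–4 use one to four crosses without grandparents; 5–8 repeat them
with grandparents at Hd (`study_scenarios()`).

What the simulator does *not* emulate: linkage disequilibrium and shared
ancestry among founders (every founder haplotype is an independent draw),
genotyping error, mutation within the pedigree, multiple chromosomes
(runs are per chromosome), and double haploids. Passing tests therefore
demonstrate correct inheritance logic and calibrated inference under clean,
linkage-equilibrium founders — not robustness to genotyping error or to
the long identical-by-descent tracts of real elite germplasm, which would
make the dose-0 run heuristic and the fixation rule more error-prone.

## Metrics and replication scales

Accuracy is the Pearson correlation between true and imputed genotype
codes over the markers where the imputed value is non-missing (undefined
for constant vectors, reported `NA`); yield is the fraction of Hd markers
imputed non-missing. Missing imputed markers are excluded from the
correlation rather than filled — accuracy and yield are deliberately
separate quantities.

The packaged validation (`tests/testthat/test-acceptance.R`,
`scripts/acceptance.R`) replicates the simulation study at desk scale:
2,000 Hd SNPs, 50 Ld SNPs, 200 F2 per cross with 10 (or 50) Hd
descendants, 20 replicates per condition — sizes chosen so the full grid
runs in about a minute while each reported contrast remains large relative
to its replicate noise. Two caveats follow from the scale-down. First,
replicate standard deviations are larger than at 25,000 SNPs and 1,000 F2
(the distortion false-positive blocks and Mendelian sampling lumps are
relatively larger), so conditions whose reported dispersion is tiny
(e.g. 0.999 ± 0.0003) cannot be pinned to that precision here. Second,
about one replicate in five draws Hd descendants whose transmitted gametes
cover one parental haplotype poorly; the affected heterozygous markers are
then unrecoverable by *any* method, which bounds the outbred/ungenotyped
condition near 0.95–0.97 at this scale.

## A worked example

```{r, eval = FALSE}
library(bipimpute)

spec <- scenario_spec(parentA_inbred = FALSE, parentA_genotyping = "none",
                      n_f2_per_cross = 200, n_hd_snps = 2000,
                      n_ld_snps = 50, n_base_sites = 12000, seed = 42)
pop <- simulate_population(spec)
fit <- impute_parent(pop$geno, pop$pedigree, pop$panel)
summary(fit)
imputation_accuracy(hap_genotype(pop$truth$A), fit$genotype)

# propagate to an Ld focal descendant
id <- pop$crosses$B$focal[1]
res <- impute_focal_to_hd(pop$geno[id, ], fit, pop$truth$B, pop$panel)
imputation_accuracy(hap_genotype(pop$truth[[id]]), res$genotype)
```

## Known limitations

* The dose-0 run heuristic and the vote-dissent thresholds are calibrated
  for linkage-equilibrium founders and error-free genotypes; real data
  would need a genotype-error model and LD-aware run lengths.
* Only one missing parent per cross is supported; imputing both parents of
  the same cross simultaneously is out of scope, as is probabilistic
  (dosage) output.
* Mates are used only where homozygous. Outbred mates contribute no
  anchors at their heterozygous markers, degrading gracefully but
  noticeably.
* With more crosses the implementation pools gametes across all crosses
  and accuracy rises monotonically; implementations that resolve
  parent-of-origin strictly within a cross can instead lose accuracy with
  more crosses for an outbred ungenotyped parent. This is the one
  qualitative point where this implementation's behaviour is knowingly
  better-behaved than the behaviour reported for the original software,
  not identical to it.
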