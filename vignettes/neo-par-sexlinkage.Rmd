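---
title: "Detecting recombination suppression on a neo-sex chromosome from family RAD-seq data"
author: "radlink"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting recombination suppression on a neo-sex chromosome from family RAD-seq data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radlink)
```

## The problem

When an autosome fuses to a sex chromosome, the fused arm (a
neo-pseudoautosomal region, neo-PAR) initially recombines in both sexes.
If recombination between its X- and Y-borne copies later stops in males
over a proximal segment, that segment becomes fully sex-linked: the
Y-borne copy is transmitted strictly father-to-son, the X-borne copy
diverges demographically (reduced effective population size, loss of
polymorphism), and crossovers in male meiosis are confined to the still
recombining distal segment.

`radlink` detects such a segment, and estimates where it ends, from
RAD-seq genotypes of full-sib families with sexed offspring.  Three lines
of evidence are implemented:

1. **Y-limited tags** — RADtags present in (nearly all) males and absent
   from all females, arising from X-null alleles, Y-specific restriction
   sites, or strong X–Y divergence.
2. **Fully sex-linked SNPs** — markers with the male-heterogametic
   segregation pattern: (i) heterozygous father, (ii) homozygous mother,
   (iii) all sons heterozygous, (iv) all daughters homozygous for the
   maternal allele.
3. **Population-genetic signatures** — collapsed heterozygosity of
   mothers (but not fathers) over the X-specific segment in 1-Mbp
   windows, and paternal recombination maps in which all proximal markers
   cosegregate.

A forward simulator of neo-XY meiosis generates pedigree genotype data
with known truth, so every stage is testable without external data.

## Data model and conventions

Genotypes are biallelic dosages (0/1/2, `NA` missing) with per-call
depth, on markers grouped into RADtags.  All coordinates are 0-based,
half-open base pairs (BED-compatible); positions are reported on the two
homologous reference chromosomes of the neo-sex chromosome
(`proximal_chr7`, `distal_chr19`), and megabase values in reports are
bp / 10^6.  Pedigrees are full-sib families with exactly one mother and
one or more sires; every per-father computation iterates over
*sire-groups* (one sire + the mother + that sire's offspring).  The
default study pedigree has three families totalling 65 individuals
(21♂/9♀; 5♂/1♀ and 4♂/3♀ by two sires sharing one mother; 12♂/3♀).

## Marker QC

The stringent preset retains a marker for a sire-group iff it is called
with depth ≥ 12 in the mother, the sire, and every one of that sire's
offspring, and its within-unit minor allele frequency is ≥ 0.05; the
relaxed preset requires depth ≥ 8 in at least ⌈n/2⌉ of the offspring
("at least half" rounds up; parents are not required).  MAF is computed
within the analysis unit from the calls that meet the depth criterion
(a pooled-MAF option exists).  The filter is idempotent and monotone in
the depth threshold, and each dropped marker is logged with the rule it
failed.

## The screens

**Presence/absence screen.**  A tag is male-limited iff present females
= 0 and present males / total males ≥ 0.9, pooled across all sequenced
individuals.  The proportion is compared as an exact rational (the
threshold numerator is scaled to an integer) so 36/40 passes a 0.9
threshold and 41/46 does not, with no floating-point edge cases.  The
sex-swapped screen (female-limited tags) is a pure false-positive
control: no true female-limited sequence exists in an XY system.

**Segregation screen.**  The four criteria above, evaluated per
sire-group; criterion (iv) requires the daughters' homozygote to equal
the mother's allele, not merely any homozygote.  Any missing call in the
unit fails the marker for that unit (on QC-filtered input none remain).
For a family of two sons and one daughter, exactly 2 of the 3^5 = 243
dosage configurations pass (mother homozygous for either allele) — this
enumeration is a frozen test.

## The boundary estimate

Within evidence on the proximal homolog, the most distal fully
sex-linked position bounds the non-recombining segment from below; the
estimator reports it per family and per evidence class.

The headline (`segregation.all`) boundary uses **consensus evidence**:
markers sex-linked in *every* sire-group where they survived QC, and
testable (QC-retained) in at least two families.  The
reason is statistical: a marker just distal of the true boundary is
genetically linked to the sex-determining region (recombination fraction
r rising from 0 at the boundary to ~0.5 at the distal telomere), so in a
single small sibship it cosegregates perfectly with sex with probability
(1−r)^n — far from negligible for n ≤ 7.  Per-family most-distal
positions therefore scatter distally of the shared boundary, while
replication across independent families suppresses these
partially-linked passes multiplicatively.  Per-family counts and
positions are still reported in the Table-style summary, and the union
rule per family is retained there.

## Recombination maps

Per parent, markers heterozygous in that parent and homozygous in the
other (pseudo-testcross markers) reveal transmission directly: the
transmitted allele is the offspring dosage minus the homozygous
partner's contribution.  Both-parents-heterozygous markers are excluded
— their transmission is ambiguous without likelihood phasing — so maps
here are sparser than those of a full likelihood mapper; this is a
deliberate simplification that preserves the qualitative target
(proximal cosegregation in fathers).

Marker phase along the parent's two homologs is chosen to minimise the
total number of inferred crossovers.  Because flipping a marker's
orientation changes only its two adjacent mismatch counts, the objective
decomposes over adjacent pairs and the greedy pass (orient each marker
to agree better with its predecessor; ties keep the current orientation;
the first marker anchors the phase) attains the global minimum — the
test suite verifies this against exhaustive phase search on small
fixtures.  Crossovers are reported as intervals between consecutive
informative markers where the transmitted haplotype switches.

Adjacent markers with identical phase-aligned transmission vectors form
one cosegregation group (one map position); between adjacent groups the
recombination fraction r̂ = recombinant offspring / offspring is
converted to centimorgans with the Kosambi function
d = 25·ln((1+2r)/(1−2r)) and accumulated along physical order (marker
order is taken from the reference positions, not estimated de novo).  A
numerical guard caps r̂ at 0.5 − 10⁻¹² so a degenerate 50%-recombinant
adjacency yields a large finite distance rather than infinity.

## MLH1 focus profiles

Crossover positions observed cytologically (MLH1 foci on the
synaptonemal complex) are binned into 10 equal intervals from the
centromere (interval 1) to the distal telomere (interval 10): a focus at
fraction f of the arm goes to interval ⌈10·f⌉, with f = 0 in interval 1
and internal boundaries closed to the right, so counts are conserved for
any interval number and the profile is invariant to rescaling the
measurements.  Profiles are compared descriptively (aligned per-interval
focus frequencies and their differences); no hypothesis test is
attached.

## The simulator and its meiotic model

`simulate_dataset()` builds founder haplotypes, gametes, and a RAD
genotyping layer on a concatenated two-arm axis (145 Mbp proximal +
61 Mbp distal), with a male non-recombining segment `[0, B)`,
B = 83.5 Mbp by default.

*Founders.*  In `[0, B)` the X haplotypes are monomorphic at a site with
probability 1 − `pi_prox_X` (default 5·10⁻⁴ — the X-specific segment is
nearly devoid of polymorphism), and a marker carries a fixed X–Y
difference with probability `p_xy_div` (default 0.05); such markers are
the truly sex-linked truth set.  Elsewhere haplotypes come from a common
pool at `pi_background` (default 0.02 per site).  A proximal tag is
Y-limited (X-null) with probability `p_y_null` (default 0.01); its
markers are hemizygous — they cannot also carry an X–Y difference, so
the two truth classes partition.

*Meiosis.*  Chiasmata form at the bivalent level: counts from
`male_co_counts` (default 1 with probability 0.98, 2 with 0.02 — mean
1.02 foci per spermatocyte, with no zero class: the neo-PAR always shows
a chiasma), positions uniform on `[B, L)` in males and on the whole axis
in females (Poisson count, mean `female_co_mean` = 1.1 — a free
parameter, as no female estimate exists).  Each chiasma involves two of
the four chromatids, so the transmitted chromatid realises it as a
crossover independently with probability 1/2.  This matters: it keeps
per-cell focus counts at the observed mean while capping recombinant
fractions at the Mendelian 50%.  Were the focus-count distribution
applied per gamete instead, the obligate crossover would make the distal
telomere of a son's paternal chromosome almost always recombined
relative to the sex-determining end — a near-deterministic
*anti*-linkage that real chromatid segregation does not produce.  The
gamete's identity at position 0 (where the ancestral sex-determining
region is attached) determines offspring sex (Y → son); in the default
pedigree the paternal gamete is conditioned on the recorded sex.  No
crossover interference is modelled (positions uniform): count data
constrain the simulation, interference estimates do not exist for this
system.

*Genotyping.*  Per-tag depth is Poisson(`depth_mean` = 20, halved for
hemizygous Y-limited tags); a tag is present iff depth ≥
`presence_min_depth` (default 3, the usual minimum stack depth), with
extra dropout at `miss_rate` = 0.01; calls on absent tags are missing.
Y-limited tags are absent from all X-only individuals.

*Null modes.*  `chromosome_type = "autosomal"` simulates the same axis
as an ordinary autosome (chiasmata anywhere, transmission independent of
offspring sex) — the situation of the autosomal-arm cytological control.
`chromosome_type = "unlinked"` makes every marker segregate
independently, as RADtags scattered across many autosomes do; this is
the textbook null for screen specificity, under which the screen's
false-positive probability given an informative parent pair is exactly
(1/2)^n per sire-group, and marker-family trials are independent.
Markers *sharing* one autosome are the wrong null for that bound: with
single-chiasma bivalents half the gametes are entirely parental, so
false positives arrive in rare family-wide blocks and the trials are
strongly over-dispersed.

*What the simulator does not emulate.*  Sequence-level reads and
alignment, population history of the founders (sites are independent;
no linkage disequilibrium beyond the pedigree), crossover interference,
genotyping error other than dropout, and the ancestral X/Y arms.
Passing tests therefore demonstrate correctness of the screens and
estimators under clean Mendelian structure with realistic depth and
dropout — not robustness to alignment artefacts or population structure
in real data.

## Problem sizes and reproducibility

The test suite and the acceptance script work at the study's scale:
5,000 tags on the 206-Mbp axis in the 65-individual pedigree for the
boundary and error-rate checks (error-free variant: depth 100, no
dropout), ~10⁵ unlinked marker-family trials for the false-positive
bound, 10,000 cells for focus means, 200 dense-marker gametes for exact
crossover recovery, and ≤ 20-marker random fixtures (1,000 of them)
for brute-force oracle equivalence.  Every source of randomness flows
from explicit seeds; the pipeline writes a manifest (package version,
seed, configuration hash, stage counts) and two runs with the same seed
are byte-identical.

## Known limitations

- Boundary resolution is limited by the local density of sex-linked
  markers: the estimate sits at the most distal evidence marker, one
  median inter-marker gap below the true boundary in expectation.
- Both-parent-heterozygous markers are discarded for mapping, so map
  totals underestimate a likelihood mapper's; cosegregation structure is
  unaffected.
- Maternal proximal maps are intrinsically sparse when proximal X
  polymorphism is low — real female recombination in that segment is
  underestimated for lack of informative markers, in the package and in
  the field.
- The consensus boundary requires ≥ 2 informative families; with a
  single family it degrades to the per-family estimate and inherits its
  distal bias from partial linkage.
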