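---
title: "Methods: consensus-based genetic markers for cannabis chemotype discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus-based genetic markers for cannabis chemotype discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cannamark)
```

## The problem

Drug-type (marijuana) and fiber-type (hemp) *Cannabis sativa* are legally
distinct but morphologically identical before cannabinoids accumulate, so
chemical assays cannot separate them in seeds or young plants. The two
synthase genes *THCAS* and *CBDAS* encode enzymes that compete for the
shared precursor cannabigerolic acid, and fixed sequence differences in
their coding regions track the chemotype. `cannamark` implements the full
marker-discovery and scoring pipeline on such data: variant discovery
against reference coding sequences, a per-locus association scan, a
consensus-allele discriminant score, diversity summaries, protein
consequence prediction, and THC/CBD chemotype arithmetic — all exercisable
end-to-end on synthetic panels, with real FASTA input accepted through the
same functions.

## The synthetic panel

`simulate_panel()` is first-class, tested code, not a fixture. Its
defaults are the study conditions the analyses assume:

* 47 drug-type plants across 11 varieties and 50 fiber-type plants across
  10 varieties, plus 20 drug-type and 50 fiber-type seeds (167 samples);
* a 1638-nt drug-type THCAS-like CDS and a 1635-nt fiber-type CBDAS-like
  CDS (so their translations are 545 and 544 amino acids);
* 25 discriminating SNPs in the THCAS-like gene (fiber-fixed alleles
  against the drug-type reference) and 8 in the CBDAS-like gene
  (drug-fixed against the fiber-type reference), at the published CDS
  positions;
* a 4-bp deletion (`CGTA`, positions 153–156) and a 3-bp insertion (`AAC`
  after position 755) in the CBDAS-like gene of drug-type samples.

The allele identities at the 33 SNP positions are an invented, fixed
design, labelled synthetic throughout, engineered so that the
protein-consequence summaries of the artificial mutant genes reproduce
the documented arithmetic: the THCAS
mutant carries 19 non-synonymous and 6 synonymous changes (two SNPs share
codon 46 and jointly change one amino acid; two synonymous SNPs share
codon 288), hence 18 amino-acid changes and a non-synonymous/synonymous
ratio of 19/6 ≈ 3.2, with exactly the four substitutions at residues 90,
165, 250 and 255 graded high-impact and 10 of the 18 changes
moderate-or-high. The CBDAS design pins Leu51/Val52 over the deletion
span, an A→T change at position 583 creating a premature stop in codon
195, and the R136H and G182A substitutions reported as deleterious in the
literature (`provean_annotations()` stores those calls; structure-based
deleteriousness is not recomputed here).

Tunable generator parameters, with defaults chosen once:

| parameter | default | meaning |
|---|---|---|
| `background_mutation_rate` | 0.001/site | private per-sample variation, so every emitted sequence is unique |
| `het_rate` | 0.3 | fraction of a drug sample's background variants emitted as heterozygous IUPAC codes |
| `indel_discordance_rate` | 0 | probability a drug sample carries only one of the two indels |
| `het_at_markers` | `FALSE` | allow heterozygous calls at planted marker loci (to exercise the 0-point rule) |

Chemotype tables are drawn per variety uniformly within the class ranges
of the bundled reference measurements (`chemotype_reference()`): drug-type
mean THC on [2.08, 11.80] % of dry weight, fiber-type on [0, 0.31] %,
with standard deviations drawn as U(0.05, 0.4) fractions of the mean —
only ranges are documented for these quantities, so uniform draws are
the least-committal choice.

What the generator does **not** emulate: chromatogram noise and base-call
quality, PCR/primer artefacts, linkage beyond the planted class structure,
and population-genetic demography within classes. Passing tests therefore
demonstrate the correctness of the algorithms under the documented marker
structure, not performance on raw Sanger traces.

## Variant discovery

Each sample sequence is globally aligned to its gene's reference CDS
(Needleman–Wunsch with affine gaps via `Biostrings::pairwiseAlignment()`;
default scores match +2 / mismatch −3 / gap open −5 / gap extend −2, so a
contiguous 4-bp deletion is preferred over scattered mismatches). Calls
are reported in 1-based reference CDS coordinates: a deletion at its
first deleted base, an insertion at the base after which material is
inserted. Adjacent gap columns merge into single events and indels are
left-normalised (VCF-style rotation), which makes coordinates
deterministic inside repeats regardless of where the aligner placed the
gap. The deletion spanning 153–156 is canonically reported at 153; inputs
labelled at 154 (an alternative convention for the same event) refer to
the same span. An IUPAC ambiguity code at a SNP yields a heterozygous
call; `N` is treated as missing data. The genotype matrix is categorical:
SNP cells hold the sample allele symbol or `"ref"`, indel loci are
`"del"`/`"ins"` vs `"ref"`.

## The association scan

Each polymorphic locus is tested with Firth's penalized-likelihood
logistic regression of class on the locus coded as indicator contrasts
(heterozygous codes are categories of their own — Sanger genotypes are
unphased, so splitting them into haplotypes would fabricate information).
The Jeffreys-prior penalty $\tfrac12 \log\det I(\beta)$ keeps estimates
finite under complete separation, which is exactly what a perfectly
discriminating marker produces.

Two numerical choices matter:

* **Profile penalized LRT.** The per-locus p-value compares the maximized
  penalized log-likelihood against the maximum of the *same* objective
  with the locus coefficients constrained to zero. Penalizing the null
  model with its own (smaller) information determinant instead would mix
  penalty dimensions into the statistic: on perfectly balanced
  no-association data it yields p ≈ 0.6 where the answer should be 1.
  The profile form makes the statistic non-negative by construction; on
  null panels (n = 97, binary loci) its rejection rate at α = 0.05 is
  ≈ 4%, slightly conservative.
* **Damped Newton steps.** The Fisher information is not the exact Hessian
  of the penalized objective, so undamped Newton steps can cycle around
  the optimum; steps are halved until they either raise the objective or
  shrink the score norm (tolerance 10⁻⁸ on the maximum modified-score
  component, at most 50 iterations; non-convergence is an error, never a
  silent result).

Multiplicity is controlled by Benjamini–Hochberg applied jointly across
all tested loci of both genes — the stricter reading of "adjusted for
multiplicity" when the per-gene alternative is not specified. Monomorphic
loci are untestable and excluded before adjustment.

## The discriminant score

For the significant loci, each class's consensus (modal) allele defines a
three-way rule: a sample scores +1 at a locus matching the drug
consensus, −1 matching the fiber consensus, 0 otherwise (so an ambiguous
heterozygous call matching neither consensus is neutral). Ties in the
modal allele are broken by a fixed ordering (A < C < G < T < IUPAC codes
< del/ins < ref) with a warning. Indel loci contribute presence/absence
points with the weight carrying the sign; with the published-style
weights (+1.1 deletion, −1 insertion) the attainable scores are exactly
−1, 0, 0.1 and 1.1, and score > 0 classifies a sample as drug-type
(strict inequality).

`optimize_weights()` reconstructs score optimisation as a deterministic
procedure: greedy forward selection of loci by marginal AUC gain, with a
per-step coordinate ascent over a fixed weight grid (steps of 0.1 on
[−2, 2]) under the constraint that at most `allow_negative` weights are
negative. "Most weights non-negative" is operationalised as
⌊(k−1)/2⌋ negative weights allowed, with the k = 2 case admitting one
negative weight (the deletion/insertion pairing requires it, and "most"
is ambiguous at k = 2). Every score of interest (single-locus weights of
1, the 1.1/−1 indel pair) is exactly representable on the grid. Greedy
steps warm-start from the previous step's weights and 0 is on the grid,
so the achieved AUC is non-decreasing in k. Ties break toward the
earlier candidate and the current weight, making the result reproducible
for a given matrix order.

AUC is the Mann–Whitney probability that a random drug-class score
exceeds a random fiber-class score, ties counted one half — computed from
midranks and tested against exhaustive pair enumeration. Sensitivity and
specificity at a threshold get class-stratified percentile-bootstrap 95%
intervals (B = 2000 by default, seed mandatory); when a metric is
constant across resamples the interval degenerates to the point, and
intervals are clipped to contain the point estimate.

## Structure, entropy and chemotype

Gower distance over categorical loci is the mismatch fraction across
compared loci (pairwise exclusion of missing cells), delegated to
`cluster::daisy()`; classical MDS is `stats::cmdscale()` with a
deterministic sign convention (largest-magnitude loading positive per
axis). Variation is summarised by mean Shannon entropy (natural log by
default, base configurable): per-locus entropy of allele frequencies
averaged over loci, overall and within groups. "Between-group" variation
has no single standard definition; here it is defined as the mean
per-locus entropy of the group-consensus alleles, which is zero exactly
when all groups share the same consensus everywhere. Because of that
definitional freedom — and because entropy summaries depend on the
actual sequence panel analysed — published entropy values from real
panels are not reproduction targets here.

Chemotype arithmetic takes ratio = mean THC / mean CBD per variety
(ratio-of-means; a few reference rows are only consistent with per-plant
averaging, so checks use rows where both conventions agree), with the
zero-CBD convention ratio = 0 when THC is also 0 and ∞ otherwise. Groups
bin the ratio at 0.05, 0.2 and 10, boundaries belonging to the lower
group ("up to 0.05" / "more than 10"). On the bundled reference table
every fiber variety lands in groups 1–2 and every drug variety in 3–4.

## Protein consequences

Translation uses the standard genetic code and halts at the first
in-frame stop. A premature stop at codon index *s* is reported with the
convention that *s* is the "amino acids" figure of the truncated protein
(so the stop at CDS position 583 → codon 195 → "195 amino acids"); the
strict residues-before-stop count would be 194 — the convention matches the documented 583 → codon 195 → "195 amino
acids" arithmetic and is flagged here. Codons carrying several SNPs
are evaluated jointly: if the joint codon's amino acid changes, each SNP
in it counts as non-synonymous while the amino-acid change counts once.
Side-chain impact grading uses fixed, configurable classes — hydrophobic
{A,V,L,I,M,F,W,C}, polar {S,T,N,Q,Y,G}, charged {D,E,K,R,H}, ring/rigid
{F,W,Y,H,P} — with hydrophobic↔charged high impact and
hydrophobic↔polar or ring↔fluid moderate (graded symmetrically). Indels
of length not divisible by 3 set the frameshift flag; in-frame indels
never do.

## Problem sizes used in the checks

The bundled test-and-verification runs use a 97-plant panel (47 drug + 50
fiber, the plants of the study design) taken through the full
alignment-and-calling path, a 12-sample noise-free panel for exact
round-trip checks, and 200 replicate null panels of 200 binary loci at
n = 97 for the false-discovery-rate check (every rejection on a null
panel is false, so the mean false-discovery proportion estimates the FDR;
its Monte-Carlo standard error at 200 replicates is about 1.4 percentage
points). Bootstrap intervals in tests use a few hundred resamples; the
exported default stays at 2000.

## Known limitations

* Figures that depend on a particular real sequencing panel (total
  discovered SNP counts, entropy values, an indel-score AUC below 100%
  driven by discordant fiber samples) are properties of that panel and
  are not reproducible from synthetic data; the synthetic
  fiber class carries no drug-type indel pattern unless
  `indel_discordance_rate` is raised.
* The weight optimiser is a deterministic greedy/grid reconstruction,
  not a reimplementation of any specific published optimiser; with
  perfectly separating loci the optimum is flat and many weightings are
  equivalent.
* Consequence annotation assumes homozygous variants; heterozygous calls
  must be resolved (or phased) upstream.
* The aligner's gap placement in repeats is canonicalised by
  left-normalisation, but pathological alignments of very diverged
  sequences are not specially handled — the intended inputs are
  same-gene coding sequences a few percent diverged.
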