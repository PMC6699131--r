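---
title: "Identifying crop varieties from SNP fingerprints: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Identifying crop varieties from SNP fingerprints: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`varident` answers a deceptively simple question — *which variety is this
seed sample?* — for inbred crops genotyped on reduced-representation
platforms such as DArTSeq. This vignette explains the statistical machinery,
the parameters that matter, what the synthetic-data generator does and does
not emulate, and the places where the design was genuinely open and a choice
had to be made.

## Identity-by-state and its error model

All computation runs on a samples × markers matrix of biallelic genotype
calls coded as alternate-allele dosage (0, 1, 2, `NA`). For two samples the
per-locus score is the fraction of shared alleles, `1 - |d_i - d_j| / 2`:
identical homozygotes score 1, opposite homozygotes 0, a heterozygote
against either homozygote 0.5. IBS is the mean score over loci non-missing
in **both** samples (pairwise-complete loci). The denominator choice
matters under missingness and is logged per pair in `n_shared`; no
imputation is performed anywhere, because imputed calls would
systematically inflate similarity toward the major allele.

Two samples of the *same* variety still fall short of IBS = 1 because
genotyping is noisy. The package therefore calibrates what "identical"
means from technical replicates: the initial threshold is the arithmetic
mean of all within-replicate-group pairwise IBS values (pooled over pairs,
unweighted — with triplicates every group contributes three pairs, so
pooling and per-group averaging coincide up to group-size imbalance), and
the minimum threshold is the smallest such pair. With a per-allele error
rate *e*, a pair of independently re-genotyped copies disagrees at a locus
with probability `≈ 2 · 2e(1-e) · ½` in IBS units, so *e* = 0.001 puts the
expected threshold at 0.998 — exactly where the calibration lands in the
acceptance simulations (29 triplicate groups, 5203 markers).

## QC cascade

`apply_qc()` runs four stages in a fixed order: heterozygote recoding to
missing, marker missingness (`>= 0.20`, inclusive), sample missingness
(`>= 0.20`, computed on the surviving markers), and MAF (`< 0.01`, strict,
over non-missing calls of the surviving samples). Heterozygotes are recoded
because low-depth platforms call them unreliably in essentially fully
inbred wheat; a consequence worth knowing is that a single flipped allele
produces a heterozygous call, so recoding *absorbs* most simulated
single-allele errors and thresholds calibrated on cleaned data sit very
near 1. Thresholds meant to describe the raw platform error should be
calibrated on raw replicate calls.

The stage order is part of the contract, because it changes results: a
marker whose only minor alleles sit in a high-missingness sample survives
the marker stage, loses its carrier at the sample stage, and then falls at
the MAF stage. The test suite pins this behavior with hand-enumerated
fixtures. Running QC on its own output removes nothing (idempotence).

## The six decision rules

The published procedure is a list of assumptions, not a flow chart, and a
faithful implementation has to close several gaps. The package evaluates,
per field sample, candidates at the initial threshold first and relaxes to
the minimum threshold when unresolved:

1. **R1** — the candidates name exactly one variety with a single library
   entry.
2. **R2** — exactly one candidate name is backed by two or more mutually
   concordant library sources (concordance = pairwise IBS at or above the
   initial threshold: one identity notion package-wide). This covers both
   the single-name and the multi-name case.
3. **R3** — one candidate name, represented two or three times in the
   library with discordant profiles; the sample agrees with a subset, and
   the other source is presumed mislabeled.
4. **R4** — only names duplicated four or more times with mutually
   discordant profiles match; such sources are too uncertain, so the
   reported name is kept iff the same-reported-name field cohort is
   cohesive, else the sample falls to R6.
5. **R5** — nothing matches at either threshold but the cohort is
   cohesive: the variety is presumed absent from the library and the
   reported name is kept.
6. **R6** — nothing matches and the cohort is not cohesive: `UNKNOWN`.

Open points and the choices made: "highly identical among themselves"
(cohesion) is quantified as *every* within-cohort pair reaching the
**minimum** threshold, singletons cohesive by convention; the relaxation to
the minimum threshold re-runs the full R1–R3 cascade rather than only the
unique-match rule; names represented two *or three* times discordantly are
routed to R3 (the published text only mentions "twice", leaving three-fold
duplication unspecified, and four-fold and higher is R4's stated domain);
and ties between equally supported names get an explicit `ambiguous`
status rather than a silent tie-break, because an auditable wrong answer is
recoverable and a silent one is not. Assignments are a pure function of the
IBS matrix and metadata — shuffling sample order changes nothing.

Agreement with farmer reports normalizes names (trim, case-fold, optional
synonym table for spelling variants) and reports the misnamed fraction
among *determined* samples, with unknown/ambiguous counted separately.

## Library auditing

Reference libraries accumulate contradictions. `audit_library()` first
excludes entries with incomplete names or pedigrees and collapses exact
duplicates (same normalized name, pedigree, and concordant profile), then
counts two inconsistency classes: **A** — same name and pedigree, distinct
profiles (exempting landraces, whose within-name heterogeneity is
biological, and flagged breeding lines, where sister lines legitimately
share a pedigree); **B** — same profile (connected component of the
IBS-threshold graph), different name or pedigree. Components that are
chains rather than cliques are flagged, since profile identity is not
transitive at a fixed threshold. An entry satisfying both definitions is
counted once, under A, keeping the entry-level accounting disjoint. On
synthetic libraries with injected inconsistencies the audit recovers the
injected sets exactly.

## Ancestry model

The published analysis used an established sparse-NMF ancestry program
whose regularization details are not reproducible from the text; the
package therefore specifies a behaviorally equivalent simplified model.
Observed dosage fractions `Y` (0, ½, 1; missing masked) are approximated
as `Q G` with each row of `Q` on the probability simplex and `G` in
`[0, 1]`. Fitting alternates projected-gradient steps (exact Euclidean
simplex projection for `Q` rows; clipping for `G`) with per-step
backtracking, so the masked squared-error loss is non-increasing by
construction — a property the tests check iteration by iteration. Defaults:
5 random restarts (best by training loss), 200 iterations, relative
tolerance 1e-6, all driven by an explicit seed. K is chosen by masking 10%
of the non-missing entries, refitting, and scoring the held-out entries
with binomial cross-entropy (predictions clipped to `[1e-6, 1 - 1e-6]`, so
the criterion is always finite and positive); the chosen K is the smallest
whose relative improvement over K−1 drops below 1% — an operationalization
of the by-eye "plateau" judgement, with the number of restarts and mask
fraction set here since the original study does not report them. Group
calls use the strict `> 0.5` coefficient cut. For exact 50/50 mosaics this
cut is boundary-noisy by design — a mosaic's realized composition is
binomial around ½, and coefficients near 0.52 legitimately produce a group
call, as happened in the original survey too; validation therefore checks
that mosaic coefficients stay within 0.5 ± 0.1.

Ward clustering runs on the distance `1 − IBS` (the transform is not
stated in the source material; this one is the natural complement and, on
heterozygote-free data, equals squared Modified Rogers' distance) via the
minimum-variance criterion, checked against an independently coded
Lance–Williams agglomeration in the tests.

## Distances and diversity

Modified Rogers' distance is
`sqrt((1 / 2m) Σ_loci Σ_alleles (p_i − p_j)²)` over pairwise-complete loci,
a Euclidean distance — which is the point, because classical MDS (double
centering + eigendecomposition) then reconstructs it exactly at full rank.
Two identities tie the modules together and are tested at tight tolerance:
`MRD² = 1 − IBS` on heterozygote-free, missing-free data (1e-9), and
full-rank MDS reconstruction of any such MRD matrix (1e-6). Per-group
diversity uses expected heterozygosity `mean(2p(1−p))` (in `[0, 0.5]` for
biallelic loci), the Shannon index with natural log (the base is not
specified in the source material; `ln` keeps the biallelic maximum at
`ln 2`), and mean within-group MRD.

## What the generator emulates — and what it does not

The synthetic generator is the package's study stand-in, and its defaults
*are* the emulated study conditions: 5203 markers with population
alternate-allele frequencies Uniform(0.05, 0.95); fully homozygous variety
founders (the cleaned study data contain no heterozygotes, and this keeps
per-locus matching binary); per-allele error 0.001 (each of the two allele
calls flips independently, giving the closed-form `2e(1−e)` single-allele
discordance the calibration targets); 5% missing calls; ~1% heterozygote
miscalls; 8% of field samples as locus-wise 50/50 mosaics of two founders;
a 41.5% misreporting rate with wrong names drawn uniformly from the other
names plus a vague `LOCAL` label; 29 technical-replicate triplicate groups;
and configurable library pathologies (concordant duplicates, discordant
same-name sources, many-fold duplications, profile aliases, landraces
perturbed at 5% of loci per entry — the heterogeneity level is a free
parameter, since no quantitative model of landrace heterogeneity exists to
copy). All randomness flows from one seed; identical configs are
bit-identical.

What it deliberately does not model: linkage disequilibrium between markers
(marker independence makes IBS variance smaller than in real genomes),
pedigree relatedness between varieties (real elite lines share ancestry, so
real between-variety IBS is far higher than the ~0.5 of independent
founders — synthetic assignment is consequently *easier* than the real
task), platform-specific error that produces wrong homozygotes rather than
heterozygotes, and geographic or sampling structure. Passing the recovery
tests therefore demonstrates correctness of the machinery under the stated
noise model, not expected field accuracy on real germplasm.

## Scale, determinism, degenerate inputs

Validation runs at the study's marker dimension (5203) but reduced sample
counts (e.g. 200 field samples, 12 varieties for recovery; 45 samples for
K selection), sizes at which every check completes in seconds on one core
while preserving the quantities being measured. Degenerate inputs fail
loudly and early: unknown genotype tokens name their cell, ragged CSV rows
their row, all-removed QC stages their stage, undefined IBS pairs (zero
shared loci) are `NA` and rejected by clustering with the offending pairs
listed, and threshold calibration without replicates instructs the user to
supply thresholds manually. Profile-identity, concordance and cohesion all
reuse the two calibrated thresholds rather than introducing new knobs.

## Known limitations

Cohesion and concordance are threshold-sharp; samples sitting exactly at a
threshold flip classes under measurement noise. The R2 support notion (any
concordant pair among candidates) can in principle be satisfied by two
names simultaneously, which is surfaced as `ambiguous` rather than
resolved. The NMF ancestry model omits the sparsity regularization of the
original program, so coefficient *values* for admixed individuals are not
directly comparable, though group structure and K selection are. And the
misnamed-fraction estimate conditions on determined samples, so it inherits
any bias in which samples end up `UNKNOWN`.
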