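# varident

Variety identification from SNP fingerprints: who is actually growing what?

Farmer-reported variety names are unreliable — seed is saved, exchanged and
renamed, and surveys built on those names misestimate the adoption of
improved varieties. `varident` identifies the variety in each field-collected
seed sample by matching its genotyping-by-sequencing SNP profile
(DArTSeq-style biallelic calls) against a curated reference library, with an
explicit, auditable decision procedure instead of an ad-hoc best-hit match.
It is aimed at breeders, genebank curators and adoption-survey teams working
with inbred crops such as bread wheat.

## The method

Identity between two samples *i*, *j* is **identity-by-state**,

```
IBS_ij = (1 / n) * sum_x  s(allele_ix, allele_jx)
```

the mean over the `n` SNP loci non-missing in both samples of the per-locus
fraction of shared alleles (identical homozygotes 1, opposite homozygotes 0,
heterozygote vs homozygote 0.5). Because genotyping is noisy, "identical" is
calibrated from **technical replicates**: the same DNA genotyped repeatedly.
The *initial threshold* is the mean within-replicate-group pairwise IBS and
the *minimum threshold* is the smallest such value.

Each field sample is then classified by six rules applied in order, first at
the initial and then at the relaxed minimum threshold: unique-match
identification (R1), identification backed by concordant duplicate library
sources (R2), match to one of a pair of discordant same-name sources (R3),
retention of the reported name when only untrustworthy many-fold-duplicated
references match (R4) or when nothing matches but the same-named field
samples are mutually identical (R5), and `UNKNOWN` otherwise (R6). Ties
between equally supported names are flagged `ambiguous` rather than broken
silently.

Around this core the package provides: QC filtering (heterozygote recoding,
missingness, MAF), reference-library deduplication and consistency auditing
(same name/pedigree with distinct profiles; same profile with distinct
names), Ward clustering on `1 - IBS`, a simplex-constrained NMF ancestry
model with masked cross-entropy selection of the number of groups K and a
`> 0.5` coefficient rule for group calls, Modified Rogers' distance with
classical MDS, per-group diversity indices (expected heterozygosity, Shannon
index, mean within-group MRD), and a synthetic-data generator with ground
truth for end-to-end validation.

## Worked example

A synthetic survey: 8 varieties, 100 field samples at the generator defaults
(5203 markers, per-allele error 0.001, 5% missing calls, 8% admixed samples,
41.5% misreported names), with 8 replicate triplicate groups.

```r
library(varident)

cfg <- sim_config(n_field_samples = 100, n_varieties = 8,
                  n_replicate_groups = 8, seed = 42)
lib  <- generate_reference_library(cfg)
fld  <- generate_field_samples(lib, cfg)
reps <- generate_technical_replicates(lib, n_groups = 8, copies_per_group = 3,
                                      error_rate = 0.001, seed = 43)

# calibrate identity thresholds from the raw replicate calls
thr <- calibrate_thresholds(compute_ibs_matrix(reps$genotypes), reps$records)
thr
#> <identity_thresholds> initial 0.9982, minimum 0.9975 (from 24 replicate pairs)

# clean, compute IBS, assign
g <- geno_matrix(rbind(unclass(lib$genotypes), unclass(fld$genotypes)))
records <- dplyr::bind_rows(lib$records, fld$records)
qc  <- apply_qc(g)
qc$report
#> <qc_report> 5861 heterozygous calls recoded to missing
#>   marker_missingness   markers: 5203 -> 5203 (removed 0)
#>   sample_missingness   samples: 108 -> 108 (removed 0)
#>   maf                  markers: 5203 -> 4387 (removed 816)
#>   final: 108 samples x 4387 markers

ibs <- compute_ibs_matrix(qc$genotypes)
asg <- apply_decision_rules(ibs, records, thr)
dplyr::count(asg, status, rule)
#>   status      rule     n
#> 1 identified     1    92
#> 2 unknown        6     8

compare_with_reported(asg, records)
#> <agreement_report> 100 samples: 51 correctly named (51.0%), 41 misnamed, 8 undetermined
```

The replicate-calibrated initial threshold lands at 0.998: with a per-allele
error of 0.001 each replicate pair disagrees at about 0.2% of allele calls.
All 92 non-admixed samples are identified by rule 1 (every variety has a
single, concordant library entry here); the 8 locus-wise 50/50 mosaics match
nothing above the minimum threshold and are declared `UNKNOWN`. Of the
identified samples, 51 carried the correct farmer-reported name — the
generator misreported 41.5% of names, and `fraction_misnamed` recovers
0.446. Results are tibbles throughout, so they pipe into dplyr/ggplot2;
`autoplot()` methods cover the IBS matrix, ancestry fits, cross-entropy
curves, MDS coordinates and agreement flows, and `tidy()`/`glance()` methods
cover the fitted objects.

`run_pipeline(pipeline_config(...))` chains
simulate → qc → ibs → thresholds → assign → audit → cluster → diversity and
writes every stage artifact (CSV/JSON/Newick) with a manifest.

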