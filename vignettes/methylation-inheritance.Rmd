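---
title: "Allele-specific methylation inheritance from bisulfite amplicons: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific methylation inheritance from bisulfite amplicons: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methcross)
library(dplyr)
```

## The problem

Nuclear insertions of mitochondrial DNA (NUMTs) in *Arabidopsis thaliana* can
be differentially methylated between strains. Crossing two strains (Columbia,
"Col", and Landsberg *erecta*, "Ler") and following two short NUMT amplicons
through parents, reciprocal F1 hybrids and selfed F2 populations asks how a
methylation state is inherited, diversified, and coupled between the two
homologous alleles that now share a nucleus. Because the two haplotypes differ
at a handful of SNPs inside each amplicon, deep bisulfite amplicon sequencing
can quantify each allele separately in every individual.

`methcross` implements this analysis end to end, together with a seeded
bisulfite read simulator that reproduces the full cross design with known
ground truth. The simulator is first-class, tested code: it is the substrate
on which every statistical property of the pipeline is verified.

## The analysis model

**Single-strand convention.** An amplicon is analysed on its top strand only.
Every cytosine on that strand is assigned a context from the two downstream
bases — `G` at +1 gives CpG, otherwise `G` at +2 gives CpHpG, else CpHpH
(H one of A, T, C). Cytosines within two bases of the 3' end are resolved
through a configured 3' flank; without one they are dropped with a warning
(an explicit policy choice: the amplicon boundary truncates context
information, and silently guessing a context would bias the CpHpH class).
Opposite-strand cytosines (G positions) are ignored; simulator and caller
share the convention, so no information is lost end to end.

**Allele discrimination.** The two haplotypes must be indel-free (true of
both study regions); every substitution is a candidate SNP. Bisulfite
chemistry collapses part of the base space: an unmethylated C reads as T, so
a reference C can legitimately appear as C or T. A SNP is *informative* only
if the possible read-base sets of the two alleles are disjoint under every
methylation state — a C/T SNP, for instance, is useless because the Col C
may read as T. Reads are matched ungapped at their primer-fixed offsets
(mate 1 anchored 5', mate 2 reverse-complemented and anchored 3'), counting
bisulfite-space mismatches (ref C vs read C/T is a match). A mate votes for
the allele with the strictly smaller mismatch count if that count is at most
`max_mismatch` (default 5 per 150-mer, about 3%; no threshold is prescribed
by the protocol this reimplements, so a value near sequencer error ceilings
was fixed once) and the mate covers at least one informative SNP; ties or
uninformative placements are ambiguous. Conflicting mates make the pair
ambiguous; ambiguous and unmapped pairs never reach genotyping or
quantification. The choice of ungapped fixed-offset matching over a general
aligner is deliberate: amplicons are primer-defined, so offsets are known,
mismatch counts are exact, and the pipeline carries no aligner dependence.

**Mapping-error rule and genotyping.** Within an individual and region, if
the minor allele holds strictly less than 5% of mapped pairs, those pairs
are treated as mapping error and discarded; exactly 5% is retained. The rule
is applied per individual x region pair. Individuals with both alleles at
or above 5% are heterozygous (CL); otherwise homozygous for the majority
allele. F2 genotype counts are tested against the Mendelian 1:2:1
expectation with a Pearson chi-square (df = 2, no continuity correction).

**Methylation estimators.** For sites shared by both alleles (identical
position and context, SNP-overlapping positions excluded), each read
observation of C increments the methylated count $C_i$ and T the
unmethylated count $T_i$; A/G observations are sequencing errors and are
tallied separately, never imputed. Overlapping mate bases are counted once
(mate 1 takes precedence). Two estimators are computed, and they are *not*
interchangeable:

* weighted level $M_w = \sum_i C_i \big/ \sum_i (C_i + T_i)$ per individual,
  allele and motif — the coverage-weighted statistic used throughout the
  cross analysis;
* fractional level, the unweighted mean of per-site ratios
  $C_i/(C_i{+}T_i)$ — used only for the region-level wild-type/mutant
  comparison from external per-site tables.

They coincide exactly under uniform coverage (a tested invariant).
Zero-coverage cells are flagged undefined and excluded from summaries;
zero-coverage sites are silently excluded from fractional means (the
upstream protocol does not state a policy; exclusion is the neutral choice
for a ratio estimator). Motif labels always come from the reference
context — a conversion-distorted read cannot re-derive its own context.

**Population statistics.** Reciprocal F1 (and F2, grouped by cross
direction) level distributions are compared per region x allele x motif
with a two-sided rank-sum test (midranks, normal approximation); crosses
are treated as poolable when no cell rejects at p < 0.001. A rank-sum test
was chosen because the question is a difference of *distributions* with no
parametric form; no multiplicity correction is applied across cells and the
raw p-values are reported. Population summaries report median, mean and
sample s.d. (n-1); single-individual cells leave s.d. blank. In F2
heterozygotes only — the generation where both alleles segregate within a
shared nuclear environment — Spearman's rho between the Col and Ler levels
is computed per motif with an OLS regression of Ler on Col (slope, its 95%
interval, and pointwise 95% confidence bounds of the line). Spearman was
chosen as the reported correlation statistic; OLS (not total least squares)
for the line, matching the regression-of-one-allele-on-the-other framing.
F1 heterozygotes are excluded: mixing generations with different class
means would manufacture correlation.

## The simulator

The generator emulates the study design exactly: 2 + 2 parents, reciprocal
F1 of 18 and 19, four selfed F2 populations of 30, 28, 30 and 30 — 159
individuals, two amplicons each. Parents are homozygous, F1 all CL, each F2
individual i.i.d. CC/CL/LL at (0.25, 0.5, 0.25).

Per individual and allele, a methylation level per region and motif is drawn
from a beta law whose mean and s.d. are the published population summaries
of the corresponding population class (parents, F1, and F2 split by
genotype). Parental dispersions are unpublished (n = 2 prints no s.d.), so a
small within-strain spread is assumed: s.d. 0.02, or 0.005 where the mean is
0.01. For heterozygotes the two allele draws are coupled by a Gaussian
copula; because beta quantile transforms are monotone, setting the latent
correlation to $2\sin(\pi\rho/6)$ makes the *Spearman* correlation of the
pair equal the target `rho` exactly. Region 1 uses the reported per-motif
correlations (0.57, 0.75, 0.97); region 2's coupling is unreported and is
fixed at a moderate 0.5. Within an individual, every site of a motif shares
the individual's level, and the methylation state is drawn independently per
read and site — no molecule-level epihaplotype structure. The weighted
estimator aggregates counts, so it is insensitive to within-molecule
correlation; nothing downstream could detect that structure anyway.

Chemistry is modelled with two separate knobs so tests can isolate each:
conversion efficiency (unmethylated C reads T with probability 0.99 by
default; failures inflate apparent methylation by ~1%) and methylated
protection (methylated C reads C with probability 1 by default). Uniform
substitution errors at 0.001 per base follow, at Q12 against a Q37 baseline
so the quality trimmer has something to act on. Fragments cover the whole
amplicon; 150-base mates are cut from both ends (mate 2 stored as
sequenced, i.e. reverse-complemented), truncated with a warning when the
amplicon is shorter, as for the 133 bp region. The default coverage of
50,000 fragments per individual and region mirrors the study's depth
(every individual above 40,000 mapped reads); tests and the bundled
analyses run at a few hundred, which already pins level estimates to within
a few percent.

**What the simulator does not emulate.** PCR chimeras and index hopping,
strand mixtures (top-strand fragments only), within-molecule methylation
correlation, coverage heterogeneity along the amplicon, and quality decay
profiles (qualities are flat except at injected errors). Passing tests
therefore certify the estimators and decision rules under clean binomial
sampling, not robustness to library artefacts.

**Synthetic reference amplicons.** The study's haplotype sequences live in
supplementary material and its reads are not deposited, so the package
ships deterministic *synthetic* amplicons (`synthetic_references()`,
`inst/extdata/synthetic_amplicons.fasta`) assembled from short motif tokens
so that the shared-site census (region 1: 2 CpG / 5 CpHpG / 23 CpHpH;
region 2: 10 CpG / 6 CpHpG / 33 CpHpH), the informative SNP counts (4 and
2, all A/G), the lengths (133 and 201 bp) and the genomic windows
(Chr3:16574335..16574467, Chr4:6341088..6341288) match the study design.
The base sequences themselves are not the genomic sequences; any analysis
of the real regions should load the real haplotypes via
`read_allele_fasta()`.

## Numerical choices and degenerate inputs

* Coordinates are 1-based inclusive throughout.
* Beta shapes come from method-of-moments; `sd = 0` is a point mass, and
  `sd^2 >= mean*(1-mean)` is a configuration error, not a silent clamp.
* The chi-square test is the plain Pearson statistic against expected
  counts; at n = 30 it is mildly conservative (type-I rate ~0.042 at
  nominal 0.05), which the calibration test measures with 50,000 simulated
  populations so that Monte-Carlo noise (3 sigma ~0.003) is small against
  the documented band.
* Rank statistics use midranks; `wilcox.test`/`cor.test` run with
  `exact = FALSE` so ties are handled uniformly.
* Constant level vectors make Spearman undefined: flagged `NA` with a
  warning, never coerced.
* Reads longer than the reference span are an error in
  `bisulfite_mismatches()` and an `Inf` (never matching) during assignment;
  zero mapped pairs flags the individual `qc_failed` rather than producing
  0/0 levels.
* Every simulation entry point takes an explicit seed; the pipeline derives
  stage seeds as `seed`, `seed+1`, `seed+2`, and the whole
  simulate-to-FASTQ-to-tables path is byte-deterministic (tested via MD5 on
  a full 159-individual run at coverage 60).

## Problem sizes used by the test-suite and bundled analyses

The estimator and calibration checks run at sizes chosen so that binomial or
Monte-Carlo error is far inside each asserted band: ~10^5 site observations
for the conversion-rate recovery, 50,000 simulated F2 populations for the
chi-square calibration, 200 replicates of 60 heterozygotes for Spearman
recovery (mean within 0.05 of truth), 1,000 replicates for the null
rejection rate, and the full 159-individual design at coverage 60-200 for
the end-to-end determinism, accounting and headline-quantity runs. At
coverage 200 the per-motif coverage of the rarest cell (2 CpG sites, ~400
observations) bounds its binomial s.e. near 0.025, well under the
population-level spreads being summarised.

## Known limitations

* Indels between haplotypes are unsupported (an error); the model is
  substitution-only, as the study regions are.
* The mapping-error rule and genotype threshold share the same 5% constant;
  individuals with true minor-allele frequencies near 5% oscillate between
  CL and homozygous calls — at study coverages the binomial width at 5% is
  ~0.3%, so this only matters for contamination-like inputs.
* `ingest_sitetable()` is a generic TSV ingester; it does not download or
  parse any repository format beyond the documented five columns.
* The package quantifies and correlates; it does not infer mechanism
  (RdDM involvement, paramutation) from the patterns it reports.
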