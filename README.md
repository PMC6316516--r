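# methcross

Allele-specific DNA methylation inheritance from bisulfite amplicon
sequencing of an *Arabidopsis thaliana* Col × Ler cross.

Short nuclear insertions of mitochondrial DNA (NUMTs) can be differentially
methylated between strains. Deep bisulfite amplicon sequencing of such a
region across parents, reciprocal F1 hybrids and selfed F2 populations —
with the two haplotypes told apart by SNPs inside the amplicon — lets each
allele's methylation be followed separately through the cross: how it is
inherited, how it diversifies, and how strongly the two homologous alleles
are coupled once they share a nucleus.

`methcross` is a tidyverse-style R package for that analysis, aimed at
plant epigenomics groups running allele-resolved bisulfite amplicon
experiments (and at anyone who wants a fully simulated, ground-truthed
replica of such an experiment). It provides:

* **Reference model** — cytosine context classification (CpG / CpHpG /
  CpHpH from the two downstream bases, top strand), SNP discovery with a
  bisulfite-aware informativeness rule (a reference C may read as C or T,
  so e.g. C/T SNPs cannot distinguish alleles), and selection of the
  cytosine sites shared by both alleles.
* **Read simulator** — the full cross design (2+2 parents, reciprocal F1 of
  18/19, four selfed F2 of 30/28/30/30), beta-distributed individual
  methylation levels per population class, Gaussian-copula coupling of
  heterozygote alleles with a target Spearman ρ, bisulfite conversion
  efficiency, methylated-C protection, sequencing error, paired 150-base
  FASTQ output, and a complete ground-truth table.
* **Read processing** — trailing-quality trimming, ungapped bisulfite-space
  matching at primer-fixed offsets, per-mate allele voting, the 5 %
  mapping-error rule.
* **Quantification** — per-site methylated/unmethylated counts at shared
  sites; the weighted level `M_w = Σ C_i / Σ (C_i + T_i)` per individual ×
  allele × motif; the fractional (per-site mean) level for region-level
  wild-type/mutant comparisons from external per-site TSVs.
* **Inheritance statistics** — genotype calls (CC/CL/LL), Pearson χ² tests
  of 1:2:1 F2 segregation, rank-sum comparison of reciprocal crosses
  (merge when p ≥ 0.001), population medians/means/s.d., and Spearman ρ
  with OLS regression (plus 95 % bounds) between Col and Ler allele levels
  in F2 heterozygotes.

Results are tibbles; fitted correlation objects have `tidy()`, `glance()`
and `autoplot()` methods, and `plot_population_levels()` draws the
per-population boxplot view.

## Worked example

Simulate the full 159-individual cross at a desk-scale coverage of 200
fragments per individual and region, then analyse it:

```r
library(methcross)
library(dplyr)

cfg <- pipeline_config(seed = 42, coverage = 200)
sim <- simulate_cross(cfg)            # pedigree + truth + reads
res <- analyze_reads(sim$reads, cfg)
res
#> methcross analysis: 159 individuals, 63544 read pairs
#>   mapped Col/Ler: 30391 / 33137 ; ambiguous: 16 ; unmapped: 0 ; mapping-error discarded: 0

res$segregation |> filter(region_id == "region1")
#>   population   region_id  n_cc  n_cl  n_ll     n statistic    df p_value
#> 1 F2-ColxLer-2 region1      11    11     8    30     2.73      2   0.255
#> 2 F2-ColxLer-4 region1       8    13     7    28     0.214     2   0.898
#> 3 F2-LerxCol-3 region1       5    16     9    30     1.2       2   0.549
#> 4 F2-LerxCol-4 region1       6    12    12    30     3.6       2   0.165

tidy(res$correlation$region1)
#>   motif n_het   rho  p_value slope intercept slope_low slope_high
#> 1 CpG      52 0.724 1.30e- 9 1.07   -0.379       0.761      1.38
#> 2 CpHpG    52 0.687 1.85e- 8 0.709  -0.0298      0.504      0.913
#> 3 CpHpH    52 0.974 4.55e-34 1.01   -0.00923     0.934      1.08
```

Every F2 population is compatible with 1:2:1 segregation, and the Col and
Ler allele levels of the F2 heterozygotes are strongly, positively coupled
— most tightly for CpHpH — mirroring the trans-allelic coupling the
generator encodes. `autoplot(res$correlation$region1)` draws the per-motif
scatter with the fitted line and its 95 % bounds;
`plot_population_levels(res$levels)` shows the population-level
diversification. `summarize_population(res$levels)` (also in
`res$summary`) is the medians/means/s.d. table per population × allele ×
motif.

The same run on disk, via FASTQ files and TSV outputs:

```r
simulate_dataset(cfg, "sim_out")                  # per-individual FASTQ + truth
res <- analyze_dataset(cfg, "sim_out", "results") # TSV tables + manifest
```

## Notes on the bundled references

The amplicon haplotypes shipped with the package
(`synthetic_references()`, `inst/extdata/synthetic_amplicons.fasta`) are
*synthetic* stand-ins, designed so that their shared-site context counts
(2/5/23 and 10/6/33), informative SNP counts (4 and 2), lengths (133 and
201 bp) and genomic windows match the study design they emulate. To analyse
real data, load the real haplotypes with `read_allele_fasta()` (records
named `<region>|<allele>`).
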