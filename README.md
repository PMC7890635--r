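# xciscape

Cross-species calling of X-chromosome inactivation (XCI) status for
X-linked genes, from allelic expression and promoter CpG-island DNA
methylation, with conservation, escape-domain, feature-enrichment and
species-clustering analyses — plus a synthetic multi-species cohort
generator with known ground truth that makes the whole pipeline testable
without any data downloads.

## Who this is for

In XX cells one X chromosome is silenced for dosage compensation, but a
minority of genes *escape* silencing and others *variably escape* between
samples. Which genes escape differs between species (mouse is a notable
outlier), matters for sex-biased traits and disease, and is hard to
measure: allelic expression needs rare skewed samples, and methylation
data come in incompatible flavours (WGBS, RRBS, 450k arrays). xciscape is
for researchers who want reproducible, threshold-explicit XCI status
calls from such data and principled cross-species comparison of the
results.

## The models at the core

**Allelic caller.** With `x` inactive-X (Xi) reads out of `n = x_Xi +
x_Xa` at a SNP, escape is defined as Xi/Xa expression ≥ 0.1, i.e. a read
fraction above `p0 = 0.1/1.1 ≈ 0.0909`. The exact two-sided
Clopper–Pearson interval at α = 0.05,

    [ qbeta(α/2, x, n−x+1),  qbeta(1−α/2, x+1, n−x) ],

decides the call: lower bound above `p0` → escape, upper bound below →
subject, interval crossing → no call. SNPs need depth ≥ 30; samples must
show skewed Xi choice (majority of genes with Xi/Xa < 0.1).

**Methylation caller.** Mean methylation of the CpG island within 2 kb of
the TSS, per female sample: < 10% escape, 10–15% uncallable, 15–60%
subject, > 60% hypermethylated (uninformative). Islands methylated in
over half of males (≥ 15%) are discarded.

**Both callers**: a gene with at least 33% of informative samples in each
state is `variable_escape`; otherwise the majority status.

**Downstream**: gene-symbol matching across species (case-insensitive);
conservation categories over 4+ informative species with a 2-vs-2 rule
for frequent discordance; escape-ish/subject transition detection against
TAD boundaries; Welch t-tests with per-species Benjamini–Hochberg
correction (significant at adjusted p < 0.01) for repeat, CTCF-bin and
ATAC female/male enrichment; Gower distance + complete linkage for
species clustering with the escape = 0 / variable = 0.5 / subject = 1
encoding.

## A worked example

```r
library(xciscape)
library(dplyr)

pipe <- run_xci_pipeline(sim = sim_config(seed = 1))
pipe
#> XCI pipeline run
#>   datasets     : 9
#>   genes merged : 300
#>   clade_a      : 96.5% conserved over 200 genes
#>   all_species  : 85.0% conserved over 300 genes
#>   transitions  : 37 (16 near TAD boundaries)
#>   domains      : 2 discordant
```

One simulated cohort: 8 species (two clades of four, the eighth a
mouse-like outlier with few escape genes), 300 genes, 4 female + 4 male
methylation samples each, allelic counts for the first species. The two
"discordant domains" are the planted clade-private escape domains, and
both are recovered:

```r
pipe$domains
#> # A tibble: 2 × 6
#>   domain chrom      start      end n_genes genes
#>    <int> <chr>      <int>    <int>   <int> <chr>
#> 1      1 chrXsim  2500000  2820000       4 GENE025,GENE026,GENE027,GENE028
#> 2      2 chrXsim 21300000 21620000       4 GENE213,GENE214,GENE215,GENE216
```

Per-dataset composition and feature enrichment come through broom-style
verbs:

```r
glance(pipe$calls$species01_meth)
#>   n_genes n_called fraction_escape fraction_variable fraction_subject
#> 1     300      270           0.174            0.0185            0.807

tidy(pipe$enrichment) |>
  filter(species == "species01",
         feature %in% c("LINE", "LTR", "ctcf_bins", "atac_fm")) |>
  select(feature, mean_escape, mean_subject, statistic, p_adj, significant)
#>   feature   mean_escape mean_subject statistic    p_adj significant
#> 1 LINE             5.45         9.97    -10.3  6.61e-16 TRUE
#> 2 LTR              9.15         5.03      7.44 1.30e- 9 TRUE
#> 3 ctcf_bins       26.7          6.31     23.5  1.15e-27 TRUE
#> 4 atac_fm          1.97         1.00     13.6  1.41e-17 TRUE
```

Read: genes subject to XCI carry about twice the LINE density within
15 kb of their islands (9.97 vs 5.45 per gene), while escape genes are
enriched for LTRs, predicted CTCF-bound bins near the TSS and a ~2×
female/male ATAC signal — exactly the differentials the generator
planted, each detected at adjusted p ≪ 0.01. `autoplot()` methods exist
for call tables, enrichment results and the species dendrogram, and
`write_call_table()` / `read_call_table()` round-trip the calls as TSV.

Individual stages are plain functions on tibbles (`call_snps()`,
`assess_skew()`, `call_genes_allelic()`, `island_methylation()`,
`call_genes_methylation()`, `merge_calls()`, `classify_conservation()`,
`detect_transitions()`, `find_discordant_domains()`, `test_enrichment()`,
`cluster_species()`, ...) and compose with the pipe; see the vignette in
`vignettes/xci-status-calling.Rmd` for the full model description.

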