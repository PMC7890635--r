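---
title: "Calling X-chromosome inactivation status across species"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling X-chromosome inactivation status across species}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(xciscape)
library(dplyr)
```

## The problem

In eutherian females one of the two X chromosomes is epigenetically
silenced (X-chromosome inactivation, XCI) to balance dosage with XY males.
Silencing is incomplete: a minority of X-linked genes *escape* XCI and stay
expressed from the inactive X (Xi), others *variably escape*, differing
between individuals, tissues or samples. xciscape infers the XCI status of
X-linked genes from two independent data types, compares the calls across
species, and asks which genomic features travel with escape.

## The two calling models

### Allelic expression

In a sample with skewed Xi choice (most cells silenced the same X), reads
at heterozygous SNPs can be assigned to the inactive (Xi) or active (Xa)
allele. A gene escapes when its Xi expression reaches at least 10% of Xa
expression. With $x$ Xi reads out of $n = x_{Xi} + x_{Xa}$ total, the Xi/Xa
ratio threshold $\tau = 0.1$ maps onto the read-fraction scale as

$$p_0 = \frac{\tau}{1+\tau} = \frac{0.1}{1.1} \approx 0.0909,$$

because $x_{Xi}/x_{Xa} = 0.1 \iff x_{Xi}/n = 1/11$. `call_snps()` computes
the exact two-sided Clopper–Pearson interval for $x/n$ at $\alpha = 0.05$
and calls escape when the lower bound clears $p_0$, subject when the upper
bound stays below it, and no call when the interval crosses the threshold.
The exact interval matters because Xi read counts at silenced genes are
very small; at typical depths an approximate interval would under-cover
near $x = 0$. SNPs need 30 or more reads (and quality 30 when provided)
before testing.

Why the Clopper–Pearson interval specifically: the calling rule is a
binomial test of the read proportion, and among exact intervals
Clopper–Pearson guarantees two-sided coverage at every $(x, n)$, which
keeps the advertised error rate conservative for the low-count regime. The
test suite verifies exhaustively (all $x \le n \le 200$) that the calls
agree with an independently computed interval, and that the simulated
false-escape rate at $p = p_0$ stays within $\alpha/2$.

Per sample, a gene's call is the majority status among its called SNPs,
with ties uninformative; the per-sample rule is a design choice (the
per-SNP model does not dictate one), and a pooled-counts alternative —
summing Xi and Xa reads across a sample's SNPs into one test — is
available via `pool_snps = TRUE`. Sample skewing itself is assessed by
`assess_skew()`: a sample qualifies when a strict majority of its genes
have a mean Xi/Xa ratio below 0.1 (the cutoff is configurable; "majority"
has no canonical numeric value).

### Promoter CpG-island methylation

Methylation does not need skewed samples. On the X, promoter CpG islands
of silenced genes are methylated on the Xi only, so female island
methylation sits near intermediate levels while males stay low.
`island_methylation()` averages per-CpG methylation fractions inside each
island (unweighted — coverage weighting is a deliberate non-choice since
the assays differ wildly in depth profile), `match_island_to_tss()`
annotates islands to genes when the nearest island edge lies within 2 kb
of a TSS, and each female sample's island mean is classified by
`classify_island_methylation()`:

* below 10% — escape;
* 10–15% — uncallable (a buffer zone that absorbs most borderline
  miscalls);
* 15–60% — subject;
* above 60% — hypermethylated, treated as uninformative rather than
  subject.

Boundary placement is left-closed at 0.10 and 0.15 with 0.60 included in
subject; the four classes partition $[0,1]$ exactly, and a property test
pins the boundaries so any revision is a single constant. Islands where
more than half of informative males are at or above 15% are discarded
(`male_hypermethylation_filter()`): a promoter methylated on the active X
can never reveal escape. When a species ships no male samples the filter
cannot run; calls are made anyway and flagged
(`male_filter_applied = FALSE`), since down-weighting them further has no
principled scale.

Gene-level aggregation uses the same variable-escape rule in both callers:
with $f$ the escape fraction among informative samples, a gene is variably
escaping when $\min(f, 1-f) \ge 1/3$ (at least 33% of informative samples
with each status), otherwise the majority status wins. The 33% constant is
deliberately strict; `xci_thresholds(variable_frac = 0.10)` reproduces the
permissive variant.

450k-style array data enter through `read_probe_table()` and
`probe_island_methylation()`: promoter-associated probes sharing an
annotated island are averaged per sample, missing betas excluded and never
imputed. The accepted promoter-annotation vocabulary is configurable
because array manifests disagree on it.

## Cross-species analysis

`merge_calls()` joins per-dataset call tables by gene symbol, matching
case-insensitively (mouse `Kdm6a` = human `KDM6A`) — symbol identity is
the only orthology used. `classify_conservation()` works within a species
group (`xci_group()`), taking one dataset per species by priority order,
and requires 4+ informative species before classifying:

* all informative species escape / subject — conserved;
* at least 2 species escaping and at least 2 subject — frequently
  discordant (`discordant_multi`);
* exactly one minority species — `discordant_single`;
* otherwise `mixed_variable` (variable cells count as informative but as
  neither pole).

`summarize_conservation()` reports the conserved fraction and the splits
by usual status (a gene is "usually subject" when more than 75% of its
informative species are subject). `detect_transitions()` collapses
statuses to escape-ish (escape or variable) versus subject along the
chromosome and marks transitions whose interval contains a TAD boundary —
using the gene-annotation rule (boundary between the two genes or inside
either gene body), not a fixed window. `find_discordant_domains()` reports
maximal runs of 2+ adjacent frequently discordant genes, the signature of
domain-level control of escape.

For clustering, calls are encoded escape = 0, variable = 0.5, subject = 1
(`encode_calls()`); `gower_distance()` averages absolute differences over
genes observed in both species of a pair (pairwise deletion, unit range),
and `cluster_species()` applies complete linkage, with ties broken by
sorting species names so the dendrogram is reproducible. The triangle
inequality is deliberately not asserted for Gower with pairwise deletion.

## Feature enrichment

`count_repeats()` counts repeat elements per class within 15 kb of the
CpG island (default) or the strand-aware 15 kb upstream of the TSS — both
windows are in circulation and both modes are provided; any overlap
counts. `count_ctcf_bins()` counts 200-bp predicted CTCF-binding bins with
probability strictly over 50% within 4 kb of the TSS (the probability
track is an input; bins are consumed as provided), and
`region_ctcf_profile()` applies the same rule to arbitrary intervals.
`atac_fm_ratio()` averages per-sample ATAC coverage within 250 bp of the
TSS, then divides the female mean by the male mean; genes with a zero male
mean are excluded with a reason instead of producing infinities.
`island_characteristics()` computes island length, GC fraction and the
Gardiner–Garden CpG observed/expected ratio
$\mathrm{o/e} = \#CG \cdot L / (\#C \cdot \#G)$.

`test_enrichment()` compares escape against subject genes per species and
feature with Welch's unequal-variance t-test — escape groups are small
and more variable than subject groups, so pooled-variance assumptions are
unsafe — excluding variably escaping genes. Benjamini–Hochberg adjustment
is applied across all testable features within one species (the family
scope is a design choice; per-species families match how per-species
significance is reported), and significance means adjusted p below 0.01.

## The synthetic cohort generator

No public multi-species benchmark with known XCI truth exists, so
`simulate_xci_cohort()` generates one. It emulates the reported
statistical structure of real cohorts, and its defaults are the package's
study conditions — they are set once, from the field's reported values,
and are not tuning knobs:

* one synthetic chromosome (`chrXsim`), 300 genes spaced 100 kb apart,
  each with a 1 kb CpG island at the TSS (20 CpGs, 50 bp spacing);
* 8 species: two clades of four, the last species a mouse-like outlier;
* 12% of genes escape in the shared core, clustered into domains of 4
  adjacent genes; 5% variably escape (a per-sample coin flip, matching the
  sample-level definition of variable escape); two further escape domains
  are private to the first clade, planting known cross-species
  discordance; the mouse-like species keeps only ~5% escape;
* female island means are Beta-distributed around 0.38 at subject genes
  (0.27 in the mouse-like species), 0.05 at escape genes; males sit at
  0.03; 10% of islands are hypermethylated (mean 0.80 in both sexes) —
  drawn outside the planted domains so the planted structure stays
  identifiable; per-CpG observed fractions are binomial draws given
  Poisson coverage (mean 30), matching the count nature of bisulfite data;
* assay degradation: WGBS keeps everything, RRBS keeps a random ~15% of
  CpGs per sample (a different subset per sample), the 450k-style array
  keeps one fixed ~10% position subset shared by all samples;
* allelic counts for the first species: 5 skewed samples, 2 SNPs per
  gene, Poisson depth (mean 100), Xi-read fractions 0.25 (escape) and 0.01
  (subject);
* repeats are Poisson-placed in the 15 kb island windows with LINE 2×
  enriched at subject genes and LTR 2× at escape genes; CTCF bin
  probabilities and ATAC female/male ratios are similarly tied to status;
* TAD intervals span the planted domains, so domain edges fall near TAD
  boundaries.

Everything is deterministic given the config seed. What the generator does
*not* emulate: real sequence content, probe cross-hybridisation, annotation
errors (wrong TSSs), tissue heterogeneity, phylogenetically graded
divergence beyond the two-clade scheme, and cell-level variation. Passing
tests therefore demonstrate that the statistical machinery recovers known
structure under realistic noise and sparsity — not that any particular
real-data call is correct.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere; 1-based sources
  (RepeatMasker, array manifests) are shifted exactly once at parse time.
* An island/sample pair with no overlapping site is uninformative — a
  state, not an error; minimum sites per island per sample defaults to 1
  and is configurable for RRBS.
* Tied SNP votes leave a sample uninformative; tied species votes skip a
  gene in consensus; clustering ties resolve by species-name order.
* Identical constant groups in the t-test give $t = 0$, $p = 1$; distinct
  constant groups give $p = 0$; groups under 2 values are untestable, with
  no p-value emitted rather than a fake one.
* Distance from TSS to island is measured to the nearest island edge, 0
  inside.

## Problem sizes

The shipped tests and the acceptance script run the default cohort
(8 species × 300 genes × 8 methylation samples, ~380k simulated CpG
observations), an exhaustive binomial-oracle sweep to $n = 200$, a 10,000
draw type-I simulation, 100 enrichment-power replicates at 300 genes, and
20 domain-recovery cohorts at 200 genes — sizes chosen so the full suite
completes in about a minute while keeping Monte-Carlo error well below the
asserted margins.

## A worked example

```{r example}
pipe <- run_xci_pipeline(sim = sim_config(seed = 1))
pipe

glance(pipe$calls$species01_meth)

pipe$conservation$clade_a$summary |>
  select(group, n_genes, fraction_conserved)

tidy(pipe$enrichment) |>
  filter(species == "species01", feature %in% c("LINE", "LTR", "ctcf_bins"))

pipe$domains
```

```{r plots, fig.width = 6, fig.height = 4}
autoplot(dplyr::bind_rows(pipe$calls[1:8]))
autoplot(pipe$tree)
```

## Known limitations

Symbol-identity orthology misses renamed or unannotated genes; a species
without male data skips the Xa-methylation filter, so its escape calls
can include genes methylated on both X's; the generator's two-clade
phylogeny cannot probe gradual divergence; and the 450k mode's accuracy
depends on how many probes land in each island, which the fixed random
subset only crudely mimics.
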