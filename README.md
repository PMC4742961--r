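# crisprcensus

Completeness-aware census of CRISPR-Cas and alternative defence systems in
metagenome-assembled genomes.

Genome bins recovered from metagenomes are almost never complete. A naive
census that counts how many bins carry a CRISPR-Cas locus therefore
*understates* the true carriage rate: a system that is genuinely present can
sit inside the unrecovered portion of the bin. `crisprcensus` implements the
full analysis loop for asking — and answering defensibly — the question *"what
fraction of these organisms actually encode CRISPR-Cas?"*:

* a **synthetic community generator** that plants CRISPR arrays, *cas*
  operons, single-copy marker genes, defence-pathway KOs and viral
  protospacers into genomes with known truth, then degrades each genome by a
  contiguous gap to a drawn completeness;
* **detectors** for CRISPR arrays (seed–extend–chain on exact k-mer
  self-matches), *cas* operons (adjacency clustering of annotation hits),
  circular (complete) viral genomes (paired-end 5′–3′ linkage), and
  spacer-to-protospacer matches (gapless, ≥ 90 % identity over the full
  spacer, both strands);
* a **defence-system inventory** built from verbatim annotation lexicons
  (restriction enzymes, abortive infection, toxin–antitoxin, BREX) plus
  KO-based pathway presence calls (nucleotide and fatty-acid synthesis);
* **census statistics**: completeness from single-copy gene recovery, the
  closed-form probability that an intact locus of length *L* falls entirely
  inside the missing region of a bin, a completeness-corrected incidence
  estimator, a log-space Poisson-binomial tail test for "is the observed
  count consistent with a reference rate?", genus-weighted logistic
  regression of carriage on lifestyle, and exact Fisher / Mann-Whitney
  wrappers.

Everything is tidyverse-native: functions take and return tibbles, results
carry `print()`, `glance()`, `tidy()` and `autoplot()` methods.

## The statistical core

For a bin with estimated genome length *G*, recovered length *M* = *cG*, and
a locus of length *L*, the probability that a single contiguous gap hides the
entire locus is

```
P(miss) = max(0, M − L + 1) / (G − M + 1)
```

(`miss_probability()`; the general form also handles the boundary clamps).
The corrected incidence estimator treats detection of a truly present system
as Bernoulli(*cᵢ*) and divides detections by summed completeness:

```
r̂ = min(1, k / Σᵢ cᵢ)
```

(`corrected_incidence()`). The deficit test asks: if every bin carried the
system at reference rate *q* and detection succeeded with probability
*q·cᵢ*, how often would we see ≤ *k* detections? That tail is a
Poisson-binomial CDF, evaluated by a log-space dynamic programme
(`deficit_tail(log_p = TRUE)`) that stays finite hundreds of orders of
magnitude below double underflow.

## Worked example

```r
library(crisprcensus)

cfg <- community_config(n_genomes = 14L, genome_length_bp = 100000L,
                        n_viruses = 8L, circular_fraction = 0.75,
                        targeted_fraction = 0.25, symbiont_fraction = 0.35,
                        true_cas_rate = 0.45, rng_seed = 17L)
bundle <- generate_community(cfg)   # genomes + viral scaffolds + truth
res <- census_community(bundle)     # detect, inventory, correct, test
print(res)
#> Defence-system census: 14 genomes, 12 lineages
#>   CRISPR-Cas present: 8 (raw 57.1%, corrected 76.4%)
#>   deficit tail (q = 0.40): log10 p = -0.0
#>   spacers with target: 1/21; circular populations targeted: 1/6

glance(res)
#>   n_genomes n_lineages n_present  raw_rate corrected_rate log10_deficit_tail
#> 1        14         12         8 0.5714286      0.7639655      -0.0002560761
```

The small community drew 8 carriers out of 14; every intact planted array is
recovered and no non-carrier is called positive (`res$per_genome` vs
`bundle$truth`). `autoplot(res)` shows per-genome completeness against
detection; `plot_repeat_similarity()` draws the repeat-consensus similarity
heatmap.

Single closed-form quantities work standalone:

```r
miss_probability(1e6, 5e5, 775)   # 1 Mb genome, half recovered, 775 nt cas1
#> [1] 0.99845
```

A command-line front end with subcommands (`simulate`, `detect-arrays`,
`call-cas`, `find-viruses`, `match-spacers`, `annotate-defence`, `stats`,
`run`) is installed at `system.file("cli", "crispr-census.R",
package = "crisprcensus")`.

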