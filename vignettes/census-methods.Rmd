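---
title: "Methods: a completeness-aware defence-system census"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a completeness-aware defence-system census}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the model behind `crisprcensus`, the rationale for
every default parameter, the known limits of the synthetic generator, and
the numerical and design decisions that are not obvious from the function
reference.

## 1. The problem and the model

A collection of draft genome bins is screened for CRISPR-Cas. Each bin $i$
recovers a fraction $c_i$ of its source genome. The census asks two
questions:

1. **Incidence.** What fraction $r$ of organisms truly carry the system,
   given that incomplete bins can hide it?
2. **Deficit.** Is the observed number of carriers $k$ consistent with a
   reference carriage rate $q$ (e.g. the ~40 % seen in isolate genomes),
   or is the group genuinely depleted?

### Completeness

Completeness is estimated from single-copy marker genes:
$c_i = \max(0.01, \text{found}_i / \text{expected}_i)$ with expected counts
of 51 (bacteria) and 54 (archaea) (`estimate_completeness()`). The 1 % floor
keeps downstream divisions finite for bins with no recovered markers.
Estimated genome length is recovered bp divided by $c_i$.

### Missing a locus: the contiguous-gap model

`miss_probability(G, M, L)` treats the unrecovered part of a genome as a
single contiguous gap of length $G - M$ placed uniformly among the
$G - M + 1$ possible positions, and a locus of length $L$ at a fixed
(centred) position. The probability that the gap covers the locus entirely
is the exact count of covering gap placements over all placements; away from
the boundary clamps this reduces to

$$P(\text{miss}) = \frac{\max(0,\, M - L + 1)}{G - M + 1}.$$

The contiguous-gap geometry is deliberately *conservative for the deficit
test*: a single gap is the arrangement most likely to swallow an intact
locus, so $P(\text{miss})$ is an upper bound relative to fragmented-loss
models, which makes the deficit tail an over-estimate (the depletion
conclusion is then safe). The centred-window convention is a design choice:
the paper-scale quantities of interest ($G \sim 10^6$, $L = 775$) are
insensitive to the locus position except within $L$ bp of the ends, and the
centred form admits a closed expression that is tested against exhaustive
enumeration of every gap placement.

### Corrected incidence

`corrected_incidence()` models detection of a truly present system in bin
$i$ as Bernoulli($c_i$) — the chance that the locus falls in the recovered
fraction — giving the estimator

$$\hat r = \min\!\left(1, \frac{k}{\sum_i c_i}\right),$$

the MLE under that detection model. Note the intentional asymmetry with the
gap model above: under a contiguous gap, an interior *point* feature
survives with probability $\min(1, M/(G-M+1)) \approx c/(1-c)$ for $c<1/2$
and the exact locus-survival probability for a length-$L$ locus is lower
than $c_i$, so $\hat r$ is slightly conservative (biased low by ~0.04 at
$c \sim U(0.6, 1)$) if losses are truly one contiguous gap. Real bins lose
many fragments, under which detection probability approaches $c_i$; the
simpler Bernoulli($c_i$) model is used for estimation and the gap model is
reserved for the worst-case deficit probability.

### The deficit tail

If all $n$ bins carried the system at rate $q$ and detection succeeded with
probability $q \cdot c_i$ per bin (carriage × recovery), the number of
detections is Poisson-binomial with $p_i = q\,c_i$. `deficit_tail()`
computes $P(X \le k)$ by the standard count-distribution dynamic programme,
carried out in log space (`log_p = TRUE`) with `log1p`-style summation so
tails like $10^{-82}$ — far below double underflow in the linear domain —
remain exact. The linear and log routes agree to machine precision where
both are representable, and the DP is tested against full $2^n$ enumeration
for $n \le 15$.

### Lifestyle association

`lifestyle_association()` fits a binomial GLM of carriage on lifestyle
(obligate symbiont vs free-living) and domain, weighted so each genus
contributes total weight 1 (`genus_weights()`), preventing heavily sampled
lineages from dominating. Numerical choices:

* `glm.control(epsilon = 1e-12, maxit = 100)` — the default 1e-8 leaves the
  IRLS fixed point loose enough that replicating fractional weights by
  integer row duplication shifts the coefficient at the 1e-6 level; at
  1e-12 the two routes agree to ~1e-9 (p-values to ~3e-8, the residue
  being floating-point summation order over different row counts).
* Fractional weights trigger R's "non-integer #successes" warning, which is
  muffled deliberately: the quasi-likelihood point estimates and Wald tests
  are exactly the weighted-likelihood ones.
* **Separation** is flagged when the fitted lifestyle coefficient exceeds
  10 in magnitude (odds ratio beyond ~22,000, outside any plausible
  biological effect); the coefficient is then reported as ±Inf. glm's own
  fitted-probability warning is not relied on — separated fits can produce
  fitted probabilities around 1e-11 without tripping glm's internal
  threshold, so the warning is not a dependable signal.

Exact small-table tests wrap `stats::fisher.test` and `stats::wilcox.test`;
both are verified in the test suite against independent enumerations
(hypergeometric point masses; all $\binom{n_x+n_y}{n_x}$ group
assignments).

## 2. Detectors

### CRISPR arrays

`detect_arrays()` is a seed–extend–chain detector:

1. every exact 11-mer that recurs downstream at period 48–127 bp
   (repeat 23–50 + spacer 26–72, with one-copy slack) seeds a diagonal;
2. runs of consecutive seeds are extended and chained across units with a
   ±5 bp period jitter allowance;
3. boundaries are refined outward column-by-column while *all* repeat
   copies agree;
4. candidate regions with sub-48 bp internal periodicity (≤10 % mismatch)
   are rejected as tandem repeats;
5. a repeat consensus recurring within ±1 kb *outside* the array voids the
   call (flank-uniqueness curation);
6. at least 3 repeat units are required.

Two documented limits:

* **Boundary jitter.** Step 3 extends one column past the true edge
  whenever the flanking characters of all units agree by chance —
  probability $4^{-(n-1)}$ per column for $n$ units. For 3-unit arrays
  that is 1/16 per flank; the extension is information-theoretically
  indistinguishable from a genuinely longer repeat, so recovered
  boundaries can differ from planted ones by 1–2 bp while unit count and
  spacer content remain exact.
* **Fully periodic arrays.** An array whose spacers are *all identical* is
  a perfect tandem repeat; the detector stays silent (conservative).
  Non-adjacent duplicate spacers — the biologically common case — are
  detected and flagged `duplicate_spacers`.

### cas operons

`call_cas_operons()` keeps annotation hits with E-value strictly below
1e-10 (one best hit per ORF), then clusters hits on the same scaffold whose
ORF ordinals differ by ≤ 5, with transitive closure. A locus is an operon
if it has ≥ 2 clustered hits *or* contains Cas1 alone (Cas1 is the
universal marker; a lone *cas1* on a contig edge still evidences a system).
Operons missing *cas1* or *cas2* are marked partial. Typing is by signature
gene: *cas3* → type I, *cas9* → II, *cas10* → III; multiple signatures →
"mixed", none → "untyped". Adjacency is measured in ORF ordinals, not bp:
annotation pipelines emit ORFs in genomic order, and gene-count gaps are
robust to intergenic length variation.

### Circular viral genomes

A scaffold is circular when ≥ 5 read pairs link its 5′ and 3′ ends, no
read pair links it to another scaffold, and it is ≥ 5000 bp
(`detect_circular()`). Dereplication groups scaffolds at ≥ 99 % identity
over ≥ 99 % of the shorter length with single-linkage closure; a shared
31-mer prefilter avoids all-vs-all alignment, the identity route is
edit-distance counting (`adist`) when lengths are within 90 % of each
other and global–local alignment otherwise, and the longest member
represents each population.

### Spacer matching

`match_spacers()` scans both strands gaplessly at every offset
(`Biostrings::matchPattern` with a mismatch budget, re-scored by
`neditAt`), requiring identity ≥ 0.90 *of the full spacer length*
(inclusive threshold, so 3 mismatches in a 30-mer passes at exactly 0.90;
`N` matches nothing; partial overlaps at target ends are not considered —
coverage is always over the full spacer). Self-targeting spacers are
matches of a genome's own spacers outside its array loci ± 500 bp.

### Defence lexicons

`defence_inventory()` tokenises annotations on non-alphanumeric boundaries
(keeping `.`, `:`, `-` inside tokens so EC numbers survive) and applies
verbatim lexicons: restriction enzymes additionally accept REBASE hits at
E ≤ 1e-10 with coverage ≥ 0.80 (both inclusive); abortive infection
requires an Abi word or ≥ 2 toxin–antitoxin genes (exclusion terms
filtered); BREX requires its token set at E < 1e-5 (strict). Pathway
status: "present" when ≥ 75 % of defining KOs are found, "absent" when
≤ 1/3, "partial" between.

## 3. The synthetic generator

`generate_community()` is the package's ground-truth instrument; its
defaults are the study conditions, not tuned values.

| Parameter | Default | Rationale |
|---|---|---|
| `n_genomes` | 200 | large enough for stable incidence estimates, small enough for seconds-scale runs |
| `genome_length_bp` | 100 000 | desk-scale stand-in for ~1 Mb genomes; every detector operates locally, so length rescales runtime, not behaviour |
| completeness | U(0.6, 1) | draft-bin range; the source distribution is not published, so a flat prior over the plausible range |
| `true_cas_rate` | 0.40 | reference isolate-genome carriage rate |
| `frac_bacteria` | 0.9, `symbiont_fraction` 0.3 | mixed community with both lifestyles represented |
| repeat 23–50 bp, spacer 26–72 bp, ≥ 3 units | — | the detector's own validity bounds |
| cas1 locus length | 775 nt | the length used throughout the miss-probability examples |

ORFs are tiled one per kb (900 bp each); marker genes take the first
51/54 slots, then pathway KOs (free-living only), defence picks, and three
consecutive *cas* slots for carriers. Degradation removes one contiguous
block (matching the gap model), truncating or dropping features and
remapping coordinates; planted truth records what survived
(`array_intact`, per-feature coordinates, protospacer substitution
counts).

**What the generator does not exercise** (and the tests therefore cannot
show): assembly chimerism, strain mosaicism inside one bin, repeat-induced
misassembly at array loci, annotation noise beyond E-value placement, and
fragmented (multi-gap) genome loss. The corrected-incidence estimator is
expected to stay accurate under fragmented loss (detection probability →
$c_i$); under strictly contiguous loss it is conservative, as derived
above.

## 4. Reproducibility

All randomness flows from a single integer seed (`rng_seed` in
`community_config()`, `--seed` in `scripts/acceptance.R` and the CLI).
`scripts/acceptance.R --seed 1 --out results/acceptance.json` regenerates
the headline numbers quoted in the README against the installed package.
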