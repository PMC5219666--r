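---
title: "Building F2 linkage maps from low-coverage SLAF-seq genotypes"
author: "slafmap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building F2 linkage maps from low-coverage SLAF-seq genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slafmap)
```

## The problem and the model

An F2 population is produced by selfing the F1 of a cross between two
fully homozygous parents. At a codominant locus where the parents carry
different alleles (`aa x bb` pattern), offspring genotypes segregate
`aa : ab : bb = 1 : 2 : 1`. Specific-locus amplified fragment sequencing
(SLAF-seq) genotypes thousands of such loci at reduced representation:
restriction-digest tags are sequenced deeply in the parents (~13-17x) but
shallowly in each of the ~130 offspring (~3x).

`slafmap` implements the full analysis path from tag-level data to a
finished genetic map:

1. **Locus identification** — equal-length tags are grouped into SLAF loci
   by single-linkage clustering at >95% sequence identity
   (`cluster_tags()`); loci with more than four distinct tags are
   discarded as repetitive, loci whose parental alleles differ at more
   than three SNPs are discarded, and loci below 2.20 mean fold-coverage
   are discarded (`classify_locus()`). Alleles are defined by
   minor-allele-frequency evaluation (`define_alleles()`), segregation
   patterns by the parental genotypes (`classify_segregation_pattern()`),
   and variants by the IUPAC code of each substitution
   (`classify_variant()`). Only `aa x bb` loci are fully informative in an
   F2 and enter mapping.
2. **Genotype calling** — reads are modelled as independent Bernoulli
   draws: an A-read has probability $1-\varepsilon$ under `aa`, $1/2$
   under `ab`, and $\varepsilon$ under `bb`. With the F2 prior
   $(\tfrac14, \tfrac12, \tfrac14)$ the posterior over genotypes gives the
   call and a phred-like quality $-10\log_{10}(1-P)$, capped at 60
   (`genotype_posterior()`). A dynamic pruning loop removes the worst
   marker or individual until the matrix-wide mean quality reaches a
   cutoff (`iterative_quality_prune()`).
3. **Marker QC** — depth filters (parents > 29-fold, progeny > 3-fold,
   both configurable), a 30% missing-data filter, and the segregation
   $\chi^2$ test against 1:2:1 with 2 df at $\alpha = 0.05$
   (`chi_square_121()`, `apply_filters()`). Markers rejecting the test
   become *accessory* (distorted) markers, set aside and re-inserted after
   the framework map is built.
4. **Two-point analysis** — for each marker pair the recombination
   fraction $r$ is the maximum-likelihood estimate under the F2 two-locus
   class model, computed by EM (`estimate_r_em()`): every cell of the
   3x3 joint genotype table fixes its recombinant-gamete count except the
   double heterozygote, which mixes parental
   ($\propto (1-r)^2/2$) and recombinant ($\propto r^2/2$) gamete pairs;
   the E-step resolves the mixture and the M-step sets $r$ to expected
   recombinant gametes over total gametes. The LOD score is
   $\log_{10} L(\hat r) - \log_{10} L(0.5)$ (`lod_score()`). Both allele
   orientations of the second marker are evaluated and the
   higher-likelihood phase kept.
5. **Grouping** — single-linkage transitive closure at a modified LOD
   (MLOD) threshold of 5 (`group_markers()`).
6. **Ordering** — within each group, simulated annealing minimises the
   sum of adjacent recombination fractions (SARF; `sarf()`,
   `order_sa()`), alternating with multipoint re-estimation of adjacent
   $r$ (`multipoint_adjacent_r()`). Map distances come from the Kosambi
   function $d = 25\ln\frac{1+2r}{1-2r}$ (`kosambi()`).
7. **Error correction and imputation** — a SMOOTH-style singleton rule
   removes observations that are nearly impossible given their flanking
   genotypes (`smooth_correct()`), and k-nearest-neighbour imputation
   fills missing genotypes from the k map-nearest markers of the same
   individual (`knn_impute()`).
8. **Accessory insertion and reporting** — distorted markers are placed by
   multipoint maximum likelihood without moving framework markers
   (`insert_skewed()`); runs of at least three consecutive distorted
   markers form segregation distortion regions (`detect_sdr()`); map and
   report tables are produced by `map_stats()`, `summary_ratios()` and
   `write_map_outputs()`.

`fit_linkage_map()` runs steps 3-8 as one fit and returns a classed
object with `print`, `summary` and `plot` methods.

## The low-coverage design

At 3x offspring coverage, hard genotype calls are unavoidably poor: a
heterozygote sampled by $d$ reads shows only one allele with probability
$2^{1-d}$, so roughly a quarter of heterozygotes are undercalled as
homozygotes from 1-3 reads (overall concordance ~80%). Every two-point
$\hat r$ then inflates by the error rate and the $\chi^2$ test sees a
spurious heterozygote deficit everywhere. No amount of downstream
filtering can undo this from hard calls alone.

`slafmap` therefore carries genotype *likelihoods* through the pipeline.
`call_genotypes()` returns, besides the hard calls, the per-call
likelihood of each genotype given the reads. The multipoint chain (a
three-state Markov chain along the map, with transition matrices
determined by the adjacent recombination fractions) accepts these
likelihoods as emissions, so adjacent $r$ is estimated at the read level
(`multipoint_adjacent_r(..., emission = )`), and a forward-backward pass
re-calls every genotype from its posterior given reads plus flanking
markers (`hmm_recall_genotypes()`) — exactly the information a single
shallow cell lacks. With one-hot emissions (the default) the multipoint
estimates reduce to complete-case two-point estimates on complete data,
so the hard-call contracts of all module functions are unchanged.

The fit iterates the whole map building (default `rounds = 3`): each
round's cleaned genotype matrix seeds the next, in which the segregation
test, grouping and ordering are redone from scratch. Early rounds use a
stricter distortion $\alpha$ (at most $10^{-3}$) and place component
accessory markers unconditionally, so that markers whose apparent
distortion or weak linkage stems from genotyping noise stay available
until the noise is corrected; the final round applies the configured
thresholds. Because posterior re-calling can imprint an assumed marker
order onto the cleaned matrix, the final order of each group is refined
by a local search (adjacent swaps, short reversals, +-2 relocations)
scored on the *original* read-level emissions, where an imprinted order
earns no spurious support.

## Design decisions on points the method leaves open

- **MLOD.** The grouping statistic is
  `min(two-point LOD at the MLE, independence G-test LOD)`
  (`independence_lod()`). Two unlinked markers that are both
  segregation-distorted toward opposite homozygotes mimic coupling
  linkage after a phase flip (ratio LOD 3-6 in our simulations) but show
  no association given their margins (independence LOD < 2); conversely
  sparse-table noise can inflate the 4-df independence statistic while
  the ratio LOD stays low. The minimum lets each statistic veto the
  other's failure mode. For truly linked pairs the two statistics agree.
- **Grouping covers all QC-passing markers.** Components are formed over
  framework *and* accessory markers, so a run of distorted markers keeps
  its chromosome in one piece; only framework members are ordered and
  mapped, and accessory members are inserted afterwards. This mirrors the
  practice of grouping on all markers (or on genome position) and mapping
  a framework.
- **Unmapped markers are re-offered.** Markers that fall out of grouping
  are offered to the finished maps by the same multipoint placement in
  every round, so a marker stranded by early noise can still join once
  its neighbours are cleaned.
- **Accessory chaining.** Insertion proceeds strongest-first and each
  placed marker joins the reference, so a distorted cluster beyond the
  framework's edge — the typical geometry of a segregation distortion
  region under strong gamete selection — is reached stepwise. If an end
  placement implies a negative coordinate all positions are shifted so
  the minimum is zero; framework spacing and order never change.
- **SMOOTH variant.** The published rising-threshold schedule is replaced
  by a probability rule: an observation whose conditional probability
  given its nearest non-missing flanks (distance-weighted through the
  inverse Kosambi function) falls below 0.001 is set to missing, never
  rewritten. Inside the fit the threshold rises by sqrt(10) after each
  clean pass, up to 0.05, which catches depth-3 undercalls
  (conditional probability ~0.006 at 8-10 cM spacing) while a clean
  matrix is never touched at the starting threshold.
- **Annealing schedule.** Initial temperature is the standard deviation
  of SARF over 100 random orders, cooling 0.995 per step, stop after
  2000 steps without improvement; two restarts; then a deterministic
  best-improvement search over reversals and reinsertions. Orientation
  is canonicalised so the lexicographically smaller terminal marker id
  comes first. Fixed seeds reproduce orders bit for bit.
- **SDR rule.** The method's definition: a maximal run of at least
  `min_run = 3` consecutive distorted markers along a group.
- **Rounding.** Report tables round half-up at one decimal (distances,
  percentages) and two decimals (average adjacent distances), matching
  conventional report arithmetic; `round_half_up()` absorbs binary
  representation error with a 1e-9 epsilon.

## The simulator

`sim_config()` / `simulate_meioses()` / `simulate_reads()` generate
synthetic studies with ground truth. Defaults emulate the motivating
design: 10 chromosomes with map lengths 132.8-300.4 cM, 130 F2
individuals, parent coverage 12.9x/16.8x, offspring coverage 2.8x, 12%
polymorphism rate, ~65% transitions among SNPs, rare InDel loci, and
gamete-viability segregation distortion (a gamete carrying the
disfavoured allele at a selected locus is rejected with probability `s`
and redrawn; zygotic selection with viability $(1-s)^k$ is an option).
Crossovers are Poisson in the map length with uniform positions (Haldane
model, no interference) — the estimation side uses Kosambi, so recovered
lengths are expected to undershoot simulated lengths by roughly 8%
before any other effect; recovery tolerances account for this. The
default distortion loci sit near chromosome ends, where segregation
distortion regions cluster in real biparental maps; under gamete
selection with s = 0.8 a mid-chromosome locus would skew genotype
frequencies along most of its chromosome and leave no framework to map.
Missing data arise from Poisson depth 0 plus an explicit masking rate.

What the simulator does not emulate: read-level FASTQ structure,
restriction-site placement on a real genome, linked-read artefacts,
locus dropout correlated with genotype (allelic dropout is symmetric
here), and interference. Passing recovery tests on these simulations
therefore demonstrates correctness of the estimation machinery under the
stated statistical model, not performance on any particular real
library preparation.

## Problem sizes used by the test-suite

Unit tests run on 1-2 chromosomes with 8-26 markers. The end-to-end
recovery test simulates 10 chromosomes (150-300 cM, 20-30 markers each,
marker count proportional to length), 130 individuals, 3x offspring
coverage, 1% read error, 10% extra masking and two terminal distortion
loci at s = 0.8; distortion-region recovery uses 20 replicates of a
two-chromosome version. The EM estimator is checked against a
grid-search likelihood oracle (step 1e-4) on 1000 random tables, and the
annealer against exhaustive search on 50 eight-marker groups.

## Known limitations

- **Imputation has an information ceiling.** The exact Bayes accuracy of
  imputing an F2 genotype from its two true flanking genotypes at
  distance $d$ each side is 92.6% at $d = 4$ cM, 86.3% at 8 cM, 83.5% at
  10 cM and 76.3% at 16 cM (enumerate
  $P(g_1)\,T_d(g_1,g_2)\,T_d(g_2,g_3)$ and sum the per-$(g_1,g_3)$
  maxima). Above ~90% accuracy therefore requires sub-5-cM marker
  spacing — the regime of the full-density design (~1 cM), not of the
  scaled-down recovery simulations, where the pipeline measures ~81-85%,
  i.e. essentially at the ceiling once flank noise is accounted for.
- Accessory markers inside a distorted tail are placed by chained
  multipoint likelihood; their order *within* the tail is approximate
  (framework recovery is unaffected).
- The multipoint machinery assumes a biallelic codominant F2;
  outcrossing configurations (the other seven segregation patterns) are
  classified but not mapped.
- Distorted genotype frequencies bias $\hat r$ slightly for pairs inside
  a selection region; no distortion-aware correction is applied
  (framework maps exclude such markers by construction).

## A minimal run

```{r example, eval = FALSE}
cfg <- sim_config(n_chromosomes = 2, chrom_lengths_cM = c(120, 150),
                  markers_per_chrom = c(18, 22), offspring_depth_mean = 3,
                  polymorphic_fraction = 1, marker_placement = "even",
                  distortion_loci = list(
                    list(chrom = 2, pos_cM = 5, s = 0.8, allele = "a")),
                  seed = 1)
sim <- simulate_slaf_population(cfg)
gm  <- call_genotypes(sim$counts_a, sim$counts_b)
fit <- fit_linkage_map(gm, seed = 1)
summary(fit)
plot(fit)
```
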