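---
title: "Mapping founder mutations by recurrent IBD in tumor haplotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping founder mutations by recurrent IBD in tumor haplotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foundertracker)
```

## The problem and the model

A pathogenic germline variant inherited from a common founder travels
through a population inside an ancestral chromosome fragment. Each meiosis
trims that fragment, so after $n$ generations the carriers of the
mutation share, around the mutant locus, an identical-by-descent (IBD)
haplotype whose expected genetic length is $1/(2n)$ Morgans. Two features
of cancer make tumors an unusually favourable substrate for finding such
haplotypes genome-wide:

* carriers of a germline mutation in a tumor-suppressor gene frequently
  lose the wild-type copy somatically (loss of heterozygosity, LOH), so
  the mutant locus tends to sit in a *recurrent region of LOH* across a
  tumor cohort;
* inside an LOH region only one parental chromosome remains, so the tumor
  SNP-array B-allele-frequency (BAF) profile reads out a *phased
  haplotype* directly, with no statistical phasing step.

The package implements the resulting pipeline: (i) call LOH from
allele-specific copy numbers (minor copy $< 0.5$, whatever the copy
number of the retained chromosome) and keep regions whose LOH frequency
clears a threshold (20% by default); (ii) convert each carrier's BAF
profile to alleles (BAF $> 0.65 \Rightarrow$ B, BAF $< 0.35 \Rightarrow$
A, in between $\Rightarrow$ unreliable, and markers unreliable in any
tumor are dropped); (iii) scan the resulting tumor haplotype panel for
*significantly recurrent* IBD.

## The IBD score and its null

Pairwise IBD is detected with a seed-and-extend matcher in the GERMLINE
style: markers are cut into words of `bits = 5` consecutive markers,
haplotype pairs agreeing on a word are extended word-wise and then
marker-by-marker, and maximal shared segments of at least `min_m = 0.4`
cM are reported. The stringent `err_hom = 0` (no tolerated mismatches) is
appropriate because haplotypes read off LOH regions carry very low error
(the package's BAF-threshold inference reproduces a known haplotype with
error well below $10^{-3}$ even at realistic BAF noise).

A shared segment $H$ over SNPs $i = s..e$ is scored by how improbable its
allele sequence is to recur by chance under linkage equilibrium:

$$S(H) \;=\; -\sum_{i=s}^{e} 2\,\ln f(H_i),$$

where $f(H_i)$ is the population frequency of the allele the segment
carries at SNP $i$ (the B-allele frequency for B, its complement for A),
estimated from the reference panel and clamped to $[10^{-4},
1-10^{-4}]$. Long segments of rare alleles score high; the per-SNP IBD
score is the sum of $S$ over all pairwise segments covering that SNP.

Linkage disequilibrium makes some genomic regions score high in *any*
panel, so raw scores are not comparable across the genome. The null is
therefore built empirically: `n_subsets` random subsets of the reference
panel, each of the tumor-panel size, are pushed through the identical
matcher + scoring path, and a Gumbel distribution
$F(x) = \exp(-\exp(-(x-\mu_i)/\beta_i))$ is fitted per SNP by maximum
likelihood (moment-based start, damped fixed-point iteration on the
profile-likelihood equation for $\beta$). The Gumbel is the natural
family for maxima-like positive scores and is heavier-tailed — hence more
conservative — than a Gaussian. The per-SNP p-value is the fitted
survival probability of the observed tumor score and q-values follow by
Benjamini–Hochberg across all scanned SNPs.

Numerical corner cases: SNPs whose null scores are constant (typically
all zero because no reference subset ever shows IBD there) get
$\beta = 10^{-6}$ and a degenerate exceedance test — p $= 0$ if the tumor
score exceeds the constant, else 1. This is the honest limit of the
resampled null; it requires a reference panel large enough that such SNPs
are rare (they are absent at the 274-haplotype reference scale used
throughout).

## The benchmark scan

`dash_scan()` implements the frequency-based comparator: pairwise
matching on the combined tumor + reference panel, clustering of
haplotypes per 0.2 cM window (connected components of the
"segment-fully-spans-window" graph; identical member sets in adjacent
windows merged), a one-sided Fisher exact test for tumor enrichment per
cluster, and BH across clusters. The published DASH algorithm's
density-based refinement is deliberately simplified to connected
components: the comparison of interest is that a cluster-frequency test
ignores haplotype *length*, which is exactly what costs it power at low
prevalence. This benchmark is not a faithful DASH reimplementation and is
documented as such.

## What the synthetic panels emulate

Real phased reference data (e.g. 1000 Genomes European haplotypes) are
not shipped with the package; the simulator generates stand-in panels
that preserve the two features the resampled null must absorb:

* a realistic allele-frequency spectrum — founder B-allele probabilities
  drawn per marker from Uniform(0.05, 0.95);
* block-wise linkage disequilibrium — each haplotype is a mosaic of
  `n_founders` founder haplotypes with Poisson(1 per cM) switch points,
  plus per-marker allele flips at rate 0.002 playing the role of
  genotyping error and recurrent mutation.

`n_founders` sets the background relatedness of the population: any two
haplotypes are co-ancestral over a fraction $1/n_\text{founders}$ of the
genome, in tracts of mean length 0.5 cM (either haplotype switching ends
a tract, at combined rate 2 per cM). The default of 400 founders gives
$\approx 0.2$ shared segments of $\ge 0.4$ cM per haplotype pair per
Morgan — the order of magnitude of an outbred European-ancestry sample —
and is the deliberate design point of the study conditions: a markedly
smaller pool (say, tens of founders) makes every pair of "unrelated"
haplotypes share several detectable segments per chromosome, which both
drowns low-prevalence planted signals in null variance and does not
resemble any population a cohort would be sampled from. Marker density
is 100 markers per cM (10,000 markers on a 100 cM chromosome), the scale
of a ~370K genome-wide array; denser maps change performance little
because block LD bounds the information content.

What the mosaic model does *not* reproduce: coalescent depth structure
(all co-ancestry is single-generation mosaic sharing), recombination
hotspots, allele-frequency/LD coupling, genotyping artifacts beyond
symmetric flips, and the long-range phase errors of statistically phased
panels. Passing simulation tests therefore demonstrates the pipeline's
statistical behaviour under calibrated LD and background IBD, not its
end-to-end accuracy on any particular array platform.

## The planted-haplotype power study

`run_power_study()` replays the planted-haplotype protocol at desk scale: per
replicate one population panel is generated and split into 274 reference
and 100 tumor-source haplotypes (mirroring the original split of one real
phased panel into two halves); a focal position is drawn uniformly;
`round(prevalence * 100)` carriers (always including the first haplotype)
receive a copy of haplotype 1 over a segment containing the focal point,
with per-carrier lengths drawn from a Gumbel distribution with location
and scale both equal to the nominal mean length (reproducing the natural
spread of real founder segments) and clamped to $(0.1\,\text{cM},
\text{span}]$; both scans run at $q \le 0.01$. A replicate is *detected*
when at least one marker inside the union of planted segments is
significant — the natural reading of a per-condition power figure.
Default study sizes are 25 replicates per condition and 50 null subsets;
the per-marker operating characteristics (ROC) average TPR/FPR over a
grid of q thresholds, pointwise per threshold.

Design choices worth recording:

* the focal point sits at a Uniform(0,1) fraction of each carrier
  segment — only the shared location is prescribed, not the alignment;
* the planted lengths are *clamped* (not resampled) at the 0.1 cM floor,
  which keeps the realized mean at $\mu(1+\gamma) \approx 1.577\,\mu$
  within a few percent; resample-truncation would inflate it by ~9%;
* carrier counts use `round()`, so 2% of 100 tumors means exactly 2
  carriers;
* each replicate regenerates both halves; nothing is shared across
  replicates.

## Known limitations

* **Far-tail calibration of the fitted null.** With 50 resampled subsets
  the per-SNP Gumbel location and scale carry ~10% estimation noise, and
  the true null of a compound-Poisson sum of segment scores is
  heavier-tailed than any fitted Gumbel far beyond the support of the 50
  subset scores. Both effects make extreme p-values ($\lesssim 10^{-4}$)
  anti-conservative by a small integer factor. This does not affect the
  power results (planted signals sit orders of magnitude beyond the
  threshold), but it inflates the pooled false-discovery rate of the
  simulation study above the nominal BH level whenever the tumor half of
  the population carries its own strong background-IBD clusters — under
  the default background-IBD level, scattered background sharing events
  among tumor haplotypes reach significance alongside the planted signal.
  Raising `n_subsets` tightens the tail at linear cost; the per-SNP
  false-positive rate of an *unplanted* scan at $q \le 0.01$ remains
  $\ll 2\%$ because BH with no strong signal leaves the genome-wide
  threshold extremely strict.
* Word seeding means a shared run containing no fully aligned
  `bits`-marker word can never be reported; at study densities every
  reportable run ($\ge 0.4$ cM $= 40$ markers) contains many full words,
  and the matcher is exactly equivalent to the exhaustive scan.
* The mismatch-tolerant path (`err_hom > 0`) extends under a shared
  mismatch budget and trims trailing mismatches; it is a best-effort
  facility outside the validated `err_hom = 0` configuration.
* LOH segmentation and allele-specific copy-number estimation are
  consumed as inputs; the package neither segments raw LRR/BAF nor
  estimates tumor purity or ploidy.

## Problem sizes used by the shipped checks

The package's simulation checks run 25 replicates per condition on
10,000-marker/100 cM panels with 50 null subsets — sizes chosen so the
whole study re-runs in minutes on one core while leaving the binomial
standard error of a power estimate at $\le 0.1$. The power pattern those
checks reproduce — detection certain at 5 cM/7% and 1 cM/50%, above 0.9
at 15% for all lengths and at 5 cM/5%, with the frequency-only benchmark
blind at 5 cM/5% — is the regime the method is built for: length-weighted
scoring keeps power at prevalences where a frequency-only test is blind.
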