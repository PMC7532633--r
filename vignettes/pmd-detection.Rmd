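---
title: "Detecting partially methylated domains with a beta-binomial HMM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting partially methylated domains with a beta-binomial HMM}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pmdscan)
```

## The problem

Partially methylated domains (PMDs) are broad genomic intervals — tens of
kilobases up to megabases — in which CpG methylation is reduced relative to
the highly methylated background that covers most of a mammalian genome.
They are a hallmark of cancers, cultured cell lines, placenta and other
tissues with a long mitotic history. Three properties make an interval a
PMD rather than a regulatory feature: its methylation is lower than the
background, PMDs jointly cover a fraction of the genome well above the few
percent occupied by promoters and CpG islands, and each domain is much
larger than any single regulatory element.

`pmdscan` segments whole-genome bisulfite sequencing (WGBS) methylomes into
PMD and background states, with particular attention to comparability
across samples of very different sequencing depth.

## The segmentation model

The observation unit is a genomic bin. A bin aggregates its CpG sites into
a pair $(m, n)$: $n$ read-level observations of which $m$ reported
methylation. A two-state hidden Markov model assigns each bin to the PMD or
background state. Emissions are beta-binomial,

$$ P(m \mid n, \alpha_k, \beta_k) \;=\; \binom{n}{m}
   \frac{B(m + \alpha_k,\; n - m + \beta_k)}{B(\alpha_k, \beta_k)}, $$

one shape pair per state $k$. The beta-binomial matters: per-bin methylation
is overdispersed relative to a binomial because CpGs within a bin have
heterogeneous methylation propensities, and because PMD methylation itself
drifts within a domain. A bin with no observations contributes probability
1 in both states but remains in the chain, so the transition geometry — and
hence the domain length distribution — follows genomic distance rather than
data density.

Transition and emission parameters are learned by Baum–Welch.
Chromosomes are independent observation sequences sharing one parameter
set. The E-step is a scaled forward–backward pass (implemented in C++);
the M-step re-estimates the transition matrix from expected transition
counts and each state's $(\alpha, \beta)$ by weighted maximum likelihood
under the state responsibilities, seeded by a method-of-moments estimate
and refined by BFGS on the log-shape scale. An emission update is accepted
only when it improves the weighted emission objective, so the algorithm is
a generalised EM and the total log-likelihood never decreases — a property
the test suite asserts across many random instances.

Domains are extracted by posterior decoding rather than Viterbi: maximal
runs of bins whose PMD posterior strictly exceeds 0.5 become domains, and a
tie at exactly 0.5 goes to the background. Posterior decoding is preferred
because the per-bin posterior is also the natural domain score and because
single-bin disagreements with the best path carry information we want
reflected in the output.

### Initialisation, identifiability and numerical guards

The two states are distinguished only by their emission means, so training
starts from a PMD mean of 0.45 and a background mean of 0.85, both at
precision $\alpha + \beta = 10$, transition diagonal 0.99, and uniform
initial probabilities. These reflect the methylation regimes the model is
meant to separate and make relabelling rare; should training nevertheless
cross the means, states are relabelled afterwards so that the PMD state is
always the lower-mean state, and the tests check that swapping the initial
labels leaves the called domains unchanged.

Three numerical guards stabilise the M-step: the precision
$\alpha + \beta$ is capped at $10^4$ (an unbounded precision collapses the
beta-binomial to a binomial and destabilises the weighted fit), each shape
is floored at $10^{-2}$, and degenerate inputs — fewer than two informative
observations, or all observed proportions identical — fall back to a
smoothed moment estimate with mean $(\sum w m + 0.5)/(\sum w n + 1)$ at a
fixed fallback precision of 10. Convergence is declared when the relative
log-likelihood change drops below $10^{-6}$, with a 100-iteration cap;
non-convergence is reported in the fit object, not raised as an error.

## Dynamic bin-size selection

Sequencing depth varies enormously across public methylomes, and depth
interacts with bin size: small bins in a shallow sample carry so few
observations that their methylation level is essentially discretised noise.
`pmdscan` therefore sizes bins per sample. A bin is sufficiently informed
at 40 read-level observations — whether 40 reads of one CpG or one read
each of 40 CpGs. Forty observations give an 80% exact (Clopper–Pearson)
confidence interval of 39%–61% around an observed level of 50%, enough to
call a bin low, medium or high. The selected bin size is the smallest
candidate (1 kb to 100 kb in 1-kb steps) for which at least 80% of
eligible bins reach 40 observations.

Eligible bins are those containing at least one CpG site. Bins in CpG-free
stretches — assembly gaps, unassayable sequence — are excluded from the
denominator, otherwise the criterion would be dominated by genome that can
never be assayed. The sufficiency fraction is almost, but not exactly,
monotone in bin size: the truncated final bin of each chromosome can cause
dips of order 1% near saturation, which is why the selection scans from
small to large rather than bisecting.

Input positions are taken as 0-based and all intervals are half-open,
matching BED; the methylated count of a site is recovered once at read
time as `round(level * coverage)` and never re-derived.

## Boundary sharpening

Decoded boundaries sit on bin edges. For each domain edge, a window
spanning one bin outside and one bin inside the edge is scanned: every
inter-CpG breakpoint is scored as the summed beta-binomial log-likelihood
of outside-side sites under the background shapes plus inside-side sites
under the PMD shapes, using exactly the trained model objects. The
maximising breakpoint becomes the new edge, placed at the first CpG on the
PMD side. By construction an edge moves at most one bin-width, domains
never invert and never cross their neighbours; a window without CpGs
leaves the edge untouched. On simulated data this reduces the median
boundary error severalfold (from roughly a quarter of a bin to a few
hundred basepairs at 1-kb bins), and the tests assert the improvement is
systematic across seeds.

## The shuffle null and small-domain removal

Posterior decoding produces some short spurious domains wherever noise
clusters. To remove them, the per-bin observations $(m, n)$ are permuted
uniformly across all bins genome-wide — coordinates fixed, marginal
observation distribution preserved, spatial structure destroyed — and the
shuffled sequence is decoded with the already-trained parameters (no
retraining, for determinism). Segment sizes from the shuffled decode form
an empirical null; each observed domain receives
$p = (1 + \#\{\text{null} \ge \text{size}\})/(1 + N)$, Benjamini–Hochberg
adjustment is applied across domains, and domains with $q > 0.01$ are
dropped.

The +1 pseudocount keeps $p$ positive, which has a practical consequence:
$p$ can never fall below $1/(1+N)$. One shuffle of a full-size genome
yields thousands of null segments, but small genomes or large bins may
not, in which case the requested FDR level would be unreachable and every
domain would be removed spuriously. `build_null()` therefore pools
additional shuffles until the null holds at least `min_null` segments
(the pipeline requests $\lceil 2/q \rceil$), capped at 50 shuffles.

## Sample classification

A sample is called PMD-containing (PC) when its segmentation covers
strictly more than 5% of the genome **and** the mean segment size strictly
exceeds 50 kb. The two cutoffs sit at the empirical inflection separating
genuine PMD samples from samples whose hypomethylated basepairs are only
regulatory features: the latter segment roughly 5% of the genome into
segments of tens of kilobases, while PC samples jump to over 10% coverage
with mean sizes above 100 kb. The denominator of the fraction is the total
length of the chromosomes present in the methylome, not merely covered
basepairs, so shallow samples are not inflated.

## The simulator

`simulate_methylome()` is the package's test bed. It plants hypomethylated
domains (sizes from a shifted exponential with mean 150 kb, floored at
10 kb, separated by at least 20 kb) until 35% of the genome is covered,
scatters CpG sites with geometric inter-site gaps of mean 100 bp (the
genome-wide CpG density of mammalian genomes), draws per-site coverage
from a Poisson with mean 30, and draws methylated counts beta-binomially
with state means 0.45 and 0.85 at precision 10 — a deeply sequenced,
clearly PMD-containing cancer methylome. `simulate_nonpc()` uses the same
machinery with 2-kb features covering 2% of the genome, emulating
CpG-island and promoter hypomethylation without PMDs. Both are bit-exactly
reproducible per seed.

What the simulator does **not** emulate: uneven library coverage and
mappability gaps, chromosome-scale methylation trends, the gradual rise of
methylation toward real PMD boundaries, CpG-density islands at boundaries,
non-CpG contexts, and subtle-PMD samples (e.g. healthy liver) whose PMD
means sit close to the background. Passing tests therefore demonstrate the
machinery is correct under the stated generative model, not that every
real methylome will segment as cleanly.

The validation suite runs each configuration at sizes chosen to keep the
whole suite in a few minutes on one core: a 10-Mb single-chromosome genome
for end-to-end recovery (Jaccard versus planted truth is ~0.99 at 30×
and >0.95 at 1× with dynamic bins), 10,000-bin sequences for parameter
recovery, 3-Mb genomes for sharpening and null-distribution properties,
and 20 + 20 ten-megabase samples for PC classification.

A limitation worth stating: with the default well-separated state means, a
1-kb bin at 1× mean depth still holds ~10 observations, so the fixed-bin
segmentation remains competitive with dynamic sizing on this simulator at
moderate depths; the decisive advantage of dynamic binning appears for
shallow samples with subtle PMDs, where per-bin information genuinely
limits state inference.

## Annotation

Escapee genes are genes that evade the hypomethylation of their
surroundings: body less than 20% covered by a PMD while each 100-kb flank
is at least 80% covered. Genes whose flanks would extend past a chromosome
end are disqualified — a partial flank makes the per-flank criterion
ill-defined. Recurrence across samples is counted by gene name with a
default threshold of 2 samples.

Observed/expected enrichment of features in regions counts a feature as
inside when its midpoint is (avoiding double-counting of partial
overlaps), takes the expected count from the binomial with success
probability equal to the regions' genome fraction, and tests with the
exact two-tailed binomial test; Benjamini–Hochberg adjustment is applied
across feature classes. Boundary enrichment builds ±2.5-kb windows around
every domain edge and merges overlapping windows before counting, so
closely spaced boundaries are not counted twice.

## Known limitations

* Two states only; a semi-Markov model with explicit duration would match
  the domain-size distribution better at the cost of much heavier training.
* The boundary-sharpening scan is local (one bin each side); a boundary
  misplaced by more than a bin cannot be recovered.
* The shuffle null inherits the decoder's smoothing: with subtle emission
  separation the shuffled decode can itself produce long segments, making
  the FDR conservative in exactly the samples where calls are least
  certain.
* Plain basepair Jaccard is used for all comparisons; no normalisation for
  differing genome coverage between samples is applied.
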