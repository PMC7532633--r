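# pmdscan

Partially methylated domains (PMDs) are broad genomic intervals — tens of
kilobases to megabases — with reduced CpG methylation relative to the
highly methylated genomic background. They mark cancers, cultured cell
lines, placenta and other tissues with a long replicative history, and
their boundaries track replication timing and gene regulation. `pmdscan`
detects PMDs in whole-genome bisulfite sequencing (WGBS) methylomes and is
built for a problem that bites hard in practice: making PMD calls
comparable across samples whose sequencing depths differ by an order of
magnitude.

## Method

`pmdscan` segments the genome with a two-state hidden Markov model over
non-overlapping bins. Each bin contributes an observation pair $(m, n)$ —
$n$ read-level CpG measurements, $m$ of them methylated — modelled per
state $k \in \{\text{PMD}, \text{background}\}$ by a beta-binomial

$$P(m \mid n, \alpha_k, \beta_k) = \binom{n}{m}
  \frac{B(m+\alpha_k,\, n-m+\beta_k)}{B(\alpha_k, \beta_k)},$$

whose overdispersion absorbs within-bin heterogeneity. Parameters are
learned by Baum–Welch; domains come from posterior decoding (PMD posterior
> 0.5).

Around that core:

* **Dynamic bin sizing.** A bin is well informed at 40 observations (an
  80% exact binomial CI of 39%–61% around an observed 50%). Per sample,
  the smallest bin size for which ≥80% of CpG-containing bins reach 40
  observations is selected, so deep and shallow samples are segmented with
  equal per-bin information.
* **Single-basepair boundaries.** Each domain edge is refined by scanning
  every inter-CpG breakpoint within one bin of the edge and maximising the
  two-sided beta-binomial likelihood under the trained state parameters.
* **Shuffle FDR.** Bin observations are permuted genome-wide, the shuffled
  sequence decoded with the trained model, and the resulting segment sizes
  used as an empirical null; domains are removed at Benjamini–Hochberg
  q > 0.01.
* **Sample classification.** A sample is PMD-containing (PC) when >5% of
  the genome is segmented with mean segment size >50 kb.
* **Evaluation and annotation.** Basepair Jaccard comparison of PMD sets,
  read-level downsampling with stability curves, 50-kb multi-sample
  conservation tracks, escapee-gene detection (body <20% PMD-covered,
  both 100-kb flanks ≥80%), and observed/expected enrichment with
  two-tailed binomial tests.
* **Simulator.** A seeded generator of methylomes with planted PMD
  architecture, so the whole pipeline is testable without downloads.

## Worked example

```r
library(pmdscan)

sim <- simulate_methylome(chrom_sizes = c(chr1 = 1e7), depth = 30, seed = 1)
seg <- pmd_segment(sim$methylome, seed = 1)
seg
#> PMD segmentation: 21 domains at bin size 1000 bp
#>   fraction segmented 0.350, mean size 166.4 kb -> PMD-containing
#>   Baum-Welch: 3 iterations, converged, logLik -46330.32

head(tidy(seg), 3)
#> # A tibble: 3 x 8
#>   chrom   start     end name  score n_bins p_empirical q_value
#>   <chr>   <dbl>   <dbl> <chr> <dbl>  <int>       <dbl>   <dbl>
#> 1 chr1   458525  573958 PMD_1 0.997    116     0.00382 0.00445
#> 2 chr1   939517 1114861 PMD_2 0.996    176     0.00382 0.00445
#> 3 chr1  1553023 1583274 PMD_3 0.996     30     0.00763 0.00763

jaccard(seg$pmds, sim$truth)
#> [1] 0.9986
```

The segmentation recovered the planted architecture almost exactly: 35% of
the 10-Mb genome falls in called domains (the simulator's target), domain
scores are mean PMD posteriors, `p_empirical`/`q_value` come from the
shuffle null, and the basepair Jaccard against the planted truth is 0.999.
`write_pmds_bed()` serialises the calls, `autoplot(seg)` draws bins,
posterior and domains along a chromosome, and `glance(seg)` gives the
one-row sample summary used for PC classification.

A command-line wrapper with the same functionality is installed at
`exec/pmdscan` (subcommands `segment`, `decide`, `compare`, `downsample`,
`simulate`, `escapees`).

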