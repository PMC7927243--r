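---
title: "Measuring single-cell expression variability by Sort-seq: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring single-cell expression variability by Sort-seq: models and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sortnoise)
```

# The measurement problem

Flow cytometry measures the full single-cell fluorescence distribution of a
reporter, but only one strain at a time. Sort-seq trades that direct view for
throughput: a pooled library is sorted by FACS into fluorescence bins, each
bin is sequenced with a bin-specific barcode, and a variant's read counts
across bins become a coarse histogram of its single-cell distribution. This
package reconstructs per-variant distribution statistics — mean, variance,
and noise (CV², the squared coefficient of variation) — from such binned
counts, scores each variant's codon usage, and provides the simulation
machinery needed to validate the whole design before running it.

# From reads to cells

Read counts are not cell counts: sequencing depth differs arbitrarily between
bins. Within each bin we therefore normalise a variant's reads by the bin's
total reads and multiply by the number of cells the sorter deposited in that
bin (a quantity the instrument records). This makes the per-bin column sums
equal `cells_sorted` exactly — an invariant the test suite asserts — and
yields the estimated *cells per bin* used everywhere downstream. The total
over bins is the variant's cells-per-sequence (CPS), its effective sample
size.

# The Gamma model and its fit

Single-cell protein abundance in bacteria is well described by a Gamma
distribution with shape $\alpha$ and scale $\beta$; its mean is
$\alpha\beta$, its variance $\alpha\beta^2$, and its noise
$CV^2 = 1/\alpha$. We fit $\alpha,\beta$ to the binned cell counts by
maximising the interval-censored likelihood

$$\ell(\alpha,\beta)=\sum_b n_b \log\left\{F_{\alpha,\beta}(u_b)-F_{\alpha,\beta}(l_b)\right\},$$

where $F$ is the Gamma CDF, $(l_b,u_b]$ the bin's fluorescence gates on the
*linear* scale (the sorter's gates are log-spaced, so they are converted
before fitting), and $n_b$ the estimated cell count. Two choices deserve
comment:

* **Censored-interval likelihood rather than midpoint moment matching.**
  Log-spaced bins are wide at the top of the range; treating all cells in a
  bin as sitting at one representative value biases variance estimates. The
  likelihood uses the exact probability mass in each interval. Moment
  estimates on the bins' geometric midpoints ($\sqrt{l_b u_b}$) only seed
  the optimiser (Nelder–Mead on $(\log\alpha,\log\beta)$, relative tolerance
  $10^{-10}$).
* **Open extreme bins.** The bottom bin is extended to 0 and the top bin to
  $+\infty$ in the likelihood: cells at the sorter's outer gates are
  boundary-censored, not impossible.

A fit requires cells in at least two bins; anything less is flagged rather
than fit (`fit_gamma_all` records `converged = FALSE` and the pipeline
excludes the variant). The identities mean $=\alpha\beta$, variance
$=\alpha\beta^2$, $CV^2=1/\alpha$ hold for every emitted fit by
construction and are asserted to $10^{-9}$ in the tests.

# Quality filters

Three gates, all configurable, with defaults matching common practice for
this assay type:

* **Occupied bins ≥ 2** — a one-bin variant carries no width information.
* **CPS ≥ 20** — below roughly 20 cells the distribution statistics are
  dominated by sampling noise. "Less than" removes, so a variant with
  exactly 20 cells in exactly 2 bins is kept.
* **Replicate concordance** — across independent experiments the percent
  error of a statistic is defined as its sample standard deviation divided
  by its mean, ×100. Defaults: a variant fails when its mean-fluorescence
  error exceeds 30% **or** its CV² error exceeds 40% (`rule = "either"`).
  The conjunctive alternative — fail only when *both* are exceeded, which
  removes fewer variants — is available as `rule = "both"`; which reading is
  intended varies between labs, so the switch is explicit. Variants seen in
  fewer than two replicates are removed with their own reason code.

The filters commute and are idempotent, so a pipeline may apply them in any
order or re-apply them after a restart without changing the result.

# Virtual binning: choosing a sorting design

Before sorting, one must pick the number of bins and their spacing. The
`virtual_bin`/`cv2_error`/`sweep_report` functions discretise raw
fluorescence samples in silico: each cell's value is replaced by the mean of
its bin's members. Because the representative is the within-bin mean, the
sample mean is preserved exactly, and the binned CV² can only underestimate
the raw CV² (within-bin variance is discarded); the percent error
$|CV^2_{binned}-CV^2_{raw}|/CV^2_{raw}\times 100$ quantifies the
discretisation cost and decreases to zero as bins are added.

Design notes:

* Bin ranges default to the sample min–max, rightmost edge inclusive.
* CV² uses the population ($n$) denominator by default, switchable to
  $n-1$; at the sample sizes involved (thousands of cells) the difference
  is negligible, but the choice is documented because the error measure
  divides one CV² by another.
* **Log versus linear spacing.** For samples spanning decades — which is
  what a fluorescence distribution on a cytometer looks like, approximately
  log-normal — log-spaced bins give clearly lower CV² error than linear at
  20 bins, and the package's property tests assert this on log-normal
  samples. For a mildly skewed Gamma sample binned over its own min–max,
  linear spacing can actually edge out log by a small margin, because the
  log grid over-resolves the thin low tail; the advantage of log spacing is
  a property of decade-spanning data, not of right-skew per se. With 20
  log-spaced bins, simulated unimodal strains of 20,000 cells typically show
  errors of 1–4%, comfortably under the 5% level usually taken as
  acceptable; that margin is what justifies sorting into 20 log-spaced bins
  rather than fewer.

# Codon-usage metrics

All three sequence scores are geometric means of per-codon weights, computed
in log space so that whole-gene scans of long CDSs cannot underflow:

* **CAI** uses a supplied relative-adaptiveness table $w_k$; the packaged
  E. coli table is taken at runtime from `seqinr::caitab`.
* **TAI** builds weights from tRNA gene copy numbers:
  $W_i=\sum_j (1-s_{ij})\,tGCN_{ij}$ over the isoacceptors that read codon
  $i$, with $s_{ij}\in[0,1]$ the codon–anticodon coupling constraint;
  $w_i = W_i/W_{max}$, and codons with $W_i=0$ receive the geometric mean of
  the nonzero $w_i$ (computed *before* any substitution).
* **nTE** divides tRNA supply by codon demand: demand is
  $U_i=\sum_j a_j c_{ij}$ (transcript abundance × codon count, summed over
  genes), normalised to $cu_i = U_i/U_{max}$; then $nTE'_i=w_i/cu_i$ is
  renormalised to a maximum of 1. A codon that never occurs in the genome
  ($cu_i=0$) but has a tRNA weight makes $nTE'$ undefined; the package
  raises an error rather than imputing, since any imputation would be
  arbitrary and silently wrong.
* **GC content** is the G+C fraction of the region, and **ΔΔG** mean-centres
  user-supplied mRNA folding free energies across the library (the package
  does not fold RNA; free energies come precomputed).

Stop codons are rejected with an error rather than skipped: the variable
regions this package scores cannot contain them by construction, so their
presence indicates a frame or parsing problem upstream.

The tAI and nTE source tables shipped under `inst/extdata` are *synthetic*
examples (generated, clearly labelled in their filenames) that demonstrate
the documented file schemas and exercise the weight builders; organism-
specific measured tables should be substituted for real analyses. The
schemas are deliberately minimal TSVs so such substitution is a one-line
change.

# The synthetic data generator

The generator is first-class, tested code: it produces ground-truthed
datasets for every stage. It emulates

* a synonymous codon library (default peptide `VKGEDAFT`, whose synonymous
  space is exactly $4\cdot2\cdot4\cdot2\cdot2\cdot4\cdot2\cdot4=4096$
  sequences, the scale of an 8-codon library);
* Gamma-distributed single-cell fluorescence per variant (shape uniform in
  1–10, mean log-uniform over two decades, 100–10,000 a.u.) — matching the
  fitting model so baseline tests have zero model mismatch; an optional
  log-normal mode with identical mean and CV² provides a mismatch stress
  test;
* broadly uneven library representation (log-normal abundance,
  `sdlog = 1.5`), reproducing the orders-of-magnitude CPS spread that
  motivates the CPS filter;
* multinomial sorting of 2.16 million cells into 20 log-spaced bins whose
  outer gates sit at the pooled library's 0.1 and 99.9 percentiles (cells
  outside the gates are not sorted, as on the instrument);
* barcoded amplicon reads — fixed 5′ flank, 24-base variable region, fixed
  3′ flank, 9-base bin index — at about 195,000 reads per bin (roughly two
  reads per sorted cell) with uniform per-base substitution errors (default
  0.1%). Bin barcodes are generated with pairwise Hamming distance ≥ 3.

It does **not** model sorter droplet physics, doublets, sort impurity, PCR
amplification bias, or cytometer measurement noise. Consequently, passing
the simulation-based tests demonstrates that the *inference machinery* is
correct and well-calibrated under the stated generative model — not that any
particular laboratory dataset satisfies that model. Substitution errors do
create spurious variant sequences at realistic rates, so the demultiplexer's
discard ledger and the CPS filter are exercised realistically.

Every stochastic stage derives its stream from the mandatory config seed
(with fixed per-stage, per-replicate offsets), so simulations are
bit-reproducible and independent replicates are genuinely independent
sorts of the same true library.

# Problem sizes

The shipped tests run scaled-down studies chosen to finish in seconds while
leaving the statistical margins wide: libraries of 20–100 variants,
20,000–60,000 sorted cells, 3,000–6,000 reads per bin (the same ~2
reads/cell ratio as the defaults), two or three replicates. Parameter
recovery at these sizes is strong — rank correlation above 0.95 between true
and recovered means for variants passing the CPS filter — and degrades
monotonically as the CPS cutoff is lowered, which is the behaviour the
filter exists to guard against. The virtual-binning studies use 10 strains
of 20,000 cells, the scale at which single-strain flow data is typically
collected.

# Known limitations

* The Gamma model is an approximation; for strongly bimodal reporters the
  fitted CV² summarises the wrong family. The log-normal stress mode shows
  the fit degrades gracefully (means remain accurate, CV² acquires bias)
  but bimodality is outside the model.
* Cells-per-bin are *estimated* from read fractions; PCR bias between
  variants within a bin would propagate directly and is not modelled.
* The replicate gate's percent-error definition (sd/mean) is one of several
  in use; it is configurable but alternatives (e.g. max pairwise deviation)
  are not implemented.
* Barcode rescue at one mismatch assumes barcodes were designed with
  adequate pairwise distance, as the generator's are.
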