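---
title: "Linking codon usage, translation efficiency and tRNA m5C: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking codon usage, translation efficiency and tRNA m5C: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(m5Ccodon)
```

## The scientific question

Loss of the tRNA cytosine-C5 methyltransferase NSUN2 removes m5C marks from
specific tRNA isodecoders — most prominently at the variable-loop and TΨC-arm
cytosines (canonically C48/C49) of the leucine tRNA Leu-CAA family —
destabilising those tRNAs and selectively slowing translation of mRNAs
enriched in the codons they decode (UUG), while CUG-decoding Leu-CAG is
untouched. Testing that chain of reasoning requires linking three very
different measurements: codon usage bias of coding sequences, translation
efficiency (TE) from paired mRNA-seq and ribosome profiling, and per-cytosine
methylation rates from tRNA bisulphite sequencing, plus qPCR-style readouts
of tRNA charging and fragmentation. `m5Ccodon` implements that analysis chain
as a tested pipeline, together with a seeded synthetic-data generator so that
every estimator can be benchmarked against a known truth.

## Codon usage statistics

For a coding sequence, codons are counted in frame 0; the terminal stop is
tallied under its own codon but stops, AUG and UGG never enter any statistic,
leaving the 59 informative codons.

**RSCU.** For a synonymous family with $n_k$ codons and observed counts
$a_{k1}, \dots, a_{kn_k}$,
$$\mathrm{RSCU}_{km} = \frac{a_{km}}{\frac{1}{n_k}\sum_m a_{km}},$$
so 1 means unbiased usage and the family sum is always $n_k$. A family with
zero observations yields "absent" (`NA`) rather than 0/0. Classes follow the
published cut-offs: over-represented above 1.6, abundant in (1, 1.6],
typical in [0.6, 1], under-represented below 0.6. Both boundary conventions
are taken literally; in particular RSCU = 1 is *typical*, 1.6 is *abundant*.

**GC3s** is the G+C fraction at third positions over codons of degenerate
families only (the three-fold isoleucine family included).

**ENC.** Wright's effective number of codons uses per-family homozygosity
$F = (n\sum p^2 - 1)/(n-1)$ for families observed at least twice, averaged
within degeneracy classes 2, 3, 4, 6, and
$\mathrm{ENC} = 2 + 9/\bar F_2 + 1/\bar F_3 + 5/\bar F_4 + 3/\bar F_6$,
capped at 61. We adopt the conventions of the classic CodonW implementation:
families observed fewer than twice are skipped, a missing three-fold average
(isoleucine unobserved) is imputed as the mean of $\bar F_2$ and $\bar F_4$,
and any other missing or non-positive class average makes ENC undefined
rather than extrapolated. The null ENC-plot curve is the closed form
$\mathrm{ENC}_{exp}(s) = 2 + s + 29/(s^2 + (1-s)^2)$ in GC3s $s$; genes well
below it are more biased than base composition alone explains.

**Correspondence analysis.** The genes × 59 RSCU matrix is decomposed under
the chi-square metric: with correspondence matrix $P = X/\sum X$, masses
$r, c$ and standardised residuals
$S = D_r^{-1/2}(P - rc^{\mathsf T})D_c^{-1/2}$, the SVD of $S$ gives
principal inertias $\lambda_i = \sigma_i^2$ and mass-scaled principal
coordinates. We implement this directly on base `svd()` because the exact
pre-scaling of the classic codon-usage tools is part of what the pipeline
pins down; tests cross-check the inertias against an independent
eigendecomposition of $S^{\mathsf T}S$ and against `MASS::corresp`. Absent
RSCU entries are imputed as 0, and genes with more than 30 absent codons are
dropped and reported — such genes carry too little usage information to
place in the 59-dimensional cloud. A rank-one input (all rows proportional)
has zero total inertia and is returned flagged rather than as an error.

## Translation efficiency

Counts are normalised to counts-per-million per sample; TE is the
pseudo-counted ratio $\mathrm{TE} = (\mathrm{ribo} + \epsilon)/(\mathrm{mRNA}
+ \epsilon)$ with $\epsilon = 0.5$ CPM, computed per replicate. CPM was
chosen over median-of-ratios because the ratio TE is then library-scale free
by construction; $\epsilon$ is the standard low-count stabiliser and pins
TE of doubly-zero genes at 1 (flagged as low evidence). Differential calls
are Welch t-tests on log2 values (CPM for mRNA, TE for TE), two-sided, with
the gates $|\log_2 FC| \ge 1$ and $p < .05$; Benjamini–Hochberg adjusted
p-values are reported alongside but not used for gating. The Welch statistic
is evaluated explicitly so that degenerate groups have well-defined limits
(identical constant groups give $p = 1$, separated constant groups give
$p \to 0$); `stats::t.test` refuses constant data, and the tests verify
agreement with it on non-degenerate inputs. With the mRNA and TE calls in
hand, genes are classified by direction concordance (homo-direction,
opposite, mRNA-only, TE-only, not significant), and the TE-down set is the
gated list ranked by ascending TE log2 fold change with gene-ID tie-breaks
for determinism.

One consequence of CPM worth knowing: when a subset of genes loses
translation, the footprint library is redistributed, so null genes acquire
a small positive TE shift (about $\log_2 1/(1 - 0.15 \cdot 0.75) \approx
0.17$ under the generator defaults) and planted effects are attenuated by
the same amount. This composition bias is inherent to within-sample
normalisation, visible in the slightly asymmetric null false-positive rates,
and left uncorrected — as it is in standard CPM-based TE analyses.

## tRNA methylation

Bisulphite sequencing leaves methylated cytosines unconverted, so the raw
per-site rate is $\mathrm{meth}/(\mathrm{meth} + \mathrm{conv})$. Incomplete
conversion inflates it by a floor $b$; the corrected rate is
$(\mathrm{raw} - b)/(1 - b)$ clamped to [0, 1]. Sites under 10× coverage are
uncalled. Isodecoder-level m5C is the unweighted mean over candidate sites
(rate at least 0.1 in some condition); a coverage-weighted or maximum
summary is switchable but the unweighted mean is the default because
candidate sites at 1000× coverage are estimated almost equally well.
An isodecoder is flagged *lost* when its summarised level falls from at
least 0.5 to at most 0.1 — thresholds chosen to make binary statements such
as "five of six Leu-CAA isodecoders lost their mark" testable; all are
configurable and recorded in the run report. Region densities group called
sites by the secondary-structure annotation (acceptor stem, D-arm,
anticodon arm, variable loop, T-arm, other); canonical labels like "C48"
are carried verbatim from the annotation and never used as indices, since
Sprinzl-style numbering does not match sequence offsets. Sequence context
around strongly methylated sites (rate ≥ 0.5 in the reference condition) is
summarised as a position frequency matrix with a majority-base consensus
(N on ties, N-padding at sequence edges) and per-column information
content; motif significance against a background model is out of scope.

## Integration

TE-down genes are placed on a 4 × 4 grid by their UUG and CUG RSCU classes.
The *explained fraction* is the share of grid genes in a selected set of
cells; the default selection — UUG class at least abundant **and** strictly
above the CUG class in the order under < typical < abundant < over —
operationalises "TE loss attributable to UUG bias relative to CUG". The
published grid memberships are encoded only as figure colours, so the rule
is explicit, configurable, and always reported with the contributing cell
counts; the printed worked example (133 + 15 + 536 of 1917, i.e. 35.7%) is
reproduced as pure arithmetic by the numeric method.

Charging is quantified from the periodate-protection design by
$2^{-[(Ct_{ox} - Ct_{ref,ox}) - (Ct_{nonox} - Ct_{ref,nonox})]}$ — textbook
ΔΔCt, since the underlying protocol publishes no formula — geometrically
averaged over replicates; fragment abundances use the same arithmetic
against U6 and a control condition. The isodecoder expression-change versus
variable-loop methylation-change association uses Pearson correlation in
the pipeline because the generator plants a linear relation; Spearman
remains available (and is the function default) for monotone claims on
real data, where no linearity is guaranteed.

## The synthetic-data generator

The generator emulates the *structure* of the study's data, not any real
genome, and its defaults are the package's fixed study conditions:

* **Coding sequences.** 2000 genes; amino-acid sequences drawn uniformly,
  lengths uniform in 100–500 codons; codons drawn per family from a
  Dirichlet-multinomial with symmetric concentration 1. A 15% subset is
  "UUG-rich": its leucine family gets Dirichlet weight 3 on UUG (others 1),
  giving expected RSCU(UUG) $= 6 \cdot 3/8 = 2.25$, inside the
  over-represented band without being deterministic.
* **Expression.** Gene abundances are log-normal (sdlog 1) around a library
  size of $10^6$; three replicates per condition. Each replicate draws a
  per-gene biological factor (gamma, mean 1) *shared* by its paired mRNA
  and footprint libraries, with independent technical negative-binomial
  noise on top; the technical dispersion is 0.02 and the biological share
  is solved so each assay's marginal dispersion is exactly 0.1 (typical
  bulk RNA-seq). The sharing matters: paired profiling prepares both
  libraries from the same sample, so biological variation cancels in TE —
  that cancellation is the reason TE is computed per replicate, and a
  generator with fully independent noise would misrepresent the design's
  power. UUG-rich genes get a TE log2 fold change of −2 in the knockdown;
  5% of genes get an mRNA-only shift of ±1; everything else is null.
* **Bisulphite.** Ten synthetic 76-nt isodecoders with cloverleaf-style
  region blocks and planted cytosines at a variable-loop position (labelled
  C48, in a C-A-C context) and a T-arm position (C49). Control rate 0.85 at
  planted sites of substrate tRNAs; knockdown 0 for five of six Leu-CAA and
  for Gly-GCC/Glu-UUC/Val-AAC, 0.25 for the spared Leu-CAA-4-1, unchanged
  for Leu-CAG; background 0.02 elsewhere. Counts are binomial at 1000×
  with a 1% non-conversion floor applied as false methylation
  ($q = \mathrm{rate} + (1-\mathrm{rate})b$); over-conversion of true m5C
  defaults to 0. Isodecoder expression changes are a linear function of
  retained knockdown methylation plus Gaussian noise (sd 0.2), so the
  spared isodecoder rises while demethylated ones fall.
* **qPCR.** $Ct = \mathrm{base} - \log_2(\mathrm{quantity}) +
  \mathcal N(0, 0.15)$ per channel, with spike-in and U6 references;
  charged fractions 0.8 → 0.4 for Leu-CAA (unchanged for Leu-CAG), mature
  Leu-CAA halved and three 3′-tRFs at 4× in the knockdown.

Every generator is a pure function of (design, seed): generators draw from
independent seed-derived streams and restore the session RNG state, so the
full pipeline is byte-reproducible. What the generator does **not** emulate:
real codon-usage covariation across families (axes of the synthetic CA are
noise-dominated, so published inertia shares such as 38.46%/5.84% are not
reproducible here), isoform structure, positional ribosome occupancy,
bisulphite mapping artefacts, or genuine motif structure beyond the planted
context. Passing tests therefore demonstrate estimator correctness and
end-to-end recovery of planted effects, not biological realism.

## Truth definitions and tolerances

Recovery tests compare estimates to generator truth as like for like:

* The TE-down recovery is judged by the purity of the ranked top 300
  (planted-gene share) and by the null false-positive rate at $p < .05$,
  on the full 2000-gene design.
* The end-to-end *truth* explained fraction applies the same cell rule to
  the genes planted with a TE effect using their realised sequences — not
  to the latent Dirichlet propensities. RSCU is computed exactly from the
  sequence, so the only estimated ingredient in the explained fraction is
  the TE call set, and the truth comparison isolates exactly that. (Judged
  against latent propensities instead, class-boundary noise at roughly 15
  leucines per gene alone shifts the fraction by about 0.08.)
* qPCR recovery is asserted within three standard errors of the ΔΔCt
  estimator: with Ct noise of sd 0.15 on each of four channels and three
  replicates, the log2 standard error is $2 \cdot 0.15/\sqrt 3 \approx
  0.17$, i.e. a single estimate is only ±13% at one sigma — tighter
  advertised recoveries would fail under the noise model itself.
* Binomial rate recovery is asserted within three binomial standard
  deviations at the simulated coverage; estimator consistency is checked
  at $10^4$ coverage with tolerance 0.02.

Problem sizes in the routine test-suite runs are scaled to desk use (80–600
genes for module tests; the full 2000-gene design for the recovery and
end-to-end checks), chosen so the whole suite runs in well under a minute
of simulation time while keeping every planted effect comfortably
identifiable.

## Degenerate inputs and numerical choices

Zero-total families are "absent", never 0/0; ENC is `NA` rather than
extrapolated when a class average is missing or non-positive; CA drops
zero-mass rows/columns before decomposition and flags zero total inertia
(below $10^{-12}$); library sizes of zero are errors, not NaNs; ties in the
TE ranking and in PFM consensus are broken deterministically (gene ID,
N respectively); uncalled methylation sites propagate as `NA` and are
counted, never silently dropped. All tabular outputs are written with
fixed, locale-independent formatting so identical seeds give byte-identical
runs.

## Known limitations

* The pipeline consumes gene-level count tables and per-site bisulphite
  counts; alignment, P-site assignment and mapping QC are upstream.
* The explained-fraction cell rule is a policy, not an inference; the
  package reports it with its cells and counts so alternatives can be
  compared, but it makes no causal claim.
* CPM composition bias (above) is reported, not corrected.
* Only the standard genetic code is supported, and tRNA positions are plain
  0-based sequence offsets; Sprinzl renumbering is carried as annotation
  only.
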