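# m5Ccodon

An integrative analysis pipeline for the chain of evidence linking **tRNA
m5C methylation**, **tRNA stability**, and **codon-biased translation**.
When the tRNA cytosine-C5 methyltransferase NSUN2 is lost, specific tRNA
isodecoders (most prominently the Leu-CAA family) lose their m5C marks at
variable-loop/TΨC-arm cytosines (C48/C49), become unstable, and translation
of mRNAs enriched in the codons they decode (UUG) drops — while the
CUG-decoding Leu-CAG is untouched. Testing that chain requires three
different measurements analysed coherently; `m5Ccodon` provides each layer
as reusable functions plus an end-to-end, seeded, fully reproducible
pipeline, with a synthetic-data generator so every estimator is benchmarked
against known truth.

The package is aimed at computational biologists working with paired
mRNA-seq/Ribo-seq experiments and tRNA bisulphite sequencing.

## What it computes

**Codon usage** — per-gene codon counts; relative synonymous codon usage
over the 59 informative codons,

```
RSCU_km = a_km / ((1/n_k) * sum_m a_km)
```

with over/abundant/typical/under classes at the 1.6 / 1 / 0.6 cut-offs;
GC3s; Wright's effective number of codons

```
ENC = 2 + 9/F2 + 1/F3 + 5/F4 + 3/F6        (capped at 61)
```

with the expected-ENC null curve `ENCexp(s) = 2 + s + 29/(s^2 + (1-s)^2)`;
and correspondence analysis of the genes × 59 RSCU matrix (chi-square
metric, SVD of standardised residuals, principal inertias and coordinates).

**Translation efficiency** — CPM normalisation; per-replicate
`TE = (ribo + 0.5)/(mRNA + 0.5)`; Welch differential tests on log2 values
with the `|log2FC| >= 1`, `p < .05` gates; direction-concordance classes
(homo-direction / opposite / mRNA-only / TE-only / ns); ranked TE-down
selection.

**tRNA methylation** — per-cytosine bisulphite rates with non-conversion
correction `(raw - b)/(1 - b)`; isodecoder-level m5C summaries and
lost-mark flags; methylation density by secondary-structure region;
sequence-context position frequency matrices with consensus.

**Integration** — the UUG × CUG cluster grid over TE-down genes and its
*explained fraction*; ΔΔCt quantification of tRNA charging
(periodate-protection design) and tRNA/3′-tRF abundance; isodecoder
expression-vs-methylation correlation.

## Worked example

```r
library(m5Ccodon)

# the 6x-TTG reporter linker: one leucine family, all mass on UUG
rscu <- compute_rscu(count_codons("TTGTTGTTGTTGTTGTTG"))
rscu["UUG"]
#> UUG
#>   6
classify_codon(rscu["UUG"])
#>               UUG
#> "overrepresented"

# the explained-fraction arithmetic on printed cluster counts
ef <- explained_fraction(c(133, 15, 536), total = 1917)
sprintf("%.1f%% (%d/%d)", 100 * ef$fraction, ef$explained_count, ef$total_count)
#> "35.7% (684/1917)"

# full synthetic run: generate data, profile TE, codon usage,
# methylation, and integrate
cfg <- run_config(seed = 1, out_dir = "m5c_run")
rep <- run_pipeline(cfg)
rep
#> <pipeline_report>
#>   seed: 1
#>   TE-down genes selected: 288
#>   CA axis 1/2 shares: 4.50% / 4.35%
#>   isodecoders lost: 8 of 10
#>   explained fraction (UUG rule): 0.670 (193/288)
```

Reading the report: of the 300 genes planted with a −2 TE log2 fold change,
288 pass the `log2FC <= -1, p < .05` gates; 8 of the 10 panel isodecoders
(five of six Leu-CAA plus the three other substrate families — not the
spared Leu-CAA-4-1, not Leu-CAG) are flagged as having lost their m5C mark;
and 67% of the called TE-down genes fall in grid cells where the UUG class
is at least abundant and exceeds the CUG class. Every backing table
(TE records, RSCU/ENC/CA, site rates, region densities, cluster grid,
charging and fragment quantities, JSON run report with the resolved
configuration) is written under `out_dir`; two runs with the same seed are
byte-identical. The CA axis shares are small by design — the synthetic
codon sampler has no cross-family covariation, so no dominant usage axis
exists (see the methods vignette in `vignettes/`).

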