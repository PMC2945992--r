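# cassettexpress

Relative transcription analysis for gene cassettes in large
integron-associated arrays, measured by degenerate-primer *attC* PCR and
high-resolution fragment analysis.

## The problem and who this is for

Integrons accumulate mobile gene cassettes — usually one ORF bounded by an
*attC* recombination site — into tandem arrays that can exceed a hundred
cassettes. The integron's own promoter can only transcribe the first few, so
the question for anyone studying these arrays is whether, where and under
what conditions the rest are expressed. A single degenerate primer pair
binding the conserved *attC* core amplifies a subset of cassettes as
size-distinguishable fragments; comparing the fragment fingerprint of cDNA
against the gDNA fingerprint of the same culture turns one multiplex PCR into
a per-cassette relative expression assay.

This package implements that assay's full analysis for microbial geneticists
working with cassette arrays:

* **in-silico attC PCR** — locate degenerate primer sites (IUPAC-aware, with
  mismatch tolerance), predict amplicons, and build the *size-class map*
  (amplicon length → cassette positions, unique vs ambiguous);
* **fingerprint processing** — peak-table I/O, ladder calibration, binning
  onto a 1 bp continuum, RNA/water contamination QC, inter-PCR normalization
  by the summed peak height above 90 bp, triplicate statistics (%SE), and
  class matching with +1 bp poly-A correction;
* **expression analysis** — per-class expression ratio

  `ratio(class) = mean normalized cDNA height / mean normalized gDNA height`

  with gDNA stoichiometry as the internal standard; conditional-expression
  calls at the replicate-derived significance threshold
  `1 + z × %SE/100` (1.96 × 50 %SE ≈ 2-fold); blocs of similarly expressed
  adjacent cassettes (< 3-fold internal spread); candidate intra-array
  promoter positions;
* **promoter localisation** — sigma-70 consensus scanning (TTGACA … 15-19 bp
  … TATAAT, match-count score), nested-PCR transcript-start bracketing, and
  qPCR promoter activity `E^(Ct_bridging − Ct_downstream)`;
* **a synthetic study generator** — a 116-cassette reference array with
  planted primer sites, expression program, noise model and junction
  promoter, so the whole pipeline is testable end to end without any
  external data.

## Worked example

```r
library(cassettexpress)

cfg <- generator_config()            # the packaged synthetic reference study
dir <- tempfile("study")
write_synthetic_dataset(dir, cfg)    # array FASTA + annotation, peak tables,
                                     # ladder, qPCR table, manifest
res <- run_pipeline(file.path(dir, "manifest.yaml"))

res$size_classes
#> <size_class_map> 90 size classes ( 75 unique, 15 ambiguous ), 116 cassette positions

sum(res$profiles[["28C"]]$gdna_detected)   # classes the wet PCR can see
#> [1] 62
p28 <- res$profiles[["28C"]]
sum(p28$cdna_detected & p28$gdna_detected) # expressed under optimal growth
#> [1] 39

max(res$calls_by_series$oxidative_18h$max_fold, na.rm = TRUE)
#> [1] 13.64201                           # planted 11.4-fold induction + noise

res$candidate_promoters                    # silent positions beside expressed
#> [1]  19  36  60  96  99 106 108 109

res$promoter_hits[1, ]                     # planted sigma-70 junction promoter
#>   minus35_offset minus10_offset spacer score junction
#> 1          12518          12541     17    12       20

res$qpcr_fold                              # promoter activity (planted 40)
#> [1] 42.85094

res$blocs[res$blocs$treatment == "28C", c("start", "end")]
#>    start end                             # includes blocs 21-23 and 31-35
#> 6      2   5
#> 7     21  23
#> 8     31  35
#> 9     40  42
#> 10    52  55
```

Reading the numbers: the in-silico PCR finds 90 distinct amplicon lengths for
116 cassettes, of which 75 identify a unique position. The simulated wet PCR
detects 62 classes in gDNA; 39 of those are detectably expressed at 28 °C.
The 18 h oxidative series recovers the planted 11.4-fold induction to within
replicate noise (triplicate PCRs at ~12 %SE make a cross-treatment fold a
ratio of four noisy means, ±20-25%). The never-expressed positions flanked by
expressed cassettes mark candidate intra-array promoters, one of which — the
cassette 20/21 *attC* junction — carries the planted sigma-70 promoter
recovered by the scan with a perfect 12/12 score and ~40-fold downstream qPCR
activity.

A thin command-line front-end is installed with the package
(`inst/scripts/cassette-xpress`): `simulate`, `predict`, `run`,
`scan-promoters`, `qpcr`.

See the methods vignette
(`vignettes/cassette-expression-methods.Rmd`) for the model, parameter
defaults, the synthetic study design and its limitations.

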