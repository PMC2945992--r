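---
title: "Relative transcription of gene cassettes in large integron arrays: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Relative transcription of gene cassettes in large integron arrays: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cassettexpress)
```

## The measurement problem

Integrons capture mobile gene cassettes — typically a single ORF bounded by an
*attC* recombination site — into tandem arrays that can run to hundreds of
cassettes. The integron-borne promoter Pc can only plausibly transcribe the
first few cassettes, so whether genes deep inside a large array are expressed
at all, and from where, is the central question this package's pipeline is
built to answer.

The measurement exploits the conserved core of *attC*: a single degenerate
primer pair (YB4 forward, YB3 reverse, both binding inside *attC* sites)
amplifies a subset of all cassettes in one multiplex PCR, each cassette as a
product of characteristic length. Run on genomic DNA (gDNA) the reaction
reports cassette stoichiometry; run on cDNA (reverse-transcribed RNA) it
reports transcript abundance. High-resolution fragment analysis of the
fluorescent products yields, per sample, a *fingerprint*: a table of fragment
sizes and peak heights. The per-cassette expression measure is the ratio of
normalized cDNA to gDNA peak height for the cassette's amplicon size class,
with the gDNA sample acting as the internal quantitative standard.

## Size classes and their ambiguity

`predict_amplicons()` performs in-silico PCR: degenerate primer sites are
located (IUPAC-aware matching, optional mismatches), and each forward site is
paired with the nearest downstream reverse-strand site within
`max_product_len` (default 1100 bp — multi-template PCR is dominated by the
shortest available product, and the instrument resolves single base pairs
only up to about 1000 bp). Product length is counted from the 5' end of the
forward site through the 3' end of the reverse site, inclusive, the standard
in-silico PCR convention. `build_size_classes()` groups amplicons by exact
length: a *size class* is **unique** when exactly one cassette position
produces it, **ambiguous** otherwise (repeated cassettes, or different
cassettes of equal length). Expression is always reported per size class;
the signal of an ambiguous class is never apportioned among its member
positions.

Coordinates are 1-based inclusive throughout, the R/Bioconductor convention;
cassettes are referred to by their 1-based ordinal in the array.

## From peak tables to expression ratios

The analytical chain, per treatment, is:

1. **Calibration** (`calibrate_sizes()`): migration units to bp by piecewise
   linear interpolation of a ladder. Any strictly monotone ladder is
   accepted; extrapolation is allowed for at most one segment length beyond
   the ladder ends and is flagged. (A local-Southern option is a recognised
   alternative calibration model but is not implemented.)
2. **Contamination QC** (`check_contamination()`): RNA and water controls
   must be free of amplification; a control peak above the normalization
   floor at or above the detection height fails the *entire* sample set,
   which is then excluded from every downstream step.
3. **Binning** (`bin_to_continuum()`): peak heights are accumulated onto a
   1 bp integer continuum (default 50-1100 bp), rounding half-up; binning
   conserves total in-range height exactly.
4. **Normalization** (`normalize_fingerprint()`): every bin is divided by the
   summed height of all bins strictly above `norm_floor_bp` (default 90 bp,
   excluding primer artefacts). This above-90 bp sum is the only inter-PCR
   standard — there is no housekeeping amplicon in a multiplex *attC* PCR —
   so cross-treatment comparability rests on it alone.
5. **Replicate statistics** (`aggregate_replicates()`): triplicate PCRs give
   per-bin mean, standard error (sample sd, n - 1, divided by sqrt(n)) and
   %SE = 100 x SE/mean. The n - 1 convention is stated explicitly because
   the noise calibration below depends on it.
6. **Class matching** (`match_classes()`): occupied bins are assigned to
   predicted class lengths within the `match_window` (default offsets
   {0, +1}), which folds the +1 bp non-templated poly-A satellite back into
   its parent class. Each bin is consumed by at most one class: the nearest
   class wins, ties go to the smaller length. Class heights are summed per
   replicate before the mean/SE are recomputed, so class-level statistics
   are exact rather than approximated from bin-level ones.
7. **Expression** (`compute_expression()`): ratio of mean normalized cDNA to
   mean normalized gDNA height per class. A class undetected in gDNA yields
   `NA`, never a silent zero. Detection uses the *raw* (pre-normalization)
   mean height against `detect_height_min` (default 50 fluorescence units, a
   configurable instrument-floor choice).

Ratios are relative: a class with equal normalized share in cDNA and gDNA has
ratio 1, and no absolute transcript units are claimed.

## Significance, conditional calls, blocs, candidate promoters

Replicate variability sets the significance rule. With a conservative 50 %SE
per amplicon measurement, a change is significant at 95% confidence when it
exceeds `derive_threshold(50, 1.96)` = 1.98 ≈ 2-fold; this is the default
`conditional_fold`. `call_conditional()` compares, per class, the maximum
fold change across *all* treatment pairs of a series (the spec leaves open
whether adjacent levels or extremes are compared; the max-over-pairs rule is
used and is the more sensitive reading). Classes expressed in some
treatments but undetectable in others are called
`conditional_from_undetectable`, since their true induction is only bounded
from below. No multiple-testing correction is applied: the 2-fold rule is a
fixed per-class threshold by design, and the z/SE knobs are exposed instead.

`detect_blocs()` finds maximal runs of at least two adjacent expressed
cassette positions whose ratios differ by less than `bloc_fold` (default 3),
the signature of a shared intra-array promoter. Only uniquely located
classes supply positions; ambiguous positions are skipped neutrally by
default (they neither join nor break a run) because their expression cannot
be placed. `candidate_promoter_regions()` reports positions detectable in
gDNA but never expressed under any treatment that sit next to an expressed
position — an expressed downstream neighbour requires a promoter between
them.

## Promoter localisation

`scan_sigma70()` enumerates every (-35, spacer, -10) placement with spacer
15-19 bp and scores it by simple match count against TTGACA/TATAAT (12
positions). A position-weight matrix would be unidentifiable from the single
consensus-like example the assay design rests on, so the plain match count
with a default threshold of 9/12 is used; the threshold admits partial -35
homology while keeping random-background hits rare, and it is configurable.
Only the forward strand is scanned: *attC* orients cassettes uniformly, so
only forward-strand promoters can drive cassette transcription.

`infer_transcript_interval()` turns nested-PCR presence/absence patterns into
a bracket on the transcript 5' end: the start lies strictly between the
rightmost forward-primer site whose cDNA pair fails and the leftmost forward
site whose pair succeeds, provided every pair amplifies on gDNA (primer-site
integrity) and no success lies upstream of a failure with the same reverse
primer (otherwise an error names the conflicting pairs). The bracket is
exclusive of the primer sites themselves, and is only guaranteed to contain
the start when the start does not fall inside a primer site — which is the
biological situation, since the primers sit in ORFs and promoters in
intergenic *attC* regions.

`qpcr_fold_change()` computes E^(Ct_bridging - Ct_downstream) with efficiency
E fixed at 2.0 by default (no standard curve is modelled; the value is
configurable). A finite residual bridging signal is a result, not an error:
it quantifies read-through transcript from a further upstream promoter.

## The synthetic reference study

`generator_config()` packages a complete synthetic emulation so that every
stage is testable without external data. The defaults *are* the study
conditions and are not tuning knobs:

* 116 cassettes in 90 size classes, 75 unique; 91 coding and 25 non-coding
  cassettes, 8 coding on the reverse strand; 62 classes amplifiable by the
  wet PCR (50 unique + 12 ambiguous, i.e. 74 accessible positions). The
  published counts fix the ambiguity arithmetic: the 12 detectable ambiguous
  classes have two members each and the 3 undetectable ones share 17
  members (6 + 6 + 5).
* Undetectable classes are realised mechanistically as a single planted
  mismatch in the forward primer site, not as zero heights: in-silico
  prediction with one tolerated mismatch sees all 90 classes, while the
  zero-mismatch wet PCR amplifies only 62. (`find_primer_sites()` itself
  defaults to zero mismatches.)
* Treatments: overnight thermal series 4/14/28 °C and two oxidative series
  (0/0.9/1.8/3.6 mM H2O2, 30 min and 18 h), triplicate PCRs throughout.
* The expression program plants: 39 of the 62 detected classes expressed
  under optimal growth (28 °C); a 128-fold dynamic range between the most
  and least expressed classes (cassettes 95 and 11) — the study statement is
  an open lower bound of 100-fold, so the emulation plants a margin above
  it; blocs at cassettes 21-23 and 31-35 with the former several-fold
  higher; two constitutive classes (cassettes 23 and 70); an 11.4-fold
  maximal induction of cassette 57's class under 18 h oxidative stress, with
  other strong responders (cassettes 10, 20, 104) peaking under different
  stressors; never-expressed detectable positions at 19, 36, 60, 96, 99,
  106, 108 and 109 adjacent to expressed neighbours (the candidate promoter
  regions); and the class of cassette 11 undetectable under oxidative
  stress.
* Every non-baseline treatment is built from the baseline by explicit
  abundance *transfers* between classes, so total transcript mass is
  conserved exactly within each series. This makes the above-90 bp
  normalization an exact cross-treatment standard in the emulation; in real
  data that is an assumption, and fold changes absorb any violation of it.
* Replicate noise is multiplicative lognormal per amplicon per replicate
  (fragment heights are positive with roughly proportional error, and the
  reported variability unit, %SE, is relative). The default sigma = 0.238
  was calibrated once by simulation so that the mean %SE across detected
  classes at n = 3 is about 12; with that convention fold estimates between
  two treatments are ratios of four triplicate means and carry a relative
  SD of roughly sqrt(4) x 12% ≈ 24%, which is the irreducible recovery
  noise of planted effect sizes at n = 3.
* A poly-A fraction of 0.5 of each amplicon's product is shifted +1 bp;
  class lengths are distinct even integers in 150-1000 bp so a +1 bp
  satellite can never collide with another class's bin.
* A full-consensus sigma-70 promoter (TTGACA, 17 bp spacer, TATAAT) is
  planted inside the *attC* junction between cassettes 20 and 21, with
  transcript start 7 bp downstream of the -10 element and a 40-fold
  downstream:bridging transcript ratio for the qPCR model
  (Ct = c0 - log_E(abundance) + N(0, 0.1 cycles)). The junction sequence is
  synthetic; no claim is made about any real cassette junction.
* The synthetic instrument migrates fragments linearly in size (ladder every
  50 bp), so piecewise-linear calibration is exact. Real electrophoretic
  mobility is nonlinear in fragment length; calibration error is therefore
  exercised by the unit tests, not by the reference fixture.
* Sequence background is i.i.d. uniform A/C/G/T outside planted sites, which
  makes motif false-positive rates predictable but is not a real genome
  composition.

Everything is deterministic under `rng_seed`; identical configuration and
seed give byte-identical datasets and reports.

What passing tests on this emulation do **not** show: performance on real
traces (peak picking, pull-up and stutter artefacts are out of scope),
robustness to non-conserved transcript mass across treatments, PCR
efficiency differences between amplicons (the gDNA ratio cancels
amplicon-specific bias only to first order), or strand-of-transcription
resolution — the *attC* PCR cannot attribute expression to reverse-strand
ORFs, which is why summaries exclude classes whose only members carry
reverse-strand genes (the generator places those cassettes in undetectable
classes so the exclusion is structural).

## Worked example

```{r example, eval = FALSE}
cfg <- generator_config()                 # the packaged reference study
dir <- tempfile("study")
write_synthetic_dataset(dir, cfg)         # FASTA, TSV, CSVs, manifest
res <- run_pipeline(file.path(dir, "manifest.yaml"))

res$size_classes                          # 90 classes, 75 unique
sum(res$profiles[["28C"]]$gdna_detected)  # 62 detected in gDNA
max(res$calls_by_series$oxidative_18h$max_fold, na.rm = TRUE)  # ~11.4
res$candidate_promoters                   # never-expressed flanked positions
res$promoter_hits[1, ]                    # the planted junction promoter
res$qpcr_fold                             # ~40
```

Problem sizes throughout (a ~72 kb array, 11 treatments, triplicates) were
chosen so the whole reference analysis runs in seconds on a single CPU.

## Known limitations

The pipeline quantifies relative transcription of amplifiable size classes;
it does not infer operon structure or transcript isoforms from fingerprints,
does not model PCR thermodynamics or template competition, and treats the
2-fold rule exactly as stated rather than embedding it in a formal multiple
testing framework. Ambiguous classes remain ambiguous: resolving them
requires sequencing, not fragment lengths.
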