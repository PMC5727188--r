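---
title: "Methods: pause-release waves, damage sensing and mutation landscapes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pause-release waves, damage sensing and mutation landscapes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wavescape)
```

## The model

After UV irradiation, RNA polymerase II (RNAPII) molecules paused at
promoter-proximal pause (PPP) sites, roughly 60 bp downstream of
transcription start sites, are released into productive elongation across
essentially the whole active gene set. This package quantifies that response
and its downstream consequences with five connected instruments:

1. **Escape Index (EI).** For each gene, EI = Db / Dp, where Dp is the mean
   read density (rpm) over the promoter-proximal window (−250 to +100 bp
   around the TSS) and Db the mean over the gene body (101 bp to 2 kb
   downstream, truncated at the TTS for short genes). The between-condition
   ratio ΔEI = EI(+UV) / EI(NO UV) measures pause release; the fraction of
   genes with ΔEI > 1 is tested against a symmetric null (50%) by a
   df = 1 chi-square.
2. **Wave kinetics.** The composite (metagene-averaged) density profile of
   elongating RNAPII after UV shows an enriched plateau from the TSS out to a
   time-dependent *front*; the front is located where the smoothed profile
   crosses a threshold midway between the enriched plateau and the
   steady-state baseline, and elongation rates are displacement over time
   between consecutive fronts. The *backend* (lagging edge, used for drained
   pri-elongating profiles) is the mirrored rising crossing.
3. **TT-locus stalling.** TT dinucleotides are the dominant UV-dimerisable
   sites. Loci matching XTTX (X ∈ {A, C, G}) on the gene's template strand —
   the strand RNAPII reads, i.e. the reference minus strand for '+' genes —
   are called from the TSS outward, isolation-filtered (no other match within
   70 bp) and stripped of PPP-proximal positions (< 2 kb). Around each locus,
   the 'S − F' score (mean density over the central summit window minus the
   pooled outer flanks) separates genuine stalling from the wave merely
   passing by; the significance threshold is mean + 3 SD of the same score at
   exon-start control loci, which are not dipyrimidine-enriched.
4. **Repair meta-analysis.** Excision-repair read pileups (XR-seq-like,
   both strands pooled) around the same TT loci are scored with the identical
   'S − F' machinery over narrower (±60 bp) windows.
5. **Mutation landscapes.** From substitution catalogs, the UV signature
   keeps C>T (and reverse complement G>A) in the TCC (GGA) trinucleotide
   context; the smoking signature keeps G>T (C>A) in TGG (CCA). Because the
   damaged base is known, each genic record maps to the template (TS) or
   non-template strand (NTS): for a '+' gene, reference-strand C>T or G>T
   means the adduct sat on the non-template strand. Prevalence is mutations
   per Mb per sample in transcription-oriented windows, divided by the local
   exon fraction for exome data, stratified by expression class (NE and
   Lo/Med/Hi terciles from the kernel-density RPKM threshold), and compared
   with Wilcoxon rank-sum tests on 15-gene bins with BH adjustment.

## Parameters that matter

| Parameter | Default | Units | Why |
|---|---|---|---|
| promoter window | −250..+100 | bp around TSS | Dp region of the escape index |
| gene-body window | 101..2000 | bp downstream | Db region, truncated at the TTS |
| activity Rd threshold | 0.7 | rpm | promoter density floor for "active" calls |
| wave threshold | midpoint of plateau/baseline | rpm | the transition is defined only up to an "arbitrary threshold"; the midpoint maximises margin to both levels and is logged |
| `min_run` | 3 | bins | consecutive-bin persistence guard against single-bin noise |
| TT isolation distance | 70 | bp | excludes clustered dipyrimidines whose windows would overlap |
| PPP exclusion | 2000 | bp | removes pause-peak signal from locus windows |
| summit / flank fractions | 0.20 / 0.25 | of window bins | ≈160 bp summit inside a ±400 bp ChIP window; ≈24 bp inside ±60 bp repair windows |
| FC threshold | 2 | ratio | high-fold-change call, strict `>` |
| 'S − F' threshold | control mean + 3 SD | rpm | ≈0.13% false positives under Gaussian control scores |
| locus window bins | 50 (ChIP), 10 (repair) | bp | figure-legend bin sizes are not printed; these resolve the two window scales and are configurable |
| metagene bin | 200 | bp | front localisation to ±1 bin at 60 kb span |
| prevalence window | 2000 | bp | gene-body profile resolution (configurable) |
| exon-fraction floor | 0.01 | fraction | windows below it are masked, never divided |
| moving-average width | 200 | genes | expression-rank smoothing of per-gene prevalence |
| comparison bin | 15 | genes | pools sparse mutation counts before rank tests |

## Numerical choices

* **Coordinates** are 0-based half-open everywhere internally (BED-native);
  catalog files are 1-based inclusive on disk and converted on read.
* **Region means** treat the binned track as a piecewise-constant density and
  integrate it exactly, so partial-bin regions have no grid artefacts, and a
  minus-strand extraction is exactly the reversed plus-strand extraction.
* **Front interpolation.** Within the crossing bin the profile value v is
  modelled as partial coverage between the neighbouring plateau (hi) and
  baseline (lo) levels: the front covers a fraction (v − lo)/(hi − lo) of the
  bin. For a clean two-level step this recovers the step position *exactly*
  for any threshold strictly between the levels; linear interpolation between
  bin centers would be exact only at the midpoint threshold.
* **Ties and ordering.** "Longest isoform" ties break lexicographically by
  id; equal-count cluster partitions put the remainder in the earliest
  clusters; expressed-gene terciles give the remainder to the highest class.
* **Degenerate inputs.** Dp = 0 genes carry an undefined flag and are
  excluded from percentages (with counts reported) rather than imputed;
  unimodal expression densities fall back to a configured quantile with a
  warning; empty locus sets return the input unchanged with a warning.
* **Statistics.** Pairwise t-tests are Welch (no pooled SD); Wilcoxon tests
  are exact where R's implementation allows; BH adjustment runs over one
  panel's pairwise family at a time; 2×2 chi-squares use no continuity
  correction.

## The synthetic world

The generators emit the statistical structure the analysis assumes, not
realistic sequencing data. Defaults describe the stated world used by the
acceptance suite:

* genome: i.i.d. bases, uniform composition (TT density is controlled by the
  base probabilities);
* annotation: genes laid with ≥2 kb gaps (inter-TSS ≥ 1 kb by construction),
  3–8 exons spread along the body, biotypes 70/20/10
  protein-coding/lncRNA/other;
* tracks: pause peak 8 rpm over −60..+100 bp, body baseline 1 rpm, post-UV
  plateau 4 rpm out to fronts of 5/15/25 kb at 30/60/120 min (decaying
  velocity 0.33 then 0.17 kb/min), Gaussian noise truncated at zero;
* escape: 90% of genes gain the plateau after UV; the remaining 10% get a
  0.7× body depletion. The depletion — rather than an unchanged profile —
  reflects that the non-escaping minority sits *below* the ΔEI = 1 diagonal
  in the observed scatter; with an unchanged profile, noise would push about
  half of that group above ΔEI = 1 and the cohort would not read out at the
  stated 90%;
* stalling: half of the upstream TT loci receive a +3 rpm summit over a
  ±160 bp core. The core width is a geometry constraint: it must cover the
  central-20% summit of the ±400 bp, 50 bp-binned window at any grid
  alignment while staying clear of the outer-25% flanks (±200 bp). The
  repair track mirrors stalled loci at ±20 bp on a 10 bp grid for the same
  reason at the ±60 bp window scale;
* expression: symmetric two-component log2 mixture at −4 and +4 (SD 1.5);
* mutations: Poisson per gene and strand at 100 (NE) vs 20 (E NTS) mutations
  per Mb per sample with TS = 0.5 × NTS in expressed genes, 20 samples,
  placed only at genuine signature-context positions so the context filter
  has true positives by construction.

What a green test does **not** establish: the generator has no read-level
error model, no alignment artefacts, no chromatin covariates, no non-uniform
genomic base composition, and a hard two-level wave (a linear-decay front is
not the default). Agreement on this world validates the *arithmetic and the
statistical machinery*, not biological discovery on real data.

## Design choices where the design was open

* **Rule order in curation.** The biotype filter runs before the TSS
  distance rules, so non-coding clutter cannot evict retained genes; a note
  is logged whenever the two orders disagree on a given input.
* **Exon-start controls.** The default mode reproduces the substring
  selection of exon ids beginning with "e2" (e2, e20, e21, ...); an
  `ordinal_second` mode returns exactly the second exon, since the substring
  behaviour is likely unintended upstream.
* **Template strand.** "Non-coding strand" is read as the template strand
  (where a TT photodimer blocks RNAPII); a flag flips the interpretation.
* **Locus scan bounds.** The scan stops at min(TTS, TSS + 1 Mb); a flag
  allows the raw 1 Mb window for genes shorter than 1 Mb.
* **Locus windows** are centred on the locus (the alternative reading —
  windows anchored at the TSS — would make per-locus scores meaningless).
* **Chi-square null for ΔEI** is 0.5 ("purely by chance" unquantified);
  configurable.
* **Activity edge case.** A gene with an elongating-isoform peak but
  promoter Rd ≤ 0.7 rpm is not active; it falls to poised only with
  ser5P/hypo evidence, and the situation is flagged in the output.
* **Per-sample normalisation** divides by the total number of samples in the
  catalog, not by samples bearing at least one mutation.
* **'S − F' control threshold** is computed per timepoint by default; the
  false-positive-rate check in the acceptance suite pools controls across
  replicates because the 0.13% Gaussian-tail figure presumes well-estimated
  control moments.
* **Orchestration** is R-native: `run_pipeline()` with a list/JSON
  configuration (unknown keys rejected), per-stage TSV outputs, resume from
  existing files, and a manifest with parameter echo and output checksums.
  The exported functions are the interface; there is no shell entry point.
* **Scaled-down nulls.** The 100-seed null simulation for the binned
  prevalence comparisons runs on a 600-gene world (the full 1000-gene world
  is used for the single-catalog recovery checks) to keep the suite inside
  its runtime budget; the Wilcoxon bin counts remain large enough for
  adjusted P ≤ 0.01 to be reachable under the alternative.

## Known limitations

* Coverage is interval-based; spliced alignments are treated as their
  aligned blocks (no CIGAR awareness).
* Reproduction of printed front positions on real data is
  threshold-sensitive, since the original transition thresholds are not
  printed; the package logs its threshold and exposes it.
* Exact figure bin sizes are likewise not printed; defaults are declared,
  not inferred.
* Exome correction divides by the window exon fraction and therefore
  amplifies Poisson noise where exons are sparse; masked windows (fraction
  < 0.01) are reported as NA rather than extrapolated.

## A worked example

```{r example, eval = FALSE}
cfg <- sim_config(seed = 1)
genome <- sim_genome(cfg)
ann <- sim_annotation(cfg)
tracks <- sim_wave_tracks(cfg, ann$genes)

ei <- delta_ei(escape_index(tracks$UV_30, ann$genes),
               escape_index(tracks$NO_UV, ann$genes))
escape_shift_test(ei)

loci <- exclude_ppp_proximal(call_tt_loci(genome, ann$genes))
sr <- sim_stalling_and_repair(cfg, tracks, loci)
scores <- sf_scores(locus_window_matrix(sr$tracks$UV_120, loci))
```

The same flow, stage by stage with on-disk intermediates, runs via
`run_pipeline(pipeline_config(seed = 1))`.
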