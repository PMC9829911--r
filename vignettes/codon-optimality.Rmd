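---
title: "Methods: codon optimality from measured tRNA pools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon optimality from measured tRNA pools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codonopt)
```

## The model and its assumptions

`codonopt` estimates how well each codon, and each mRNA, is adapted to the
measured tRNA pool of a cell, for organisms where tRNA gene copy number is
uninformative (single-copy tRNA genomes such as *M. tuberculosis*). Three
quantities build on each other:

1. **Supply.** The absolute adaptiveness of codon $i$ is
   $W_i = \sum_{j} (1 - s_{ij})\, t_j$ over the anticodons $j$ that can
   decode it, where $t_j$ is the log2 abundance of decoder $j$ and
   $s_{ij} \in [0,1]$ penalizes non-Watson–Crick pairing at the third
   position. Relative adaptability is $TAc_i = W_i / W_{max}$, with codons
   lacking any decoder assigned the geometric mean of the non-zero
   normalized values — a typical, strictly positive adaptability rather
   than an uninformative zero.
2. **Demand.** Genomic codon usage $cu_i$ is the codon's share of all
   counted codons; demand-weighted usage $ncu_i$ weights each gene's codon
   counts by its log2 mRNA abundance, so the transcriptome's actual draw on
   the tRNA pool is represented.
3. **Optimality.** $cOpt_i = \log_2(TAc_i / nCU_i)$ is positive when supply
   exceeds demand. An mRNA's score aggregates the cOpt of its codons.

Assumptions worth stating: anticodon read counts are taken as proportional
to functional tRNA abundance (aminoacylation and modification stoichiometry
are not modelled); the decoding rules are the classical wobble geometry
with fixed published penalties, not organism-refit values; and prokaryotic
single-CDS gene models are assumed throughout (no isoforms).

## Parameters that matter

| Parameter | Default | Why |
|---|---|---|
| wobble penalties $s$ | G:U 0.41, I:C 0.28, I:A 0.9999, U:G 0.68, L:A 0.89; WC 0 | the classical tAI constants; bundled as YAML so they can be overridden per organism |
| modification rules | A34 → inosine; Ile CAT → lysidine | standard bacterial decoding chemistry; editable in the same YAML |
| codon space | 60 sense codons, no ATG | single Met anticodon makes ATG uninformative; stop codons are never decoded by tRNAs |
| tRNA/RNA normalization | CPM per replicate → mean → log2(+1) | replicates of unequal depth become comparable; the pseudocount keeps zero-count anticodons defined |
| pseudocount | 1 (CPM units) | guarantees non-negative log2 abundances; configurable |
| mOpt aggregation | length-normalized (mean cOpt), then scaled by max absolute score | an unnormalized sum scales with gene length and would rank long genes as extreme by construction |
| outlier fences | Q1 − 1.5 IQR, Q3 + 1.5 IQR; quartiles type 7 | outlier counts are sensitive to the quartile convention, so it is fixed and recorded in output metadata |
| metagene window | [−50, +200) nt, half-open, 250 positions | a stated 250-length vector over "−50 to +200" only closes under a half-open reading; documented as such |
| A-site assignment | 5′ end + offset + 3 nt | offsets are estimated at the P site from the initiation peak, but codon-specific dwell happens one codon downstream at the A site; set `asite_shift = 0` for P-site density |
| coverage filter | length ≥ 100 nt, skip 21 nt, mean ≥ 40 reads/nt | standard footprint-coverage gating; thresholds inclusive |
| `skip_5p_codons` | 1 (pause scoring) | see below |

## Numerical and convention choices

**Log-scale abundances compress ranks.** Because $t_j$ is a log2 CPM
(values around 12–16 for realistic depths), a wobble decoder contributes
$0.32\, t_j$ even at penalty 0.68, which is large relative to differences
between log abundances. Consequently codons with two decoders (e.g.
G-ending codons in four-box families) systematically out-score single-
decoder codons: in the bundled Mtb-like profile, GCG tops the TAc ranking
through its CGC + TGC decoders while the single-decoder GAC/GTC lead only
among single-decoder codons, and wobble-only codons such as GAT sit
mid-range. Rank statements about TAc should be read with this compression
in mind; it follows directly from summing penalty-weighted *log*
abundances. The robust features — CGA last (its only decoder pays the
0.9999 I:A penalty), the Asp/Val/Ala codons high — are what the tests
assert.

**The literal $F_g$.** The pause normalizer is computed exactly as
$F_g = \mathrm{sum}(R_g)/(L_g - 2)$: the full density sum over the
interior length. Under uniform coverage this makes every positional score
$(L-2)/L$, not 1. An `interior_only_F` variant (numerator restricted to
scored codons) is available and scores uniform coverage as exactly 1. The
default is the literal form; the discrepancy is a constant factor per gene
and cancels in any ratio of pause scores.

**Initiation dwell vs codon dwell.** The simulator places a strong
initiation pause (default 25×) at the first P-site position of every gene
— this is what creates the metagene peak that offset calling needs, and it
mirrors real bacterial profiles. Its A-site density lands one codon into
the CDS, so the codon occupying position 2 of any gene inherits initiation
signal that has nothing to do with its own decoding speed. Pause scoring
therefore takes `skip_5p_codons`: the default 1 excludes only the start
codon (the literal convention), while codon-level dwell comparisons in the
pipeline use 7 codons (21 nt), matching the coverage-filter skip. The
positional formula itself is unchanged.

**Genomic pause pooling.** "Mean across genes" can mean pooling all
positional scores or averaging per-gene means; both are implemented
(`genomic_mean = "pooled"` is the default, and the two coincide on
balanced designs).

**Degenerate inputs.** Codons with zero usage are floored (default
$10^{-6}$, with a warning) before the cOpt log-ratio; an all-zero tRNA
table, an all-zero $W$ vector, fewer than 4 mRNAs at the outlier step, and
empty gene overlaps are hard errors. Abundance bins break ties by gene id
so binning is deterministic. Negative log2 abundances (possible only with
pseudocount < 1) are floored at 0 to keep $W$ non-negative.

## What the generators emulate — and what they do not

`simulate_trna_pool` draws anticodon counts (two replicates, multinomial
at 1e6 depth) around either a log-uniform spread (default 10×, matching
the order-of-magnitude variability of measured single-copy pools) or a
bundled Mtb-like rank profile (Asp-GTC > Val-GAC > Ala-CGC at the top,
Leu-TAA and Ile-TAT at the bottom). The bundled anticodon set holds 44
unique anticodons standing in for a 45-gene single-copy repertoire: the
initiator/elongator Met tRNAs share the CAT anticodon with the
lysidine-modified Ile2 decoder, and since ATG lies outside the codon
space, the CAT entry is assigned to Ile2. `simulate_transcriptome` builds
CDS codon-by-codon from a configurable bias (uniform by default, 400
genes of 100–300 codons) with log-normal expression (SD 2 log2 units).
`simulate_ribo_profile` places ribosomes P-site-wise with dwell
proportional to the A-site codon's multiplier, lengths 26–35 nt
(triangular, peak 30), and true offsets of length − 16.

Passing tests on these generators shows the *computations* are correct
and recover planted parameters; it does not validate the biology of real
libraries: no ligation/PCR bias, no rRNA contamination, no tRNA
modification-induced misincorporation, no coverage heterogeneity beyond
Poisson, and expression is independent of sequence unless explicitly
coupled. Real-data claims need the real GEO inputs, which the pipeline
accepts as plain TSV/FASTA.

## Problem sizes

The shipped tests and the acceptance script run entirely on synthetic
data at desk scale — pools of 44 anticodons, transcriptomes of 40–400
genes, footprint sets up to ~750k reads — chosen so the full suite
completes in seconds while leaving parameter-recovery margins (offset
recovery, 5× dwell recovery within 10%, null correlations within
sampling error at $n = 400$) clearly resolvable.

## Known limitations

* Translation efficiency is a plain CPM log-ratio, deliberately labelled
  non-equivalent to model-based TE estimators (no dispersion, no
  significance).
* The mOpt scale divides by the maximum absolute raw score; with mostly
  negative cOpt values scores land in [−1, 0). Published mOpt ranges on
  other scales depend on an aggregation convention their sources do not
  fully specify; the convention used here is recorded in the output
  metadata rather than silently assumed.
* Wobble penalties are global constants; organism-specific refitting is
  out of scope.
* Position-resolved optimality (5′ ramps) and inter-strain genome
  comparisons beyond generic usage correlation are not implemented.
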