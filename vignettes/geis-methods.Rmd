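---
title: "Methods: models, conventions and design choices in geis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in geis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(geis)
```

This vignette is the package's own account of the science it implements:
what is modelled, which knobs matter, what the synthetic data does and does
not emulate, and where the design was genuinely open, which choice was made
and why.

## The conversion-tract model

An HDR knock-in with an intronic selection marker places the Cas9 cut in an
intron and the desired variants on a homology arm, at distances of tens to
hundreds of nucleotides from the double-strand break (DSB). During repair a
*conversion tract* of donor sequence is copied into the genome around the
break; a variant at distance $d$ is incorporated only if the tract reaches
it. Empirically, incorporation frequency decays with distance and is
strongly *nested*: a read carrying a far variant almost always carries all
nearer ones.

`fit_tract_model` formalises this with a one-parameter geometric family.
Copying continues past each nucleotide with probability $p$, so the tract
length $L$ satisfies

$$S(d) = \Pr(L \ge d) = p^d,$$

and a read converts exactly the variants with distance $\le L$. The calls of
one read therefore censor $L$ into an interval
$[d_{\text{far converted}},\, d_{\text{next unconverted}})$, contributing
$S(d_1) - S(d_2)$ to the likelihood; all-unconverted reads contribute
$1 - S(d_{\min})$ and all-converted reads $S(d_{\max})$. The assumptions to
keep in mind:

* *Memorylessness.* A geometric (exponential-like) tail is the simplest
  monotone decay; real resection/synthesis may have heavier or lighter
  tails. The family is named (`family = "geometric"`) so alternatives can be
  added without changing the interface.
* *Per-read independence.* Tract lengths are drawn independently per
  molecule; clonal structure or strand correlations in real repair are not
  modelled.
* *One-sided symmetry.* Distance is measured from the cut regardless of
  side; the bundled experiment places all variants on the left arm, so no
  left/right asymmetry is estimable from it.

Distances are measured **from the blunt cut** (3 nt 5′ of the PAM), not from
the sgRNA end, counting the edited base itself: the base adjacent to the cut
has distance 1; an insertion exactly at the cut has distance 0.

Reads that violate nesting (an unconverted site nearer than a converted one)
exist in real data — template switching, PCR chimeras, call errors. The
fitter excludes them by default and reports the count
(`nonnested = "exclude"`); `"relax"` keeps them, censoring by the furthest
converted site and the nearest unconverted site beyond it. They always stay
in the descriptive profile and co-occurrence statistics.

### Numerics

The likelihood is aggregated over distinct censoring intervals (for $K$
variants there are at most $K + 1$ nested patterns plus rare relaxed ones),
evaluated as $a\log p + \log(1 - p^{b-a})$ for stability, and maximised with
`stats::optimize` on $p \in (10^{-9}, 1 - 10^{-9})$ at tolerance $10^{-12}$,
comfortably below the $10^{-8}$ log-likelihood tolerance the package aims
for. The 95% interval is a profile-likelihood interval (log-likelihood drop
of $\chi^2_{1,0.95}/2$, found by `uniroot` at tolerance $10^{-10}$).
Degenerate inputs — a single distance with all calls converted (or all
unconverted) — drive the MLE to the parameter boundary; the fit is returned
with `non_identifiable = TRUE` and the unbounded CI side set to the
boundary rather than erroring, since such matrices do occur in small
screens.

## Annotation statistics

The editability argument: a DSB can be placed in either flanking intron, so
an internal exon never needs a tract longer than half its length
(`nearest_intron` returns that budget; midpoint ties break toward the 5′
intron, an arbitrary but fixed rule). Consequently the fraction of coding
exons longer than 600 nt bounds the fraction of targets needing more than a
300-nt tract. Conventions:

* Exon lengths come in two modes: `utr_included` (full exon) and
  `utr_excluded` (summed overlap with the transcript's CDS). Fully
  untranslated exons are excluded from UTR-excluded denominators — a
  fraction over them would be undefined, not zero.
* Exons are counted once per (transcript, exon) pair by default, matching a
  naive scan of the annotation; `dedupe = TRUE` collapses identical
  (chrom, strand, start, end) intervals shared between transcripts. Both
  universes are defensible, so both are exposed;
  `editability_report` on a named list of annotations also emits per-species
  and pooled rows, since headline percentages can be quoted either way.
* Only `protein_coding` transcripts are kept when the annotation carries a
  transcript-type attribute (UTR-excluded analysis is undefined otherwise);
  unstranded features are rejected because first/last exon flags are
  strand-aware; first/last rank follows transcription order, not genomic
  order.
* Coordinates are **1-based closed throughout**, the R/Bioconductor
  convention (IRanges, GenomicRanges, Biostrings, and GFF3 itself). Parsing
  therefore involves no coordinate shift, and serialisation round-trips
  exactly.

## Guide enumeration and donor assembly

`enumerate_guides` returns every 20-mer + NGG site on both strands whose
blunt cut lies inside the host intron outside two exclusion windows
(`splice_policy`): 20 nt from the donor (5′) end and 50 nt from the acceptor
(3′) end. The biology fixes only that the GT/AG dinucleotides, branch point
and polypyrimidine tract must be spared; the window sizes are conservative,
literature-typical extents and are configurable (both must be ≥ 2 nt).
Candidates are ordered purely by distance to a target position — no
on-target activity or off-target scoring, which dedicated tools do better.
Sites overlapping `N` bases are never admissible.

`assemble_donor` copies `ha_length` nt from each side of the cut, applies
the variant table to the arms (validating every `ref` allele against the
locus and naming the offending position on mismatch), and records two safety
checks: `ha_ok` (arms ≥ 500 nt, the empirical minimum for recombination at
the tested locus) and a scan for poly(A)-signal hexamers `AATAAA`/`ATTAAA`
on the donor sense strand. "Terminator" is interpreted as polyadenylation
signal — the failure mode that matters for a cassette transcribed within an
intron; transcriptional pause sites are out of scope.

## Amplicon alignment and calling

Reads are aligned with `Biostrings::pairwiseAlignment`, affine gap costs
(match +2, mismatch −3, gap open 5, gap extend 2; a length-$L$ gap costs
$5 + 2L$), in **ends-free (overlap) mode**: truncated Sanger reads and reads
padded with extra flanking sequence must both align without terminal-gap
penalties, and calls are invariant to such padding. Both orientations are
aligned and the better score kept. The suite cross-checks this production
route against an independently implemented quadratic Gotoh dynamic program
(`nw_reference_score`, compiled) on hundreds of random pairs.

QC (all configurable): reads shorter than 50 nt, reads whose *aligned span*
is under 50 columns — ends-free alignment happily clips a junk read down to
a short perfect stretch, so identity alone is not a guard — and reads under
0.9 identity (matches / aligned columns) are dropped, with counts reported.

Calls are ternary. Substitutions are read base-by-base off the aligned span:
donor allele → `converted`, reference allele → `unconverted`, anything else
(including truncation before the site or a non-designed indel across it) →
`ambiguous`. Designed indels are read by *windowed sequence comparison*: the
read bases aligned to reference window ±8 nt around the site must spell
either the wild-type window or the window with the designed indel applied.
This makes indel calls invariant to equivalent gap placements in repetitive
context, where "the same" indel admits several optimal alignments; the cost
is that an unrelated error inside the window yields `ambiguous`, a
deliberately conservative trade.

`ambiguous` calls are excluded from both numerator and denominator of
conversion frequencies by default (a truncated read should not count as
unconverted), so per-site denominators vary; `denominator = "total"`
restores the fixed-total convention of dividing every count by the number of
sequenced clones. Clone percentages are rounded half-up to one decimal
(41.666… → 41.7) purely for display; exact rationals and exact
Clopper–Pearson intervals are kept underneath.

## What the synthetic generator emulates — and what it does not

`sim_config` defaults are the bundled experiment's conditions: variant
distances 45/90/171/386/490/596/696 nt on a 800-nt left arm, 624 amplicon
reads, a 24-clone screen per donor type with true-positive probabilities
21/24 (ssDNA) and 10/24 (dsDNA), and no wild-type read contamination.
The default continuation probability $p = 0.9989$ was chosen once so that
$S(400) \approx 0.65$, the conversion level observed around 400 nt at the
best-behaved locus, and the default sequencing error rate 0.001/base is
Sanger-consensus-like; neither is tuned per analysis. `make_locus` builds
loci with canonical splice anatomy (GT…AG, branch-point adenine 20–40 nt
upstream of the acceptor, 10-nt polypyrimidine tract), and indel variants
are placed in contexts with distinct flanks so their alignments are
unambiguous.

What passing simulator-based tests shows: the pipeline is internally
consistent (error-free reads round-trip to the exact truth table; empirical
frequencies sit in exact binomial bands around $p^d$; the MLE recovers the
generating $p$; profile CIs attain near-nominal coverage). What it does not
show: robustness to real Sanger artefacts (chromatograms, base-quality
structure, chimeric PCR products, locus-dependent repair pathway choice,
correlated tracts) — none of which the generator models. Sequencing error is
substitution-only by default, with indel errors behind a flag.

All generators run under an internal seed scope derived from `config$seed`
(the session RNG is saved and restored), so outputs are byte-identical
across runs and machines for the same configuration.

## Problem sizes

The test suite and acceptance script run entirely from generated data at
sizes chosen to keep statistical checks sharp but the full run at minutes of
CPU: alignment-based round trips at 150–400 reads of ~800 nt; truth-table
statistics at 3 000–10 000 reads; MLE recovery at n = 5 000; CI coverage over
200 replicates of n = 500; oracle comparisons over 100 random loci and 200
random alignment pairs. Annotation operations are verified exactly on a
hand-counted toy GFF3 shipped with the package; the same code runs unchanged
on full GENCODE annotations, whose headline fraction of >600-nt coding exons
(~3%) is then reproduced at genome scale.

## Known limitations

* The geometric family is a modelling convention; the true human tract-length
  distribution is unknown and likely locus-dependent. Comparisons across
  loci should use the empirical profile, not only $\hat p$.
* Conversion frequencies from FACS-enriched amplicons estimate conversion
  *given selection-cassette integration*, not absolute editing rates.
* Guide candidates are unscored; splice-safety windows are heuristics, not a
  splicing predictor.
* `parse_gff3` targets the GENCODE GFF3 dialect (features carrying
  `transcript_id`); other dialects may need their identifiers mapped first.
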