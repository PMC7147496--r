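---
title: "Methods: homology-based miRNA mining from EST collections"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: homology-based miRNA mining from EST collections}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirest)
```

## The problem

Many plant species have no sequenced genome but do have public expressed
sequence tags (ESTs). Because mature microRNAs are strongly conserved across
plants, candidate miRNAs can be mined from such collections by homology: a
reference set of known mature miRNAs is matched against the ESTs, matching
regions are folded to test whether they sit inside a plausible pre-miRNA
stem-loop, and surviving candidates are used to predict target transcripts
by complementarity. `mirest` implements that pipeline as composable,
deterministic functions with a synthetic-data generator that plants known
hairpins and target sites so that every stage can be validated against
ground truth.

## Homology screen

`find_hits()` reports every end-to-end, ungapped match of a mature sequence
against an EST (both strands) with at most `max_mismatches = 2`
substitutions, the biologically operative filter in this class of screens.
We deliberately do not compute E-values: they depend on database-size
statistics of a particular aligner run and are not reproducible from the
data alone, whereas the mismatch bound is. A BLAST-style exact-word seed of
`word_size = 7` accelerates the scan, but only for matures long enough that
the pigeonhole bound guarantees an intact word (length at least
`(k + 1) * w + k` for `k` mismatches and word size `w`, i.e. 23 nt under
defaults); shorter matures are scanned exhaustively, so the seeded path can
never lose a hit. Matures shorter than 19 nt are excluded up front, and
`dedupe()` collapses hits that share an EST locus and mature sequence,
keeping the fewest-mismatch representative with a lexicographic tie-break.
N is never treated as a match: conservative, because downstream structure
checks cannot rehabilitate an uncertain base.

Gaps are not modeled. Matches of interest here preserve the mature/EST
length parity, and allowing indels would only loosen the criterion the
screen is supposed to enforce.

## Coding-sequence exclusion

miRNA precursors are non-coding, so ESTs that look protein-coding are
removed. When a protein-homology search of the ESTs is available (the
12-column BLASTX tabular format), `classify_coding()` uses it directly: any
hit with E-value at most `1e-3` marks the EST coding. Without external
evidence it falls back to a six-frame ORF heuristic: an EST whose longest
ATG-initiated, stop-terminated ORF reaches `orf_aa_threshold = 80` amino
acids is called coding. 80 aa is a common cutoff for separating long ORFs
from the short spurious ORFs expected in non-coding sequence (a random
reading frame terminates on average every ~21 codons), and the threshold is
exposed because no universal value exists.

## Hairpin validation

For every retained hit, `excise_precursor()` cuts candidate precursor
windows around the mature site: a total flank budget of `2 * flank` nt
(default 200) is distributed left/right in five placements at three scales,
clipped to the EST and filtered to 60-300 nt. The grid spans the precursor
lengths reported for real plant pre-miRNAs (roughly 75-220 nt windows
against a published 79-169 nt range). Minus-strand hits are excised from
the reverse complement so the mature always reads 5'-3'.

Each window is folded by the bundled folder (`fold()`): an interval dynamic
program over pseudoknot-free structures in which each pair encloses at most
one branch. Multi-branch precursors are genuinely out of scope here --
canonical pre-miRNAs are single stem-loops -- and excluding them keeps the
recursion quadratic in states. The objective is a stacking-aware score:
pair terms GC = 3, AU = 2, GU = 1, +1 per stacked pair, a flat hairpin-loop
penalty of 4 (minimum loop 3 nt), and an interior/bulge penalty of
`2 + 0.5 * size` with a 30-nt per-side bound, as in standard folders. The
reported energy proxy is -0.5 kcal/mol per score unit, calibrated so that
typical planted precursors land in the -30 to -50 kcal/mol range reported
for real pre-miRNAs. This is intentionally not a full nearest-neighbor
thermodynamic model; when exact published energies matter, externally
computed structures enter through `read_structure()` (Vienna-style
sequence/dot-bracket/energy files) and bypass the folder entirely. The
folder's defining property, checked in the test suite by exhaustive
enumeration of all structures up to 12 nt, is exact optimality under its
own scoring.

A candidate passes (`evaluate_candidate()`) if

1. the structure contains a stem of at least `min_stem_pairs = 15`
   cumulative base pairs closing a single terminal loop on the mature's
   arm. The count is deliberately cumulative across bulges: published
   hairpins of this class keep ~15+ pairs in the duplex region while
   tolerating interior loops. No numeric definition of "an appropriate
   stem-loop" exists in the literature, so this operationalization is
   exposed as a parameter;
2. the mature lies on one arm (`locate_arm()` returns 5p or 3p, never
   loop-spanning);
3. the mature/star duplex has at most `star_mm_max = 5` mismatches, where
   mismatches are mature positions left unpaired inside the duplex plus
   excess bulged star bases, and the star span follows the 2-nt 3' overhang
   convention of Dicer products;
4. MFEI is at least 0.5, with `MFE = -dG`, `AMFE = MFE * 100 / length`,
   `MFEI = AMFE / GC%`.

Reported GC/AMFE/MFEI values are truncated (not rounded) to two decimals;
the published table this package replays is arithmetically consistent with
truncation (e.g. 4255/107 = 39.766 printed as 39.76) and the package
follows that convention everywhere. Mature lengths outside 19-21 nt are
flagged `length_out_of_range`; both bounds are configurable because the
upstream length filter (>= 19) and the downstream characterization (19-21)
are stated separately in this literature.

When several windows pass, the one with the highest MFEI is reported (ties:
shorter precursor, then leftmost) -- one precursor per mature, favoring
thermodynamic stability. When none passes, the representative window is the
one with the fewest failure reasons, so an engineered single-criterion
violation surfaces as exactly that reason.

## Target prediction

`scan_transcripts()` scores the complementarity of each miRNA against every
transcript window in the given sense. The miRNA is aligned globally against
the reverse complement of the window, minimizing an expectation penalty:
mismatch 1, G:U wobble 0.5, gap 2, doubled at miRNA positions 2-13 (the
seed region). These constants follow the published psRNATarget (Schema V2)
scheme; the scheme is re-implemented here, not proxied through the hosted
service, and all constants are arguments. Calls require expectation <= 3
and at most 2 mismatch states (wobbles optionally counted). Since two gaps
already cost at least 4, scanning window widths L-1, L and L+1 covers every
alignment reportable under the default cutoff. Overlapping windows are
resolved best-expectation-first with leftmost/fewest-gap tie-breaks.
`classify_inhibition()` calls translational repression when any state at
miRNA positions 10-11 is not a perfect match, and cleavage otherwise --
central-position pairing is what licenses slicing.

A note on coordinates with gaps: a bulged target base (gap in the miRNA
row) has no miRNA position of its own and inherits the seed status of the
following miRNA position; central-position classification uses miRNA
nucleotide positions, not alignment columns.

## Synthetic data and what it shows

`synth_preset()` builds a desk-scale study with a ground-truth manifest:
random background ESTs rejection-sampled to contain no reference mature
within 2 mismatches; planted precursors of the form
`tail + ext + mature + loop + star + revcomp(ext) + tail` with exactly
`stem_mismatches` non-pairing substitutions engineered into the star at
interior, non-adjacent positions; and transcripts with target sites built
base-by-base from per-position state profiles whose expectation is computed
by hand from the penalty table, independently of the aligner.

The "full" preset (seed 42) holds 200 background ESTs and 20 planted
hairpins -- 15 compliant (stem mismatches 0-3, precursors spanning the
realistic length range) and 5 engineered to violate exactly one criterion
each. Engineering single-criterion violations against a free-energy
optimizer requires care, because refolding can rescue a naively corrupted
hairpin:

* the star-mismatch violator deletes 7 star bases rather than substituting
  them -- the partners are physically absent, so no alternative register
  restores the pairing;
* the MFEI violator is an A/T-only duplex around a ~100 nt C-only terminal
  loop: C pairs nothing in an A/T context, so every window either lacks the
  star (and cannot pass the stem criterion) or carries the GC-rich loop
  that pins MFEI below 0.5;
* the stem-too-short violator truncates the star to 11 pairable bases;
* the loop-spanning violator embeds the mature inside the terminal loop of
  an unrelated 18-bp stem;
* the length violator is a fully compliant hairpin for a 22-nt mature.

Every planted EST is verified at generation time through the actual
excision/folding/criteria path (hosts re-drawn, hairpins re-built on
failure), so the manifest states what the data actually contain rather
than what the construction intended.

What passing these tests shows: the pipeline recovers exactly the planted
signal and attributes failures to the intended criterion under the
package's own folding model. What it does not show: recovery rates on real
ESTs, which depend on a thermodynamic folder, sequencing error, EST
chimerism and reference-set composition -- none of which the generator
emulates (uniform background composition is a deliberate neutral null for
false-positive measurement).

## Numerical and design choices

* Truncation to 2 decimals for reported metrics; internal arithmetic in
  double precision.
* All randomness flows through explicit seeds; re-running any generator or
  the pipeline with the same inputs is byte-identical.
* Deterministic orderings everywhere: hits by (EST, start, strand, miRNA),
  target calls by (miRNA, expectation, transcript, start); alignment
  tracebacks prefer pairing over gaps.
* Internal alphabet is DNA (U converted to T on input, back to U only on
  RNA export), so the matcher, folder and target scanner share one
  alphabet. Ambiguity codes other than N are rejected because mismatch
  counting is undefined for them.
* Degenerate inputs: empty reference sets and empty EST files are errors;
  an EST shorter than every mature simply yields no hits; a structure with
  zero pairs is a valid (open-chain, zero-energy) fold but can never pass
  the stem criterion.
* The test suite sizes its randomized cross-checks (30 homology instances,
  enumeration to 12 nt, small transcriptomes) to run the whole suite in a
  few minutes on one core while still exercising both the seeded and
  exhaustive homology paths, minus-strand logic and every failure reason.

## Known limitations

* The bundled folder optimizes a surrogate score, not free energy; its
  MFE/AMFE/MFEI values are internally consistent and useful for ranking and
  thresholding synthetic data, but absolute agreement with thermodynamic
  folders should not be expected -- use the external-structure path for
  that.
* Published discovery counts from real screens (how many ESTs hit, how many
  survive each filter) depend on reference-database releases and external
  protein databases; they are treated as funnel-shape properties, not as
  reproducible numbers.
* Target prediction re-implements a documented scoring scheme; it is not
  guaranteed bit-identical to any hosted service.
* No gapped homology search, no multi-branch precursors, no target-site
  accessibility energetics.
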