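# mirest

Homology-based mining of microRNAs — and their targets — from EST
collections, for plant species that have public expressed sequence tags but
no assembled genome.

Conserved mature miRNAs make a simple and effective screen possible: match
a reference set of known matures against the ESTs, keep near-exact hits,
discard protein-coding ESTs, check that each surviving hit sits inside a
plausible pre-miRNA stem-loop, and predict targets by complementarity.
`mirest` implements that pipeline as deterministic, composable R functions,
together with a synthetic-data generator that plants hairpins and target
sites with a ground-truth manifest so every stage can be validated.

## The model in brief

* **Homology screen** — every end-to-end, ungapped match of a mature miRNA
  (≥ 19 nt) against an EST or its reverse complement with ≤ 2
  substitutions; BLAST-style 7-mer seeding where lossless, exhaustive scan
  otherwise; redundant loci collapsed.
* **Coding filter** — six-frame longest-ORF heuristic (≥ 80 aa ⇒ coding),
  or imported BLASTX tabular results (E ≤ 10⁻³) when available.
* **Hairpin validation** — candidate precursor windows (60–300 nt) are
  folded by a bundled stacking-aware dynamic program; a candidate passes if
  it has a ≥ 15-bp stem closing a single terminal loop, the mature on one
  arm, at most 5 mature/miRNA\* duplex mismatches, and

  MFE = −ΔG, AMFE = MFE·100 / L, MFEI = AMFE / GC% ≥ 0.5,

  with all reported metrics truncated to two decimals.
* **Target prediction** — psRNATarget-style expectation scoring (mismatch
  1, G:U wobble 0.5, gap 2, doubled over seed positions 2–13), cutoff
  expectation ≤ 3 and ≤ 2 mismatches; pairing defects at miRNA positions
  10–11 call translational repression, otherwise cleavage.

## Worked example

```r
library(mirest)

syn <- synth_preset("smoke", seed = 42)   # planted study with manifest
rep <- run_pipeline(syn$refs, syn$ests, transcripts = syn$transcripts)
rep
#> run_report
#>   funnel:  ests=34 > hits=7 > after_dedupe=7 > noncoding_hits=7 > candidates=7 > passing=6
#>   families: miR201=2, miR202=2, miR203=2
#>   target calls: 6
```

The funnel counts each stage: 34 input ESTs yield 7 homology hits, none
redundant or coding, and 6 of the 7 excised precursors pass all four
hairpin criteria (the seventh is an engineered violator that fails with
exactly its planted reason). Passing candidates carry the usual metrics:

```r
head(subset(rep$candidates, passed,
     c(est_id, mirna_id, precursor_length, gc_percent, mfe, amfe, mfei)), 3)
#>       est_id   mirna_id precursor_length gc_percent  mfe  amfe mfei
#> 1 synEST0031 syn-miR201               77      51.94 53.5 69.48 1.33
#> 2 synEST0031 syn-miR201               77      51.94 53.0 68.83 1.32
#> 3 synEST0032 syn-miR202               76      59.21 53.0 69.73 1.17
```

and the target table mirrors the planted sites, including one engineered
central-position defect called as translational repression:

```r
head(rep$targets[, c("mirna_id", "transcript_id", "tx_start",
                     "expectation", "inhibition")], 3)
#>     mirna_id transcript_id tx_start expectation  inhibition
#> 1 syn-miR201      synTX001      371         0.0    Cleavage
#> 2 syn-miR201      synTX002      131         2.0 Translation
#> 3 syn-miR202      synTX002      274         0.5    Cleavage
```

The packaged report tables of a published orchid EST screen replay
directly:

```r
table1_summary()$family_counts   # miR390=11, miR414=1, miR528=2
replay_table2()$by_inhibition   # Cleavage=131, Translation=3
```

A thin command-line front end is included:

```sh
Rscript inst/cli/mine.R synth --preset full --seed 42 --out study/
Rscript inst/cli/mine.R run --refs study/refs.fa --ests study/ests.fa \
        --transcripts study/transcripts.fa --out study/out/
Rscript inst/cli/mine.R replay-tables --out study/replay/
```

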