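# rdrpscreen

Large protein databases are full of records named "hypothetical protein",
"uncharacterized protein" or "DUF"-something. A measurable fraction of them
are RNA-viral RNA-dependent RNA polymerases (RdRp) — the one protein every
RNA virus carries — hiding under host, bacterial or metagenomic taxonomy
labels, either because a sample was infected, contaminated or mislabelled,
or because the sequence is an endogenous viral element (EVE) integrated
into a host genome. `rdrpscreen` implements, as a tested R package plus an
analysis workflow, a triage pipeline that:

- gates candidates by a profile-HMM **domain score ≥ 25 bits** (a
  simplified, self-contained HMMER stand-in: Plan7-like local Viterbi and
  forward scoring in bits against an i.i.d. background null);
- purges reverse transcriptase (RT), the chief false-positive class, by
  splitting a mixed reference alignment into RdRp-like and RT-like clades
  on its tree and assigning each candidate to the higher-scoring of the
  two paired profiles;
- classifies survivors with a **2-of-5 evidence rule**: structure-search
  bits > 100, a palmprint core (ordered A/B/C motif blocks, GDD in motif
  B), BLAST-type bits > 50 against a known RdRp, patristic distance < 1.5
  substitutions/site to the nearest known virus, domain score > 50 — with
  RT exclusion (RT-like palm core, or an RT BLAST hit ≥ 50 bits beating
  the RdRp hit);
- characterizes EVEs: DNA-vs-RNA source cohorts (Mb-scale chromosomes vs
  kb-scale transcripts), shortened ORFs, premature stops and frameshifts,
  and a shared-insertion-site test on whole-genome alignment blocks
  (> 8000 nt with non-EVE flanks on both sides);
- curates negative controls: the near-miss band (domain score in
  [10, 25)), term enrichment as log2 fold changes, and the NC/NM control
  sets built from BLAST/CDD/palmprint/score exclusion filters.

Because the real inputs (NCBI Protein, UniRef100, Pfam profiles) are
snapshots behind external tools, the package ships a **synthetic-data
module**: a generator that emits labelled corpora with the statistical
structure the analysis assumes — intact RdRps (mean ~1228 aa on ~5.4 kb
RNA contigs), RT proteins, degraded EVE fragments (mean ~480 aa on
~14.7 Mb DNA chromosomes), near-miss decoys carrying one planted motif
block, and unrelated background — so every stage is testable end to end
without downloads.

## Worked example

```r
library(rdrpscreen)
corpus <- generate_corpus(corpus_config(150, 150, 100, 100, 100, seed = 2024))
res <- run_screen(corpus$records)
res$funnel
```

On this corpus the run prints the stage funnel

```
input=600 selected=600 deduplicated=600 gated=368 after_rt_purge=218 rdrp=216
```

i.e. 600 uncharacterized records, 368 past the 25-bit gate (all 150
planted RdRps, all 150 RTs — the mixed-seed gate profile attracts both,
as the real Pfam profiles do — plus 67 EVE fragments and one near-miss
decoy), 218 after the RT
purge (every planted RT routed to RT), and 216 final RdRp calls: recall
1.000 on intact RdRps, 0 RTs and 0 unrelated records called RdRp, and 66
of 100 EVE fragments recovered (the rest lost too much of the polymerase
domain to degradation). Cohort signatures on the same corpus give a
DNA-source mean contig of 14.0 Mb vs 5224 nt for RNA-source (fold ≈ 2686)
and mean proteins of 473 vs 856 aa.

The numbered scripts under `analysis/` run the same stages as a narrative
workflow (simulate → scan → RT filter → classify → place/assign →
EVE signatures → near-miss/controls), writing tables under `results/`.

## Acceptance script

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

regenerates the default corpus from the seed, runs the full screen end to
end, logs the funnel and recovery rates, and writes the JSON report.
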