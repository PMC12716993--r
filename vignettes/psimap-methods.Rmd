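---
title: "Calling pseudouridine sites and mapping synthase dependency with psimap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling pseudouridine sites and mapping synthase dependency with psimap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psimap)
```

## The measurement model

Chemical conversion sequencing reads pseudouridine (Ψ) out as a U→C mutation
(T→C in the DNA-alphabet reference): a treated library converts modified
uridines with efficiency γ, while an untreated control library of the same
RNA reports only background miscalls. At a reference-T position covered by
`n` informative (T or C) base calls, with true stoichiometry θ, the treated
C-count is modelled as

\[ C \sim \mathrm{Binomial}\bigl(n,\; \theta\gamma + (1-\theta)\,
\varepsilon(\text{context})\bigr), \]

where ε(context) is the background conversion rate of the trinucleotide
context centred on the T. The modification level reported by `call_psi()` is
the raw treated conversion rate `nC / (nC + nT)` — no control subtraction by
default, because background is already handled by the control filters and
the binomial test; a `subtract_ctrl` toggle exists for users who prefer the
subtracted estimator.

## The five calling criteria

`call_psi()` evaluates every reference-T position present in both libraries:

1. **Coverage** ≥ 50 in both treated and control libraries.
2. **Control background**: control conversion rate ≤ 0.01 *or* control T→C
   count ≤ 2 (an OR — at moderate coverage a handful of miscalls should not
   disqualify a clean site).
3. **Control T→R ratio** ≤ 0.10 (R = A or G), guarding against positions
   that misalign or carry non-conversion artefacts.
4. **Level** ≥ 0.10 for cytosolic RNA, ≥ 0.05 for mitochondrial RNA (the
   mitochondrial transcriptome tolerates a lower bound because its
   background is cleaner and stoichiometries run lower).
5. **Significance**: a one-sided upper-tail exact binomial p-value of the
   treated count under the context's false-positive rate, adjusted by
   Benjamini–Hochberg across *all* candidate positions of the run, must be
   < 0.001.

Cytosolic tRNA calls are additionally restricted to *expressed isodecoders*:
genes whose median per-position control coverage reaches 50 (the same value
as criterion 1; positions without reads count as zero coverage). These
defaults live in `psi_thresholds()` and every one is overridable.

Three places in this scheme are genuinely open to interpretation, and we
fixed them as follows:

* the *background conversion rate* of criterion 2 is `nC / (nC + nT)`,
  consistent with the level estimator, rather than `nC / coverage`;
* the BH family is the full candidate set of the run (one adjustment per
  experiment), not per gene or per reference class;
* the false-positive-rate model is estimated from unmodified **spike-ins in
  the treated library** when available — false conversion is a
  treated-chemistry phenomenon — with a control-derived fallback
  (`estimate_motif_fpr()` pools `ΣnC / Σ(nC+nT)` per k-mer context, k = 3,
  falling back to the global rate for contexts with pooled denominator
  below 200).

## Knockout dependency

A site's dependency on a synthase is decided by a threshold rule, not a
test: with two or three replicates per condition, a site is *eligible* when
every knockout replicate covers it with ≥ 20 reads, and *dependent* when its
mean level drops by more than 0.20 in the knockout. We read "20% reduction"
as an **absolute** drop in stoichiometry units, because levels are fractions
and the comparison plots live on that scale; a relative mode
(`mode = "relative"` in `classify_dependency()`) is available. Knockdown
conditions are treated identically to knockouts. `aggregate_views()`
produces the two standard summaries: per-Sprinzl-position box-plot tables
(type-7 linear-interpolation quartiles, whiskers at 1.5 × IQR — recorded
because box bounds depend on the quartile convention) and an isodecoder ×
synthase matrix of level drops at one position, the classic view of
position-55 redundancy between TRUB1 and PUS10.

## Canonical tRNA numbering

All per-position summaries use Sprinzl numbering. `assign_sprinzl()` parses
a dot-bracket cloverleaf strictly: 7-bp acceptor stem, positions 8–9, 4-bp
D-stem (10–13), a D-loop of length 6–11 handled by a fixed allocation table
(length 8 → 14–21; 9 → insert 20A; 10 → also 17A; 11 → also 20B; 7 → drop
17; 6 → drop 17 and 20), 22–26, 5-bp anticodon stem and 7-nt loop (anticodon
34–36), a variable region of up to 5 nt labelled 44–48, or — for long-armed
tRNAs (Leu/Ser) — 44,45 followed by an e-stem-loop labelled e11…e1k along
the 5′ strand, e1…em around the loop and e2k…e21 along the 3′ strand, then
the 5-bp T-stem (49–53), 7-nt T-loop (54–60), 61–73 and CCA 74–76. The
community has no single published convention for ordering e-positions; we
place the e-block between 45 and 49, omit 46–48 on long arms, and expose a
per-gene override table (`load_numbering_override()`) for anything the
strict parser rejects — notably mitochondrial tRNAs with non-canonical
cloverleaves, which we deliberately do not attempt to parse heuristically.

## Motifs

`extract_windows()` takes fixed windows around called sites, default
−5…+8 — wide enough to hold an 11-position motif with the Ψ at its observed
offset — skipping (not padding) windows that cross a gene end.
`build_pfm()` adds a 0.01 pseudocount per base; `iupac_consensus()` renders,
per offset, the smallest IUPAC code covering all bases at frequency ≥ 0.15
(no published rule exists for collapsing a logo into a degenerate string;
0.15 keeps a base that appears in roughly one sequence in six).
`diff_motif()` computes the columnwise Jensen–Shannon divergence in bits
(base-2 entropy, bounded by 1, zero iff the columns agree) with signed
per-base contributions scaled to stack to the column JSD, as differential
logos draw them.

## Precursor tRNA

Reads proving precursor origin are the ones overlapping at least one
nucleotide of the 5′-leader, an intron, or the 3′-trailer
(`classify_pre_read()`); exon-only reads are indistinguishable from mature
tRNA and discarded. Kept reads are piled and called like any library, and
`compare_pre_mature()` classifies each called mature site: *pre-installed*
when the precursor level reaches 0.8 × the mature level and the precursor
site is itself called, *mature-specific* when a covered precursor position
sits below 0.1 × the mature level, *partial* in between, and *uncovered*
below 20 reads of precursor coverage. These states are usually described
verbally, without numeric boundaries; 0.8/0.1 separate them cleanly under
the binomial noise at the coverages involved, and both are arguments. The
precursor coverage bound reuses the knockout-eligibility value (20), since
precursor coverage is intrinsically scarce.

## The synthetic generator

`simulate_experiment()` is first-class, tested code, and its defaults *are*
the study conditions of the validation suite:

* cloverleaf-consistent references (numbering succeeds on every gene),
  D-loop lengths drawn 8/9/10/11 with probabilities 0.55/0.25/0.12/0.08,
  10% mitochondrial genes, 15% of cytosolic genes with a long variable arm;
* planted site classes at Sprinzl 55 (90% of genes, θ ∈ [0.6, 0.95],
  TRUB1), 54 (25%, PUS10), 13 (30%, PUS7), 38 (15%, PUS3), 32/31 (RPUSD2),
  and e12 on long-armed genes (50%, PUS7L) — prevalences and stoichiometry
  ranges chosen to mirror the dominant tRNA Ψ positions;
* conversion efficiency γ = 0.98; context background ε between 0.001 and
  0.009 via a flanking-base rule (×3 per flanking G, ×1.5 per flanking C on
  a 0.001 baseline — background miscalls are enriched next to G/C in this
  chemistry's error profile); T→R miscalls at 0.002 split evenly between A
  and G, independent of Ψ status (the chemistry's signal is C-specific);
* unmodified spike-ins (θ = 0 by construction), matching their role as the
  false-positive-rate substrate;
* fixed coverage 200 by default, or negative binomial per position.

What the generator deliberately does **not** emulate: alignment and mapping
artefacts, UMI duplication, RT drop-off and truncation, within-read indels,
quality scores, and real isodecoder sequence families (genes are random
cloverleaves, not GtRNAdb sequences). Green tests therefore demonstrate that
the *statistics* of the pipeline behave as designed under its own model —
recall ≥ 95% at θ ≥ 0.2 with zero false calls among >10,000 nulls at
coverage 200 — not that any particular mapping pipeline upstream is sound.

## Numerical and design notes

* Positions are 1-based inclusive throughout the R API and in every emitted
  table; BED input is converted on read and read-record TSVs interchange a
  0-based `start_0based` column.
* `binomial_tail_p()` returns exactly 1 at k = 0; the BH step is the
  classical step-up with clipping at 1; both are cross-checked in the test
  suite against independent brute-force oracles (log-scale tail summation,
  O(m²) step-up).
* Degenerate inputs: zero-coverage rates are defined as 0; empty window sets
  refuse to build a PFM; empty FASTA loads to an empty set; a zero-length
  intron list is a valid (intron-free) precursor.
* The pipeline (`run_pipeline()`) is single-threaded and deterministic:
  identical config + seed reproduce byte-identical outputs, which the test
  suite asserts file by file.
* Validation problem sizes were chosen to exercise the asymptotics while
  staying desk-sized: 1,000 genes (~20,000 candidate positions) for
  recovery and stoichiometry accuracy, 250 genes × 2 replicates × 3
  conditions for dependency classification, 10–40 genes elsewhere.

## Known limitations

Real headline counts from deposited sequencing data are not reproducible at
desk scale, so validation is property-based on synthetic data. The strict
cloverleaf parser rejects non-canonical mitochondrial structures (override
table required). Stoichiometry is reported as the raw conversion rate and is
therefore biased low by a factor γ at a true site; estimating γ from data is
out of scope. Dependency classification is a threshold rule, not
a significance test on the replicate deltas.
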