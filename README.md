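# psimap

Pseudouridine (Ψ) is the most abundant internal RNA modification, installed
in tRNA by a family of pseudouridine synthases (PUS). Chemical
conversion-based sequencing reads Ψ out as a U→C mutation: a treated library
converts modified uridines with high efficiency, an untreated control
library of the same RNA reports only background. **psimap** turns paired
treated/control per-position base-call counts into a quantitative Ψ map:

* **Site calling** (`call_psi()`) — every reference-T position is tested
  against five criteria: coverage ≥ 50 in both libraries; control conversion
  rate ≤ 0.01 *or* control T→C count ≤ 2; control T→R ratio ≤ 0.10;
  modification level ≥ 0.10 (cytosolic) / ≥ 0.05 (mitochondrial); and a
  BH-adjusted one-sided binomial p-value < 0.001 under a motif-specific
  false-positive rate. The level estimate is the treated conversion rate
  `nC / (nC + nT)`, an estimate of θγ + (1−θ)ε for stoichiometry θ,
  conversion efficiency γ and context background ε.
* **Knockout dependency** (`classify_dependency()`) — a site is dependent
  on a PUS when, with every knockout replicate covered at ≥ 20 reads, its
  mean level drops by more than 0.20 in that knockout; isodecoder × PUS
  matrices and per-position box-plot tables come from `aggregate_views()`.
* **Sprinzl numbering** (`assign_sprinzl()`) — canonical tRNA coordinates
  (1–76) from a dot-bracket cloverleaf, including D-loop insertions
  (17A/20A/20B) and variable-arm e-positions (e11…, e1…, e2…), with a
  per-gene override table for non-canonical structures.
* **Motifs** (`build_pfm()`, `iupac_consensus()`, `diff_motif()`) — position
  frequency matrices around called sites, IUPAC consensus strings, and
  columnwise Jensen–Shannon differential motifs in bits.
* **Precursor tRNA** (`classify_pre_read()`, `compare_pre_mature()`) — reads
  overlapping a 5′-leader, intron or 3′-trailer prove precursor origin;
  kept-read calls classify each site as pre-installed, partial or
  mature-specific.
* **Synthetic experiments** (`simulate_experiment()`) — a seeded generator
  of cloverleaf references, planted stoichiometries, knockout effects,
  spike-ins and count libraries, used throughout the validation suite.

## Worked example

Simulate a 60-gene experiment with a TRUB1 knockout, estimate per-context
false-positive rates from the unmodified spike-ins, and call sites:

```r
library(psimap)

cfg <- sim_config(seed = 4, n_genes = 60, replicates = 2,
                  ko_drop = c(TRUB1 = 0.5))
sim <- simulate_experiment(cfg)
types <- vapply(unclass(sim$refs), function(g) g$type, character(1))

fpr <- estimate_motif_fpr(sim$libraries[["WT_rep1_treated"]],
                          sim$refs[types == "spikein"])
#> <fpr_model> 16 context(s) (k = 3, source = spikein), global 0.002234

res <- call_psi(sim$libraries[["WT_rep1_treated"]],
                sim$libraries[["WT_rep1_control"]],
                sim$refs[types == "trna"], fpr_model = fpr)
res
#> <psi_calls> WT_rep1_treated vs WT_rep1_control (WT, rep 1)
#>   1241 candidate T position(s), 130 called (cyto: 116, mito: 14)

head(subset(as.data.frame(res), called,
            c(ref_id, pos, sprinzl_label, level, ctrl_rate, q)), 4)
#>                ref_id pos sprinzl_label     level ctrl_rate q
#> 21 mt-tRNA-His-CGA-14  57            55 0.8350000         0 0
#> 27 mt-tRNA-Ile-CAG-37  13            13 0.4600000         0 0
#> 36 mt-tRNA-Ile-CAG-37  55            54 0.7500000         0 0
#> 37 mt-tRNA-Ile-CAG-37  56            55 0.6884422         0 0
```

Each row is a called Ψ site: its linear position, canonical Sprinzl label
(linear 55 can be canonical 54 when the D-loop carries an insertion), the
stoichiometry estimate, and the control background. Knockout comparison and
the position-55 motif:

```r
wt <- summarize_levels(list(res, call_psi(sim$libraries[["WT_rep2_treated"]],
                                          sim$libraries[["WT_rep2_control"]],
                                          sim$refs[types == "trna"],
                                          fpr_model = fpr)))
ko <- summarize_levels(lapply(1:2, function(r)
  call_psi(sim$libraries[[sprintf("KO-TRUB1_rep%d_treated", r)]],
           sim$libraries[[sprintf("KO-TRUB1_rep%d_control", r)]],
           sim$refs[types == "trna"], fpr_model = fpr)))
dep <- classify_dependency(wt[wt$mean_level > 0.1, ], ko, "TRUB1")
sum(dep$dependent)
#> [1] 57     # all 57 are the planted position-55 TRUB1 targets

cc <- as.data.frame(res)
s55 <- cc[cc$called & !is.na(cc$sprinzl_label) & cc$sprinzl_label == "55", ]
win <- extract_windows(s55, sim$refs[types == "trna"], u = 2, d = 3,
                       only_called = FALSE)
iupac_consensus(build_pfm(win))
#> [1] "GUΨCRA"   # the canonical T-loop motif
```

The whole analysis can also be driven as a staged pipeline
(`run_pipeline()`, or the `inst/scripts/psimap` wrapper) from a YAML config,
producing deterministic TSV outputs.

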