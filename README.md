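# tfcourse

Transcription-factor discovery from two-lineage differentiation time
courses.

Bone-marrow mesenchymal stromal cells can differentiate into osteoblasts or
adipocytes, and the balance between the two fates underlies senile
osteoporosis. A classic route to finding the regulators of that choice is to
profile both induced lineages over time against a shared uninduced time-0
control, classify how every transcription factor behaves in each course, and
look for genes that move in opposite directions in the two lineages —
candidate *molecular switches* (in the ST2 cell study this analysis was
modeled on, the bHLH genes *Bhlhe40*, *Hes1* and *Id4*). `tfcourse`
implements that analysis as a tested, reusable R pipeline, with a seeded
synthetic-data module standing in for the original microarray deposition so
that every stage is verifiable offline.

## The method

For gene $g$, lineage $\ell$ and time $t$, the pipeline works on log2 ratios
$r_{g\ell}(t) = x_{g\ell}(t) - x_g(0)$ of already-normalized log2
intensities. Its stages:

* **TF universe** — genes whose GO annotation intersects a fixed list of 39
  transcription-related GO accessions; families (bHLH by default) by
  InterPro domain IPR001092.
* **Behavior calls** — time point $t$ fires upward iff
  $r_{g\ell}(t) > 1$ or $r_{g\ell}(t) > \mu_\ell(t) + 3\sigma_\ell(t)$
  (array-wide per-time-point bounds), downward for the mirrored conditions;
  genes are called UP / DOWN / UP_DOWN / UNCHANGED (↑ / ↓ / ↑↓ / ≈).
* **Cross-lineage 4×4 contingency table**, changed-gene count, and switch
  candidates (pure UP in one lineage, pure DOWN in the other).
* **Temporal phases** — each regulated gene is binned into the contiguous
  phase window containing its peak ratio; hierarchical clustering
  (correlation distance, average linkage) orders genes for heat-map display
  and can propose window boundaries from the sample axis.
* **Family enrichment** — per (phase, family), the 2×2 Pearson chi-square
  test of independence, $\chi^2 = N(ad-bc)^2/((a{+}b)(c{+}d)(a{+}c)(b{+}d))$,
  df = 1, no continuity correction, against the whole catalog as background.

See the methods vignette (`vignettes/tfcourse-methods.Rmd`) for assumptions,
parameter rationale, and the exact conventions for ties and degenerate
inputs.

## Worked example

The deterministic reference fixture encodes the printed gene-list structure
of the ST2 study: 110 phase-labeled osteoblast-up-regulated transcription
factors and the eleven profiled bHLH genes.

```r
library(tfcourse)

fx      <- build_reference_fixture()
ratios  <- compute_ratios(fx, "osteoblast")
calls_o <- classify_lineage(ratios)
calls_a <- classify_lineage(compute_ratios(fx, "adipocyte"))

table(osteoblast = calls_o$call, adipocyte = calls_a$call)
#>            adipocyte
#> osteoblast   UP DOWN UP_DOWN UNCHANGED
#>   UP          1    3       0       102
#>   DOWN        0    0       0         0
#>   UP_DOWN     0    4       0         0
#>   UNCHANGED   0    0       0         0
```

All 110 fixture genes are up-regulated in the osteoblast course (four of
them transiently, UP_DOWN); in the adipocyte course seven go down, one
(*Clock*) goes up and the rest are unchanged. Binning by peak time recovers
the five osteoblast phase memberships exactly:

```r
asg <- assign_phases(calls_o, ratios, osteoblast_phase_windows())
rp  <- phase_report(asg, osteoblast_phase_windows())
rp[rp$direction == "UP", c("window_label", "n")]
#>   window_label  n
#> 1           1h 46
#> 3        6-24h 29
#> 5       30-48h  4
#> 7         4-6d  7
#> 9        8-14d 24

candidate_switch_genes(calls_o, calls_a)
#> [1] "Bhlhe40" "Hes1"    "Id4"
```

The numbers are the phase sizes of the study's osteoblast course
(46 + 29 + 4 + 7 + 24 genes) and its three switch candidates: genes at
least two-fold up in the osteoblast course and at least two-fold down in
the adipocyte course.

The same analysis runs end to end from a single config:

```r
report <- run_pipeline(pipeline_config(simulate = "fixture",
                                       outdir = "out", seed = 1))
```

which writes `behavior_calls.tsv`, `contingency.tsv`/`.json`,
`phase_membership.tsv`, `enrichment.tsv`, `switch_candidates.tsv`,
`run_report.json` and `run.log`. A thin command-line wrapper with
subcommands (`fixture`, `simulate`, `classify`, `phases`, `enrich`,
`run-all`) ships in `inst/cli/tfcourse`.

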