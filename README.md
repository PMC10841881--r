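# capriq

Model quality assessment for predicted protein assemblies, in the CAPRI
tradition.

When a structure-prediction method proposes a 3D model of a protein
complex, assessors need to quantify how well the model reproduces the
experimentally determined reference ("target"): which native inter-chain
contacts it recalls, how far the docked subunit sits from its true pose,
how accurate the interface itself is — and then to aggregate those
per-interface judgements over multi-interface assemblies and over whole
prediction rounds to rank participating groups. capriq implements that
entire chain as a tidyverse-style R package, exercisable end-to-end on
deterministic synthetic complexes with analytically known answers.

## The measures at its core

For one evaluated interface (a receptor/ligand chain pair):

- **f(nat)** — fraction of the target's native residue contacts (any
  heavy-atom pair < 5 Å) recalled by the model; missing residues count as
  missed.
- **L_rms** — ligand backbone RMSD after superposing the receptor
  backbones (no refit on the ligand).
- **i_rms** — backbone RMSD over the interface residues (any atom within
  10 Å of the partner), superposed on themselves.
- **S_rms** — side-chain RMSD of interface residues under the i_rms fit
  (diagnostic only).
- **clashes** — inter-chain heavy-atom pairs < 3 Å; excessive counts
  disqualify a model.

Models are classified High / Medium / Acceptable / Incorrect by the
canonical CAPRI threshold table, and scored continuously by

    DockQ = ( f(nat) + 1/(1+(L_rms/8.5)^2) + 1/(1+(i_rms/1.5)^2) ) / 3.

Multi-interface assessment units aggregate per-group best categories as
`Score_AU = 1*n_ACC + 2*n_MED + 3*n_HIGH` (normalized by the number of
distinct interfaces K), and groups are ranked across targets by the
analogous weighted count, by summed DockQ, and by positive-truncated
Z-score sums. See the vignette
(`vignettes/assessment-methodology.Rmd`) for the full model and the design
choices.

## Worked example

Generate a toy dimer, one decoy per quality category, and score them:

```r
library(capriq)
library(dplyr)

base <- make_toy_complex(toy_complex_spec(2, 20))
lad  <- make_decoy_ladder(base, n_per_category = 1, seed = 42)
iface <- native_contacts(base, "A", "B")

bind_rows(lapply(names(lad$decoys), function(id) {
  dec <- lad$decoys[[id]]
  interface_metrics(dec, base, build_correspondence(dec, base), iface) |>
    append_quality() |>
    mutate(decoy = id, .before = 1)
}))
```

```
          decoy fnat   lrms  irms   srms clashes   category  dockq
1       high_01  0.9  0.557 0.266  0.276       0       High 0.9551
2     medium_01  1.0  4.238 1.873  1.886      46     Medium 0.7305
3 acceptable_01  0.9  5.367 2.284  2.425      99 Acceptable 0.6388
4  incorrect_01  0.0 23.011 9.855 10.048       0  Incorrect 0.0476
```

Each row is one decoy against the reference dimer: the High decoy keeps
90% of native contacts with a sub-Angstrom ligand displacement, while the
Incorrect one has lost the binding mode entirely (no recalled contacts,
ligand 23 Å off) and its DockQ sits far below the 0.23 incorrect cutoff.

Ranking a simulated round of four groups with decreasing skill:

```r
man <- make_submission_manifest(4, 6, skills = c(0.9, 0.7, 0.5, 0.3), seed = 1)
rk  <- rank_groups(man)
tidy(rk)
```

```
  capri_rank group_id      role score_g n_acc n_med n_high n_correct sum_dockq sum_z
1          1      G01 predictor      18     0     0      6         6     5.243 7.193
2          2      G02 predictor      12     0     6      0         6     3.939 1.984
3          3      G03 predictor      12     0     6      0         6     2.858 0.000
4          4      G04 predictor       6     6     0      0         6     1.737 0.000
```

G01's six High-quality AUs give the maximal CAPRI score 3 × 6 = 18; the
weaker groups fall in skill order, and the DockQ-based columns agree.
`autoplot(rk)` draws the stacked category-contribution bars;
`glance(rk)` gives the one-row round summary.

A thin command-line dispatcher ships at `inst/scripts/capriq`
(`assess`, `batch`, `rank`, `simulate` subcommands) for running the same
workflows from a shell.

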