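# moacliff

Scaffold, matched-molecular-pair (MMP) and mechanism-of-action (MOA) cliff
analysis for paired agonist/antagonist screens.

Screening campaigns against one target often run two complementary assays
over a common library: one for activation, one for inhibition. `moacliff`
provides a deterministic, tidyverse-native pipeline over such a pair:

- **Curation** of PubChem-BioAssay-style result tables in six audited
  stages (missing readouts, redundant records, discrepant outcomes,
  non-binary outcomes, mixtures, ringless compounds).
- **Scaffolds**: Bemis–Murcko scaffold and cyclic-skeleton (CSK)
  decomposition, ring-count histograms, exclusivity (active-only /
  inactive-only / overlap) and singleton statistics, exclusive-scaffold
  potency profiles with the one-log-order pIC50 aggregation rule.
- **Diversity**: 1024-bit path fingerprints (OpenBabel FP2) and the mean
  pairwise Tanimoto-distance diversity index.
- **MMPs** by fragment-and-index with the classic size restrictions
  (core ≥ 2× each fragment, fragments ≤ 13 heavy atoms, difference ≤ 8),
  one pair per compound couple, activity-cliff calling, GraphML/SIF
  network export.
- **MOA-cliffs**: compounds active in both arms get label sets
  ({agonist}, {antagonist}, {agonist, antagonist}); MMPs over them are
  classified `same_moa` / `weak_cliff` / `strong_cliff` by set logic.
- A **synthetic paired-screen generator** with planted, analytically
  enumerable ground truth (every within-series pair is an MMP), so the
  whole pipeline is testable offline.

## Example

```r
library(moacliff)

lib <- generate_library(simulation_config(seed = 1))
agonist <- run_pipeline(lib$agonist)
audit_trail(agonist)
#> # A tibble: 6 × 5
#>   stage              n_before n_removed n_after n_records_after
#>   <chr>                 <int>     <int>   <int>           <int>
#> 1 missing_readouts        615         5     610             645
#> 2 collapse_redundant      610         0     610             620
#> 3 drop_discrepant         610        10     600             600
#> 4 binary_outcomes         600        25     575             575
#> 5 remove_mixtures         575        50     525             525
#> 6 remove_ringless         525        25     500             500

bm_scaffold("CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O")  # steroid-like input
#> [1] "O=C1CCC2C(=C1)CCC1C2CCC2C1CCC2"

summarize_scaffolds(assign_scaffolds(agonist))
#> <scaffold_summary: 500 compounds, 50 scaffolds, 2 CSKs>
#>   singleton scaffolds: 12%
#>   exclusivity: 9 active-only / 24 overlap / 17 inactive-only

mmps <- generate_mmps(agonist, seed = 1)
table(mmps$category)
#>     active_mmp activity_cliff   inactive_mmp
#>             15            325           2431

antagonist <- run_pipeline(lib$antagonist)
profiles <- drop_both_inactive(intersect_assays(agonist, antagonist))
moa_mmp_pipeline(profiles, seed = 1)
#> <moa_result: 74 MMPs; 35 same MOA, 3 weak MOA-cliffs, 36 strong MOA-cliffs>
#>  moa_category                         pattern n_mmps
#>      same_moa Active/Inactive/Active/Inactive     12
#>      same_moa Inactive/Active/Inactive/Active     23
#>    weak_cliff   Active/Active/Active/Inactive      3
#>  strong_cliff Active/Inactive/Inactive/Active     12
#>  strong_cliff Inactive/Active/Active/Inactive     24
```

Real exports are read with `read_bioassay_table()` plus a
`bioassay_dialect()` column mapping (YAML via `read_dialect()`); small
examples ship in `inst/extdata/`. `run_all()` chains both arms end to end
and writes every summary table, network and a checksummed manifest. A thin
command-line front end lives at `inst/cli/moacliff.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "moacliff.R", package = "moacliff"))')" \
    simulate --seed 1 --out-dir results/
```

For users holding local copies of the original androgen-receptor deposits,
`compute_study_counts()` and `verify_reference_counts()` compare a run
against the published headline counts.

See the vignette (`vignettes/moa-cliff-analysis.Rmd`) for the methods in
detail.

## License

MIT
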