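# arasdm

Entropy-weighted **additive ratio assessment (ARAS)** for multi-criteria
treatment selection, with a bundled clinical case study: choosing the
provisional (temporary) restoration during the healing interval of
single-tooth implant treatment.

## The problem and the model

A clinician choosing among `m` treatment alternatives scored on `n`
mixed benefit/cost criteria faces a classic multi-criteria
decision-making (MCDM) problem. `arasdm` implements one complete,
objective pipeline:

1. **Ordinal conversion.** Qualitative assessments ("excellent" …
   "poor", "lengthy" … "minimal", …) are mapped to small integers by
   five fixed ordinal rules, giving a decision matrix `x[i, j]` with a
   declared direction (max = benefit, min = cost) and scale per
   criterion.
2. **Entropy weighting.** After reflecting cost columns onto their
   benefit orientation (`x' = scale_max + scale_min − x`), each column
   is normalized to shares `p[i, j] = x[i, j] / Σᵢ x[i, j]`, its
   normalized Shannon entropy `e_j = −(1/ln m) Σᵢ p[i,j] ln p[i,j]` and
   dispersion `d_j = |1 − e_j|` are computed, and weights
   `w_j = d_j / Σ d_j` follow. Criteria that discriminate more among
   alternatives weigh more; constant columns get weight 0.
3. **ARAS ranking.** An ideal "optimal alternative" (column max for
   benefit, min for cost) is prepended; columns are normalized to sum
   to 1 (cost columns via reciprocals `1/x`), weighted by `w`, and
   summed per row into the optimality function `S_i`. The utility
   degree `K_i = S_i / S_opt ∈ (0, 1]` scores each alternative against
   the ideal; alternatives are ranked by descending `K`.
4. **Sensitivity analysis.** Besides entropy weights, the pipeline runs
   equal weights (`S0`) and single-criterion dominance scenarios where
   one criterion is `k` times as important as each other
   (`k = 3` → "S1" with weights 0.30/0.10 for 8 criteria; `k = 2` →
   "S2" with 2/9 and 1/9), once per criterion, and compares the
   resulting rankings (Kendall tau, first divergence).

## Worked example

```r
library(arasdm)

cs <- convert_table(load_case_study())  # 7 alternatives x 8 criteria
w  <- entropy_weights(cs)
print(w, digits = 3)
#> Weight vector (entropy):
#> esthetic potential    patient comfort     treatment time    laboratory cost
#>              0.120              0.195              0.142              0.094
#> occlusal clearance    ease of removal         durability      modifications
#>              0.094              0.067              0.140              0.148

run_aras(cs, w)
#> ARAS result (S_opt = 0.201)
#>                                                   alternative     S     K rank
#>               Implant-supported fixed provisional restoration 0.157 0.782    1
#>               Acrylic resin provisional fixed partial denture 0.131 0.649    2
#>                                      Vacuum-formed appliances 0.114 0.565    3
#>              Wire-retained resin-bonded fixed partial denture 0.111 0.552    4
#>                                     Removable partial denture 0.106 0.528    5
#>                             Bonded extracted tooth or denture 0.093 0.463    6
#>  Metal or fiber-reinforced resin-bonded fixed partial denture 0.087 0.433    7
```

Patient comfort is the most influential criterion (`w = 0.19` at 2 dp),
and the implant-supported fixed provisional restoration is the
top-ranked option (`K = 0.782`), with the same ordering under equal
weighting. Dominance scenarios change the winner only when treatment
time or occlusal clearance dominates:

```r
grid <- run_scenario_grid(cs)           # 8 criteria x {S1, S2}
best_option_report(grid)$cells[c(5, 9), ]
#>            criterion scenario                   winner    K
#> 5     treatment time       S1 Vacuum-formed appliances 0.69
#> 9 occlusal clearance       S1 Vacuum-formed appliances 0.70
```

User-supplied problems enter as a CSV (first column = alternative
names) plus a YAML/JSON criterion config; see `read_decision_csv()` and
`read_criteria_config()`. Random problems for property testing come
from `simulate_decision_problem()`.

## Command line

A front-end script is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "arasdm.R", package = "arasdm"))')" \
  rank --input bundled-case-study --format json --out rank.json
```

Subcommands: `weights`, `rank`, `scenarios`, `simulate`; see
`?aras_cli` for flags.

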