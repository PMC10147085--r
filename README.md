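# fuzzyMCDA

Fuzzy multi-criteria decision analysis in R: PROMETHEE I/II outranking on
linguistic (triangular-fuzzy) ratings with Yager-index defuzzification,
plus weighted-sum and TOPSIS comparators and one-at-a-time
weight-sensitivity analysis.

The package was built around a concrete clinical decision problem —
prioritizing 15 tau PET radiotracer candidates (e.g. [18F]RO-948,
[18F]MK-6240, [18F]AV-1451) for imaging tau pathology in Alzheimer's
disease and other tauopathies — and ships that problem, with its published
reference results, as a worked fixture. All machinery is generic: any
alternatives × criteria problem with linguistic or crisp cells can be
loaded from CSV + JSON/YAML and pushed through the same pipeline.

## The model

Ratings and weights on a linguistic scale (VH, H, M, L, VL) map to
triangular fuzzy numbers *(l, N, r)* and are defuzzified with the Yager
index *F = (3N − a + b)/3* where *a = N − l*, *b = r − N*. With
normalized weights *w_k* and per-criterion preference functions *P_k*
(usual, U-shape, V-shape, level, linear, Gaussian), PROMETHEE computes

    π(a_t, a_u) = Σ_k w_k · P_k(d_tuk)          (preference index)
    Φ+(t) = 1/(n−1) Σ_u π(a_t, a_u)             (strength)
    Φ−(t) = 1/(n−1) Σ_u π(a_u, a_t)             (weakness)
    Φnet  = Φ+ − Φ−                             (PROMETHEE II ranking)

PROMETHEE I reports the partial order (preference / indifference /
incomparability) from (Φ+, Φ−). The weighted-sum method and TOPSIS
(closeness C = D− / (D+ + D−) to ideal/anti-ideal points) run on the same
defuzzified matrix as cross-checks.

## Worked example

```r
library(fuzzyMCDA)

fx <- tau_pet_fixture()                 # 15 tracers x 4 criteria
res <- promethee(fx$matrix, fx$scale)   # calibrated Gaussian config
print(res)
```

```
PROMETHEE II ranking (phi_net = phi_plus - phi_minus):
 rank  alternative phi_net phi_plus phi_minus
    1  [18F]RO-948  0.0051   0.0051    0.0000
    2  [11C]RO-643  0.0044   0.0047    0.0003
    2  [11C]RO-963  0.0044   0.0047    0.0003
    4 [18F]MK-6240  0.0042   0.0044    0.0001
    5 [18F]JNJ-067  0.0033   0.0035    0.0003
    6 [18F]PI-2620  0.0026   0.0032    0.0006
    7 [18F]JNJ-311  0.0019   0.0023    0.0005
    7 [18F]PM-PBB3  0.0019   0.0023    0.0005
    9    [18F]GTP1  0.0012   0.0020    0.0008
   10    [11C]PBB3 -0.0010   0.0009    0.0019
   11 [18F]AV-1451 -0.0028   0.0013    0.0041
   12 [18F]THK5351 -0.0047   0.0006    0.0053
   13 [18F]THK5317 -0.0063   0.0004    0.0067
   14 [18F]THK5105 -0.0070   0.0000    0.0070
   14 [18F]THK5117 -0.0070   0.0000    0.0070
```

[18F]RO-948 is weakly best on every criterion, so its weakness Φ− is
exactly 0 and it ranks first; RO-643/RO-963 tie (identical rating rows),
and the first-generation THK tracers close the field. A TOPSIS
cross-check on the same matrix puts RO-948 at closeness 1.0000 and the
weakly-dominated THK5105/THK5117 at 0.0000 — endpoints forced by
dominance under any convention:

```r
cm <- crispify(fx$matrix, fx$scale)
topsis_scores(cm, normalization = "vector")   # closeness coefficients
weighted_sum_scores(cm, cost_handling = "ratio")
perturb_weight(fx$matrix, "Specificity", "H", fx$scale)  # sensitivity
```

The sensitivity run (specificity weight VH → H) leaves the ranking
essentially unchanged — only MK-6240's rounded rank moves, joining the
RO-643/RO-963 tie — mirroring the stability finding of the reference
analysis.

A command-line wrapper is installed under `inst/cli/`:

```sh
Rscript inst/cli/fuzzymcda rank --matrix inst/extdata/tau_pet_matrix.csv --method all --out out/
Rscript inst/cli/fuzzymcda replicate --out out/
Rscript inst/cli/fuzzymcda calibrate --out out/
```

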