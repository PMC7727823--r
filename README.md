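# geosens

Infer bond-length-change patterns in π-conjugated chromophores from
¹³C chemical-shift changes.

Bilin photoreceptors (phytochromes, cyanobacteriochromes) tune their
absorption colour through the effective conjugation length of their
tetrapyrrole chromophore. Their photoproduct states usually lack crystal
structures, but magic-angle-spinning NMR delivers per-atom shift changes
Δδ (ppm) between dark state and photoproduct. `geosens` exploits the
*geometric sensitivity* of ¹³C shifts — the linear dependence of
instantaneous shifts δᵢ on instantaneous C–C bond lengths dⱼ in a
thermally fluctuating dark-state trajectory:

    Δδᵢ = Σⱼ Mᵢⱼ Δdⱼ,        Mᵢⱼ in ppm/Å

The package

- estimates the significance-filtered sensitivity matrix **M** from
  trajectory fluctuations (per-atom multivariate OLS, batch-means
  standard errors for autocorrelated frames, Benjamini–Hochberg filtering),
- inverts the relationship — centred unscaled PCA of the shift
  fluctuations followed by multivariate regression of bond lengths on the
  component scores — to predict Δd (pm) with bootstrap uncertainties from
  an experimental Δδ vector, with a Moore–Penrose pseudoinverse route as
  an independent cross-check,
- translates predictions into single/double/intermediate bond-alternation
  patterns, conjugation-extent summaries over the ring C/D chain, and
  two-state antagonism reports,
- ships a seeded Ornstein–Uhlenbeck surrogate-trajectory generator with a
  known ground-truth map, so the entire pipeline is testable by parameter
  recovery.

Everything is tidyverse-shaped: wide tibbles (`time_fs` + one column per
bond/atom) in, tibbles out, `tidy()`/`glance()` on fitted objects,
`autoplot()` for the matrix and the predictions.

## Worked example

Simulate a dark-state trajectory with a known map, apply a known
bond-change pattern (at the tens-of-pm scale typical of photoproduct
formation), and recover it from the noisy observed shift changes:

```r
library(geosens)

spec <- synthetic_spec(sigma_shift_ppm = 0.5, seed = 42)
dd_true <- setNames(c(-17, 5, -14, 0, 2, 16), spec$bonds)
pair <- simulate_state_pair(spec, dd_true, n_frames = 1000, noise_ppm = 0.5)
traj <- pair$trajectory

sens <- build_sensitivity_matrix(traj$shifts, traj$bonds)
sens
#> <sensitivity_matrix> 6 atoms x 6 bonds, 34/36 significant (alpha 0.05, bh)
#>     C13-C14 C14-C15 C15-C16 C16-C17 C17-C18 C18-C19
#> C13  120.37  -48.56   20.33   -7.15    2.62   -1.57
#> C14  117.72   29.97  -12.42    5.07    0.00    0.00
#> C15  -11.94   30.41  121.76  -48.05   20.81   -6.48
#> C16   17.41  -47.29  122.01   30.03  -10.82    4.21
#> C17   -2.31    4.41  -11.65   30.53  120.42  -48.31
#> C18    2.81   -8.29   20.15  -47.25  120.55   29.89

model <- fit_inverse_model(fit_shift_pca(traj$shifts),
                           traj$shifts, traj$bonds)
pred <- predict_bond_deltas(model, pair$observed_delta,
                            n_boot = 200, seed = 42)
dplyr::mutate(pred, truth_pm = unname(dd_true))
#>   transition bond    delta_pm uncertainty_pm method        truth_pm
#> 1 Pr->Pg     C13-C14   -17.3           0.123 pc_regression      -17
#> 2 Pr->Pg     C14-C15     2.20          0.256 pc_regression        5
#> 3 Pr->Pg     C15-C16   -14.0           0.112 pc_regression      -14
#> 4 Pr->Pg     C16-C17    -2.83          0.295 pc_regression        0
#> 5 Pr->Pg     C17-C18     1.16          0.150 pc_regression        2
#> 6 Pr->Pg     C18-C19    11.3           0.437 pc_regression       16
```

The recovered slopes sit on the generator's banded, alternating-sign,
asymmetric map (row C13: +120 on its preferred originating bond C13–C14,
−49 on the adjacent bond, decaying outward), and the predicted Δd tracks
the truth; the residual 1–5 pm discrepancies come from the 0.5 ppm noise
on the observed shift-change vector, which the frame bootstrap deliberately
does not absorb into the reported fit uncertainty. Reading the prediction
as bond orders against the dark-state average lengths:

```r
ref <- colMeans(traj$bonds[spec$bonds])
classify_bond_orders(ref, pred)[, c("bond", "predicted_A", "order")]
#>   bond    predicted_A order
#> 1 C13-C14        1.26 double
#> 2 C14-C15        1.49 single
#> 3 C15-C16        1.29 double
#> 4 C16-C17        1.44 single
#> 5 C17-C18        1.44 single
#> 6 C18-C19        1.58 single
```

A strongly shortened C13–C14 / C15–C16 with lengthened ring-D bonds is the
short-conjugation signature expected for a green-shifted photoproduct;
running `compare_states()` on a second, sign-flipped transition reports
the antagonistic pattern of the far-red-shifted one.

A command-line wrapper over the same functions lives at
`inst/cli/geosens.R` (`simulate` / `analyze` subcommands, YAML or JSON
config, `--seed`, `--out`).

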