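# dropsizer

Droplet metrology and print-parameter modelling for microvolume bioprinting.

When cell-laden hydrogel droplets are dispensed onto a hydrophobic substrate,
the dispensed volume decides whether downstream cultures (organoids, droplet
arrays) behave reproducibly. `dropsizer` is for labs that photograph sessile
droplets from the side and want two things automated:

1. **Measurement.** A side-view photograph is reduced to grayscale, edge and
   binary views; the droplet silhouette is found with a gradient-voting Hough
   circle transform; the substrate baseline `y = a` is located; and the base
   diameter `D` and contact angle `θ` follow from the circle–line
   intersection. The droplet is modelled as a spherical cap, so its volume is

   ```
   V = (π D³ / 24) · (2 − 3 cos θ + cos³ θ) / sin³ θ
   ```

   with `D` in mm and `V` in µL. A pixel calibration (a known length and its
   pixel span, e.g. 10 mm over 1028 px → 0.009728 mm/px) converts pixel
   geometry to physical units.

2. **Modelling.** Given tabular records of print parameters (bioink
   viscosity, nozzle inner diameter, dispensing time, pressure, cell
   concentration) with measured volumes, the harness compares five
   regressors — decision tree, random forest, polynomial regression, a
   multilayer perceptron and a single-step LSTM — with a seeded 70/30 split,
   10-fold cross-validation, exhaustive grid search, MAE/MSE/RMSE/R²
   metrics, wall-clock timing, and normalized impurity-based feature
   importance from the random forest.

Because real droplet photographs are rarely shareable, the package ships
seeded synthetic generators: a renderer that draws spherical-cap silhouettes
with analytic ground truth, and a tabular simulator over the factorial
design grid of print parameters. Every pipeline property is testable
without external data.

## Worked example

```r
library(dropsizer)

cal <- calibrate(10, 1028)
#> <calibration> 10 mm over 1028 px = 0.009728 mm/px

# render a synthetic droplet with known geometry, then measure it back
r <- render_droplet(render_spec(diameter_mm = 2.6, theta_deg = 105,
                                noise = 5/255, seed = 7))
measure_droplet(r$image, cal)[, 1:4]
#>   diameter_mm theta_deg height_mm volume_uL
#> 1       2.605     104.9     1.693     7.048
r$truth$volume_uL
#> [1] 7.0437
```

The measured diameter (2.605 mm), contact angle (104.9°) and volume
(7.048 µL) come entirely from the image; the render's analytic truth is
7.044 µL, a 0.06 % error.

```r
# simulate a 1758-record parameter-to-volume dataset and fit the MLP
records <- generate_records(1758, generator_config(noise_cv = 0.02, seed = 42),
                            seed = 42)
sp <- split_dataset(records, 0.7, seed = 42)   # 1230 train / 528 test
mlp <- fit_droplet_model(sp$train, model_spec("mlp", seed = 42))
evaluate_model(mlp, sp$test)
#>   algorithm   mae    mse  rmse    r2 train_time_ms test_time_ms
#> 1 mlp       0.161 0.0470 0.217 0.997          1470            1

feature_importance(records, model_spec("random_forest", seed = 42))
#>            feature importance
#> 1  printing_time_s   0.565886
#> 2     nozzle_id_mm   0.292259
#> 3     pressure_psi   0.071974
#> 4  viscosity_mPa_s   0.069645
#> 5 cell_conc_per_mL   0.000236
```

The held-out R² of 0.997 says the network explains nearly all volume
variance on unseen parameter combinations; the importance table says
dispensing time dominates volume control, followed by nozzle diameter,
with cell concentration essentially irrelevant — the ranking the synthetic
generator is constructed to exhibit.

`compare_algorithms()` produces the five-algorithm summary table
(mean ± sd of each metric over repeated seeded runs plus train/test times),
`grid_search()` returns tuning traces with an `autoplot()` method, and
fitted objects support `tidy()`/`glance()`. A command-line surface is
installed at `exec/dropsizer` with `measure`, `render`, `simulate`,
`train`, `tune`, `importance` and `predict` subcommands.

## Vignette

`vignettes/droplet-volume-pipeline.Rmd` documents the measurement model and
its assumptions, the detector and generator parameters, numerical choices,
and known limitations.
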