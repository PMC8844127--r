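# metaboclock

Demography-linked metabolomic aging clocks for genetically replicated
cohorts.

Inbred panels (e.g. the Drosophila Genetic Reference Panel) allow the
same genotype to be both followed to death and destructively sampled
for molecular profiling at several ages. `metaboclock` implements the
full analysis chain that connects the two kinds of data, for
researchers asking whether a metabolome is a *biological clock*: does
it predict chronological age, and does its residual — age
acceleration — predict lifespan and mortality?

The chain has five stages, each usable on its own:

1. **Demography.** Interval-censored death tables (deaths recorded at
   vial transfers) are fit by exact maximum likelihood to the
   Gompertz–Makeham hazard

   μ(x) = α·e^(βx) + M,

   giving each genotype its baseline mortality α, rate of aging β, and
   extrinsic mortality M; Kaplan–Meier restricted mean lifespans,
   log-rank comparisons, the Strehler–Mildvan correlation (ln α vs β),
   and the linear model of lifespan on (ln α, β) round out the stage.
2. **Phenotypes.** Fecundity per female-day and weekly climbing
   activity, with the week-3–6 activity-decline slope and Spearman
   correlations against the demographic parameters.
3. **Per-metabolite models.** Log + per-sample standardized
   intensities; per-metabolite `level ~ Age + Genotype + Age:Genotype`
   F-tests with Benjamini–Hochberg FDR; PCA; age-specific level and
   age-trajectory associations with lifespan, ln α, and β.
4. **The clock.** An elastic net (coordinate descent, the loss
   (1/2N)Σ(yᵢ−β₀−xᵢᵀβ)² + λ₂[(1−λ₁)‖β‖²/2 + λ₁‖β‖₁]) tuned by
   repeated 80/20 splits with inner 5-fold CV, leave-one-out predicted
   ages, and age-acceleration associations with demography.
5. **Synthetic data.** A generator that reproduces the statistical
   structure above (mortality-correlated parameter draws, planted
   age/genotype/interaction effects, a planted clock direction with a
   lifespan-coupled mid-life shift), with ground-truth labels for every
   planted effect — so the whole pipeline is testable offline.

## Worked example

```r
library(metaboclock)

# a 20-genotype cohort study, fully synthetic
pop  <- simulate_population(seed = 42)          # deaths, census every 2 d
sim  <- simulate_metabolome(pop$specs,
                            metabolome_sim_config(seed = 43))

demog <- demography_table(pop$deaths)
head(demog[, 1:6], 3)
#>   genotype mean_lifespan mean_lifespan_se  ln_alpha       beta      makeham
#> 1      G01        50.800         1.285189  -7.42005 0.08804733 0.0005239642
#> 2      G02        89.248         1.321461 -14.09491 0.12715788 0.0003982754
#> 3      G03        56.368         1.211229 -10.04314 0.12763422 0.0016031007

strehler_mildvan(demog)$rho                     # ln(alpha) vs beta
#> [1] -0.7458647
lifespan_variance_model(demog)$adj_r2           # lifespan ~ ln(alpha) + beta
#> [1] 0.8868868

norm <- preprocess(sim$mat)                     # log + row-standardize + QC
an   <- fit_age_genotype_model(norm)            # Age*Genotype screen
mean(an$age_direction != "none")                # fraction age-significant
#> [1] 0.6551724

hp <- clock_hyperparams(lambda1_grid = c(0, 0.5, 1),
                        lambda2_grid = c(seq(1e-6, 1, length.out = 20),
                                         seq(1, 100, length.out = 30)),
                        n_repeats = 5, seed = 7)
tuned <- tune_and_evaluate(norm, hp)            # 80/20 x inner 5-fold CV
median(tuned$results$test_r2)                   # held-out age prediction
#> [1] 0.9132465

pred <- loocv_predict(norm, tuned$consensus$lambda1, tuned$consensus$lambda2)
aa   <- age_acceleration(pred)                  # predicted - chronological
aa_demography_assoc(aa, demog, at_age = 45)[1, c("parameter", "rho")]
#>       parameter        rho
#> 1 mean_lifespan -0.7984962   # older-reading genotypes die sooner
```

The numbers above are what the code printed for these seeds: the
demography stage recovers the planted mortality structure (a strongly
negative Strehler–Mildvan ρ; most lifespan variance explained by the
two parameters), the metabolome screen flags roughly the planted
fraction of age-responsive metabolites, and the clock predicts held-out
sample age with R² ≈ 0.9. Genotype-mean age acceleration at day 45
correlates strongly and negatively with lifespan, recovering the
planted coupling; with only 20 genotypes the exact strength varies
from seed to seed, which is what the packaged tests quantify.

One call runs everything and writes all output tables plus a run
manifest:

```r
run_pipeline(pipeline_config(out_dir = "out", seed = 1))
```

A thin command-line wrapper over the same function is installed at
`inst/scripts/run-pipeline.R`.

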