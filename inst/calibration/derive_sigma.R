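# Derivation of the default residual standard deviations shipped in
# cohort_spec().
#
# The study reports an R-square for each multivariate model but no
# residual variance.  Given the default covariate marginals, the
# population R-square of a linear model y = lp + e with Var(e) = sigma^2
# is Var(lp) / (Var(lp) + sigma^2), so the sigma that reproduces a target
# R-square is
#
#     sigma = sqrt(Var(lp) * (1 - R2) / R2).
#
# Var(lp) is estimated once from a large noiseless draw of the default
# cohort design (both linear predictors evaluated on 2e6 subjects in the
# default 22:20 group mixture).  Run from the package root:
#
#     Rscript inst/calibration/derive_sigma.R
#
# and copy the printed values into PCT_RATIO_SIGMA_DEFAULT and
# BCVA_SIGMA_DEFAULT (R/synthetic_cohort.R).

library(pctopo)

n_scale <- 2e6 / 42
spec <- cohort_spec(n_op = round(22 * n_scale), n_rn = round(20 * n_scale),
                    pct_ratio_sigma = 0, bcva_sigma = 0, seed = 20260101)
d <- augment_cohort(generate_cohort(spec))

lp_pct <- predict_pct_ratio(d$rnfl_ratio, d$disc_swelling,
                            d$refraction_lesion, d$age, d$male)
r2_pct <- 0.6482                                 # published model R-square
sigma_pct <- sqrt(stats::var(lp_pct) * (1 - r2_pct) / r2_pct)

# trough BCVA linear predictor (published multivariate terms)
b <- c(intercept = 0.2234, age = 0.001, male = -0.081,
       autoimmune = 0.241, vf = -0.051)
lp_bcva <- b[["intercept"]] + b[["age"]] * d$age + b[["male"]] * d$male +
  b[["autoimmune"]] * d$autoimmune_flag + b[["vf"]] * d$vf_defect
r2_bcva <- 0.3978                                # published model R-square
sigma_bcva <- sqrt(stats::var(lp_bcva) * (1 - r2_bcva) / r2_bcva)

cat(sprintf("Var(lp_pct)  = %.6f -> PCT_RATIO_SIGMA_DEFAULT = %.5f\n",
            stats::var(lp_pct), sigma_pct))
cat(sprintf("Var(lp_bcva) = %.6f -> BCVA_SIGMA_DEFAULT      = %.5f\n",
            stats::var(lp_bcva), sigma_bcva))
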