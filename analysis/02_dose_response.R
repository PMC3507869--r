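#!/usr/bin/env Rscript
# Stage 2: fit the constrained logistic dose-response curve.
#
# Fits y(x) = A + (100 - A) / (1 + (x/m)^b) to the simulated survival
# counts, tests whether the lower asymptote is required (extra-sum-of-
# squares F), tests lack of fit against pure replicate error, and reports
# the two decision doses: the dose at which absolute survival reaches 50%
# and the half-reduction dose m (where (100+A)/2 percent survive).

suppressPackageStartupMessages(library(epimsap))
out <- "results"
tab <- read.csv("results/run/dose_response.csv")

fit1 <- fit_dose_response(tab, estimate_lower_asymptote = TRUE)
fit0 <- fit_dose_response(tab, estimate_lower_asymptote = FALSE)
print(fit1)

at <- asymptote_test(fit1, fit0)
message(sprintf("lower asymptote required: F = %.2f on (%d, %d) df, p = %.3g",
                at$F, at$df[1], at$df[2], at$p_value))

lof <- lack_of_fit_test(fit1)
message(sprintf("lack of fit: F = %.2f on (%d, %d) df, p = %.3g (%d observations)",
                lof$F, lof$df_lof, lof$df_pure_error, lof$p_value, lof$n_obs))

doses <- report_doses(fit1)
message(sprintf("dose at absolute 50%% survival: %.3f mM", doses$dose_at_absolute_50))
message(sprintf("half-reduction dose: %.3f mM (%.1f%% expected to survive there)",
                doses$half_reduction_dose, doses$survival_at_half_reduction))

write.csv(data.frame(
  quantity = c("A", "b", "m", "residual_ss", "asymptote_F", "asymptote_p",
               "lack_of_fit_F", "lack_of_fit_p", "n_obs",
               "dose_at_absolute_50", "half_reduction_dose",
               "survival_at_half_reduction"),
  value = c(fit1$A, fit1$b, fit1$m, fit1$residual_ss, at$F, at$p_value,
            lof$F, lof$p_value, lof$n_obs, doses$dose_at_absolute_50,
            doses$half_reduction_dose, doses$survival_at_half_reduction)),
  file.path(out, "dose_response_fit.csv"), row.names = FALSE)

grid <- seq(0, max(tab$dose), length.out = 200)
write.csv(data.frame(dose = grid,
                     fitted_percent = logistic100(grid, fit1$A, fit1$b, fit1$m)),
          file.path(out, "dose_response_curve.csv"), row.names = FALSE)
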