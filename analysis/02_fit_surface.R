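#!/usr/bin/env Rscript
# Stage 2: fit the second-order response surface to the 20-run rotatable CCD
# over the three factors retained by screening (CMC, MgSO4, pH), and test it
# by ANOVA with a lack-of-fit check against the six replicated center runs.

library(pbrsm)
dir.create("results", showWarnings = FALSE)

study <- cellulase_ccd()
fit <- quad_fit(study$design, study$response)
print(fit, digits = 5)

an <- rsm_anova(fit)
print(an)
st <- fit_stats(fit, an)
cat(sprintf("\nR2 = %.4f (adj %.4f), CV = %.2f%%, adequate precision = %.3f\n",
            st$R2, st$adj_R2, st$CV_pct, st$adequate_precision))

write.csv(data.frame(term = names(fit$coefficients),
                     estimate = as.numeric(fit$coefficients)),
          "results/02_coefficients.csv", row.names = FALSE)
write.csv(as.data.frame(an), "results/02_anova.csv", row.names = FALSE)
write.csv(data.frame(run = study$design$run, observed = study$response,
                     predicted = fit$fitted, residual = fit$residuals),
          "results/02_predictions.csv", row.names = FALSE)
cat("Wrote results/02_{coefficients,anova,predictions}.csv\n")
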