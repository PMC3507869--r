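#!/usr/bin/env Rscript
# Stage 4: forward-screen trait statistics.
#
# Decomposes seed area into between- and within-line variance components
# per treatment group, contrasts treated vs control group means with
# line-clustered standard errors and Wald tests (seed area, oil, protein),
# and computes fatty-acid correlations on line means with Fisher-z
# intervals, plus box-plot summaries.

suppressPackageStartupMessages(library(epimsap))
out <- "results"
tt <- read.csv("results/run/traits.csv")

vc_rows <- do.call(rbind, lapply(c("control", "treated"), function(g) {
  vc <- variance_components(tt, "seed_area", subset = tt$treatment == g)
  message(sprintf("seed area, %s lines: between = %.4f, within = %.4f",
                  g, vc$between, vc$within))
  data.frame(group = g, trait = "seed_area",
             between = vc$between, within = vc$within)
}))
write.csv(vc_rows, file.path(out, "trait_variance_components.csv"),
          row.names = FALSE)

ctr <- do.call(rbind, lapply(c("seed_area", "oil", "protein"), function(tr) {
  gc <- group_contrast(tt, tr)
  message(sprintf(
    "%s: treated - control = %.3f (SE %.3f), Wald = %.1f on 1 df, p = %.3g",
    tr, gc$estimate, gc$se, gc$wald, gc$p_value))
  data.frame(trait = tr, estimate = gc$estimate, se = gc$se,
             wald = gc$wald, p_value = gc$p_value)
}))
write.csv(ctr, file.path(out, "trait_contrasts.csv"), row.names = FALSE)

fa <- trait_correlations(tt, c("palmitic", "linoleic", "erucic"))
print(fa)
message(sprintf("erucic:linoleic r = %.2f [%.2f, %.2f]",
                fa$r["erucic", "linoleic"],
                fa$conf_low["erucic", "linoleic"],
                fa$conf_high["erucic", "linoleic"]))
write.csv(data.frame(trait = rownames(fa$r), round(fa$r, 4)),
          file.path(out, "fatty_acid_correlations.csv"), row.names = FALSE)

bx <- do.call(rbind, lapply(c("seed_area", "oil", "protein"), function(tr)
  cbind(trait = tr, boxplot_summary(tt, tr))))
write.csv(bx, file.path(out, "trait_boxplots.csv"), row.names = FALSE)
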