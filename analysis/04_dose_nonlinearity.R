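#!/usr/bin/env Rscript
# Step 4: dose nonlinearity of active-metabolite exposure across the
# microdose-to-therapeutic range, dissected into its two opposing gut-level
# mechanisms: solubility/precipitation-limited absorption of the parent
# (Fa falls with dose) and saturable enterocyte oxidation of the ethyl-ester
# intermediate (its Fg rises with dose).

suppressPackageStartupMessages(library(dabepbpk))
dir.create("results", showWarnings = FALSE)

doses <- c(0.1, 0.375, 1, 3, 10, 30, 75, 150, 300, 400)
cat("== Single ascending oral doses (solid IR above 1 mg, solution below) ==\n\n")
rows <- lapply(doses, function(d) {
  form <- if (d <= 1) "solution" else "solid"
  s <- simulate_scenario(scenario = scenario_spec(d, form, horizon_h = 36,
                                                  dt_out_h = 0.5))
  p <- substrate_profile(s, "DAB")
  m <- nca(p$time, p$conc)
  data.frame(dose_mg = d, formulation = form, auc = m$auc_0_inf,
             cmax = m$cmax, fa_dabe = s$summary$fa[1],
             fg_dabe = s$summary$fg[1], fg_0951 = s$summary$fg[2],
             fh_0951 = s$summary$fh[2])
})
tab <- do.call(rbind, rows)

lin <- dose_linearity(tab$dose_mg, tab$auc, ref_dose = 300)
tab$dose_norm_ratio <- lin$ratio
tab$deviation_factor <- lin$deviation_factor
print(cbind(tab[, c("dose_mg", "formulation")],
            round(tab[, c("auc", "fa_dabe", "fg_dabe", "fg_0951", "fh_0951",
                          "dose_norm_ratio", "deviation_factor")], 3)),
      row.names = FALSE)

micro_dev <- tab$deviation_factor[tab$dose_mg == 0.375]
hi <- tab[tab$dose_mg >= 150, ]
cat(sprintf("\nMicrodose exposure sits %.1f-fold below the therapeutic-range proportionality line.\n",
            micro_dev))
cat(sprintf("Across 150-400 mg the dose-normalized exposure spread is %.0f%% (approximately dose-proportional); at 75 mg the saturation transition is still visible in this calibration.\n",
            100 * (max(hi$dose_norm_ratio) / min(hi$dose_norm_ratio) - 1)))
cat("Fa of the parent falls from ~1 toward ~0.3 while the intermediate's Fg\n")
cat("rises severalfold; the two opposing trends moderate the net nonlinearity.\n")

write.csv(tab, "results/dose_nonlinearity.csv", row.names = FALSE)
cat("\nwrote results/dose_nonlinearity.csv\n")
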