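#!/usr/bin/env Rscript
# Model validation against the welding-simulation measurements: predict
# NF/FF concentrations for the 12 welding conditions with the two-zone
# model, regress measured on predicted per metal and zone, and test the
# NF-vs-FF rank correlation of the measured concentrations.

library(weldfume)

dir.create("results", showWarnings = FALSE)
er_table <- read_emission_table(
  weldfume_example("chamber_emission_rates.csv"))
measured <- read_concentration_table(
  weldfume_example("simulation_measured_concentrations.csv"))

# hall parameters for the 30-min welding simulation: mid-range interzonal
# flow per process, modest supply air; 30 min of continuous arc is long
# against the near-field turnover, so the steady state is used
beta_mid <- c(FCAW = mean(c(6.78, 11.1)), GMAW = mean(c(5.11, 9.08)))
Q <- 30  # m3/min

pred <- er_table
pred$c_nf <- NA_real_; pred$c_ff <- NA_real_
for (i in seq_len(nrow(pred))) {
  p <- two_zone_params(Q = Q, beta = beta_mid[[pred$process[i]]],
                       V_F = 500)
  ss <- tz_steady_state(p, pred$er_mg_min[i])
  pred$c_nf[i] <- ss$c_nf; pred$c_ff[i] <- ss$c_ff
}

# pair predictions with measurements, long format
key <- function(d) paste(d$metal, d$process, d$wire, d$current)
paired <- do.call(rbind, lapply(c("NF", "FF"), function(zone) {
  m <- measured[measured$zone == zone, ]
  i <- match(key(m), key(pred))
  data.frame(metal = m$metal, zone = zone,
             c_p = if (zone == "NF") pred$c_nf[i] else pred$c_ff[i],
             c_m = m$conc_mg_m3)
}))
write.csv(paired, "results/predicted_vs_measured.csv", row.names = FALSE)

fits <- fit_table(paired, by = c("metal", "zone"))
write.csv(fits, "results/validation_fits.csv", row.names = FALSE)
cat("per metal/zone regressions of measured on predicted:\n")
print(fits, digits = 3)
cat(sprintf("R2 range across groupings: %.2f-%.2f\n",
            min(fits$r2), max(fits$r2)))

pz <- pair_zones(measured)
sp <- spearman_cor(pz$NF, pz$FF)
cat(sprintf("measured NF vs FF Spearman rho = %.2f (p = %.2g, n = %d)\n",
            sp$rho, sp$p_value, sp$n))

ppred <- spearman_cor(pred$c_nf, pred$c_ff)
cat(sprintf("predicted NF vs FF Spearman rho = %.2f (p = %.2g, n = %d)\n",
            ppred$rho, ppred$p_value, ppred$n))
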