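#!/usr/bin/env Rscript
# Flap-gliding performance of the giant pterosaur planforms.
#
# Evaluates the two-term glide polar for every planform in the packaged
# wing-attribute table: stall speeds at the steady (1.8) and unsteady
# membrane (2.2) lift ceilings, best glide and minimum sink speeds, sink
# rate and glide ratio. For the broad (heavy) Quetzalcoatlus
# reconstruction it also computes the anaerobic burst climb-out: maximum
# range speed under the configured burst-muscle power budget and the
# one-minute range that speed buys to find external lift.

library(pterosoar)
dir.create("results", showWarnings = FALSE)

cfg <- read_run_config(system.file("extdata", "config_default.yml",
                                   package = "pterosoar"))
t1 <- wing_attribute_table()

rows <- lapply(seq_len(nrow(t1)), function(i) {
  pf <- planform(t1$span_m[i], t1$area_m2[i], t1$mass_kg[i],
                 label = paste(t1$taxon[i], t1$reference[i]))
  perf <- glide_performance(pf, cfg$glide)
  data.frame(label = pf$label, group = t1$group[i],
             mass_kg = pf$mass, span_m = pf$span,
             v_stall = perf$v_stall, v_best_glide = perf$v_best_glide,
             v_min_sink = perf$v_min_sink,
             min_sink_rate = perf$min_sink_rate,
             glide_ratio = perf$best_glide_ratio,
             flap_freq_Hz = flapping_frequency(pf$mass, pf$span, pf$area,
                                               cfg$glide))
})
perf_table <- do.call(rbind, rows)
print(perf_table[perf_table$group == "pterosaur",
                 c("label", "v_stall", "v_best_glide", "v_min_sink")],
      digits = 3)
write_report(perf_table, "results/flight_performance.csv", "csv")

# anaerobic burst climb-out for the broad Quetzalcoatlus reconstruction
witton <- planform(9.64, 11.36, 259.06, "Quetzalcoatlus (broad)")
P <- anaerobic_power(witton$mass, cfg$burst)
v_burst <- burst_speed(witton, cfg$glide, P, cfg$burst$climb_rate)
rng <- burst_range(v_burst, cfg$burst)
cat(sprintf("\nBurst climb-out (broad Quetzalcoatlus): %.0f W available,\n",
            P))
cat(sprintf("  max range speed %.1f m/s at %.1f m/s climb -> %.2f km in %d s\n",
            v_burst, cfg$burst$climb_rate, rng / 1000,
            cfg$burst$burst_duration))
burst_out <- data.frame(label = witton$label, power_W = P,
                        burst_speed = v_burst, burst_range_m = rng)
write_report(burst_out, "results/burst_performance.json", "json")
cat("written: results/flight_performance.csv, results/burst_performance.json\n")
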