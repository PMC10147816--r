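#!/usr/bin/env Rscript

# Stage 1 -- simulate the study cohort.
#
# Generates the default synthetic atlas (97 ROIs: 45 bilateral pairs + 7
# midline, ten planted modules of which two are lateralized 15-ROI
# super-modules hiding two sub-modules each), 33 subjects x 264 volumes of
# latent-factor AR(1) time series with planted hub pairs, and two jittered
# network-overlap tables. Everything is written under results/cohort/ as
# TSV, including the planted ground truth.

library(dogconn)

seed <- 1L
out <- "results/cohort"
co <- simulate_cohort(seed = seed, out_dir = out)

message("cohort: ", length(co$ts), " subjects x ", nrow(co$ts[[1]]),
        " volumes x ", nrow(co$meta), " ROIs -> ", out)
message("planted modules: ",
        paste(names(table(co$meta$group)), table(co$meta$group),
              sep = "=", collapse = ", "))
message("planted hub pairs: ", paste(co$hub_units, collapse = ", "))
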