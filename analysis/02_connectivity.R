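#!/usr/bin/env Rscript

# Stage 2 -- first- and second-level connectivity.
#
# Per subject: symmetrized semi-partial correlation matrix and its Fisher
# z-transform. Group level: per-edge one-sample t-tests of z against zero,
# a per-seed sign-flip omnibus test (5000 permutations) with BH-FDR
# correction across ROIs, and the two-level threshold (seed q < 0.05,
# edge p < 0.01). Writes per-subject matrices, the edge/seed statistic
# tables and the retained edge list under results/.

library(dogconn)

seed <- 1L
meta <- read_metadata("results/cohort/metadata.tsv")
files <- sort(list.files("results/cohort/timeseries", full.names = TRUE))
ts <- lapply(files, read_timeseries)
names(ts) <- sub("\\.tsv$", "", basename(files))

cohort <- lapply(ts, semipartial_matrix)
dir.create("results/connectivity", recursive = TRUE, showWarnings = FALSE)
for (s in names(cohort))
  write_connectivity(cohort[[s]], file.path("results/connectivity",
                                            paste0(s, ".csv")))

stage_seeds <- derive_seeds(seed, 4)   # stage split used by run_pipeline()
stats <- group_edge_stats(cohort, n_perm = 5000, seed = stage_seeds[1])
write_group_stats(stats, "results/edge_stats.tsv", "results/seed_stats.tsv")

edges <- threshold_edges(stats, seed_alpha = 0.05, edge_alpha = 0.01)
write.table(edges, "results/retained_edges.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(nrow(edges), " of ", nrow(stats$edges),
        " edges survive the two-level threshold (",
        round(100 * nrow(edges) / nrow(stats$edges), 1), "%)")
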