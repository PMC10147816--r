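#!/usr/bin/env Rscript

# Stage 5 -- hub structure.
#
# Weighted degree, degree and betweenness per ROI; bilateral pairs averaged
# before ranking (midline ROIs compete unchanged); top-20 rankings per
# metric and the consensus hub set (ROIs in all three top-20 lists).

library(dogconn)

meta <- read_metadata("results/cohort/metadata.tsv")
edges <- read.table("results/retained_edges.tsv", header = TRUE,
                    stringsAsFactors = FALSE)
g <- build_graph(edges, meta)

cent <- node_centralities(g)
pairs <- bilateral_average(cent, meta)
rankings <- list(wd = top_k_nodes(pairs, "wd", 20),
                 d = top_k_nodes(pairs, "d", 20),
                 bc = top_k_nodes(pairs, "bc", 20))
hubs <- consensus_hubs(rankings, 20)
write_rankings(rankings, hubs, "results")

message("top-5 by weighted degree: ",
        paste(head(rankings$wd$unit, 5), collapse = ", "))
message(length(hubs), " consensus hubs (top-20 in all three metrics): ",
        paste(hubs, collapse = ", "))
truth <- read.table("results/cohort/ground_truth.tsv", header = TRUE)
hub_units <- unique(sub("_[LR]$", "", truth$roi[truth$hub]))
message("planted hub pairs recovered: ",
        sum(hub_units %in% hubs), "/", length(hub_units))
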