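#!/usr/bin/env Rscript

# Stage 6 -- parcellation comparison.
#
# Allocates ROIs to networks by overlap majority vote (bilateral pairs
# averaged before the argmax) for two independently jittered overlap
# tables, then scores the agreement of the two network-to-ROI parcellations
# with one-to-one greedy Jaccard matching.

library(dogconn)

meta <- read_metadata("results/cohort/metadata.tsv")
ov_a <- read_overlap("results/cohort/overlap_a.tsv")
ov_b <- read_overlap("results/cohort/overlap_b.tsv")

assign_a <- allocate_rois(ov_a, meta)
assign_b <- allocate_rois(ov_b, meta)
tab <- match_networks(assign_a, assign_b)
write.table(tab, "results/jaccard.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)

print(tab)
message("mean Jaccard over matched networks: ",
        round(mean(tab$jaccard, na.rm = TRUE), 3))
message("unallocated ROIs: ",
        length(assign_a$unallocated), " (table A), ",
        length(assign_b$unallocated), " (table B)")
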