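#!/usr/bin/env Rscript
# Stage 4: consensus scanning and best-match alignment of screen winners.
#
# The two element consensuses under study: the 11-bp GACRNANNACG (128
# concrete sequences) and the 13-bp TTCCCTBTAAWTG (6 concrete sequences).
# This stage scans a synthetic promoter panel with planted element
# instances (forward and reverse), and aligns the pathway-dependent
# winners from stage 3 against promoters carrying a near-match, the way
# enriched screen sequences are related to native promoter elements.

library(selseq)

seed <- 20260922
dir.create("results", showWarnings = FALSE)

for (pat in c("GACRNANNACG", "TTCCCTBTAAWTG")) {
  message(sprintf("consensus %s covers %d concrete sequences", pat,
                  degeneracy(pat)))
}
message(sprintf("binding-site orientations: forward %s / reverse %s",
                "ggaaacccttagag", revcomp("ggaaacccttagag")))

# Promoter panel: 12 x 1 kb, the 11-bp element planted in promoters 2, 5
# and 9 (promoter 9 on the reverse strand).
element <- "GACGTACAACG"
proms <- gen_promoters(12, length = 1000, element = element,
                       planted_in = c(2, 5, 9), offsets = c(250, 430, 120),
                       strand = c("+", "+", "-"), seed = seed)
scan <- scan_promoters("GACRNANNACG", proms, window = 1000,
                       both_strands = TRUE)
message(sprintf("scan: %d promoters of %d carry the consensus in their 1 kb window",
                scan$n_promoters_with_match, length(proms)))
utils::write.table(scan$matches, "results/04_consensus_scan.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)

# Align screen winners against a promoter carrying a single-mismatch copy
# of the element (a 10/11 match).
run <- run_pipeline(pipeline_config(seed = seed))
winners <- run$pathway_dependent$sequence
near <- winners[1]
substr(near, 6, 6) <- setdiff(c("A", "C", "G", "T"),
                              substr(near, 6, 6))[1]
panel <- gen_promoters(3, length = 600, element = near, planted_in = 2,
                       offsets = 300, seed = seed + 1)
hits <- do.call(rbind, lapply(winners, function(w) {
  best <- NULL
  for (nm in names(panel)) {
    m <- cbind(query = w, best_ungapped_match(w, panel[[nm]],
                                              both_strands = TRUE,
                                              target_name = nm))
    if (is.null(best) || m$identities > best$identities) best <- m
  }
  best
}))
message(sprintf("best match of winner %s in the panel: %d/%d bp (%s)",
                winners[1], hits$identities[1], hits$pattern_length[1],
                hits$target_name[1]))
utils::write.table(hits, "results/04_winner_matches.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
message("wrote results/04_consensus_scan.tsv and results/04_winner_matches.tsv")
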