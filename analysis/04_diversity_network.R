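#!/usr/bin/env Rscript
# Haplotype collapsing, per-species diversity statistics (the Table 1
# analogue) and the 95% statistical-parsimony haplotype network with gaps as a
# fifth character state.

library(cyanodelim)

aln <- read_alignment("results/alignment.fasta")
truth <- unlist(jsonlite::read_json("results/truth.json")$species)
groups <- setNames(paste0("species", truth[aln$ids]), aln$ids)

tab <- diversity_table(aln, groups, min_n = 5)
write.table(tab, "results/diversity_table.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(paste(capture.output(print(tab)), collapse = "\n"))

haps <- collapse_haplotypes(aln)
message(sprintf("%d unique haplotypes from %d sequences",
                nrow(haps$haplotypes), length(aln$ids)))

steps <- pairwise_steps(haps, gap_as_fifth = TRUE)
limit <- connection_limit(aln$length, prob = 0.95)
net <- build_network(steps, limit,
                     freq = setNames(haps$haplotypes$size, haps$haplotypes$id))
write_network(net, "results/network")
message(sprintf("connection limit %d steps -> %d subnetworks (%d inferred nodes)",
                limit, max(net$subnetwork), sum(net$nodes$inferred)))
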