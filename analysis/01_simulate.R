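#!/usr/bin/env Rscript
# Generate the synthetic study system: an ultrametric photobiont gene tree
# with 5 species x 6 specimens, a posterior-like sample of 100 jittered trees,
# a 582 bp alignment with indels, and an environmentally driven locality x OTU
# table over 32 localities. Everything downstream reads from results/.

library(cyanodelim)

dir.create("results", showWarnings = FALSE)
seed <- 20150716  # publication date of the study system's description

sim <- simulate_species_tree_sample(n_species = 5, tips_per_species = 6,
                                    separation_ratio = 20, n_posterior = 100,
                                    jitter_sd = 0.1, seed = seed)
write_tree_sample(sim$sample, "results/tree_sample.nwk")
ape::write.tree(sim$tree, "results/true_tree.nwk")

aln <- simulate_alignment(sim$tree, n_sites = 582, mut_rate = 0.15,
                          indel_rate = 1, seed = seed + 1)
write_alignment(aln, "results/alignment.fasta")

comm <- simulate_community(n_localities = 32, otu_pool = 22, n_env_vars = 10,
                           driver_vars = 1:2, effect_size = 2, seed = seed + 2)
write.csv(data.frame(locality = rownames(comm$community), comm$community,
                     check.names = FALSE),
          "results/community.csv", row.names = FALSE)
write.csv(data.frame(locality = rownames(comm$env), comm$env,
                     check.names = FALSE),
          "results/env.csv", row.names = FALSE)

truth <- list(species = as.list(sim$truth$partition),
              drivers = comm$truth$drivers, master_seed = seed)
jsonlite::write_json(truth, "results/truth.json", auto_unbox = TRUE)

message(sprintf("tree: %d tips, height %.3f; alignment: %d x %d; community: %d x %d",
                ape::Ntip(sim$tree), sim$truth$height, length(aln$ids),
                aln$length, nrow(comm$community), ncol(comm$community)))
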