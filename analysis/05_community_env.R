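#!/usr/bin/env Rscript
# Locality-level composition vs geography and environment: ANOSIM with
# a-priori geographic groups, SIMPER decomposition of the strongest contrast,
# BIO-ENV/BVSTEP matching of the environmental matrix, and the rank
# correlation between two biotic matrices (the Tables 3-4 / gradient-analysis
# analogue). Permutation and restart counts are desk-scale stand-ins for the
# study's 10,000.

library(cyanodelim)

comm <- read_community_table("results/community.csv")
env <- read_env_table("results/env.csv", substrate_col = NULL)
check_pairing(comm, env)

D <- dissimilarity(comm, "sorensen")
groups <- setNames(rep(c("North", "Center", "South", "Islands"), each = 8),
                   rownames(comm))

an <- anosim(D, groups, n_perm = 2000, seed = 1)
write.table(
  cbind(data.frame(group = rownames(an$pairwise_R)),
        round(an$pairwise_R, 3),
        signif = apply(an$pairwise_p, 1, function(p) {
          paste(ifelse(is.na(p), "-",
                       ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "n.s."))),
                collapse = "/")
        })),
  "results/anosim_table.tsv", sep = "\t", quote = FALSE, row.names = FALSE)
message(sprintf("global ANOSIM R = %.3f, p = %.4g (%d permutations)",
                an$R, an$p, an$n_perm))

pair <- c("North", "Islands")
sm <- simper(comm, groups, pair = pair)
write.table(sm, "results/simper.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("top SIMPER contributor %s vs %s: %s (%.2f%%)",
                pair[1], pair[2], sm$unit[1], sm$percent[1]))

env_n <- normalize_env(env)
bv <- bioenv_bvstep(D, env_n, n_restarts = 100, n_perm = 99,
                    collin_mode = "correlation", seed = 2)
write.table(bv$models, "results/bvstep_models.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
message(sprintf("best model {%s}: rho = %.3f in %.1f%% of restarts, p = %.3g",
                paste(bv$best$vars, collapse = ", "), bv$best$rho,
                100 * bv$models$frequency[1], bv$p))

# correlation between the halves of the OTU pool, mimicking the comparison of
# the two lichen species' photobiont similarity matrices
D1 <- dissimilarity(comm[, 1:11], "sorensen")
D2 <- dissimilarity(comm[, 12:22], "sorensen")
mc <- matrix_correlation(D1, D2, n_perm = 2000, seed = 3)
message(sprintf("matrix rank correlation between OTU-pool halves: rho = %.3f, p = %.4g",
                mc$rho, mc$p))
jsonlite::write_json(list(anosim_R = an$R, anosim_p = an$p,
                          bvstep = bv$best, matrix_rho = mc$rho,
                          matrix_p = mc$p),
                     "results/community_env.json", auto_unbox = TRUE)
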