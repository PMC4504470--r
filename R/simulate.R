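## Seeded generators for every input the pipeline consumes: species trees
## with within-species coalescents, posterior-like jittered tree samples,
## alignments evolved along a tree, and environmentally driven community
## tables. Every generator is a pure function of its parameters and seed and
## emits the ground truth alongside the data.

#' Simulate a species tree with within-species coalescents and a
#' posterior-like tree sample
#'
#' A pure-birth species tree is drawn, and each species tip is replaced by a
#' neutral coalescent of its individuals scaled so the mean within-species
#' depth equals the shallowest species divergence on the species tree divided
#' by `separation_ratio` (so every species is separated from every other by at
#' least that factor, and a single threshold can delimit them). The
#' posterior-like sample re-draws the within-species coalescent times,
#' multiplies every branch by lognormal noise and re-ultrametrizes, emulating
#' the topological and branch-length uncertainty of a Bayesian tree sample.
#'
#' @param n_species Number of species (default 5).
#' @param tips_per_species Individuals sampled per species (default 6).
#' @param birth_rate Speciation rate of the pure-birth process (default 1).
#' @param theta Within-species coalescent scale; `NULL` (default) derives it
#'   from `separation_ratio`.
#' @param separation_ratio Ratio of the shallowest species divergence to the
#'   mean within-species coalescent depth (default 20; larger = cleaner
#'   separation).
#' @param n_posterior Number of jittered trees in the sample (default 100).
#' @param jitter_sd Lognormal sd of the branch-length noise (default 0.1).
#' @param seed Integer seed.
#' @return List: `tree` (the true ultrametric tree), `sample` (a
#'   [tree_sample()]), `truth` (species partition of tips and the generator
#'   parameters).
#' @export
simulate_species_tree_sample <- function(n_species = 5L, tips_per_species = 6L,
                                         birth_rate = 1, theta = NULL,
                                         separation_ratio = 20,
                                         n_posterior = 100L, jitter_sd = 0.1,
                                         seed = NULL) {
  stopifnot(separation_ratio > 1, n_species >= 1L, tips_per_species >= 1L,
            n_posterior >= 0L)
  with_seed(seed, {
    sp_tree <- NULL
    H <- 1
    if (n_species > 1L) {
      sp_tree <- ape::rphylo(n_species, birth = birth_rate, death = 0)
      H <- max(node_heights(sp_tree))
    }
    build <- function() graft_coalescents(sp_tree, n_species, tips_per_species,
                                          separation_ratio, H)
    tree <- build()
    sample_trees <- lapply(seq_len(n_posterior), function(i) {
      jitter_ultrametric(build(), jitter_sd)
    })
    truth <- list(
      partition = setNames(rep(seq_len(n_species), each = tips_per_species),
                           tree$tip.label),
      n_species = n_species, tips_per_species = tips_per_species,
      birth_rate = birth_rate, theta = theta %||% (H / separation_ratio),
      separation_ratio = separation_ratio, jitter_sd = jitter_sd,
      height = max(node_heights(tree)), seed = seed)
    list(tree = tree,
         sample = if (n_posterior > 0L) tree_sample(sample_trees) else NULL,
         truth = truth)
  })
}

# Replace each species tip by a within-species coalescent of its individuals.
# Coalescent times are drawn with mean subtree depth equal to the shallowest
# species divergence (the shortest pendant branch of the species tree, since
# tips are contemporaneous) divided by `separation_ratio`; subtrees deeper
# than their species' pendant branch are resampled, erroring after 1000
# attempts.
graft_coalescents <- function(sp_tree, n_species, tips_per_species,
                              separation_ratio, H) {
  sub <- function(sp, within_h) {
    labs <- paste0("sp", sp, "_", seq_len(tips_per_species))
    if (tips_per_species == 1L) return(NULL)
    ct <- ape::rcoal(tips_per_species, tip.label = labs)
    # E[height of rcoal] = 2 (1 - 1/k) on its time scale
    ct$edge.length <- ct$edge.length * within_h /
      (2 * (1 - 1 / tips_per_species))
    ct
  }
  if (is.null(sp_tree)) {  # single species: the tree is one coalescent
    ct <- ape::rcoal(tips_per_species,
                     tip.label = paste0("sp1_", seq_len(tips_per_species)))
    ct$edge.length <- ct$edge.length * H / max(node_heights(ct))
    return(ct)
  }
  tr <- sp_tree
  pend_all <- sp_tree$edge.length[match(seq_len(n_species), sp_tree$edge[, 2L])]
  within_h <- min(pend_all) / separation_ratio
  for (sp in seq_len(n_species)) {
    tip_lab <- sp_tree$tip.label[sp]
    if (tips_per_species == 1L) {
      tr$tip.label[tr$tip.label == tip_lab] <- paste0("sp", sp, "_1")
      next
    }
    wi <- which(tr$tip.label == tip_lab)
    pend <- tr$edge.length[tr$edge[, 2L] == wi]
    ct <- NULL
    for (attempts in seq_len(1000L)) {
      ct <- sub(sp, within_h)
      if (max(node_heights(ct)) < pend) break
      if (attempts == 1000L) {
        stopf("cannot graft coalescent for species %d: pendant branch too short", sp)
      }
    }
    # shorten the pendant edge and bind the coalescent subtree at its end
    ch <- max(node_heights(ct))
    tr$edge.length[tr$edge[, 2L] == wi] <- pend - ch
    tr <- ape::bind.tree(tr, ct, where = wi)
  }
  tr
}

# Multiply branch lengths by lognormal noise, then rebuild node ages
# bottom-up (age of a node = mean over children of child age + jittered edge,
# clamped above the oldest child) so the tree stays ultrametric.
jitter_ultrametric <- function(tree, jitter_sd) {
  if (jitter_sd <= 0) return(tree)
  tr <- ape::reorder.phylo(tree, "postorder")
  ntip <- ape::Ntip(tr)
  el <- tr$edge.length * rlnorm(length(tr$edge.length),
                                -jitter_sd^2 / 2, jitter_sd)
  age <- numeric(ntip + tr$Nnode)
  kids <- split(seq_len(nrow(tr$edge)), tr$edge[, 1L])
  # postorder edge order: a parent's first occurrence follows all edges below it
  ord <- unique(tr$edge[, 1L])
  for (p in ord) {
    ke <- kids[[as.character(p)]]
    ch <- tr$edge[ke, 2L]
    a <- mean(age[ch] + el[ke])
    age[p] <- max(a, max(age[ch]) * (1 + 1e-9) + 1e-12)
  }
  tr$edge.length <- age[tr$edge[, 1L]] - age[tr$edge[, 2L]]
  ape::reorder.phylo(tr, "cladewise")
}

#' Simulate an alignment along an ultrametric tree
#'
#' Characters evolve under a one-parameter (Jukes-Cantor) substitution process
#' via `phangorn::simSeq`; optional single-column indel events place gaps over
#' a random clade to exercise gap-handling policies.
#'
#' @param tree Ultrametric `phylo` object.
#' @param n_sites Alignment length (default 582).
#' @param mut_rate Substitution rate per site per unit tree depth
#'   (default 0.15).
#' @param indel_rate Expected number of single-column indel events per 100
#'   sites (default 0).
#' @param seed Integer seed.
#' @return A [alignment()] object.
#' @export
simulate_alignment <- function(tree, n_sites = 582L, mut_rate = 0.15,
                               indel_rate = 0, seed = NULL) {
  stopifnot(mut_rate >= 0, indel_rate >= 0, n_sites >= 1L)
  with_seed(seed, {
    if (mut_rate == 0) {
      base <- paste(sample(c("A", "C", "G", "T"), n_sites, replace = TRUE),
                    collapse = "")
      seqs <- setNames(rep(base, ape::Ntip(tree)), tree$tip.label)
      return(alignment(seqs))
    }
    sim <- phangorn::simSeq(tree, l = n_sites, rate = mut_rate)
    m <- toupper(as.character(sim))
    seqs <- apply(m, 1L, paste, collapse = "")
    if (indel_rate > 0) {
      n_events <- rbinom(1L, n_sites, indel_rate / 100)
      if (n_events > 0) {
        chars <- t(vapply(seqs, function(s) strsplit(s, "")[[1L]],
                          character(n_sites)))
        prep <- gmyc_prep(tree)
        for (ev in seq_len(n_events)) {
          col <- sample.int(n_sites, 1L)
          node <- sample((prep$ntip + 2L):(prep$ntip + prep$nnode), 1L)
          tips <- tip_descendants(prep, node)
          chars[tips, col] <- "-"
        }
        seqs <- apply(chars, 1L, paste, collapse = "")
        names(seqs) <- rownames(chars)
      }
    }
    alignment(seqs[tree$tip.label])
  })
}

tip_descendants <- function(prep, node) {
  if (node <= prep$ntip) return(node)
  inside <- logical(prep$ntip + prep$nnode)
  inside[node] <- TRUE
  for (e in seq_len(nrow(prep$edge))) {  # cladewise: parents precede children
    if (inside[prep$edge[e, 1L]]) inside[prep$edge[e, 2L]] <- TRUE
  }
  which(inside[seq_len(prep$ntip)])
}

#' Simulate an environmentally driven community table
#'
#' Environmental variables are drawn with exchangeable cross-correlation
#' `env_cor`; the occurrence probability of each OTU at each locality is
#' `plogis(intercept + sum(effects * driver values))` with OTU-specific
#' coefficients of magnitude `effect_size` (random sign) on the planted driver
#' variables; optional Gaussian noise of sd `noise_sd` on the linear predictor
#' is off by default. All-absent or all-present OTU columns are resampled.
#'
#' @param n_localities Number of localities (default 32, the study's sampling
#'   scale).
#' @param otu_pool Number of OTUs (default 22).
#' @param n_env_vars Number of environmental variables (default 10).
#' @param driver_vars Indices or names of the true driver variables
#'   (default `1:2`).
#' @param effect_size Coefficient magnitude on drivers (default 2; 0 = no
#'   environmental signal).
#' @param noise_sd Sd of extra noise on the linear predictor (default 0, the
#'   plain logistic occurrence model).
#' @param env_cor Exchangeable correlation between environmental variables
#'   (default 0.2).
#' @param intercept Baseline logit occupancy (default -0.5).
#' @param seed Integer seed.
#' @return List: `community` (presence/absence matrix), `env` (raw
#'   environmental table), `truth` (drivers, coefficients, parameters).
#' @export
simulate_community <- function(n_localities = 32L, otu_pool = 22L,
                               n_env_vars = 10L, driver_vars = 1:2,
                               effect_size = 2, noise_sd = 0,
                               env_cor = 0.2, intercept = -0.5, seed = NULL) {
  stopifnot(n_env_vars >= 1L, otu_pool >= 1L, n_localities >= 2L)
  vars <- paste0("env", seq_len(n_env_vars))
  drivers <- if (is.character(driver_vars)) driver_vars else vars[driver_vars]
  stopifnot(all(drivers %in% vars))
  with_seed(seed, {
    # exchangeable correlation via a shared latent factor
    z <- rnorm(n_localities)
    env <- vapply(seq_len(n_env_vars), function(j) {
      sqrt(env_cor) * z + sqrt(1 - env_cor) * rnorm(n_localities)
    }, numeric(n_localities))
    dimnames(env) <- list(paste0("loc", seq_len(n_localities)), vars)
    beta <- matrix(0, n_env_vars, otu_pool, dimnames = list(vars, NULL))
    for (k in seq_len(otu_pool)) {
      beta[drivers, k] <- effect_size * sample(c(-1, 1), length(drivers),
                                               replace = TRUE)
    }
    draw_otu <- function(k) {
      eta <- intercept + env %*% beta[, k] + rnorm(n_localities, 0, noise_sd)
      rbinom(n_localities, 1L, plogis(eta))
    }
    comm <- matrix(0L, n_localities, otu_pool,
                   dimnames = list(rownames(env),
                                   paste0("OTU", seq_len(otu_pool))))
    for (k in seq_len(otu_pool)) {
      for (att in seq_len(50L)) {
        v <- draw_otu(k)
        if (length(unique(v)) > 1L) break
      }
      comm[, k] <- v
    }
    # no locality may be empty (required downstream by Sorensen)
    empty <- rowSums(comm) == 0L
    if (any(empty)) comm[empty, sample.int(otu_pool, 1L)] <- 1L
    env_df <- as.data.frame(env)
    attr(env_df, "normalized") <- FALSE
    list(community = comm, env = env_df,
         truth = list(drivers = drivers, beta = beta,
                      effect_size = effect_size, noise_sd = noise_sd,
                      env_cor = env_cor, intercept = intercept, seed = seed))
  })
}
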