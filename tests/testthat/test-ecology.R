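test_that("environmental normalization z-scores and expands substrate", {
  env <- data.frame(a = c(1, 2, 3), b = c(10, 0, 5),
                    row.names = paste0("l", 1:3))
  ne <- normalize_env(env)
  expect_equal(unname(colMeans(ne)), c(0, 0))
  expect_equal(unname(apply(ne, 2, sd)), c(1, 1))
  expect_equal(ne$a, (c(1, 2, 3) - 2) / 1)
  # idempotence
  expect_equal(as.matrix(normalize_env(ne)), as.matrix(ne), tolerance = 1e-12)

  env2 <- data.frame(x = c(1, 4, 2, 5),
                     substrate = c("acid", "volcanic", "acid", "volcanic"),
                     row.names = paste0("l", 1:4))
  ne2 <- normalize_env(env2)
  expect_setequal(names(ne2),
                  c("x", "substrate_acid", "substrate_volcanic"))
  expect_equal(sd(ne2$substrate_acid), 1)

  expect_error(normalize_env(data.frame(k = c(2, 2, 2))), "constant")
})

test_that("dissimilarities match their closed forms", {
  m <- matrix(c(1, 1, 0,
                1, 0, 1,
                1, 1, 0), 3, 3, byrow = TRUE,
              dimnames = list(paste0("l", 1:3), paste0("u", 1:3)))
  D <- dissimilarity(m, "sorensen")
  expect_equal(D["l1", "l2"], 1 - 2 * 1 / (2 * 1 + 1 + 1))  # a=1, b=1, c=1
  expect_equal(D["l1", "l3"], 0)
  disj <- rbind(l1 = c(1, 1, 0, 0), l2 = c(0, 0, 1, 1))
  expect_equal(dissimilarity(disj, "sorensen")[1, 2], 1)
  zero <- rbind(l1 = c(1, 0), l2 = c(0, 0))
  expect_error(dissimilarity(zero, "sorensen"), "all-zero.*l2")

  counts <- rbind(l1 = c(4, 0, 2), l2 = c(1, 3, 2))
  expect_equal(dissimilarity(counts, "braycurtis")[1, 2],
               sum(abs(counts[1, ] - counts[2, ])) / sum(counts))
  ev <- rbind(l1 = c(0, 0), l2 = c(3, 4))
  expect_equal(dissimilarity(ev, "euclidean")[1, 2], 5)
})

test_that("ANOSIM matches closed forms, enumeration and the reference", {
  # perfect separation: R = 1
  m <- rbind(a1 = c(1, 1, 0, 0), a2 = c(1, 1, 1, 0),
             b1 = c(0, 0, 1, 1), b2 = c(0, 1, 1, 1))
  D <- dissimilarity(m, "sorensen")
  g <- setNames(c("A", "A", "B", "B"), rownames(m))
  expect_equal(anosim(D, g, n_perm = 99, seed = 1, pairwise = FALSE)$R, 1)

  # all distances equal: R = 0
  De <- matrix(1, 4, 4); diag(De) <- 0
  dimnames(De) <- dimnames(D)
  expect_equal(anosim(De, g, n_perm = 99, seed = 1, pairwise = FALSE)$R, 0)

  # exact enumeration equals the naive oracle for 2 groups of 3
  sc <- simulate_community(n_localities = 6, otu_pool = 8, seed = 41)
  D6 <- dissimilarity(sc$community, "sorensen")
  g6 <- setNames(rep(c("N", "S"), each = 3), rownames(D6))
  res <- anosim(D6, g6, exact_limit = 30, pairwise = FALSE)
  expect_true(res$exact)
  perms <- combn(6, 3, simplify = FALSE)
  R_all <- vapply(perms, function(idx) {
    gg <- rep("S", 6); gg[idx] <- "N"
    naive_anosim_R(D6, gg)
  }, numeric(1))
  expect_equal(res$R, naive_anosim_R(D6, g6))
  expect_equal(res$p, mean(R_all >= res$R - 1e-12))

  # sampled permutations approximate the exact value
  res_s <- anosim(D6, g6, n_perm = 2000, seed = 2, pairwise = FALSE)
  expect_lt(abs(res_s$p - res$p), 0.05)
  expect_true(res_s$p > 0 && res_s$p <= 1)

  # rank-based: invariant to monotone transforms of the dissimilarities
  sc2 <- simulate_community(n_localities = 12, otu_pool = 10, seed = 42)
  D12 <- dissimilarity(sc2$community, "sorensen")
  g12 <- setNames(rep(c("A", "B", "C"), each = 4), rownames(D12))
  r1 <- anosim(D12, g12, n_perm = 99, seed = 3, pairwise = FALSE)$R
  r2 <- anosim(D12^2, g12, n_perm = 99, seed = 3, pairwise = FALSE)$R
  expect_equal(r1, r2)

  # agreement with the reference implementation's R statistic
  ref <- vegan::anosim(stats::as.dist(D12), grouping = g12, permutations = 0)
  expect_equal(r1, unname(ref$statistic))

  # pairwise table: size-1 groups are not computable
  g_bad <- setNames(c("A", "A", "A", "A", "B", "B", "B", "B", "C", "C",
                      "C", "D"), rownames(D12))
  pw <- anosim(D12, g_bad, n_perm = 99, seed = 4)
  expect_true(is.na(pw$pairwise_R["A", "D"]))
  expect_false(is.na(pw$pairwise_R["A", "B"]))
})

test_that("SIMPER decomposes dissimilarity with percents summing to 100", {
  # groups differing in exactly one unit: that unit contributes 100%
  m <- rbind(a1 = c(1, 1, 0), a2 = c(1, 1, 0),
             b1 = c(1, 1, 1), b2 = c(1, 1, 1))
  colnames(m) <- paste0("u", 1:3)
  g <- setNames(c("A", "A", "B", "B"), rownames(m))
  tab <- simper(m, g)
  expect_equal(tab$unit[1], "u3")
  expect_equal(tab$percent[1], 100)

  # hand-computed 2x2 example
  m2 <- rbind(x = c(2, 1), y = c(0, 1))
  colnames(m2) <- c("u1", "u2")
  t2 <- simper(m2, setNames(c("G1", "G2"), c("x", "y")))
  expect_equal(t2$average, c(2 / 4, 0 / 4))
  expect_equal(t2$percent, c(100, 0))

  sc <- simulate_community(n_localities = 10, otu_pool = 12, seed = 43)
  g10 <- setNames(rep(c("A", "B"), each = 5), rownames(sc$community))
  t3 <- simper(sc$community, g10)
  expect_equal(sum(t3$percent), 100, tolerance = 1e-6)
  expect_equal(t3$cumulative[nrow(t3)], 100, tolerance = 1e-6)
  # average contributions agree with the reference implementation
  ref <- vegan::simper(sc$community, g10, permutations = 0)
  refavg <- summary(ref)$A_B[t3$unit, "average"]
  expect_equal(t3$average, unname(refavg), tolerance = 1e-12)

  expect_warning(t0 <- simper(rbind(a = c(1, 1), b = c(1, 1)),
                              c(a = "A", b = "B")), "zero")
  expect_equal(nrow(t0), 0L)
})

test_that("matrix correlation reproduces hand values and the Mantel rho", {
  sc <- simulate_community(n_localities = 8, otu_pool = 10, seed = 44)
  D1 <- dissimilarity(sc$community, "sorensen")
  expect_equal(matrix_correlation(D1, D1, n_perm = 49, seed = 1)$rho, 1)

  # reversed ranks give rho = -1
  D2 <- max(D1) + min(D1[D1 > 0]) - D1
  diag(D2) <- 0
  expect_equal(matrix_correlation(D1, D2, n_perm = 49, seed = 1)$rho, -1)

  # 5x5 hand matrices: rho over the 10 lower-triangle pairs
  A <- matrix(0, 5, 5); A[lower.tri(A)] <- 1:10; A <- A + t(A)
  B <- matrix(0, 5, 5); B[lower.tri(B)] <- c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9)
  B <- B + t(B)
  expect_equal(matrix_correlation(A, B, n_perm = 9, seed = 1)$rho,
               cor(1:10, c(2, 1, 4, 3, 6, 5, 8, 7, 10, 9),
                   method = "spearman"))

  env <- normalize_env(sc$env)
  D3 <- dissimilarity(env, "euclidean")
  mc <- matrix_correlation(D1, D3, n_perm = 999, seed = 5)
  ref <- vegan::mantel(stats::as.dist(D1), stats::as.dist(D3),
                       method = "spearman", permutations = 99)
  expect_equal(mc$rho, unname(ref$statistic))
  expect_true(mc$p > 0 && mc$p <= 1)

  expect_error(matrix_correlation(D1, D1[1:7, 1:7]), "differ|dimensions")
})

test_that("collinearity filtering follows both interpretations", {
  env <- withr::with_seed(9, {
    x <- rnorm(20)
    data.frame(v1 = x, v2 = x + rnorm(20, 0, 0.1), v3 = rnorm(20))
  })
  ne <- normalize_env(env)
  # literal distance rule: z-scored columns are > 0.8 apart unless nearly
  # identical, so it keeps the near-duplicate pair and drops the rest
  lit <- filter_collinear(ne, 0.80, "distance")
  expect_setequal(names(lit), c("v1", "v2"))
  expect_equal(attr(lit, "dropped"), "v3")
  # correlation rule drops only the near-duplicate
  cr <- filter_collinear(ne, 0.80, "correlation")
  expect_setequal(names(cr), c("v1", "v3"))
  expect_equal(attr(cr, "dropped"), "v2")
})

test_that("BVSTEP finds planted drivers and never beats exhaustive search", {
  sc <- simulate_community(n_localities = 30, otu_pool = 18, n_env_vars = 8,
                           driver_vars = 1:2, effect_size = 3,
                           noise_sd = 0.3, seed = 51)
  D <- dissimilarity(sc$community, "sorensen")
  env <- normalize_env(sc$env)
  bv <- bioenv_bvstep(D, env, n_restarts = 25, n_perm = 19, seed = 52)
  expect_true(all(c("env1", "env2") %in% bv$best$vars))
  ex <- bioenv_exhaustive(D, env)
  expect_lte(bv$best$rho, ex$rho + 1e-12)
  expect_true(all(bv$models$frequency <= 1))
  expect_lte(sum(bv$models$frequency), 1 + 1e-12)
  expect_true(bv$p > 0 && bv$p <= 1)

  # one variable constructed as a monotone transform of the biotic gradient:
  # selected alone, search stops by the rho criterion
  D_b <- as.matrix(D)
  grad <- cmdscale(stats::as.dist(D_b), k = 1)[, 1]
  env2 <- normalize_env(data.frame(signal = grad + rnorm(30, 0, 1e-4),
                                   noise1 = rnorm(30), noise2 = rnorm(30),
                                   row.names = rownames(D_b)))
  # biotic matrix exactly the euclidean distance of the signal variable
  D_sig <- dissimilarity(env2["signal"], "euclidean")
  bv2 <- bioenv_bvstep(D_sig, env2, n_restarts = 10, n_perm = 0, seed = 53)
  expect_equal(bv2$best$vars, "signal")
  expect_gte(bv2$best$rho, 0.95)

  # the exhaustive search agrees with the reference implementation
  ref <- vegan::bioenv(stats::as.dist(D), env, index = "euclidean",
                       method = "spearman")
  ref_best <- names(env)[ref$models[[which.max(vapply(ref$models,
                         function(m) m$est, numeric(1)))]]$best]
  expect_setequal(ex$vars, ref_best)

  expect_error(bioenv_bvstep(D, env[, 1, drop = FALSE], seed = 1),
               "fewer than 2")
})
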