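test_that("species tree simulation: shape, determinism, degenerate input", {
  expect_error(simulate_species_tree(2), "at least 3")

  tr3 <- simulate_species_tree(3, seed = 4)
  expect_s3_class(tr3, "phylo")
  expect_equal(length(tr3$tip.label), 3)
  # the unrooted 3-leaf topology is unique: unrooting leaves a single node
  expect_equal(ape::unroot(tr3)$Nnode, 1L)

  a <- simulate_species_tree(10, seed = 1)
  b <- simulate_species_tree(10, seed = 1)
  expect_identical(ape::write.tree(a), ape::write.tree(b))
  expect_true(all(a$edge.length > 0))
  # ultrametric with height equal to tree_height after rescaling
  d <- ape::node.depth.edgelength(a)[seq_len(10)]
  expect_equal(d, rep(1, 10), tolerance = 1e-10)
})

test_that("Yule cherry counts match an independent minimal simulator", {
  set.seed(20)
  n_draws <- 1500
  pkg <- replicate(n_draws, {
    tr <- simulate_species_tree(8, seed = NULL)
    # cherries: internal nodes with two tip children
    tab <- table(tr$edge[tr$edge[, 2] <= 8, 1])
    sum(tab == 2)
  })
  oracle <- replicate(n_draws, yule_cherries(8))
  se <- sqrt(var(pkg) / n_draws + var(oracle) / n_draws)
  expect_lt(abs(mean(pkg) - mean(oracle)), 4 * se)
  # closed-form Yule expectation E[cherries] = n/3
  expect_lt(abs(mean(oracle) - 8 / 3), 4 * sd(oracle) / sqrt(n_draws))
})

test_that("binary character simulation: dimensions, polymorphism, determinism", {
  cfg <- sim_config(n_species = 10,
                    individuals_per_species = c(4, 4, 4, 4, 4, 4, 4, 4, 3, 3),
                    n_loci = 659, n_replicate_samples = 0, seed = 3)
  tr <- simulate_species_tree(10, seed = 3, tree_height = cfg$tree_height)
  truth <- simulate_binary_characters(tr, cfg)
  expect_equal(dim(truth$matrix$calls), c(38L, 659L))
  cs <- colSums(truth$matrix$calls)
  expect_true(all(cs > 0 & cs < 38))

  truth2 <- simulate_binary_characters(tr, cfg)
  expect_identical(truth$matrix$calls, truth2$matrix$calls)
})

test_that("degenerate configurations are rejected", {
  expect_error(sim_config(presence_freq = 1), "strictly in")
  expect_error(sim_config(presence_freq = 0), "strictly in")
  cfg <- sim_config(n_species = 4, n_loci = 20, polymorphism_rate = 0,
                    n_replicate_samples = 0, seed = 1)
  tr <- simulate_species_tree(4, seed = 1)
  tr$edge.length[] <- 0
  expect_error(simulate_binary_characters(tr, cfg), "degenerate")
})

test_that("sister-species discordance matches a single-branch Monte Carlo oracle", {
  ## two sister species at known path length; no within-species flips
  cfg <- sim_config(n_species = 4, individuals_per_species = 1,
                    n_loci = 4000, polymorphism_rate = 0,
                    n_replicate_samples = 0, tree_height = 0.4, seed = 9)
  tr <- simulate_species_tree(4, seed = 9, tree_height = 0.4)
  truth <- simulate_binary_characters(tr, cfg)
  D <- ape::cophenetic.phylo(tr)
  pair <- rownames(D)[order(D[1, ])[1:2]]
  t_path <- D[pair[1], pair[2]]
  obs <- mean(truth$matrix$calls[paste0(pair[1], "_1"), ] !=
                truth$matrix$calls[paste0(pair[2], "_1"), ])

  ## independent oracle: simulate the same 4-tip process locus by locus
  ## with plain transition draws, apply the same polymorphic-only filter
  set.seed(99)
  pi1 <- cfg$presence_freq
  mu <- 1 / (2 * pi1 * (1 - pi1))
  po <- ape::reorder.phylo(tr, "cladewise")
  n_mc <- 40000
  tips <- matrix(NA_integer_, 4, n_mc, dimnames = list(po$tip.label, NULL))
  states <- matrix(NA_integer_, 4 + tr$Nnode, n_mc)
  states[5, ] <- as.integer(runif(n_mc) < pi1)
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; chi <- po$edge[k, 2]
    e <- exp(-mu * po$edge.length[k])
    stay <- ifelse(states[par, ] == 1, pi1 + (1 - pi1) * e,
                   (1 - pi1) + pi1 * e)
    flip <- runif(n_mc) >= stay
    states[chi, ] <- ifelse(flip, 1L - states[par, ], states[par, ])
  }
  tipm <- states[1:4, ]
  rownames(tipm) <- po$tip.label
  poly <- colSums(tipm) > 0 & colSums(tipm) < 4
  exp_disc <- mean(tipm[pair[1], poly] != tipm[pair[2], poly])
  se <- sqrt(exp_disc * (1 - exp_disc) / cfg$n_loci +
               exp_disc * (1 - exp_disc) / sum(poly))
  expect_lt(abs(obs - exp_disc), 4 * se)
  ## unconditional closed form checked against the unconditional oracle
  closed <- 2 * pi1 * (1 - pi1) * (1 - exp(-mu * t_path))
  uncond <- mean(tipm[pair[1], ] != tipm[pair[2], ])
  expect_lt(abs(uncond - closed), 4 * sqrt(closed * (1 - closed) / n_mc))
})

test_that("plant_hybrid builds mosaics and leaves other rows untouched", {
  cfg <- sim_config(n_species = 6, individuals_per_species = 3,
                    n_loci = 1000, n_replicate_samples = 0, seed = 5)
  truth <- simulate_binary_characters(
    simulate_species_tree(6, seed = 5, tree_height = cfg$tree_height), cfg)
  cons <- species_consensus(truth$matrix)

  expect_error(hybrid_spec("sp01", "sp02", "sp02"), "distinct")

  t1 <- plant_hybrid(truth, hybrid_spec("sp03", "sp01", "sp02", 1), seed = 2)
  h_rows <- names(t1$matrix$species)[t1$matrix$species == "sp03"]
  for (r in h_rows)
    expect_identical(unname(t1$matrix$calls[r, ]), unname(cons["sp01", ]))

  t2 <- plant_hybrid(truth, hybrid_spec("sp03", "sp01", "sp02", 0.5),
                     seed = 7)
  frac_a <- mean(t2$hybrid_assignments$sp03$origin == "sp01")
  bounds <- qbinom(c(0.005, 0.995), 1000, 0.5) / 1000
  expect_gt(frac_a, bounds[1])
  expect_lt(frac_a, bounds[2])
  ## non-hybrid rows untouched
  other <- names(truth$matrix$species)[truth$matrix$species != "sp03"]
  expect_identical(t2$matrix$calls[other, ], truth$matrix$calls[other, ])
  expect_length(t2$hybrid_assignments$sp03$origin, 1000)
  ## determinism
  t2b <- plant_hybrid(truth, hybrid_spec("sp03", "sp01", "sp02", 0.5),
                      seed = 7)
  expect_identical(t2$matrix$calls, t2b$matrix$calls)
})

test_that("peak-height synthesis: separability, replicates, dropout oracle", {
  cfg0 <- sim_config(n_species = 4, individuals_per_species = 2, n_loci = 60,
                     noise_sd = 0, dropout_rate = 0,
                     n_replicate_samples = 4, seed = 8)
  truth <- simulate_binary_characters(
    simulate_species_tree(4, seed = 8, tree_height = cfg0$tree_height), cfg0)
  peaks <- synthesize_peak_heights(truth$matrix, cfg0)
  expect_equal(nrow(peaks$replicate_pairs), 4)
  expect_true(all(peaks$bin_sizes >= 50 & peaks$bin_sizes <= 500))
  ## any threshold strictly between baseline and signal recovers the truth
  for (cut in c(100, 275, 450)) {
    calls <- (peaks$heights[rownames(truth$matrix$calls), ] >= cut) * 1L
    expect_equal(unname(calls), unname(truth$matrix$calls))
  }

  ## dropout-driven replicate discordance matches a two-draw simulation
  cfg1 <- sim_config(n_species = 4, individuals_per_species = 2,
                     n_loci = 3000, noise_sd = 1, dropout_rate = 0.03,
                     n_replicate_samples = 8, seed = 13)
  truth1 <- simulate_binary_characters(
    simulate_species_tree(4, seed = 13, tree_height = cfg1$tree_height), cfg1)
  peaks1 <- synthesize_peak_heights(truth1$matrix, cfg1)
  calls1 <- call_phenotypes(peaks1, scoring_thresholds(0, "absolute", 275))
  rep1 <- estimate_mismatch_error_rate(calls1, peaks1$replicate_pairs)
  ## oracle: per locus, two independent renders disagree iff the band is
  ## truly present and exactly one render drops it
  set.seed(77)
  d <- cfg1$dropout_rate
  truth_rows <- truth1$matrix$calls[peaks1$replicate_pairs$sample, ]
  n_mc <- 20
  sims <- replicate(n_mc, {
    d1 <- matrix(runif(length(truth_rows)) < d, nrow(truth_rows))
    d2 <- matrix(runif(length(truth_rows)) < d, nrow(truth_rows))
    mean(colMeans((truth_rows == 1) & (d1 != d2)))
  })
  expect_lt(abs(rep1$overall_error - mean(sims)),
            4 * sd(sims) + 4 * sd(sims) / sqrt(n_mc) + 0.002)
})

test_that("band-presence frequency tracks the configured target", {
  cfg <- sim_config(n_species = 8, individuals_per_species = 4,
                    n_loci = 5000, n_replicate_samples = 0,
                    tree_height = 0.5, seed = 21)
  truth <- simulate_binary_characters(
    simulate_species_tree(8, seed = 21, tree_height = 0.5), cfg)
  ## conditioning on polymorphic loci shifts the frequency slightly upward;
  ## the tolerance reflects that documented bias
  expect_lt(abs(mean(truth$matrix$calls) - cfg$presence_freq), 0.06)
})
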