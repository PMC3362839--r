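rtree_bl <- function(n, lo = 0.01, hi = 2) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), lo, hi)
  tr
}

test_that("state frequency estimation and model validation", {
  m <- matrix(c(1L, 0L, 1L, 0L), 2, 2,
              dimnames = list(c("a", "b"), c("L1", "L2")))
  expect_equal(estimate_state_frequencies(m)$pi1, 0.5)

  ## frequencies in the ratio 2.44 : 1.00 give pi1 = 1/3.44
  m2 <- matrix(0L, 100, 86, dimnames = list(sprintf("s%03d", 1:100),
                                            sprintf("L%02d", 1:86)))
  m2[seq_len(2500)] <- 1L   # 2500 of 8600 entries = 1.00/3.44 of the total
  expect_equal(estimate_state_frequencies(m2)$pi1, 2500 / 8600)
  expect_equal(1.00 / 3.44, 0.2907, tolerance = 1e-4)

  set.seed(2)
  m3 <- matrix(rbinom(400, 1, 0.3), 20, 20,
               dimnames = list(paste0("s", 1:20), paste0("L", 1:20)))
  expect_equal(estimate_state_frequencies(m3)$pi1, sum(m3) / 400)

  expect_error(estimate_state_frequencies(m3 * 0L), "degenerate")
  expect_error(binary_model(0), "strictly")
  expect_error(binary_model(1), "strictly")
})

test_that("two-leaf limits: zero-length and independence", {
  tr <- ape::read.tree(text = "(a:0,b:0);")
  mod <- binary_model(0.3)
  ## t -> 0: identical patterns get their stationary frequency,
  ## discordant patterns probability 0
  expect_equal(exp(site_log_likelihood(tr, mod, c(a = 1, b = 1))), 0.3)
  expect_equal(exp(site_log_likelihood(tr, mod, c(a = 0, b = 0))), 0.7)
  expect_equal(exp(site_log_likelihood(tr, mod, c(a = 1, b = 0))), 0)

  ## t -> infinity: independence, product of stationary frequencies
  trL <- ape::read.tree(text = "(a:500,b:500);")
  expect_equal(exp(site_log_likelihood(trL, mod, c(a = 1, b = 0))),
               0.3 * 0.7, tolerance = 1e-10)
  expect_equal(exp(site_log_likelihood(trL, mod, c(a = 1, b = 1))),
               0.09, tolerance = 1e-10)
})

test_that("pruning equals exhaustive enumeration on random instances", {
  set.seed(17)
  for (i in 1:40) {
    n <- sample(4:6, 1)
    tr <- rtree_bl(n)
    pi1 <- runif(1, 0.1, 0.9)
    mod <- binary_model(pi1)
    pat <- setNames(sample(0:1, n, replace = TRUE), tr$tip.label)
    expect_equal(site_log_likelihood(tr, mod, pat),
                 brute_site_loglik(tr, pi1, pat), tolerance = 1e-12)
  }
})

test_that("pattern probabilities normalise, conditioned and not", {
  set.seed(23)
  tr <- rtree_bl(4)
  mod <- binary_model(0.29)
  pats <- as.matrix(expand.grid(rep(list(0:1), 4)))
  colnames(pats) <- tr$tip.label
  ll <- apply(pats, 1, function(p) site_log_likelihood(tr, mod, p))
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)

  ## under noabsencesites the non-all-zero patterns renormalise to 1
  modc <- binary_model(0.29, "noabsencesites")
  nz <- rowSums(pats) > 0
  m <- t(pats[nz, ])
  rownames(m) <- tr$tip.label
  colnames(m) <- sprintf("L%02d", seq_len(ncol(m)))
  sl <- matrix_log_likelihood(tr, modc, m)
  expect_equal(sum(exp(sl$per_locus_loglik)), 1, tolerance = 1e-10)

  ## toggling conditioning shifts the total by n_loci * log(1 - L0)
  sl0 <- matrix_log_likelihood(tr, mod, m)
  L0 <- exp(site_log_likelihood(tr, mod,
                                setNames(rep(0, 4), tr$tip.label)))
  expect_equal(sl$total_loglik,
               sl0$total_loglik - ncol(m) * log1p(-L0), tolerance = 1e-8)
})

test_that("likelihood is invariant under re-rooting (pulley principle)", {
  set.seed(31)
  tr <- rtree_bl(6)
  mod <- binary_model(0.4)
  pat <- setNames(sample(0:1, 6, replace = TRUE), tr$tip.label)
  l0 <- site_log_likelihood(tr, mod, pat)
  for (og in c(2, 5)) {
    tr2 <- ape::root(ape::unroot(tr), og, resolve.root = TRUE)
    expect_equal(site_log_likelihood(tr2, mod, pat), l0, tolerance = 1e-10)
  }
})

test_that("input validation: pattern mismatch and branch lengths", {
  tr <- rtree_bl(4)
  mod <- binary_model(0.3)
  expect_error(site_log_likelihood(tr, mod, c(a = 1)), "must equal")
  expect_error(site_log_likelihood(tr, mod,
                                   setNames(c(1, 0, 1, 0), paste0("x", 1:4))),
               "tip labels")
  trn <- tr; trn$edge.length[1] <- -0.1
  expect_error(site_log_likelihood(trn, mod,
                                   setNames(c(1, 0, 1, 0), tr$tip.label)),
               ">= 0")
})

test_that("branch-length optimization: oracle and invariances", {
  set.seed(41)
  ## one-branch two-leaf problem vs a dense grid
  m <- matrix(rbinom(2 * 400, 1, 0.5), 2, 400,
              dimnames = list(c("a", "b"), sprintf("L%03d", 1:400)))
  m[2, 1:250] <- m[1, 1:250]  # correlated -> finite optimum
  tr <- ape::read.tree(text = "(a:0.1,b:0.1);")
  mod <- binary_model(0.45)
  fit <- optimize_branch_lengths(tr, mod, m)
  t_hat <- sum(fit$tree$edge.length)
  grid <- seq(0.001, 3, length.out = 3000)
  gl <- vapply(grid, function(t) {
    tg <- tr; tg$edge.length <- c(t / 2, t / 2)
    matrix_log_likelihood(tg, mod, m)$total_loglik
  }, numeric(1))
  expect_lt(abs(t_hat - grid[which.max(gl)]), 0.01)
  expect_gte(fit$loglik$total_loglik, max(gl) - 1e-6)

  ## duplicating every column doubles the log-likelihood, same lengths
  m2 <- cbind(m, m)
  colnames(m2) <- sprintf("L%03d", 1:800)
  fit2 <- optimize_branch_lengths(tr, mod, m2)
  expect_equal(sum(fit2$tree$edge.length), t_hat, tolerance = 1e-4)
  expect_equal(fit2$loglik$total_loglik, 2 * fit$loglik$total_loglik,
               tolerance = 1e-4)
})

test_that("branch-length recovery improves with more loci", {
  ## data from the unconditioned process with all-absent loci removed --
  ## exactly the ascertainment the noabsencesites correction models
  tr <- simulate_species_tree(4, seed = 7, tree_height = 0.5)
  pi1 <- 0.29
  mod <- binary_model(pi1, "noabsencesites")
  sim_fit_err <- function(n_loci, seed) {
    set.seed(seed)
    m <- sim_tips_raw(tr, pi1, n_loci)
    m <- m[, colSums(m) > 0, drop = FALSE]
    fit <- optimize_branch_lengths(tr, mod, m)
    ## compare total tree lengths (robust to clamping at tiny branches)
    abs(sum(fit$tree$edge.length) - sum(tr$edge.length)) /
      sum(tr$edge.length)
  }
  e_small <- median(sapply(1:3, sim_fit_err, n_loci = 500))
  e_large <- median(sapply(4:6, sim_fit_err, n_loci = 5000))
  expect_lt(e_large, e_small + 0.02)
  expect_lt(e_large, 0.15)
})
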