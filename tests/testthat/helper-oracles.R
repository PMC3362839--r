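## Independent oracles used across the suite. These deliberately avoid the
## package's own code paths: enumeration instead of pruning, double loops
## instead of vectorised algebra, a second minimal Yule implementation.

## Exhaustive-enumeration log-likelihood of a 0/1 pattern under the
## reversible two-state chain: sum over all internal-node state assignments.
brute_site_loglik <- function(tr, pi1, pattern) {
  mu <- 1 / (2 * pi1 * (1 - pi1))
  nt <- length(tr$tip.label)
  nn <- nt + tr$Nnode
  pi <- c(1 - pi1, pi1)
  P <- function(i, j, t) {
    e <- exp(-mu * t)
    if (i == j) pi[j + 1] + (1 - pi[j + 1]) * e else pi[j + 1] * (1 - e)
  }
  ints <- (nt + 1):nn
  tot <- 0
  for (m in 0:(2^length(ints) - 1)) {
    st <- integer(nn)
    st[seq_len(nt)] <- pattern[tr$tip.label]
    st[ints] <- as.integer(intToBits(m))[seq_along(ints)]
    pr <- pi[st[nt + 1] + 1]
    for (k in seq_len(nrow(tr$edge)))
      pr <- pr * P(st[tr$edge[k, 1]], st[tr$edge[k, 2]], tr$edge.length[k])
    tot <- tot + pr
  }
  log(tot)
}

## Random tree with known positive branch lengths plus its exact additive
## (path-length) distance matrix, labels sorted.
rand_additive <- function(n, min_len = 0.05, max_len = 1) {
  tr <- ape::rtree(n)
  tr$edge.length <- runif(nrow(tr$edge), min_len, max_len)
  D <- ape::cophenetic.phylo(tr)
  ord <- sort(rownames(D))
  list(tree = tr, D = D[ord, ord])
}

## Minimal independent Yule topology simulator (labelled-history process):
## start with 2 lineages, repeatedly split a uniformly chosen one. Returns
## the number of cherries.
yule_cherries <- function(n) {
  n_internal <- 1L
  pending <- c(1L, 1L)             # parent internal node of each open lineage
  while (length(pending) < n) {
    i <- sample.int(length(pending), 1L)
    n_internal <- n_internal + 1L
    pending[i] <- n_internal
    pending <- c(pending, n_internal)
  }
  ## pending lineages are the tips; a cherry = internal node with 2 tips
  sum(tabulate(pending, nbins = n_internal) == 2L)
}

## Unconditioned two-state tip simulation (no polymorphic-only filter),
## independent of the package's generator internals.
sim_tips_raw <- function(tr, pi1, L) {
  mu <- 1 / (2 * pi1 * (1 - pi1))
  po <- ape::reorder.phylo(tr, "cladewise")
  nt <- length(po$tip.label)
  states <- matrix(NA_integer_, nt + po$Nnode, L)
  states[nt + 1L, ] <- as.integer(runif(L) < pi1)
  for (k in seq_len(nrow(po$edge))) {
    par <- po$edge[k, 1]; chi <- po$edge[k, 2]
    e <- exp(-mu * po$edge.length[k])
    stay <- ifelse(states[par, ] == 1, pi1 + (1 - pi1) * e,
                   (1 - pi1) + pi1 * e)
    flip <- runif(L) >= stay
    states[chi, ] <- ifelse(flip, 1L - states[par, ], states[par, ])
  }
  out <- states[seq_len(nt), , drop = FALSE]
  dimnames(out) <- list(po$tip.label, sprintf("L%05d", seq_len(L)))
  out
}

## Small noisy peak table with known truth for scoring tests.
toy_peaks <- function(seed = 1, n_samples = 8, n_loci = 40, noise_sd = 25,
                      dropout = 0.05, n_rep = 3) {
  cfg <- sim_config(n_species = 4, individuals_per_species = n_samples / 4,
                    n_loci = n_loci, n_replicate_samples = n_rep,
                    noise_sd = noise_sd, dropout_rate = dropout, seed = seed)
  simulate_aflp_dataset(cfg)
}

## Count distinct polymorphic columns with a hash-set, independently of
## filter_unique_loci's internals.
count_unique_loci <- function(m) {
  keep <- colSums(m) > 0 & colSums(m) < nrow(m)
  length(unique(apply(m[, keep, drop = FALSE], 2, paste, collapse = ",")))
}
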