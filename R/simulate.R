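## Synthetic AFLP world: Yule species trees, two-state characters evolving
## along them, within-species flips, planted mosaic hybrids, and noisy
## peak-height renderings with replicate profiles.

#' Simulation configuration
#'
#' Defaults emulate the scale of a typical deepwater-cichlid AFLP study:
#' ten species, ~40 individuals, 659 polymorphic dominant loci in the
#' 50-500 bp range, 20 replicate profiles, a band-presence frequency near
#' 0.29 (the value implied by 0/1 state frequencies in the ratio 2.44:1.00),
#' and a dropout rate chosen so that the replicate mismatch error rate lands
#' near 3%.
#'
#' @param n_species number of species (>= 3)
#' @param individuals_per_species scalar or length-`n_species` vector of
#'   individuals sampled per species
#' @param n_loci number of polymorphic loci to emit (exact; monomorphic draws
#'   are replaced)
#' @param birth_rate Yule speciation rate per lineage per unit time
#' @param tree_height root-to-tip height of the species tree in expected
#'   substitutions per locus
#' @param min_internal_frac backbone floor passed to
#'   [simulate_species_tree()] (0 = pure Yule)
#' @param presence_freq target stationary band-presence frequency in (0, 1)
#' @param gain_loss_ratio optional alternative parameterisation: ratio of
#'   gain to loss rates; if given, overrides `presence_freq` via
#'   `presence_freq = r / (1 + r)`
#' @param polymorphism_rate per-individual, per-locus probability of
#'   flipping away from the species state (within-species polymorphism)
#' @param hybrid_specs list of [hybrid_spec()] entries to plant
#' @param n_replicate_samples number of replicate profiles rendered when
#'   synthesising peak heights
#' @param noise_sd Gaussian fluorescence noise s.d. (peak-height units)
#' @param dropout_rate probability that a truly present band yields only
#'   baseline signal (the main driver of replicate mismatch error)
#' @param signal_mean mean fluorescence of a present band
#' @param baseline_mean mean fluorescence of an absent band
#' @param seed integer seed; every generator call derived from this config is
#'   deterministic given the seed
#' @return a list of class `sim_config`
#' @export
sim_config <- function(n_species = 10L,
                       individuals_per_species = 4L,
                       n_loci = 659L,
                       birth_rate = 1,
                       tree_height = 0.15,
                       min_internal_frac = 0,
                       presence_freq = 1.00 / 3.44,
                       gain_loss_ratio = NULL,
                       polymorphism_rate = 0.02,
                       hybrid_specs = list(),
                       n_replicate_samples = 20L,
                       noise_sd = 30,
                       dropout_rate = 0.05,
                       signal_mean = 500,
                       baseline_mean = 50,
                       seed = 1L) {
  if (!is.null(gain_loss_ratio)) {
    stopifnot(gain_loss_ratio > 0)
    presence_freq <- gain_loss_ratio / (1 + gain_loss_ratio)
  }
  cfg <- list(n_species = as.integer(n_species),
              individuals_per_species = as.integer(individuals_per_species),
              n_loci = as.integer(n_loci),
              birth_rate = birth_rate, tree_height = tree_height,
              min_internal_frac = min_internal_frac,
              presence_freq = presence_freq,
              polymorphism_rate = polymorphism_rate,
              hybrid_specs = hybrid_specs,
              n_replicate_samples = as.integer(n_replicate_samples),
              noise_sd = noise_sd, dropout_rate = dropout_rate,
              signal_mean = signal_mean, baseline_mean = baseline_mean,
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(n_species >= 1, all(individuals_per_species >= 1), n_loci >= 1,
              birth_rate > 0, tree_height > 0,
              polymorphism_rate >= 0, polymorphism_rate <= 1,
              dropout_rate >= 0, dropout_rate < 1, noise_sd >= 0,
              n_replicate_samples >= 0, signal_mean > baseline_mean)
  })
  if (cfg$presence_freq <= 0 || cfg$presence_freq >= 1)
    stop("`presence_freq` must lie strictly in (0, 1): ",
         "a fixed-state process yields no polymorphic loci")
  for (h in cfg$hybrid_specs) validate_hybrid_spec(h)
  class(cfg) <- "sim_config"
  cfg
}

#' Specification of a planted hybrid taxon
#'
#' @param hybrid species label of the hybrid (may replace an existing species
#'   or add a new one)
#' @param parent_a,parent_b distinct labels of the two parental species
#' @param proportion probability that a locus is inherited from `parent_a`
#' @export
hybrid_spec <- function(hybrid, parent_a, parent_b, proportion = 0.5) {
  out <- list(hybrid = hybrid, parent_a = parent_a, parent_b = parent_b,
              proportion = proportion)
  validate_hybrid_spec(out)
  out
}

validate_hybrid_spec <- function(h) {
  stopifnot(is.character(h$hybrid), is.character(h$parent_a),
            is.character(h$parent_b),
            h$proportion >= 0, h$proportion <= 1)
  if (identical(h$parent_a, h$parent_b))
    stop("hybrid parents must be two distinct species")
  invisible(h)
}

#' Simulate a pure-birth (Yule) species tree
#'
#' Lineages split at rate `birth_rate`; with k extant lineages the waiting
#' time to the next split is exponential with rate `k * birth_rate` and the
#' splitting lineage is chosen uniformly. The tree is cut one exponential
#' waiting time after the n-th lineage is born and rescaled so the
#' (ultrametric) root-to-tip height equals `tree_height`.
#'
#' With `min_internal_frac > 0`, trees are rejection-sampled until every
#' internal edge is at least that fraction of the tree height. Raw Yule
#' trees routinely contain near-zero internal edges (rapid radiations);
#' datasets emulating a study system with a well-supported backbone should
#' set a floor so that every internode is resolvable at the simulated
#' locus count.
#'
#' @param n_species number of tips, >= 3
#' @param birth_rate speciation rate (only sets the pre-rescaling time scale)
#' @param tree_height final root-to-tip height in expected substitutions
#' @param seed integer seed, or NULL to use the current RNG state
#' @param min_internal_frac minimum internal edge length as a fraction of
#'   `tree_height` (0 = pure Yule, no rejection)
#' @return a rooted binary ultrametric [ape::phylo] with tips
#'   `sp01, sp02, ...`
#' @export
simulate_species_tree <- function(n_species, birth_rate = 1, tree_height = 1,
                                  seed = NULL, min_internal_frac = 0) {
  if (n_species < 3) stop("`n_species` must be at least 3")
  if (!is.null(seed)) set.seed(seed)
  if (min_internal_frac > 0) {
    for (i in seq_len(500L)) {
      phy <- simulate_species_tree(n_species, birth_rate, tree_height,
                                   seed = NULL)
      internal <- phy$edge[, 2] > n_species
      if (min(phy$edge.length[internal]) >=
            min_internal_frac * tree_height)
        return(phy)
    }
    stop("could not sample a tree meeting `min_internal_frac` within ",
         "500 attempts; lower the floor")
  }
  n <- as.integer(n_species)
  ## split times: t[1] = 0 is the root split, then Exp(k * rate) waits
  waits <- rexp(n - 1, rate = birth_rate * (2:n))
  t_split <- cumsum(c(0, waits[seq_len(n - 2)]))
  t_tip <- t_split[n - 1] + waits[n - 1]

  root <- n + 1L
  edge <- matrix(0L, 2L * n - 2L, 2L)
  elen <- numeric(2L * n - 2L)
  parent <- c(root, root)       # active lineages: parent node and birth time
  btime <- c(0, 0)
  next_internal <- n + 2L
  ei <- 0L
  for (j in seq_len(n - 2L)) {
    i <- sample.int(length(parent), 1L)
    ei <- ei + 1L
    edge[ei, ] <- c(parent[i], next_internal)
    elen[ei] <- t_split[j + 1L] - btime[i]
    parent[i] <- next_internal
    btime[i] <- t_split[j + 1L]
    parent <- c(parent, next_internal)
    btime <- c(btime, t_split[j + 1L])
    next_internal <- next_internal + 1L
  }
  for (i in seq_along(parent)) {
    ei <- ei + 1L
    edge[ei, ] <- c(parent[i], i)
    elen[ei] <- t_tip - btime[i]
  }
  phy <- structure(
    list(edge = edge,
         edge.length = elen * (tree_height / t_tip),
         tip.label = sprintf("sp%02d", seq_len(n)),
         Nnode = n - 1L),
    class = "phylo", order = "cladewise")
  ape::reorder.phylo(phy, "cladewise")
}

## Two-state CFN-style rate normalisation: branch lengths are expected
## substitutions per locus at stationarity, so the overall rate
## 2*pi0*pi1*mu = 1.
rate_mu <- function(pi1) 1 / (2 * pi1 * (1 - pi1))

#' Simulate binary dominant-marker characters on a species tree
#'
#' Each locus evolves as a reversible two-state (absence/presence) Markov
#' process with stationary frequencies `(1 - presence_freq, presence_freq)`
#' down the tree; each individual then copies its species' tip state and
#' flips it with probability `polymorphism_rate`. Loci monomorphic across
#' all individuals are discarded and re-drawn until exactly `n_loci`
#' polymorphic loci exist (mirroring the fact that only polymorphic bins are
#' scored in real AFLP data).
#'
#' @param tree species tree ([ape::phylo]) whose tips match
#'   `config$n_species`
#' @param config a [sim_config()]
#' @return a list of class `aflp_truth` with elements `matrix` (the
#'   individual-level [aflp_binary]), `species_tree`, `species_states`
#'   (species x loci tip states before individual flips), and
#'   `hybrid_assignments` (filled by [plant_hybrid()])
#' @export
simulate_binary_characters <- function(tree, config) {
  stopifnot(inherits(tree, "phylo"))
  if (length(tree$tip.label) != config$n_species)
    stop("tree has ", length(tree$tip.label), " tips but config expects ",
         config$n_species, " species")
  set.seed(config$seed + 1L)
  pi1 <- config$presence_freq
  if (sum(tree$edge.length) == 0 && config$polymorphism_rate == 0)
    stop("degenerate configuration: zero-length tree with no ",
         "within-species polymorphism cannot produce polymorphic loci")

  n_ind <- rep_len(config$individuals_per_species, config$n_species)
  sample_ids <- unlist(lapply(seq_len(config$n_species), function(i)
    sprintf("%s_%d", tree$tip.label[i], seq_len(n_ind[i]))))
  species <- setNames(rep(tree$tip.label, n_ind), sample_ids)

  species_states <- NULL
  calls <- NULL
  batch <- config$n_loci
  tries <- 0L
  while (is.null(calls) || ncol(calls) < config$n_loci) {
    tries <- tries + 1L
    if (tries > 200L)
      stop("could not generate ", config$n_loci, " polymorphic loci; ",
           "configuration appears degenerate")
    tips <- sim_markov_tips(tree, pi1, batch)
    ind <- tips[species, , drop = FALSE]
    if (config$polymorphism_rate > 0) {
      flip <- matrix(runif(length(ind)) < config$polymorphism_rate,
                     nrow(ind), ncol(ind))
      ind <- abs(ind - flip * 1L)
    }
    cs <- colSums(ind)
    poly <- cs > 0 & cs < nrow(ind)
    species_states <- cbind(species_states, tips[, poly, drop = FALSE])
    calls <- cbind(calls, ind[, poly, drop = FALSE])
  }
  keep <- seq_len(config$n_loci)
  calls <- calls[, keep, drop = FALSE]
  species_states <- species_states[, keep, drop = FALSE]
  locus_ids <- sprintf("L%04d", keep)
  colnames(calls) <- colnames(species_states) <- locus_ids
  rownames(calls) <- sample_ids
  storage.mode(calls) <- "integer"
  storage.mode(species_states) <- "integer"

  truth <- structure(
    list(matrix = aflp_binary(calls, species),
         species_tree = tree,
         species_states = species_states,
         hybrid_assignments = list()),
    class = "aflp_truth")
  for (h in config$hybrid_specs)
    truth <- plant_hybrid(truth, h, seed = config$seed + 2L)
  truth
}

## Simulate two-state tip states for `L` loci down `tree`; returns a
## species x loci 0/1 matrix. Transition probabilities follow the
## reversible binary chain: P(stay) = pi_state + (1 - pi_state) * exp(-mu t).
sim_markov_tips <- function(tree, pi1, L) {
  mu <- rate_mu(pi1)
  phy <- ape::reorder.phylo(tree, "cladewise")
  nt <- length(phy$tip.label)
  nn <- nt + phy$Nnode
  states <- matrix(NA_integer_, nn, L)
  root <- nt + 1L
  states[root, ] <- as.integer(runif(L) < pi1)
  e <- exp(-mu * phy$edge.length)
  for (k in seq_len(nrow(phy$edge))) {
    par <- phy$edge[k, 1L]; chi <- phy$edge[k, 2L]
    s <- states[par, ]
    ## stay probability given current state
    p_stay <- ifelse(s == 1L, pi1 + (1 - pi1) * e[k], (1 - pi1) + pi1 * e[k])
    change <- runif(L) >= p_stay
    states[chi, ] <- ifelse(change, 1L - s, s)
  }
  out <- states[seq_len(nt), , drop = FALSE]
  rownames(out) <- phy$tip.label
  out
}

#' Plant a hybrid taxon as a per-locus mosaic of two parents
#'
#' The hybrid's individuals receive, at each locus, the consensus state of
#' `parent_a` with probability `proportion` and of `parent_b` otherwise
#' (a first-generation mosaic, the mechanism the homoplasy excess test
#' assumes). All hybrid individuals share the same mosaic; the per-locus
#' parent-of-origin vector is recorded in the ground truth. Non-hybrid rows
#' are left untouched.
#'
#' @param truth an `aflp_truth` object from [simulate_binary_characters()]
#' @param spec a [hybrid_spec()]
#' @param seed integer seed
#' @return the updated `aflp_truth`
#' @export
plant_hybrid <- function(truth, spec, seed = NULL) {
  validate_hybrid_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  x <- truth$matrix
  sp_all <- unique(x$species)
  for (p in c(spec$parent_a, spec$parent_b)) {
    if (!(p %in% sp_all)) stop("parent species not in matrix: ", p)
    if (p %in% names(truth$hybrid_assignments))
      stop("parent species is itself a planted hybrid: ", p)
  }
  cons <- species_consensus(x)
  L <- ncol(x$calls)
  from_a <- runif(L) < spec$proportion
  mosaic <- ifelse(from_a, cons[spec$parent_a, ], cons[spec$parent_b, ])

  calls <- x$calls
  species <- x$species
  if (spec$hybrid %in% sp_all) {
    rows <- names(species)[species == spec$hybrid]
  } else {
    n_new <- max(table(species))
    rows <- sprintf("%s_%d", spec$hybrid, seq_len(n_new))
    add <- matrix(0L, n_new, L, dimnames = list(rows, colnames(calls)))
    calls <- rbind(calls, add)
    species <- c(species, setNames(rep(spec$hybrid, n_new), rows))
  }
  calls[rows, ] <- matrix(rep(as.integer(mosaic), each = length(rows)),
                          nrow = length(rows))
  truth$matrix <- aflp_binary(calls, species, x$replicates)
  truth$hybrid_assignments[[spec$hybrid]] <-
    list(parent_a = spec$parent_a, parent_b = spec$parent_b,
         proportion = spec$proportion,
         origin = ifelse(from_a, spec$parent_a, spec$parent_b))
  truth
}

#' Render a binary matrix as noisy binned peak heights with replicates
#'
#' Present bands emit fluorescence around `signal_mean`, absent bands around
#' `baseline_mean`, both with Gaussian noise truncated at zero; truly present
#' peaks drop to baseline with probability `dropout_rate` (amplification
#' failure, the driver of replicate mismatch). The first
#' `n_replicate_samples` samples are re-rendered with fresh noise and dropout
#' as replicate profiles named `<sample>_rep`. Bin labels are fragment sizes
#' evenly spaced in 50-500 bp.
#'
#' @param x an [aflp_binary] matrix (the truth to render)
#' @param config a [sim_config()]
#' @return an [aflp_peaks] table
#' @export
synthesize_peak_heights <- function(x, config) {
  set.seed(config$seed + 3L)
  n <- nrow(x$calls); L <- ncol(x$calls)
  if (config$n_replicate_samples > n)
    stop("more replicate samples requested than samples available")
  rep_of <- rownames(x$calls)[seq_len(config$n_replicate_samples)]
  rep_ids <- if (length(rep_of)) paste0(rep_of, "_rep") else character()

  render <- function(truth_rows) {
    m <- x$calls[truth_rows, , drop = FALSE]
    present <- m == 1L
    if (config$dropout_rate > 0)
      present <- present & (matrix(runif(length(m)), nrow(m)) >=
                              config$dropout_rate)
    mu <- ifelse(present, config$signal_mean, config$baseline_mean)
    h <- mu + matrix(rnorm(length(m), sd = config$noise_sd), nrow(m))
    pmax(h, 0)
  }
  heights <- rbind(render(rownames(x$calls)), render(rep_of))
  rownames(heights) <- c(rownames(x$calls), rep_ids)
  bins <- round(seq(50, 500, length.out = L), 3)
  colnames(heights) <- sprintf("bin%g", bins)
  aflp_peaks(heights, bins,
             data.frame(sample = rep_of, replicate = rep_ids,
                        stringsAsFactors = FALSE),
             species = x$species)
}

#' Suggest a plantable hybrid for a species tree
#'
#' Picks the pair of species whose patristic distance is closest to the
#' given quantile of all pairwise distances as parents, and labels the
#' hybrid as a new taxon. Moderately separated parents give the hybrid a
#' genuinely ambiguous attachment point; parents that are maximally distant
#' produce a mosaic that attaches stably midway and is largely invisible to
#' support-based detection.
#'
#' @param tree species tree ([ape::phylo])
#' @param separation_quantile target quantile of pairwise distances
#' @param proportion mixing proportion of the first parent
#' @param hybrid_label species label for the hybrid taxon
#' @return a [hybrid_spec()]
#' @export
suggest_hybrid_plant <- function(tree, separation_quantile = 0.6,
                                 proportion = 0.5, hybrid_label = "hyb") {
  D <- ape::cophenetic.phylo(tree)
  cand <- which(upper.tri(D), arr.ind = TRUE)
  tgt <- quantile(D[upper.tri(D)], separation_quantile)
  pair <- cand[which.min(abs(D[cand] - tgt)), ]
  hybrid_spec(hybrid_label, rownames(D)[pair[1]], rownames(D)[pair[2]],
              proportion)
}

#' One-call synthetic dataset generator
#'
#' Convenience wrapper: species tree, binary characters, optional hybrids,
#' and a peak-height rendering, all from one config and one seed.
#'
#' @param config a [sim_config()]
#' @return `aflp_truth` with an extra `peaks` element
#' @export
simulate_aflp_dataset <- function(config = sim_config()) {
  tree <- simulate_species_tree(config$n_species, config$birth_rate,
                                config$tree_height, seed = config$seed,
                                min_internal_frac =
                                  config$min_internal_frac)
  truth <- simulate_binary_characters(tree, config)
  truth$peaks <- synthesize_peak_heights(truth$matrix, config)
  truth
}
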