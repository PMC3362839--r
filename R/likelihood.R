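## Two-state (restriction-site style) likelihood engine for dominant
## presence/absence characters: Felsenstein pruning on the reversible binary
## chain, with optional "no absence sites" ascertainment-bias conditioning
## (all-absent loci can never be observed in AFLP data, so each site's
## likelihood is renormalised by 1 - P(all-absent)).

#' Reversible two-state substitution model
#'
#' Stationary frequencies `(pi0, pi1)` for absence/presence; branch lengths
#' are measured in expected substitutions per locus at stationarity
#' (rate normalised so that `2 * pi0 * pi1 * mu = 1`).
#'
#' @param pi1 stationary band-presence frequency, strictly in (0, 1)
#' @param conditioning `"none"` or `"noabsencesites"` (exclude the
#'   all-absent pattern, the standard AFLP ascertainment correction)
#' @return a list of class `binary_model`
#' @export
binary_model <- function(pi1, conditioning = c("none", "noabsencesites")) {
  conditioning <- match.arg(conditioning)
  if (!(pi1 > 0 && pi1 < 1)) stop("pi1 must lie strictly in (0, 1)")
  structure(list(pi0 = 1 - pi1, pi1 = pi1, mu = rate_mu(pi1),
                 conditioning = conditioning),
            class = "binary_model")
}

#' Empirical state frequencies from a matrix
#'
#' `pi1` is the global fraction of 1-entries; degenerate all-zero or all-one
#' matrices are rejected.
#'
#' @param x an [aflp_binary] or 0/1 matrix
#' @param conditioning passed to [binary_model()]
#' @return a [binary_model()]
#' @export
estimate_state_frequencies <- function(x,
                                       conditioning = c("none",
                                                        "noabsencesites")) {
  m <- if (inherits(x, "aflp_binary")) x$calls else x
  if (length(m) == 0) stop("empty matrix")
  p1 <- mean(m)
  if (p1 <= 0 || p1 >= 1)
    stop("degenerate state frequencies: matrix is all-", round(p1),
         "; a two-state model cannot be fit")
  binary_model(p1, match.arg(conditioning))
}

## Build a pruning closure for a fixed (topology, pattern set): postorder
## traversal and tip partials are computed once, so repeated likelihood
## evaluations during optimization or MCMC only pay for the per-edge
## algebra. An extra all-absent pattern is appended when `with_zero` so the
## ascertainment term comes out of the same pass.
build_pruner <- function(phy, patterns, with_zero = FALSE) {
  nt <- length(phy$tip.label)
  if (nrow(patterns) != nt || !all(phy$tip.label %in% rownames(patterns)))
    stop("pattern rows must match the tree's tip labels")
  patterns <- patterns[phy$tip.label, , drop = FALSE]
  if (with_zero) patterns <- cbind(patterns, 0L)
  po <- ape::reorder.phylo(phy, "postorder")
  ord <- match(paste(po$edge[, 1], po$edge[, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
  pedge <- po$edge
  np <- ncol(patterns)
  nn <- nt + phy$Nnode
  tip0 <- (patterns == 0) * 1
  tip1 <- (patterns == 1) * 1
  first_seen <- !duplicated(pedge[, 1])
  function(model, elen) {
    if (any(elen < 0)) stop("branch lengths must be >= 0")
    el <- elen[ord]
    F0 <- matrix(NA_real_, nn, np)
    F1 <- matrix(NA_real_, nn, np)
    F0[seq_len(nt), ] <- tip0
    F1[seq_len(nt), ] <- tip1
    e <- exp(-model$mu * el)
    pi0 <- model$pi0; pi1 <- model$pi1
    for (k in seq_len(nrow(pedge))) {
      par <- pedge[k, 1]; chi <- pedge[k, 2]
      c0 <- (pi0 + pi1 * e[k]) * F0[chi, ] + pi1 * (1 - e[k]) * F1[chi, ]
      c1 <- pi0 * (1 - e[k]) * F0[chi, ] + (pi1 + pi0 * e[k]) * F1[chi, ]
      if (first_seen[k]) {
        F0[par, ] <- c0; F1[par, ] <- c1
      } else {
        F0[par, ] <- F0[par, ] * c0; F1[par, ] <- F1[par, ] * c1
      }
    }
    root <- nt + 1L
    log(pi0 * F0[root, ] + pi1 * F1[root, ])
  }
}

## One-shot pattern log-likelihoods (tips x npat 0/1 matrix with rownames =
## tip labels), optionally overriding the tree's branch lengths.
prune_loglik <- function(phy, model, patterns, elen = phy$edge.length) {
  build_pruner(phy, patterns)(model, elen)
}

#' Log-likelihood of a single site pattern
#'
#' Probability of one presence/absence pattern under the reversible
#' two-state process on a tree, computed by Felsenstein pruning. The model
#' is reversible, so the value does not depend on the root placement.
#'
#' @param tree an [ape::phylo] with branch lengths
#' @param model a [binary_model()] (its `conditioning` is ignored here;
#'   conditioning is applied at the matrix level)
#' @param pattern 0/1 vector named by tip label (or in `tree$tip.label`
#'   order)
#' @return log-probability (nats)
#' @export
site_log_likelihood <- function(tree, model, pattern) {
  if (length(pattern) != length(tree$tip.label))
    stop("pattern length (", length(pattern), ") must equal the number of ",
         "leaves (", length(tree$tip.label), ")")
  if (is.null(names(pattern))) names(pattern) <- tree$tip.label
  if (!all(tree$tip.label %in% names(pattern)))
    stop("pattern names do not match the tree's tip labels")
  patt <- matrix(pattern[tree$tip.label], ncol = 1,
                 dimnames = list(tree$tip.label, NULL))
  as.numeric(prune_loglik(tree, model, patt))
}

## Compress a tips x loci matrix into unique patterns. Returns patterns
## (tips x npat), and the per-locus pattern index.
compress_patterns <- function(m) {
  key <- apply(m, 2, paste, collapse = "")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(patterns = m[, u, drop = FALSE], index = idx)
}

#' Log-likelihood of a binary character matrix on a tree
#'
#' Sums per-locus pattern log-likelihoods; under `"noabsencesites"`
#' conditioning each site likelihood is divided by `1 - P(all-absent)`, so
#' the total changes by exactly `- n_loci * log(1 - L0)`.
#'
#' @param tree [ape::phylo] whose tips are a subset of the matrix samples
#' @param model a [binary_model()]
#' @param x an [aflp_binary] or 0/1 matrix (samples x loci)
#' @return list of class `site_likelihoods`: `per_locus_loglik`,
#'   `total_loglik`, `conditioning`, `conditioning_correction`
#'   (`log(1 - L0)`, or 0 when unconditioned)
#' @export
matrix_log_likelihood <- function(tree, model, x) {
  m <- if (inherits(x, "aflp_binary")) x$calls else x
  if (!all(tree$tip.label %in% rownames(m)))
    stop("matrix lacks rows for tips: ",
         paste(setdiff(tree$tip.label, rownames(m)), collapse = ", "))
  tipm <- m[tree$tip.label, , drop = FALSE]     # tips x loci
  cp <- compress_patterns(tipm)
  ll <- prune_loglik(tree, model, cp$patterns)
  corr <- 0
  if (model$conditioning == "noabsencesites") {
    zero <- matrix(0L, length(tree$tip.label), 1,
                   dimnames = list(tree$tip.label, NULL))
    L0 <- exp(prune_loglik(tree, model, zero))
    if (L0 >= 1 - 1e-12)
      stop("numerical degeneracy: P(all-absent) is 1 within tolerance; ",
           "conditioning impossible")
    corr <- log1p(-L0)
    ll <- ll - corr
  }
  per_locus <- ll[cp$index]
  structure(list(per_locus_loglik = per_locus,
                 total_loglik = sum(per_locus),
                 conditioning = model$conditioning,
                 conditioning_correction = corr,
                 n_loci = ncol(tipm)),
            class = "site_likelihoods")
}

#' Maximum-likelihood branch lengths on a fixed topology
#'
#' Coordinate ascent: each branch in turn is optimised by a bounded
#' one-dimensional search (conditioning included in the objective, since
#' the ascertainment term depends on the branch lengths), sweeping until the
#' total log-likelihood improves by less than `tol`. Non-convergence within
#' `max_sweeps` is flagged, not silent.
#'
#' @param topology [ape::phylo]; starting lengths are taken from the tree
#'   when present, else 0.1
#' @param model a [binary_model()]
#' @param x an [aflp_binary] or 0/1 matrix
#' @param max_t upper bound on any branch length (expected substitutions)
#' @param tol convergence tolerance on the total log-likelihood
#' @param max_sweeps maximum number of passes over all branches
#' @return list: `tree` (optimised lengths), `loglik`
#'   (a `site_likelihoods`), `converged`, `n_sweeps`
#' @export
optimize_branch_lengths <- function(topology, model, x, max_t = 10,
                                    tol = 1e-4, max_sweeps = 30L) {
  m <- if (inherits(x, "aflp_binary")) x$calls else x
  if (!all(topology$tip.label %in% rownames(m)))
    stop("matrix lacks rows for tips: ",
         paste(setdiff(topology$tip.label, rownames(m)), collapse = ", "))
  tipm <- m[topology$tip.label, , drop = FALSE]
  cp <- compress_patterns(tipm)
  wt <- tabulate(cp$index, nbins = ncol(cp$patterns))
  nt <- length(topology$tip.label)
  phy <- topology
  if (is.null(phy$edge.length)) phy$edge.length <- rep(0.1, nrow(phy$edge))
  phy$edge.length <- pmin(pmax(phy$edge.length, 1e-8), max_t)
  cond <- model$conditioning == "noabsencesites"
  pruner <- build_pruner(phy, cp$patterns, with_zero = TRUE)
  nw <- length(wt)

  total <- function(elen) {
    ll <- pruner(model, elen)
    tot <- sum(ll[seq_len(nw)] * wt)
    if (cond) tot <- tot - sum(wt) * log1p(-exp(ll[nw + 1L]))
    tot
  }
  elen <- phy$edge.length
  cur <- total(elen)
  converged <- FALSE
  sweep <- 0L
  while (sweep < max_sweeps) {
    sweep <- sweep + 1L
    sweep_start <- cur
    for (k in seq_along(elen)) {
      f <- function(t) {
        e2 <- elen; e2[k] <- t
        -total(e2)
      }
      opt <- optimize(f, c(0, max_t), tol = 1e-7)
      if (-opt$objective > cur) {
        elen[k] <- opt$minimum
        cur <- -opt$objective
      }
    }
    if (cur - sweep_start < tol) { converged <- TRUE; break }
  }
  if (!converged)
    warning("branch-length optimization did not converge within ",
            max_sweeps, " sweeps")
  phy$edge.length <- elen
  list(tree = phy, loglik = matrix_log_likelihood(phy, model, tipm),
       converged = converged, n_sweeps = sweep)
}
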