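## Topology comparison: Shimodaira-Hasegawa test with RELL resampling over
## per-locus log-likelihoods, harmonic-mean marginal likelihoods from a
## branch-length Metropolis sampler, and the 2 x lnBF > 10 decision rule.

#' Shimodaira-Hasegawa test over candidate topologies
#'
#' Branch lengths of every candidate topology are freshly optimised on the
#' data ("full optimization"), then the SH procedure is applied to the
#' per-locus log-likelihoods: loci are resampled with replacement (RELL,
#' no re-optimisation), each topology's replicate log-likelihoods are
#' centred by their own mean, and the p-value of topology k is the fraction
#' of replicates in which the centred best-vs-k gap reaches the observed
#' gap. The best topology always has gap 0 and p = 1; the test is known to
#' be conservative.
#'
#' @param x an [aflp_binary] or 0/1 matrix
#' @param topologies list of [ape::phylo] candidates with identical leaf
#'   sets (branch lengths, if any, are used only as starting values)
#' @param model a [binary_model()]
#' @param n_rell number of RELL bootstrap replicates
#' @param seed integer seed
#' @return list of class `topology_test`: `logliks` (per-topology totals),
#'   `deltas` (lnL shortfall vs the best), `sh_pvalues`, `trees`
#'   (optimised), `n_rell`
#' @export
sh_test <- function(x, topologies, model, n_rell = 1000L, seed = 1L) {
  if (length(topologies) < 2)
    stop("the SH test needs at least 2 candidate topologies")
  leaf_sets <- lapply(topologies, function(t) sort(t$tip.label))
  for (i in seq_along(leaf_sets)[-1])
    if (!identical(leaf_sets[[i]], leaf_sets[[1]]))
      stop("topology ", i, " has a different leaf set than topology 1")
  if (is.null(names(topologies)))
    names(topologies) <- paste0("topo", seq_along(topologies))

  fits <- lapply(topologies, function(tp)
    optimize_branch_lengths(tp, model, x))
  ll <- do.call(rbind, lapply(fits, function(f) f$loglik$per_locus_loglik))
  tot <- rowSums(ll)
  best <- max(tot)
  T_obs <- best - tot                      # observed shortfalls, >= 0

  set.seed(seed)
  L <- ncol(ll)
  K <- nrow(ll)
  Lb <- matrix(0, K, n_rell)
  for (b in seq_len(n_rell)) {
    cnt <- tabulate(sample.int(L, L, replace = TRUE), nbins = L)
    Lb[, b] <- ll %*% cnt
  }
  Lb_c <- Lb - rowMeans(Lb)                # centre by each topology's mean
  S <- matrix(apply(Lb_c, 2, max), K, n_rell, byrow = TRUE) - Lb_c
  p <- rowMeans(S >= matrix(T_obs, K, n_rell))
  structure(list(logliks = tot, deltas = T_obs,
                 sh_pvalues = setNames(p, names(topologies)),
                 trees = lapply(fits, `[[`, "tree"),
                 converged = vapply(fits, `[[`, logical(1), "converged"),
                 n_rell = n_rell),
            class = "topology_test")
}

#' @export
print.topology_test <- function(x, ...) {
  cat("Shimodaira-Hasegawa test (RELL,", x$n_rell, "replicates)\n")
  for (k in names(x$sh_pvalues))
    cat(sprintf("  %-12s lnL = %.3f  delta = %.3f  p = %.4f\n",
                k, x$logliks[k], x$deltas[k], x$sh_pvalues[k]))
  invisible(x)
}

#' Harmonic-mean marginal likelihood on a fixed topology
#'
#' Metropolis sampling of branch lengths under independent exponential
#' priors, then the harmonic-mean estimator of the marginal likelihood over
#' the post-burn-in samples. The estimator is retained for comparability
#' with classic MrBayes/Tracer workflows despite its well-known instability;
#' two independent runs are performed by default so the run-to-run spread is
#' visible. Proposals are single-branch multipliers, with the step size
#' adapted during burn-in toward ~30% acceptance; a final acceptance rate
#' outside (0.05, 0.8) is flagged.
#'
#' @param topology [ape::phylo] (fixed; only branch lengths are sampled)
#' @param model a [binary_model()]
#' @param x an [aflp_binary] or 0/1 matrix
#' @param n_gens Metropolis iterations per run (>= 1)
#' @param burnin_frac fraction of iterations discarded as burn-in
#' @param sample_freq thinning interval for likelihood samples
#' @param prior_mean mean of the exponential branch-length prior
#' @param n_runs number of independent runs
#' @param seed integer master seed (per-run seeds derived from it)
#' @return list of class `marginal_likelihood`: `ln_marginal` (mean of run
#'   estimates), `runs` (per-run estimate, acceptance rate, flag),
#'   `n_samples`
#' @export
marginal_likelihood_harmonic <- function(topology, model, x,
                                         n_gens = 20000L,
                                         burnin_frac = 0.5,
                                         sample_freq = 10L,
                                         prior_mean = 0.1,
                                         n_runs = 2L, seed = 1L) {
  if (n_gens < 1) stop("`n_gens` must be at least 1 (empty chain requested)")
  stopifnot(burnin_frac >= 0, burnin_frac < 1, prior_mean > 0, n_runs >= 1)
  m <- if (inherits(x, "aflp_binary")) x$calls else x
  tipm <- m[topology$tip.label, , drop = FALSE]
  cp <- compress_patterns(tipm)
  wt <- tabulate(cp$index, nbins = ncol(cp$patterns))
  cond <- model$conditioning == "noabsencesites"
  pruner <- build_pruner(topology, cp$patterns, with_zero = TRUE)
  nw <- length(wt)
  loglik <- function(elen) {
    v <- pruner(model, elen)
    ll <- sum(v[seq_len(nw)] * wt)
    if (cond) ll <- ll - sum(wt) * log1p(-exp(v[nw + 1L]))
    ll
  }
  n_edge <- nrow(topology$edge)
  burn <- floor(n_gens * burnin_frac)

  one_run <- function(run_seed) {
    set.seed(run_seed)
    elen <- if (is.null(topology$edge.length)) rep(prior_mean, n_edge)
            else pmax(topology$edge.length, 1e-6)
    curL <- loglik(elen)
    lambda <- 1
    acc <- 0L; acc_win <- 0L
    samples <- numeric(0)
    for (i in seq_len(n_gens)) {
      k <- sample.int(n_edge, 1L)
      mult <- exp(lambda * (runif(1) - 0.5))
      prop <- elen
      prop[k] <- elen[k] * mult
      propL <- loglik(prop)
      ## exponential prior + multiplier-proposal Hastings term log(mult)
      log_r <- (propL - curL) - (prop[k] - elen[k]) / prior_mean + log(mult)
      if (log(runif(1)) < log_r) {
        elen <- prop; curL <- propL
        acc <- acc + 1L; acc_win <- acc_win + 1L
      }
      if (i <= burn && i %% 200L == 0L) {
        rate <- acc_win / 200
        lambda <- lambda * exp(rate - 0.3)   # adapt toward ~30% acceptance
        acc_win <- 0L
      }
      if (i > burn && (i - burn) %% sample_freq == 0L)
        samples <- c(samples, curL)
    }
    if (length(samples) == 0) samples <- curL
    ## ln of the harmonic mean: -(logsumexp(-lnL) - log(B))
    neg <- -samples
    mx <- max(neg)
    ln_hm <- -(mx + log(sum(exp(neg - mx))) - log(length(samples)))
    rate <- acc / n_gens
    list(ln_marginal = ln_hm, acceptance = rate,
         flagged = rate < 0.05 || rate > 0.8,
         n_samples = length(samples))
  }
  runs <- lapply(seq_len(n_runs), function(r)
    one_run(derive_seed(seed, paste0("mcmcrun", r))))
  est <- vapply(runs, `[[`, numeric(1), "ln_marginal")
  structure(list(ln_marginal = mean(est),
                 runs = data.frame(
                   run = seq_len(n_runs), ln_marginal = est,
                   acceptance = vapply(runs, `[[`, numeric(1), "acceptance"),
                   flagged = vapply(runs, `[[`, logical(1), "flagged")),
                 n_samples = runs[[1]]$n_samples),
            class = "marginal_likelihood")
}

#' Bayes factor from two log marginal likelihoods
#'
#' `2 x lnBF = 2 * (lnM1 - lnM2)`; values above 10 are conventionally taken
#' as strong evidence for model 1 over model 2.
#'
#' @param lnM1,lnM2 finite log marginal likelihoods
#' @return list: `bf_2ln`, `verdict` (`"strong"` or `"not_strong"`)
#' @export
bayes_factor <- function(lnM1, lnM2) {
  if (!is.finite(lnM1) || !is.finite(lnM2))
    stop("log marginal likelihoods must be finite")
  v <- 2 * (lnM1 - lnM2)
  list(bf_2ln = v, verdict = if (v > 10) "strong" else "not_strong")
}
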