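## Peak-height scoring: threshold-based phenotype calling, replicate-based
## mismatch error rates, and error-driven threshold optimization (the
## AFLPScore-style workflow for dominant markers).

#' Scoring thresholds for phenotype calling
#'
#' @param retention_threshold minimum per-locus mean peak height (over
#'   non-replicate samples) for a locus to be retained; loci below it are
#'   dropped as ambiguous low-intensity bins
#' @param calling_mode `"absolute"` (threshold in fluorescence units) or
#'   `"relative"` (threshold as a fraction of the locus mean)
#' @param calling_threshold the phenotype-calling threshold; a height at or
#'   above it is called 1
#' @return a list of class `scoring_thresholds`
#' @export
scoring_thresholds <- function(retention_threshold,
                               calling_mode = c("absolute", "relative"),
                               calling_threshold) {
  calling_mode <- match.arg(calling_mode)
  if (retention_threshold < 0) stop("retention_threshold must be >= 0")
  if (calling_mode == "relative" &&
      (calling_threshold <= 0 || calling_threshold > 1))
    stop("relative calling_threshold must lie in (0, 1]")
  if (calling_mode == "absolute" && calling_threshold <= 0)
    stop("absolute calling_threshold must be > 0")
  structure(list(retention_threshold = retention_threshold,
                 calling_mode = calling_mode,
                 calling_threshold = calling_threshold),
            class = "scoring_thresholds")
}

## Mean peak height per locus over non-replicate samples.
locus_means <- function(peaks) {
  primary <- setdiff(rownames(peaks$heights), peaks$replicate_pairs$replicate)
  colMeans(peaks$heights[primary, , drop = FALSE])
}

#' Call binary phenotypes from peak heights
#'
#' Loci whose mean height over non-replicate profiles falls below the
#' retention threshold are dropped; retained loci are called present when
#' the height reaches the calling threshold (absolute units, or a fraction
#' of the locus mean in relative mode). Replicate profiles are called too so
#' error rates can be estimated downstream.
#'
#' @param peaks an [aflp_peaks] table
#' @param thresholds a [scoring_thresholds()]
#' @return an [aflp_binary] matrix over the retained loci (replicate rows
#'   flagged in `$replicates`)
#' @export
call_phenotypes <- function(peaks, thresholds) {
  stopifnot(inherits(peaks, "aflp_peaks"),
            inherits(thresholds, "scoring_thresholds"))
  lm <- locus_means(peaks)
  keep <- lm >= thresholds$retention_threshold
  if (!any(keep))
    stop("retention threshold ", thresholds$retention_threshold,
         " drops every locus; no matrix can be produced")
  h <- peaks$heights[, keep, drop = FALSE]
  cut <- if (thresholds$calling_mode == "absolute") {
    thresholds$calling_threshold
  } else {
    rep(thresholds$calling_threshold * lm[keep], each = nrow(h))
  }
  calls <- (h >= cut) * 1L
  species <- peaks$species
  if (is.null(species)) {
    primary <- setdiff(rownames(h), peaks$replicate_pairs$replicate)
    species <- setNames(primary, primary)  # each sample its own species
  }
  aflp_binary(calls, species, replicates = peaks$replicate_pairs$replicate)
}

#' Replicate-based mismatch error rates
#'
#' The mismatch error rate of a locus is the fraction of replicate pairs
#' whose two profiles disagree at that locus; the overall rate is the
#' unweighted mean over retained loci. Because the locus-averaged and
#' pair-averaged summaries can differ, both are reported (`overall_error`
#' averages over loci; `pair_mean_error` averages each pair's mismatch
#' fraction over pairs — for complete data the two coincide).
#'
#' @param calls an [aflp_binary] containing both members of each pair
#' @param replicate_pairs data.frame with columns `sample`, `replicate`
#' @return a list of class `error_report` with `per_locus_error`,
#'   `overall_error`, `pair_mean_error`, `n_retained_loci`
#' @export
estimate_mismatch_error_rate <- function(calls, replicate_pairs) {
  stopifnot(inherits(calls, "aflp_binary"))
  if (is.null(replicate_pairs) || nrow(replicate_pairs) == 0)
    stop("at least one replicate pair is required to estimate error rates")
  ids <- rownames(calls$calls)
  miss <- setdiff(c(replicate_pairs$sample, replicate_pairs$replicate), ids)
  if (length(miss) > 0)
    stop("replicate pair members absent from calls: ",
         paste(miss, collapse = ", "))
  a <- calls$calls[replicate_pairs$sample, , drop = FALSE]
  b <- calls$calls[replicate_pairs$replicate, , drop = FALSE]
  mism <- a != b
  per_locus <- colMeans(mism)
  structure(list(per_locus_error = per_locus,
                 overall_error = mean(per_locus),
                 pair_mean_error = mean(rowMeans(mism)),
                 n_retained_loci = ncol(a),
                 n_pairs = nrow(replicate_pairs)),
            class = "error_report")
}

#' @export
print.error_report <- function(x, ...) {
  cat(sprintf(
    "mismatch error: %.4f (locus-averaged), %.4f (pair-averaged); %d loci, %d pairs\n",
    x$overall_error, x$pair_mean_error, x$n_retained_loci, x$n_pairs))
  invisible(x)
}

#' Default threshold grid
#'
#' Retention 0-500 in 26 steps; relative calling 5%-50% of the locus mean in
#' 10 steps; absolute calling 50-500 fluorescence units in 10 steps. All
#' three vectors are user-overridable; the defaults span the dynamic range
#' of typical ABI peak heights.
#'
#' @param retention,relative,absolute numeric grids; set `relative` or
#'   `absolute` to NULL to skip that calling mode
#' @export
threshold_grid <- function(retention = seq(0, 500, length.out = 26),
                           relative = seq(0.05, 0.50, length.out = 10),
                           absolute = seq(50, 500, length.out = 10)) {
  list(retention = retention, relative = relative, absolute = absolute)
}

#' Optimize scoring thresholds against replicate error rates
#'
#' Evaluates every (retention, mode, calling) grid point, scoring each by
#' the locus-averaged mismatch error, subject to retaining at least
#' `min_retained_frac` of the loci. Ties are broken toward more retained
#' loci, then lower retention threshold, then lower calling threshold, then
#' absolute before relative mode. Both calling modes are evaluated and the
#' better one kept.
#'
#' @param peaks an [aflp_peaks] with at least one replicate pair
#' @param grid a [threshold_grid()]
#' @param min_retained_frac minimum fraction of loci a candidate must retain
#' @return list with `thresholds` (the winning [scoring_thresholds()]),
#'   `report` (its [estimate_mismatch_error_rate()] report), and
#'   `evaluations` (a data.frame of every feasible grid point)
#' @export
optimize_thresholds <- function(peaks, grid = threshold_grid(),
                                min_retained_frac = 0.1) {
  stopifnot(inherits(peaks, "aflp_peaks"))
  if (nrow(peaks$replicate_pairs) == 0)
    stop("threshold optimization requires replicate pairs")
  n_total <- ncol(peaks$heights)
  rows <- list()
  for (ret in grid$retention) {
    cand <- list()
    for (cc in grid$absolute) cand <- c(cand, list(c("absolute", cc)))
    for (cc in grid$relative) cand <- c(cand, list(c("relative", cc)))
    for (p in cand) {
      th <- scoring_thresholds(ret, p[1], as.numeric(p[2]))
      calls <- tryCatch(call_phenotypes(peaks, th), error = function(e) NULL)
      if (is.null(calls)) next
      n_ret <- ncol(calls$calls)
      if (n_ret / n_total < min_retained_frac) next
      rep <- estimate_mismatch_error_rate(calls, peaks$replicate_pairs)
      rows[[length(rows) + 1L]] <- data.frame(
        retention = ret, mode = p[1], calling = as.numeric(p[2]),
        error = rep$overall_error, n_retained = n_ret,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    stop("no grid point retains at least ",
         round(100 * min_retained_frac), "% of loci; grid infeasible")
  ev <- do.call(rbind, rows)
  ord <- order(ev$error, -ev$n_retained, ev$retention, ev$calling,
               match(ev$mode, c("absolute", "relative")))
  best <- ev[ord[1], ]
  th <- scoring_thresholds(best$retention, best$mode, best$calling)
  calls <- call_phenotypes(peaks, th)
  list(thresholds = th,
       report = estimate_mismatch_error_rate(calls, peaks$replicate_pairs),
       evaluations = ev)
}

#' Reduce a matrix to its unique polymorphic loci
#'
#' Drops loci monomorphic across all samples (uninformative) and collapses
#' groups of loci with byte-identical call columns to a single
#' representative; identical columns in AFLP data are presumed size-homoplasy
#' artifacts of the binning. The collapse map is attached as attribute
#' `collapse_map` (representative -> collapsed locus ids). The operation is
#' idempotent.
#'
#' @param x an [aflp_binary]
#' @param drop_monomorphic,collapse_duplicates toggles for the two filters
#' @return filtered [aflp_binary] with a `collapse_map` attribute
#' @export
filter_unique_loci <- function(x, drop_monomorphic = TRUE,
                               collapse_duplicates = TRUE) {
  stopifnot(inherits(x, "aflp_binary"))
  calls <- x$calls
  if (drop_monomorphic && ncol(calls) > 0) {
    cs <- colSums(calls)
    calls <- calls[, cs > 0 & cs < nrow(calls), drop = FALSE]
  }
  cmap <- list()
  if (collapse_duplicates && ncol(calls) > 1) {
    key <- apply(calls, 2, paste, collapse = "")
    first <- !duplicated(key)
    reps <- colnames(calls)[first]
    groups <- split(colnames(calls), key)
    for (g in groups) {
      if (length(g) > 1) cmap[[g[1]]] <- g[-1]
    }
    calls <- calls[, first, drop = FALSE]
  }
  out <- aflp_binary(calls, x$species, x$replicates)
  attr(out, "collapse_map") <- cmap
  out
}
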