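## Leave-one-species-out homoplasy excess test for hybrid taxa.
##
## A hybrid carries a per-locus mosaic of its two parents' characters, which
## injects homoplasy into clades containing the parents; removing the hybrid
## therefore raises bootstrap support of those clades, while removing a
## non-hybrid barely moves any node. The test removes one species at a
## time, re-bootstraps, and flags outlier support increases.

#' Restrict a bipartition to a reduced leaf set
#'
#' Drops the removed leaves from both sides of a split; the restriction is
#' NULL (trivial) when either side falls below two leaves. The canonical key
#' is recomputed for the reduced universe.
#'
#' @param key canonical split key (see [tree_splits()])
#' @param leaves full leaf universe of the key
#' @param removed leaves to drop (need not all occur in the universe)
#' @return the restricted canonical key, or NULL if the split becomes
#'   trivial
#' @export
restrict_bipartition <- function(key, leaves, removed) {
  sides <- split_sides(key, leaves)
  a <- setdiff(sides$a, removed)
  b <- setdiff(sides$b, removed)
  if (length(a) < 2 || length(b) < 2) return(NULL)
  split_key(b, c(a, b))
}

#' Per-species removal records for the homoplasy excess test
#'
#' For each species, all its samples are dropped, the NJ bootstrap is rerun
#' with a seed derived from the master seed and the species label, and the
#' change in bootstrap frequency is recorded for every baseline split that
#' remains non-trivial on the reduced leaf set. Removals are independent:
#' the baseline is always the full dataset.
#'
#' Only species-respecting baseline splits are tracked by default: a split
#' that scatters one species' individuals over both sides reflects
#' within-species sampling noise, not phylogenetic structure, and its
#' support deltas would swamp the outlier fences with noise. Set
#' `species_level_splits = FALSE` to track every baseline split.
#'
#' @param x an [aflp_binary] with >= 4 species
#' @param n_boot bootstrap pseudoreplicates per removal (and baseline)
#' @param seed master seed
#' @param baseline optional precomputed result of [bootstrap_support()] on
#'   the full data (saves one bootstrap run)
#' @param transform distance transform, see [nei_li_distance()]
#' @param species_level_splits track only splits on which every species is
#'   monophyletic-or-absent (default TRUE)
#' @return list with `baseline` (the full-data [bootstrap_support()] result)
#'   and `records`: one list per species with elements `removed_species`,
#'   `support_after` (the reduced-data support table) and `deltas` (named
#'   by baseline split key, in percentage points)
#' @export
leave_one_out_support <- function(x, n_boot = 1000L, seed = 1L,
                                  baseline = NULL,
                                  transform = "one-minus-f",
                                  species_level_splits = TRUE) {
  stopifnot(inherits(x, "aflp_binary"))
  species <- sort(unique(x$species))
  if (length(species) < 4)
    stop("the homoplasy excess test needs at least 4 species")
  if (is.null(baseline))
    baseline <- bootstrap_support(x, n_boot, seed = derive_seed(seed, "base"),
                                  transform = transform)
  base_st <- baseline$support
  leaves <- attr(base_st, "leaves")
  if (species_level_splits) {
    keep <- vapply(base_st$split, function(k) {
      side <- split_sides(k, leaves)$b
      all(vapply(species, function(sp) {
        members <- intersect(names(x$species)[x$species == sp], leaves)
        n_in <- sum(members %in% side)
        n_in == 0 || n_in == length(members)
      }, logical(1)))
    }, logical(1))
    base_st <- base_st[keep, , drop = FALSE]
    attr(base_st, "leaves") <- leaves
  }

  records <- lapply(species, function(sp) {
    reduced <- aflp_drop_species(x, sp)
    bs <- bootstrap_support(reduced, n_boot,
                            seed = derive_seed(seed, sp),
                            transform = transform)
    removed_leaves <- setdiff(leaves, rownames(reduced$calls))
    deltas <- numeric(0)
    for (i in seq_len(nrow(base_st))) {
      rk <- restrict_bipartition(base_st$split[i], leaves, removed_leaves)
      if (is.null(rk)) next
      deltas[base_st$split[i]] <- support_of(bs$support, rk) -
        base_st$support[i]
    }
    list(removed_species = sp, support_after = bs$support, deltas = deltas)
  })
  names(records) <- species
  list(baseline = baseline, tracked = base_st, records = records)
}

#' Flag hybrid taxa from leave-one-out support changes
#'
#' For every baseline split, the support deltas across all removals form a
#' distribution; a removal is an outlier when its delta strictly exceeds the
#' fence. The fence for a candidate removal is computed from the *other*
#' removals' deltas at that split (with only ~10 removals, including the
#' candidate in its own fence masks exactly the extreme values the test is
#' looking for), and is the larger of the Tukey upper fence (Q3 + k IQR)
#' and a minimum-delta floor (percentage points) that guards against fences
#' collapsing when all deltas are tightly clustered. A species is flagged
#' as a candidate hybrid when it produces at least one outlier; the
#' strengthened splits are the candidate parental clades.
#'
#' @param loo result of [leave_one_out_support()]
#' @param min_delta floor on the support increase, in percentage points
#' @param fence `"tukey"` (Q3 + k IQR) or `"zscore"` (mean + k sd)
#' @param k fence multiplier (1.5 for tukey, 3 for zscore by convention)
#' @return a list of class `homoplasy_result`: `baseline`, `records`,
#'   `deltas` (matrix removal x split), `outliers` (data.frame), `flagged`
#'   (character vector of flagged species), `verdict` (named logical),
#'   `parameters`
#' @export
detect_hybrids <- function(loo, min_delta = 10, fence = c("tukey", "zscore"),
                           k = NULL) {
  fence <- match.arg(fence)
  if (is.null(k)) k <- if (fence == "tukey") 1.5 else 3
  records <- loo$records
  if (length(records) < 3)
    stop("need removal records for at least 3 species to form distributions")
  splits <- if (!is.null(loo$tracked)) loo$tracked$split
            else loo$baseline$support$split
  sp <- names(records)
  dm <- matrix(NA_real_, length(sp), length(splits),
               dimnames = list(sp, splits))
  for (s in sp) dm[s, names(records[[s]]$deltas)] <- records[[s]]$deltas
  if (all(is.na(dm)))
    stop("no baseline bipartition survives any removal; no signal to test")

  out <- list()
  for (j in seq_along(splits)) {
    v <- dm[, j]
    for (s in names(v)) {
      x <- v[s]
      if (is.na(x)) next
      rest <- v[setdiff(names(v), s)]
      rest <- rest[!is.na(rest)]
      if (length(rest) < 3) next
      fv <- if (fence == "tukey") {
        q <- quantile(rest, c(0.25, 0.75), names = FALSE, type = 7)
        q[2] + k * (q[2] - q[1])
      } else {
        mean(rest) + k * sd(rest)
      }
      fv <- max(fv, min_delta)
      if (x > fv)
        out[[length(out) + 1L]] <- data.frame(
          removed_species = s, split = splits[j], delta = unname(x),
          fence_value = fv, stringsAsFactors = FALSE)
    }
  }
  outliers <- if (length(out)) do.call(rbind, out) else
    data.frame(removed_species = character(), split = character(),
               delta = numeric(), fence_value = numeric())
  flagged <- unique(outliers$removed_species)
  structure(
    list(baseline = loo$baseline, records = records, deltas = dm,
         outliers = outliers, flagged = flagged,
         verdict = setNames(sp %in% flagged, sp),
         parameters = list(min_delta = min_delta, fence = fence, k = k)),
    class = "homoplasy_result")
}

#' @export
print.homoplasy_result <- function(x, ...) {
  cat("Homoplasy excess test (leave-one-species-out)\n")
  cat(sprintf("  removals: %d species; baseline splits tracked: %d\n",
              nrow(x$deltas), ncol(x$deltas)))
  if (length(x$flagged) == 0) {
    cat("  no evidence for hybrid taxa (no outlier support increases)\n")
  } else {
    cat("  candidate hybrids:", paste(x$flagged, collapse = ", "), "\n")
    for (i in seq_len(nrow(x$outliers)))
      cat(sprintf("   %s: +%.1f points on {%s} (fence %.1f)\n",
                  x$outliers$removed_species[i], x$outliers$delta[i],
                  x$outliers$split[i], x$outliers$fence_value[i]))
  }
  invisible(x)
}

#' Run the full homoplasy excess test
#'
#' Convenience wrapper: [leave_one_out_support()] then [detect_hybrids()].
#'
#' @inheritParams leave_one_out_support
#' @inheritParams detect_hybrids
#' @return a `homoplasy_result`
#' @export
homoplasy_excess_test <- function(x, n_boot = 1000L, seed = 1L,
                                  min_delta = 10, fence = "tukey",
                                  transform = "one-minus-f") {
  loo <- leave_one_out_support(x, n_boot, seed, transform = transform)
  detect_hybrids(loo, min_delta = min_delta, fence = fence)
}
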