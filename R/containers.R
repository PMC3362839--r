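#' Binary character matrix of dominant-marker calls
#'
#' The central data object of the pipeline: a samples x loci matrix of 0/1
#' presence/absence calls plus a sample-to-species map. Replicate profiles
#' (re-runs of the same DNA used for error-rate estimation) may be present as
#' extra rows; they do not need a species assignment.
#'
#' @param calls integer or numeric matrix with entries in \{0, 1\}; rows are
#'   samples, columns loci. Row and column names are required (sample ids and
#'   locus ids).
#' @param species named character vector mapping sample id -> species label.
#'   Must cover every row of `calls` that is not listed in `replicates`.
#' @param replicates optional character vector of row names that are
#'   replicate profiles rather than primary samples.
#' @return an object of class `aflp_binary`: a list with elements `calls`,
#'   `species`, `replicates`.
#' @export
aflp_binary <- function(calls, species, replicates = character()) {
  if (!is.matrix(calls)) stop("`calls` must be a matrix")
  if (is.null(rownames(calls)) || is.null(colnames(calls)))
    stop("`calls` must have row (sample) and column (locus) names")
  if (anyDuplicated(rownames(calls))) stop("duplicate sample ids in `calls`")
  if (anyDuplicated(colnames(calls))) stop("duplicate locus ids in `calls`")
  if (!all(calls %in% c(0L, 1L)))
    stop("`calls` entries must be exactly 0 or 1")
  storage.mode(calls) <- "integer"
  primary <- setdiff(rownames(calls), replicates)
  if (!all(primary %in% names(species)))
    stop("`species` must cover all non-replicate samples; missing: ",
         paste(setdiff(primary, names(species)), collapse = ", "))
  if (!all(replicates %in% rownames(calls)))
    stop("unknown replicate sample ids")
  structure(
    list(calls = calls, species = species[primary], replicates = replicates),
    class = "aflp_binary"
  )
}

#' @export
print.aflp_binary <- function(x, ...) {
  cat(sprintf(
    "AFLP binary matrix: %d samples (%d replicates) x %d loci, %d species\n",
    nrow(x$calls), length(x$replicates), ncol(x$calls),
    length(unique(x$species))))
  cat(sprintf("band-presence frequency: %.3f\n", mean(x$calls)))
  invisible(x)
}

#' @export
dim.aflp_binary <- function(x) dim(x$calls)

#' Subset an AFLP binary matrix by samples and/or loci
#'
#' @param x an [aflp_binary] object
#' @param samples character vector of sample ids to keep (default all)
#' @param loci character or integer index of loci to keep (default all)
#' @return an [aflp_binary] restricted to the requested rows/columns
#' @export
aflp_subset <- function(x, samples = rownames(x$calls), loci = NULL) {
  calls <- x$calls[samples, , drop = FALSE]
  if (!is.null(loci)) calls <- calls[, loci, drop = FALSE]
  aflp_binary(calls, x$species, intersect(x$replicates, samples))
}

#' Drop all samples of given species from a matrix
#'
#' @param x an [aflp_binary] object
#' @param species_labels species to remove
#' @return an [aflp_binary] without those species' samples
#' @export
aflp_drop_species <- function(x, species_labels) {
  keep_primary <- names(x$species)[!(x$species %in% species_labels)]
  if (length(keep_primary) == 0)
    stop("removal would drop every sample in the dataset")
  aflp_subset(x, c(keep_primary, x$replicates))
}

#' Per-species consensus (majority-rule) profiles
#'
#' For each species, the per-locus majority call over its individuals. Ties
#' (possible with an even number of individuals) are broken toward presence,
#' so a 50/50 locus is called 1; the tie-break is documented rather than
#' configurable because consensus profiles are only used for coarse
#' species-level summaries and for hybrid planting.
#'
#' @param x an [aflp_binary] object
#' @return integer matrix species x loci
#' @export
species_consensus <- function(x) {
  sp <- sort(unique(x$species))
  out <- matrix(0L, length(sp), ncol(x$calls),
                dimnames = list(sp, colnames(x$calls)))
  for (s in sp) {
    rows <- names(x$species)[x$species == s]
    out[s, ] <- as.integer(colMeans(x$calls[rows, , drop = FALSE]) >= 0.5)
  }
  out
}

#' Table of peak heights from binned AFLP electropherograms
#'
#' @param heights numeric matrix samples x bins of fluorescence intensities,
#'   all entries >= 0; row names are sample ids, column names are bin labels.
#' @param bin_sizes numeric vector of fragment sizes in base pairs, strictly
#'   increasing and within \[50, 500\].
#' @param replicate_pairs data.frame with columns `sample` and `replicate`
#'   naming rows of `heights` that are re-runs of the same DNA.
#' @param species optional named character vector sample -> species, carried
#'   through to scoring.
#' @return an object of class `aflp_peaks`
#' @export
aflp_peaks <- function(heights, bin_sizes, replicate_pairs, species = NULL) {
  if (!is.matrix(heights) || any(heights < 0))
    stop("`heights` must be a non-negative matrix")
  if (length(bin_sizes) != ncol(heights))
    stop("one bin size per column required")
  if (any(diff(bin_sizes) <= 0)) stop("bin sizes must be strictly increasing")
  if (any(bin_sizes < 50 | bin_sizes > 500))
    stop("bin sizes must lie in [50, 500] bp")
  if (!all(c("sample", "replicate") %in% names(replicate_pairs)))
    stop("`replicate_pairs` needs columns `sample` and `replicate`")
  ids <- rownames(heights)
  bad <- setdiff(c(replicate_pairs$sample, replicate_pairs$replicate), ids)
  if (length(bad) > 0)
    stop("replicate pairs reference unknown samples: ",
         paste(bad, collapse = ", "))
  structure(
    list(heights = heights, bin_sizes = bin_sizes,
         replicate_pairs = replicate_pairs, species = species),
    class = "aflp_peaks"
  )
}

#' @export
print.aflp_peaks <- function(x, ...) {
  cat(sprintf(
    "AFLP peak-height table: %d profiles x %d bins (%g-%g bp), %d replicate pairs\n",
    nrow(x$heights), ncol(x$heights), min(x$bin_sizes), max(x$bin_sizes),
    nrow(x$replicate_pairs)))
  invisible(x)
}

## ---- bipartition bookkeeping -------------------------------------------

## Canonical key of a split of `leaves`: the side NOT containing the
## lexicographically smallest leaf, sorted and joined with "|". This makes
## split identity independent of rooting and of tree orientation.
split_key <- function(side, leaves) {
  ref <- min(leaves)
  if (ref %in% side) side <- setdiff(leaves, side)
  paste(sort(side), collapse = "|")
}

split_sides <- function(key, leaves) {
  b <- strsplit(key, "|", fixed = TRUE)[[1]]
  list(a = setdiff(leaves, b), b = b)
}

#' Non-trivial bipartitions (splits) of a tree
#'
#' Every internal edge of an unrooted leaf-labelled tree cuts the leaves into
#' two sets; splits with both sides of size >= 2 are the units of clade
#' identity used for bootstrap bookkeeping. Keys are canonical: the side not
#' containing the alphabetically first leaf, sorted, joined with `|`.
#'
#' @param phy an [ape::phylo] tree
#' @return character vector of canonical split keys (possibly empty)
#' @export
tree_splits <- function(phy) {
  nt <- length(phy$tip.label)
  if (nt < 4) return(character())
  pp <- ape::prop.part(phy)
  leaves <- phy$tip.label
  keys <- character()
  for (i in seq_along(pp)) {
    side <- phy$tip.label[pp[[i]]]
    if (length(side) < 2 || length(side) > nt - 2) next
    keys <- c(keys, split_key(side, leaves))
  }
  unique(keys)
}

#' Bootstrap support table
#'
#' @param splits character vector of canonical split keys (the splits of the
#'   point-estimate tree)
#' @param support numeric vector of support percentages in \[0, 100\]
#' @param leaves leaf universe the keys refer to
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates
#' @param freq_all named numeric vector of bootstrap frequencies (percent) of
#'   every split observed in any pseudoreplicate, including splits absent
#'   from the point tree
#' @param n_redrawn number of pseudoreplicates redrawn because a resampled
#'   matrix yielded an undefined distance
#' @return a data.frame of class `aflp_support` with columns `split`,
#'   `support`
#' @export
support_table <- function(splits, support, leaves, n_pseudoreplicates,
                          freq_all = NULL, n_redrawn = 0L) {
  stopifnot(length(splits) == length(support),
            all(support >= 0 & support <= 100))
  out <- data.frame(split = splits, support = support,
                    stringsAsFactors = FALSE)
  structure(out, class = c("aflp_support", "data.frame"),
            leaves = leaves, n_pseudoreplicates = n_pseudoreplicates,
            freq_all = freq_all, n_redrawn = n_redrawn)
}

## Bootstrap frequency (percent) of an arbitrary split key in a support
## table, 0 if the split was never observed.
support_of <- function(st, key) {
  fa <- attr(st, "freq_all")
  if (!is.null(fa) && key %in% names(fa)) return(unname(fa[key]))
  i <- match(key, st$split)
  if (is.na(i)) 0 else st$support[i]
}
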