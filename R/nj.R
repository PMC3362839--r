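## Neighbour joining and locus-bootstrap clade support.

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration: repeatedly join the pair minimising
#' the Q criterion, with branch lengths from the usual rate-corrected
#' formulas. Negative branch-length estimates are clamped to zero with the
#' deficit moved to the sibling edge. Ties in Q are broken by lexicographic
#' label order, so the result is a pure function of the input.
#'
#' @param d symmetric labelled distance matrix (zero diagonal, non-negative
#'   finite entries), at least 3 labels
#' @return an unrooted [ape::phylo] tree
#' @export
neighbor_joining <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d) || nrow(d) < 3)
    stop("`d` must be a square matrix with at least 3 labels")
  if (is.null(rownames(d))) stop("`d` must have row/column labels")
  if (!all(is.finite(d))) stop("`d` contains non-finite distances")
  if (any(d < 0)) stop("`d` contains negative distances")
  if (max(abs(d - t(d))) > 1e-8) stop("`d` is not symmetric")
  n <- nrow(d)
  labels <- rownames(d)
  if (n == 3) {
    # unique unrooted topology; three-point branch lengths
    x <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
           (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
           (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
    phy <- structure(
      list(edge = cbind(4L, 1:3), edge.length = pmax(x, 0),
           tip.label = labels, Nnode = 1L),
      class = "phylo", order = "cladewise")
    return(phy)
  }
  res <- .nj_cpp(d, labels)
  phy <- structure(
    list(edge = res$edge, edge.length = as.numeric(res$edge.length),
         tip.label = labels, Nnode = res$Nnode),
    class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}

## Derive a 31-bit seed from a master seed and a string tag, so per-removal
## and per-run sub-streams are reproducible independent of iteration order.
derive_seed <- function(master, tag) {
  h <- sum(utf8ToInt(as.character(tag)) *
             (seq_along(utf8ToInt(as.character(tag))) %% 7 + 1))
  as.integer((as.numeric(master) * 48271 + h * 16807) %% 2147483647)
}

#' Locus-bootstrap support for a neighbour-joining tree
#'
#' Resamples loci (matrix columns) with replacement, recomputes the Nei-Li
#' distance matrix and NJ tree for each pseudoreplicate, and records how
#' often each internal bipartition of the point-estimate tree occurs among
#' the pseudoreplicate trees. Pseudoreplicates whose resampled matrix yields
#' an undefined distance (a pair sharing no scorable bands) are redrawn and
#' counted.
#'
#' @param x an [aflp_binary]
#' @param n_pseudoreplicates number of bootstrap pseudoreplicates (>= 1)
#' @param seed integer seed
#' @param level,transform passed to [nei_li_matrix()]
#' @return list with `tree` (the point-estimate [ape::phylo], support
#'   percentages as `node.label`) and `support` (a [support_table()];
#'   attribute `freq_all` holds bootstrap frequencies of every observed
#'   split, including ones absent from the point tree)
#' @export
bootstrap_support <- function(x, n_pseudoreplicates = 1000L, seed = 1L,
                              level = "sample",
                              transform = "one-minus-f") {
  stopifnot(n_pseudoreplicates >= 1)
  m0 <- if (inherits(x, "aflp_binary")) {
    if (level == "species") species_consensus(x)
    else x$calls[setdiff(rownames(x$calls), x$replicates), , drop = FALSE]
  } else x
  if (nrow(m0) < 3) stop("bootstrap requires at least 3 profiles")
  point <- neighbor_joining(nei_li_matrix(m0, transform = transform))
  point_keys <- tree_splits(point)
  L <- ncol(m0)

  set.seed(seed)
  counts <- new.env(parent = emptyenv())
  n_redrawn <- 0L
  b <- 0L
  while (b < n_pseudoreplicates) {
    idx <- sample.int(L, L, replace = TRUE)
    d <- tryCatch(nei_li_matrix(m0[, idx, drop = FALSE],
                                transform = transform),
                  error = function(e) NULL)
    if (is.null(d) || !all(is.finite(d))) {
      n_redrawn <- n_redrawn + 1L
      if (n_redrawn > 100L * n_pseudoreplicates)
        stop("bootstrap stalled: resampled matrices keep producing ",
             "undefined distances")
      next
    }
    b <- b + 1L
    for (k in tree_splits(neighbor_joining(d))) {
      counts[[k]] <- (if (is.null(counts[[k]])) 0L else counts[[k]]) + 1L
    }
  }
  all_keys <- ls(counts)
  freq_all <- setNames(
    vapply(all_keys, function(k) 100 * counts[[k]] / n_pseudoreplicates,
           numeric(1)),
    all_keys)
  supp <- vapply(point_keys, function(k)
    if (k %in% all_keys) freq_all[[k]] else 0, numeric(1))
  st <- support_table(point_keys, unname(supp), rownames(m0),
                      n_pseudoreplicates, freq_all = freq_all,
                      n_redrawn = n_redrawn)
  list(tree = annotate_support(point, st), support = st)
}

## Attach support percentages as node labels of the point tree.
annotate_support <- function(phy, st) {
  nt <- length(phy$tip.label)
  labs <- rep("", phy$Nnode)
  pp <- ape::prop.part(phy)
  leaves <- phy$tip.label
  for (i in seq_along(pp)) {
    side <- leaves[pp[[i]]]
    if (length(side) < 2 || length(side) > nt - 2) next
    key <- split_key(side, leaves)
    j <- match(key, st$split)
    if (!is.na(j)) labs[i] <- format(round(st$support[j], 1), trim = TRUE)
  }
  phy$node.label <- labs
  phy
}
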