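## Nei-Li restriction-fragment distances for dominant binary profiles.

#' Nei-Li similarity and distance between two band profiles
#'
#' The fraction of shared fragments is `F = 2 * n_xy / (n_x + n_y)`, with
#' `n_x`, `n_y` the band counts of the two profiles and `n_xy` the number of
#' shared bands. The default transform is `d = 1 - F`, bounded in \[0, 1\]
#' and finite for disjoint profiles; `d = -ln F` is available for users who
#' want an evolutionary-distance-like scale (it is infinite when no bands
#' are shared).
#'
#' @param x,y binary vectors of equal length
#' @param transform `"one-minus-f"` (default) or `"neg-log-f"`
#' @return the distance (non-negative scalar)
#' @export
nei_li_distance <- function(x, y, transform = c("one-minus-f", "neg-log-f")) {
  transform <- match.arg(transform)
  stopifnot(length(x) == length(y), all(x %in% 0:1), all(y %in% 0:1))
  nx <- sum(x); ny <- sum(y)
  if (nx + ny == 0)
    stop("Nei-Li distance undefined: both profiles carry no bands")
  f <- 2 * sum(x & y) / (nx + ny)
  if (transform == "one-minus-f") 1 - f else -log(f)
}

#' All pairwise Nei-Li distances for a binary matrix
#'
#' @param x an [aflp_binary] or a plain 0/1 matrix with row names
#' @param level `"sample"` (default; one row per profile, replicates
#'   excluded) or `"species"` (majority-rule consensus per species)
#' @param transform see [nei_li_distance()]
#' @return symmetric labelled distance matrix with a zero diagonal
#' @export
nei_li_matrix <- function(x, level = c("sample", "species"),
                          transform = c("one-minus-f", "neg-log-f")) {
  level <- match.arg(level)
  transform <- match.arg(transform)
  m <- if (inherits(x, "aflp_binary")) {
    if (level == "species") species_consensus(x)
    else x$calls[setdiff(rownames(x$calls), x$replicates), , drop = FALSE]
  } else x
  if (nrow(m) < 3) stop("need at least 3 profiles for a distance matrix")
  storage.mode(m) <- "double"
  nb <- rowSums(m)
  tot <- outer(nb, nb, "+")
  if (any(tot == 0 & upper.tri(tot))) {
    idx <- which(tot == 0 & upper.tri(tot), arr.ind = TRUE)[1, ]
    stop("Nei-Li distance undefined for pair ", rownames(m)[idx[1]], " / ",
         rownames(m)[idx[2]], ": no bands in either profile")
  }
  f <- 2 * tcrossprod(m) / tot
  d <- if (transform == "one-minus-f") 1 - f else -log(f)
  diag(d) <- 0
  dimnames(d) <- list(rownames(m), rownames(m))
  d
}
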