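#' @keywords internal
"_PACKAGE"

# Clamp numeric values into [lo, hi].
clamp <- function(x, lo = 0, hi = 1) pmin(pmax(x, lo), hi)

#' Dice overlap coefficient between two binary masks
#'
#' `2|A∩B| / (|A|+|B|)`. Two empty masks are in perfect agreement (Dice 1);
#' one empty mask against a non-empty one scores 0.
#'
#' @param a,b binary matrices of equal dimensions (values 0/1).
#' @return a number in \[0, 1\].
#' @export
dice <- function(a, b) {
  stopifnot(all(dim(a) == dim(b)))
  sa <- sum(a != 0)
  sb <- sum(b != 0)
  if (sa + sb == 0) return(1)
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Label connected components of a binary mask (8-connectivity)
#'
#' Diagonal neighbours belong to the same component. Implemented as connected
#' components of the pixel adjacency graph.
#'
#' @param mask binary matrix.
#' @return integer matrix of the same shape; 0 for background, components
#'   numbered from 1.
#' @export
label_components <- function(mask) {
  stopifnot(is.matrix(mask))
  fg <- which(mask != 0)
  out <- matrix(0L, nrow(mask), ncol(mask))
  if (!length(fg)) return(out)
  nr <- nrow(mask)
  nc <- ncol(mask)
  id <- matrix(0L, nr, nc)
  id[fg] <- seq_along(fg)
  edges <- integer(0)
  for (s in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    di <- s[1]; dj <- s[2]
    ri <- seq_len(nr); ri <- ri[ri + di >= 1 & ri + di <= nr]
    rj <- seq_len(nc); rj <- rj[rj + dj >= 1 & rj + dj <= nc]
    a <- id[ri, rj, drop = FALSE]
    b <- id[ri + di, rj + dj, drop = FALSE]
    keep <- a > 0L & b > 0L
    if (any(keep)) edges <- c(edges, rbind(a[keep], b[keep]))
  }
  g <- igraph::make_empty_graph(n = length(fg), directed = FALSE)
  if (length(edges)) g <- igraph::add_edges(g, edges)
  memb <- igraph::components(g)$membership
  out[fg] <- as.integer(memb)
  out
}

#' Count connected components (8-connectivity)
#' @inheritParams label_components
#' @return integer component count.
#' @export
n_components <- function(mask) {
  lab <- label_components(mask)
  if (!length(lab)) 0L else max(lab)
}

# Reflect (mirror) padding of a matrix by `r` pixels on every side.
# Requires r < dim; mirrored without repeating the edge row/col twice
# would be "reflect"; here we use symmetric-style mirroring (edge included),
# which keeps opening/closing exactly idempotent on the tiled extension.
pad_reflect <- function(m, r) {
  nr <- nrow(m); nc <- ncol(m)
  stopifnot(r >= 1, r < nr, r < nc)
  ri <- c(r:1, seq_len(nr), nr:(nr - r + 1))
  ci <- c(r:1, seq_len(nc), nc:(nc - r + 1))
  m[ri, ci, drop = FALSE]
}

# Rasterized disc: logical matrix of pixels within Euclidean distance
# `radius` of `center` (row, col), on an nr x nc grid.
disc_mask <- function(center, radius, nr, nc) {
  dr <- matrix(seq_len(nr) - center[1], nr, nc)
  dc <- matrix(rep(seq_len(nc) - center[2], each = nr), nr, nc)
  (dr * dr + dc * dc) <= radius^2
}

# Seed derivation for sub-stages; keeps results < 2^31.
derive_seed <- function(seed, offset) {
  (as.integer(seed) + as.integer(offset)) %% 2000000011L
}
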