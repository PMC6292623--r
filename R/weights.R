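# Contiguity neighbour lists, row-standardized weights and spatial lags.
#
# Weights are kept as sparse neighbour lists (one integer vector and one
# weight vector per entity), which is all a linear transect needs and
# extends to arbitrary adjacency.

#' First-order contiguity neighbours on a line
#'
#' Entity k of a linear transect is adjacent to k - 1 and k + 1; the two
#' endpoints have a single neighbour each.
#'
#' @param n Number of entities (quadrats), at least 2.
#' @return A `neighbor_list`: a list of integer neighbour vectors.
#' @examples
#' linear_contiguity(4)
#' @export
linear_contiguity <- function(n) {
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 2L) {
    stop("n must be a single integer >= 2; contiguity is undefined otherwise")
  }
  nb <- lapply(seq_len(n), function(k) {
    as.integer(c(if (k > 1L) k - 1L, if (k < n) k + 1L))
  })
  structure(nb, class = "neighbor_list", n = n)
}

#' Row-standardize a neighbour list ("W style" weights)
#'
#' Each entity's neighbours receive equal weight 1/degree, so every row of
#' the implied weight matrix sums to one. For a linear transect this gives
#' interior quadrats two weights of 0.5 and endpoints a single weight of 1.
#'
#' @param neighbors A `neighbor_list` (or plain list of integer vectors).
#' @return A `neighbor_weights` object: list with elements `neighbors`,
#'   `weights` and `n`.
#' @export
row_standardize <- function(neighbors) {
  deg <- lengths(neighbors)
  if (any(deg == 0L)) {
    stop("entity ", which(deg == 0L)[1L],
         " has no neighbours; the statistic is undefined for isolates")
  }
  structure(list(neighbors = lapply(neighbors, as.integer),
                 weights = lapply(deg, function(d) rep(1 / d, d)),
                 n = length(neighbors)),
            class = "neighbor_weights")
}

#' Spatial lag of a variable
#'
#' The lag of entity i is the weighted average of its neighbours' values,
#' `sum_j w_ij x_j`. With row-standardized weights this is a convex
#' combination, so a constant vector is its own lag.
#'
#' @param weights A `neighbor_weights` object.
#' @param x Numeric vector, one value per entity.
#' @return Numeric vector of lagged values.
#' @export
spatial_lag <- function(weights, x) {
  stopifnot(inherits(weights, "neighbor_weights"))
  if (length(x) != weights$n) {
    stop("length of x (", length(x), ") does not match the number of entities (",
         weights$n, ")")
  }
  vapply(seq_len(weights$n), function(i) {
    sum(weights$weights[[i]] * x[weights$neighbors[[i]]])
  }, numeric(1L))
}

#' Export weights as a sparse edge list
#'
#' @param weights A `neighbor_weights` object.
#' @return Data frame with columns `i`, `j`, `w`.
#' @export
weights_edge_list <- function(weights) {
  stopifnot(inherits(weights, "neighbor_weights"))
  i <- rep(seq_len(weights$n), lengths(weights$neighbors))
  data.frame(i = i,
             j = unlist(weights$neighbors, use.names = FALSE),
             w = unlist(weights$weights, use.names = FALSE))
}
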