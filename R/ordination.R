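# Dissimilarities, transformations and ordination of quadrat composition.
# Bray-Curtis, Hellinger and chord computations are delegated to vegan
# behind validated wrappers; PCoA and PCA use stats::cmdscale / prcomp.

.as_count_matrix <- function(m) {
  m <- as.matrix(m)
  if (any(!is.finite(m)) || any(m < 0)) stop("abundance matrix must be non-negative and finite")
  m
}

#' Bray-Curtis dissimilarity between quadrats
#'
#' `d(u, v) = sum |u_s - v_s| / sum (u_s + v_s)` on raw counts, bounded in
#' `[0, 1]`.
#'
#' @param m Quadrats-by-species abundance matrix (rows are quadrats).
#' @return A `dist` object with attribute `metric = "bray_curtis"`.
#' @export
bray_curtis <- function(m) {
  m <- .as_count_matrix(m)
  zero <- rownames(m)[rowSums(m) == 0]
  if (is.null(rownames(m))) zero <- which(rowSums(m) == 0)
  if (length(zero) > 1L) {
    stop("Bray-Curtis undefined between all-zero quadrats: ",
         paste(utils::head(zero, 5L), collapse = ", "))
  }
  d <- vegan::vegdist(m, method = "bray")
  attr(d, "metric") <- "bray_curtis"
  d
}

#' Hellinger transformation
#'
#' Square root of relative abundance per row, `y_is = sqrt(x_is / N_i)`;
#' every transformed row has unit sum of squares, which makes
#' Euclidean-based ordination appropriate for count data.
#'
#' @param m Quadrats-by-species abundance matrix; all row sums must be > 0.
#' @return Transformed numeric matrix of the same dimension.
#' @export
hellinger <- function(m) {
  m <- .as_count_matrix(m)
  if (any(rowSums(m) == 0)) {
    stop("Hellinger transformation undefined for all-zero row(s): ",
         paste(utils::head(which(rowSums(m) == 0), 5L), collapse = ", "))
  }
  out <- as.matrix(vegan::decostand(m, method = "hellinger"))
  attributes(out) <- list(dim = dim(out), dimnames = dimnames(m))
  out
}

#' Chord distance between quadrats
#'
#' Euclidean distance between rows scaled to unit L2 norm; proportional
#' rows are at distance 0 and rows with disjoint species at sqrt(2).
#'
#' @param m Quadrats-by-species abundance matrix; all row norms must be > 0.
#' @return A `dist` object with attribute `metric = "chord"`.
#' @export
chord_distance <- function(m) {
  m <- .as_count_matrix(m)
  nrm <- sqrt(rowSums(m^2))
  if (any(nrm == 0)) {
    stop("chord distance undefined for all-zero row(s): ",
         paste(utils::head(which(nrm == 0), 5L), collapse = ", "))
  }
  d <- stats::dist(m / nrm)
  attr(d, "metric") <- "chord"
  d
}

#' Principal coordinate analysis (classical MDS)
#'
#' Gower double-centering of `-d^2 / 2` followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their
#' (positive) eigenvalues. Negative eigenvalues, which arise for
#' non-Euclidean dissimilarities such as Bray-Curtis, are reported as-is
#' and never silently corrected.
#'
#' @param d A `dist` object over at least 3 objects.
#' @param k Number of axes requested (default 2); truncated with a warning
#'   if fewer positive eigenvalues exist.
#' @return An `ordination_result`: list with `points` (n x k), `eig` (all
#'   eigenvalues, non-increasing), `prop_explained` (share of the positive
#'   eigenvalue total), `negative_eig` flag and `method = "pcoa"`.
#' @export
pcoa <- function(d, k = 2L) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3L) stop("PCoA needs a dist object over at least 3 objects")
  # cmdscale warns whenever trailing eigenvalues are <= 0; that is the
  # expected situation here and the eigenvalues are reported explicitly
  fit <- suppressWarnings(stats::cmdscale(d, k = n - 1L, eig = TRUE))
  eig <- fit$eig
  npos <- sum(eig > sqrt(.Machine$double.eps) * max(abs(eig)))
  if (k > npos) {
    warning("only ", npos, " positive eigenvalue(s); truncating k from ", k)
    k <- npos
  }
  pts <- fit$points[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(k))
  structure(list(points = pts,
                 eig = eig,
                 prop_explained = pmax(eig, 0)[seq_len(k)] / sum(eig[eig > 0]),
                 negative_eig = any(eig < -sqrt(.Machine$double.eps) * max(abs(eig))),
                 method = "pcoa"),
            class = "ordination_result")
}

#' Principal component analysis of (transformed) abundances
#'
#' Columns are centred internally; no unit-variance scaling is applied,
#' which is the standard choice for Hellinger-transformed input whose row
#' magnitudes are already standardized.
#'
#' @param m Numeric matrix (e.g. Hellinger-transformed counts), n >= 3 rows.
#' @param k Number of axes (default 2), truncated with a warning if the
#'   matrix has lower rank.
#' @return An `ordination_result` with `points` (scores), `eig` (axis
#'   variances), `prop_explained`, `species_scores` (loadings) and
#'   `method = "pca"`.
#' @export
pca <- function(m, k = 2L) {
  m <- as.matrix(m)
  if (nrow(m) < 3L) stop("PCA needs at least 3 rows")
  fit <- stats::prcomp(m, center = TRUE, scale. = FALSE)
  eig <- fit$sdev^2
  tol <- sqrt(.Machine$double.eps) * max(eig)
  nax <- sum(eig > tol)
  if (k > nax) {
    warning("only ", nax, " non-degenerate axis/axes; truncating k from ", k)
    k <- nax
  }
  pts <- fit$x[, seq_len(k), drop = FALSE]
  colnames(pts) <- paste0("axis", seq_len(k))
  load <- fit$rotation[, seq_len(k), drop = FALSE]
  colnames(load) <- paste0("axis", seq_len(k))
  structure(list(points = pts,
                 eig = eig,
                 prop_explained = eig[seq_len(k)] / sum(eig),
                 species_scores = load,
                 method = "pca"),
            class = "ordination_result")
}

#' @export
print.ordination_result <- function(x, ...) {
  cat(toupper(x$method), " ordination: ", nrow(x$points), " objects, ",
      ncol(x$points), " axes (",
      paste0(sprintf("%.1f", 100 * x$prop_explained), "%", collapse = ", "),
      ")\n", sep = "")
  if (isTRUE(x$negative_eig)) cat("note: negative eigenvalues present\n")
  invisible(x)
}
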