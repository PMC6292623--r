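# Hierarchical clustering of cluster quadrats: linkage methods, cophenetic
# model selection, and multiscale bootstrap support (approximately unbiased
# p-values and bootstrap probabilities) for dendrogram nodes.

.linkage_map <- c(single = "single", complete = "complete",
                  upgma = "average", wpgma = "mcquitty", ward = "ward.D2")

#' Agglomerative hierarchical clustering
#'
#' Thin validated front end to [stats::hclust()] with field-standard
#' method names (`upgma` = average linkage, `wpgma` = McQuitty,
#' `ward` = Ward's criterion on squared distances).
#'
#' @param d A `dist` object over at least 2 objects.
#' @param method One of `single`, `complete`, `upgma`, `wpgma`, `ward`.
#' @return A `dendrogram_result`: list with the `hclust` tree, `method`,
#'   and `cophenetic_correlation` (Pearson correlation between `d` and the
#'   tree's cophenetic distances). Bootstrap support is unset until
#'   [multiscale_bootstrap()] is run.
#' @export
hierarchical_cluster <- function(d, method = "upgma") {
  if (!method %in% names(.linkage_map)) {
    stop("unknown linkage method '", method, "'; choices: ",
         paste(names(.linkage_map), collapse = ", "))
  }
  n <- attr(d, "Size")
  if (is.null(n) || n < 2L) stop("need a dist object over at least 2 objects")
  hc <- stats::hclust(stats::as.dist(d), method = .linkage_map[[method]])
  cv <- as.vector(stats::cophenetic(hc))
  coph <- if (stats::sd(d) > 0 && stats::sd(cv) > 0) {
    stats::cor(as.vector(d), cv)
  } else NA_real_
  structure(list(hclust = hc, method = method,
                 cophenetic_correlation = coph, support = NULL),
            class = "dendrogram_result")
}

#' @export
print.dendrogram_result <- function(x, ...) {
  cat("dendrogram (", x$method, " linkage) over ",
      length(x$hclust$order), " objects; cophenetic correlation ",
      sprintf("%.3f", x$cophenetic_correlation), "\n", sep = "")
  invisible(x)
}

#' Select the linkage with the highest cophenetic correlation
#'
#' Fits each candidate linkage and returns the dendrogram whose cophenetic
#' distances correlate best (Pearson) with the original dissimilarities.
#' Ties are broken by the order methods are listed, with a warning.
#'
#' @param d A `dist` object (non-constant).
#' @param methods Character vector of linkage names (default all five).
#' @return List with `best` (a `dendrogram_result`) and `correlations`
#'   (data frame method/cophenetic_correlation).
#' @export
cophenetic_selection <- function(d, methods = names(.linkage_map)) {
  if (length(methods) < 1L) stop("need at least one linkage method")
  if (stats::sd(d) == 0) stop("constant distance vector; cophenetic correlation undefined")
  fits <- lapply(methods, function(m) hierarchical_cluster(d, m))
  cors <- vapply(fits, `[[`, numeric(1L), "cophenetic_correlation")
  if (all(is.na(cors))) stop("cophenetic correlation undefined for every method")
  ranked <- ifelse(is.na(cors), -Inf, cors)
  best <- which(ranked == max(ranked))
  if (length(best) > 1L) {
    warning("cophenetic correlation tie between: ",
            paste(methods[best], collapse = ", "),
            "; keeping '", methods[best[1L]], "'")
  }
  list(best = fits[[best[1L]]],
       correlations = data.frame(method = methods,
                                 cophenetic_correlation = cors,
                                 stringsAsFactors = FALSE))
}

# Leaf sets of every internal node of an hclust tree, as canonical keys.
.node_keys <- function(hc) {
  n <- length(hc$order)
  sets <- vector("list", n - 1L)
  for (k in seq_len(n - 1L)) {
    members <- integer(0)
    for (side in hc$merge[k, ]) {
      members <- c(members, if (side < 0) -side else sets[[side]])
    }
    sets[[k]] <- sort(members)
  }
  vapply(sets, paste, character(1L), collapse = ",")
}

#' Multiscale bootstrap support for dendrogram clusters
#'
#' Resamples species (columns) with replacement at a ladder of sample
#' sizes `round(r * S)` for scale factors `r` around 1, rebuilds the
#' dendrogram each time, and records how often every original cluster
#' (leaf set) reappears. The bootstrap probability BP is the recovery
#' frequency at the scale closest to 1. The approximately unbiased value
#' AU corrects BP for the curvature of the cluster boundary: writing
#' `z(r) = qnorm(1 - BP(r))`, a weighted least-squares fit of
#' `z(r) = v * sqrt(r) + c / sqrt(r)` gives `AU = 1 - pnorm(v - c)`.
#'
#' @param m Quadrats-by-species abundance matrix (rows are clustered).
#' @param dist_fun Function mapping the matrix to a `dist` (default
#'   [chord_distance()]).
#' @param method Linkage passed to [hierarchical_cluster()] (default
#'   `"upgma"`).
#' @param scales Scale factors spanning values below and above 1
#'   (default ten steps from 0.5 to 1.4).
#' @param n_boot Bootstrap replicates per scale (default 1000, >= 100).
#' @param seed Optional integer seed; same seed gives identical AU/BP.
#' @return A `dendrogram_result` for the original data whose `support` is
#'   a data frame with one row per internal node: `node`, `au`, `bp`,
#'   `v`, `c`, `flat` (TRUE when every BP(r) was 0 or 1 and the fit was
#'   skipped), plus attribute `bp_by_scale` (nodes x scales recovery
#'   frequencies).
#' @export
multiscale_bootstrap <- function(m, dist_fun = chord_distance,
                                 method = "upgma",
                                 scales = seq(0.5, 1.4, length.out = 10),
                                 n_boot = 1000L, seed = NULL) {
  m <- as.matrix(m)
  if (n_boot < 100L) stop("n_boot must be at least 100 per scale")
  if (!(any(scales < 1) && any(scales >= 1))) {
    stop("scales must span values below and above (or at) 1")
  }
  if (!is.null(seed)) set.seed(seed)
  S <- ncol(m)
  base <- hierarchical_cluster(dist_fun(m), method)
  keys <- .node_keys(base$hclust)
  sizes <- pmax(2L, as.integer(round(scales * S)))
  r_eff <- sizes / S

  counts <- matrix(0L, nrow = length(keys), ncol = length(scales))
  for (s in seq_along(scales)) {
    for (b in seq_len(n_boot)) {
      for (attempt in seq_len(100L)) {
        cols <- sample.int(S, sizes[s], replace = TRUE)
        mb <- m[, cols, drop = FALSE]
        ok <- all(rowSums(abs(mb)) > 0)
        if (ok) break
      }
      if (!ok) stop("bootstrap resample kept producing empty quadrat rows")
      kb <- .node_keys(hierarchical_cluster(dist_fun(mb), method)$hclust)
      hit <- keys %in% kb
      counts[hit, s] <- counts[hit, s] + 1L
    }
  }
  bp_scale <- counts / n_boot
  at1 <- which.min(abs(r_eff - 1))

  fit_node <- function(bp) {
    if (all(bp == 0)) return(c(au = 0, v = NA, c = NA, flat = 1))
    if (all(bp == 1)) return(c(au = 1, v = NA, c = NA, flat = 1))
    use <- bp > 0 & bp < 1
    if (sum(use) < 2L) {
      # no usable curvature information; fall back to the frequency near 1
      return(c(au = bp[at1], v = NA, c = NA, flat = 1))
    }
    r <- r_eff[use]
    zq <- stats::qnorm(1 - bp[use])
    wt <- n_boot * stats::dnorm(zq)^2 / (bp[use] * (1 - bp[use]))
    X <- cbind(sqrt(r), 1 / sqrt(r))
    cf <- tryCatch(stats::lm.wfit(X, zq, wt)$coefficients,
                   error = function(e) c(NA_real_, NA_real_))
    if (anyNA(cf)) return(c(au = bp[at1], v = NA, c = NA, flat = 1))
    c(au = 1 - stats::pnorm(cf[1L] - cf[2L]), v = cf[1L], c = cf[2L],
      flat = 0)
  }
  fits <- t(vapply(seq_along(keys), function(k) fit_node(bp_scale[k, ]),
                   numeric(4L)))
  support <- data.frame(node = seq_along(keys),
                        au = pmin(1, pmax(0, fits[, 1L])),
                        bp = bp_scale[, at1],
                        v = fits[, 2L],
                        c = fits[, 3L],
                        flat = fits[, 4L] == 1,
                        stringsAsFactors = FALSE)
  attr(support, "bp_by_scale") <- bp_scale
  attr(support, "scales") <- r_eff
  base$support <- support
  base
}

#' Cut a supported dendrogram into k groups
#'
#' @param dres A `dendrogram_result`.
#' @param k Number of groups.
#' @return Integer vector of group memberships named by leaf label.
#' @export
cut_groups <- function(dres, k) {
  stopifnot(inherits(dres, "dendrogram_result"))
  stats::cutree(dres$hclust, k = k)
}

#' Export a dendrogram as Newick with AU/BP node comments
#'
#' Internal nodes are labelled `"AU<au>_BP<bp>"` (values in percent) when
#' support has been computed.
#'
#' @param dres A `dendrogram_result`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(dres, path) {
  stopifnot(inherits(dres, "dendrogram_result"))
  phy <- ape::as.phylo(dres$hclust)
  if (!is.null(dres$support)) {
    # ape internal node i corresponds to hclust merge row via node heights;
    # map by matching clade leaf sets.
    hc_keys <- .node_keys(dres$hclust)
    lab <- character(phy$Nnode)
    for (nd in seq_len(phy$Nnode)) {
      tips <- sort(unlist(.phylo_clade_tips(phy, nd + length(phy$tip.label))))
      key <- paste(sort(match(phy$tip.label[tips], dres$hclust$labels)),
                   collapse = ",")
      hit <- match(key, hc_keys)
      lab[nd] <- if (!is.na(hit)) {
        sprintf("AU%.0f_BP%.0f", 100 * dres$support$au[hit],
                100 * dres$support$bp[hit])
      } else ""
    }
    phy$node.label <- lab
  }
  ape::write.tree(phy, file = path)
  invisible(path)
}

.phylo_clade_tips <- function(phy, node) {
  ntip <- length(phy$tip.label)
  kids <- phy$edge[phy$edge[, 1L] == node, 2L]
  unlist(lapply(kids, function(k) {
    if (k <= ntip) k else .phylo_clade_tips(phy, k)
  }))
}
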