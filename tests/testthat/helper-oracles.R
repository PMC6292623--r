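# Independent oracles and small fixture builders shared across the suite.
# The oracles deliberately use naive double loops so they cannot share a
# code path with the package implementation.

# Dense weight matrix from a neighbor_weights object.
dense_weights <- function(w) {
  W <- matrix(0, w$n, w$n)
  for (i in seq_len(w$n)) W[i, w$neighbors[[i]]] <- w$weights[[i]]
  W
}

# Literal double-sum local Moran: I_i = (x_i - xbar)/S_i^2 *
# sum_{j != i} w_ij (x_j - xbar), with the leave-one-out S_i^2 or the
# global second moment depending on `variant`.
oracle_local_moran <- function(x, W, variant = "anselin") {
  n <- length(x)
  xbar <- mean(x)
  I <- numeric(n)
  for (i in seq_len(n)) {
    s2 <- 0
    for (j in seq_len(n)) {
      if (j != i && variant == "anselin") s2 <- s2 + (x[j] - xbar)^2
    }
    s2 <- if (variant == "anselin") s2 / (n - 1) else sum((x - xbar)^2) / n
    acc <- 0
    for (j in seq_len(n)) {
      if (j != i) acc <- acc + W[i, j] * (x[j] - xbar)
    }
    I[i] <- (x[i] - xbar) / s2 * acc
  }
  I
}

# Cophenetic distances extracted by explicit recursion over the merge
# tree: the cophenetic distance of two leaves is the height of their
# lowest common internal node.
oracle_cophenetic <- function(hc) {
  n <- length(hc$order)
  members <- vector("list", n - 1L)
  D <- matrix(0, n, n)
  for (k in seq_len(n - 1L)) {
    sides <- lapply(hc$merge[k, ], function(s) {
      if (s < 0) -s else members[[s]]
    })
    members[[k]] <- sort(unlist(sides))
    for (a in sides[[1L]]) {
      for (b in sides[[2L]]) {
        D[a, b] <- D[b, a] <- hc$height[k]
      }
    }
  }
  stats::as.dist(D)
}

# Minimal occurrence fixture: one transect, three quadrats, two species.
toy_records <- function() {
  data.frame(
    transect = c("T1", "T1", "T1"),
    quadrat = c(1L, 2L, 2L),
    species = c("Alpha alba", "Alpha alba", "Beta bella"),
    habit = c("tree", "tree", "shrub"),
    count = c(2L, 1L, 3L),
    stringsAsFactors = FALSE
  )
}

# Two-transect fixture with an obvious planted run in T1 (positions 5-7)
# and a flat T2; several species so ordination and clustering have
# composition to work with.
fixture_two_transects <- function() {
  sp <- sprintf("sp%02d", 1:6)
  habit <- c("tree", "tree", "shrub", "shrub", "palm", "vine")
  n1 <- c(1, 1, 1, 1, 8, 9, 8, 1, 1, 1)
  n2 <- c(1, 1, 2, 1, 1, 2, 1, 1, 2, 1)
  rows <- list()
  set.seed(99)
  add_quadrat <- function(tid, q, total) {
    cnt <- as.integer(stats::rmultinom(1, total, rep(1 / 6, 6)))
    hit <- which(cnt > 0)
    data.frame(transect = tid, quadrat = q, species = sp[hit],
               habit = habit[hit], count = cnt[hit],
               stringsAsFactors = FALSE)
  }
  for (q in seq_along(n1)) rows[[length(rows) + 1L]] <- add_quadrat("T1", q, n1[q])
  for (q in seq_along(n2)) rows[[length(rows) + 1L]] <- add_quadrat("T2", q, n2[q])
  records <- do.call(rbind, rows)
  layouts <- transect_layouts(c("T1", "T2"), n_quadrats = 10,
                              quadrat_area = 4,
                              lithology = c("limestone", "alluvium"))
  list(records = records, layouts = layouts)
}

# Total-randomization z-score and one-sided p recomputed from first
# principles (moment-variant statistic), independent of the package path.
oracle_total_z <- function(x, W) {
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  m4 <- sum(z^4) / n
  b2 <- m4 / m2^2
  I <- oracle_local_moran(x, W, variant = "moment")
  out <- data.frame(I = I, z = NA_real_, p = NA_real_)
  for (i in seq_len(n)) {
    wi <- sum(W[i, ])
    wi2 <- sum(W[i, ]^2)
    e <- -wi / (n - 1)
    ei2 <- wi2 * (n - b2) / (n - 1) +
      (wi^2 - wi2) * (2 * b2 - n) / ((n - 1) * (n - 2))
    sdv <- sqrt(ei2 - e^2)
    out$z[i] <- (I[i] - e) / sdv
    out$p[i] <- stats::pnorm(out$z[i], lower.tail = FALSE)
  }
  out
}
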