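# Local Moran's I, analytic and conditional-permutation inference,
# Bonferroni correction, LISA classification and Moran-scatterplot data.
#
# The statistic for entity i is
#   I_i = (x_i - xbar) / S_i^2 * sum_{j != i} w_ij (x_j - xbar)
# with, in the "anselin" variant,
#   S_i^2 = sum_{j != i} (x_j - xbar)^2 / (n - 1)
# (the denominator excludes entity i and divides by n - 1). The "moment"
# variant replaces S_i^2 by the second moment m2 = sum_j (x_j - xbar)^2 / n
# taken over all entities, the convention of most spatial-statistics
# software; it is exposed for cross-checking.

.moran_s2 <- function(z, variant, n) {
  ss <- sum(z^2)
  switch(variant,
         anselin = (ss - z^2) / (n - 1),
         moment = rep(ss / n, length(z)),
         stop("unknown variant '", variant, "'"))
}

#' Local Moran's I
#'
#' Computes the per-entity local Moran statistic of a numeric variable under
#' sparse row-standardized weights. The mean, sample size and scale terms
#' are taken over the entities supplied here (the "scope"); for
#' transect-wise analysis call it once per transect.
#'
#' @param x Numeric vector of values (here: per-quadrat density dN).
#' @param weights A `neighbor_weights` object over the same entities.
#' @param variant `"anselin"` (default): the leave-one-out scale
#'   `S_i^2 = sum_{j != i}(x_j - xbar)^2 / (n - 1)`; `"moment"`: the global
#'   second moment `m2 = sum(z^2)/n`.
#' @return A `local_moran` object: list with `I`, `x`, `z` (centred values),
#'   `xbar`, `s2`, `lag` (lag of raw x), `lag_z` (lag of centred x), `n`,
#'   `variant` and the `weights`.
#' @export
local_moran <- function(x, weights, variant = c("anselin", "moment")) {
  variant <- match.arg(variant)
  stopifnot(inherits(weights, "neighbor_weights"))
  n <- length(x)
  if (n < 3L) stop("local Moran's I needs at least 3 entities in scope")
  if (length(x) != weights$n) stop("x and weights disagree on the number of entities")
  if (anyNA(x)) stop("x contains missing values")
  xbar <- mean(x)
  z <- x - xbar
  if (all(z == 0)) stop("statistic undefined for constant density (zero variance in scope)")
  s2 <- .moran_s2(z, variant, n)
  if (any(s2 <= 0)) {
    stop("scale term S_i^2 is zero for entity ", which(s2 <= 0)[1L],
         "; statistic undefined")
  }
  lag_z <- spatial_lag(weights, z)
  structure(list(I = z / s2 * lag_z, x = x, z = z, xbar = xbar, s2 = s2,
                 lag = spatial_lag(weights, x), lag_z = lag_z, n = n,
                 variant = variant, weights = weights),
            class = "local_moran")
}

# Null moments of I_i under conditional randomization: x_i is held at its
# observed value and the remaining n - 1 values are randomly permuted over
# the other positions. The neighbour values are then a simple random sample
# without replacement from z[-i], and because the scale term is fixed given
# z_i, the moments are exact for both variants.
.moments_conditional <- function(lm_obj) {
  z <- lm_obj$z
  n <- lm_obj$n
  w <- lm_obj$weights
  e <- v <- numeric(n)
  for (i in seq_len(n)) {
    wi <- w$weights[[i]]
    Wi <- sum(wi)
    Wi2 <- sum(wi^2)
    others <- z[-i]
    N <- n - 1L
    mu <- mean(others)
    sig2 <- sum((others - mu)^2) / N
    ci <- z[i] / lm_obj$s2[i]
    e[i] <- ci * Wi * mu
    # Var of a weighted sum under sampling without replacement:
    # sig2 * (N * sum(w^2) - (sum w)^2) / (N - 1)
    v[i] <- ci^2 * sig2 * (N * Wi2 - Wi^2) / (N - 1)
  }
  list(expectation = e, variance = pmax(v, 0))
}

# Null moments under total randomization (all n values permuted), the
# closed forms of Anselin (1995) / Sokal et al. (1998). Exact for the
# "moment" variant; for the "anselin" variant they are a close large-n
# approximation because the leave-one-out scale varies with the value
# placed at i.
.moments_total <- function(lm_obj) {
  z <- lm_obj$z
  n <- lm_obj$n
  w <- lm_obj$weights
  m2 <- sum(z^2) / n
  m4 <- sum(z^4) / n
  b2 <- m4 / m2^2
  e <- v <- numeric(n)
  for (i in seq_len(n)) {
    wi <- w$weights[[i]]
    Wi <- sum(wi)
    Wi2 <- sum(wi^2)
    Wikh2 <- Wi^2 - Wi2 # sum over ordered pairs k != h of w_ik w_ih
    e[i] <- -Wi / (n - 1)
    ei2 <- Wi2 * (n - b2) / (n - 1) +
      Wikh2 * (2 * b2 - n) / ((n - 1) * (n - 2))
    v[i] <- ei2 - e[i]^2
  }
  list(expectation = e, variance = pmax(v, 0))
}

#' Analytic significance test for local Moran's I
#'
#' Standardizes each I_i by its null moments and reports a one-sided
#' p-value `Pr(Z > z)` for positive spatial association, the alternative of
#' interest when hunting High-High clusters.
#'
#' @param lm_obj A `local_moran` object.
#' @param null `"total"` (default): closed-form moments under total
#'   randomization of all values, `E(I_i) = -sum_j(w_ij) / (n - 1)` with
#'   the matching second moment (exact for the `"moment"` statistic
#'   variant, a close approximation for `"anselin"`);  `"conditional"`:
#'   moments under conditional randomization holding `x_i` fixed, exact
#'   for both variants and matching [local_moran_perm()].
#' @return Data frame with `I`, `expectation`, `sd`, `z`, `p` per entity.
#' @export
local_moran_test <- function(lm_obj, null = c("total", "conditional")) {
  null <- match.arg(null)
  stopifnot(inherits(lm_obj, "local_moran"))
  mom <- switch(null,
                conditional = .moments_conditional(lm_obj),
                total = .moments_total(lm_obj))
  sdv <- sqrt(mom$variance)
  zsc <- ifelse(sdv > 0, (lm_obj$I - mom$expectation) / sdv, 0)
  data.frame(I = lm_obj$I,
             expectation = mom$expectation,
             sd = sdv,
             z = zsc,
             p = stats::pnorm(zsc, lower.tail = FALSE))
}

#' Conditional permutation test for local Moran's I
#'
#' For each entity i, holds x_i fixed and redraws its neighbours' values
#' from the remaining entities without replacement `n_perm` times; the
#' pseudo p-value is `(1 + #{I_i^perm >= I_i^obs}) / (1 + n_perm)`.
#'
#' @param x Numeric vector of values.
#' @param weights A `neighbor_weights` object.
#' @param n_perm Number of conditional permutations (>= 99).
#' @param seed Optional integer seed; the same seed reproduces the same
#'   p-values exactly.
#' @param variant Statistic variant, see [local_moran()].
#' @param entities Integer indices of the entities to test (default all).
#' @return Data frame with `entity`, `I` and `p`, one row per tested
#'   entity.
#' @export
local_moran_perm <- function(x, weights, n_perm = 999L, seed = NULL,
                             variant = c("anselin", "moment"),
                             entities = seq_along(x)) {
  variant <- match.arg(variant)
  if (n_perm < 99L) stop("n_perm must be at least 99")
  if (!is.null(seed)) set.seed(seed)
  obs <- local_moran(x, weights, variant)
  n <- obs$n
  p <- numeric(length(entities))
  for (k_i in seq_along(entities)) {
    i <- entities[k_i]
    others <- obs$z[-i]
    wi <- weights$weights[[i]]
    deg <- length(wi)
    ci <- obs$z[i] / obs$s2[i]
    iperm <- vapply(seq_len(n_perm), function(k) {
      ci * sum(wi * others[sample.int(n - 1L, deg)])
    }, numeric(1L))
    p[k_i] <- (1 + sum(iperm >= obs$I[i])) / (1 + n_perm)
  }
  data.frame(entity = entities, I = obs$I[entities], p = p)
}

#' Bonferroni adjustment
#'
#' @param p Vector of raw p-values.
#' @param m Number of tests in the family (>= 1).
#' @return `pmin(1, m * p)`.
#' @export
adjust_bonferroni <- function(p, m) {
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * p)
}

#' Classify quadrats into LISA cluster classes
#'
#' Significant entities are labelled by the quadrant of
#' `(x - xbar, lag - xbar)`: High-High, Low-Low, High-Low or Low-High;
#' everything else is NS. Interior entities are significant when
#' `p_adj < alpha`. Transect endpoints, which have a single neighbour and
#' are prone to edge artefacts, face a stricter rule: `p_adj <
#' alpha_endpoint` and their neighbour's value must exceed the scope mean.
#'
#' @param x Values (dN) per entity.
#' @param lag Spatial lag of `x`.
#' @param p_adj Adjusted p-values.
#' @param alpha Significance level for interior entities (default 0.05).
#' @param alpha_endpoint Stricter level for endpoints (default 0.01).
#' @param is_endpoint Logical vector flagging endpoints.
#' @param neighbor_high Logical vector: for endpoints, is the single
#'   neighbour's value above the scope mean? Ignored for interior entities;
#'   may be NA there.
#' @param xbar Scope mean used for centring (default `mean(x)`).
#' @return Factor with levels HH, LL, HL, LH, NS.
#' @export
classify_lisa <- function(x, lag, p_adj, alpha = 0.05, alpha_endpoint = 0.01,
                          is_endpoint = rep(FALSE, length(x)),
                          neighbor_high = rep(NA, length(x)),
                          xbar = mean(x)) {
  stopifnot(length(lag) == length(x), length(p_adj) == length(x))
  if (!(alpha_endpoint > 0 && alpha_endpoint <= alpha && alpha < 1)) {
    stop("need 0 < alpha_endpoint <= alpha < 1")
  }
  sig <- ifelse(is_endpoint,
                p_adj < alpha_endpoint & !is.na(neighbor_high) & neighbor_high,
                p_adj < alpha)
  dx <- x - xbar
  dl <- lag - xbar
  cls <- rep("NS", length(x))
  cls[sig & dx > 0 & dl > 0] <- "HH"
  cls[sig & dx < 0 & dl < 0] <- "LL"
  cls[sig & dx > 0 & dl < 0] <- "HL"
  cls[sig & dx < 0 & dl > 0] <- "LH"
  ties <- sig & (dx == 0 | dl == 0)
  if (any(ties)) {
    warning("entity exactly at the scope mean is significant but has no ",
            "quadrant; classified NS")
  }
  factor(cls, levels = c("HH", "LL", "HL", "LH", "NS"))
}

#' Moran scatterplot data
#'
#' Returns the centred pairs `(x - xbar, W(x - xbar))` and the
#' least-squares slope through the origin, which equals Moran's I as a
#' regression coefficient of the lag on the value.
#'
#' @param x Numeric values.
#' @param weights A `neighbor_weights` object.
#' @param xbar Optional scope mean (default `mean(x)`).
#' @return List with `points` (data frame `z`, `lag_z`) and `slope`.
#' @export
moran_scatter_data <- function(x, weights, xbar = mean(x)) {
  z <- x - xbar
  if (all(z == 0)) stop("zero variance in scope; scatterplot undefined")
  lag_z <- spatial_lag(weights, z)
  list(points = data.frame(z = z, lag_z = lag_z),
       slope = sum(z * lag_z) / sum(z^2))
}

#' Full LISA table for a community matrix
#'
#' Runs the whole local-Moran workflow over per-quadrat density: builds
#' linear-contiguity weights per transect, computes I_i, tests it
#' (analytically or by conditional permutation), applies Bonferroni
#' correction and classifies every quadrat. By default the scope of the
#' mean, sample size and scale term is each transect; `scope = "pooled"`
#' uses the whole sample as one scope (weights stay within transects).
#'
#' @param cm A `community_matrix`.
#' @param alpha,alpha_endpoint Significance levels (see [classify_lisa()]).
#' @param scope `"transect"` (default) or `"pooled"`.
#' @param inference `"analytic"` (default) or `"permutation"`.
#' @param variant Statistic variant, see [local_moran()].
#' @param null Analytic null, see [local_moran_test()].
#' @param n_perm Permutations when `inference = "permutation"`.
#' @param seed Seed for permutation inference.
#' @param bonferroni_m Multiplicity; default is the number of tests in the
#'   scope (quadrats per transect, or all quadrats when pooled).
#' @return A `lisa_table` data frame with one row per quadrat: `transect`,
#'   `quadrat`, `position`, `is_endpoint`, `N`, `dN`, `lag_dN`, `Ii`,
#'   `expectation`, `z`, `p_raw`, `p_adj`, `lisa_class`.
#' @export
local_moran_table <- function(cm, alpha = 0.05, alpha_endpoint = 0.01,
                              scope = c("transect", "pooled"),
                              inference = c("analytic", "permutation"),
                              variant = c("anselin", "moment"),
                              null = c("total", "conditional"),
                              n_perm = 999L, seed = NULL,
                              bonferroni_m = NULL) {
  scope <- match.arg(scope)
  inference <- match.arg(inference)
  variant <- match.arg(variant)
  null <- match.arg(null)
  d <- densities(cm)
  lay <- attr(cm, "layouts")
  if (!is.null(seed)) set.seed(seed)

  if (scope == "pooled") {
    pooled_mean <- mean(d$dN)
    pooled_z <- d$dN - pooled_mean
    pooled_ss <- sum(pooled_z^2)
    pooled_n <- nrow(d)
    if (pooled_ss == 0) stop("statistic undefined for constant density (zero variance in scope)")
  }

  out <- vector("list", nrow(lay))
  for (t in seq_len(nrow(lay))) {
    tid <- lay$transect[t]
    rows <- which(d$transect == tid)
    x <- d$dN[rows]
    n <- length(x)
    w <- row_standardize(linear_contiguity(n))
    is_end <- c(TRUE, rep(FALSE, n - 2L), TRUE)

    if (scope == "transect") {
      lm_obj <- local_moran(x, w, variant)
      xbar <- lm_obj$xbar
      m_tests <- if (is.null(bonferroni_m)) n else bonferroni_m
    } else {
      xbar <- pooled_mean
      z <- x - xbar
      s2 <- switch(variant,
                   anselin = (pooled_ss - z^2) / (pooled_n - 1),
                   moment = rep(pooled_ss / pooled_n, n))
      lag_z <- spatial_lag(w, z)
      lm_obj <- structure(list(I = z / s2 * lag_z, x = x, z = z, xbar = xbar,
                               s2 = s2, lag = spatial_lag(w, x),
                               lag_z = lag_z, n = n, variant = variant,
                               weights = w,
                               pooled = list(z_all = pooled_z, n = pooled_n,
                                             rows = rows)),
                          class = "local_moran")
      m_tests <- if (is.null(bonferroni_m)) pooled_n else bonferroni_m
    }

    if (inference == "analytic") {
      tst <- if (scope == "transect") {
        local_moran_test(lm_obj, null)
      } else {
        .pooled_conditional_test(lm_obj)
      }
      p_raw <- tst$p
      e_i <- tst$expectation
      z_i <- tst$z
    } else {
      prm <- if (scope == "transect") {
        local_moran_perm(x, w, n_perm = n_perm, variant = variant)
      } else {
        .pooled_perm_test(lm_obj, n_perm)
      }
      p_raw <- prm$p
      e_i <- rep(NA_real_, n)
      z_i <- rep(NA_real_, n)
    }

    p_adj <- adjust_bonferroni(p_raw, m_tests)
    nb_high <- vapply(seq_len(n), function(i) {
      all(x[w$neighbors[[i]]] > xbar)
    }, logical(1L))
    cls <- classify_lisa(x, lm_obj$lag, p_adj, alpha, alpha_endpoint,
                         is_endpoint = is_end, neighbor_high = nb_high,
                         xbar = xbar)
    out[[t]] <- data.frame(transect = tid,
                           quadrat = sprintf("Q%02d", seq_len(n)),
                           position = seq_len(n),
                           is_endpoint = is_end,
                           N = d$N[rows],
                           dN = x,
                           lag_dN = lm_obj$lag,
                           Ii = lm_obj$I,
                           expectation = e_i,
                           z = z_i,
                           p_raw = p_raw,
                           p_adj = p_adj,
                           lisa_class = cls,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- .quadrat_key(res$transect, res$position)
  attr(res, "alpha") <- alpha
  attr(res, "alpha_endpoint") <- alpha_endpoint
  attr(res, "scope") <- scope
  attr(res, "inference") <- inference
  class(res) <- c("lisa_table", "data.frame")
  res
}

# Conditional analytic moments when the scope is the pooled sample: the
# neighbour values of entity i are a simple random sample from the other
# pooled_n - 1 centred values.
.pooled_conditional_test <- function(lm_obj) {
  pool <- lm_obj$pooled
  z_all <- pool$z_all
  N <- pool$n - 1L
  n <- lm_obj$n
  e <- v <- numeric(n)
  for (i in seq_len(n)) {
    wi <- lm_obj$weights$weights[[i]]
    Wi <- sum(wi)
    Wi2 <- sum(wi^2)
    zi <- lm_obj$z[i]
    others <- z_all[-pool$rows[i]]
    mu <- mean(others)
    sig2 <- sum((others - mu)^2) / N
    ci <- zi / lm_obj$s2[i]
    e[i] <- ci * Wi * mu
    v[i] <- ci^2 * sig2 * (N * Wi2 - Wi^2) / (N - 1)
  }
  sdv <- sqrt(pmax(v, 0))
  zsc <- ifelse(sdv > 0, (lm_obj$I - e) / sdv, 0)
  data.frame(I = lm_obj$I, expectation = e, sd = sdv, z = zsc,
             p = stats::pnorm(zsc, lower.tail = FALSE))
}

.pooled_perm_test <- function(lm_obj, n_perm) {
  pool <- lm_obj$pooled
  n <- lm_obj$n
  p <- numeric(n)
  for (i in seq_len(n)) {
    others <- pool$z_all[-pool$rows[i]]
    wi <- lm_obj$weights$weights[[i]]
    deg <- length(wi)
    ci <- lm_obj$z[i] / lm_obj$s2[i]
    iperm <- vapply(seq_len(n_perm), function(k) {
      ci * sum(wi * others[sample.int(length(others), deg)])
    }, numeric(1L))
    p[i] <- (1 + sum(iperm >= lm_obj$I[i])) / (1 + n_perm)
  }
  data.frame(I = lm_obj$I, p = p)
}

#' Moran-scatterplot points and slopes for every transect
#'
#' @param cm A `community_matrix`.
#' @param scope Scope of the centring mean, as in [local_moran_table()].
#' @return List with `points` (data frame: transect, position, z, lag_z)
#'   and `slopes` (data frame: transect, slope).
#' @export
moran_scatter_table <- function(cm, scope = c("transect", "pooled")) {
  scope <- match.arg(scope)
  d <- densities(cm)
  lay <- attr(cm, "layouts")
  pooled_mean <- mean(d$dN)
  pts <- vector("list", nrow(lay))
  slp <- numeric(nrow(lay))
  for (t in seq_len(nrow(lay))) {
    tid <- lay$transect[t]
    rows <- which(d$transect == tid)
    x <- d$dN[rows]
    w <- row_standardize(linear_contiguity(length(x)))
    xbar <- if (scope == "transect") mean(x) else pooled_mean
    sc <- moran_scatter_data(x, w, xbar = xbar)
    pts[[t]] <- data.frame(transect = tid, position = seq_along(x),
                           sc$points, stringsAsFactors = FALSE)
    slp[t] <- sc$slope
  }
  list(points = do.call(rbind, pts),
       slopes = data.frame(transect = lay$transect, slope = slp,
                           stringsAsFactors = FALSE))
}
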