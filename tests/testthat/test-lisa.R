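test_that("local Moran reproduces the hand-computed three-quadrat case", {
  w <- row_standardize(linear_contiguity(3))
  lm3 <- local_moran(c(0, 0, 4), w)
  # xbar = 4/3, S_3^2 = 16/9, lag term = -(4/3) => I_3 = -2
  expect_equal(lm3$I[3], -2, tolerance = 1e-12)
  expect_equal(lm3$I, oracle_local_moran(c(0, 0, 4), dense_weights(w)),
               tolerance = 1e-12)
  # a value exactly at the mean has I = 0
  x <- c(1, 2, 3)
  expect_equal(local_moran(x, w)$I[2], 0)
  expect_error(local_moran(rep(2, 3), w), "constant density")
  expect_error(local_moran(c(1, 2), row_standardize(linear_contiguity(2))),
               "at least 3")
})

test_that("vectorized statistic equals the literal double sum", {
  set.seed(42)
  w <- row_standardize(linear_contiguity(25))
  W <- dense_weights(w)
  for (rep in 1:50) {
    x <- rpois(25, 4) / 4
    if (stats::var(x) == 0) next
    for (v in c("anselin", "moment")) {
      expect_equal(local_moran(x, w, variant = v)$I,
                   oracle_local_moran(x, W, variant = v),
                   tolerance = 1e-12)
    }
  }
})

test_that("total-randomization moments match Monte-Carlo permutations", {
  set.seed(101)
  x <- rpois(25, 4) / 4
  w <- row_standardize(linear_contiguity(25))
  lm_obj <- local_moran(x, w, variant = "moment")
  tst <- local_moran_test(lm_obj, null = "total")
  i <- 13L
  expect_equal(tst$expectation[i], -1 / 24, tolerance = 1e-12)

  # permute all values and recompute I_i for the interior quadrat; the
  # empirical mean and sd must match the closed forms
  z <- x - mean(x)
  m2 <- sum(z^2) / 25
  nperm <- 1e5
  iperm <- vapply(seq_len(nperm), function(k) {
    trip <- sample.int(25, 3)            # values landing on i and its neighbours
    z[trip[1]] * (0.5 * z[trip[2]] + 0.5 * z[trip[3]]) / m2
  }, numeric(1))
  expect_lt(abs(mean(iperm) - (-1 / 24)), 4 * stats::sd(iperm) / sqrt(nperm))
  expect_lt(abs(stats::sd(iperm) - tst$sd[i]) / tst$sd[i], 0.02)
})

test_that("conditional moments match conditional permutations", {
  set.seed(202)
  x <- rpois(25, 4) / 4
  w <- row_standardize(linear_contiguity(25))
  lm_obj <- local_moran(x, w)
  tst <- local_moran_test(lm_obj, null = "conditional")
  i <- 7L
  z <- lm_obj$z
  others <- z[-i]
  ci <- z[i] / lm_obj$s2[i]
  nperm <- 1e5
  iperm <- vapply(seq_len(nperm), function(k) {
    pick <- others[sample.int(24, 2)]
    ci * 0.5 * sum(pick)
  }, numeric(1))
  expect_lt(abs(mean(iperm) - tst$expectation[i]),
            4 * stats::sd(iperm) / sqrt(nperm) + 1e-12)
  expect_lt(abs(stats::sd(iperm) - tst$sd[i]) / tst$sd[i], 0.02)
})

test_that("a centred entity gets z = 0 and one-sided p = 0.5", {
  x <- c(1, 2, 3, 4, 5)
  w <- row_standardize(linear_contiguity(5))
  lm_obj <- local_moran(x, w)
  tst <- local_moran_test(lm_obj, null = "conditional")
  expect_equal(lm_obj$I[3], 0)          # x_3 is exactly the mean
  expect_equal(tst$z[3], 0)
  expect_equal(tst$p[3], 0.5)
})

test_that("permutation p-values are deterministic and handle degeneracy", {
  x <- c(5, rep(1, 9))
  w <- row_standardize(linear_contiguity(10))
  p1 <- local_moran_perm(x, w, n_perm = 199, seed = 5)
  p2 <- local_moran_perm(x, w, n_perm = 199, seed = 5)
  expect_identical(p1, p2)
  # entity 1: all other values constant, so every permuted I equals the
  # observed one and the pseudo-p is 1
  expect_equal(p1$p[1], 1)
  expect_error(local_moran_perm(x, w, n_perm = 50), "at least 99")
})

test_that("analytic conditional and permutation p-values agree on null data", {
  set.seed(303)
  x <- rnorm(25)
  w <- row_standardize(linear_contiguity(25))
  tst <- local_moran_test(local_moran(x, w), null = "conditional")
  prm <- local_moran_perm(x, w, n_perm = 9999, seed = 42)
  # interior quadrats: two-neighbour lag, where the normal approximation
  # to the conditional permutation distribution is accurate
  interior <- 2:24
  expect_lt(max(abs(tst$p[interior] - prm$p[interior])), 0.03)
  # endpoints average a single permuted value; allow a coarser agreement
  expect_lt(max(abs(tst$p[c(1, 25)] - prm$p[c(1, 25)])), 0.15)
})

test_that("Bonferroni adjustment multiplies and clamps", {
  expect_equal(adjust_bonferroni(0.002, 25), 0.05)
  expect_equal(adjust_bonferroni(0.2, 25), 1.0)
  expect_equal(adjust_bonferroni(c(0.1, 0.7), 1), c(0.1, 0.7))
  expect_error(adjust_bonferroni(0.1, 0), ">= 1")
})

test_that("LISA classification follows the quadrant and endpoint rules", {
  x <- c(9, 1, 1, 1, 8)
  lag <- c(7, 2, 1, 2, 1)
  xbar <- mean(x)                       # 4
  # interior HH at alpha = 0.05
  cls <- classify_lisa(x, lag, p_adj = c(0.5, 0.5, 0.5, 0.5, 0.5),
                       is_endpoint = c(TRUE, FALSE, FALSE, FALSE, TRUE))
  expect_true(all(cls == "NS"))
  cls <- classify_lisa(x, lag, p_adj = c(0.001, 0.01, 0.5, 0.01, 0.001),
                       is_endpoint = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                       neighbor_high = c(FALSE, NA, NA, NA, FALSE))
  # endpoints blocked by the neighbour-high rule despite tiny p
  expect_equal(as.character(cls), c("NS", "LL", "NS", "LL", "NS"))
  cls <- classify_lisa(x, lag, p_adj = c(0.001, 0.5, 0.5, 0.5, 0.02),
                       is_endpoint = c(TRUE, FALSE, FALSE, FALSE, TRUE),
                       neighbor_high = c(TRUE, NA, NA, NA, TRUE))
  # endpoint 1 passes alpha_endpoint and its neighbour is high => HH;
  # endpoint 5 has p = 0.02 > 0.01 => NS
  expect_equal(as.character(cls), c("HH", "NS", "NS", "NS", "NS"))
  # High-Low quadrant
  cls <- classify_lisa(c(9, 1, 1, 1, 1), c(1, 5, 1, 1, 1),
                       p_adj = rep(0.001, 5),
                       is_endpoint = rep(FALSE, 5))
  expect_equal(as.character(cls)[1], "HL")
  expect_equal(as.character(cls)[2], "LH")
  # value exactly at the mean: significant but unclassifiable
  expect_warning(
    cls <- classify_lisa(c(2, 2, 2, 1, 3), c(2.5, 2, 2, 2, 2),
                         p_adj = rep(0.001, 5), is_endpoint = rep(FALSE, 5)),
    "quadrant")
  expect_equal(as.character(cls)[1], "NS")
})

test_that("Moran scatter slope is the through-origin regression of lag on value", {
  w <- row_standardize(linear_contiguity(25))
  set.seed(9)
  x <- rnorm(25)
  sc <- moran_scatter_data(x, w)
  fit <- stats::lm(sc$points$lag_z ~ 0 + sc$points$z)
  expect_equal(sc$slope, unname(stats::coef(fit)[1]), tolerance = 1e-12)
  # proportional lag: slope recovers the factor exactly
  z <- x - mean(x)
  expect_equal(moran_scatter_data(z * 2 + mean(x),
                                  w)$slope / moran_scatter_data(x, w)$slope,
               1, tolerance = 1e-10)
  expect_error(moran_scatter_data(rep(1, 25), w), "zero variance")
})

test_that("scope statistics are invariant under permutation of values", {
  set.seed(15)
  x <- rpois(25, 4) / 4
  w <- row_standardize(linear_contiguity(25))
  a <- local_moran(x, w)
  b <- local_moran(sample(x), w)
  expect_equal(a$xbar, b$xbar)
  expect_equal(sum(a$z^2), sum(b$z^2), tolerance = 1e-12)
})

test_that("raising a quadrat and its neighbours never lowers I_i", {
  w <- row_standardize(linear_contiguity(9))
  base <- rep(1, 9)                      # others stay below the mean
  i <- 5L
  prev <- -Inf
  for (bump in seq(0.5, 4, by = 0.5)) {
    x <- base
    x[c(i - 1, i, i + 1)] <- x[c(i - 1, i, i + 1)] + bump
    ii <- local_moran(x, w)$I[i]
    expect_gte(ii, prev - 1e-12)
    prev <- ii
  }
})

test_that("the full LISA table is coherent across scopes and inference", {
  fx <- fixture_two_transects()
  cm <- build_community_matrix(fx$records, fx$layouts)
  for (scope in c("transect", "pooled")) {
    lt <- local_moran_table(cm, scope = scope)
    expect_s3_class(lt, "lisa_table")
    expect_equal(nrow(lt), 20L)
    expect_true(all(lt$p_adj >= lt$p_raw - 1e-15))
    expect_true(all(lt$p_raw >= 0 & lt$p_raw <= 1))
    hh <- lt[lt$lisa_class == "HH", ]
    if (nrow(hh) > 0) {
      for (t in unique(hh$transect)) {
        xbar <- if (scope == "transect") {
          mean(lt$dN[lt$transect == t])
        } else mean(lt$dN)
        expect_true(all(hh$dN[hh$transect == t] > xbar))
        expect_true(all(hh$lag_dN[hh$transect == t] > xbar))
      }
    }
  }
  ltp <- local_moran_table(cm, inference = "permutation", n_perm = 199,
                           seed = 3)
  ltp2 <- local_moran_table(cm, inference = "permutation", n_perm = 199,
                            seed = 3)
  expect_identical(ltp$p_raw, ltp2$p_raw)
})
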