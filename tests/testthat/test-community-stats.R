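make_group_fixture <- function() {
  # 2 transects x 5 quadrats, counts chosen so group arithmetic is easy
  sp <- c("Acacia a", "Beta b", "Cactus c", "Delta d", "Epsilon e")
  habit <- c("tree", "shrub", "cactus", "palm", "vine")
  rows <- list()
  add <- function(t, q, s, n) {
    rows[[length(rows) + 1L]] <<- data.frame(
      transect = t, quadrat = q, species = sp[s], habit = habit[s],
      count = n, stringsAsFactors = FALSE)
  }
  add("T1", 1, 2, 4)  # shrub count 4
  add("T1", 2, 2, 8)  # shrub count 8
  add("T1", 3, 1, 2)
  add("T2", 1, 4, 3)
  add("T2", 2, 5, 1)
  add("T2", 4, 3, 2)
  rec <- do.call(rbind, rows)
  cm <- build_community_matrix(rec, transect_layouts(c("T1", "T2"), 5, 4))
  cm
}

test_that("partitioning is disjoint and exhaustive", {
  fx <- fixture_two_transects()
  cm <- build_community_matrix(fx$records, fx$layouts)
  lt <- local_moran_table(cm)
  g <- partition_groups(lt)
  expect_length(intersect(g$hh, g$rest), 0)
  expect_setequal(c(g$hh, g$rest), rownames(lt))
  expect_true(all(lt[g$hh, "lisa_class"] == "HH"))
})

test_that("group summaries reproduce hand-computed density moments", {
  cm <- make_group_fixture()
  s <- summarize_group(cm, c("T1:Q01", "T1:Q02"), "pair")
  # shrub densities 4/4 = 1 and 8/4 = 2: mean 1.5, sd = 0.7071, SE = 0.5
  row <- s$density[s$density$habit == "shrubs", ]
  expect_equal(row$mean, 1.5)
  expect_equal(row$se, 0.5, tolerance = 1e-12)
  expect_equal(s$n_individuals, 12)
  expect_equal(s$area, 8)
  # only shrubs present: percentage 100, everything else 0
  expect_equal(unname(s$habit_percent["shrubs"]), 100)
  expect_equal(unname(s$habit_percent["trees"]), 0)
  expect_error(summarize_group(cm, character(0)), "empty")
})

test_that("habit percentages sum to 100 and groups add up", {
  cm <- make_group_fixture()
  all_q <- rownames(cm)
  a <- all_q[1:4]
  b <- setdiff(all_q, a)
  sa <- summarize_group(cm, a, "a")
  sb <- summarize_group(cm, b, "b")
  se <- summarize_group(cm, all_q, "entire")
  expect_equal(sum(sa$habit_percent), 100, tolerance = 0.1)
  expect_equal(se$n_individuals, sa$n_individuals + sb$n_individuals)
  expect_equal(se$n_quadrats, sa$n_quadrats + sb$n_quadrats)
  expect_equal(se$area, sa$area + sb$area)
  # group mean density equals total individuals / total area when areas
  # are equal across quadrats
  expect_equal(se$density$mean[se$density$habit == "all"],
               se$n_individuals / se$area, tolerance = 1e-12)
})

test_that("density ratios divide group means and guard the denominator", {
  expect_equal(round(density_ratio(c(shrubs = 0.986), c(shrubs = 0.338),
                                   "shrubs"), 1), 2.9)
  cm <- make_group_fixture()
  s <- summarize_group(cm, rownames(cm), "entire")
  expect_equal(density_ratio(s, s, "all"), 1.0)
  expect_error(density_ratio(c(all = 1), c(all = 0), "all"), "not positive")
})

test_that("t-test wrapper matches the textbook pooled closed form", {
  a <- c(1, 2, 3)
  b <- a + 10
  tt <- ttest_density(a, b, var_equal = TRUE)
  # pooled s^2 = 1, t = (mean(a) - mean(b)) / sqrt(s2 * (1/3 + 1/3))
  expect_equal(tt$t, -10 / sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(tt$df, 4)
  tt0 <- ttest_density(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tt0$t, 0)
  expect_equal(tt0$p, 1)
  expect_error(ttest_density(1, c(1, 2)), "at least 2")
  # Welch df never exceeds the pooled df
  set.seed(8)
  for (k in 1:10) {
    x <- rnorm(12)
    y <- rnorm(20, sd = 4)
    expect_lte(ttest_density(x, y)$df,
               ttest_density(x, y, var_equal = TRUE)$df)
  }
})

test_that("rank-abundance filters by occupancy and ranks deterministically", {
  # sp A in 3 quadrats (2, 2, 1), sp B in 2 quadrats (5, 5): only A
  # qualifies at min_quadrats = 3; proportion counts ALL individuals
  rec <- data.frame(
    transect = "T1",
    quadrat = c(1L, 2L, 3L, 1L, 2L),
    species = c("spA", "spA", "spA", "spB", "spB"),
    habit = c(rep("shrub", 3), rep("tree", 2)),
    count = c(2L, 2L, 1L, 5L, 5L), stringsAsFactors = FALSE)
  cm <- build_community_matrix(rec, transect_layouts("T1", 3))
  ra <- suppressMessages(rank_abundance(cm, rownames(cm), min_quadrats = 3,
                                        top_k = 17))
  expect_equal(ra$species, "spA")
  expect_equal(ra$proportion, 100 * 5 / 15, tolerance = 1e-12)

  ra1 <- suppressMessages(rank_abundance(cm, rownames(cm), min_quadrats = 1,
                                         top_k = 1))
  expect_equal(ra1$species, "spB")
  expect_equal(nrow(ra1), 1L)

  # abundance ties break alphabetically
  rec2 <- rec
  rec2$count <- c(2L, 2L, 1L, 4L, 1L)   # both species total 5
  cm2 <- build_community_matrix(rec2, transect_layouts("T1", 3))
  ra2 <- suppressMessages(rank_abundance(cm2, rownames(cm2),
                                         min_quadrats = 1, top_k = 2))
  expect_equal(ra2$species, c("spA", "spB"))
  # proportions never increase with rank
  expect_true(all(diff(ra2$proportion) <= 1e-12))
})

test_that("the three-group comparison table conserves counts", {
  fx <- fixture_two_transects()
  cm <- build_community_matrix(fx$records, fx$layouts)
  lt <- local_moran_table(cm)
  g <- partition_groups(lt)
  tab <- suppressMessages(group_comparison_table(cm, g))
  if (all(c("HH", "rest") %in% names(tab))) {
    ind <- tab[tab$trait == "n_individuals", ]
    expect_equal(ind$entire, ind$HH + ind$rest)
    area <- tab[tab$trait == "area", ]
    expect_equal(area$entire, area$HH + area$rest)
  }
  expect_true("entire" %in% names(tab))
})
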