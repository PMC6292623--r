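test_that("species pool honours habit proportions and the abundance series", {
  cfg <- simulation_config(n_species = 5L,
                           habit_mix = c(tree = 0, shrub = 1, palm = 0,
                                         vine = 0, cactus = 0))
  pool <- generate_species_pool(cfg, seed = 1)
  expect_equal(pool$habit, rep("shrub", 5))

  cfg_u <- simulation_config(n_species = 10L, sad_decay = 1)
  pool_u <- generate_species_pool(cfg_u, seed = 1)
  expect_equal(pool_u$rel_abund, rep(0.1, 10))

  set.seed(3)
  for (k in 1:5) {
    cfg_r <- simulation_config(n_species = sample(20:200, 1),
                               sad_decay = runif(1, 0.8, 1))
    pr <- generate_species_pool(cfg_r, seed = k)
    expect_equal(sum(pr$rel_abund), 1, tolerance = 1e-12)
    # largest-remainder rounding: counts within 1 of the exact shares
    tab <- table(factor(pr$habit, levels = GROWTH_HABITS))
    expect_true(all(abs(tab - cfg_r$n_species * cfg_r$habit_mix[GROWTH_HABITS])
                    < 1))
  }
  expect_error(simulation_config(habit_mix = c(tree = 0.6, shrub = 0.6,
                                               palm = 0, vine = 0,
                                               cactus = 0)), "sum to 1")
  expect_error(simulation_config(kappa = 0.5), "kappa")
})

test_that("the generator is deterministic and its totals follow the intensity", {
  cfg <- simulation_config()
  a <- generate_transects(cfg, seed = 77)
  b <- generate_transects(cfg, seed = 77)
  expect_identical(a$records, b$records)
  expect_identical(a$truth, b$truth)

  # planted quadrats are inside the grid and total a plausible run sum
  expect_true(all(a$truth$position >= 1 & a$truth$position <= cfg$n_quadrats))
  expect_gte(nrow(a$truth), cfg$n_clusters * cfg$run_length[1])
  expect_lte(nrow(a$truth), cfg$n_clusters * cfg$run_length[2])

  # expected individuals: lambda0 * non-cluster + kappa * lambda0 * cluster
  nrep <- 25
  totals <- numeric(nrep)
  ncl <- numeric(nrep)
  for (r in seq_len(nrep)) {
    s <- generate_transects(cfg, seed = 500 + r)
    totals[r] <- sum(s$records$count)
    ncl[r] <- nrow(s$truth)
  }
  expected <- cfg$lambda0 * (575 - mean(ncl)) + cfg$kappa * cfg$lambda0 * mean(ncl)
  se <- stats::sd(totals) / sqrt(nrep)
  expect_lt(abs(mean(totals) - expected), 4 * se)
})

test_that("a null generator stays near the baseline intensity", {
  cfg0 <- simulation_config(kappa = 1, habit_bias = 1, n_clusters = 0)
  nrep <- 25
  totals <- vapply(seq_len(nrep), function(r) {
    sum(generate_transects(cfg0, seed = 900 + r)$records$count)
  }, numeric(1))
  expect_lt(abs(mean(totals) - 575 * cfg0$lambda0),
            4 * stats::sd(totals) / sqrt(nrep))
})

test_that("recovery scoring counts hits and false alarms", {
  fx <- fixture_two_transects()
  cm <- build_community_matrix(fx$records, fx$layouts)
  lt <- local_moran_table(cm)
  truth <- data.frame(transect = "T1", position = 5:7,
                      stringsAsFactors = FALSE)
  sc <- score_recovery(lt, truth)
  expect_true(sc$sensitivity >= 0 && sc$sensitivity <= 1)
  expect_true(sc$fpr >= 0 && sc$fpr <= 1)
  expect_equal(sc$n_true, 3L)
  # boundary: an impossible truth set outside the grid errors
  expect_error(score_recovery(lt, data.frame(transect = "T9", position = 1)),
               "outside")
  # no HH anywhere gives (0, 0)
  fake <- lt
  fake$lisa_class[] <- "NS"
  sc0 <- score_recovery(fake, truth)
  expect_equal(sc0$sensitivity, 0)
  expect_equal(sc0$fpr, 0)
})

test_that("detection power increases with the planted intensity ratio", {
  sens <- vapply(c(1.5, 4), function(kp) {
    cfg <- simulation_config(kappa = kp, run_length = 3)
    mean(vapply(1:8, function(r) {
      sim <- generate_transects(cfg, seed = 4000 + r)
      cm <- build_community_matrix(sim$records, sim$layouts)
      score_recovery(local_moran_table(cm), sim$truth)$sensitivity
    }, numeric(1)))
  }, numeric(1))
  expect_gt(sens[2], sens[1])
})

test_that("simulation files round-trip through the standard readers", {
  cfg <- simulation_config(n_transects = 3, n_quadrats = 8, n_species = 20)
  sim <- generate_transects(cfg, seed = 12)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  rec <- read_occurrences(paths[["occurrences"]])
  expect_equal(sum(rec$count), sum(sim$records$count))
  lay <- read_layouts(paths[["layouts"]])
  expect_equal(lay$transect, sim$layouts$transect)
  expect_equal(lay$lithology, sim$layouts$lithology)
})
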