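# Synthetic transect-survey generator with planted high-density runs and
# ground truth, for calibration, power studies and end-to-end testing.
#
# Counts factorize as Poisson totals per quadrat times a multinomial over
# species, so the analyzed variable (total density) and the composition
# (the ordination input) are controlled independently. Lithology acts on
# species preference weights at transect level; the habit bias enriches
# shrub/palm/vine species inside planted clusters.

#' Simulation configuration
#'
#' Defaults mirror the survey design the package targets: 23 transects of
#' 25 contiguous 2 m x 2 m quadrats (575 quadrats, 2300 m^2), a pool of
#' 172 species across five growth habits, and a baseline intensity of
#' 2158 / 575 ~ 3.75 individuals per quadrat. Planted clusters are short
#' contiguous runs (1-3 quadrats) whose intensity is multiplied by
#' `kappa`; the default `kappa = 2.5` matches the density contrast such
#' surveys report between High-High clusters and the rest of the sample.
#'
#' @param n_transects Number of transects (default 23).
#' @param n_quadrats Quadrats per transect (default 25).
#' @param quadrat_area Quadrat area in m^2 (default 4).
#' @param n_species Species pool size (default 172).
#' @param habit_mix Named proportions over [GROWTH_HABITS] summing to 1.
#' @param sad_decay Geometric-series decay of relative abundances in
#'   (0, 1]; 1 gives a uniform pool (default 0.96).
#' @param lambda0 Baseline expected individuals per quadrat
#'   (default 2158/575).
#' @param n_clusters Number of planted high-density runs (default 10).
#' @param run_length Length range of a planted run in quadrats, either a
#'   scalar or `c(min, max)` (default `c(1, 3)`).
#' @param kappa Intensity multiplier inside clusters, >= 1 (default 2.5).
#' @param habit_bias Multiplier on shrub, palm and vine species weights
#'   inside clusters, >= 1 (default 2.5).
#' @param n_lithologies Number of substrate classes assigned to transects
#'   (default 3).
#' @param lithology_sd Standard deviation (log scale) of per-lithology
#'   species preference weights; 0 disables the effect (default 0.5).
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(n_transects = 23L, n_quadrats = 25L,
                              quadrat_area = 4,
                              n_species = 172L,
                              habit_mix = c(tree = 0.45, shrub = 0.35,
                                            palm = 0.05, vine = 0.12,
                                            cactus = 0.03),
                              sad_decay = 0.96,
                              lambda0 = 2158 / 575,
                              n_clusters = 10L,
                              run_length = c(1L, 3L),
                              kappa = 2.5,
                              habit_bias = 2.5,
                              n_lithologies = 3L,
                              lithology_sd = 0.5) {
  if (abs(sum(habit_mix) - 1) > 1e-8) stop("habit_mix must sum to 1")
  if (!all(names(habit_mix) %in% GROWTH_HABITS)) {
    stop("habit_mix names must be drawn from: ",
         paste(GROWTH_HABITS, collapse = ", "))
  }
  if (any(habit_mix < 0)) stop("habit_mix proportions must be non-negative")
  if (kappa < 1) stop("kappa must be >= 1")
  if (habit_bias < 1) stop("habit_bias must be >= 1")
  if (!(sad_decay > 0 && sad_decay <= 1)) stop("sad_decay must be in (0, 1]")
  run_length <- as.integer(run_length)
  if (length(run_length) == 1L) run_length <- rep(run_length, 2L)
  if (run_length[1L] < 1L || run_length[2L] < run_length[1L]) {
    stop("run_length must be >= 1 (min <= max)")
  }
  if (run_length[2L] > n_quadrats) stop("run_length exceeds transect length")
  if (lambda0 <= 0) stop("lambda0 must be > 0")
  structure(list(n_transects = as.integer(n_transects),
                 n_quadrats = as.integer(n_quadrats),
                 quadrat_area = quadrat_area,
                 n_species = as.integer(n_species),
                 habit_mix = habit_mix,
                 sad_decay = sad_decay,
                 lambda0 = lambda0,
                 n_clusters = as.integer(n_clusters),
                 run_length = run_length,
                 kappa = kappa,
                 habit_bias = habit_bias,
                 n_lithologies = as.integer(n_lithologies),
                 lithology_sd = lithology_sd),
            class = "simulation_config")
}

#' Generate a species pool with habits and relative abundances
#'
#' Habit counts follow the configured proportions via largest-remainder
#' rounding; relative abundances follow a geometric series with decay
#' `sad_decay`, normalized to sum exactly to 1.
#'
#' @param config A `simulation_config`.
#' @param seed Integer seed.
#' @return Data frame with `species`, `habit`, `rel_abund`.
#' @export
generate_species_pool <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(seed)
  S <- config$n_species
  mix <- config$habit_mix
  raw <- S * mix
  cnt <- floor(raw)
  rem <- S - sum(cnt)
  if (rem > 0) {
    extra <- order(raw - cnt, decreasing = TRUE)[seq_len(rem)]
    cnt[extra] <- cnt[extra] + 1
  }
  habit <- sample(rep(names(mix), cnt))
  theta <- config$sad_decay
  a <- if (theta == 1) rep(1, S) else theta^(seq_len(S) - 1L)
  data.frame(species = sprintf("species_%03d", seq_len(S)),
             habit = habit,
             rel_abund = a / sum(a),
             stringsAsFactors = FALSE)
}

# Deterministic per-transect seed derived from the root seed, so datasets
# are stable for the leading transects when n_transects changes.
.transect_seed <- function(seed, t) {
  (abs(as.integer(seed)) %% 1000003L) * 2047L + 7919L * t
}

#' Generate a full synthetic survey with ground truth
#'
#' Plants `n_clusters` contiguous runs of elevated intensity (`kappa *
#' lambda0` per quadrat, shrub/palm/vine-enriched composition), draws
#' Poisson quadrat totals and multinomial species counts re-weighted by
#' transect-level lithology preferences, and returns the long-format
#' records together with the planted-cluster positions.
#'
#' @param config A `simulation_config`.
#' @param seed Integer root seed; the same seed reproduces the records
#'   byte-for-byte.
#' @return List with `records` (occurrence data frame), `layouts`
#'   (`transect_layouts` with lithology labels), `truth` (data frame of
#'   planted transect/position pairs) and `pool` (the species pool).
#' @export
generate_transects <- function(config, seed = 1L) {
  stopifnot(inherits(config, "simulation_config"))
  pool <- generate_species_pool(config, seed)
  set.seed(seed)
  nt <- config$n_transects
  nq <- config$n_quadrats
  S <- config$n_species

  lith <- sprintf("lith_%d", sample.int(config$n_lithologies, nt, replace = TRUE))
  # per-lithology log-normal species preferences
  pref <- matrix(exp(stats::rnorm(config$n_lithologies * S, 0,
                                  config$lithology_sd)),
                 nrow = config$n_lithologies)

  # plant clusters: non-overlapping runs within randomly chosen transects
  truth <- data.frame(transect = character(0), position = integer(0),
                      stringsAsFactors = FALSE)
  occupied <- vector("list", nt)
  k <- 0L
  guard <- 0L
  while (k < config$n_clusters && guard < 1000L) {
    guard <- guard + 1L
    t <- sample.int(nt, 1L)
    len <- sample(seq(config$run_length[1L], config$run_length[2L]), 1L)
    start <- sample.int(nq - len + 1L, 1L)
    run <- seq(start, start + len - 1L)
    if (length(intersect(run, occupied[[t]])) > 0L) next
    occupied[[t]] <- c(occupied[[t]], run)
    truth <- rbind(truth, data.frame(transect = sprintf("T%02d", t),
                                     position = run,
                                     stringsAsFactors = FALSE))
    k <- k + 1L
  }
  if (k < config$n_clusters) stop("could not place all clusters without overlap")

  bias <- ifelse(pool$habit %in% c("shrub", "palm", "vine"),
                 config$habit_bias, 1)
  recs <- vector("list", nt)
  for (t in seq_len(nt)) {
    set.seed(.transect_seed(seed, t))
    tid <- sprintf("T%02d", t)
    lw <- pref[match(lith[t], sprintf("lith_%d", seq_len(config$n_lithologies))), ]
    base_w <- pool$rel_abund * lw
    in_cluster <- seq_len(nq) %in% occupied[[t]]
    rows <- vector("list", nq)
    for (q in seq_len(nq)) {
      lambda <- config$lambda0 * if (in_cluster[q]) config$kappa else 1
      total <- stats::rpois(1L, lambda)
      if (total == 0L) next
      wq <- if (in_cluster[q]) base_w * bias else base_w
      cnt <- as.integer(stats::rmultinom(1L, total, wq / sum(wq)))
      hit <- which(cnt > 0L)
      rows[[q]] <- data.frame(transect = tid, quadrat = q,
                              species = pool$species[hit],
                              habit = pool$habit[hit],
                              count = cnt[hit],
                              stringsAsFactors = FALSE)
    }
    recs[[t]] <- do.call(rbind, rows[!vapply(rows, is.null, logical(1L))])
  }
  records <- do.call(rbind, recs[!vapply(recs, is.null, logical(1L))])
  if (is.null(records)) {
    records <- data.frame(transect = character(0), quadrat = integer(0),
                          species = character(0), habit = character(0),
                          count = integer(0), stringsAsFactors = FALSE)
  }
  rownames(records) <- NULL
  records <- validate_occurrences(records)
  layouts <- transect_layouts(sprintf("T%02d", seq_len(nt)), nq,
                              config$quadrat_area, lith)
  list(records = records, layouts = layouts,
       truth = truth[order(truth$transect, truth$position), , drop = FALSE],
       pool = pool)
}

#' Score cluster recovery against ground truth
#'
#' Sensitivity is the fraction of planted-cluster quadrats classified HH;
#' the false-positive rate is the fraction of all other quadrats
#' classified HH.
#'
#' @param lisa_tab A `lisa_table`.
#' @param truth Data frame with `transect` and `position` of planted
#'   quadrats (as returned by [generate_transects()]).
#' @return List with `sensitivity`, `fpr`, `n_true`, `n_detected`.
#' @export
score_recovery <- function(lisa_tab, truth) {
  stopifnot(inherits(lisa_tab, "lisa_table"))
  true_keys <- .quadrat_key(truth$transect, truth$position)
  keys <- rownames(lisa_tab)
  if (!all(true_keys %in% keys)) stop("truth references quadrats outside the table")
  hh <- keys[lisa_tab$lisa_class == "HH"]
  is_true <- keys %in% true_keys
  is_hh <- keys %in% hh
  sens <- if (any(is_true)) mean(is_hh[is_true]) else NA_real_
  fpr <- if (any(!is_true)) mean(is_hh[!is_true]) else NA_real_
  list(sensitivity = sens, fpr = fpr,
       n_true = sum(is_true), n_detected = length(hh))
}

#' Write a simulated survey to disk
#'
#' Emits the long-format occurrence CSV the reader consumes, the layout
#' CSV, and a ground-truth CSV of planted quadrats.
#'
#' @param sim Output of [generate_transects()].
#' @param dir Output directory (created if needed).
#' @return Named character vector of written paths, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  occ <- file.path(dir, "occurrences.csv")
  lay <- file.path(dir, "layouts.csv")
  tru <- file.path(dir, "ground_truth.csv")
  write_occurrences(sim$records, occ)
  lay_df <- as.data.frame(sim$layouts)
  names(lay_df) <- c("transect", "n_quadrats", "quadrat_area_m2", "lithology")
  utils::write.csv(lay_df, lay, row.names = FALSE)
  utils::write.csv(sim$truth, tru, row.names = FALSE)
  invisible(c(occurrences = occ, layouts = lay, ground_truth = tru))
}
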