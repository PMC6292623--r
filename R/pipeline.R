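# One-command orchestration: data (read or simulated) -> weights -> LISA ->
# classification -> group comparison -> rank abundance -> ordination and
# clustering -> plot-ready CSV tables plus a JSON run manifest.

#' Run the full cluster-detection pipeline
#'
#' Reads a survey from CSV (or simulates one), computes the LISA table,
#' partitions High-High clusters from the rest, writes trait-comparison
#' and rank-abundance tables, ordinates the HH quadrats (Bray-Curtis PCoA
#' and Hellinger PCA) and clusters them by UPGMA on chord distance with
#' multiscale bootstrap support. All outputs are plain CSV plus one
#' Newick file; a JSON manifest records the configuration, the seed and
#' the row counts of every artifact. The run is a pure function of
#' (inputs, configuration, seed): re-running with the same arguments
#' reproduces every file byte-for-byte.
#'
#' @param outdir Output directory (created, must be writable).
#' @param occurrences,layouts Paths to the occurrence and layout CSVs;
#'   leave `NULL` when simulating.
#' @param sim_config A [simulation_config()] to simulate instead of
#'   reading files. Exactly one of `occurrences` / `sim_config` must be
#'   supplied.
#' @param seed Integer seed for every stochastic step.
#' @param alpha,alpha_endpoint,scope,inference,variant,n_perm,bonferroni_m
#'   LISA settings, see [local_moran_table()].
#' @param min_quadrats,top_k Rank-abundance settings, see
#'   [rank_abundance()].
#' @param ordination `"both"` (default), `"pcoa"` or `"pca"`.
#' @param linkage_methods Linkages screened by [cophenetic_selection()].
#' @param scales,n_boot Multiscale bootstrap settings, see
#'   [multiscale_bootstrap()].
#' @param ordination_species `"all"` (default) to ordinate on the full
#'   species set, or `"filtered"` to restrict to the rank-abundance
#'   species of the HH group.
#' @return Invisibly, a list with the main in-memory results
#'   (`lisa_table`, `groups`, `comparison`, paths of written files,
#'   `manifest`).
#' @export
run_pipeline <- function(outdir,
                         occurrences = NULL, layouts = NULL,
                         sim_config = NULL, seed = 1L,
                         alpha = 0.05, alpha_endpoint = 0.01,
                         scope = "transect", inference = "analytic",
                         variant = "anselin", n_perm = 999L,
                         bonferroni_m = NULL,
                         min_quadrats = 3L, top_k = 17L,
                         ordination = c("both", "pcoa", "pca"),
                         linkage_methods = c("single", "complete", "upgma",
                                             "wpgma", "ward"),
                         scales = seq(0.5, 1.4, length.out = 10),
                         n_boot = 1000L,
                         ordination_species = c("all", "filtered")) {
  ordination <- match.arg(ordination)
  ordination_species <- match.arg(ordination_species)
  if (is.null(sim_config) == is.null(occurrences)) {
    stop("supply exactly one of 'occurrences'+'layouts' or 'sim_config'")
  }
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  emit <- function(df, name) {
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    written[[length(written) + 1L]] <<- path
    path
  }

  res <- tryCatch({
    if (!is.null(sim_config)) {
      sim <- generate_transects(sim_config, seed = seed)
      rec <- sim$records
      lay <- sim$layouts
      paths <- write_simulation(sim, outdir)
      written <- c(written, unname(paths))
    } else {
      rec <- read_occurrences(occurrences)
      lay <- read_layouts(layouts)
      sim <- NULL
    }
    cm <- build_community_matrix(rec, lay)
    message("pipeline: ", nrow(cm), " quadrats, ", ncol(cm), " species, ",
            sum(cm), " individuals")

    lt <- local_moran_table(cm, alpha = alpha,
                            alpha_endpoint = alpha_endpoint, scope = scope,
                            inference = inference, variant = variant,
                            null = "total", n_perm = n_perm,
                            seed = seed, bonferroni_m = bonferroni_m)
    emit(data.frame(quadrat_key = rownames(lt), lt, check.names = FALSE),
         "local_moran.csv")
    emit(lt[, c("transect", "position", "lisa_class")], "lisa_map.csv")

    sc <- moran_scatter_table(cm, scope = scope)
    emit(sc$points, "moran_scatter_points.csv")
    emit(sc$slopes, "moran_scatter_slopes.csv")

    groups <- partition_groups(lt)
    n_sig <- sum(lt$p_adj < alpha)
    message("pipeline: ", nrow(lt), " quadrats tested, ", n_sig,
            " significant, ", length(groups$hh), " HH")
    cmp <- group_comparison_table(cm, groups)
    emit(cmp, "group_comparison.csv")

    ra_tables <- list()
    for (g in c("hh", "rest")) {
      if (length(groups[[g]]) > 0L) {
        ra <- rank_abundance(cm, groups[[g]], min_quadrats, top_k)
        ra_tables[[g]] <- ra
        emit(ra, paste0("rank_abundance_", g, ".csv"))
      }
    }

    ttest <- NULL
    d_all <- densities(cm)
    key <- d_all$quadrat
    if (length(groups$hh) >= 2L && length(groups$rest) >= 2L) {
      ttest <- ttest_density(d_all$dN[key %in% groups$hh],
                             d_all$dN[key %in% groups$rest])
      emit(data.frame(t = ttest$t, df = ttest$df, p = ttest$p,
                      mean_hh = ttest$mean_a, mean_rest = ttest$mean_b,
                      variant = ttest$variant), "ttest_density.csv")
    }

    ord_out <- list()
    dend <- NULL
    if (length(groups$hh) >= 3L) {
      hh_m <- cm[match(groups$hh, rownames(cm)), , drop = FALSE]
      if (ordination_species == "filtered" && length(ra_tables$hh$species) > 0L) {
        hh_m <- hh_m[, colnames(hh_m) %in% ra_tables$hh$species, drop = FALSE]
      } else {
        hh_m <- hh_m[, colSums(hh_m) > 0, drop = FALSE]
      }
      lith <- stats::setNames(lay$lithology, lay$transect)
      row_lith <- as.character(lith[sub(":Q[0-9]+$", "", rownames(hh_m))])

      if (ordination %in% c("both", "pcoa")) {
        pco <- pcoa(bray_curtis(hh_m), k = 2L)
        ord_out$pcoa <- pco
        emit(data.frame(quadrat = rownames(hh_m), pco$points,
                        lithology = row_lith), "ordination_pcoa_scores.csv")
        emit(data.frame(axis = seq_along(pco$eig), eigenvalue = pco$eig),
             "ordination_pcoa_eigenvalues.csv")
      }
      if (ordination %in% c("both", "pca")) {
        pc <- pca(hellinger(hh_m), k = 2L)
        ord_out$pca <- pc
        emit(data.frame(quadrat = rownames(hh_m), pc$points,
                        lithology = row_lith), "ordination_pca_scores.csv")
        emit(data.frame(species = rownames(pc$species_scores),
                        pc$species_scores), "ordination_pca_species_scores.csv")
        emit(data.frame(axis = seq_along(pc$eig), eigenvalue = pc$eig),
             "ordination_pca_eigenvalues.csv")
      }

      cd <- chord_distance(hh_m)
      sel <- cophenetic_selection(cd, linkage_methods)
      emit(sel$correlations, "cophenetic_correlations.csv")
      dend <- multiscale_bootstrap(hh_m, dist_fun = chord_distance,
                                   method = sel$best$method,
                                   scales = scales, n_boot = n_boot,
                                   seed = seed)
      emit(dend$support[, c("node", "au", "bp", "flat")],
           "cluster_support.csv")
      nwk <- file.path(outdir, "dendrogram.nwk")
      write_dendrogram_newick(dend, nwk)
      written <- c(written, nwk)
    } else {
      message("pipeline: fewer than 3 HH quadrats; ",
              "ordination and clustering skipped")
    }

    manifest <- list(
      package = "lisatransect",
      version = as.character(utils::packageVersion("lisatransect")),
      seed = seed,
      config = list(alpha = alpha, alpha_endpoint = alpha_endpoint,
                    scope = scope, inference = inference, variant = variant,
                    n_perm = n_perm, bonferroni_m = bonferroni_m,
                    min_quadrats = min_quadrats, top_k = top_k,
                    ordination = ordination,
                    ordination_species = ordination_species,
                    linkage_methods = linkage_methods, scales = scales,
                    n_boot = n_boot,
                    simulated = !is.null(sim_config)),
      counts = list(quadrats = nrow(cm), species = ncol(cm),
                    individuals = sum(cm), tested = nrow(lt),
                    significant = n_sig, hh = length(groups$hh)),
      files = lapply(stats::setNames(written, basename(written)), function(f) {
        if (grepl("\\.csv$", f)) length(utils::count.fields(f, sep = ",", quote = "\"")) - 1L else NA
      })
    )
    mpath <- file.path(outdir, "manifest.json")
    jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, mpath)
    list(community_matrix = cm, lisa_table = lt, groups = groups,
         comparison = cmp, rank_abundance = ra_tables, ttest = ttest,
         ordination = ord_out, dendrogram = dend, files = written,
         manifest = manifest, truth = if (!is.null(sim)) sim$truth)
  }, error = function(e) {
    # remove partial outputs so a failed run leaves no half-written bundle
    unlink(written)
    stop("pipeline failed: ", conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
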