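# Comparison of High-High cluster quadrats with the rest of the sample:
# group summaries by growth habit, density ratios, two-sample t-tests and
# rank-abundance tables.

#' Partition quadrats into High-High clusters and the rest
#'
#' Low-Low, spatial-outlier and not-significant quadrats all count as "the
#' rest of the sample"; only the HH class forms the cluster group.
#'
#' @param lisa_tab A `lisa_table` (see [local_moran_table()]).
#' @return List with character vectors `hh` and `rest` of quadrat keys
#'   (`"<transect>:Q<pos>"`), a disjoint exhaustive partition.
#' @export
partition_groups <- function(lisa_tab) {
  stopifnot(inherits(lisa_tab, "lisa_table"))
  keys <- rownames(lisa_tab)
  hh <- keys[lisa_tab$lisa_class == "HH"]
  list(hh = hh, rest = setdiff(keys, hh))
}

#' Summarize a group of quadrats
#'
#' Computes richness, abundance, area, the percentage of individuals per
#' growth habit and per-habit densities (mean and standard error over the
#' group's quadrats). Vines and cacti are pooled into one reporting
#' category; an undifferentiated (all habits pooled) density row is
#' included. SE uses the sample standard deviation (n - 1) over per-quadrat
#' densities divided by the square root of the number of quadrats.
#'
#' @param cm A `community_matrix`.
#' @param quadrats Character vector of quadrat row keys (non-empty).
#' @param label Group label (e.g. `"entire"`, `"HH"`, `"rest"`).
#' @return A `group_summary` list: `label`, `n_species`, `n_individuals`,
#'   `n_quadrats`, `area`, `habit_percent` (named vector summing to 100
#'   when the group has individuals), and `density` (data frame with
#'   `habit`, `mean`, `se`, including the `"all"` pooled row).
#' @export
summarize_group <- function(cm, quadrats, label = "group") {
  stopifnot(inherits(cm, "community_matrix"))
  if (length(quadrats) == 0L) stop("cannot summarize an empty quadrat set")
  idx <- match(quadrats, rownames(cm))
  if (anyNA(idx)) {
    stop("unknown quadrat key(s): ",
         paste(utils::head(quadrats[is.na(idx)], 3L), collapse = ", "))
  }
  sub <- cm[idx, , drop = FALSE]
  lay <- attr(cm, "layouts")
  area_by_tr <- stats::setNames(lay$quadrat_area, lay$transect)
  row_area <- as.numeric(area_by_tr[attr(cm, "transect")[idx]])
  habits <- attr(cm, "habits")
  hab_cat <- .habit_report_map[habits[colnames(sub)]]

  total <- sum(sub)
  pct <- vapply(.habit_report_levels, function(h) {
    if (total == 0) return(NA_real_)
    100 * sum(sub[, hab_cat == h, drop = FALSE]) / total
  }, numeric(1L))

  dens <- lapply(c(.habit_report_levels, "all"), function(h) {
    counts <- if (h == "all") rowSums(sub) else {
      rowSums(sub[, hab_cat == h, drop = FALSE])
    }
    dq <- counts / row_area
    m <- mean(dq)
    se <- if (length(dq) > 1L) stats::sd(dq) / sqrt(length(dq)) else NA_real_
    data.frame(habit = h, mean = m, se = se, stringsAsFactors = FALSE)
  })
  structure(list(label = label,
                 n_species = sum(colSums(sub) > 0),
                 n_individuals = total,
                 n_quadrats = nrow(sub),
                 area = sum(row_area),
                 habit_percent = pct,
                 density = do.call(rbind, dens)),
            class = "group_summary")
}

#' @export
print.group_summary <- function(x, ...) {
  cat("group '", x$label, "': ", x$n_species, " species, ",
      x$n_individuals, " individuals, ", x$n_quadrats, " quadrats (",
      x$area, " m^2)\n", sep = "")
  invisible(x)
}

#' Ratio of mean densities between two groups
#'
#' @param a,b `group_summary` objects (numerator, denominator), or named
#'   numeric vectors of per-habit mean densities.
#' @param habit One of `"trees"`, `"shrubs"`, `"palms"`, `"vines_cacti"`,
#'   `"all"`.
#' @return `mean_a / mean_b`.
#' @export
density_ratio <- function(a, b, habit = "all") {
  get_mean <- function(s) {
    if (inherits(s, "group_summary")) {
      s$density$mean[s$density$habit == habit]
    } else {
      as.numeric(s[[habit]])
    }
  }
  ma <- get_mean(a)
  mb <- get_mean(b)
  if (length(ma) != 1L || length(mb) != 1L || is.na(ma) || is.na(mb)) {
    stop("no mean density available for habit '", habit, "'")
  }
  if (mb <= 0) stop("denominator mean density is not positive")
  ma / mb
}

#' Two-sample t-test on per-quadrat pooled densities
#'
#' Compares the density of individuals between two quadrat groups (e.g. HH
#' clusters versus the rest). Defaults to Welch's unequal-variance test;
#' the pooled-variance variant is available via `var_equal = TRUE`.
#'
#' @param d_a,d_b Numeric vectors of per-quadrat densities (length >= 2).
#' @param var_equal Use the pooled-variance test? Default `FALSE` (Welch).
#' @param alternative Passed to [stats::t.test()].
#' @return List with `t`, `df`, `p`, `mean_a`, `mean_b`, `variant`.
#' @export
ttest_density <- function(d_a, d_b, var_equal = FALSE,
                          alternative = "two.sided") {
  if (length(d_a) < 2L || length(d_b) < 2L) {
    stop("each group needs at least 2 quadrats")
  }
  tt <- stats::t.test(d_a, d_b, var.equal = var_equal,
                      alternative = alternative)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, mean_a = mean(d_a), mean_b = mean(d_b),
       variant = if (var_equal) "pooled" else "welch")
}

#' Rank-abundance table for a group of quadrats
#'
#' Species occurring in at least `min_quadrats` quadrats of the group are
#' ranked by their within-group abundance (descending, ties broken
#' alphabetically) and truncated to the `top_k` most abundant. Proportions
#' are percentages of ALL individuals in the group, including species
#' filtered out by the occupancy rule, so listed proportions sum below 100.
#'
#' @param cm A `community_matrix`.
#' @param quadrats Character vector of quadrat row keys.
#' @param min_quadrats Minimum number of occupied quadrats (default 3).
#' @param top_k Number of species to keep (default 17).
#' @return Data frame with `rank`, `species`, `habit`, `count`,
#'   `n_quadrats` and `proportion` (percent).
#' @export
rank_abundance <- function(cm, quadrats, min_quadrats = 3L, top_k = 17L) {
  stopifnot(inherits(cm, "community_matrix"))
  if (length(quadrats) == 0L) stop("cannot tabulate an empty quadrat set")
  idx <- match(quadrats, rownames(cm))
  if (anyNA(idx)) stop("unknown quadrat key(s) in group")
  sub <- cm[idx, , drop = FALSE]
  habits <- attr(cm, "habits")
  total <- sum(sub)
  counts <- colSums(sub)
  occ <- colSums(sub > 0)
  keep <- occ >= min_quadrats & counts > 0
  sp <- colnames(sub)[keep]
  if (length(sp) == 0L) {
    return(data.frame(rank = integer(0), species = character(0),
                      habit = character(0), count = numeric(0),
                      n_quadrats = numeric(0), proportion = numeric(0),
                      stringsAsFactors = FALSE))
  }
  ord <- order(-counts[sp], sp)
  sp <- sp[ord]
  if (length(sp) > top_k) sp <- sp[seq_len(top_k)] else if (length(sp) < top_k) {
    message("only ", length(sp), " species meet the occupancy filter (top_k = ",
            top_k, ")")
  }
  data.frame(rank = seq_along(sp),
             species = sp,
             habit = unname(habits[sp]),
             count = unname(counts[sp]),
             n_quadrats = unname(occ[sp]),
             proportion = unname(100 * counts[sp] / total),
             stringsAsFactors = FALSE)
}

#' Trait-comparison table for entire sample, HH clusters and the rest
#'
#' Convenience wrapper producing the group-by-trait comparison (richness,
#' abundance, quadrats, area, habit percentages, habit densities) for the
#' three standard groups.
#'
#' @param cm A `community_matrix`.
#' @param groups Output of [partition_groups()].
#' @return Data frame of traits by group (`entire`, `HH`, `rest`); groups
#'   without quadrats are omitted with a message.
#' @export
group_comparison_table <- function(cm, groups) {
  sets <- list(entire = rownames(cm), HH = groups$hh, rest = groups$rest)
  sets <- Filter(function(s) length(s) > 0L, sets)
  if (length(sets) < 3L) {
    message("group(s) without quadrats omitted from the comparison: ",
            paste(setdiff(c("entire", "HH", "rest"), names(sets)),
                  collapse = ", "))
  }
  sums <- lapply(names(sets), function(nm) summarize_group(cm, sets[[nm]], nm))
  trait_names <- c("n_species", "n_individuals", "n_quadrats", "area",
                   paste0("pct_", .habit_report_levels),
                   paste0("density_", c(.habit_report_levels, "all")),
                   paste0("density_se_", c(.habit_report_levels, "all")))
  cols <- lapply(sums, function(s) {
    c(s$n_species, s$n_individuals, s$n_quadrats, s$area,
      unname(s$habit_percent),
      s$density$mean, s$density$se)
  })
  out <- data.frame(trait = trait_names, stats::setNames(cols, names(sets)),
                    stringsAsFactors = FALSE, check.names = FALSE)
  out
}
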