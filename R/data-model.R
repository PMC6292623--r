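# Long-format occurrence records, transect layouts, community matrices and
# per-quadrat densities.

#' Validate a data frame of occurrence records
#'
#' Checks the invariants of the long-format occurrence table: integer counts
#' that are not negative, 1-based quadrat positions, and growth habits drawn
#' from [GROWTH_HABITS]. Species names are whitespace-trimmed.
#'
#' @param records Data frame with columns `transect`, `quadrat`, `species`,
#'   `habit`, `count`.
#' @return The validated (and trimmed) data frame, invisibly classed as
#'   `occurrence_records`.
#' @export
validate_occurrences <- function(records) {
  req <- c("transect", "quadrat", "species", "habit", "count")
  miss <- setdiff(req, names(records))
  if (length(miss) > 0L) {
    stop("occurrence table is missing column(s): ", paste(miss, collapse = ", "))
  }
  records$transect <- as.character(records$transect)
  records$species <- trimws(as.character(records$species))
  records$habit <- as.character(records$habit)

  bad <- which(!is.finite(records$count) | records$count < 0 |
                 records$count != floor(records$count))
  if (length(bad) > 0L) {
    stop("count must be a non-negative integer; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which(!is.finite(records$quadrat) | records$quadrat < 1 |
                 records$quadrat != floor(records$quadrat))
  if (length(bad) > 0L) {
    stop("quadrat position must be an integer >= 1; offending row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  bad <- which(!records$habit %in% GROWTH_HABITS)
  if (length(bad) > 0L) {
    stop("unknown growth habit '", records$habit[bad[1L]], "' in row ",
         bad[1L], "; allowed values: ", paste(GROWTH_HABITS, collapse = ", "))
  }
  records$quadrat <- as.integer(records$quadrat)
  records$count <- as.integer(records$count)
  class(records) <- c("occurrence_records", "data.frame")
  invisible(records)
}

#' Read long-format occurrence records from a delimited text file
#'
#' Expects one row per transect x quadrat x species with an individual count
#' and a growth-habit label. Duplicate (transect, quadrat, species) rows are
#' summed with a warning. Column names are configurable so that files using
#' other headers can be read without renaming.
#'
#' @param path Path to a delimited text file with a header row.
#' @param columns Named character vector mapping the canonical names
#'   `transect`, `quadrat`, `species`, `habit`, `count` to the column names
#'   present in the file.
#' @param delim Field delimiter (default comma).
#' @return A validated `occurrence_records` data frame with canonical column
#'   names.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("transect,quadrat,species,habit,count",
#'              "T11,3,Coccothrinax argentea,palm,2"), f)
#' read_occurrences(f)
#' @export
read_occurrences <- function(path,
                             columns = c(transect = "transect",
                                         quadrat = "quadrat",
                                         species = "species",
                                         habit = "habit",
                                         count = "count"),
                             delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, quote = "\"",
                          comment.char = "", check.names = FALSE)
  req <- c("transect", "quadrat", "species", "habit", "count")
  cols <- columns[req]
  if (anyNA(cols)) {
    stop("'columns' must map all of: ", paste(req, collapse = ", "))
  }
  miss <- cols[!cols %in% names(df)]
  if (length(miss) > 0L) {
    stop("input file is missing column(s): ", paste(miss, collapse = ", "))
  }
  rec <- data.frame(transect = df[[cols[["transect"]]]],
                    quadrat = df[[cols[["quadrat"]]]],
                    species = df[[cols[["species"]]]],
                    habit = df[[cols[["habit"]]]],
                    count = df[[cols[["count"]]]],
                    stringsAsFactors = FALSE)
  rec <- validate_occurrences(rec)

  key <- paste(rec$transect, rec$quadrat, rec$species, sep = "\r")
  if (anyDuplicated(key) > 0L) {
    ndup <- sum(duplicated(key))
    warning(ndup, " duplicate (transect, quadrat, species) row(s) summed")
    agg <- stats::aggregate(count ~ transect + quadrat + species + habit,
                            data = rec, FUN = sum)
    rec <- validate_occurrences(agg)
  }
  rec <- rec[order(rec$transect, rec$quadrat, rec$species), ]
  rownames(rec) <- NULL
  class(rec) <- c("occurrence_records", "data.frame")
  rec
}

#' Write occurrence records to CSV
#'
#' @param records Occurrence data frame (see [read_occurrences()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_occurrences <- function(records, path) {
  records <- validate_occurrences(records)
  utils::write.csv(as.data.frame(records), path, row.names = FALSE,
                   quote = TRUE)
  invisible(path)
}

#' Define transect layouts
#'
#' A layout gives, per transect, the number of contiguous quadrats, the
#' quadrat area in square metres and an optional lithology label. Adjacency
#' is ordinal along the transect; no geographic coordinates are kept.
#'
#' @param transect Character vector of transect identifiers (unique).
#' @param n_quadrats Integer vector (>= 2), recycled if scalar.
#' @param quadrat_area Numeric vector of quadrat areas in m^2 (> 0),
#'   recycled if scalar.
#' @param lithology Character vector of substrate labels, recycled if scalar.
#' @return A `transect_layouts` data frame.
#' @export
transect_layouts <- function(transect, n_quadrats = 25L, quadrat_area = 4,
                             lithology = "unknown") {
  transect <- as.character(transect)
  if (anyDuplicated(transect) > 0L) stop("duplicated transect identifiers")
  out <- data.frame(transect = transect,
                    n_quadrats = as.integer(rep_len(n_quadrats, length(transect))),
                    quadrat_area = as.numeric(rep_len(quadrat_area, length(transect))),
                    lithology = as.character(rep_len(lithology, length(transect))),
                    stringsAsFactors = FALSE)
  if (any(out$n_quadrats < 2L)) stop("n_quadrats must be >= 2")
  if (any(out$quadrat_area <= 0)) stop("quadrat_area must be > 0")
  class(out) <- c("transect_layouts", "data.frame")
  out
}

#' Read transect layout metadata from CSV
#'
#' @param path Path to a delimited file.
#' @param columns Named map from canonical names (`transect`, `n_quadrats`,
#'   `quadrat_area`, `lithology`) to file column names.
#' @param delim Field delimiter.
#' @return A `transect_layouts` data frame.
#' @export
read_layouts <- function(path,
                         columns = c(transect = "transect",
                                     n_quadrats = "n_quadrats",
                                     quadrat_area = "quadrat_area_m2",
                                     lithology = "lithology"),
                         delim = ",") {
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          stringsAsFactors = FALSE, check.names = FALSE)
  req <- c("transect", "n_quadrats", "quadrat_area")
  miss <- columns[req][!columns[req] %in% names(df)]
  if (length(miss) > 0L) {
    stop("layout file is missing column(s): ", paste(miss, collapse = ", "))
  }
  lith <- if (!is.na(columns["lithology"]) &&
              columns[["lithology"]] %in% names(df)) {
    df[[columns[["lithology"]]]]
  } else "unknown"
  transect_layouts(df[[columns[["transect"]]]],
                   df[[columns[["n_quadrats"]]]],
                   df[[columns[["quadrat_area"]]]],
                   lith)
}

.quadrat_key <- function(transect, position) {
  sprintf("%s:Q%02d", transect, as.integer(position))
}

#' Build a quadrats-by-species community matrix
#'
#' Every (transect, position) pair declared in the layouts gets a row, so
#' empty quadrats appear explicitly as zero rows; species columns are sorted
#' alphabetically. The species-to-habit map and the layouts travel with the
#' matrix as attributes.
#'
#' @param records Occurrence records (see [read_occurrences()]).
#' @param layouts A `transect_layouts` data frame covering every transect
#'   referenced by `records`.
#' @return A `community_matrix`: an integer matrix with row names
#'   `"<transect>:Q<pos>"` and attributes `transect`, `position`, `habits`
#'   (named species -> habit vector) and `layouts`.
#' @export
build_community_matrix <- function(records, layouts) {
  records <- validate_occurrences(records)
  if (!inherits(layouts, "transect_layouts")) {
    layouts <- transect_layouts(layouts$transect, layouts$n_quadrats,
                                layouts$quadrat_area, layouts$lithology)
  }
  unknown <- setdiff(unique(records$transect), layouts$transect)
  if (length(unknown) > 0L) {
    stop("record(s) reference unknown transect(s): ",
         paste(unknown, collapse = ", "))
  }
  nq <- stats::setNames(layouts$n_quadrats, layouts$transect)
  bad <- which(records$quadrat > nq[records$transect])
  if (length(bad) > 0L) {
    stop("record(s) with quadrat position beyond the transect layout, e.g. ",
         records$transect[bad[1L]], " position ", records$quadrat[bad[1L]])
  }

  row_transect <- rep(layouts$transect, layouts$n_quadrats)
  row_position <- unlist(lapply(layouts$n_quadrats, seq_len), use.names = FALSE)
  row_keys <- .quadrat_key(row_transect, row_position)
  species <- sort(unique(records$species))

  m <- matrix(0L, nrow = length(row_keys), ncol = length(species),
              dimnames = list(row_keys, species))
  if (nrow(records) > 0L) {
    hab <- tapply(records$habit, records$species, function(h) unique(h))
    multi <- names(hab)[lengths(hab) > 1L]
    if (length(multi) > 0L) {
      stop("species with conflicting habit labels: ",
           paste(multi, collapse = ", "))
    }
    habits <- vapply(hab, `[[`, character(1L), 1L)[species]
    ri <- match(.quadrat_key(records$transect, records$quadrat), row_keys)
    ci <- match(records$species, species)
    for (k in seq_len(nrow(records))) {
      m[ri[k], ci[k]] <- m[ri[k], ci[k]] + records$count[k]
    }
  } else {
    habits <- stats::setNames(character(0L), character(0L))
  }

  structure(m,
            transect = row_transect,
            position = row_position,
            habits = habits,
            layouts = layouts,
            class = c("community_matrix", class(m)))
}

#' @export
print.community_matrix <- function(x, ...) {
  lay <- attr(x, "layouts")
  cat("community_matrix: ", nrow(x), " quadrats (",
      nrow(lay), " transects) x ", ncol(x), " species; ",
      sum(x), " individuals\n", sep = "")
  invisible(x)
}

#' Per-quadrat abundance and density
#'
#' Computes, for every quadrat row of a community matrix, the number of
#' individuals N (row sum) and the density dN = N / quadrat area in
#' individuals per square metre (with the study's 4 m^2 quadrats,
#' dN = N / 4).
#'
#' @param cm A `community_matrix`.
#' @return A data frame with columns `transect`, `position`, `quadrat`
#'   (row key), `N` and `dN`, one row per quadrat in layout order.
#' @export
densities <- function(cm) {
  stopifnot(inherits(cm, "community_matrix"))
  lay <- attr(cm, "layouts")
  area <- stats::setNames(lay$quadrat_area, lay$transect)
  tr <- attr(cm, "transect")
  n <- as.numeric(rowSums(cm))
  data.frame(transect = tr,
             position = attr(cm, "position"),
             quadrat = rownames(cm),
             N = n,
             dN = n / as.numeric(area[tr]),
             stringsAsFactors = FALSE)
}

#' Write a community matrix as wide CSV
#'
#' The composite quadrat key (`"<transect>:Q<pos>"`) is the first column.
#'
#' @param cm A `community_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_community_matrix <- function(cm, path) {
  stopifnot(inherits(cm, "community_matrix"))
  df <- data.frame(quadrat = rownames(cm), as.data.frame(unclass(cm)),
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}
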