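# Plankton-habitat association by torus-translation randomization: the
# habitat raster is cyclically shifted (and optionally reflected), which
# preserves its internal spatial structure while decoupling it from the
# species field; per-habitat abundance envelopes classify each (group,
# macro-habitat) pair as positively associated, negatively associated or
# not significant.

#' Association test configuration
#'
#' @param n_randomizations Number of randomized habitat maps (default
#'   100).
#' @param alpha Two-sided significance level (default 0.01);
#'   `n_randomizations >= 1/alpha` is recommended.
#' @param seed Integer seed.
#' @param shared_maps Reuse the same randomized-map sequence for every
#'   plankton group (default `TRUE`, for comparability across groups).
#' @return An `association_config` list (randomization method is fixed
#'   to torus translation).
#' @export
association_config <- function(n_randomizations = 100L, alpha = 0.01,
                               seed = 1L, shared_maps = TRUE) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (n_randomizations < 1L) stop("n_randomizations must be >= 1")
  if (n_randomizations < 1 / alpha)
    warning("n_randomizations < 1/alpha: envelope quantiles sit on the ",
            "extreme order statistics")
  structure(list(n_randomizations = as.integer(n_randomizations),
                 alpha = alpha, randomization_method = "torus_translation",
                 seed = as.integer(seed), shared_maps = shared_maps),
            class = "association_config")
}

# cyclic shift + optional reflections of a matrix
.torus_shift <- function(m, dr, dc, flip_h, flip_v) {
  nr <- nrow(m); nc <- ncol(m)
  if (flip_v) m <- m[nr:1, , drop = FALSE]
  if (flip_h) m <- m[, nc:1, drop = FALSE]
  ri <- ((seq_len(nr) - 1L + dr) %% nr) + 1L
  ci <- ((seq_len(nc) - 1L + dc) %% nc) + 1L
  m[ri, ci, drop = FALSE]
}

#' Torus-translation randomization of a habitat map
#'
#' Cyclically shifts the label raster by a uniformly drawn (row, column)
#' offset and reflects it horizontally/vertically with probability 1/2
#' each.  The label multiset is exactly preserved on a fully valid grid.
#' The invalid-cell mask is geographic and does NOT shift: shifted labels
#' landing on invalid cells are dropped (set `NA`).
#'
#' @param map A [habitat_map()].
#' @param seed Integer seed (`NULL` to use the current RNG state, as the
#'   envelope loop does).
#' @return A randomized [habitat_map()].
#' @export
randomize_map <- function(map, seed = NULL) {
  stopifnot(inherits(map, "habitat_map"))
  lab <- map$labels
  if (!any(lab >= 0L, na.rm = TRUE))
    stop("map has no non-transition habitat labels")
  if (!is.null(seed)) set.seed(seed)
  nr <- nrow(lab); nc <- ncol(lab)
  dr <- sample.int(nr, 1L) - 1L
  dc <- sample.int(nc, 1L) - 1L
  flips <- stats::runif(2) < 0.5
  valid <- !is.na(lab)
  out <- .torus_shift(lab, dr, dc, flips[1L], flips[2L])
  out[!valid] <- NA_integer_
  map$labels <- out
  map
}

#' Per-habitat abundance sums
#'
#' Sums a species density raster over each macro-habitat's valid cells;
#' transition (`-1`) and invalid cells are excluded.
#'
#' @param species Numeric density matrix aligned with the map.
#' @param map A [habitat_map()].
#' @param habitats Optional integer vector of habitat labels to report
#'   (defaults to those present); habitats absent from the map get sum 0.
#' @return Named numeric vector of abundance sums.
#' @export
habitat_abundance <- function(species, map, habitats = NULL) {
  stopifnot(inherits(map, "habitat_map"))
  lab <- map$labels
  if (!identical(dim(species), dim(lab)))
    stop("species raster shape does not match the habitat map")
  use <- !is.na(lab) & lab >= 0L & !is.na(species)
  sums <- tapply(species[use], lab[use], sum)
  if (is.null(habitats)) habitats <- sort(as.integer(names(sums)))
  out <- stats::setNames(numeric(length(habitats)), habitats)
  hit <- intersect(names(sums), names(out))
  out[hit] <- sums[hit]
  out
}

#' Classify plankton-habitat associations
#'
#' Draws `n_randomizations` torus-translated habitat maps once (shared
#' across all groups when `shared_maps`), accumulates per-habitat
#' abundance sums for each group under each randomized map, and compares
#' the observed abundance with the empirical `alpha/2` and `1 - alpha/2`
#' quantile envelope: above the envelope is a positive association,
#' below a negative one, inside not significant (`n.s.`).
#'
#' @param species_rasters Named list of density matrices (one per
#'   plankton group), aligned with the map.
#' @param map The observed [habitat_map()].
#' @param config An [association_config()].
#' @return A data.frame with columns `group`, `habitat`, `observed`,
#'   `envelope_lo`, `envelope_hi`, `classification`, `unreliable` (the
#'   habitat had no valid overlap in more than half the randomized
#'   maps).
#' @export
associate <- function(species_rasters, map,
                      config = association_config()) {
  stopifnot(inherits(map, "habitat_map"))
  if (is.null(names(species_rasters)))
    stop("species_rasters must be a named list")
  habitats <- sort(unique(map$labels[map$labels >= 0L]))
  if (!length(habitats)) stop("map has no non-transition habitats")
  nR <- config$n_randomizations
  groups <- names(species_rasters)
  # rand_sums[[g]] is an nR x n_habitat matrix
  rand_sums <- lapply(groups, function(g)
    matrix(NA_real_, nR, length(habitats)))
  names(rand_sums) <- groups
  present <- matrix(FALSE, nR, length(habitats))
  run_maps <- function(group_set, stream_seed, record_presence) {
    set.seed(stream_seed)
    for (r in seq_len(nR)) {
      rmap <- randomize_map(map)
      # a habitat can vanish when all its shifted cells land on the mask
      if (record_presence) present[r, ] <<- habitats %in% rmap$labels
      for (g in group_set) {
        rand_sums[[g]][r, ] <<-
          habitat_abundance(species_rasters[[g]], rmap, habitats)
      }
    }
  }
  if (config$shared_maps) {
    run_maps(groups, config$seed, record_presence = TRUE)
  } else {
    for (k in seq_along(groups))
      run_maps(groups[k], config$seed + k - 1L,
               record_presence = (k == 1L))
  }
  lo_q <- config$alpha / 2; hi_q <- 1 - config$alpha / 2
  unreliable <- colMeans(present) < 0.5
  out <- NULL
  for (g in groups) {
    obs <- habitat_abundance(species_rasters[[g]], map, habitats)
    lo <- apply(rand_sums[[g]], 2L, stats::quantile, probs = lo_q,
                type = 7, names = FALSE)
    hi <- apply(rand_sums[[g]], 2L, stats::quantile, probs = hi_q,
                type = 7, names = FALSE)
    cls <- ifelse(obs > hi, "positive",
                  ifelse(obs < lo, "negative", "n.s."))
    out <- rbind(out, data.frame(group = g, habitat = habitats,
                                 observed = as.numeric(obs),
                                 envelope_lo = lo, envelope_hi = hi,
                                 classification = cls,
                                 unreliable = unreliable,
                                 row.names = NULL))
  }
  out
}

#' Summarize associations across transects
#'
#' @param results Named list of per-transect [associate()] data.frames.
#' @param min_transects Minimum number of transects a habitat must occur
#'   in before a cross-transect ("general") association is reported
#'   (default 4).
#' @return A data.frame per (group, habitat): counts of positive /
#'   negative / n.s. classifications, the number of transects the
#'   habitat occurred in, and `general` (`"positive"` / `"negative"`
#'   when that class holds in more than half of `>= min_transects`
#'   occurrences, else `"none"`).
#' @export
summarize_associations <- function(results, min_transects = 4L) {
  if (is.data.frame(results)) results <- list(results)
  if (!length(results)) stop("no association results to summarize")
  all <- do.call(rbind, results)
  key <- interaction(all$group, all$habitat, drop = TRUE)
  rows <- lapply(split(all, key), function(df) {
    np <- sum(df$classification == "positive")
    nn <- sum(df$classification == "negative")
    ns <- sum(df$classification == "n.s.")
    nt <- nrow(df)
    general <- "none"
    if (nt >= min_transects) {
      if (np > nt / 2) general <- "positive"
      if (nn > nt / 2) general <- "negative"
    }
    data.frame(group = df$group[1L], habitat = df$habitat[1L],
               n_transects = nt, n_positive = np, n_negative = nn,
               n_ns = ns, general = general)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out[order(out$group, out$habitat), ]
}

#' Downsample a habitat map along the track
#'
#' Companion to [downsample_grid()]: merges `factor_cols` adjacent
#' columns by majority label over the valid constituent cells (ties go
#' to the smaller label; all-invalid blocks stay `NA`).
#'
#' @param map A [habitat_map()].
#' @param factor_cols Number of adjacent columns to merge.
#' @return A [habitat_map()] at the reduced resolution.
#' @export
downsample_map <- function(map, factor_cols) {
  stopifnot(inherits(map, "habitat_map"))
  factor_cols <- as.integer(factor_cols)
  if (factor_cols < 1L) stop("factor_cols must be >= 1")
  if (factor_cols == 1L) return(map)
  lab <- map$labels
  blocks <- (seq_len(ncol(lab)) - 1L) %/% factor_cols + 1L
  nb <- max(blocks)
  out <- matrix(NA_integer_, nrow(lab), nb)
  for (b in seq_len(nb)) {
    sub <- lab[, blocks == b, drop = FALSE]
    out[, b] <- apply(sub, 1L, function(v) {
      v <- v[!is.na(v)]
      if (!length(v)) return(NA_integer_)
      tab <- table(v)
      as.integer(names(tab)[which.max(tab)])
    })
  }
  habitat_map(map$transect_id, out,
              cell_length_m = map$cell_length_m * factor_cols,
              cell_depth_m = map$cell_depth_m)
}
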