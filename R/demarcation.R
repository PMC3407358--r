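#' Single-linkage partition of taxa at a distance threshold
#'
#' Clusters are the connected components of the graph joining every pair of
#' taxa whose PED is at or below the threshold. Computed via single-linkage
#' hierarchical clustering cut at the threshold height, which yields exactly
#' those components, deterministically and independent of input order.
#'
#' @param m A `ped_matrix`.
#' @param threshold Non-negative distance cutoff.
#' @return Named integer vector mapping each taxon to a cluster ID; clusters
#'   are numbered in order of first appearance along `m$taxa`.
#' @export
single_linkage_partition <- function(m, threshold) {
  stopifnot(threshold >= 0)
  hc <- hclust(as.dist(m$values), method = "single")
  relabel_partition(cutree(hc, h = threshold))
}

# renumber cluster ids by order of first appearance (stable labels)
relabel_partition <- function(p) {
  first <- match(unique(p), p)
  setNames(match(p, p[sort(first)]), names(p))
}

#' Clustering cost of a threshold
#'
#' Measures how badly a candidate demarcation threshold violates the
#' within/between structure of the distances. With `P` the single-linkage
#' partition at threshold `t`, the cost sums the violation magnitudes:
#' intra-cluster pairs more distant than `t` contribute `PED - t`, and
#' inter-cluster pairs closer than `t` contribute `t - PED`. The cost is 0
#' exactly when `t` perfectly separates intra- from inter-cluster
#' distances; thresholds lying in a clean gap of the divergence
#' distribution therefore have zero cost.
#'
#' @param m A `ped_matrix`.
#' @param threshold Non-negative distance cutoff.
#' @param partition Optional precomputed partition (named or plain vector
#'   in `m$taxa` order); computed from `m` and `threshold` if omitted.
#' @return Non-negative number.
#' @export
clustering_cost <- function(m, threshold, partition = NULL) {
  stopifnot(threshold >= 0)
  partition <- partition %||% single_linkage_partition(m, threshold)
  idx <- lower.tri(m$values)
  d <- m$values[idx]
  same <- outer(partition, partition, "==")[idx]
  sum(pmax(0, d[same] - threshold)) + sum(pmax(0, threshold - d[!same]))
}

#' Derive demarcation thresholds from a distance matrix
#'
#' Searches for the PED cutoffs that best separate the hierarchical levels
#' (species, genus, ...) implied by the divergence distribution. Candidate
#' thresholds are the midpoints between consecutive sorted unique pairwise
#' distances — a finite, complete search space whose resolution is limited
#' only by the data. Each candidate is scored with [clustering_cost()];
#' the profile is collapsed into runs of equal cost, and every run lying
#' strictly below its neighbours is a basin. A basin's support is the
#' interval of the threshold continuum over which its cost holds — from
#' the distance just below its first candidate to the distance just above
#' its last — so a wide distance gap yields a wide zero-cost basin.
#' Basins are ranked by cost (zero-cost basins — thresholds that separate
#' perfectly — come first), then by support width (the wider gap is the
#' stronger demarcation signal), then by depth (topographic prominence of
#' the cost profile); remaining ties go to the smaller threshold, refusing
#' to lump at a coarser cutoff than the data support. Each selected basin
#' is reported at the midpoint of its support, and the `n_levels` best
#' basins are returned in ascending threshold order.
#'
#' @param m A `ped_matrix`.
#' @param n_levels Number of taxonomic levels (thresholds) sought; default 1
#'   (species demarcation only).
#' @return A `demarcation` object: list with
#'   \describe{
#'     \item{thresholds}{ascending numeric vector (possibly shorter than
#'       `n_levels`, with a warning)}
#'     \item{partitions}{list of named membership vectors, one per threshold}
#'     \item{costs}{tibble `threshold`, `cost` over all candidates}
#'     \item{basins}{tibble `threshold`, `cost`, `width`, `depth` of all
#'       local-minimum basins}
#'     \item{model, gamma_shape}{distance model metadata carried from `m`}
#'   }
#' @export
find_thresholds <- function(m, n_levels = 1L) {
  stopifnot(n_levels >= 1L)
  v <- sort(unique(ped_values(m)))
  empty <- structure(
    list(thresholds = numeric(), partitions = list(),
         costs = tibble(threshold = numeric(), cost = numeric()),
         basins = tibble(threshold = numeric(), cost = numeric(),
                         width = numeric(), depth = numeric()),
         model = m$model, gamma_shape = m$gamma_shape),
    class = "demarcation")
  if (length(v) < 2L) {
    warn("Fewer than two distinct distances: no informative threshold")
    return(empty)
  }
  candidates <- (head(v, -1L) + tail(v, -1L)) / 2

  hc <- hclust(as.dist(m$values), method = "single")
  mem <- cutree(hc, h = candidates)  # n_taxa x n_candidates
  if (is.null(dim(mem))) mem <- matrix(mem, ncol = length(candidates))
  idx <- lower.tri(m$values)
  d <- m$values[idx]
  cost <- vapply(seq_along(candidates), function(k) {
    same <- outer(mem[, k], mem[, k], "==")[idx]
    sum(pmax(0, d[same] - candidates[k])) +
      sum(pmax(0, candidates[k] - d[!same]))
  }, numeric(1))
  costs <- tibble(threshold = candidates, cost = cost)

  basins <- cost_basins(v, candidates, cost)
  if (nrow(basins) < n_levels) {
    warn(paste0("Only ", nrow(basins), " informative cost basin(s) found; ",
                n_levels, " level(s) requested"))
  }
  sel <- basins[order(basins$cost, -basins$width, -basins$depth,
                      basins$threshold), , drop = FALSE]
  sel <- head(sel, n_levels)
  thresholds <- sort(sel$threshold)
  partitions <- purrr::map(thresholds, function(t) {
    relabel_partition(cutree(hc, h = t))
  })
  structure(
    list(thresholds = thresholds, partitions = partitions, costs = costs,
         basins = as_tibble(basins[order(basins$threshold), ]),
         model = m$model, gamma_shape = m$gamma_shape),
    class = "demarcation")
}

# Local-minimum plateaus of the cost profile.
# Candidates are collapsed into runs of equal cost; a run is a basin when
# no neighbouring run has lower-or-equal cost (edge runs qualify: the run
# bordering the smallest distances is how a clean intra-species region
# presents). Candidate k is the midpoint of unique distances (v[k], v[k+1]),
# so a run spanning candidates i..j holds its cost over the open interval
# (v[i], v[j+1]): that interval is the basin's support, its width the gap
# size, and its midpoint the reported threshold. Depth is topographic
# prominence (barrier walk stopping at the first strictly lower run; the
# profile is 0 outside the range), kept as a diagnostic and tie-breaker.
cost_basins <- function(v, candidates, cost, eps = 1e-12) {
  run_id <- cumsum(c(TRUE, abs(diff(cost)) > eps))
  run_cost <- as.numeric(tapply(cost, run_id, `[[`, 1L))
  run_first <- match(unique(run_id), run_id)
  run_last <- c(run_first[-1L] - 1L, length(candidates))
  r <- length(run_cost)
  out <- purrr::map(seq_len(r), function(i) {
    ci <- run_cost[[i]]
    if (i > 1L && run_cost[[i - 1L]] <= ci + eps) return(NULL)
    if (i < r && run_cost[[i + 1L]] <= ci + eps) return(NULL)
    sup_lo <- v[[run_first[[i]]]]
    sup_hi <- v[[run_last[[i]] + 1L]]
    barrier <- function(side) {
      best <- 0
      for (cval in side) {
        if (cval < ci - eps) break
        best <- max(best, cval)
      }
      best
    }
    bl <- if (i > 1L) barrier(run_cost[seq.int(i - 1L, 1L)]) else 0
    br <- if (i < r) barrier(run_cost[seq.int(i + 1L, r)]) else 0
    tibble(threshold = (sup_lo + sup_hi) / 2, cost = ci,
           width = sup_hi - sup_lo, depth = max(0, min(bl, br) - ci))
  })
  res <- dplyr::bind_rows(out)
  if (nrow(res) == 0L) {
    return(tibble(threshold = numeric(), cost = numeric(),
                  width = numeric(), depth = numeric()))
  }
  res
}

#' @export
print.demarcation <- function(x, ...) {
  cat("Demarcation result (model ", x$model, ")\n", sep = "")
  if (length(x$thresholds) == 0L) {
    cat("No informative thresholds found\n")
  } else {
    for (i in seq_along(x$thresholds)) {
      cat(sprintf("  level %d: threshold %.4f -> %d cluster(s)\n",
                  i, x$thresholds[i], max(x$partitions[[i]])))
    }
  }
  invisible(x)
}

#' Tidy a demarcation result
#'
#' @param x A `demarcation` object.
#' @param ... Unused.
#' @return Tibble with one row per recovered level: `level`, `threshold`,
#'   `n_clusters`, `cost`, `basin_width`, `basin_depth`.
#' @method tidy demarcation
#' @export
tidy.demarcation <- function(x, ...) {
  if (length(x$thresholds) == 0L) {
    return(tibble(level = integer(), threshold = numeric(),
                  n_clusters = integer(), cost = numeric(),
                  basin_width = numeric(), basin_depth = numeric()))
  }
  at <- match(x$thresholds, x$basins$threshold)
  tibble(
    level = seq_along(x$thresholds),
    threshold = x$thresholds,
    n_clusters = vapply(x$partitions, max, integer(1)),
    cost = x$basins$cost[at],
    basin_width = x$basins$width[at],
    basin_depth = x$basins$depth[at]
  )
}

#' @rdname tidy.demarcation
#' @method glance demarcation
#' @export
glance.demarcation <- function(x, ...) {
  n_taxa <- if (length(x$partitions) > 0L) length(x$partitions[[1]]) else NA_integer_
  tibble(
    n_levels = length(x$thresholds),
    n_candidates = nrow(x$costs),
    n_taxa = n_taxa,
    model = x$model,
    gamma_shape = x$gamma_shape
  )
}

#' Plot the clustering-cost profile of a demarcation
#'
#' Cost of every candidate threshold, with the selected demarcation
#' thresholds marked. Zero-cost valleys flanked by cost humps are the
#' distance gaps separating taxonomic levels.
#'
#' @param object A `demarcation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot demarcation
#' @export
autoplot.demarcation <- function(object, ...) {
  p <- ggplot2::ggplot(object$costs,
                       ggplot2::aes(x = .data$threshold, y = .data$cost)) +
    ggplot2::geom_line(colour = "grey30") +
    ggplot2::labs(x = "Candidate threshold (subst./site)",
                  y = "Clustering cost") +
    ggplot2::theme_minimal()
  if (length(object$thresholds) > 0L) {
    p <- p + ggplot2::geom_vline(xintercept = object$thresholds,
                                 linetype = "dashed", colour = "red3")
  }
  p
}

#' Classify a pair of taxa as same or different species
#'
#' Decides whether two taxa belong to the same group, either against
#' reference labels — the pair is conspecific if its PED does not exceed the
#' largest intra-species divergence observed among the labelled reference
#' species — or against explicit demarcation thresholds (one verdict per
#' level).
#'
#' @param m A `ped_matrix` containing both taxa.
#' @param taxon_a,taxon_b Taxon IDs.
#' @param labels Optional reference labels (tibble `taxon`, `species` or
#'   named vector); see [intra_group_max()].
#' @param thresholds Optional numeric thresholds or a `demarcation` object.
#' @return Tibble with one row per verdict: `taxon_a`, `taxon_b`, `ped`,
#'   `criterion` (`"intra_species_max"` or `"threshold_level_<i>"`),
#'   `reference` (the cutoff used), `same_group`.
#' @export
classify_pair <- function(m, taxon_a, taxon_b, labels = NULL,
                          thresholds = NULL) {
  if (is.null(labels) && is.null(thresholds)) {
    abort("Provide reference `labels` and/or `thresholds`")
  }
  missing <- setdiff(c(taxon_a, taxon_b), m$taxa)
  if (length(missing) > 0L) {
    abort(paste0("Taxa not in distance matrix: ",
                 paste(missing, collapse = ", ")))
  }
  d <- m$values[taxon_a, taxon_b]
  rows <- list()
  if (!is.null(labels)) {
    ref <- intra_group_max(m, labels)
    if (nrow(ref) == 0L) {
      abort("No labelled group with >= 2 members; cannot form a reference")
    }
    rows[[length(rows) + 1L]] <- tibble(
      taxon_a = taxon_a, taxon_b = taxon_b, ped = d,
      criterion = "intra_species_max",
      reference = max(ref$max_ped),
      same_group = d <= max(ref$max_ped)
    )
  }
  if (!is.null(thresholds)) {
    if (inherits(thresholds, "demarcation")) thresholds <- thresholds$thresholds
    for (i in seq_along(thresholds)) {
      rows[[length(rows) + 1L]] <- tibble(
        taxon_a = taxon_a, taxon_b = taxon_b, ped = d,
        criterion = paste0("threshold_level_", i),
        reference = thresholds[[i]],
        same_group = d <= thresholds[[i]]
      )
    }
  }
  dplyr::bind_rows(rows)
}
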