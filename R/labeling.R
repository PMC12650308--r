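#' Annotate cluster centroids with kinetic descriptions
#'
#' Detects, per centroid, the dominant kinetic pattern against the phase
#' schedule: whole-run monotone trends (Spearman |rho| >= `monotone_rho`),
#' phase-restricted ramps in the first or final phase, single peaks (placed
#' on a phase, or on a boundary when the maximum falls within one collection
#' of a phase transition), twin-peak biphasic shapes, and fluctuating
#' profiles. Centroids are standardized internally so margins are in z units.
#'
#' @param centroids Matrix with one centroid trajectory per row (columns =
#'   collections of `schedule`).
#' @param schedule A `phase_schedule`.
#' @param monotone_rho Spearman threshold for whole-run monotone trends.
#' @param peak_margin Minimum z-score height difference for a local maximum
#'   to count as a comparable peak.
#' @param edge_flat Maximum z range outside a phase for a phase-restricted
#'   ramp.
#' @return Tibble of class `cluster_annotation`: `cluster` (row id),
#'   `peak_location` (phase, boundary token, `"all"` or `"none"`), `trend`
#'   (increase / decrease / peak / biphasic / fluctuating), `description`.
#' @export
annotate_clusters <- function(centroids, schedule = build_schedule(),
                              monotone_rho = 0.8, peak_margin = 1.0,
                              edge_flat = 0.5) {
  if (is.null(dim(centroids))) centroids <- matrix(centroids, nrow = 1)
  if (ncol(centroids) != n_collections(schedule)) {
    abort("Centroid length does not match the schedule's collection count.")
  }
  ph <- as.character(schedule$phase)
  t <- schedule$collection_index
  bounds <- phase_boundaries(schedule)
  boundary_of <- function(idx) {
    for (b in bounds) if (idx %in% b$indices) return(b$token)
    NA_character_
  }
  phases_present <- unique(ph)
  first_phase <- phases_present[1]
  last_phase <- phases_present[length(phases_present)]

  ann_one <- function(v) {
    rng <- diff(range(v))
    if (rng < 1e-9) {
      return(list(peak_location = "none", trend = "fluctuating",
                  description = "constant profile, no dominant pattern"))
    }
    z <- (v - mean(v)) / sd(v)
    rho <- suppressWarnings(cor(z, t, method = "spearman"))
    ## a whole-run trend must also spread its variation across the run:
    ## rank correlation alone is fooled by a one-phase ramp with a long
    ## shallow monotone tail
    half <- seq_along(z) <= length(z) / 2
    spread <- min(diff(range(z[half])), diff(range(z[!half]))) /
      diff(range(z))
    if (!is.na(rho) && abs(rho) >= monotone_rho && spread >= 0.25) {
      tr <- if (rho > 0) "increase" else "decrease"
      return(list(
        peak_location = "all", trend = tr,
        description = sprintf("gradual %s throughout all phases", tr)
      ))
    }
    ## phase-restricted ramp in the final or first phase
    for (p in c(last_phase, first_phase)) {
      inp <- ph == p
      if (sum(inp) < 3) next
      z_in <- z[inp]
      z_out <- z[!inp]
      rho_in <- suppressWarnings(cor(z_in, t[inp], method = "spearman"))
      if (diff(range(z_out)) <= edge_flat &&
        diff(range(z_in)) >= 1 &&
        !is.na(rho_in) && abs(rho_in) >= 0.9) {
        tr <- if (rho_in > 0) "increase" else "decrease"
        return(list(
          peak_location = p, trend = tr,
          description = sprintf("%s restricted to phase %s", tr, p)
        ))
      }
    }
    ## peak census on a lightly smoothed profile
    zs <- smooth_spectrum(z, 3)
    peaks_at <- local_maxima(zs)
    peaks_at <- peaks_at[zs[peaks_at] > max(zs) - peak_margin]
    argmax <- which.max(v)
    loc <- boundary_of(t[argmax])
    if (is.na(loc)) loc <- ph[argmax]
    if (length(peaks_at) >= 3) {
      return(list(peak_location = "none", trend = "fluctuating",
                  description = "continuous fluctuation throughout all phases"))
    }
    if (length(peaks_at) == 2) {
      return(list(
        peak_location = loc, trend = "biphasic",
        description = sprintf("twin peaks, the larger in %s", loc)
      ))
    }
    list(
      peak_location = loc, trend = "peak",
      description = sprintf("peak %s %s",
        if (grepl("/", loc)) "at the boundary" else "in phase", loc)
    )
  }

  ann <- purrr::map(seq_len(nrow(centroids)), ~ ann_one(centroids[.x, ]))
  out <- tibble::tibble(
    cluster = rownames(centroids) %||% as.character(seq_len(nrow(centroids))),
    peak_location = purrr::map_chr(ann, "peak_location"),
    trend = purrr::map_chr(ann, "trend"),
    description = purrr::map_chr(ann, "description")
  )
  class(out) <- c("cluster_annotation", class(out))
  out
}

## interior local maxima plus endpoints strictly above their inner neighbour
local_maxima <- function(z) {
  n <- length(z)
  if (n < 3) return(which.max(z))
  interior <- which(z[2:(n - 1)] >= z[1:(n - 2)] & z[2:(n - 1)] > z[3:n]) + 1
  ends <- c(if (z[1] > z[2]) 1L, if (z[n] > z[n - 1]) n)
  sort(unique(c(interior, ends)))
}

#' Assign canonical letter codes to clusters
#'
#' Orders clusters along the experiment timeline and labels them A, B, C,
#' ... in that order: phase-localized patterns (peaks, boundary peaks,
#' phase-restricted ramps) sorted by the time of their dominant feature,
#' followed by fluctuating profiles, then whole-run monotone trends
#' (decrease before increase). This yields a reproducible lettering in the
#' narrative style of kinetic-signature taxonomies.
#'
#' @param centroids Centroid matrix (rows = clusters).
#' @param schedule A `phase_schedule`.
#' @param annotations Optional precomputed [annotate_clusters()] result.
#' @return Character vector of codes, one per centroid row, a permutation of
#'   `LETTERS[1:nrow(centroids)]` (or `K01...` beyond 26).
#' @export
assign_cluster_codes <- function(centroids, schedule = build_schedule(),
                                 annotations = NULL) {
  if (is.null(annotations)) {
    annotations <- annotate_clusters(centroids, schedule)
  }
  n <- nrow(centroids)
  position <- vapply(seq_len(n), function(i) {
    a <- annotations[i, ]
    v <- centroids[i, ]
    if (a$peak_location == "all") {
      ## whole-run trends sort last; decrease before increase
      1e6 + if (a$trend == "decrease") 0 else 1
    } else if (a$trend == "fluctuating") {
      1e5
    } else if (a$trend %in% c("increase", "decrease")) {
      mean(schedule$collection_index[as.character(schedule$phase) == a$peak_location])
    } else {
      which.max(v) - 1 + if (a$trend == "biphasic") -0.25 else 0
    }
  }, numeric(1))
  ord <- order(position, annotations$trend, seq_len(n))
  codes <- if (n <= 26) LETTERS[seq_len(n)] else sprintf("K%02d", seq_len(n))
  codes[order(ord)] # code of cluster i = rank of i in the ordering
}

#' Identify dominant clusters by membership mass
#'
#' Returns the `k` clusters holding the largest total membership mass
#' \eqn{\sum_i u_{ik}} — the clusters that absorb most features' memberships
#' and thereby mask ("drown") distinctive trajectories. Ties break by column
#' order.
#'
#' @param u Membership matrix with cluster codes as column names.
#' @param k Number of dominant clusters (< number of clusters).
#' @return Character vector of dominant cluster codes (empty if `k = 0`).
#' @export
identify_dominant <- function(u, k = 4) {
  stopifnot(k >= 0)
  if (k >= ncol(u)) abort("k must be smaller than the number of clusters.")
  if (k == 0) return(character(0))
  codes <- colnames(u) %||% as.character(seq_len(ncol(u)))
  mass <- colSums(u)
  codes[order(-mass, seq_along(mass))][seq_len(k)]
}

#' Assign kinetic labels with the dominant-cluster correction
#'
#' Per feature: the primary cluster is the global argmax of its membership
#' row; the masked primary is the argmax over the non-dominant clusters (the
#' drowning-effect correction); and the feature is selected for presentation
#' iff any non-dominant membership strictly exceeds `threshold`.
#'
#' @param u Membership matrix (features x clusters, cluster codes as column
#'   names).
#' @param annotations A [annotate_clusters()] tibble whose `cluster` column
#'   matches the membership column names (optional; adds descriptions).
#' @param dominant Character vector of dominant cluster codes (e.g. from
#'   [identify_dominant()]); must not cover all clusters.
#' @param threshold Strict membership threshold for selection, in (0, 1).
#' @return Tibble with one row per feature: `feature_id`, `primary_cluster`,
#'   `masked_primary`, `masked_membership`, `selected`, and a list-column
#'   `above_threshold` of (cluster, membership) pairs strictly above the
#'   threshold.
#' @export
assign_labels <- function(u, annotations = NULL, dominant = character(0),
                          threshold = 0.5) {
  stopifnot(threshold > 0, threshold < 1)
  codes <- colnames(u) %||% as.character(seq_len(ncol(u)))
  colnames(u) <- codes
  if (!all(dominant %in% codes)) abort("Dominant set contains unknown cluster codes.")
  non_dom <- setdiff(codes, dominant)
  if (length(non_dom) == 0) abort("Dominant set covers all clusters; nothing to mask.")
  nd_idx <- match(non_dom, codes)

  primary <- codes[apply(u, 1, which.max)]
  u_nd <- u[, nd_idx, drop = FALSE]
  masked <- non_dom[apply(u_nd, 1, which.max)]
  masked_u <- apply(u_nd, 1, max)
  selected <- apply(u_nd, 1, function(r) any(r > threshold))
  above <- purrr::map(seq_len(nrow(u)), function(i) {
    hit <- which(u[i, ] > threshold)
    tibble::tibble(cluster = codes[hit], membership = unname(u[i, hit]))
  })
  out <- tibble::tibble(
    feature_id = rownames(u) %||% sprintf("F%05d", seq_len(nrow(u))),
    primary_cluster = primary,
    masked_primary = masked,
    masked_membership = unname(masked_u),
    selected = unname(selected),
    above_threshold = above
  )
  if (!is.null(annotations)) {
    out <- dplyr::left_join(
      out,
      dplyr::select(tibble::as_tibble(annotations),
        masked_primary = "cluster", annotation = "description"
      ),
      by = "masked_primary"
    )
  }
  out
}

#' Hierarchical clustering of features in membership space
#'
#' Uses the membership rows as soft labels for agglomerative clustering with
#' Ward's linkage on Euclidean distances, cut at `n_groups`.
#'
#' @param u Membership matrix (features x clusters).
#' @param n_groups Number of groups to cut the dendrogram into.
#' @return List with `groups` (tibble `feature_id`, `group`), `tree` (the
#'   `hclust` object) and `newick` (Newick serialization of the dendrogram).
#' @export
hca_on_memberships <- function(u, n_groups) {
  stopifnot(n_groups >= 1)
  if (n_groups > nrow(u)) abort("n_groups exceeds the number of features.")
  ids <- rownames(u) %||% sprintf("F%05d", seq_len(nrow(u)))
  rownames(u) <- ids
  tree <- hclust(dist(u), method = "ward.D2")
  groups <- cutree(tree, k = n_groups)
  newick <- if (nrow(u) >= 3) {
    ape::write.tree(ape::as.phylo(tree))
  } else {
    NA_character_
  }
  list(
    groups = tibble::tibble(feature_id = ids, group = as.integer(groups)),
    tree = tree,
    newick = newick
  )
}
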