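#' Fuzzy membership update
#'
#' Computes the fuzzy c-means membership matrix for fixed centroids: with
#' Euclidean distances \eqn{d_{ik} = \lVert x_i - v_k \rVert},
#' \deqn{u_{ik} = \left[ \sum_{j=1}^{c} \left( d_{ik} / d_{ij} \right)^{2/(m-1)} \right]^{-1}.}
#' Rows sum to one. A point coinciding with one or more centroids splits its
#' membership equally among the coincident centroids (the formula's singular
#' case, resolved by symmetry).
#'
#' @param x Numeric matrix, rows are the objects being clustered (features)
#'   in trajectory space.
#' @param centroids Numeric matrix, one centroid per row, same columns as `x`.
#' @param m Fuzzifier, must be > 1.
#' @return Membership matrix, `nrow(x)` x `nrow(centroids)`.
#' @export
update_memberships <- function(x, centroids, m) {
  if (m <= 1) abort("Fuzzifier m must be > 1 (m -> 1 is the hard k-means limit).")
  d2 <- pmax(dist2_matrix(x, centroids), 0)
  ## divide by the row minimum before raising to -1/(m-1): mathematically a
  ## no-op after normalization, numerically it prevents overflow when m is
  ## close to 1 (exponents like -100)
  dmin <- apply(d2, 1, min)
  ratio <- d2 / pmax(dmin, 1e-300)
  pw <- ratio^(-1 / (m - 1))
  u <- pw / rowSums(pw)
  ## coincident points: d = 0; split membership equally among the coincident
  ## centroids (the formula's singular case, resolved by symmetry)
  zero_rows <- which(dmin < 1e-24)
  for (i in zero_rows) {
    hit <- d2[i, ] < 1e-24
    u[i, ] <- ifelse(hit, 1 / sum(hit), 0)
  }
  u
}

## squared Euclidean distances between rows of x and rows of v
dist2_matrix <- function(x, v) {
  xx <- rowSums(x^2)
  vv <- rowSums(v^2)
  outer(xx, vv, `+`) - 2 * tcrossprod(x, v)
}

#' Fuzzy centroid update
#'
#' Weighted-mean centroid step of fuzzy c-means:
#' \eqn{v_k = \sum_i u_{ik}^m x_i / \sum_i u_{ik}^m}. A cluster whose total
#' weight vanishes is re-seeded from the point farthest from its nearest
#' centroid.
#'
#' @param x Data matrix (objects in rows).
#' @param u Membership matrix.
#' @param m Fuzzifier (> 1).
#' @return Centroid matrix, one row per cluster.
#' @export
update_centroids <- function(x, u, m) {
  w <- u^m
  tot <- colSums(w)
  v <- crossprod(w, x) / tot
  dead <- which(tot < 1e-300 | !is.finite(tot))
  if (length(dead) > 0) {
    d2 <- dist2_matrix(x, v[-dead, , drop = FALSE])
    far <- order(apply(d2, 1, min), decreasing = TRUE)
    v[dead, ] <- x[far[seq_along(dead)], , drop = FALSE]
  }
  v
}

fcm_objective <- function(x, u, v, m) {
  sum(u^m * pmax(dist2_matrix(x, v), 0))
}

#' Xie-Beni cluster validity index
#'
#' Ratio of the fuzzy within-cluster compactness to the minimum squared
#' separation between centroids:
#' \deqn{XB = \frac{\sum_i \sum_k u_{ik}^m \lVert x_i - v_k \rVert^2}{n \cdot \min_{k \ne l} \lVert v_k - v_l \rVert^2}.}
#' Lower values indicate tighter, better-separated partitions.
#'
#' @param x Data matrix.
#' @param u Membership matrix.
#' @param v Centroid matrix (>= 2 distinct rows).
#' @param m Fuzzifier.
#' @return Positive scalar.
#' @export
xie_beni <- function(x, u, v, m) {
  stopifnot(nrow(v) >= 2)
  sep <- dist2_matrix(v, v)
  diag(sep) <- Inf
  min_sep <- min(sep)
  if (min_sep < 1e-24) abort("Duplicate centroids: Xie-Beni separation is zero.")
  fcm_objective(x, u, v, m) / (nrow(x) * min_sep)
}

#' Fit fuzzy c-means
#'
#' Alternates membership and centroid updates from k-means++-style seedings
#' until the largest entrywise membership change falls below `tol` or
#' `max_iter` is reached; the best of `n_init` restarts by final objective is
#' returned. Deterministic under a fixed seed.
#'
#' @param x Numeric matrix of standardized trajectories (features in rows).
#' @param c Number of clusters (>= 2, < number of rows).
#' @param m Fuzzifier (> 1).
#' @param seed Integer seed.
#' @param tol Convergence tolerance on max |change in membership|.
#' @param max_iter Iteration cap per restart.
#' @param n_init Number of random restarts.
#' @return List of class `fcm_fit`: `centroids`, `memberships`, `m`, `c`,
#'   `objective_trace` (non-increasing), `objective`, `xb`, `n_iter`,
#'   `converged`, `seed`.
#' @examples
#' x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 6), 10))
#' fit <- fit_fcm(x, c = 2, m = 2, seed = 1)
#' glance(fit)
#' @export
fit_fcm <- function(x, c, m, seed = 1L, tol = 1e-6, max_iter = 200L,
                    n_init = 10L) {
  stopifnot(is.matrix(x))
  if (any(!is.finite(x))) abort("Non-finite values in the input matrix.")
  if (c < 2) abort("Need at least 2 clusters.")
  if (nrow(x) <= c) abort("Need more features than clusters.")
  if (m <= 1) abort("Fuzzifier m must be > 1.")
  set.seed(seed)
  best <- NULL
  for (init in seq_len(n_init)) {
    ## first restart: deterministic farthest-point (maximin) seeding, which
    ## covers well-separated groups reliably; remaining restarts: k-means++
    v <- if (init == 1) maximin_init(x, c) else kmeanspp_init(x, c)
    u_prev <- NULL
    trace <- numeric(0)
    converged <- FALSE
    for (it in seq_len(max_iter)) {
      u <- update_memberships(x, v, m)
      v <- update_centroids(x, u, m)
      trace <- c(trace, fcm_objective(x, u, v, m))
      if (!is.null(u_prev) && max(abs(u - u_prev)) < tol) {
        converged <- TRUE
        break
      }
      u_prev <- u
    }
    j <- trace[length(trace)]
    if (is.null(best) || j < best$objective - 1e-12) {
      best <- list(
        centroids = v, memberships = u, objective = j,
        objective_trace = trace, n_iter = length(trace),
        converged = converged
      )
    }
  }
  rownames(best$centroids) <- NULL
  if (!is.null(rownames(x))) rownames(best$memberships) <- rownames(x)
  ## a degenerate partition (coincident centroids, typically from overfit c)
  ## has zero separation: score it as infinitely bad rather than fail the fit
  xb <- tryCatch(
    xie_beni(x, best$memberships, best$centroids, m),
    error = function(e) Inf
  )
  structure(
    c(best, list(c = as.integer(c), m = m, seed = seed, xb = xb)),
    class = "fcm_fit"
  )
}

## farthest-point seeding: start from the point farthest from the data mean,
## then repeatedly take the point maximizing the distance to the nearest
## chosen centroid (deterministic)
maximin_init <- function(x, c) {
  n <- nrow(x)
  mu <- colMeans(x)
  idx <- integer(c)
  idx[1] <- which.max(rowSums((x - matrix(mu, n, ncol(x), byrow = TRUE))^2))
  d2 <- rep(Inf, n)
  for (k in 2:c) {
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[k - 1], ], n, ncol(x), byrow = TRUE))^2))
    idx[k] <- which.max(d2)
  }
  x[idx, , drop = FALSE]
}

## k-means++ seeding: spread initial centroids with distance-weighted draws
kmeanspp_init <- function(x, c) {
  n <- nrow(x)
  idx <- integer(c)
  idx[1] <- sample.int(n, 1)
  d2 <- rep(Inf, n)
  for (k in 2:c) {
    d2 <- pmin(d2, rowSums((x - matrix(x[idx[k - 1], ], n, ncol(x), byrow = TRUE))^2))
    p <- d2 / sum(d2)
    idx[k] <- if (all(p == 0)) sample.int(n, 1) else sample.int(n, 1, prob = p)
  }
  x[idx, , drop = FALSE] + matrix(rnorm(c * ncol(x), 0, 1e-9), c)
}

#' @export
print.fcm_fit <- function(x, ...) {
  cat(sprintf(
    "<fcm_fit> c=%d clusters, m=%.3g, n=%d features, J=%.4g, XB=%.4g (%s in %d iter)\n",
    x$c, x$m, nrow(x$memberships), x$objective, x$xb,
    if (x$converged) "converged" else "not converged", x$n_iter
  ))
  invisible(x)
}

#' Joint grid search for the cluster count and fuzzifier
#'
#' Fits fuzzy c-means at every combination of `c_grid` and `m_grid` and
#' selects the pair minimizing the Xie-Beni index; ties break toward the
#' smaller cluster count, then the smaller fuzzifier.
#'
#' @param x Standardized trajectory matrix.
#' @param c_grid Integer vector of candidate cluster counts.
#' @param m_grid Numeric vector of candidate fuzzifiers (> 1).
#' @param seed Integer seed (each grid point fits with the same seed).
#' @param ... Passed to [fit_fcm()] (`tol`, `max_iter`, `n_init`).
#' @return List with `c_opt`, `m_opt`, and `xb_table` — a tibble of the full
#'   grid (`c`, `m`, `xb`, `objective`, `n_iter`, `selected`).
#' @export
select_parameters <- function(x, c_grid = c(8, 12, 16, 20),
                              m_grid = c(1.25, 1.5, 2),
                              seed = 1L, ...) {
  if (length(c_grid) == 0 || length(m_grid) == 0) abort("Parameter grids must be non-empty.")
  if (any(m_grid <= 1)) abort("All fuzzifier grid values must be > 1.")
  grid <- tidyr::expand_grid(c = sort(unique(c_grid)), m = sort(unique(m_grid)))
  res <- purrr::pmap_dfr(grid, function(c, m) {
    fit <- fit_fcm(x, c = c, m = m, seed = seed, ...)
    tibble::tibble(
      c = c, m = m, xb = fit$xb,
      objective = fit$objective, n_iter = fit$n_iter
    )
  })
  ## argmin XB; ties toward smaller c, then smaller m (row order encodes this)
  best <- res[order(res$xb, res$c, res$m), ][1, ]
  res$selected <- res$c == best$c & res$m == best$m
  list(c_opt = as.integer(best$c), m_opt = best$m, xb_table = res)
}

#' @describeIn fit_fcm Per-cluster summary: membership mass and centroid
#'   coordinates in long form.
#' @param x An `fcm_fit`.
#' @param ... Unused.
#' @method tidy fcm_fit
#' @export
tidy.fcm_fit <- function(x, ...) {
  cl <- cluster_ids(x)
  tibble::tibble(
    cluster = cl,
    membership_mass = colSums(x$memberships),
    n_primary = as.integer(table(factor(
      cl[apply(x$memberships, 1, which.max)],
      levels = cl
    )))
  )
}

#' @describeIn fit_fcm One-row model summary.
#' @method glance fcm_fit
#' @export
glance.fcm_fit <- function(x, ...) {
  tibble::tibble(
    c = x$c, m = x$m, n = nrow(x$memberships),
    objective = x$objective, xb = x$xb,
    n_iter = x$n_iter, converged = x$converged
  )
}

#' @describeIn fit_fcm Feature-level memberships with the argmax cluster.
#' @param data Optional tibble of feature metadata to bind (one row per
#'   feature, same order).
#' @method augment fcm_fit
#' @export
augment.fcm_fit <- function(x, data = NULL, ...) {
  cl <- cluster_ids(x)
  u <- x$memberships
  out <- tibble::tibble(
    feature_id = rownames(u) %||% sprintf("F%05d", seq_len(nrow(u))),
    primary_cluster = cl[apply(u, 1, which.max)],
    max_membership = apply(u, 1, max)
  )
  um <- tibble::as_tibble(u, .name_repair = ~ paste0("u_", cl))
  out <- dplyr::bind_cols(out, um)
  if (!is.null(data)) out <- dplyr::bind_cols(tibble::as_tibble(data), out)
  out
}

cluster_ids <- function(fit) {
  cl <- colnames(fit$memberships)
  if (is.null(cl)) {
    if (fit$c <= 26) LETTERS[seq_len(fit$c)] else sprintf("K%02d", seq_len(fit$c))
  } else {
    cl
  }
}

#' Serialize an FCM model to JSON
#'
#' @param fit An `fcm_fit`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_fcm_model <- function(fit, path) {
  jsonlite::write_json(
    list(
      c = fit$c, m = fit$m, xb = fit$xb, objective = fit$objective,
      seed = fit$seed, n_iter = fit$n_iter, converged = fit$converged,
      centroids = fit$centroids
    ),
    path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(path)
}
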