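#' Gower distance matrix for categorical risk-factor profiles
#'
#' With all variables unordered categorical and equally weighted, the Gower
#' dissimilarity between two patients reduces to the proportion of variables
#' on which they differ (simple matching). Binary variables are treated
#' symmetrically. Distances lie in `[0, 1]`, are zero on the diagonal, and
#' satisfy the triangle inequality.
#'
#' @param features data.frame of factors / characters / logicals, one row
#'   per patient.
#' @return symmetric `n x n` distance matrix.
#' @export
gower_matrix <- function(features) {
  stopifnot(nrow(features) >= 2L)
  n <- nrow(features); p <- ncol(features)
  d <- matrix(0, n, n)
  for (j in seq_len(p)) {
    v <- as.character(features[[j]])
    if (anyNA(v)) stop("features must not contain missing values")
    d <- d + outer(v, v, "!=")
  }
  d <- d / p
  if (all(d == 0)) warning("constant feature table: all distances are zero")
  dimnames(d) <- list(rownames(features), rownames(features))
  d
}

#' Partition around medoids on a precomputed distance matrix
#'
#' k-medoids clustering minimising the total distance of each point to its
#' cluster medoid. When the number of candidate medoid sets `choose(n, k)`
#' is at most `exact_limit`, the global optimum is found by exhaustive
#' enumeration (the classic BUILD+SWAP search is a local search and can,
#' rarely, stop in a local optimum on small problems). Otherwise BUILD
#' initialisation followed by steepest-descent SWAP iterations is used,
#' with ties broken by the lowest row index, so the result is deterministic.
#'
#' @param d symmetric distance matrix (or `dist`).
#' @param k number of clusters, `2 <= k <= n` (`k = n` gives cost 0).
#' @param exact_limit enumerate all medoid sets when `choose(n, k)` is at
#'   most this value (default 5000).
#' @return object of class `pam_solution`: `k`, `medoid_ids`, `assignment`
#'   (each point's cluster, 1..k), `total_cost`, `avg_silhouette`.
#' @export
pam_fit <- function(d, k, exact_limit = 5000) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must satisfy 1 <= k <= n")
  cost_of <- function(med) {
    sum(do.call(pmin, c(as.data.frame(d[, med, drop = FALSE]), na.rm = FALSE)))
  }
  if (k == n) {
    med <- seq_len(n)
  } else if (choose(n, k) <= exact_limit) {
    sets <- utils::combn(n, k)
    costs <- colSums(Reduce(pmin, lapply(seq_len(k), function(r) {
      d[, sets[r, ], drop = FALSE]
    })))
    med <- sets[, which.min(costs)]
  } else {
    # BUILD: greedily add the medoid giving the largest cost decrease
    med <- which.min(colSums(d))
    dn <- d[, med]
    while (length(med) < k) {
      gains <- colSums(pmax(dn - d, 0))
      gains[med] <- -Inf
      j <- which.max(gains)
      med <- c(med, j)
      dn <- pmin(dn, d[, j])
    }
    # SWAP: steepest descent over single medoid replacements, using the
    # nearest/second-nearest decomposition to score all swaps in O(n^2 k)
    repeat {
      dm <- d[, med, drop = FALSE]
      near_i <- max.col(-dm, ties.method = "first")
      dn <- dm[cbind(seq_len(n), near_i)]
      dm[cbind(seq_len(n), near_i)] <- Inf
      ds <- do.call(pmin, as.data.frame(dm))
      cur <- sum(dn)
      cand <- setdiff(seq_len(n), med)
      best <- cur; best_i <- NA; best_j <- NA
      for (i in seq_along(med)) {
        base <- ifelse(near_i == i, ds, dn)
        costs <- colSums(pmin(d[, cand, drop = FALSE], base))
        j <- which.min(costs)
        if (costs[j] < best - 1e-12) {
          best <- costs[j]; best_i <- i; best_j <- cand[j]
        }
      }
      if (is.na(best_i)) break
      med[best_i] <- best_j
    }
    med <- sort(med)
  }
  assign_idx <- apply(d[, med, drop = FALSE], 1, which.min)
  sol <- structure(list(k = k, medoid_ids = med,
                        assignment = as.integer(assign_idx),
                        total_cost = cost_of(med),
                        avg_silhouette = NA_real_),
                   class = "pam_solution")
  sol$avg_silhouette <- avg_silhouette(d, sol$assignment)
  sol
}

#' Average silhouette width of a clustering
#'
#' `s(i) = (b - a) / max(a, b)` where `a` is the mean distance of `i` to its
#' own cluster's other members and `b` the smallest mean distance to another
#' cluster. Points in singleton clusters get `s(i) = 0` (the standard
#' convention).
#'
#' @param d symmetric distance matrix.
#' @param assignment integer cluster labels.
#' @return mean silhouette width over all points.
#' @export
avg_silhouette <- function(d, assignment) {
  d <- as.matrix(d)
  n <- nrow(d)
  ks <- sort(unique(assignment))
  if (length(ks) < 2L) return(NA_real_)
  s <- numeric(n)
  sizes <- table(assignment)
  for (i in seq_len(n)) {
    ci <- assignment[i]
    if (sizes[[as.character(ci)]] == 1L) { s[i] <- 0; next }
    a <- mean(d[i, assignment == ci & seq_len(n) != i])
    b <- min(vapply(ks[ks != ci], function(cc) mean(d[i, assignment == cc]),
                    numeric(1)))
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  mean(s)
}

#' Select the number of clusters by average silhouette width
#'
#' Fits [pam_fit()] for every `k` in `k_range` and returns the `k`
#' maximising the average silhouette width, together with the whole profile.
#'
#' @param d symmetric distance matrix.
#' @param k_range candidate cluster counts (default 2:10).
#' @param exact_limit passed to [pam_fit()].
#' @return list with `best_k`, `profile` (data.frame `k`,
#'   `avg_silhouette`), and `solutions` (one [pam_fit()] object per k).
#' @export
select_k <- function(d, k_range = 2:10, exact_limit = 5000) {
  d <- as.matrix(d)
  k_range <- k_range[k_range > 1 & k_range < nrow(d)]
  sols <- lapply(k_range, function(k) pam_fit(d, k, exact_limit))
  sil <- vapply(sols, function(s) s$avg_silhouette, numeric(1))
  list(best_k = k_range[which.max(sil)],
       profile = data.frame(k = k_range, avg_silhouette = sil),
       solutions = stats::setNames(sols, paste0("k", k_range)))
}

#' Cluster patients on categorical risk factors
#'
#' Builds the Gower distance on the feature table and runs silhouette-based
#' model selection. For populations larger than `subsample_threshold` the
#' full n-by-n distance matrix is not materialised: clustering runs on a
#' seeded subsample and the remaining patients are assigned to the nearest
#' medoid by direct Gower distance to the medoids (a CLARA-style strategy).
#'
#' @param features categorical feature data.frame (one row per patient).
#' @param k_range candidate numbers of clusters (default 2:10).
#' @param subsample_threshold n above which subsample-and-assign is used
#'   (default 10000).
#' @param subsample_size subsample size in that regime (default 2000).
#' @param seed seed controlling the subsample draw only.
#' @return list with `best_k`, `profile`, `assignment` (full-population
#'   cluster labels), `medoid_rows` (row indices of the medoids).
#' @export
cluster_patients <- function(features, k_range = 2:10,
                             subsample_threshold = 10000,
                             subsample_size = 2000, seed = 1) {
  n <- nrow(features)
  if (n <= subsample_threshold) {
    d <- gower_matrix(features)
    sel <- select_k(d, k_range)
    sol <- sel$solutions[[paste0("k", sel$best_k)]]
    return(list(best_k = sel$best_k, profile = sel$profile,
                assignment = sol$assignment,
                medoid_rows = sol$medoid_ids))
  }
  set.seed(seed)
  sub <- sort(sample.int(n, subsample_size))
  d <- gower_matrix(features[sub, , drop = FALSE])
  sel <- select_k(d, k_range)
  sol <- sel$solutions[[paste0("k", sel$best_k)]]
  med_rows <- sub[sol$medoid_ids]
  dm <- gower_to_rows(features, med_rows)
  list(best_k = sel$best_k, profile = sel$profile,
       assignment = as.integer(apply(dm, 1, which.min)),
       medoid_rows = med_rows)
}

# rectangular Gower distances from every row to the given reference rows
gower_to_rows <- function(features, rows) {
  p <- ncol(features)
  out <- matrix(0, nrow(features), length(rows))
  for (j in seq_len(p)) {
    v <- as.character(features[[j]])
    out <- out + outer(v, v[rows], "!=")
  }
  out / p
}
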