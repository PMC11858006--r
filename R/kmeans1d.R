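#' Exact one-dimensional k-means clustering
#'
#' Fits the globally optimal k-means partition of a univariate sample.  In
#' one dimension the optimal clusters are contiguous intervals of the
#' sorted sample, so the exact optimum is found by dynamic programming —
#' no random restarts, no seed, and the within-cluster sum of squares is
#' never worse than any Lloyd-style run.
#'
#' @param sample numeric vector of finite values (e.g. follicle diameters
#'   in mm).
#' @param k number of clusters, `1 <= k <= length(sample)`.
#' @return an object of class `cluster_model`: `k`, `centres` (ascending
#'   cluster means), `assignments` (cluster index per input observation,
#'   1 = lowest centre), `within_ss` (total), `cluster_withinss`,
#'   `cluster_sizes`, `cluster_means`, `cluster_sds`,
#'   `min_of_upper_cluster` (smallest value assigned to the top cluster).
#' @examples
#' kmeans_1d(c(1, 2, 3, 100, 101, 102), k = 2)
#' @export
kmeans_1d <- function(sample, k) {
  x <- as.numeric(sample)
  if (anyNA(x) || any(!is.finite(x))) stop("sample contains non-finite values")
  k <- as.integer(k)
  if (k < 1) stop("k must be at least 1")
  if (k > length(x)) stop("k exceeds the number of observations")
  ord <- order(x)
  fit <- .kmeans1d_cpp(x[ord], k)
  assignments <- integer(length(x))
  assignments[ord] <- fit$assignments
  sds <- vapply(seq_len(k), function(q) {
    v <- x[assignments == q]
    if (length(v) > 1) sd(v) else 0
  }, numeric(1))
  structure(
    list(k = k,
         centres = as.numeric(fit$centres),
         assignments = assignments,
         within_ss = fit$tot_withinss,
         cluster_withinss = as.numeric(fit$withinss),
         cluster_sizes = as.integer(fit$sizes),
         cluster_means = as.numeric(fit$centres),
         cluster_sds = sds,
         min_of_upper_cluster = min(x[assignments == k])),
    class = "cluster_model"
  )
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("Exact 1-D k-means, k = %d, within-SS = %.6g\n",
              x$k, x$within_ss))
  print(data.frame(centre = x$centres, size = x$cluster_sizes,
                   sd = x$cluster_sds, withinss = x$cluster_withinss))
  invisible(x)
}

# mean distance from each point to every cluster, via per-cluster sorted
# prefix sums: O(n k log n) instead of a full distance matrix
.mean_silhouette <- function(x, assignments, k) {
  n <- length(x)
  pre <- lapply(seq_len(k), function(q) {
    v <- sort(x[assignments == q])
    list(v = v, cs = cumsum(v), n = length(v))
  })
  sum_abs <- function(p, pts) {
    # sum over v in cluster of |pt - v| for each pt
    r <- findInterval(pts, p$v)
    csr <- ifelse(r > 0, p$cs[pmax(r, 1L)], 0)
    (pts * r - csr) + (p$cs[p$n] - csr) - pts * (p$n - r)
  }
  s <- numeric(n)
  a <- numeric(n)
  b <- rep(Inf, n)
  for (q in seq_len(k)) {
    tot <- sum_abs(pre[[q]], x)
    own <- assignments == q
    a[own] <- if (pre[[q]]$n > 1) tot[own] / (pre[[q]]$n - 1) else NA_real_
    b[!own] <- pmin(b[!own], tot[!own] / pre[[q]]$n)
  }
  singleton <- is.na(a)
  s[!singleton] <- (b[!singleton] - a[!singleton]) /
    pmax(a[!singleton], b[!singleton])
  s[singleton] <- 0  # silhouette of a singleton cluster defined as 0
  mean(s)
}

#' Choose the number of clusters by elbow and silhouette criteria
#'
#' Runs [kmeans_1d()] over a grid of candidate cluster counts and reports
#' two selections: the elbow (the k maximising the second difference of
#' total within-cluster sum of squares, ties resolved towards smaller k)
#' and the silhouette (the k >= 2 maximising mean silhouette width, with
#' singleton clusters contributing width 0).
#'
#' @inheritParams kmeans_1d
#' @param candidate_ks integer vector of candidate cluster counts within
#'   `[1, 10]`; the elbow needs at least three consecutive candidates.
#' @return an object of class `k_selection`: `candidate_ks`, `elbow_k`,
#'   `silhouette_k`, `total_within_ss_by_k`, `mean_silhouette_by_k`.
#' @export
select_k <- function(sample, candidate_ks = 1:8) {
  x <- as.numeric(sample)
  candidate_ks <- sort(unique(as.integer(candidate_ks)))
  if (any(candidate_ks < 1L) || any(candidate_ks > 10L)) {
    stop("candidate_ks must lie within [1, 10]")
  }
  if (length(x) <= max(candidate_ks)) {
    stop("sample size must exceed max(candidate_ks)")
  }
  if (length(unique(x)) == 1L) stop("no dispersion")

  fits <- lapply(candidate_ks, function(k) kmeans_1d(x, k))
  wss <- vapply(fits, `[[`, numeric(1), "within_ss")
  sil <- vapply(seq_along(candidate_ks), function(i) {
    if (candidate_ks[i] < 2L) return(NA_real_)
    .mean_silhouette(x, fits[[i]]$assignments, candidate_ks[i])
  }, numeric(1))

  # elbow: maximal second difference of within-SS over consecutive ks
  elbow_k <- NA_integer_
  interior <- which(candidate_ks %in% (candidate_ks + 1L) &
                    candidate_ks %in% (candidate_ks - 1L))
  if (length(interior)) {
    idx <- match(candidate_ks[interior], candidate_ks)
    d2 <- wss[idx - 1L] - 2 * wss[idx] + wss[idx + 1L]
    elbow_k <- candidate_ks[interior][which.max(d2)]  # ties: smaller k wins
  }
  sil_ok <- which(!is.na(sil))
  silhouette_k <- if (length(sil_ok)) {
    candidate_ks[sil_ok][which.max(sil[sil_ok])]
  } else NA_integer_

  structure(
    list(candidate_ks = candidate_ks,
         elbow_k = elbow_k,
         silhouette_k = silhouette_k,
         total_within_ss_by_k = setNames(wss, candidate_ks),
         mean_silhouette_by_k = setNames(sil, candidate_ks)),
    class = "k_selection"
  )
}

#' @export
print.k_selection <- function(x, ...) {
  cat("Cluster-count selection\n")
  print(data.frame(k = x$candidate_ks,
                   within_ss = unname(x$total_within_ss_by_k),
                   mean_silhouette = unname(x$mean_silhouette_by_k)))
  cat(sprintf("  elbow k = %s, silhouette k = %s\n",
              x$elbow_k, x$silhouette_k))
  invisible(x)
}

#' Derive the dominant-follicle diameter threshold
#'
#' Given a two-cluster model of follicle diameters, returns the integer
#' threshold (mm) below which follicles are classified non-dominant: the
#' floor of the smallest diameter in the upper cluster, interpreted as a
#' strict lower bound (a follicle is dominant iff its diameter exceeds the
#' threshold; a diameter exactly at the threshold is non-dominant).
#'
#' @param model a `cluster_model` with `k = 2` fitted to diameters in mm.
#' @return threshold in mm (single number).
#' @examples
#' m <- kmeans_1d(c(rnorm(60, 8, 2), rnorm(60, 30, 2.5)), 2)
#' derive_dominance_threshold(m)
#' @export
derive_dominance_threshold <- function(model) {
  if (!inherits(model, "cluster_model")) stop("model must be a cluster_model")
  if (model$k != 2L) stop("threshold derivation requires k = 2")
  floor(model$min_of_upper_cluster)
}
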