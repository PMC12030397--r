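#' K-means autonomic profiling with cluster-count validation
#'
#' Runs k-means (multiple restarts) on z-scored marker features over a range
#' of cluster counts, computes the elbow curve (total within-cluster sum of
#' squares vs k) and the average silhouette width per k, and returns the
#' full solution for the silhouette-maximizing k.
#'
#' @param data Wide-format data (e.g. [marker_table_wide()] output).
#' @param features Feature column names (default the two workload-relevant
#'   markers, sympathetic EDA_TVSYMP and vagal HF_VFCDM).
#' @param k_range Candidate cluster counts (default 2:8).
#' @param n_restarts Random restarts per k (default 25).
#' @param seed Integer seed.
#' @param scope Either "all" (cluster all subject-by-condition rows) or a
#'   condition label (e.g. "COG") to cluster that condition only.
#' @return A list of class `cluster_solution`: `k`, `assignments`,
#'   `centroids`, `wcss` (per cluster), `tot_wcss`, `between_ss`, `total_ss`,
#'   `between_ratio`, `avg_silhouette`, `elbow` (k, wcss, silhouette), `rows`
#'   (subject/condition of each clustered row).
#' @export
kmeans_profiles <- function(data, features = c("EDA_TVSYMP", "HF_VFCDM"),
                            k_range = 2:8, n_restarts = 25, seed = 1L,
                            scope = "all") {
  df <- as.data.frame(data)
  if (!identical(scope, "all")) df <- df[df$condition == scope, ]
  miss <- setdiff(features, names(df))
  if (length(miss)) stop("feature column(s) not found: ", paste(miss, collapse = ", "))
  X <- as.matrix(df[features])
  if (nrow(X) < 10) stop("need at least 10 rows to cluster")
  if (max(k_range) >= nrow(X)) stop("k_range exceeds number of rows")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0) || sum(stats::dist(X)) == 0)
    stop("degenerate features: zero variance, silhouette undefined")
  X <- scale(X)

  D <- stats::dist(X)
  elbow <- data.frame(k = k_range, wcss = NA_real_, silhouette = NA_real_)
  fits <- list()
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    set.seed(seed + k)
    km <- stats::kmeans(X, centers = k, nstart = n_restarts, iter.max = 100)
    sil <- cluster::silhouette(km$cluster, D)
    elbow$wcss[i] <- km$tot.withinss
    elbow$silhouette[i] <- mean(sil[, 3])
    fits[[i]] <- km
  }
  best <- which.max(elbow$silhouette)
  km <- fits[[best]]
  structure(list(
    k = k_range[best], assignments = km$cluster,
    centroids = km$centers, wcss = km$withinss, tot_wcss = km$tot.withinss,
    between_ss = km$betweenss, total_ss = km$totss,
    between_ratio = km$betweenss / km$totss,
    avg_silhouette = elbow$silhouette[best], elbow = elbow,
    rows = df[c("subject", "condition")], scope = scope,
    features = features),
    class = "cluster_solution")
}

#' @export
print.cluster_solution <- function(x, ...) {
  cat(sprintf("<cluster_solution> k = %d (%s rows), between_SS/total_SS = %.1f%%, avg silhouette %.3f\n",
              x$k, x$scope, 100 * x$between_ratio, x$avg_silhouette))
  cat("  cluster sizes:", paste(table(x$assignments), collapse = ", "), "\n")
  invisible(x)
}
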