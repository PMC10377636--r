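#' K-means clustering of similarity coordinates
#'
#' Clusters items in the two-dimensional similarity plane (color similarity
#' `1 - BCD` on one axis, texture similarity on the other) with k-means
#' (Lloyd iterations, 10 seeded random restarts keeping the lowest
#' within-cluster sum of squares), and summarizes each cluster by its mean
#' perceptual color and texture scores when rater panels are supplied.
#' A coherent metric pair places items with similar perceptual scores in
#' the same cluster.
#'
#' @param data data frame with one row per item.
#' @param color_col,texture_col columns holding the two similarity
#'   coordinates.
#' @param k number of clusters (default 4, one per visibility level).
#' @param seed RNG seed for the restarts.
#' @param color_scores,texture_scores optional columns with perceptual
#'   (gold) scores to average per cluster.
#' @return an object of class `"cluster_report"`: `assignments` tibble
#'   (the input data plus a `cluster` column), `centroids` tibble (cluster,
#'   color and texture centroid coordinates, size, and mean perceptual
#'   scores when available; ordered by increasing color similarity
#'   centroid), and `tot_withinss`.
#' @export
kmeans_cluster <- function(data, color_col = "color_similarity",
                           texture_col = "texture_similarity",
                           k = 4L, seed = 1L,
                           color_scores = NULL, texture_scores = NULL) {
  pts <- cbind(data[[color_col]], data[[texture_col]])
  if (is.null(pts) || anyNA(pts)) {
    abort_percsim("similarity columns missing or incomplete.",
                  "percsim_usage_error")
  }
  n <- nrow(pts)
  if (n < k) {
    abort_percsim(sprintf("need at least k = %d points; got %d.", k, n),
                  "percsim_usage_error")
  }
  n_distinct <- nrow(unique(pts))
  k_eff <- min(k, n_distinct)
  if (k_eff < k) {
    warning(sprintf(paste0("only %d distinct point(s); fitting %d cluster(s) ",
                           "instead of %d."), n_distinct, k_eff, k),
            call. = FALSE)
  }
  km <- withr::with_seed(seed, {
    if (k_eff == 1L) {
      list(cluster = rep(1L, n), centers = matrix(colMeans(pts), nrow = 1),
           tot.withinss = sum(scale(pts, scale = FALSE)^2))
    } else {
      kmeans(pts, centers = k_eff, nstart = 10L, iter.max = 100L,
             algorithm = "Lloyd")
    }
  })
  assignments <- dplyr::mutate(tibble::as_tibble(data),
                               cluster = as.integer(km$cluster))
  centroids <- tibble::tibble(
    cluster = seq_len(k_eff),
    color_centroid = km$centers[, 1],
    texture_centroid = km$centers[, 2],
    size = as.integer(tabulate(km$cluster, k_eff))
  )
  add_mean <- function(col, out_name) {
    if (is.null(col)) return(NULL)
    v <- data[[col]]
    vapply(seq_len(k_eff), function(cl) mean(v[km$cluster == cl]), numeric(1))
  }
  if (!is.null(color_scores)) {
    centroids$mean_color_score <- add_mean(color_scores)
  }
  if (!is.null(texture_scores)) {
    centroids$mean_texture_score <- add_mean(texture_scores)
  }
  centroids <- dplyr::arrange(centroids, .data$color_centroid)
  structure(
    list(assignments = assignments, centroids = centroids,
         tot_withinss = km$tot.withinss, k = k_eff, seed = seed),
    class = "cluster_report"
  )
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> k = %d, total within-SS %.4f\n",
              x$k, x$tot_withinss))
  print(x$centroids)
  invisible(x)
}
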