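cosine_distance_matrix <- function(m) {
  m[is.na(m)] <- 0
  nrm <- sqrt(rowSums(m^2))
  zero <- nrm == 0
  nrm[zero] <- 1
  sim <- tcrossprod(m / nrm)
  if (any(zero)) {
    sim[zero, ] <- 0
    sim[, zero] <- 0
    sim[zero, zero] <- 1 # identical emptiness is maximal agreement
  }
  d <- 1 - sim
  d[d < 0] <- 0
  diag(d) <- 0
  d
}

# silhouette of the full clustering (small clusters still act as neighbors),
# averaged over members of valid clusters only
mean_valid_silhouette <- function(d, labels, valid_ids) {
  idx <- which(labels %in% valid_ids)
  if (length(unique(labels[idx])) < 2) return(NA_real_)
  sil <- cluster::silhouette(labels, dmatrix = d)
  mean(sil[idx, "sil_width"])
}

#' Cluster daily traces into behavioral modes
#'
#' Agglomerative (hierarchical) clustering of the binary day traces under
#' cosine distance (1 minus cosine similarity, with the zero-vector
#' convention of [cosine_similarity()]). For each candidate number of
#' clusters `k` in `2..k_max`, clusters with fewer than `n_sam` member days
#' are marked too small to be considered; the `k` maximizing the mean
#' silhouette score over members of valid clusters is selected (smallest
#' `k` on ties). Valid clusters are relabeled 1, 2, ... by decreasing size,
#' so cluster 1 is the dominant behavioral mode; members of too-small
#' clusters are labeled `"small-cluster"`. Each valid cluster's prototype
#' is the Sensor Profile estimated from its member days only.
#'
#' If no candidate yields at least two valid clusters (e.g., all traces
#' identical), a degenerate single-cluster result is returned with an
#' undefined (NA) silhouette.
#'
#' @param traces A `day_traces` tibble with at least `2 * n_sam` days.
#' @param n_sam Minimum days a cluster needs to be considered (default 5).
#' @param k_max Largest candidate number of clusters (default 8).
#' @param linkage `"average"` (default) or `"complete"`.
#' @return An object of class `trace_clusters`: list with `labels` (tibble
#'   `date`, `cluster`, `assignment`), `n_clus`, `prototypes` (named list
#'   of [estimate_profile()] results), `silhouette`, `candidates` (tibble
#'   of the k-selection path), `linkage`.
#' @export
#' @examples
#' sim <- sample_day_traces(sleep_mode_presets(), n_days = 40, seed = 5)
#' cl <- cluster_day_traces(sim$traces)
#' cl$n_clus
cluster_day_traces <- function(traces, n_sam = 5, k_max = 8,
                               linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  n <- nrow(traces)
  if (n < 2 * n_sam) {
    abort(sprintf("need at least 2 * n_sam = %d traces; got %d.", 2 * n_sam, n))
  }
  m <- trace_matrix(traces)
  d <- cosine_distance_matrix(m)
  hc <- hclust(as.dist(d), method = linkage)
  cand <- list_rbind(map(2:min(k_max, n - 1), function(k) {
    lab <- cutree(hc, k)
    sizes <- table(lab)
    valid <- as.integer(names(sizes)[sizes >= n_sam])
    sil <- if (length(valid) >= 2) mean_valid_silhouette(d, lab, valid) else NA_real_
    tibble(k = k, n_valid = length(valid), mean_silhouette = sil)
  }))
  usable <- filter(cand, !is.na(.data$mean_silhouette) & is.finite(.data$mean_silhouette))
  if (nrow(usable) == 0) {
    proto <- list(`1` = estimate_profile(traces))
    out <- list(
      labels = tibble(date = traces$date, cluster = 1L, assignment = "1"),
      n_clus = 1L, prototypes = proto, silhouette = NA_real_,
      candidates = cand, linkage = linkage
    )
    return(structure(out, class = "trace_clusters"))
  }
  best_k <- usable$k[which.max(usable$mean_silhouette)]
  lab <- cutree(hc, best_k)
  sizes <- sort(table(lab), decreasing = TRUE)
  valid_old <- as.integer(names(sizes)[sizes >= n_sam])
  relabel <- setNames(seq_along(valid_old), valid_old)
  cluster_id <- unname(relabel[as.character(lab)])
  assignment <- ifelse(is.na(cluster_id), "small-cluster", as.character(cluster_id))
  prototypes <- lapply(seq_along(valid_old), function(i) {
    estimate_profile(traces[which(cluster_id == i), , drop = FALSE])
  })
  names(prototypes) <- as.character(seq_along(valid_old))
  out <- list(
    labels = tibble(date = traces$date, cluster = cluster_id,
                    assignment = assignment),
    n_clus = length(valid_old),
    prototypes = prototypes,
    silhouette = max(usable$mean_silhouette),
    candidates = cand,
    linkage = linkage
  )
  structure(out, class = "trace_clusters")
}

#' @export
print.trace_clusters <- function(x, ...) {
  cat(sprintf("Trace clustering: %d valid cluster(s), mean silhouette %s\n",
              x$n_clus,
              ifelse(is.na(x$silhouette), "undefined", sprintf("%.3f", x$silhouette))))
  print(count(x$labels, .data$assignment))
  invisible(x)
}

#' @export
glance.trace_clusters <- function(x, ...) {
  tibble(n_clus = x$n_clus, silhouette = x$silhouette,
         n_days = nrow(x$labels),
         n_small = sum(x$labels$assignment == "small-cluster"),
         linkage = x$linkage)
}
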