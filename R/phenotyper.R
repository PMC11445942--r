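# Phenotype derivation: dimensionality reduction (UMAP or PCA), k-means in
# embedding space, and model selection over (method, dimension, k) by three
# internal-validity indices with the full score table always emitted.

#' Fit a dimensionality-reduction embedding
#'
#' UMAP (via uwot, single-threaded for determinism) or PCA. The
#' reconstruction MSE is the mean squared error of the least-squares linear
#' decoder from embedding coordinates back to the scaled features; for PCA
#' this equals the standard orthogonal back-projection error.
#'
#' @param x scaled, complete feature matrix.
#' @param method "umap" or "pca".
#' @param dimension embedding dimension (>= 2 recommended; must not exceed
#'   the feature count).
#' @param seed RNG seed (UMAP optimization is stochastic).
#' @param n_neighbors,min_dist UMAP hyperparameters.
#' @return list with method, dimension, seed, `coords` (n x dimension),
#'   `reconstruction_mse`, and the fitted decoder.
#' @export
fit_embedding <- function(x, method = c("umap", "pca"), dimension = 2,
                          seed = 1L, n_neighbors = 15, min_dist = 0.1) {
  method <- match.arg(method)
  if (dimension > ncol(x)) stop("embedding dimension exceeds feature count")
  if (dimension < 1) stop("embedding dimension must be >= 1")
  if (method == "pca") {
    pc <- stats::prcomp(x, center = FALSE, scale. = FALSE)
    rot <- pc$rotation[, seq_len(dimension), drop = FALSE]
    coords <- x %*% rot
    recon <- coords %*% t(rot)
  } else {
    set.seed(seed)
    coords <- uwot::umap(x, n_components = dimension,
                         n_neighbors = n_neighbors, min_dist = min_dist,
                         n_threads = 1, n_sgd_threads = 0, verbose = FALSE)
    fit <- stats::lm.fit(cbind(1, coords), x)
    recon <- cbind(1, coords) %*% fit$coefficients
  }
  colnames(coords) <- paste0("dim", seq_len(dimension))
  list(method = method, dimension = dimension, seed = seed,
       coords = coords,
       reconstruction_mse = mean((recon - x)^2))
}

#' Mean silhouette width
#'
#' @param x coordinate matrix. @param cl integer cluster assignments.
#' @return mean silhouette in `[-1, 1]`; singleton-cluster points score 0.
#' @export
silhouette_score <- function(x, cl) {
  cl <- as.integer(factor(cl))
  n <- nrow(x)
  k <- max(cl)
  if (k < 2) stop("silhouette requires >= 2 clusters")
  D <- as.matrix(stats::dist(x))
  G <- matrix(0, n, k)
  for (j in seq_len(k)) G[, j] <- rowSums(D[, cl == j, drop = FALSE])
  sizes <- tabulate(cl, k)
  a <- G[cbind(seq_len(n), cl)] / pmax(sizes[cl] - 1, 1)
  Gm <- sweep(G, 2, sizes, "/")
  Gm[cbind(seq_len(n), cl)] <- Inf
  b <- apply(Gm, 1, min)
  s <- (b - a) / pmax(a, b)
  s[sizes[cl] == 1] <- 0
  mean(s)
}

#' Calinski-Harabasz index (variance-ratio criterion)
#' @inheritParams silhouette_score
#' @export
calinski_harabasz <- function(x, cl) {
  cl <- as.integer(factor(cl))
  n <- nrow(x); k <- max(cl)
  if (k < 2) stop("requires >= 2 clusters")
  gmean <- colMeans(x)
  cent <- rowsum(x, cl) / tabulate(cl, k)
  sizes <- tabulate(cl, k)
  B <- sum(sizes * rowSums(sweep(cent, 2, gmean)^2))
  W <- sum((x - cent[cl, , drop = FALSE])^2)
  (B / (k - 1)) / (W / (n - k))
}

#' Davies-Bouldin index
#' @inheritParams silhouette_score
#' @export
davies_bouldin <- function(x, cl) {
  cl <- as.integer(factor(cl))
  k <- max(cl)
  if (k < 2) stop("requires >= 2 clusters")
  cent <- rowsum(x, cl) / tabulate(cl, k)
  s <- vapply(seq_len(k), function(j)
    mean(sqrt(rowSums(sweep(x[cl == j, , drop = FALSE], 2, cent[j, ])^2))),
    numeric(1))
  M <- as.matrix(stats::dist(cent))
  r <- vapply(seq_len(k), function(j) {
    ratio <- (s[j] + s[-j]) / M[j, -j]
    max(ratio)
  }, numeric(1))
  mean(r)
}

#' K-means clustering with internal-validity scores
#'
#' Best-of-`n_init` inertia solution; silhouette, Calinski-Harabasz and
#' Davies-Bouldin are computed on the embedded coordinates. Flags weak
#' cluster structure when the silhouette falls below 0.25.
#'
#' @param coords embedded coordinates.
#' @param k number of clusters (>= 2, <= number of distinct points).
#' @param seed RNG seed. @param n_init random restarts.
#' @return list(k, assignments, centroids, silhouette, calinski_harabasz,
#'   davies_bouldin, inertia, weak_structure).
#' @export
cluster_kmeans <- function(coords, k, seed = 1L, n_init = 10) {
  if (k < 2) stop("k must be >= 2")
  ndistinct <- nrow(unique(round(coords, 12)))
  if (k > ndistinct)
    stop("k exceeds the number of distinct points (", ndistinct, ")")
  set.seed(seed)
  km <- stats::kmeans(coords, centers = k, nstart = n_init, iter.max = 100)
  sil <- silhouette_score(coords, km$cluster)
  list(k = k, assignments = km$cluster, centroids = km$centers,
       silhouette = sil,
       calinski_harabasz = calinski_harabasz(coords, km$cluster),
       davies_bouldin = davies_bouldin(coords, km$cluster),
       inertia = km$tot.withinss,
       weak_structure = sil < 0.25)
}

#' Select embedding method, dimension and cluster number
#'
#' Fits every (method, dimension) embedding, clusters each at every k, and
#' emits the full score table (silhouette, Calinski-Harabasz,
#' Davies-Bouldin, reconstruction MSE). The winning combination has the
#' highest count of first places across the three validity indices
#' (silhouette high, CH high, DB low); ties are broken by silhouette, then
#' smaller k, then smaller dimension.
#'
#' @param x scaled feature matrix.
#' @param methods,dimensions,ks the search grids.
#' @param seed,n_init passed to the embedding and k-means fits.
#' @return list(best = list(method, dimension, k), table, embedding,
#'   clustering) where embedding/clustering are the winning fits.
#' @export
model_select <- function(x, methods = c("umap", "pca"), dimensions = 2:5,
                         ks = 2:8, seed = 1L, n_init = 10) {
  stopifnot(length(methods) > 0, length(dimensions) > 0, length(ks) > 0)
  rows <- list(); fits <- list()
  for (m in methods) for (d in dimensions) {
    emb <- fit_embedding(x, m, d, seed = seed)
    for (k in ks) {
      cls <- cluster_kmeans(emb$coords, k, seed = seed, n_init = n_init)
      key <- paste(m, d, k, sep = "_")
      fits[[key]] <- list(embedding = emb, clustering = cls)
      rows[[key]] <- data.frame(
        method = m, dimension = d, k = k,
        silhouette = cls$silhouette,
        calinski_harabasz = cls$calinski_harabasz,
        davies_bouldin = cls$davies_bouldin,
        reconstruction_mse = emb$reconstruction_mse,
        stringsAsFactors = FALSE
      )
    }
  }
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  wins <- (tab$silhouette == max(tab$silhouette)) +
    (tab$calinski_harabasz == max(tab$calinski_harabasz)) +
    (tab$davies_bouldin == min(tab$davies_bouldin))
  tab$first_places <- wins
  ord <- order(-wins, -tab$silhouette, tab$k, tab$dimension)
  best <- tab[ord[1], ]
  key <- paste(best$method, best$dimension, best$k, sep = "_")
  list(best = list(method = best$method, dimension = best$dimension,
                   k = best$k),
       table = tab,
       embedding = fits[[key]]$embedding,
       clustering = fits[[key]]$clustering)
}

#' Stable encounter-to-cluster assignment table
#'
#' @param clustering a [cluster_kmeans()] result.
#' @param encounter_ids encounter ids in the row order of the clustered
#'   matrix.
#' @return data.frame(encounter_id, cluster), sorted by encounter id.
#' @export
assign_phenotype_indices <- function(clustering, encounter_ids) {
  stopifnot(length(encounter_ids) == length(clustering$assignments))
  out <- data.frame(encounter_id = encounter_ids,
                    cluster = unname(clustering$assignments),
                    stringsAsFactors = FALSE)
  out[order(out$encounter_id), , drop = FALSE]
}

#' Adjusted Rand index between two partitions
#'
#' @param a,b label vectors of equal length.
#' @return chance-corrected agreement in `[-1, 1]`.
#' @export
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  exp_idx <- sum_a * sum_b / choose(n, 2)
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == exp_idx) return(1)
  (sum_ij - exp_idx) / (max_idx - exp_idx)
}
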