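#' 26-connected cluster labelling
#'
#' Labels the connected components of a logical 3D mask under 26-neighbour
#' connectivity (faces, edges and corners).
#'
#' @param mask logical 3D array.
#' @return A list with `labels` (integer 3D array, 0 outside clusters) and
#'   `sizes` (cluster voxel counts, label order).
#' @export
label_clusters <- function(mask) {
  stopifnot(length(dim(mask)) == 3L)
  lin <- which(mask)
  labels <- array(0L, dim(mask))
  if (length(lin) == 0L) return(list(labels = labels, sizes = integer(0)))
  comp <- cluster_components(lin, dim(mask))
  labels[lin] <- comp
  list(labels = labels, sizes = as.integer(tabulate(comp)))
}

# 26-neighbour offsets as coordinate deltas, half (13) for undirected edges.
half_offsets_26 <- local({
  g <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  g <- g[!(g[, 1] == 0 & g[, 2] == 0 & g[, 3] == 0), , drop = FALSE]
  g[seq_len(13L), , drop = FALSE]
})

# Union-find connected components for a set of voxels given by linear index.
# Returns per-voxel component ids (1..k, in order of first appearance).
cluster_components <- function(lin, dims) {
  n <- length(lin)
  if (n == 1L) return(1L)
  coords <- arrayInd(lin, dims)
  cx <- coords[, 1L]; cy <- coords[, 2L]; cz <- coords[, 3L]
  nxy <- dims[1L] * dims[2L]
  m <- nrow(half_offsets_26)
  idx0 <- rep.int(seq_len(n), m)
  nx <- cx + rep(half_offsets_26[, 1L], each = n)
  ny <- cy + rep(half_offsets_26[, 2L], each = n)
  nz <- cz + rep(half_offsets_26[, 3L], each = n)
  ok <- nx >= 1L & nx <= dims[1L] & ny >= 1L & ny <= dims[2L] &
    nz >= 1L & nz <= dims[3L]
  hit <- match((nz[ok] - 1L) * nxy + (ny[ok] - 1L) * dims[1L] + nx[ok], lin)
  found <- !is.na(hit)
  edges_i <- idx0[ok][found]
  edges_j <- hit[found]
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  for (e in seq_along(edges_i)) {
    ra <- find(edges_i[e]); rb <- find(edges_j[e])
    if (ra != rb) parent[rb] <- ra
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

max_cluster_size <- function(lin, dims) {
  if (length(lin) == 0L) return(0L)
  max(tabulate(cluster_components(lin, dims)))
}

as_map_array <- function(x) {
  if (inherits(x, "static_image")) x$voxels else x
}

#' Voxelwise two-sample permutation cluster test
#'
#' Two-sample t-test (pooled variance) at every voxel, thresholded at the
#' two-sided `p_voxel` t-quantile (voxels with `|t| > qt(1 - p_voxel/2, df)`
#' form the excursion sets, one per direction), with cluster-level
#' family-wise-error correction by group-label permutation. Each direction
#' (group 1 > group 2 and the reverse) is treated as its own contrast, as in
#' standard SPM-style analyses: its null distribution is the maximum
#' 26-connected cluster size in that direction across permutations, and each
#' observed cluster's corrected p-value is the fraction of permutations whose
#' maximum is at least as large. All
#' distinct group assignments are enumerated when their number does not
#' exceed `n_perm`; otherwise `n_perm` random assignments (including the
#' observed one) are drawn.
#'
#' @param maps_pos,maps_neg lists of 3D arrays or `static_image`s (>= 3 per
#'   group, one grid).
#' @param p_voxel voxel-forming threshold (one-sided per direction).
#' @param alpha_cluster cluster-level significance threshold.
#' @param n_perm maximum number of permutations.
#' @param seed integer seed for random permutation sampling.
#' @param mask optional logical 3D array restricting the test.
#' @return An object of class `cluster_result`: `t_map`, `t_threshold`,
#'   `df`, `clusters` (data.frame: direction, size, p_fwe, significant),
#'   `cluster_labels` (list of labelled arrays, pos/neg), `null_max`,
#'   `n_perm_used`.
#' @export
voxelwise_permutation_test <- function(maps_pos, maps_neg, p_voxel = 0.005,
                                       alpha_cluster = 0.05, n_perm = 1000,
                                       seed = 1, mask = NULL) {
  n1 <- length(maps_pos); n2 <- length(maps_neg)
  if (n1 < 3L || n2 < 3L) stop("at least 3 maps per group are required")
  arrs <- c(lapply(maps_pos, as_map_array), lapply(maps_neg, as_map_array))
  dims <- dim(arrs[[1L]])
  if (length(dims) != 3L || !all(vapply(arrs, function(a)
    identical(dim(a), dims), logical(1))))
    stop("all maps must be 3D arrays on one grid")
  n <- n1 + n2
  total_combos <- choose(n, n1)
  if (total_combos < 20)
    stop("too few subjects for the permutation space")
  X <- vapply(arrs, as.vector, numeric(prod(dims)))  # V x n
  finite_ok <- rowSums(!is.finite(X)) == 0
  if (is.null(mask)) {
    mu <- rowMeans(X)
    ss <- rowSums(X * X) - n * mu * mu
    mask_vec <- finite_ok & is.finite(ss) & ss > 0
  } else {
    mask_vec <- as.vector(mask) & finite_ok
  }
  keep <- which(mask_vec)
  if (length(keep) == 0L) stop("empty analysis mask")
  Xm <- X[keep, , drop = FALSE]
  df <- n - 2L
  t_thr <- stats::qt(1 - p_voxel / 2, df)

  # columns = group-1 membership per permutation; observed assignment first
  if (total_combos <= n_perm) {
    splits <- utils::combn(n, n1)
    obs_col <- which(apply(splits, 2L, function(s)
      identical(as.integer(s), seq_len(n1))))
    splits <- cbind(splits[, obs_col], splits[, -obs_col, drop = FALSE])
  } else {
    splits <- matrix(0L, n1, n_perm)
    splits[, 1L] <- seq_len(n1)
    with_local_seed(seed, {
      for (p in 2:n_perm) splits[, p] <- sort(sample.int(n, n1))
    })
  }
  P <- ncol(splits)

  rs_all <- rowSums(Xm)
  rs2_all <- rowSums(Xm * Xm)
  X2 <- Xm * Xm
  null_max_pos <- integer(P)
  null_max_neg <- integer(P)
  t_obs <- NULL
  chunk <- max(1L, floor(2e7 / length(keep)))
  for (start in seq(1L, P, by = chunk)) {
    cols <- start:min(start + chunk - 1L, P)
    G <- matrix(0, n, length(cols))
    for (ci in seq_along(cols)) G[splits[, cols[ci]], ci] <- 1
    S1 <- Xm %*% G
    S1sq <- X2 %*% G
    m1 <- S1 / n1
    m2 <- (rs_all - S1) / n2
    v1 <- (S1sq - n1 * m1 * m1) / (n1 - 1)
    v2 <- ((rs2_all - S1sq) - n2 * m2 * m2) / (n2 - 1)
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
    tmat <- (m1 - m2) / se
    tmat[se == 0] <- 0
    for (ci in seq_along(cols)) {
      tv <- tmat[, ci]
      null_max_pos[cols[ci]] <- max_cluster_size(keep[tv > t_thr], dims)
      null_max_neg[cols[ci]] <- max_cluster_size(keep[tv < -t_thr], dims)
      if (cols[ci] == 1L) t_obs <- tv
    }
  }

  t_map <- array(NA_real_, dims)
  t_map[keep] <- t_obs
  cluster_dir <- function(sel) {
    m <- array(FALSE, dims)
    m[keep[sel]] <- TRUE
    label_clusters(m)
  }
  lab_pos <- cluster_dir(t_obs > t_thr)
  lab_neg <- cluster_dir(t_obs < -t_thr)
  mk_rows <- function(lab, direction, null_max) {
    if (length(lab$sizes) == 0L) return(NULL)
    data.frame(direction = direction, cluster = seq_along(lab$sizes),
               size = lab$sizes,
               p_fwe = vapply(lab$sizes,
                              function(s) mean(null_max >= s), numeric(1)),
               stringsAsFactors = FALSE)
  }
  clusters <- rbind(mk_rows(lab_pos, "pos>neg", null_max_pos),
                    mk_rows(lab_neg, "neg>pos", null_max_neg))
  if (is.null(clusters))
    clusters <- data.frame(direction = character(0), cluster = integer(0),
                           size = integer(0), p_fwe = numeric(0))
  clusters$significant <- clusters$p_fwe < alpha_cluster
  clusters <- clusters[order(clusters$p_fwe, -clusters$size), , drop = FALSE]
  rownames(clusters) <- NULL
  structure(list(t_map = t_map, t_threshold = t_thr, df = df,
                 clusters = clusters,
                 cluster_labels = list(pos = lab_pos$labels,
                                       neg = lab_neg$labels),
                 null_max = list(pos = null_max_pos, neg = null_max_neg),
                 n_perm_used = P,
                 alpha_cluster = alpha_cluster, p_voxel = p_voxel),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf(
    "<cluster_result> t>%.2f (df=%d), %d permutations, %d clusters (%d significant)\n",
    x$t_threshold, x$df, x$n_perm_used, nrow(x$clusters),
    sum(x$clusters$significant)))
  invisible(x)
}
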