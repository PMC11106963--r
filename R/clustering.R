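## z-scored TE-profile clustering: k-means partition (k-means++ seeded
## Lloyd iterations, best of n restarts) with average-linkage
## hierarchical ordering within each cluster.

#' Row-wise z-scoring of condition profiles
#'
#' Each gene's profile is centred and scaled by its sample standard
#' deviation (n - 1); genes with zero variance carry no profile shape
#' and are dropped.
#'
#' @param m Numeric matrix, genes x conditions (>= 2 conditions), e.g.
#'   from [conditionMeans()].
#' @return `list(z=, dropped=)`: the z-scored matrix and the ids of the
#'   dropped constant genes.
#' @export
zscoreProfiles <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 conditions")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  keep <- sd > 0
  list(z = (m[keep, , drop = FALSE] - mu[keep]) / sd[keep],
       dropped = rownames(m)[!keep])
}

## k-means++ seeding: first center uniform, then each next center drawn
## with probability proportional to the squared distance to the nearest
## chosen center.
.kmeansppInit <- function(z, k) {
  n <- nrow(z)
  centers <- matrix(NA_real_, k, ncol(z))
  idx <- sample.int(n, 1)
  centers[1, ] <- z[idx, ]
  d2 <- rowSums((z - rep(centers[1, ], each = n))^2)
  for (j in seq_len(k - 1) + 1) {
    if (all(d2 == 0)) idx <- sample.int(n, 1)
    else idx <- sample.int(n, 1, prob = d2)
    centers[j, ] <- z[idx, ]
    d2 <- pmin(d2, rowSums((z - rep(centers[j, ], each = n))^2))
  }
  centers
}

.assignToCenters <- function(z, centers) {
  ## dist2[i, j] = ||z_i - c_j||^2, via the expansion trick
  d2 <- outer(rowSums(z^2), rowSums(centers^2), "+") -
    2 * tcrossprod(z, centers)
  max.col(-d2, ties.method = "first")
}

## Lloyd iterations; an emptied cluster is re-seeded from the point
## farthest from its current centroid.
.lloyd <- function(z, centers, iterMax = 100) {
  n <- nrow(z); k <- nrow(centers)
  assign <- rep(0L, n)
  for (iter in seq_len(iterMax)) {
    newAssign <- .assignToCenters(z, centers)
    repeat {
      empty <- setdiff(seq_len(k), unique(newAssign))
      if (!length(empty)) break
      far <- which.max(rowSums((z - centers[newAssign, , drop = FALSE])^2))
      centers[empty[1], ] <- z[far, ]
      newAssign <- .assignToCenters(z, centers)
    }
    if (identical(newAssign, assign)) break
    assign <- newAssign
    for (j in seq_len(k))
      centers[j, ] <- colMeans(z[assign == j, , drop = FALSE])
  }
  wss <- sum((z - centers[assign, , drop = FALSE])^2)
  list(assign = assign, centers = centers, wss = wss)
}

.kmeansBest <- function(z, k, nInit, extraCenters = NULL) {
  best <- NULL
  for (i in seq_len(nInit)) {
    fit <- .lloyd(z, .kmeansppInit(z, k))
    if (is.null(best) || fit$wss < best$wss) best <- fit
  }
  if (!is.null(extraCenters)) {
    fit <- .lloyd(z, extraCenters)
    if (fit$wss < best$wss) best <- fit
  }
  best
}

#' Within-cluster sum of squares over a range of k
#'
#' For each k, the best (lowest-WSS) of `nInit` k-means++ seeded Lloyd
#' runs. Each k additionally warm-starts from the previous k's best
#' centers plus the point farthest from its centroid, which makes the
#' curve non-increasing in k.
#'
#' @param z z-scored matrix from [zscoreProfiles()].
#' @param kValues Integer vector of cluster numbers (each `<=` n genes).
#' @param seed Integer seed.
#' @param nInit Random restarts per k (default 10).
#' @return Named numeric: WSS by k.
#' @seealso [elbowK()]
#' @export
kmeansWss <- function(z, kValues, seed, nInit = 10) {
  if (any(kValues > nrow(z)))
    stop("k cannot exceed the number of genes")
  set.seed(as.integer(seed))
  kValues <- sort(as.integer(kValues))
  out <- numeric(length(kValues))
  prev <- NULL
  for (i in seq_along(kValues)) {
    k <- kValues[i]
    extra <- NULL
    if (!is.null(prev) && nrow(prev$centers) < k) {
      far <- which.max(rowSums(
        (z - prev$centers[prev$assign, , drop = FALSE])^2))
      extra <- prev$centers
      while (nrow(extra) < k) extra <- rbind(extra, z[far, ])
    }
    prev <- .kmeansBest(z, k, nInit, extraCenters = extra)
    out[i] <- prev$wss
  }
  stats::setNames(out, kValues)
}

#' Elbow heuristic for the number of clusters
#'
#' Largest second difference of the WSS curve; provided as a helper ---
#' the pipeline default keeps k fixed at 15.
#'
#' @param wss Named numeric from [kmeansWss()] over consecutive k.
#' @return The k at the elbow.
#' @export
elbowK <- function(wss) {
  if (length(wss) < 3) stop("need WSS at >= 3 values of k")
  k <- as.integer(names(wss))
  second <- diff(diff(wss))
  k[which.max(second) + 1]
}

#' K-means partition of z-scored TE profiles
#'
#' Best of `nInit` k-means++ seeded Lloyd runs (Euclidean distance;
#' emptied clusters re-seeded from the point farthest from its
#' centroid), deterministic given the seed, followed by average-linkage
#' hierarchical ordering within each cluster.
#'
#' @param z z-scored matrix from [zscoreProfiles()], genes in rows.
#' @param k Number of clusters (default 15).
#' @param seed Integer seed.
#' @param nInit Random restarts (default 10).
#' @return A [ClusterResult].
#' @export
kmeansCluster <- function(z, k = 15, seed = 1L, nInit = 10) {
  k <- as.integer(k)
  if (k > nrow(z)) stop("k cannot exceed the number of genes")
  if (is.null(rownames(z))) stop("z must have gene rownames")
  set.seed(as.integer(seed))
  best <- .kmeansBest(z, k, nInit)
  assignments <- stats::setNames(best$assign, rownames(z))
  leafOrders <- lapply(seq_len(k), function(j) {
    hierarchicalWithin(z, names(assignments)[assignments == j])$order
  })
  names(leafOrders) <- seq_len(k)
  new("ClusterResult", assignments = assignments,
      centroids = best$centers, wss = best$wss,
      wssCurve = stats::setNames(best$wss, k), leafOrders = leafOrders,
      k = k, seed = as.integer(seed))
}

#' Average-linkage ordering within one cluster
#'
#' Agglomerative hierarchical clustering (Euclidean distance, average
#' linkage) of the members of one cluster; ties resolve by input index,
#' so the leaf order is deterministic.
#'
#' @param z z-scored matrix, genes in rows.
#' @param members Gene ids of the cluster (>= 1).
#' @return `list(hclust=, order=)`: the [stats::hclust] tree (`NULL`
#'   for fewer than 2 members) and the gene ids in leaf order.
#' @export
hierarchicalWithin <- function(z, members) {
  if (!length(members)) stop("cluster has no members")
  if (length(members) == 1)
    return(list(hclust = NULL, order = members))
  h <- stats::hclust(stats::dist(z[members, , drop = FALSE]),
                     method = "average")
  list(hclust = h, order = members[h$order])
}

#' Genes in the dendrogram vicinity of a gene
#'
#' Genes within `radius` positions of the query in the leaf order of its
#' cluster (truncated at the cluster edges), the way a heat map reader
#' inspects a gene's immediate neighbourhood.
#'
#' @param gene Gene id.
#' @param result A [ClusterResult].
#' @param radius Number of positions on each side (default 2).
#' @return Character vector of gene ids, in leaf order (includes the
#'   query).
#' @export
clusterNeighbors <- function(gene, result, radius = 2) {
  stopifnot(is(result, "ClusterResult"))
  cl <- clusterAssignments(result)[gene]
  if (is.na(cl)) stop("unknown gene: ", gene)
  ord <- leafOrder(result, cl)
  pos <- match(gene, ord)
  ord[max(1, pos - radius):min(length(ord), pos + radius)]
}
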