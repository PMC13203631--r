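#' Variance-standardized genomic relationship matrix
#'
#' Each site's dosages are centered at twice the alternate-allele frequency
#' and scaled by the binomial standard deviation sqrt(2p(1-p)); missing
#' entries contribute zero after standardization (mean imputation).
#' Monomorphic sites carry no information and are skipped. R = Z Z' / m over
#' the m used sites.
#'
#' @param gm a [genotype_matrix()] with at least 2 samples
#' @return n x n symmetric matrix with sample names as dimnames and the
#'   used-site count in attribute `n_sites_used`
#' @export
relationship_matrix <- function(gm) {
  if (n_samples(gm) < 2L) stop("need at least 2 samples")
  d <- gm$dosage
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * pmax(n_obs, 1L))
  usable <- n_obs > 0L & p > 0 & p < 1
  if (!any(usable)) stop("all sites are monomorphic or fully missing")
  d <- d[, usable, drop = FALSE]
  p <- p[usable]
  z <- sweep(d, 2L, 2 * p)
  z <- sweep(z, 2L, sqrt(2 * p * (1 - p)), "/")
  z[is.na(z)] <- 0
  r <- tcrossprod(z) / ncol(z)
  r <- (r + t(r)) / 2
  dimnames(r) <- list(gm$samples, gm$samples)
  attr(r, "n_sites_used") <- ncol(z)
  r
}

#' PCA of a relationship matrix
#'
#' Eigendecomposition of the symmetric relationship matrix; sample
#' coordinates are eigenvectors scaled by sqrt(eigenvalue), and each
#' component's variance fraction is its eigenvalue over the sum of positive
#' eigenvalues. For reproducible plots every eigenvector's
#' largest-magnitude entry is made positive.
#'
#' @param r symmetric relationship matrix, as from [relationship_matrix()]
#' @param k number of components to return (default 10, capped at n - 1)
#' @return list with `coordinates` (n x k matrix) and `variance_fraction`
#'   (length-k vector, non-increasing)
#' @export
pca_relationship <- function(r, k = 10L) {
  if (!isSymmetric(unname(r), tol = 1e-10))
    stop("relationship matrix is not symmetric")
  n <- nrow(r)
  k <- min(as.integer(k), n - 1L)
  if (k < 1L) stop("need k >= 1 and at least 2 samples")
  eig <- eigen(r, symmetric = TRUE)
  lambda <- eig$values
  vecs <- eig$vectors[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-|entry| positive
  for (j in seq_len(k)) {
    i_max <- which.max(abs(vecs[, j]))
    if (vecs[i_max, j] < 0) vecs[, j] <- -vecs[, j]
  }
  lam_k <- pmax(lambda[seq_len(k)], 0)
  coords <- sweep(vecs, 2L, sqrt(lam_k), "*")
  rownames(coords) <- rownames(r)
  colnames(coords) <- paste0("PC", seq_len(k))
  list(coordinates = coords,
       variance_fraction = lam_k / sum(pmax(lambda, 0)))
}

#' Allele-sharing p-distance matrix
#'
#' d(i, j) is the mean over sites non-missing in both samples of
#' |dosage_i - dosage_j| / 2, the expected allele mismatch between the two
#' diploid genotypes.
#'
#' @param gm a [genotype_matrix()] with at least 3 samples
#' @return n x n symmetric distance matrix, zero diagonal
#' @export
p_distance_matrix <- function(gm) {
  if (n_samples(gm) < 3L) stop("need at least 3 samples")
  d <- gm$dosage
  obs <- !is.na(d)
  a0 <- (d == 0L) & obs; a1 <- (d == 1L) & obs; a2 <- (d == 2L) & obs
  storage.mode(a0) <- "double"; storage.mode(a1) <- "double"
  storage.mode(a2) <- "double"
  m_obs <- obs; storage.mode(m_obs) <- "double"
  # sum over sites of |g_i - g_j|: cross terms weighted 1 (hom-het) or 2
  # (opposite homozygotes)
  diffsum <- tcrossprod(a0, a1) + tcrossprod(a1, a0) +
    2 * (tcrossprod(a0, a2) + tcrossprod(a2, a0)) +
    tcrossprod(a1, a2) + tcrossprod(a2, a1)
  n_joint <- tcrossprod(m_obs)
  if (any(n_joint[upper.tri(n_joint)] == 0)) {
    bad <- which(n_joint == 0 & upper.tri(n_joint), arr.ind = TRUE)[1, ]
    stop("samples ", gm$samples[bad[1]], " and ", gm$samples[bad[2]],
         " share no non-missing sites")
  }
  dist <- diffsum / (2 * n_joint)
  diag(dist) <- 0
  dist <- (dist + t(dist)) / 2
  dimnames(dist) <- list(gm$samples, gm$samples)
  dist
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomeration: repeatedly join the pair minimizing
#' Q(i,j) = (n-2) d(i,j) - r_i - r_j (with r_i the row sum), branch lengths
#' from the three-point formulas. Negative branch lengths are clamped to
#' zero with the deficit transferred to the sister branch. The unrooted tree
#' is serialized as newick with a trifurcating root. Ties in Q break on the
#' first (row-major) minimal pair, making the output deterministic.
#'
#' @param d symmetric distance matrix with row/col names, n >= 3
#' @return newick string (terminated by `;`)
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (anyNA(d)) stop("distance matrix contains NA/NaN")
  if (is.null(rownames(d))) rownames(d) <- paste0("t", seq_len(n))
  labels <- rownames(d)
  fmt <- function(x) sprintf("%.10g", x)
  nodes <- labels  # newick fragment per active node
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)
    ij <- ij[order(ij[, 1], ij[, 2]), , drop = FALSE][1, ]
    i <- min(ij); j <- max(ij)
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    new_node <- paste0("(", nodes[i], ":", fmt(bi), ",",
                       nodes[j], ":", fmt(bj), ")")
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
               c(du[keep], 0))
    nodes <- c(nodes[keep], new_node)
  }
  # trifurcating root from the last three nodes
  b1 <- (d[1, 2] + d[1, 3] - d[2, 3]) / 2
  b2 <- (d[1, 2] + d[2, 3] - d[1, 3]) / 2
  b3 <- (d[1, 3] + d[2, 3] - d[1, 2]) / 2
  b <- pmax(c(b1, b2, b3), 0)
  paste0("(", nodes[1], ":", fmt(b[1]), ",", nodes[2], ":", fmt(b[2]),
         ",", nodes[3], ":", fmt(b[3]), ");")
}
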