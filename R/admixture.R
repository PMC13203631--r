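#' Ancestry proportions by masked nonnegative matrix factorization
#'
#' Factorizes the scaled dosage matrix X (n x L, entries dosage/2) as
#' X ~ Q F with Q row-stochastic (each row an individual's ancestry
#' proportions over K clusters) and F in [0,1] (cluster allele
#' frequencies), by alternating least squares with projection: Q rows are
#' Euclidean-projected onto the probability simplex, F is clipped to [0,1].
#' Missing entries are excluded from the loss (they are refilled from the
#' current reconstruction each iteration). Before fitting, a random
#' `mask_fraction` of the observed entries is held out; the masked
#' cross-entropy of the fit on those entries is the model-selection
#' criterion. An update that would increase the training loss is rejected
#' and the fit stops there, so the logged loss trace is non-increasing.
#'
#' @param gm a [genotype_matrix()]
#' @param K number of ancestral clusters, 2 <= K <= n (K = 1 allowed as the
#'   degenerate single-cluster model)
#' @param seed RNG seed for initialization
#' @param mask_fraction fraction of observed entries held out, in (0, 0.5]
#' @param mask_seed RNG seed for the held-out mask (defaults to `seed`);
#'   model selection across K uses a common mask per restart so that
#'   cross-entropies are compared on the same validation entries
#' @param max_iter iteration cap
#' @param tol relative training-loss change declaring convergence
#' @return list with `Q` (n x K, rows sum to 1), `F` (K x L in [0,1]),
#'   `masked_cross_entropy`, `loss_trace`, `converged`, `seed`, `K`
#' @export
admixture_nmf <- function(gm, K, seed = 1L, mask_fraction = 0.05,
                          mask_seed = seed, max_iter = 500L, tol = 1e-6) {
  n <- n_samples(gm); L <- n_sites(gm)
  K <- as.integer(K)
  if (K < 1L || K > n) stop("K must be in [1, n_samples]")
  if (mask_fraction <= 0 || mask_fraction > 0.5)
    stop("mask_fraction must be in (0, 0.5]")
  x <- gm$dosage / 2
  obs <- which(!is.na(x))
  set.seed(mask_seed)
  held <- sample(obs, max(1L, round(mask_fraction * length(obs))))
  train <- matrix(FALSE, n, L)
  train[obs] <- TRUE
  train[held] <- FALSE
  set.seed(seed)

  if (K == 1L) {
    qmat <- matrix(1, n, 1)
    fmat <- matrix(colMeans(x, na.rm = TRUE), 1, L)
    fmat[is.nan(fmat)] <- 0.5
    xhat <- qmat %*% fmat
    return(list(Q = qmat, F = fmat,
                masked_cross_entropy = .masked_ce(x, xhat, held),
                loss_trace = .masked_mse(x, xhat, train),
                converged = TRUE, seed = seed, K = 1L))
  }

  qmat <- matrix(stats::runif(n * K, 0.2, 1), n, K)
  qmat <- qmat / rowSums(qmat)
  fmat <- matrix(stats::runif(K * L), K, L)
  xw <- x
  xw[!train] <- mean(x[train])
  ridge <- diag(1e-8, K)
  loss <- .masked_mse(x, qmat %*% fmat, train)
  trace <- loss
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    xw[!train] <- (qmat %*% fmat)[!train]
    f_new <- solve(crossprod(qmat) + ridge, crossprod(qmat, xw))
    f_new[f_new < 0] <- 0; f_new[f_new > 1] <- 1
    xw[!train] <- (qmat %*% f_new)[!train]
    q_new <- t(solve(tcrossprod(f_new) + ridge, f_new %*% t(xw)))
    q_new <- .project_rows_simplex(q_new)
    loss_new <- .masked_mse(x, q_new %*% f_new, train)
    if (loss_new > loss) { converged <- TRUE; break }  # reject uphill step
    qmat <- q_new; fmat <- f_new
    trace <- c(trace, loss_new)
    if (loss - loss_new < tol * max(loss, .Machine$double.eps)) {
      loss <- loss_new; converged <- TRUE; break
    }
    loss <- loss_new
  }
  if (!converged) warning("admixture_nmf did not converge in ", max_iter,
                          " iterations")
  xhat <- qmat %*% fmat
  list(Q = qmat, F = fmat,
       masked_cross_entropy = .masked_ce(x, xhat, held),
       loss_trace = trace, converged = converged, seed = seed, K = K)
}

.masked_mse <- function(x, xhat, train) {
  mean((x[train] - xhat[train])^2)
}

# binomial cross-entropy of held-out scaled dosages against the
# reconstruction, clipped away from {0,1}
.masked_ce <- function(x, xhat, held) {
  f <- pmin(pmax(xhat[held], 1e-6), 1 - 1e-6)
  g <- x[held]
  -mean(g * log(f) + (1 - g) * log(1 - f))
}

# Euclidean projection of each row onto the probability simplex
.project_rows_simplex <- function(q) {
  t(apply(q, 1L, function(v) {
    u <- sort(v, decreasing = TRUE)
    css <- cumsum(u)
    rho <- max(which(u + (1 - css) / seq_along(u) > 0))
    theta <- (1 - css[rho]) / rho
    pmax(v + theta, 0)
  }))
}

#' Select the number of ancestral clusters by masked cross-entropy
#'
#' Fits [admixture_nmf()] for each K in `K_range`, `seeds_per_K` times with
#' distinct seeds, keeps each K's minimum masked cross-entropy, and returns
#' the argmin K (first on ties).
#'
#' @param gm a [genotype_matrix()]
#' @param K_range integer vector of candidate K values
#' @param seeds_per_K restarts per K
#' @param base_seed seed from which per-fit seeds are derived
#' @param mask_fraction passed to [admixture_nmf()]
#' @return list with `best_K`, `table` (data.frame K / cross_entropy), and
#'   `fits` (best fit per K)
#' @export
select_K <- function(gm, K_range = 2:10, seeds_per_K = 3L, base_seed = 1L,
                     mask_fraction = 0.05) {
  K_range <- as.integer(K_range)
  if (any(K_range < 1L) || any(K_range > n_samples(gm)))
    stop("K_range must lie within [1, n_samples]")
  if (seeds_per_K < 1L) stop("seeds_per_K must be >= 1")
  best_fits <- vector("list", length(K_range))
  ce <- numeric(length(K_range))
  for (i in seq_along(K_range)) {
    fits <- lapply(seq_len(seeds_per_K), function(s) {
      # one mask per restart index, shared across K: paired comparison
      admixture_nmf(gm, K_range[i],
                    seed = (base_seed + 7919L * (i - 1L) + s) %% 2147483647L,
                    mask_seed = (base_seed + 104729L * s) %% 2147483647L,
                    mask_fraction = mask_fraction)
    })
    ces <- vapply(fits, `[[`, 0, "masked_cross_entropy")
    best_fits[[i]] <- fits[[which.min(ces)]]
    ce[i] <- min(ces)
  }
  list(best_K = K_range[which.min(ce)],
       table = data.frame(K = K_range, cross_entropy = ce),
       fits = stats::setNames(best_fits, paste0("K", K_range)))
}
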