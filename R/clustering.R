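# N-dimensional Dirichlet-process clustering of SBSs by their VAF vectors
# across a patient's microbiopsies. Chinese-restaurant-process collapsed
# Gibbs sampler with a Binomial(depth, vaf) emission per microbiopsy and a
# conjugate Beta(1, 1) prior on each cluster's per-sample VAF; the DP
# concentration is resampled each sweep under a Gamma(1, 1) hyperprior
# (Escobar & West auxiliary-variable update). Microbiopsies with zero
# depth at a mutation contribute no likelihood term: missing data, not
# evidence of absence.

#' Clustering configuration
#'
#' @param alpha Initial DP concentration (resampled during the chain).
#' @param n_iter Total Gibbs sweeps.
#' @param burn_in Sweeps discarded before recording.
#' @param thin Record every \code{thin}-th sweep after burn-in.
#' @param min_cluster_size Point-estimate clusters smaller than this are
#'   dissolved into the best-fitting remaining cluster.
#' @param rng_seed Integer seed; the point clustering is a deterministic
#'   function of data and configuration.
#' @return List of class \code{clustering_config}.
#' @export
clustering_config <- function(alpha = 1, n_iter = 3000, burn_in = 1000,
                              thin = 5, min_cluster_size = 2, rng_seed = 1L) {
  stopifnot(alpha > 0, burn_in < n_iter, min_cluster_size >= 1, thin >= 1)
  structure(as.list(environment()), class = "clustering_config")
}

# log predictive of count vector (a, d) joining a cluster with accumulated
# counts (A, D): integrates the Beta posterior per dimension.
.log_pred <- function(a, d, A, D) {
  if (is.null(dim(A))) {
    sum(lbeta(a + A + 1, d - a + D - A + 1) - lbeta(A + 1, D - A + 1))
  } else {
    rowSums(lbeta(sweep(A, 2, a, "+") + 1,
                  sweep(D - A, 2, d - a, "+") + 1) -
              lbeta(A + 1, D - A + 1))
  }
}

#' Dirichlet-process clustering of mutations by VAF profiles
#'
#' Clusters a patient's autosomal single-base substitutions by their
#' alt/depth vectors over the patient's microbiopsies. Returns a point
#' clustering (the recorded partition minimizing Binder loss against the
#' posterior co-clustering matrix, a deterministic label-alignment rule),
#' per-cluster posterior-mean VAF centroids, the co-clustering matrix and
#' an occupied-cluster trace.
#'
#' @param mat A [count_matrix()] restricted to one patient's SBSs.
#' @param config A [clustering_config()].
#' @return Object of class \code{dp_clusters}: \code{assignment} (integer
#'   cluster per mutation), \code{clusters} (sizes), \code{vaf_centroid}
#'   and \code{cf_centroid} (clusters x samples; CF = 2 VAF),
#'   \code{coclustering}, \code{trace} (occupied clusters per sweep),
#'   \code{config}.
#' @export
fit_dp_clusters <- function(mat, config = clustering_config()) {
  a <- mat$alt; d <- mat$depth
  n <- nrow(a); J <- ncol(a)
  empty <- structure(list(assignment = integer(0),
                          clusters = data.frame(cluster_id = integer(0),
                                                n = integer(0)),
                          vaf_centroid = matrix(0, 0, J),
                          cf_centroid = matrix(0, 0, J),
                          coclustering = NULL, trace = integer(0),
                          config = config),
                     class = "dp_clusters")
  if (n == 0) return(empty)
  set.seed(config$rng_seed)
  storage.mode(a) <- "integer"; storage.mode(d) <- "integer"
  # all beta-function arguments are integers: use an lgamma lookup table
  lg <- lgamma(seq_len(sum(as.numeric(d)) + max(d) + 4L))
  ta <- t(a); td <- t(d)                # J x n column access
  # log predictive of each mutation opening its own cluster (Beta(1,1))
  new_ll <- colSums(matrix(lg[ta + 1L] + lg[td - ta + 1L] - lg[td + 2L],
                           J, n))
  # all-singletons initialization: clusters coalesce bottom-up, which
  # mixes far better than a single-cluster start (escaping an established
  # cluster through a one-mutation state is prohibitively unlikely under
  # the diffuse Beta(1, 1) base measure once many microbiopsies are zero)
  z <- seq_len(n)
  AT <- ta + 0L; DT <- td + 0L
  sizes <- rep(1L, n)
  alpha <- config$alpha
  kept <- list(); trace <- integer(0)
  for (it in seq_len(config$n_iter)) {
    for (i in seq_len(n)) {
      ai <- ta[, i]; di <- td[, i]
      k <- z[i]
      AT[, k] <- AT[, k] - ai; DT[, k] <- DT[, k] - di
      sizes[k] <- sizes[k] - 1L
      if (sizes[k] == 0L) {             # cluster dies
        AT <- AT[, -k, drop = FALSE]; DT <- DT[, -k, drop = FALSE]
        sizes <- sizes[-k]
        z[z > k] <- z[z > k] - 1L
      }
      K <- length(sizes)
      ll <- .colSums(lg[AT + (ai + 1L)] + lg[DT - AT + (di - ai + 1L)] -
                       lg[DT + (di + 2L)] -
                       lg[AT + 1L] - lg[DT - AT + 1L] + lg[DT + 2L],
                     J, K)
      logw <- c(log(sizes) + ll, log(alpha) + new_ll[i])
      logw <- logw - max(logw)
      k_new <- sample.int(K + 1L, 1L, prob = exp(logw))
      if (k_new > K) {                  # birth of a new cluster
        AT <- cbind(AT, 0L); DT <- cbind(DT, 0L)
        sizes <- c(sizes, 0L)
      }
      z[i] <- k_new
      AT[, k_new] <- AT[, k_new] + ai; DT[, k_new] <- DT[, k_new] + di
      sizes[k_new] <- sizes[k_new] + 1L
    }
    # Escobar-West concentration update, Gamma(1, 1) hyperprior
    K <- length(sizes)
    eta <- stats::rbeta(1, alpha + 1, n)
    odds <- (1 + K - 1) / (n * (1 - log(eta)))
    comp <- stats::runif(1) < odds / (1 + odds)
    alpha <- stats::rgamma(1, 1 + K - !comp, 1 - log(eta))
    trace[it] <- K
    if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
      kept[[length(kept) + 1L]] <- z
    }
  }
  if (length(kept) == 0) kept <- list(z)
  # posterior co-clustering and Binder-loss point estimate
  P <- matrix(0, n, n)
  for (zz in kept) {
    M <- outer(zz, zz, "==")
    P <- P + M
  }
  P <- P / length(kept)
  binder <- vapply(kept, function(zz) {
    M <- outer(zz, zz, "==")
    sum(M * (1 - 2 * P))
  }, numeric(1))
  z_hat <- kept[[which.min(binder)]]
  z_hat <- match(z_hat, unique(z_hat))  # relabel in order of appearance
  # dissolve undersized clusters into the best-fitting remaining cluster
  repeat {
    tab <- tabulate(z_hat)
    small <- which(tab > 0 & tab < config$min_cluster_size)
    if (length(small) == 0 || length(unique(z_hat)) == 1) break
    k <- small[which.min(tab[small])]
    keep_k <- setdiff(sort(unique(z_hat)), k)
    Ak <- t(vapply(keep_k, function(kk) colSums(a[z_hat == kk, , drop = FALSE]),
                   numeric(J)))
    Dk <- t(vapply(keep_k, function(kk) colSums(d[z_hat == kk, , drop = FALSE]),
                   numeric(J)))
    for (i in which(z_hat == k)) {
      z_hat[i] <- keep_k[which.max(.log_pred(a[i, ], d[i, ], Ak, Dk))]
    }
  }
  z_hat <- match(z_hat, unique(z_hat))
  K <- max(z_hat)
  Af <- t(vapply(seq_len(K), function(k) colSums(a[z_hat == k, , drop = FALSE]),
                 numeric(J)))
  Df <- t(vapply(seq_len(K), function(k) colSums(d[z_hat == k, , drop = FALSE]),
                 numeric(J)))
  vaf_centroid <- (Af + 1) / (Df + 2)   # posterior mean under Beta(1, 1)
  rownames(vaf_centroid) <- paste0("cluster", seq_len(K))
  colnames(vaf_centroid) <- colnames(a)
  structure(list(assignment = z_hat,
                 clusters = data.frame(cluster_id = seq_len(K),
                                       n = tabulate(z_hat, K)),
                 vaf_centroid = vaf_centroid,
                 cf_centroid = 2 * vaf_centroid,
                 coclustering = P, trace = trace, config = config),
            class = "dp_clusters")
}

#' @export
print.dp_clusters <- function(x, ...) {
  cat(sprintf("dp_clusters: %d mutations in %d clusters\n",
              length(x$assignment), nrow(x$clusters)))
  if (nrow(x$clusters)) {
    cat("  sizes:", paste(x$clusters$n, collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
plot.dp_clusters <- function(x, ...) {
  plot(x$trace, type = "l", xlab = "Gibbs sweep",
       ylab = "occupied clusters", main = "DP chain diagnostic", ...)
  graphics::abline(v = x$config$burn_in, lty = 2)
  invisible(x)
}

#' Adjusted Rand index and per-cluster purity against truth labels
#'
#' @param assignment Integer/character cluster labels (or a
#'   \code{dp_clusters} object).
#' @param truth True labels of the same length.
#' @return List with \code{ari} and \code{purity} (named per cluster).
#' @export
cluster_quality <- function(assignment, truth) {
  if (inherits(assignment, "dp_clusters")) assignment <- assignment$assignment
  stopifnot(length(assignment) == length(truth))
  if (length(truth) < 2) {
    return(list(ari = NA_real_, purity = NA_real_))
  }
  tab <- table(assignment, truth)
  n <- length(truth)
  sum_comb <- function(x) sum(choose(x, 2))
  a <- sum_comb(tab); b <- sum_comb(rowSums(tab)); c_ <- sum_comb(colSums(tab))
  e <- b * c_ / choose(n, 2)
  ari <- if (abs((b + c_) / 2 - e) < 1e-12) 1 else (a - e) / ((b + c_) / 2 - e)
  purity <- apply(tab, 1, function(r) max(r) / sum(r))
  list(ari = ari, purity = purity)
}
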