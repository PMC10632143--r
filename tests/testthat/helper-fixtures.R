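# Shared fixture builders for the test suite. Everything is generated in
# code; no data files.

# count matrix from explicit alt/depth vectors or matrices
make_matrix <- function(alt, depth, chrom = NULL, pos = NULL,
                        ref = "A", alt_base = "T", clone_id = NULL,
                        gene_id = NULL) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  n <- nrow(alt)
  muts <- data.frame(chrom = chrom %||% rep("chr1", n),
                     pos = pos %||% seq(1, by = 10, length.out = n),
                     ref = rep_len(ref, n), alt = rep_len(alt_base, n),
                     stringsAsFactors = FALSE)
  muts$mut_class <- microclone::mutation_class(muts$ref, muts$alt)
  if (!is.null(clone_id)) muts$clone_id <- rep_len(clone_id, n)
  if (!is.null(gene_id)) muts$gene_id <- rep_len(gene_id, n)
  microclone::count_matrix(muts, alt, depth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# two well-separated clones over two microbiopsies for clustering tests
make_two_clone_matrix <- function(n_per = 60, depth = 100, seed = 42) {
  set.seed(seed)
  alt <- rbind(cbind(rbinom(n_per, depth, 0.40), rbinom(n_per, depth, 0.05)),
               cbind(rbinom(n_per, depth, 0.05), rbinom(n_per, depth, 0.40)))
  d <- matrix(depth, 2 * n_per, 2)
  list(mat = make_matrix(alt, d), truth = rep(1:2, each = n_per))
}

# independent exact-binomial oracle (base R implementation)
oracle_binom_p <- function(x, n, p0) {
  if (n == 0) return(NA_real_)
  stats::binom.test(x, n, p0)$p.value
}

# independent beta-binomial likelihood via the rising-factorial product
# form of the pmf (no beta/gamma functions; works at extreme rho where
# numerical integration over the latent p collapses)
oracle_betabin_loglik <- function(alt, depth, mu, rho) {
  a <- mu * (1 - rho) / rho
  b <- (1 - mu) * (1 - rho) / rho
  sum(vapply(seq_along(alt), function(j) {
    d <- depth[j]; x <- alt[j]
    if (d == 0) return(0)
    lchoose(d, x) +
      sum(log(a + seq_len(x) - 1)) +
      sum(log(b + seq_len(d - x) - 1)) -
      sum(log(a + b + seq_len(d) - 1))
  }, numeric(1)))
}

oracle_rho_hat <- function(alt, depth, grid = microclone:::RHO_GRID) {
  mu <- sum(alt) / sum(depth)
  mu <- min(max(mu, 1e-6), 1 - 1e-6)
  ll <- vapply(grid, function(r) oracle_betabin_loglik(alt, depth, mu, r),
               numeric(1))
  grid[which.max(ll)]
}
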