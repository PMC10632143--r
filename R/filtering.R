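# Post-calling genotyping and filtering: aggregation thresholds, the
# exact-binomial germline filter, the beta-binomial overdispersion (rho)
# artifact filter, DBS merging by Fisher test, and replicate-based
# sensitivity estimation. All filters operate on one patient's count
# matrix (the germline hypothesis pools reads across the patient's
# microbiopsies).

#' Overdispersion grid for the beta-binomial artifact filter
#'
#' 100 log-spaced values of the beta-binomial overdispersion parameter rho
#' between 1e-6 and 10^-0.05, the range over which [rho_filter()]
#' maximizes the likelihood.
#' @export
RHO_GRID <- 10^seq(-6, -0.05, length.out = 100)

#' Genotyping threshold flags
#'
#' A mutation is genotypable when at least one sample covers the site at
#' depth >= 4 with >= 3 reads reporting the alternate allele; all other
#' mutations are flagged \code{low_support}.
#'
#' @param mat A [count_matrix()].
#' @param min_depth,min_alt Thresholds (defaults 4 and 3).
#' @return The matrix with a logical \code{low_support} column added to
#'   \code{$mutations}.
#' @export
genotype_mutations <- function(mat, min_depth = 4, min_alt = 3) {
  ok <- rowSums(mat$depth >= min_depth & mat$alt >= min_alt) > 0
  mat$mutations$low_support <- !ok
  mat
}

# Exact two-sided binomial p-value (likelihood method, as in the classical
# exact test): sum of all outcome probabilities not exceeding that of the
# observed count. Vectorized over observations.
.exact_binom_p <- function(x, n, p0) {
  vapply(seq_along(x), function(i) {
    if (n[i] == 0) return(NA_real_)
    d <- stats::dbinom(0:n[i], n[i], p0[i])
    sum(d[d <= d[x[i] + 1] * (1 + 1e-7)])
  }, numeric(1))
}

#' Exact-binomial germline filter
#'
#' Heterozygous germline variants sit at VAF 0.5 in every sample from a
#' patient (0.95 on sex chromosomes in men, allowing for hemizygosity and
#' residual error). Reads are pooled across the patient's samples and
#' tested two-sided against \code{Binomial(pooled_depth, p0)};
#' Benjamini-Hochberg correction is applied across mutations and calls
#' consistent with the germline hypothesis (q > 1e-3) are flagged
#' \code{germline}.
#'
#' @param mat A [count_matrix()] for one patient.
#' @param sex \code{"male"} or \code{"female"}.
#' @param q_threshold Germline verdict threshold on the BH-adjusted p.
#' @return Data frame: \code{pooled_alt}, \code{pooled_depth},
#'   \code{germline_p}, \code{germline_q}, and \code{verdict} in
#'   \code{c("germline", "somatic", "low_support")} (low_support when the
#'   pooled depth is zero).
#' @export
germline_filter <- function(mat, sex = "female", q_threshold = 1e-3) {
  pooled_alt <- rowSums(mat$alt)
  pooled_depth <- rowSums(mat$depth)
  chrom <- mat$mutations$chrom %||% rep("chr1", nrow(mat$alt))
  p0 <- ifelse(sex == "male" & chrom %in% c("chrX", "chrY", "X", "Y"),
               0.95, 0.5)
  p <- .exact_binom_p(pooled_alt, pooled_depth, p0)
  q <- stats::p.adjust(p, method = "BH")
  verdict <- ifelse(pooled_depth == 0, "low_support",
                    ifelse(q > q_threshold, "germline", "somatic"))
  data.frame(pooled_alt = pooled_alt, pooled_depth = pooled_depth,
             p0 = p0, germline_p = p, germline_q = q, verdict = verdict,
             stringsAsFactors = FALSE)
}

# Beta-binomial log-likelihood of count vectors at overdispersion rho,
# mean fixed per mutation. Cells with depth 0 contribute nothing.
.betabin_loglik_grid <- function(alt, depth, mu, grid = RHO_GRID) {
  mu <- pmin(pmax(mu, 1e-6), 1 - 1e-6)
  covered <- rowSums(depth > 0)
  ll <- matrix(-Inf, nrow(alt), length(grid))
  for (g in seq_along(grid)) {
    rho <- grid[g]
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    ll[, g] <- rowSums(lbeta(alt + a, depth - alt + b)) - covered * lbeta(a, b)
  }
  ll
}

#' Beta-binomial overdispersion (rho) artifact filter
#'
#' Recurrent sequencing artifacts scatter low alt counts across all
#' samples and are well described by a binomial (overdispersion near 0);
#' true clonal mutations are present at high VAF in some samples and
#' absent in others, demanding high overdispersion. For every mutation the
#' likelihood of its alt/depth vector under a beta-binomial with the mean
#' fixed at the pooled VAF is maximized over a 100-point log-spaced grid
#' of rho in \[1e-6, 10^-0.05\]; calls with \code{rho_hat < 0.1} are
#' flagged artifacts.
#'
#' @param mat A [count_matrix()] for one patient (>= 2 samples).
#' @param rho_threshold Verdict threshold (default 0.1).
#' @param grid Overdispersion grid.
#' @return Data frame with \code{rho_hat} and \code{verdict} in
#'   \code{c("artifact", "somatic", "low_support")}.
#' @export
rho_filter <- function(mat, rho_threshold = 0.1, grid = RHO_GRID) {
  if (ncol(mat$alt) < 2) stop("rho filter needs >= 2 samples")
  pooled_depth <- rowSums(mat$depth)
  mu <- ifelse(pooled_depth > 0, rowSums(mat$alt) / pmax(pooled_depth, 1), NA)
  ll <- .betabin_loglik_grid(mat$alt, mat$depth, ifelse(is.na(mu), 0.5, mu), grid)
  rho_hat <- grid[max.col(ll, ties.method = "first")]
  verdict <- ifelse(pooled_depth == 0, "low_support",
                    ifelse(rho_hat < rho_threshold, "artifact", "somatic"))
  rho_hat[pooled_depth == 0] <- NA_real_
  data.frame(rho_hat = rho_hat, verdict = verdict, stringsAsFactors = FALSE)
}

#' Combined filtering verdicts for one patient
#'
#' Runs genotyping, the germline filter and the rho filter and assigns one
#' verdict per mutation with precedence low_support > germline > artifact
#' > somatic.
#'
#' @param mat A [count_matrix()] for one patient.
#' @param sex Patient sex.
#' @return Data frame combining the per-filter statistics with a single
#'   \code{verdict} column; the four verdicts partition the mutations.
#' @export
filter_calls <- function(mat, sex = "female") {
  geno <- genotype_mutations(mat)
  g <- germline_filter(mat, sex)
  r <- rho_filter(mat)
  verdict <- ifelse(geno$mutations$low_support | g$verdict == "low_support",
                    "low_support",
                    ifelse(g$verdict == "germline", "germline",
                           ifelse(r$verdict == "artifact", "artifact",
                                  "somatic")))
  out <- data.frame(mut_id = mat$mutations$mut_id %||%
                      sprintf("row%06d", seq_len(nrow(mat$alt))),
                    pooled_alt = g$pooled_alt, pooled_depth = g$pooled_depth,
                    germline_p = g$germline_p, germline_q = g$germline_q,
                    rho_hat = r$rho_hat, verdict = verdict,
                    stringsAsFactors = FALSE)
  out
}

#' Merge adjacent substitutions into double-base substitutions
#'
#' Adjacent single-base substitutions (same chromosome, consecutive
#' positions) are merged into one DBS call when a two-sided Fisher exact
#' test finds no significant difference between the alt/ref read counts of
#' the two sites (pooled across the patient's samples). Runs of more than
#' two adjacent calls are merged greedily left to right.
#'
#' @param mat A [count_matrix()]; rows must be SBS calls.
#' @param p_threshold Merge when the Fisher p-value is >= this (default
#'   0.05: counts not significantly different).
#' @return Data frame of calls in which merged pairs are replaced by one
#'   DBS record (two-base ref/alt, position of the first site).
#' @export
merge_dbs <- function(mat, p_threshold = 0.05) {
  muts <- mat$mutations
  pooled_alt <- rowSums(mat$alt)
  pooled_ref <- rowSums(mat$depth) - pooled_alt
  ord <- order(muts$chrom, muts$pos)
  merged_into <- rep(NA_integer_, nrow(muts))
  i <- 1
  while (i < length(ord)) {
    r1 <- ord[i]; r2 <- ord[i + 1]
    adjacent <- muts$chrom[r1] == muts$chrom[r2] &&
      muts$pos[r2] == muts$pos[r1] + 1 &&
      muts$mut_class[r1] == "SBS" && muts$mut_class[r2] == "SBS"
    if (adjacent) {
      tab <- matrix(c(pooled_alt[r1], pooled_ref[r1],
                      pooled_alt[r2], pooled_ref[r2]), 2, byrow = TRUE)
      if (stats::fisher.test(tab)$p.value >= p_threshold) {
        merged_into[r2] <- r1
        i <- i + 2          # greedy: the right member cannot merge again
        next
      }
    }
    i <- i + 1
  }
  out <- muts
  keep <- is.na(merged_into)
  for (r2 in which(!keep)) {
    r1 <- merged_into[r2]
    out$ref[r1] <- paste0(muts$ref[r1], muts$ref[r2])
    out$alt[r1] <- paste0(muts$alt[r1], muts$alt[r2])
    out$mut_class[r1] <- "DBS"
  }
  out[keep, , drop = FALSE]
}

#' Replicate-based sensitivity estimation
#'
#' For each near-replicate pair, computes the fraction of the first
#' member's calls also called in the second and vice versa, averages the
#' two directions, and reports the per-pair values and their median: an
#' empirical estimate of the per-dissection sensitivity of the calling
#' pipeline.
#'
#' @param pairs List of pairs with call-set elements \code{a} and
#'   \code{b}, as from [simulate_replicate_pairs()].
#' @return List with \code{per_pair} (data frame: both directions and
#'   their mean) and \code{median}.
#' @export
estimate_sensitivity <- function(pairs) {
  if (length(pairs) < 1) stop("need at least one replicate pair")
  rows <- lapply(seq_along(pairs), function(i) {
    p <- pairs[[i]]
    if (length(p$a) == 0) {
      warning("pair ", i, " has an empty first call set; skipped")
      return(NULL)
    }
    ab <- mean(p$a %in% p$b)
    ba <- if (length(p$b) == 0) NA_real_ else mean(p$b %in% p$a)
    data.frame(pair = i, frac_a_in_b = ab, frac_b_in_a = ba,
               shared = mean(c(ab, ba), na.rm = TRUE))
  })
  per_pair <- do.call(rbind, rows)
  list(per_pair = per_pair, median = stats::median(per_pair$shared))
}
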