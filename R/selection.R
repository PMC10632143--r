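# Per-patient, per-gene mutated-cell-fraction estimation and
# lesional-vs-nonlesional comparison.

#' Fraction of cells carrying a mutation in each gene
#'
#' For each patient, gene and tissue (lesional / nonlesional), sums
#' 2 x VAF x microbiopsy volume over the patient's microbiopsies in that
#' tissue and divides by the total dissected volume in that tissue. When
#' a clone carries several mutations in the same gene only the one with
#' the highest VAF is counted (ties broken by genomic position); without
#' clone labels the rule is applied per microbiopsy.
#'
#' @param mat A [count_matrix()]; \code{$mutations} must have
#'   \code{gene_id} (NA rows are ignored) and may have \code{clone_id}.
#' @param microbiopsies Data frame with \code{sample_id},
#'   \code{patient_id}, \code{lesional}, \code{volume}.
#' @return Data frame: \code{patient_id}, \code{gene}, \code{tissue},
#'   \code{fraction} (capped at 1, with \code{capped} flag),
#'   \code{n_mutations}.
#' @export
mutated_cell_fraction <- function(mat, microbiopsies) {
  muts <- mat$mutations
  stopifnot(!is.null(muts$gene_id))
  v <- vaf(mat)
  mb <- microbiopsies[match(mat$samples, microbiopsies$sample_id), ]
  if (any(is.na(mb$sample_id))) stop("microbiopsy metadata missing for some samples")
  rows <- list()
  for (pid in unique(mb$patient_id)) {
    for (tissue in c("lesional", "nonlesional")) {
      jj <- which(mb$patient_id == pid &
                    (mb$lesional == (tissue == "lesional")))
      if (length(jj) == 0) next
      total_vol <- sum(mb$volume[jj])
      if (total_vol <= 0) stop("zero total volume for patient ", pid)
      genic <- which(!is.na(muts$gene_id))
      for (gene in unique(muts$gene_id[genic])) {
        gi <- genic[muts$gene_id[genic] == gene]
        contrib <- 0; n_used <- 0L
        if (!is.null(muts$clone_id) && !all(is.na(muts$clone_id[gi]))) {
          # one mutation per clone: the one with the highest VAF overall
          groups <- split(gi, muts$clone_id[gi])
          use <- vapply(groups, function(ix) {
            vmax <- apply(v[ix, jj, drop = FALSE], 1, max, na.rm = TRUE)
            vmax[!is.finite(vmax)] <- -1
            ix[order(-vmax, muts$pos[ix])][1]
          }, integer(1))
        } else {
          use <- gi  # per-microbiopsy max applied below
        }
        for (j in jj) {
          vj <- v[use, j]
          vj <- vj[!is.na(vj) & vj > 0]
          if (length(vj) == 0) next
          if (is.null(muts$clone_id) || all(is.na(muts$clone_id[gi]))) {
            vj <- max(vj)  # per-microbiopsy rule without clone labels
          }
          contrib <- contrib + sum(2 * vj * mb$volume[mb$sample_id == mat$samples[j]])
          n_used <- n_used + length(vj)
        }
        frac <- contrib / total_vol
        rows[[length(rows) + 1L]] <- data.frame(
          patient_id = pid, gene = gene, tissue = tissue,
          fraction = min(frac, 1), capped = frac > 1,
          n_mutations = n_used, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0) {
    return(data.frame(patient_id = character(0), gene = character(0),
                      tissue = character(0), fraction = numeric(0),
                      capped = logical(0), n_mutations = integer(0)))
  }
  do.call(rbind, rows)
}

#' Paired lesional-vs-nonlesional comparison of mutated-cell fractions
#'
#' For each gene, pairs patients' lesional and nonlesional fractions
#' (patients missing either tissue contribute a 0 for the missing one
#' only if the gene was measured in the other; otherwise skipped), runs a
#' Wilcoxon signed-rank test, and applies Benjamini-Hochberg correction
#' across genes.
#'
#' @param fractions Output of [mutated_cell_fraction()].
#' @return Data frame: \code{gene}, \code{n_pairs}, \code{p},
#'   \code{q} (BH), \code{median_lesional}, \code{median_nonlesional};
#'   genes with no complete pair are noted in the \code{note} column.
#' @export
compare_tissues <- function(fractions) {
  genes <- unique(fractions$gene)
  rows <- lapply(genes, function(g) {
    d <- fractions[fractions$gene == g, ]
    wide <- merge(d[d$tissue == "lesional", c("patient_id", "fraction")],
                  d[d$tissue == "nonlesional", c("patient_id", "fraction")],
                  by = "patient_id", suffixes = c("_l", "_nl"))
    if (nrow(wide) == 0) {
      return(data.frame(gene = g, n_pairs = 0L, p = NA_real_,
                        median_lesional = NA_real_,
                        median_nonlesional = NA_real_,
                        note = "no complete pairs", stringsAsFactors = FALSE))
    }
    p <- if (all(wide$fraction_l == wide$fraction_nl)) 1 else
      suppressWarnings(stats::wilcox.test(wide$fraction_l, wide$fraction_nl,
                                          paired = TRUE)$p.value)
    data.frame(gene = g, n_pairs = nrow(wide), p = p,
               median_lesional = stats::median(wide$fraction_l),
               median_nonlesional = stats::median(wide$fraction_nl),
               note = "", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out
}
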