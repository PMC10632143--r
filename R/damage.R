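# Damage potential of a mutational signature: the expected fraction of
# coding mutations in each functional annotation class, normalized by a
# baseline process, computed by exhaustive enumeration of all possible
# single-base substitutions in a gene set.

GENETIC_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

# Expand a gene model into per-position records: base, role
# (coding/splice/intron), codon info for coding positions.
.gene_positions <- function(gene) {
  if (!is.null(gene$cds)) {
    exons <- gene$cds; introns <- character(0)
  } else {
    exons <- gene$exons; introns <- gene$introns %||% character(0)
  }
  cds <- paste(exons, collapse = "")
  if (nchar(cds) < 3 || nchar(cds) %% 3 != 0) return(NULL)
  pieces <- list(); cds_off <- 0L
  for (i in seq_along(exons)) {
    b <- strsplit(toupper(exons[i]), "")[[1]]
    pieces[[length(pieces) + 1L]] <- data.frame(
      base = b, role = "coding", cds_pos = cds_off + seq_along(b),
      stringsAsFactors = FALSE)
    cds_off <- cds_off + length(b)
    if (i <= length(introns)) {
      ib <- strsplit(toupper(introns[i]), "")[[1]]
      role <- rep("intron", length(ib))
      role[c(1, 2, length(ib) - 1, length(ib))] <- "splice"
      pieces[[length(pieces) + 1L]] <- data.frame(
        base = ib, role = role, cds_pos = NA_integer_,
        stringsAsFactors = FALSE)
    }
  }
  pos <- do.call(rbind, pieces)
  pos$cds <- cds
  pos
}

#' Damage potential of a signature by annotation class
#'
#' Enumerates every possible single-base substitution in a set of toy
#' gene models, classifies each by functional consequence (synonymous,
#' missense, nonsense, or splice site -- the first/last 2 bp of each
#' intron) and by its 96-class context, and computes the expected
#' fraction of mutations in each consequence class when substitutions are
#' weighted by the signature's class probabilities. Fractions are
#' normalized by the same quantity under a baseline: a uniform mutation
#' rate, or another signature (e.g. the UV spectrum).
#'
#' @param signature 96-vector of class probabilities.
#' @param genes List of gene models; each needs \code{cds} (in-frame
#'   coding sequence) or \code{exons} plus \code{introns}. Genes without
#'   a valid ORF (length < 3 or not a codon multiple) are excluded with a
#'   warning.
#' @param baseline \code{"uniform"} or a 96-vector.
#' @return Data frame per consequence class: expected fractions under
#'   signature and baseline, and their \code{ratio}.
#' @export
damage_potential <- function(signature, genes, baseline = "uniform") {
  stopifnot(length(signature) == 96)
  base_vec <- if (identical(baseline, "uniform")) NULL else {
    stopifnot(length(baseline) == 96); baseline
  }
  classes <- c("synonymous", "missense", "nonsense", "splice")
  w_sig <- stats::setNames(numeric(4), classes)
  w_base <- stats::setNames(numeric(4), classes)
  names(signature) <- sbs_classes()
  if (!is.null(base_vec)) names(base_vec) <- sbs_classes()
  for (gi in seq_along(genes)) {
    pos <- .gene_positions(genes[[gi]])
    if (is.null(pos)) {
      warning("gene ", genes[[gi]]$name %||% gi,
              " has no valid ORF; excluded")
      next
    }
    n <- nrow(pos)
    for (i in seq_len(n)) {
      if (i == 1 || i == n) next               # no flanking context
      if (pos$role[i] == "intron") next
      ref <- pos$base[i]
      tri <- paste0(pos$base[i - 1], ref, pos$base[i + 1])
      for (alt in setdiff(BASES, ref)) {
        cls <- sbs_class_of(ref, alt, tri)
        if (pos$role[i] == "splice") {
          cons <- "splice"
        } else {
          cp <- pos$cds_pos[i]
          codon_i <- (cp - 1) %/% 3
          off <- (cp - 1) %% 3
          codon <- substr(pos$cds[i], codon_i * 3 + 1, codon_i * 3 + 3)
          new_codon <- codon
          substr(new_codon, off + 1, off + 1) <- alt
          aa_old <- GENETIC_CODE[[codon]]
          aa_new <- GENETIC_CODE[[new_codon]]
          cons <- if (aa_new == aa_old) "synonymous"
                  else if (aa_new == "*") "nonsense" else "missense"
        }
        w_sig[cons] <- w_sig[cons] + signature[[cls]]
        w_base[cons] <- w_base[cons] +
          (if (is.null(base_vec)) 1 else base_vec[[cls]])
      }
    }
  }
  if (sum(w_sig) == 0) stop("no enumerable substitutions in gene set")
  f_sig <- w_sig / sum(w_sig)
  f_base <- w_base / sum(w_base)
  data.frame(class = classes, expected_sig = as.numeric(f_sig),
             expected_baseline = as.numeric(f_base),
             ratio = as.numeric(f_sig / f_base),
             stringsAsFactors = FALSE)
}

#' Bundled toy gene models
#'
#' Deterministic synthetic coding genes (random in-frame codon sequences
#' without internal stops, two introns each) for damage-potential
#' calculations; these stand in for real gene annotations, which are not
#' bundled.
#'
#' @param n_genes Number of genes.
#' @param n_codons Codons per gene.
#' @return List of gene models with \code{exons} and \code{introns}.
#' @export
toy_gene_models <- function(n_genes = 15, n_codons = 300) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(20260101)
  codons <- names(GENETIC_CODE)[GENETIC_CODE != "*"]
  lapply(seq_len(n_genes), function(i) {
    cds <- c("ATG", sample(codons, n_codons - 1, replace = TRUE))
    cds <- paste(cds, collapse = "")
    cut1 <- 3 * floor(n_codons / 3); cut2 <- 3 * floor(2 * n_codons / 3)
    intron <- function() paste0("GT", paste(sample(BASES, 40, TRUE),
                                            collapse = ""), "AG")
    list(name = sprintf("TG%02d", i),
         exons = c(substr(cds, 1, cut1), substr(cds, cut1 + 1, cut2),
                   substr(cds, cut2 + 1, nchar(cds))),
         introns = c(intron(), intron()))
  })
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
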