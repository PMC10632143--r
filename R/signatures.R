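# Mutational-signature catalog, 96-class spectra and exposure attribution.

#' Reference spectrum of psoralen mutagenesis
#'
#' Psoralen photoadducts form at TpA dinucleotides and give rise to T>A,
#' T>C and T>G substitutions at the mutated T. The reference vector places
#' all probability mass on the twelve classes \code{N[T>A]A},
#' \code{N[T>C]A} and \code{N[T>G]A} (mutated T with 3' A after pyrimidine
#' normalization), zero elsewhere.
#'
#' @param type_weights Named weights for the three substitution types;
#'   default emphasizes T>A. Normalized internally.
#' @return Named numeric vector of length 96 summing to 1.
#' @export
psoralen_reference <- function(type_weights = c("T>A" = 0.5, "T>C" = 0.3, "T>G" = 0.2)) {
  stopifnot(all(names(type_weights) %in% c("T>A", "T>C", "T>G")),
            all(type_weights >= 0), sum(type_weights) > 0)
  type_weights <- type_weights / sum(type_weights)
  cls <- sbs_classes()
  v <- stats::setNames(numeric(96), cls)
  for (tp in names(type_weights)) {
    hit <- substr(cls, 3, 5) == tp & substr(cls, 7, 7) == "A"
    # four 5' contexts share the type weight uniformly
    v[hit] <- type_weights[[tp]] / sum(hit)
  }
  v / sum(v)
}

# Internal builders for the bundled process spectra. These are synthetic
# constructions that mimic the shape of the corresponding COSMIC processes
# (UV dipyrimidine C>T, clock-like CpG C>T plus a flat component, APOBEC
# TpC C>T/C>G); they are not copies of the COSMIC matrices.
.sig_uv_like <- function() {
  cls <- sbs_classes()
  v <- stats::setNames(numeric(96), cls)
  ct <- substr(cls, 3, 5) == "C>T"
  py5 <- substr(cls, 1, 1) %in% c("C", "T")   # dipyrimidine: 5' pyrimidine
  v[ct & py5 & substr(cls, 1, 1) == "T"] <- 0.115
  v[ct & py5 & substr(cls, 1, 1) == "C"] <- 0.095
  rest <- v == 0
  v[rest] <- 0.16 / sum(rest)
  v / sum(v)
}

.sig_clock_like <- function() {
  cls <- sbs_classes()
  v <- stats::setNames(rep(0.55 / 96, 96), cls)  # flat SBS5-like component
  cpg <- substr(cls, 3, 5) == "C>T" & substr(cls, 7, 7) == "G"
  v[cpg] <- v[cpg] + 0.45 / sum(cpg)             # SBS1-like CpG C>T
  v / sum(v)
}

.sig_apobec_like <- function() {
  cls <- sbs_classes()
  v <- stats::setNames(numeric(96), cls)
  tpc <- substr(cls, 1, 1) == "T" & substr(cls, 3, 3) == "C"
  tcw <- tpc & substr(cls, 7, 7) %in% c("A", "T")
  ct <- substr(cls, 5, 5) == "T"; cg <- substr(cls, 5, 5) == "G"
  v[tcw & ct] <- 0.21; v[tcw & cg] <- 0.21
  v[tpc & !tcw & (ct | cg)] <- 0.02
  rest <- v == 0
  v[rest] <- 0.04 / sum(rest)
  v / sum(v)
}

#' Bundled signature catalog
#'
#' A fixed catalog of 96-class signature spectra covering the four
#' mutational processes active in sun-exposed psoriatic epidermis: a UV
#' dipyrimidine C>T signature (SBS7b-like), a merged clock-like signature
#' (SBS1/5-like; the CpG and flat components cannot be separated at
#' microbiopsy scale and are modelled as one entry), an APOBEC signature
#' (SBS2/13-like) and the psoralen TpA signature.
#'
#' @param include Character vector of entries to keep.
#' @return Matrix with one row per signature (rows sum to 1), 96 columns
#'   named by class.
#' @export
signature_catalog <- function(include = c("UV", "SBS1/5", "APOBEC", "psoralen")) {
  all <- rbind(
    "UV"       = .sig_uv_like(),
    "SBS1/5"   = .sig_clock_like(),
    "APOBEC"   = .sig_apobec_like(),
    "psoralen" = psoralen_reference()
  )
  bad <- setdiff(include, rownames(all))
  if (length(bad)) stop("unknown catalog entries: ", paste(bad, collapse = ", "))
  all[include, , drop = FALSE]
}

#' 96-class mutation spectrum
#'
#' Tabulates single-base substitutions over the 96 pyrimidine-centred
#' trinucleotide classes.
#'
#' @param mutations Data frame with columns \code{ref}, \code{alt} and
#'   \code{trinucleotide} (context on the reference strand), or a character
#'   vector of class labels.
#' @return Named integer vector of length 96 with attribute
#'   \code{n_excluded}: the number of mutations lacking a valid context.
#' @export
spectrum_96 <- function(mutations) {
  cls <- if (is.character(mutations)) mutations
         else sbs_class_of(mutations$ref, mutations$alt, mutations$trinucleotide)
  valid <- !is.na(cls) & cls %in% sbs_classes()
  counts <- table(factor(cls[valid], levels = sbs_classes()))
  out <- stats::setNames(as.integer(counts), sbs_classes())
  attr(out, "n_excluded") <- sum(!valid)
  out
}

#' Signature exposure attribution by multinomial EM
#'
#' Fits maximum-likelihood mixture weights of the catalog signatures to an
#' observed 96-class count spectrum by expectation--maximization, and
#' converts them to attributed mutation counts. Weights whose fitted
#' exposure falls below \code{sparsity} (as a fraction of the total) are
#' zeroed and their mass reported as unassigned.
#'
#' @param spectrum Non-negative 96-vector of counts.
#' @param catalog Signature matrix as from [signature_catalog()].
#' @param sparsity Minimum fraction of the total attributable to a
#'   signature before it is zeroed into the unassigned pool (default 0, no
#'   sparsification).
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations.
#' @return List with \code{exposure} (named counts per signature),
#'   \code{weights} (mixture proportions), \code{unassigned},
#'   \code{loglik} and \code{iterations}. Exposures plus unassigned equal
#'   the spectrum total.
#' @export
fit_exposures <- function(spectrum, catalog = signature_catalog(),
                          sparsity = 0, tol = 1e-8, max_iter = 10000) {
  stopifnot(length(spectrum) == ncol(catalog), all(spectrum >= 0))
  n <- sum(spectrum)
  k <- nrow(catalog)
  if (n == 0) {
    return(list(exposure = stats::setNames(numeric(k), rownames(catalog)),
                weights = stats::setNames(numeric(k), rownames(catalog)),
                unassigned = 0, loglik = 0, iterations = 0L))
  }
  S <- pmax(catalog, 1e-12)          # guard zero catalog entries in logs
  w <- rep(1 / k, k)
  ll_old <- -Inf
  it <- 0L
  repeat {
    it <- it + 1L
    mix <- crossprod(S, w)[, 1]                     # length-96 mixture density
    ll <- sum(spectrum * log(mix))
    if (is.finite(ll_old) && abs(ll - ll_old) <= tol * abs(ll_old)) break
    # E-step responsibilities, M-step reweight, in one pass
    resp <- S * w                                    # k x 96
    resp <- sweep(resp, 2, mix, "/")
    w <- as.numeric(resp %*% spectrum) / n
    ll_old <- ll
    if (it >= max_iter) break
  }
  w <- stats::setNames(pmax(w, 0), rownames(catalog))
  w <- w / sum(w)
  exposure <- w * n
  unassigned <- 0
  if (sparsity > 0) {
    drop <- exposure < sparsity * n & exposure > 0
    unassigned <- sum(exposure[drop])
    exposure[drop] <- 0
  }
  list(exposure = exposure, weights = w, unassigned = unassigned,
       loglik = ll, iterations = it)
}

#' Exposure table for a set of clones
#'
#' Applies [fit_exposures()] to each clone's spectrum.
#'
#' @param spectra Matrix of clone spectra (clones x 96) or a list of
#'   96-vectors.
#' @param catalog Signature matrix.
#' @param ... Passed to [fit_exposures()].
#' @return Data frame: one row per clone, one column per signature plus
#'   \code{unassigned} and \code{total}.
#' @export
exposure_table <- function(spectra, catalog = signature_catalog(), ...) {
  if (is.list(spectra)) spectra <- do.call(rbind, spectra)
  rows <- lapply(seq_len(nrow(spectra)), function(i) {
    f <- fit_exposures(spectra[i, ], catalog, ...)
    c(f$exposure, unassigned = f$unassigned, total = sum(spectra[i, ]))
  })
  out <- as.data.frame(do.call(rbind, rows))
  if (!is.null(rownames(spectra))) out$clone <- rownames(spectra)
  out
}
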