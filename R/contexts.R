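# Trinucleotide context machinery for the 96-class SBS representation.

BASES <- c("A", "C", "G", "T")
SUBSTITUTIONS <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96 single-base-substitution classes
#'
#' Returns the 96 pyrimidine-centred trinucleotide substitution classes in
#' the conventional order: the six substitution types \code{C>A, C>G, C>T,
#' T>A, T>C, T>G}, each expanded over the sixteen flanking-base combinations
#' in alphabetical order, labelled \code{"A[C>A]A"} etc.
#'
#' @return Character vector of length 96.
#' @export
sbs_classes <- function() {
  out <- character(0)
  for (sub in SUBSTITUTIONS) {
    for (f5 in BASES) {
      for (f3 in BASES) {
        out <- c(out, paste0(f5, "[", sub, "]", f3))
      }
    }
  }
  out
}

#' Reverse complement of a DNA string
#'
#' @param x Character vector of DNA strings (A/C/G/T).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(x) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  vapply(strsplit(toupper(x), ""), function(b) {
    paste(rev(unname(comp[b])), collapse = "")
  }, character(1))
}

#' Pyrimidine-normalized SBS class of a mutation
#'
#' Maps a single-base substitution with its trinucleotide context onto one of
#' the 96 canonical classes. Purine-reference mutations are reverse
#' complemented so that the mutated base is always a pyrimidine (C or T).
#' The normalization is an involution: applying it to the reverse-complement
#' representation of the same event yields the same class.
#'
#' @param ref,alt Single reference and alternate bases.
#' @param trinucleotide Three-base context centred on the mutated base, on
#'   the same strand as \code{ref}.
#' @return Class label such as \code{"T[C>T]A"}, or \code{NA} if the inputs
#'   are not a valid SBS.
#' @export
sbs_class_of <- function(ref, alt, trinucleotide) {
  n <- max(length(ref), length(alt), length(trinucleotide))
  ref <- toupper(rep_len(ref, n)); alt <- toupper(rep_len(alt, n))
  tri <- toupper(rep_len(trinucleotide, n))
  out <- rep(NA_character_, n)
  ok <- !is.na(ref) & !is.na(alt) & !is.na(tri) &
    nchar(ref) == 1L & nchar(alt) == 1L & nchar(tri) == 3L &
    ref %in% BASES & alt %in% BASES & ref != alt &
    substr(tri, 2, 2) == ref
  if (any(ok)) {
    r <- ref[ok]; a <- alt[ok]; t3 <- tri[ok]
    purine <- r %in% c("A", "G")
    if (any(purine)) {
      comp <- c(A = "T", C = "G", G = "C", T = "A")
      r[purine] <- unname(comp[r[purine]])
      a[purine] <- unname(comp[a[purine]])
      t3[purine] <- revcomp(t3[purine])
    }
    out[ok] <- paste0(substr(t3, 1, 1), "[", r, ">", a, "]", substr(t3, 3, 3))
  }
  out
}

#' Is a mutation a TpA-site thymine mutation?
#'
#' TRUE when the mutated base is a T immediately followed by an A on either
#' strand -- i.e. the pyrimidine-normalized class has central base T and
#' 3' flank A. These are the sites targeted by psoralen photoadducts.
#'
#' @param ref,alt,trinucleotide As in [sbs_class_of()].
#' @return Logical vector.
#' @export
is_tpa_site <- function(ref, alt, trinucleotide) {
  cls <- sbs_class_of(ref, alt, trinucleotide)
  !is.na(cls) & substr(cls, 3, 3) == "T" & substr(cls, 7, 7) == "A"
}

#' Cosine similarity between two non-negative spectra
#'
#' @param a,b Numeric vectors of equal length, non-negative.
#' @return Similarity in \[0, 1\]; 0 (with a warning) if either vector is
#'   all zero.
#' @export
cosine_similarity <- function(a, b) {
  stopifnot(length(a) == length(b))
  if (any(a < 0) || any(b < 0)) stop("spectra must be non-negative")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) {
    warning("all-zero spectrum; cosine similarity undefined, returning 0")
    return(0)
  }
  sum(a * b) / (na * nb)
}
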