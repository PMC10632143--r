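# Core domain containers: patients, microbiopsies, mutation calls and the
# mutation x microbiopsy read-count matrix. Cohorts are plain data frames
# (one row per patient / per microbiopsy); the count matrix is a light S3
# class holding paired alt/depth integer matrices.

PUVA_BANDS <- c("0", "1-50", "51-200", ">200", "unknown")

#' Construct a patient table
#'
#' @param patient_id Character ids.
#' @param age Ages in years (>= 0).
#' @param disease_duration Disease duration in years (may be NA), at most
#'   \code{age} where present.
#' @param puva_cycles_band Ordinal PUVA-treatment bands, one of
#'   \code{"0"}, \code{"1-50"}, \code{"51-200"}, \code{">200"},
#'   \code{"unknown"}.
#' @param sex \code{"male"} or \code{"female"}.
#' @param uvb_history Logical.
#' @return Data frame with one row per patient; \code{puva_cycles_band} is
#'   an ordered factor.
#' @export
patient_table <- function(patient_id, age, disease_duration = NA_real_,
                          puva_cycles_band = "0", sex = "female",
                          uvb_history = FALSE) {
  n <- length(patient_id)
  age <- rep_len(age, n)
  disease_duration <- rep_len(disease_duration, n)
  stopifnot(all(age >= 0),
            all(is.na(disease_duration) | disease_duration <= age),
            all(puva_cycles_band %in% PUVA_BANDS),
            all(sex %in% c("male", "female")))
  data.frame(patient_id = as.character(patient_id), age = age,
             disease_duration = disease_duration,
             puva_cycles_band = factor(rep_len(puva_cycles_band, n),
                                       levels = PUVA_BANDS, ordered = TRUE),
             sex = rep_len(sex, n),
             uvb_history = rep_len(uvb_history, n),
             stringsAsFactors = FALSE)
}

#' Construct a microbiopsy table
#'
#' One row per laser-capture microbiopsy. Positions \code{x}, \code{y} are
#' micrometres within the biopsy section; \code{volume} (um^3) and
#' \code{area} (um^2, skin-surface projection) must be positive.
#' Microbiopsies sharing a \code{biopsy_id} must share a patient.
#'
#' @param sample_id,patient_id,biopsy_id Character ids.
#' @param lesional Logical: dissected from lesional skin.
#' @param site Anatomical site label.
#' @param x,y Spatial position (um).
#' @param volume,area Dissected volume (um^3) and surface area (um^2).
#' @param mean_depth Mean sequencing depth (reads).
#' @return Data frame with one row per microbiopsy.
#' @export
microbiopsy_table <- function(sample_id, patient_id, biopsy_id, lesional = TRUE,
                              site = "leg", x = 0, y = 0,
                              volume = 1e5, area = 2000, mean_depth = 56) {
  n <- length(sample_id)
  out <- data.frame(sample_id = as.character(sample_id),
                    patient_id = rep_len(as.character(patient_id), n),
                    biopsy_id = rep_len(as.character(biopsy_id), n),
                    lesional = rep_len(lesional, n),
                    site = rep_len(site, n),
                    x = rep_len(x, n), y = rep_len(y, n),
                    volume = rep_len(volume, n), area = rep_len(area, n),
                    mean_depth = rep_len(mean_depth, n),
                    stringsAsFactors = FALSE)
  stopifnot(all(out$volume > 0), all(out$area > 0))
  pb <- unique(out[, c("patient_id", "biopsy_id")])
  if (anyDuplicated(pb$biopsy_id))
    stop("microbiopsies with the same biopsy_id must share patient_id")
  out
}

#' Construct a mutation x microbiopsy count matrix
#'
#' Pairs an alt-read matrix with a depth matrix over the same mutations
#' (rows) and microbiopsies (columns). The variant allele fraction is
#' \code{alt/depth} where depth > 0 and undefined (NA) at uncovered cells.
#'
#' @param mutations Data frame of mutation calls (at least \code{chrom},
#'   \code{pos}, \code{ref}, \code{alt}); one row per matrix row.
#' @param alt,depth Non-negative integer matrices, \code{alt <= depth}
#'   cellwise, with matching dimensions; columns named by sample id.
#' @return Object of class \code{count_matrix}.
#' @export
count_matrix <- function(mutations, alt, depth) {
  alt <- as.matrix(alt); depth <- as.matrix(depth)
  if (!all(dim(alt) == dim(depth))) stop("alt and depth dimensions differ")
  if (nrow(alt) != nrow(mutations)) stop("mutations/matrix row mismatch")
  if (any(alt < 0) || any(depth < 0)) stop("negative read counts")
  bad <- which(alt > depth, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stop(sprintf("alt > depth at mutation row %d, sample '%s'",
                 bad[1, 1], colnames(alt)[bad[1, 2]] %||% bad[1, 2]))
  }
  if (is.null(colnames(alt))) colnames(alt) <- paste0("S", seq_len(ncol(alt)))
  colnames(depth) <- colnames(alt)
  structure(list(mutations = mutations, alt = alt, depth = depth,
                 samples = colnames(alt)),
            class = "count_matrix")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d mutations x %d microbiopsies\n",
              nrow(x$alt), ncol(x$alt)))
  cat(sprintf("  median depth %.0f, median VAF (covered cells) %.3f\n",
              stats::median(x$depth),
              stats::median(vaf(x), na.rm = TRUE)))
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$alt)

#' Variant allele fractions of a count matrix
#'
#' @param x A \code{count_matrix}.
#' @return Matrix of \code{alt/depth}; NA where depth is 0 (undefined, not
#'   zero -- uncovered sites carry no evidence).
#' @export
vaf <- function(x) {
  v <- x$alt / x$depth
  v[x$depth == 0] <- NA_real_
  v
}

#' Subset a count matrix by mutation rows and/or samples
#'
#' @param x A \code{count_matrix}.
#' @param i Row index (mutations).
#' @param j Column index (samples).
#' @export
subset_matrix <- function(x, i = NULL, j = NULL) {
  if (is.null(i)) i <- seq_len(nrow(x$alt))
  if (is.null(j)) j <- seq_len(ncol(x$alt))
  count_matrix(x$mutations[i, , drop = FALSE],
               x$alt[i, j, drop = FALSE],
               x$depth[i, j, drop = FALSE])
}

#' Classify a ref/alt pair as SBS, DBS or indel
#'
#' @param ref,alt Allele strings.
#' @return Character vector in \code{c("SBS", "DBS", "indel")}.
#' @export
mutation_class <- function(ref, alt) {
  lr <- nchar(ref); la <- nchar(alt)
  out <- rep("indel", length(ref))
  out[lr == 1 & la == 1] <- "SBS"
  out[lr == 2 & la == 2] <- "DBS"
  out
}
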