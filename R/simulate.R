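# Synthetic cohort generator. Emulates the statistical structure of an LCM
# microbiopsy study of psoriatic epidermis: nested clones spread across
# spatially arranged microbiopsies, binomial read sampling, germline and
# recurrent-artifact contaminants, signature-mixture mutation spectra with
# age / disease-duration / PUVA effects, strand-asymmetric genic TpA
# mutagenesis, and near-replicate dissection pairs. Every emitted mutation
# carries ground-truth labels so downstream stages can be scored.

#' Simulation configuration
#'
#' Defaults encode the cohort conditions the generator emulates: exonic
#' clone burdens growing by 14.6 mutations per exome per year of age
#' (excluding psoralen mutations), a clock-like SBS1/5 component growing by
#' 0.65 per year of age plus 0.16 per year of disease duration, 616 extra
#' psoralen-attributed exonic mutations per clone in the >200 PUVA-cycle
#' band relative to untreated patients, per-dissection mutation-call
#' sensitivity of 0.89, a 1.72 untranscribed:transcribed TpA strand ratio
#' inside transcripts and a 1.09 leading:lagging replication-strand ratio.
#' Sequencing depth defaults to 56x and ages span 18--88 years.
#'
#' @param n_patients Number of patients.
#' @param age_range Uniform age range (years).
#' @param biopsies_per_patient Punch biopsies per patient (the first is
#'   lesional, the second nonlesional).
#' @param microbiopsies_per_biopsy LCM microbiopsies per biopsy.
#' @param root_clones_mean Mean number of independent root clones per
#'   biopsy (1 + Poisson).
#' @param subclone_prob Probability that a root clone carries one nested
#'   subclone.
#' @param mean_depth Mean sequencing depth (reads); per-cell depths are
#'   Poisson.
#' @param age_effect Non-psoralen exonic mutations per exome per year of age.
#' @param clock_age_effect SBS1/5 exonic mutations per exome per year of age.
#' @param duration_effect_sbs15 SBS1/5 mutations per exome per year of
#'   disease duration.
#' @param puva_extra_burden Extra psoralen-attributed exonic mutations per
#'   clone in the >200-cycle band versus the no-PUVA band.
#' @param psoralen_base_burden Mean psoralen burden per clone in the
#'   no-PUVA band (nonzero: psoralen exposure also occurs outside
#'   documented PUVA treatment).
#' @param puva_band_probs Sampling probabilities of the PUVA bands
#'   \code{0, 1-50, 51-200, >200}.
#' @param apobec_fraction Fraction of the UV-plus-APOBEC burden assigned to
#'   the APOBEC process.
#' @param burden_noise_sd Residual SD of clone total (non-psoralen) burden;
#'   \code{patient_sd}/\code{biopsy_sd} are the nested random-effect SDs.
#' @param patient_sd,biopsy_sd Random-effect SDs for the total burden.
#' @param sbs15_patient_sd,sbs15_noise_sd Random-effect and residual SDs of
#'   the clock-like component.
#' @param psoralen_patient_cv,psoralen_clone_cv Coefficients of variation
#'   of the psoralen component at the patient and clone level. Psoralen
#'   burdens are drawn from compositional Gamma distributions (a
#'   patient-level mean around the band mean, then clone-level burdens
#'   around the patient mean), which keeps them non-negative and
#'   right-skewed while preserving the configured band means exactly in
#'   expectation.
#' @param germline_rate,artifact_rate Contaminant rows added per true
#'   somatic row by [spike_contaminants()].
#' @param detection_sensitivity Per-dissection probability that a truly
#'   present mutation is called (used by [simulate_replicate_pairs()]).
#' @param strand_asymmetry_tpa Untranscribed:transcribed TpA mutation ratio
#'   inside transcripts.
#' @param leading_lagging_ratio Leading:lagging replication-strand ratio.
#' @param expression_effect Log-rate drop of genic mutation rate from the
#'   least to the most expressed gene.
#' @param clone_spatial_scale Exponential decay scale (um) of clone sharing
#'   with distance between microbiopsies.
#' @param median_area Median microbiopsy surface area (um^2), calibrated so
#'   that a 9-um basal-cell footprint gives a median of ~30 founding basal
#'   stem cells.
#' @param rng_seed Integer seed; all generator output is a pure function of
#'   the configuration.
#' @return A list of class \code{simulation_config}.
#' @export
simulation_config <- function(n_patients = 50,
                              age_range = c(18, 88),
                              biopsies_per_patient = 2,
                              microbiopsies_per_biopsy = 5,
                              root_clones_mean = 2.2,
                              subclone_prob = 0.5,
                              mean_depth = 56,
                              age_effect = 14.6,
                              clock_age_effect = 0.65,
                              duration_effect_sbs15 = 0.16,
                              puva_extra_burden = 616,
                              psoralen_base_burden = 25,
                              puva_band_probs = c(0.5, 0.2, 0.15, 0.15),
                              apobec_fraction = 0.02,
                              burden_noise_sd = 150,
                              patient_sd = 100,
                              biopsy_sd = 50,
                              sbs15_patient_sd = 4,
                              sbs15_noise_sd = 6,
                              psoralen_patient_cv = 0.3,
                              psoralen_clone_cv = 0.2,
                              germline_rate = 0.05,
                              artifact_rate = 0.05,
                              detection_sensitivity = 0.89,
                              strand_asymmetry_tpa = 1.72,
                              leading_lagging_ratio = 1.09,
                              expression_effect = 0.5,
                              clone_spatial_scale = 500,
                              median_area = 30 * pi * 4.5^2,
                              rng_seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_patients >= 1, cfg$age_range[1] >= 0,
            cfg$mean_depth > 0, cfg$age_effect >= 0,
            cfg$germline_rate >= 0, cfg$germline_rate <= 1,
            cfg$artifact_rate >= 0, cfg$artifact_rate <= 1,
            cfg$detection_sensitivity > 0, cfg$detection_sensitivity <= 1,
            cfg$strand_asymmetry_tpa > 0, cfg$leading_lagging_ratio > 0,
            abs(sum(cfg$puva_band_probs) - 1) < 1e-8)
  class(cfg) <- "simulation_config"
  cfg
}

# Draw ref/alt/trinucleotide (reference-strand representation) for class
# indices into sbs_classes(); half are emitted as the purine representation.
.realize_classes <- function(idx) {
  cls <- sbs_classes()[idx]
  ref <- substr(cls, 3, 3); alt <- substr(cls, 5, 5)
  tri <- paste0(substr(cls, 1, 1), ref, substr(cls, 7, 7))
  flip <- stats::runif(length(idx)) < 0.5
  if (any(flip)) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    tri[flip] <- revcomp(tri[flip])
    ref[flip] <- unname(comp[ref[flip]])
    alt[flip] <- unname(comp[alt[flip]])
  }
  data.frame(ref = ref, alt = alt, trinucleotide = tri,
             stringsAsFactors = FALSE)
}

#' Simulate a synthetic microbiopsy cohort with ground truth
#'
#' Generates patients, spatially arranged microbiopsies, a nested clone
#' structure per biopsy (each root clone may carry one subclone, whose
#' cellular fraction never exceeds its parent's), and per-branch mutation
#' sets drawn from the four process spectra. Clone presence across
#' microbiopsies decays exponentially with the distance from the clone's
#' focal microbiopsy. Per-clone expected burden follows the linear model
#' \code{age_effect * age} (non-psoralen), with the clock-like component
#' \code{clock_age_effect * age + duration_effect_sbs15 * duration} and a
#' psoralen component set by the patient's PUVA band.
#'
#' @param config A [simulation_config()].
#' @return Object of class \code{cohort}: \code{patients},
#'   \code{microbiopsies}, \code{clones} (one row per tree branch, with
#'   parent and per-process mutation counts), \code{clone_cf} (long table
#'   of true cellular fractions per clone and microbiopsy),
#'   \code{mutations} (per-mutation truth: clone, process, position,
#'   context) and the \code{config}.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$rng_seed)
  catalog <- signature_catalog()
  bands <- c("0", "1-50", "51-200", ">200")
  band_means <- c(config$psoralen_base_burden,
                  config$psoralen_base_burden + 0.12 * config$puva_extra_burden,
                  config$psoralen_base_burden + 0.36 * config$puva_extra_burden,
                  config$psoralen_base_burden + config$puva_extra_burden)
  names(band_means) <- bands

  ages <- stats::runif(config$n_patients, config$age_range[1], config$age_range[2])
  durations <- stats::runif(config$n_patients, 0, pmin(40, ages - config$age_range[1]))
  patients <- patient_table(
    patient_id = sprintf("P%02d", seq_len(config$n_patients)),
    age = ages, disease_duration = durations,
    puva_cycles_band = sample(bands, config$n_patients, replace = TRUE,
                              prob = config$puva_band_probs),
    sex = sample(c("male", "female"), config$n_patients, replace = TRUE),
    uvb_history = stats::runif(config$n_patients) < 0.23)

  micro_list <- list(); clone_list <- list(); cf_list <- list()
  mut_list <- list()
  clone_counter <- 0L
  for (p in seq_len(config$n_patients)) {
    pid <- patients$patient_id[p]
    b_re_tot <- stats::rnorm(config$biopsies_per_patient, 0, config$biopsy_sd)
    p_re_tot <- stats::rnorm(1, 0, config$patient_sd)
    p_re_15 <- stats::rnorm(1, 0, config$sbs15_patient_sd)
    ps_mean_p <- stats::rgamma(1, shape = 1 / config$psoralen_patient_cv^2,
                               scale = band_means[as.character(patients$puva_cycles_band[p])] *
                                 config$psoralen_patient_cv^2)
    band <- as.character(patients$puva_cycles_band[p])
    for (b in seq_len(config$biopsies_per_patient)) {
      bid <- sprintf("%s_B%d", pid, b)
      nm <- config$microbiopsies_per_biopsy
      # microbiopsies scattered over a ~2 mm section
      mx <- stats::runif(nm, 0, 2000); my <- stats::runif(nm, 0, 2000)
      area <- config$median_area * exp(stats::rnorm(nm, 0, 0.4))
      micro <- microbiopsy_table(
        sample_id = sprintf("%s_M%d", bid, seq_len(nm)),
        patient_id = pid, biopsy_id = bid, lesional = (b == 1),
        site = sample(c("leg", "arm", "trunk"), 1),
        x = mx, y = my, volume = area * 50, area = area,
        mean_depth = config$mean_depth)
      micro_list[[length(micro_list) + 1L]] <- micro

      n_root <- 1L + stats::rpois(1, config$root_clones_mean - 1)
      focal <- sample.int(nm, n_root, replace = TRUE)
      # raw cellular fractions of root clones per microbiopsy
      cfm <- matrix(0, n_root, nm)
      for (k in seq_len(n_root)) {
        d <- sqrt((mx - mx[focal[k]])^2 + (my - my[focal[k]])^2)
        present <- stats::runif(nm) < exp(-d / config$clone_spatial_scale)
        present[focal[k]] <- TRUE
        # calibrated so the median VAF of called mutations sits near the
        # oligoclonal ~0.25 regime typical of epidermal microbiopsies
        cfm[k, present] <- stats::rbeta(sum(present), 2.5, 1.5)
      }
      tot <- colSums(cfm)
      over <- tot > 0.95
      if (any(over)) cfm[, over] <- sweep(cfm[, over, drop = FALSE], 2,
                                          0.95 / tot[over], "*")
      for (k in seq_len(n_root)) {
        has_sub <- stats::runif(1) < config$subclone_prob
        # clade (tip) burden from the linear burden model
        tip_np <- max(50, config$age_effect * ages[p] + p_re_tot +
                        b_re_tot[b] + stats::rnorm(1, 0, config$burden_noise_sd))
        tip_15 <- max(0, config$clock_age_effect * ages[p] +
                        config$duration_effect_sbs15 * durations[p] +
                        p_re_15 + stats::rnorm(1, 0, config$sbs15_noise_sd))
        tip_15 <- min(tip_15, 0.5 * tip_np)
        tip_ps <- stats::rgamma(1, shape = 1 / config$psoralen_clone_cv^2,
                                scale = ps_mean_p * config$psoralen_clone_cv^2)
        shares <- if (has_sub) {q <- stats::runif(1, 0.4, 0.8); c(q, 1 - q)} else 1
        parent_id <- NA_character_
        for (s in seq_along(shares)) {
          clone_counter <- clone_counter + 1L
          cl_id <- sprintf("clone%05d", clone_counter)
          n15 <- round(tip_15 * shares[s])
          nps <- round(tip_ps * shares[s])
          nuv_ap <- max(0, round(tip_np * shares[s])) - n15
          nap <- round(config$apobec_fraction * max(0, nuv_ap))
          nuv <- max(0, nuv_ap - nap)
          nin <- stats::rpois(1, 3)   # indel process, shared by all clones
          cf_here <- if (s == 1) cfm[k, ] else cfm[k, ] * stats::runif(1, 0.4, 0.9)
          clone_list[[length(clone_list) + 1L]] <- data.frame(
            clone_id = cl_id, patient_id = pid, biopsy_id = bid,
            parent = parent_id, is_tip = (s == length(shares)),
            n_uv = nuv, n_sbs15 = n15, n_apobec = nap, n_psoralen = nps,
            n_indel = nin, stringsAsFactors = FALSE)
          cf_list[[length(cf_list) + 1L]] <- data.frame(
            clone_id = cl_id, sample_id = micro$sample_id,
            cf = cf_here, stringsAsFactors = FALSE)
          n_sbs <- nuv + n15 + nap + nps
          proc <- rep(c("UV", "SBS1/5", "APOBEC", "psoralen"),
                      c(nuv, n15, nap, nps))
          if (n_sbs > 0) {
            idx <- c(
              sample.int(96, nuv, replace = TRUE, prob = catalog["UV", ]),
              sample.int(96, n15, replace = TRUE, prob = catalog["SBS1/5", ]),
              sample.int(96, nap, replace = TRUE, prob = catalog["APOBEC", ]),
              sample.int(96, nps, replace = TRUE, prob = catalog["psoralen", ]))
            alle <- .realize_classes(idx)
            mut_list[[length(mut_list) + 1L]] <- data.frame(
              patient_id = pid, clone_id = cl_id,
              chrom = sample(paste0("chr", 1:22), n_sbs, replace = TRUE),
              pos = sample.int(240000000L, n_sbs),
              ref = alle$ref, alt = alle$alt,
              trinucleotide = alle$trinucleotide,
              mut_class = "SBS", process = proc,
              is_germline = FALSE, is_artifact = FALSE,
              stringsAsFactors = FALSE)
          }
          if (nin > 0) {
            # one indel process for every clone: deletion-dominated and
            # A/T-rich, as in homopolymer-slippage indels
            ins <- stats::runif(nin) < 0.3
            rb <- sample(BASES, nin, replace = TRUE)
            ib <- sample(BASES, nin, replace = TRUE,
                         prob = c(0.3, 0.06, 0.04, 0.6))
            mut_list[[length(mut_list) + 1L]] <- data.frame(
              patient_id = pid, clone_id = cl_id,
              chrom = sample(paste0("chr", 1:22), nin, replace = TRUE),
              pos = sample.int(240000000L, nin),
              ref = ifelse(ins, rb, paste0(rb, ib)),
              alt = ifelse(ins, paste0(rb, ib), rb),
              trinucleotide = NA_character_,
              mut_class = "indel", process = "indel",
              is_germline = FALSE, is_artifact = FALSE,
              stringsAsFactors = FALSE)
          }
          parent_id <- cl_id
        }
      }
    }
  }
  mutations <- do.call(rbind, mut_list)
  mutations$mut_id <- sprintf("mut%07d", seq_len(nrow(mutations)))
  structure(list(patients = patients,
                 microbiopsies = do.call(rbind, micro_list),
                 clones = do.call(rbind, clone_list),
                 clone_cf = do.call(rbind, cf_list),
                 mutations = mutations,
                 config = config),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("cohort: %d patients, %d microbiopsies, %d clone branches, %d mutations\n",
              nrow(x$patients), nrow(x$microbiopsies), nrow(x$clones),
              nrow(x$mutations)))
  invisible(x)
}

#' Emit read counts for a patient's mutations
#'
#' Draws per-cell sequencing depths \code{Poisson(mean_depth)} and alt reads
#' \code{Binomial(depth, CF/2)} for every mutation carried by a clone
#' present in the microbiopsy (diploid, copy-neutral: a clone at cellular
#' fraction CF yields expected VAF CF/2), and 0 alt reads elsewhere. A
#' mutation on a branch is carried by all cells of its clade, so the
#' cellular fraction used is that of the branch's own clone.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param patient_id One patient id; if NULL, all patients are emitted as a
#'   named list.
#' @param mean_depth Mean depth; defaults to the cohort configuration.
#' @return A [count_matrix()] (or a named list of them).
#' @export
emit_reads <- function(cohort, patient_id = NULL, mean_depth = NULL) {
  if (is.null(mean_depth)) mean_depth <- cohort$config$mean_depth
  if (is.null(patient_id)) {
    out <- lapply(cohort$patients$patient_id, function(p)
      emit_reads(cohort, p, mean_depth))
    names(out) <- cohort$patients$patient_id
    return(out)
  }
  micro <- cohort$microbiopsies[cohort$microbiopsies$patient_id == patient_id, ]
  muts <- cohort$mutations[cohort$mutations$patient_id == patient_id, ]
  cfs <- cohort$clone_cf[cohort$clone_cf$clone_id %in% muts$clone_id, ]
  cf_mat <- matrix(0, nrow(muts), nrow(micro),
                   dimnames = list(muts$mut_id, micro$sample_id))
  cf_by_clone <- split(cfs, cfs$clone_id)
  for (cl in names(cf_by_clone)) {
    rows <- which(muts$clone_id == cl)
    cc <- cf_by_clone[[cl]]
    j <- match(cc$sample_id, micro$sample_id)
    ok <- !is.na(j)
    cf_mat[rows, j[ok]] <- matrix(cc$cf[ok], length(rows), sum(ok), byrow = TRUE)
  }
  n <- length(cf_mat)
  depth <- matrix(stats::rpois(n, mean_depth), nrow(muts), ncol(cf_mat))
  alt <- matrix(stats::rbinom(n, as.vector(depth), as.vector(cf_mat) / 2),
                nrow(muts), ncol(cf_mat))
  colnames(alt) <- colnames(depth) <- micro$sample_id
  count_matrix(muts, alt, depth)
}

#' Spike germline and artifact contaminants into a count matrix
#'
#' Germline spikes are heterozygous variants present in every sample of the
#' patient at binomial success probability 0.5 (0.95 on sex chromosomes in
#' men, mimicking hemizygous X variants with residual mismapping). Artifact
#' spikes mimic recurrent sequencing errors: a single low success
#' probability shared by all samples (true overdispersion ~ 0).
#'
#' @param mat A [count_matrix()] for one patient.
#' @param germline_rate,artifact_rate Number of spiked rows per existing
#'   row; 0 leaves the matrix unchanged.
#' @param sex Patient sex; \code{"male"} places a fraction of germline
#'   spikes on chrX at p = 0.95.
#' @param mean_depth Mean depth for the spiked rows.
#' @return A new \code{count_matrix}; spiked rows carry
#'   \code{is_germline}/\code{is_artifact} = TRUE in \code{$mutations}.
#' @export
spike_contaminants <- function(mat, germline_rate = 0.05, artifact_rate = 0.05,
                               sex = "female", mean_depth = 56) {
  stopifnot(germline_rate >= 0, germline_rate <= 1,
            artifact_rate >= 0, artifact_rate <= 1)
  n0 <- nrow(mat$alt); ns <- ncol(mat$alt)
  ng <- round(germline_rate * n0); na <- round(artifact_rate * n0)
  if (ng + na == 0) return(mat)
  new_rows <- function(n, kind) {
    if (n == 0) return(NULL)
    on_x <- if (kind == "germline" && sex == "male")
      stats::runif(n) < 0.05 else rep(FALSE, n)
    base <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
    alt_b <- vapply(base, function(b) sample(setdiff(BASES, b), 1), "")
    df <- data.frame(
      patient_id = mat$mutations$patient_id[1] %||% NA_character_,
      clone_id = NA_character_,
      chrom = ifelse(on_x, "chrX", sample(paste0("chr", 1:22), n, replace = TRUE)),
      pos = sample.int(240000000L, n), ref = base, alt = alt_b,
      trinucleotide = NA_character_, mut_class = "SBS", process = kind,
      is_germline = kind == "germline", is_artifact = kind == "artifact",
      stringsAsFactors = FALSE)
    depth <- matrix(stats::rpois(n * ns, mean_depth), n, ns)
    p <- if (kind == "germline") ifelse(on_x, 0.95, 0.5)
         else stats::runif(n, 0.005, 0.03)
    altm <- matrix(stats::rbinom(n * ns, as.vector(depth),
                                 rep(p, ns)), n, ns)
    list(df = df, alt = altm, depth = depth)
  }
  g <- new_rows(ng, "germline"); a <- new_rows(na, "artifact")
  muts <- mat$mutations
  for (col in c("patient_id", "clone_id", "trinucleotide", "process")) {
    if (is.null(muts[[col]])) muts[[col]] <- NA_character_
  }
  if (is.null(muts$is_germline)) muts$is_germline <- FALSE
  if (is.null(muts$is_artifact)) muts$is_artifact <- FALSE
  common <- c("patient_id", "clone_id", "chrom", "pos", "ref", "alt",
              "trinucleotide", "mut_class", "process", "is_germline",
              "is_artifact")
  if (is.null(muts$mut_class)) muts$mut_class <- mutation_class(muts$ref, muts$alt)
  muts2 <- rbind(muts[, common], if (!is.null(g)) g$df[, common],
                 if (!is.null(a)) a$df[, common])
  alt2 <- rbind(mat$alt, if (!is.null(g)) g$alt, if (!is.null(a)) a$alt)
  dep2 <- rbind(mat$depth, if (!is.null(g)) g$depth, if (!is.null(a)) a$depth)
  colnames(alt2) <- colnames(dep2) <- mat$samples
  muts2$mut_id <- c(mat$mutations$mut_id %||% sprintf("mut%07d", seq_len(n0)),
                    sprintf("spike%05d", seq_len(ng + na)))
  count_matrix(muts2, alt2, dep2)
}

#' Simulate near-replicate dissection pairs
#'
#' Each pair shares one true mutation set; every mutation enters each
#' member's call set independently with probability
#' \code{detection_sensitivity}, emulating two independent dissections and
#' sequencing runs of the same histological feature.
#'
#' @param n_pairs Number of replicate pairs.
#' @param n_mutations True mutations per pair (Poisson mean).
#' @param detection_sensitivity Per-dissection call probability in (0, 1].
#' @return List of pairs, each with character call sets \code{a} and
#'   \code{b} and the true set \code{truth}.
#' @export
simulate_replicate_pairs <- function(n_pairs = 18, n_mutations = 400,
                                     detection_sensitivity = 0.89) {
  stopifnot(detection_sensitivity > 0, detection_sensitivity <= 1)
  if (n_pairs == 0) return(list())
  lapply(seq_len(n_pairs), function(i) {
    n <- stats::rpois(1, n_mutations)
    ids <- sprintf("pair%02d_m%04d", i, seq_len(n))
    list(a = ids[stats::runif(n) < detection_sensitivity],
         b = ids[stats::runif(n) < detection_sensitivity],
         truth = ids)
  })
}

#' Toy gene annotation for strand analyses
#'
#' Builds a synthetic annotation track: genes with strand, TSS, a 10-kb
#' transcript, a log-normal expression value and a replication-timing
#' value in \[0, 1\] (1 = late). Also records the background
#' pentanucleotide weights used when placing TpA mutations.
#'
#' @param n_genes Number of genes.
#' @param tx_length Transcript length (bp).
#' @param seed Optional seed.
#' @return List of class \code{annotation_track} with \code{genes} and
#'   \code{penta_background}.
#' @export
toy_annotation <- function(n_genes = 1000, tx_length = 10000, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n_genes)),
    chrom = sample(paste0("chr", 1:22), n_genes, replace = TRUE),
    tss = sample.int(200000000L, n_genes),
    strand = sample(c("+", "-"), n_genes, replace = TRUE),
    tx_length = tx_length,
    expression = exp(stats::rnorm(n_genes, 2, 1.5)),
    rep_timing = stats::runif(n_genes),
    stringsAsFactors = FALSE)
  # genomic background weights of the (p1, p2, p5) flank combinations
  # around the mutated TpA core (p1 p2 T A p5); uniform toy genome
  flanks <- expand.grid(p1 = BASES, p2 = BASES, p5 = BASES,
                        stringsAsFactors = FALSE)
  structure(list(genes = genes,
                 penta_background = data.frame(flanks, weight = 1 / 64)),
            class = "annotation_track")
}

#' Simulate genic TpA mutations with strand and replication structure
#'
#' Places TpA-site T mutations in 20-kb windows around gene TSSs
#' (10 kb upstream, 10 kb of transcript). Inside the transcript the
#' untranscribed:transcribed strand ratio equals
#' \code{strand_asymmetry_tpa}, with the per-strand rates scaled by
#' \code{tc_net} (net transcription effect on the summed rate: < 1 means
#' repair outweighs damage). Gene choice is weighted down with expression
#' (\code{exp(-expression_effect * rank)}), up with late replication
#' timing, and the mutated-T strand carries a leading:lagging weight of
#' \code{leading_lagging_ratio}. Pentanucleotide contexts enrich the ATAT
#' double palindrome by \code{atat_enrichment}.
#'
#' @param annotation A [toy_annotation()].
#' @param n Number of mutations; \code{n <= 0} returns an empty frame.
#' @param strand_asymmetry_tpa Untranscribed:transcribed ratio in
#'   transcripts.
#' @param expression_effect Log-rate decline over the expression range.
#' @param leading_lagging_ratio Leading:lagging weight on the mutated-T
#'   strand.
#' @param timing_effect Log-rate increase from earliest to latest
#'   replication timing.
#' @param tc_net Net transcription scaling of the within-transcript rate.
#' @param atat_enrichment Weight multiplier for ATAT-containing
#'   pentanucleotides.
#' @param psoralen_weights Substitution-type weights passed to the psoralen
#'   spectrum.
#' @return Data frame of mutations with truth labels: \code{gene_id},
#'   position \code{offset} relative to TSS (transcript direction),
#'   \code{region} (upstream/genic), \code{strand_class}
#'   (transcribed/untranscribed, NA upstream), \code{rep_strand}
#'   (leading/lagging), \code{rep_timing}, \code{expression}, genomic
#'   \code{ref}/\code{alt}/\code{trinucleotide}/\code{pentanucleotide}.
#' @export
simulate_genic_mutations <- function(annotation, n,
                                     strand_asymmetry_tpa = 1.72,
                                     expression_effect = 0.5,
                                     leading_lagging_ratio = 1.09,
                                     timing_effect = 0.3,
                                     tc_net = 0.89,
                                     atat_enrichment = 3,
                                     psoralen_weights = c("T>A" = 0.5, "T>C" = 0.3,
                                                          "T>G" = 0.2)) {
  if (n <= 0) {
    return(data.frame(gene_id = character(0)))
  }
  g <- annotation$genes
  stopifnot(length(unique(g$expression)) >= 2)
  expr_rank <- (rank(g$expression) - 1) / (nrow(g) - 1)
  w_gene <- exp(-expression_effect * expr_rank + timing_effect * g$rep_timing)
  gi <- sample.int(nrow(g), n, replace = TRUE, prob = w_gene)
  offset <- round(stats::runif(n, -10000, pmin(g$tx_length[gi], 10000)))
  genic <- offset >= 0
  a <- strand_asymmetry_tpa; r <- leading_lagging_ratio
  # per-strand weights on the genomic strand carrying the mutated T
  # untranscribed strand = the gene (coding) strand
  w_plus <- w_minus <- rep(1, n)
  gene_plus <- g$strand[gi] == "+"
  u <- 2 * tc_net * a / (1 + a); tr <- 2 * tc_net / (1 + a)
  w_plus[genic & gene_plus] <- u;  w_minus[genic & gene_plus] <- tr
  w_plus[genic & !gene_plus] <- tr; w_minus[genic & !gene_plus] <- u
  t_on_plus <- stats::runif(n) < w_plus / (w_plus + w_minus)
  strand_class <- rep(NA_character_, n)
  strand_class[genic] <- ifelse(t_on_plus[genic] == gene_plus[genic],
                                "untranscribed", "transcribed")
  # replication origins fire within as well as between genes, so the
  # mutated-T replication strand is drawn independently of transcription
  rep_strand <- ifelse(stats::runif(n) < r / (1 + r), "leading", "lagging")
  # substitution type and contexts (mutated T, 3' A)
  types <- sample(names(psoralen_weights), n, replace = TRUE,
                  prob = psoralen_weights / sum(psoralen_weights))
  alt_py <- substr(types, 3, 3)
  # pentamer p1 p2 T A p5 contains the ATAT palindrome iff p2 == "A" and
  # p5 == "T"; such flank combinations get an enrichment weight
  flank_grid <- expand.grid(p1 = BASES, p2 = BASES, p5 = BASES,
                            stringsAsFactors = FALSE)
  wgrid <- ifelse(flank_grid$p2 == "A" & flank_grid$p5 == "T",
                  atat_enrichment, 1)
  fi <- sample.int(nrow(flank_grid), n, replace = TRUE, prob = wgrid)
  p1 <- flank_grid$p1[fi]; p2 <- flank_grid$p2[fi]; p5 <- flank_grid$p5[fi]
  penta_t <- paste0(p1, p2, "T", "A", p5)  # on the mutated-T strand
  tri_t <- substr(penta_t, 2, 4)
  ref <- ifelse(t_on_plus, "T", "A")
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  alt_out <- ifelse(t_on_plus, alt_py, unname(comp[alt_py]))
  tri <- ifelse(t_on_plus, tri_t, revcomp(tri_t))
  penta <- ifelse(t_on_plus, penta_t, revcomp(penta_t))
  pos <- ifelse(g$strand[gi] == "+", g$tss[gi] + offset, g$tss[gi] - offset)
  data.frame(gene_id = g$gene_id[gi], chrom = g$chrom[gi], pos = pos,
             offset = offset, region = ifelse(genic, "genic", "upstream"),
             gene_strand = g$strand[gi], strand_class = strand_class,
             rep_strand = rep_strand, rep_timing = g$rep_timing[gi],
             expression = g$expression[gi],
             ref = ref, alt = alt_out, trinucleotide = tri,
             pentanucleotide = penta, mut_class = "SBS",
             stringsAsFactors = FALSE)
}

#' Simulate clone-level burden records from the mixed-model generative
#' process
#'
#' Draws clone burden components directly from the linear mixed model the
#' burden analyses assume: nested patient and biopsy random intercepts plus
#' clone-level residual noise around fixed effects of age (total
#' non-psoralen and clock-like responses), disease duration (clock-like)
#' and PUVA band (psoralen). Optionally realizes each clone's 96-class
#' spectrum by multinomial sampling from the process signatures, for use
#' with [fit_exposures()].
#'
#' @param config A [simulation_config()]; effect sizes and noise SDs are
#'   taken from it.
#' @param n_patients,clones_per_patient,biopsies_per_patient Cohort shape.
#' @param spectra Also return the clone x 96 spectrum matrix?
#' @param seed Optional seed.
#' @return List with \code{records} (one row per clone: covariates and true
#'   component burdens) and, if requested, \code{spectra}.
#' @export
simulate_burden_records <- function(config = simulation_config(),
                                    n_patients = 100,
                                    clones_per_patient = 5,
                                    biopsies_per_patient = 2,
                                    spectra = FALSE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  bands <- c("0", "1-50", "51-200", ">200")
  band_means <- c(config$psoralen_base_burden,
                  config$psoralen_base_burden + 0.12 * config$puva_extra_burden,
                  config$psoralen_base_burden + 0.36 * config$puva_extra_burden,
                  config$psoralen_base_burden + config$puva_extra_burden)
  names(band_means) <- bands
  age <- stats::runif(n_patients, config$age_range[1], config$age_range[2])
  duration <- stats::runif(n_patients, 0, pmin(40, age - config$age_range[1]))
  band <- sample(bands, n_patients, replace = TRUE, prob = config$puva_band_probs)
  site <- sample(c("leg", "arm", "trunk"), n_patients, replace = TRUE)
  rows <- list()
  for (p in seq_len(n_patients)) {
    pre_t <- stats::rnorm(1, 0, config$patient_sd)
    pre_15 <- stats::rnorm(1, 0, config$sbs15_patient_sd)
    ps_mean_p <- stats::rgamma(1, shape = 1 / config$psoralen_patient_cv^2,
                               scale = band_means[band[p]] *
                                 config$psoralen_patient_cv^2)
    bre_t <- stats::rnorm(biopsies_per_patient, 0, config$biopsy_sd)
    bix <- rep_len(seq_len(biopsies_per_patient), clones_per_patient)
    for (k in seq_len(clones_per_patient)) {
      tot <- max(20, config$age_effect * age[p] + pre_t + bre_t[bix[k]] +
                   stats::rnorm(1, 0, config$burden_noise_sd))
      s15 <- max(0, config$clock_age_effect * age[p] +
                   config$duration_effect_sbs15 * duration[p] + pre_15 +
                   stats::rnorm(1, 0, config$sbs15_noise_sd))
      s15 <- min(s15, 0.5 * tot)
      ps <- stats::rgamma(1, shape = 1 / config$psoralen_clone_cv^2,
                          scale = ps_mean_p * config$psoralen_clone_cv^2)
      rows[[length(rows) + 1L]] <- data.frame(
        patient_id = sprintf("P%03d", p),
        biopsy_id = sprintf("P%03d_B%d", p, bix[k]),
        clone_id = sprintf("P%03d_C%d", p, k),
        age = age[p], duration = duration[p],
        puva_cycles_band = band[p], site = site[p],
        burden_nonpsoralen = tot, burden_sbs15 = s15, burden_psoralen = ps,
        stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  records$puva_cycles_band <- factor(records$puva_cycles_band, levels = bands,
                                     ordered = TRUE)
  out <- list(records = records)
  if (spectra) {
    catalog <- signature_catalog()
    sp <- matrix(0L, nrow(records), 96,
                 dimnames = list(records$clone_id, sbs_classes()))
    nuv <- pmax(0, round(records$burden_nonpsoralen - records$burden_sbs15))
    nap <- round(config$apobec_fraction * nuv)
    nuv <- nuv - nap
    n15 <- round(records$burden_sbs15)
    nps <- round(records$burden_psoralen)
    for (i in seq_len(nrow(records))) {
      sp[i, ] <- stats::rmultinom(1, nuv[i], catalog["UV", ]) +
        stats::rmultinom(1, n15[i], catalog["SBS1/5", ]) +
        stats::rmultinom(1, nap[i], catalog["APOBEC", ]) +
        stats::rmultinom(1, nps[i], catalog["psoralen", ])
    }
    out$spectra <- sp
  }
  out
}
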