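# Transcription- and replication-linked asymmetries of TpA mutagenesis.
# Strand conventions: the transcribed strand is the template strand (the
# complement of the gene/coding strand); a mutated T lies on the
# untranscribed strand when the T's strand equals the gene strand.

# strand of the mutated T relative to the gene: needs genomic ref base
# (T => plus strand, A => minus strand) and the gene strand
.t_strand_class <- function(ref, gene_strand) {
  t_on_plus <- ref == "T"
  ifelse(is.na(gene_strand), NA_character_,
         ifelse((t_on_plus & gene_strand == "+") |
                  (!t_on_plus & gene_strand == "-"),
                "untranscribed", "transcribed"))
}

#' Transcriptional strand asymmetry of genic TpA mutations
#'
#' Computes the untranscribed:transcribed ratio of TpA-site T mutations
#' inside transcripts, with an exact binomial test against strand
#' symmetry.
#'
#' @param mutations Data frame of TpA mutations; either a
#'   \code{strand_class} column or \code{ref} plus \code{gene_strand}
#'   must be present. If a \code{region} column exists, only
#'   \code{"genic"} rows are used.
#' @return List: \code{ratio} (untranscribed / transcribed; Inf flagged
#'   \code{degenerate} when one strand has no mutations),
#'   \code{n_untranscribed}, \code{n_transcribed}, \code{p_value},
#'   \code{degenerate}.
#' @export
strand_asymmetry <- function(mutations) {
  m <- mutations
  if (!is.null(m$region)) m <- m[m$region == "genic", , drop = FALSE]
  sc <- m$strand_class %||% .t_strand_class(m$ref, m$gene_strand)
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0) {
    return(list(ratio = NA_real_, n_untranscribed = 0L, n_transcribed = 0L,
                p_value = NA_real_, degenerate = TRUE))
  }
  nu <- sum(sc == "untranscribed"); nt <- sum(sc == "transcribed")
  degenerate <- nu == 0 || nt == 0
  list(ratio = if (nt == 0) Inf else nu / nt,
       n_untranscribed = nu, n_transcribed = nt,
       p_value = stats::binom.test(nu, nu + nt, 0.5)$p.value,
       degenerate = degenerate)
}

#' TSS-centred strand-resolved mutation profile with TCD/TCR tests
#'
#' Bins TpA mutations into twenty 1-kb windows from -10 kb to +10 kb
#' around the TSS (transcript direction), per strand and per expression
#' quintile, and reports rates relative to the -10 kb bin (the intergenic
#' bin furthest from the TSS). Transcription-coupled damage (TCD) is
#' tested by a likelihood-ratio test between linear models of the
#' untranscribed-strand per-bin counts with and without an indicator for
#' being downstream of the TSS; the analogous test on the transcribed
#' strand measures transcription-coupled repair (TCR).
#'
#' @param mutations Data frame with \code{offset} (bp relative to TSS,
#'   transcript direction), \code{strand_class}, \code{expression} (or
#'   \code{gene_id} joined against \code{annotation}).
#' @param annotation Optional [toy_annotation()] used to quintile genes
#'   when \code{mutations$expression} is absent.
#' @param n_quantiles Number of expression bins (default 5).
#' @return List: \code{profile} (bin x strand x quintile counts and
#'   relative rates, long format), \code{tcd_p}, \code{tcr_p}.
#' @export
tss_profile <- function(mutations, annotation = NULL, n_quantiles = 5) {
  m <- mutations
  if (is.null(m$expression) && !is.null(annotation)) {
    m$expression <- annotation$genes$expression[
      match(m$gene_id, annotation$genes$gene_id)]
  }
  m <- m[!is.na(m$strand_class) | m$offset < 0, , drop = FALSE]
  m <- m[abs(m$offset) <= 10000 & m$offset < 10000, , drop = FALSE]
  m$bin <- floor(m$offset / 1000)                      # -10 .. 9
  qs <- stats::quantile(m$expression, probs = seq(0, 1, length.out = n_quantiles + 1),
                        na.rm = TRUE)
  qs[1] <- -Inf; qs[length(qs)] <- Inf
  m$quintile <- cut(m$expression, qs, labels = FALSE)
  # upstream of the TSS there is no transcription, but the profile still
  # tracks the two strands using the same gene-relative convention
  fallback <- if (!is.null(m$gene_strand))
    .t_strand_class(m$ref, m$gene_strand)
  else ifelse(m$ref == "T", "untranscribed", "transcribed")
  m$strand_use <- ifelse(is.na(m$strand_class), fallback, m$strand_class)
  bins <- -10:9
  rows <- list()
  for (q in seq_len(n_quantiles)) {
    if (!any(m$quintile == q, na.rm = TRUE)) {
      warning("expression bin ", q, " contains no mutations; skipped")
      next
    }
    for (s in c("untranscribed", "transcribed")) {
      cnt <- table(factor(m$bin[m$quintile == q & m$strand_use == s],
                          levels = bins))
      ref_count <- max(1L, cnt[["-10"]])
      rows[[length(rows) + 1L]] <- data.frame(
        quintile = q, strand = s, bin = bins,
        count = as.integer(cnt),
        rate_rel = as.integer(cnt) / ref_count)
    }
  }
  profile <- do.call(rbind, rows)
  lrt_strand <- function(s) {
    d <- stats::aggregate(count ~ bin, data = profile[profile$strand == s, ], sum)
    d$downstream <- d$bin >= 0
    full <- stats::lm(count ~ downstream, data = d)
    red <- stats::lm(count ~ 1, data = d)
    stat <- 2 * (stats::logLik(full) - stats::logLik(red))
    stats::pchisq(as.numeric(stat), df = 1, lower.tail = FALSE)
  }
  list(profile = profile,
       tcd_p = lrt_strand("untranscribed"),
       tcr_p = lrt_strand("transcribed"))
}

#' Relative mutation rates across expression deciles
#'
#' Splits genes into ten equally sized bins by ascending expression and
#' computes the per-bp genic mutation rate in each, relative to the
#' lowest-expression decile.
#'
#' @param mutations Data frame with \code{gene_id} and (optionally)
#'   \code{region}; only genic rows are counted.
#' @param annotation A [toy_annotation()] providing expression and
#'   transcript lengths.
#' @return Data frame: decile, n_genes, total bp, count, rate,
#'   \code{rate_rel} (decile 1 = 1).
#' @export
expression_decile_rates <- function(mutations, annotation) {
  g <- annotation$genes
  m <- mutations
  if (!is.null(m$region)) m <- m[m$region == "genic", , drop = FALSE]
  ord <- order(g$expression)
  decile <- integer(nrow(g))
  decile[ord] <- ceiling(seq_along(ord) / (length(ord) / 10))
  decile <- pmin(decile, 10L)
  g$decile <- decile
  bp <- tapply(g$tx_length, g$decile, sum)
  if (any(bp == 0)) stop("expression decile with zero total length")
  cnt <- table(factor(g$decile[match(m$gene_id, g$gene_id)], levels = 1:10))
  rate <- as.numeric(cnt) / as.numeric(bp)
  data.frame(decile = 1:10, n_genes = as.integer(table(factor(g$decile, levels = 1:10))),
             bp = as.numeric(bp), count = as.integer(cnt), rate = rate,
             rate_rel = rate / rate[1])
}

#' Replication-strand and replication-timing effects
#'
#' Computes the leading:lagging ratio of mutated-T strand assignments and
#' per-timing-bin relative mutation rates (early to late).
#'
#' @param mutations Data frame with \code{rep_strand} in
#'   \code{c("leading", "lagging")} and \code{rep_timing} in \[0, 1\]
#'   (1 = latest); NULL/absent columns give an explicit unavailable
#'   result.
#' @param annotation Optional [toy_annotation()] used to normalize timing
#'   bins by the gene weight in each bin.
#' @param n_timing_bins Number of timing bins.
#' @return List: \code{ratio}, \code{percent_excess} (leading over
#'   lagging, percent), \code{ci} (95\% on the ratio), \code{p_value},
#'   \code{timing} (per-bin counts and relative rate), or
#'   \code{available = FALSE}.
#' @export
replication_effects <- function(mutations, annotation = NULL,
                                n_timing_bins = 5) {
  if (is.null(mutations$rep_strand)) {
    return(list(available = FALSE))
  }
  rs <- mutations$rep_strand[!is.na(mutations$rep_strand)]
  nl <- sum(rs == "leading"); ng <- sum(rs == "lagging")
  bt <- stats::binom.test(nl, nl + ng, 0.5)
  ratio <- nl / ng
  timing <- NULL
  if (!is.null(mutations$rep_timing)) {
    brk <- seq(0, 1, length.out = n_timing_bins + 1)
    bin <- cut(mutations$rep_timing, brk, include.lowest = TRUE, labels = FALSE)
    cnt <- table(factor(bin, levels = seq_len(n_timing_bins)))
    w <- rep(1, n_timing_bins)
    if (!is.null(annotation)) {
      gbin <- cut(annotation$genes$rep_timing, brk, include.lowest = TRUE,
                  labels = FALSE)
      w <- as.numeric(table(factor(gbin, levels = seq_len(n_timing_bins))))
      w <- pmax(w, 1)
    }
    rate <- as.numeric(cnt) / w
    timing <- data.frame(bin = seq_len(n_timing_bins),
                         midpoint = (brk[-1] + brk[-length(brk)]) / 2,
                         count = as.integer(cnt),
                         rate_rel = rate / rate[1])
  }
  list(available = TRUE, ratio = ratio,
       percent_excess = 100 * (ratio - 1),
       ci = bt$conf.int / (1 - bt$conf.int),
       p_value = bt$p.value, n_leading = nl, n_lagging = ng,
       timing = timing)
}

#' Pentanucleotide context enrichment of TpA mutations
#'
#' Normalizes observed 5-mer mutation counts by background 5-mer weights
#' and ranks the contexts; the ApTpApT double palindrome is expected to
#' top the ranking under psoralen mutagenesis.
#'
#' @param mutations Data frame with a \code{pentanucleotide} column
#'   (5-mer centred on the mutated T, mutated-T strand or genomic strand;
#'   normalized internally to the mutated-T representation).
#' @param background Data frame with columns \code{p1}, \code{p2},
#'   \code{p5} (flanks around the TpA core) and \code{weight}, or NULL
#'   for a uniform background.
#' @return Data frame ranked by normalized rate: \code{pentamer},
#'   \code{count}, \code{background}, \code{rate_norm}, \code{contains_atat}.
#' @export
pentanucleotide_enrichment <- function(mutations, background = NULL) {
  p <- mutations$pentanucleotide
  if (is.null(p)) stop("pentanucleotide contexts absent")
  p <- toupper(p[!is.na(p)])
  # normalize to the representation with the mutated T at the centre
  flip <- substr(p, 3, 3) != "T"
  p[flip] <- revcomp(p[flip])
  cnt <- table(p)
  if (is.null(background)) {
    bg <- stats::setNames(rep(1 / length(cnt), length(cnt)), names(cnt))
  } else {
    key <- paste0(background$p1, background$p2, "TA", background$p5)
    bg <- stats::setNames(background$weight, key)
    bg <- bg[names(cnt)]
    bg[is.na(bg)] <- min(background$weight)
  }
  out <- data.frame(pentamer = names(cnt), count = as.integer(cnt),
                    background = as.numeric(bg),
                    rate_norm = as.integer(cnt) / as.numeric(bg),
                    stringsAsFactors = FALSE)
  out$contains_atat <- grepl("ATAT", out$pentamer) |
    grepl("ATAT", revcomp(out$pentamer))
  out[order(-out$rate_norm), ]
}
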