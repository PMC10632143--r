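test_that("96-class spectra count correctly and report exclusions", {
  m <- data.frame(ref = c("C", "G", "T"), alt = c("T", "A", "A"),
                  trinucleotide = c("ACA", "TGA", NA))
  sp <- spectrum_96(m)
  expect_equal(sum(sp), 2)
  expect_equal(unname(sp["A[C>T]A"]), 1)
  # G>A at TGA is C>T at TCA on the other strand
  expect_equal(unname(sp["T[C>T]A"]), 1)
  expect_equal(attr(sp, "n_excluded"), 1)
})

test_that("sampling from a catalog spectrum reproduces it", {
  set.seed(10)
  cat96 <- signature_catalog()
  idx <- sample.int(96, 10000, replace = TRUE, prob = cat96["UV", ])
  sp <- spectrum_96(sbs_classes()[idx])
  expect_gte(cosine_similarity(as.numeric(sp), cat96["UV", ]), 0.99)
})

test_that("psoralen reference confines mass to mutated T with 3' A", {
  v <- psoralen_reference()
  expect_equal(sum(v), 1)
  cls <- sbs_classes()
  on_target <- substr(cls, 3, 3) == "T" & substr(cls, 7, 7) == "A"
  expect_true(all(v[!on_target] == 0))
  expect_equal(sum(v > 0), 12)
  # T>A carries the largest share by default
  byt <- tapply(v, substr(cls, 3, 5), sum)
  expect_gt(byt[["T>A"]], byt[["T>C"]])
})

test_that("catalog rows are proper distributions", {
  cat96 <- signature_catalog()
  expect_equal(unname(rowSums(cat96)), rep(1, 4))
  expect_true(all(cat96 >= 0))
  expect_error(signature_catalog("SBS99"), "unknown")
})

test_that("exposure fitting is identifiable at a catalog vertex", {
  cat96 <- signature_catalog()
  sp <- cat96["psoralen", ] * 500
  fit <- fit_exposures(sp, cat96)
  expect_equal(unname(fit$exposure["psoralen"]), 500, tolerance = 0.02)
  expect_lt(sum(fit$exposure[names(fit$exposure) != "psoralen"]), 10)
  # conservation
  expect_equal(sum(fit$exposure) + fit$unassigned, sum(sp))
})

test_that("EM recovers a 50/50 two-signature mixture", {
  set.seed(12)
  cat96 <- signature_catalog()
  sp <- rmultinom(1, 2000, 0.5 * cat96["UV", ] + 0.5 * cat96["psoralen", ])[, 1]
  fit <- fit_exposures(sp, cat96)
  expect_lt(abs(fit$exposure[["UV"]] - 1000), 100)
  expect_lt(abs(fit$exposure[["psoralen"]] - 1000), 100)
})

test_that("attribution is scale-equivariant and handles zero spectra", {
  cat96 <- signature_catalog()
  set.seed(13)
  sp <- rmultinom(1, 800, 0.7 * cat96["UV", ] + 0.3 * cat96["SBS1/5", ])[, 1]
  f1 <- fit_exposures(sp, cat96)
  f2 <- fit_exposures(2 * sp, cat96)
  expect_equal(f2$exposure, 2 * f1$exposure, tolerance = 1e-4)
  f0 <- fit_exposures(rep(0, 96), cat96)
  expect_equal(sum(f0$exposure), 0)
})

test_that("EM matches a brute-force ML grid on a 3-signature catalog", {
  set.seed(14)
  cat3 <- signature_catalog(c("UV", "SBS1/5", "psoralen"))
  sp <- rmultinom(1, 50, 0.5 * cat3[1, ] + 0.3 * cat3[2, ] + 0.2 * cat3[3, ])[, 1]
  fit <- fit_exposures(sp, cat3)
  # oracle: dense grid over the simplex
  S <- pmax(cat3, 1e-12)
  best <- -Inf; best_w <- NULL
  gr <- seq(0, 1, by = 0.02)
  for (w1 in gr) for (w2 in gr) {
    if (w1 + w2 > 1) next
    w <- c(w1, w2, 1 - w1 - w2)
    ll <- sum(sp * log(crossprod(S, w)))
    if (ll > best) { best <- ll; best_w <- w }
  }
  expect_true(all(abs(fit$weights - best_w) < 0.025))
  expect_gte(fit$loglik, best - 1e-6)
})

test_that("indel spectra are process-invariant across psoralen burden groups", {
  # the generator uses a single indel process, so indel spectra from
  # high- and low-psoralen clones are near-identical
  co <- simulate_cohort(simulation_config(n_patients = 40, rng_seed = 31))
  med <- stats::median(co$clones$n_psoralen)
  hi <- co$clones$clone_id[co$clones$n_psoralen > med]
  lo <- co$clones$clone_id[co$clones$n_psoralen <= med]
  ind <- co$mutations[co$mutations$mut_class == "indel", ]
  # 8-channel indel spectrum: insertion/deletion x changed base
  cls <- function(ids) {
    x <- ind[ind$clone_id %in% ids, ]
    del <- nchar(x$ref) > nchar(x$alt)
    base <- ifelse(del, substr(x$ref, 2, 2), substr(x$alt, 2, 2))
    as.numeric(table(factor(paste0(ifelse(del, "del", "ins"), base),
                            levels = paste0(rep(c("del", "ins"), each = 4),
                                            c("A", "C", "G", "T")))))
  }
  expect_gt(cosine_similarity(cls(hi), cls(lo)), 0.99)
})

test_that("damage potential is exact on a hand-enumerable toy gene", {
  # gene ATG GAT TAA has, excluding the unflanked first and last base,
  # 7 enumerable positions x 3 alts
  gene <- list(name = "toy", cds = "ATGGATTAA")
  unif <- damage_potential(rep(1 / 96, 96), list(gene))
  # ratios are 1 wherever the class occurs at all in the gene set
  defined <- unif$expected_baseline > 0
  expect_equal(unif$ratio[defined], rep(1, sum(defined)))
  # a gene set with all four classes populated
  unif2 <- damage_potential(rep(1 / 96, 96), toy_gene_models(2, 40))
  expect_equal(unif2$ratio, rep(1, 4))
  # hand count of consequences for the 21 substitutions
  # pos2 T>(ACG): ATG start codon -> all missense (A/C/G at codon pos 2)
  # pos3 G>(ACT): codon ATG pos 3 -> ATA/ATC/ATT all I: missense (M->I)
  # pos4 G>(ACT): GAT pos1 -> AAT N, CAT H, TAT Y: missense x3
  # pos5 A>(CGT): GAT pos2 -> GCT A, GGT G, GTT V: missense x3
  # pos6 T>(ACG): GAT pos3 -> GAA E, GAC D(syn), GAG E: 1 syn, 2 missense
  # pos7 T>(ACG): TAA pos1 -> AAA K, CAA Q, GAA E: stop-loss (missense) x3
  # pos8 A>(CGT): TAA pos2 -> TCA S, TGA *, TTA L: 1 nonsense-preserving
  #   (TGA is still a stop: synonymous), 2 stop-loss
  expect_equal(unif$expected_sig[unif$class == "synonymous"], 2 / 21)
  expect_equal(unif$expected_sig[unif$class == "missense"], 19 / 21)
  expect_equal(unif$expected_sig[unif$class == "nonsense"], 0)

  # one-hot signature: only G[T>A]T sites contribute; the only such
  # context is pos 6 (ATT..?); verify against direct enumeration
  sig <- setNames(numeric(96), sbs_classes())
  sig["G[T>A]A"] <- 1   # pos 6: context ATT? compute independently below
  seqs <- strsplit("ATGGATTAA", "")[[1]]
  hits <- 0; syn_hits <- 0
  for (i in 2:8) {
    for (alt in setdiff(c("A", "C", "G", "T"), seqs[i])) {
      cls <- sbs_class_of(seqs[i], alt, paste0(seqs[i - 1], seqs[i], seqs[i + 1]))
      if (cls == "G[T>A]A") hits <- hits + 1
    }
  }
  if (hits > 0) {
    dp <- damage_potential(sig, list(gene))
    expect_equal(sum(dp$expected_sig), 1)
  } else {
    expect_error(damage_potential(sig, list(gene)), "no enumerable")
  }

  # invalid ORF is excluded with a warning
  expect_warning(
    expect_error(damage_potential(rep(1 / 96, 96),
                                  list(list(name = "bad", cds = "ATGG"))),
                 "no enumerable"),
    "excluded")
})

test_that("psoralen damage is relatively depleted for synonymous changes vs UV", {
  genes <- toy_gene_models()
  dp <- damage_potential(psoralen_reference(), genes,
                         baseline = signature_catalog()["UV", ])
  expect_lt(dp$ratio[dp$class == "synonymous"], 1)
})
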