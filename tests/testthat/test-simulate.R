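test_that("configuration validation rejects invalid rates", {
  expect_error(simulation_config(detection_sensitivity = 0))
  expect_error(simulation_config(germline_rate = 1.5))
  expect_error(simulation_config(puva_band_probs = c(1, 1, 1, 1)))
})

test_that("cohorts are deterministic functions of the configuration", {
  cfg <- simulation_config(n_patients = 3, rng_seed = 99)
  c1 <- simulate_cohort(cfg)
  c2 <- simulate_cohort(cfg)
  expect_identical(c1$mutations, c2$mutations)
  expect_identical(c1$clone_cf, c2$clone_cf)
  c3 <- simulate_cohort(simulation_config(n_patients = 3, rng_seed = 100))
  expect_false(identical(c1$mutations, c3$mutations))
})

test_that("cohort structure satisfies its invariants", {
  cfg <- simulation_config(n_patients = 4, rng_seed = 5)
  co <- simulate_cohort(cfg)
  # every mutation has exactly one truth record / clone
  expect_false(any(duplicated(co$mutations$mut_id)))
  expect_true(all(co$mutations$clone_id %in% co$clones$clone_id))
  # cellular fractions of distinct cell populations never exceed 1:
  # root-clone CFs per microbiopsy sum below 1
  roots <- co$clones$clone_id[is.na(co$clones$parent)]
  cfr <- co$clone_cf[co$clone_cf$clone_id %in% roots, ]
  tot <- tapply(cfr$cf, cfr$sample_id, sum)
  expect_true(all(tot <= 1 + 1e-9))
  # subclone CF never exceeds its parent's in any microbiopsy
  kids <- co$clones[!is.na(co$clones$parent), ]
  for (i in seq_len(nrow(kids))) {
    k <- co$clone_cf[co$clone_cf$clone_id == kids$clone_id[i], ]
    p <- co$clone_cf[co$clone_cf$clone_id == kids$parent[i], ]
    m <- merge(k, p, by = "sample_id")
    expect_true(all(m$cf.x <= m$cf.y + 1e-9))
  }
  # burdens scale with age as configured (law of large numbers)
  cl <- merge(co$clones, co$patients, by = "patient_id")
  tips <- cl[cl$is_tip, ]
  fam <- tapply((cl$n_uv + cl$n_sbs15 + cl$n_apobec), cl$clone_id, sum)
  # clade totals: tip + parent branch
  clade_total <- vapply(seq_len(nrow(tips)), function(i) {
    tot <- tips$n_uv[i] + tips$n_sbs15[i] + tips$n_apobec[i]
    p <- tips$parent[i]
    while (!is.na(p)) {
      j <- which(cl$clone_id == p)
      tot <- tot + cl$n_uv[j] + cl$n_sbs15[j] + cl$n_apobec[j]
      p <- cl$parent[j]
    }
    tot
  }, numeric(1))
  ratio <- mean(clade_total) / mean(14.6 * tips$age)
  expect_lt(abs(ratio - 1), 0.15)
})

test_that("read emission follows the binomial model", {
  cfg <- simulation_config(n_patients = 2, rng_seed = 8)
  co <- simulate_cohort(cfg)
  m <- emit_reads(co, "P01", mean_depth = 1000)
  # pick the highest-CF clone in its focal microbiopsy
  cfs <- co$clone_cf[co$clone_cf$clone_id %in% m$mutations$clone_id, ]
  top <- cfs[which.max(cfs$cf), ]
  rows <- which(m$mutations$clone_id == top$clone_id)
  j <- match(top$sample_id, m$samples)
  v <- m$alt[rows, j] / m$depth[rows, j]
  expect_lt(abs(mean(v) - top$cf / 2), 0.02)
  # mutation absent from a sample -> 0 alt reads
  zero <- cfs[cfs$cf == 0, ]
  if (nrow(zero) > 0) {
    r0 <- which(m$mutations$clone_id == zero$clone_id[1])
    expect_true(all(m$alt[r0, match(zero$sample_id[1], m$samples)] == 0))
  }
  # VAF distribution matches the binomial at fixed depth (KS)
  set.seed(2)
  sim <- stats::rbinom(length(rows), 1000, top$cf / 2) / 1000
  ks <- suppressWarnings(stats::ks.test(v, sim))
  expect_gt(ks$p.value, 0.001)
})

test_that("contaminant spikes have the promised read structure", {
  cfg <- simulation_config(n_patients = 2, rng_seed = 3)
  co <- simulate_cohort(cfg)
  m <- emit_reads(co, "P01")
  # rates of zero leave the matrix unchanged
  expect_identical(spike_contaminants(m, 0, 0)$alt, m$alt)
  set.seed(9)
  ms <- spike_contaminants(m, 0.05, 0.05, mean_depth = 50)
  n0 <- nrow(m$alt)
  expect_equal(nrow(ms$alt), n0 + 2 * round(0.05 * n0))
  g <- which(ms$mutations$is_germline)
  # germline spikes sit near VAF 0.5 in every sample
  vg <- ms$alt[g, ] / ms$depth[g, ]
  expect_lt(abs(mean(vg) - 0.5), 0.02)
  a <- which(ms$mutations$is_artifact)
  va <- ms$alt[a, ] / ms$depth[a, ]
  expect_lt(max(apply(va, 1, mean)), 0.1)  # uniformly low artifact signal
})

test_that("replicate pairs share calls at the configured sensitivity", {
  expect_length(simulate_replicate_pairs(0), 0)
  set.seed(4)
  perfect <- simulate_replicate_pairs(3, 100, detection_sensitivity = 1)
  for (p in perfect) expect_identical(p$a, p$b)
  pairs <- simulate_replicate_pairs(50, 400, detection_sensitivity = 0.89)
  fr <- vapply(pairs, function(p) mean(p$a %in% p$b), numeric(1))
  expect_lt(abs(mean(fr) - 0.89), 0.02)
})

test_that("genic mutation simulation recovers its own dials", {
  ann <- toy_annotation(400, seed = 6)
  expect_equal(nrow(simulate_genic_mutations(ann, 0)), 0)
  set.seed(7)
  # symmetric null
  g0 <- simulate_genic_mutations(ann, 20000, strand_asymmetry_tpa = 1,
                                 leading_lagging_ratio = 1,
                                 expression_effect = 0)
  s0 <- strand_asymmetry(g0)
  expect_lt(abs(s0$ratio - 1), 0.1)
  expect_gt(s0$p_value, 0.001)
  # asymmetry 2 recovered
  g2 <- simulate_genic_mutations(ann, 50000, strand_asymmetry_tpa = 2)
  expect_lt(abs(strand_asymmetry(g2)$ratio - 2), 0.15)
  # flat expression effect gives flat deciles
  ed0 <- expression_decile_rates(g0, ann)
  expect_lt(max(abs(ed0$rate_rel - 1)), 0.25)
  # all mutations are TpA-site T mutations
  expect_true(all(is_tpa_site(g2$ref, g2$alt, g2$trinucleotide)))
})

test_that("burden records follow the generative mixed model", {
  cfg <- simulation_config()
  sb <- simulate_burden_records(cfg, n_patients = 150, clones_per_patient = 4,
                                seed = 10)
  r <- sb$records
  expect_equal(nrow(r), 600)
  fit <- stats::lm(burden_nonpsoralen ~ age, data = r)
  expect_lt(abs(unname(stats::coef(fit)["age"]) - 14.6), 1.5)
  expect_true(all(r$duration <= r$age))
  # spectra match component burdens
  sb2 <- simulate_burden_records(cfg, n_patients = 10, clones_per_patient = 2,
                                 spectra = TRUE, seed = 11)
  r2 <- sb2$records
  expect_equal(unname(rowSums(sb2$spectra)),
               round(r2$burden_nonpsoralen - r2$burden_sbs15) +
                 round(r2$burden_sbs15) + round(r2$burden_psoralen))
})
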