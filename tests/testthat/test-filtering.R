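test_that("genotyping threshold requires depth >= 4 and alt >= 3 in one sample", {
  mat <- make_matrix(alt = rbind(c(3, 0, 0), c(2, 2, 2), c(0, 0, 0)),
                     depth = rbind(c(4, 10, 10), c(50, 50, 50), c(50, 50, 50)))
  flagged <- genotype_mutations(mat)$mutations$low_support
  expect_equal(flagged, c(FALSE, TRUE, TRUE))
})

test_that("germline filter matches the exact-binomial oracle", {
  # worked examples: balanced reads are germline, skewed are somatic
  mat <- make_matrix(alt = rbind(c(25, 26, 24), c(20, 0, 0)),
                     depth = rbind(c(50, 50, 50), c(40, 50, 60)))
  res <- germline_filter(mat)
  expect_equal(res$verdict, c("germline", "somatic"))
  expect_true(res$germline_q[1] > 0.9)
  expect_true(res$germline_q[2] < 1e-3)

  # male X chromosome tested against p0 = 0.95
  matx <- make_matrix(alt = matrix(48), depth = matrix(50), chrom = "chrX")
  resx <- germline_filter(matx, sex = "male")
  expect_equal(resx$p0, 0.95)
  expect_equal(resx$verdict, "germline")
  # the same counts on an autosome are not consistent with VAF 0.5
  expect_equal(germline_filter(make_matrix(matrix(48), matrix(50)))$verdict,
               "somatic")

  # randomized agreement with the independent oracle (binom.test)
  set.seed(7)
  for (r in 1:40) {
    ns <- sample(1:20, 1)
    depth <- rpois(ns, sample(10:60, 1))
    depth <- pmin(depth, floor(200 / ns))          # pooled depth <= 200
    alt <- rbinom(ns, depth, runif(1, 0, 1))
    m <- make_matrix(matrix(alt, 1), matrix(depth, 1))
    got <- germline_filter(m)
    want <- oracle_binom_p(sum(alt), sum(depth), 0.5)
    expect_equal(got$germline_p, want, tolerance = 1e-9)
  }
})

test_that("BH-adjusted q is monotone in p", {
  set.seed(2)
  alt <- matrix(rbinom(200, 50, runif(100, 0.05, 0.6)), 100)
  mat <- make_matrix(alt, matrix(50, 100, 2))
  res <- germline_filter(mat)
  o <- order(res$germline_p)
  expect_true(all(diff(res$germline_q[o]) >= -1e-12))
})

test_that("rho filter separates shared artifacts from clonal mutations", {
  # low-level signal in every sample: binomial-like, rho at grid bottom
  art <- make_matrix(matrix(2, 1, 20), matrix(50, 1, 20))
  res_art <- rho_filter(art)
  expect_equal(res_art$verdict, "artifact")
  expect_lt(res_art$rho_hat, 1e-3)

  # present in one sample, absent from 19: needs high overdispersion
  som <- make_matrix(matrix(c(20, rep(0, 19)), 1), matrix(50, 1, 20))
  res_som <- rho_filter(som)
  expect_equal(res_som$verdict, "somatic")
  expect_gt(res_som$rho_hat, 0.1)

  # grid endpoints are honoured
  expect_true(all(RHO_GRID >= 1e-6 & RHO_GRID <= 10^-0.05))
  set.seed(3)
  for (r in 1:20) {
    ns <- sample(2:8, 1)
    depth <- sample(20:60, ns, replace = TRUE)
    alt <- rbinom(ns, depth, runif(ns, 0, 0.5))
    m <- make_matrix(matrix(alt, 1), matrix(depth, 1))
    expect_true(rho_filter(m)$rho_hat >= 1e-6)
    expect_true(rho_filter(m)$rho_hat <= 10^-0.05)
  }
})

test_that("rho grid ML agrees with a numerical-integration oracle", {
  set.seed(11)
  for (r in 1:12) {
    ns <- sample(3:8, 1)
    depth <- sample(20:60, ns, replace = TRUE)
    true_p <- if (r %% 2 == 0) runif(1, 0.01, 0.05) else runif(ns, 0, 0.5)
    alt <- rbinom(ns, depth, true_p)
    if (sum(alt) == 0) next
    m <- make_matrix(matrix(alt, 1), matrix(depth, 1))
    got <- rho_filter(m)$rho_hat
    want <- oracle_rho_hat(alt, depth)
    # same grid: the argmax must agree up to likelihood ties between
    # neighbouring grid points
    expect_lt(abs(log10(got) - log10(want)), 0.13)
  }
})

test_that("filter verdicts partition all mutations", {
  set.seed(5)
  alt <- matrix(rbinom(300, 40, rep(runif(60, 0, 0.5), each = 5)), 60,
                byrow = TRUE)
  mat <- make_matrix(alt, matrix(40, 60, 5))
  res <- filter_calls(mat)
  expect_equal(nrow(res), 60)
  expect_true(all(res$verdict %in% c("somatic", "germline", "artifact",
                                     "low_support")))
})

test_that("adjacent substitutions merge into DBS by the Fisher rule", {
  # similar counts at adjacent sites merge
  m1 <- make_matrix(alt = matrix(c(20, 22), 2), depth = matrix(c(50, 51), 2),
                    pos = c(100, 101), ref = c("C", "C"), alt_base = c("T", "T"))
  out1 <- merge_dbs(m1)
  expect_equal(nrow(out1), 1)
  expect_equal(out1$mut_class, "DBS")
  expect_equal(out1$ref, "CC")
  expect_gte(stats::fisher.test(matrix(c(20, 30, 22, 29), 2))$p.value, 0.05)

  # discordant counts do not merge
  m2 <- make_matrix(alt = matrix(c(20, 2), 2), depth = matrix(c(50, 50), 2),
                    pos = c(100, 101))
  expect_equal(nrow(merge_dbs(m2)), 2)

  # non-adjacent positions never merge
  m3 <- make_matrix(alt = matrix(c(20, 22), 2), depth = matrix(c(50, 51), 2),
                    pos = c(100, 102))
  expect_equal(nrow(merge_dbs(m3)), 2)

  # a triple of adjacent similar calls merges greedily left-to-right
  m4 <- make_matrix(alt = matrix(c(20, 21, 22), 3),
                    depth = matrix(c(50, 50, 50), 3), pos = c(100, 101, 102))
  out4 <- merge_dbs(m4)
  expect_equal(out4$mut_class, c("DBS", "SBS"))
})

test_that("replicate sensitivity estimation handles edge and typical cases", {
  ids <- sprintf("m%03d", 1:100)
  expect_equal(estimate_sensitivity(list(list(a = ids, b = ids)))$median, 1)
  expect_equal(estimate_sensitivity(list(list(a = ids[1:50],
                                              b = ids[51:100])))$median, 0)
  expect_warning(
    res <- estimate_sensitivity(list(list(a = character(0), b = ids),
                                     list(a = ids, b = ids))),
    "empty")
  expect_equal(res$median, 1)
  expect_error(estimate_sensitivity(list()), "at least one")
})
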