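test_that("pigeonhole evidence grades follow the CF rules", {
  cf <- rbind(A = c(0.9, 0.8), B = c(0.5, 0.3))
  e <- pigeonhole_nesting(cf)
  expect_equal(e[e$child == "B", "evidence"], "strong")  # 0.9 + 0.5 > 1

  cf2 <- rbind(A = c(0.4, 0.4), B = c(0.2, 0.1))
  e2 <- pigeonhole_nesting(cf2)
  expect_equal(e2[e2$child == "B", "evidence"], "weak")

  cf3 <- rbind(A = c(0.6, 0.1), B = c(0.1, 0.6))
  expect_equal(nrow(pigeonhole_nesting(cf3)), 0)         # independent
})

test_that("near-identical high-CF clusters give a flagged conflict", {
  cf <- rbind(A = c(0.8, 0.8), B = c(0.79, 0.81))
  e <- pigeonhole_nesting(cf, epsilon = 0.05)
  expect_true(all(e$conflict))
})

test_that("forests follow the tightest-superset rule and detect structure", {
  cf <- rbind(A = c(0.9, 0.9), B = c(0.6, 0.55), C = c(0.45, 0.3))
  cl <- list(cf_centroid = cf, vaf_centroid = cf / 2,
             clusters = data.frame(n = c(200, 100, 50)))
  tree <- build_forest(cl)
  expect_equal(tree$nodes$parent[tree$nodes$cluster_id == "B"], "A")
  expect_equal(tree$nodes$parent[tree$nodes$cluster_id == "C"], "B")

  # two independent clusters both sit at the root
  cf2 <- rbind(A = c(0.6, 0.05), B = c(0.05, 0.6))
  cl2 <- list(cf_centroid = cf2, vaf_centroid = cf2 / 2,
              clusters = data.frame(n = c(10, 10)))
  tree2 <- build_forest(cl2)
  expect_true(all(is.na(tree2$nodes$parent)))
})

test_that("forest construction matches exhaustive search on random instances", {
  # oracle: for each cluster enumerate all dominating clusters and pick
  # the one with the smallest mean CF, preferring strong evidence
  oracle_forest <- function(cf, eps = 0.05) {
    K <- nrow(cf)
    parent <- rep(NA_integer_, K)
    for (b in seq_len(K)) {
      cand <- c(); strong <- c()
      for (a in seq_len(K)) {
        if (a == b) next
        dom_ab <- all(cf[b, ] <= cf[a, ] + eps)
        dom_ba <- all(cf[a, ] <= cf[b, ] + eps)
        if (!dom_ab) next
        s_ab <- any(cf[a, ] + cf[b, ] > 1)
        if (dom_ba) {
          s_ba <- any(cf[a, ] + cf[b, ] > 1)
          if (s_ab && s_ba) next                    # conflict: unresolved
          if (mean(cf[a, ]) < mean(cf[b, ])) next   # only larger dominates
        }
        cand <- c(cand, a)
        if (s_ab) strong <- c(strong, a)
      }
      pool <- if (length(strong)) strong else cand
      if (length(pool))
        parent[b] <- pool[which.min(rowMeans(cf)[pool])]
    }
    parent
  }
  set.seed(21)
  for (r in 1:30) {
    K <- sample(2:6, 1)
    cf <- matrix(runif(K * 3, 0, 0.95), K)
    rownames(cf) <- paste0("c", seq_len(K))
    cl <- list(cf_centroid = cf, vaf_centroid = cf / 2,
               clusters = data.frame(n = rep(10, K)))
    got <- tryCatch(build_forest(cl), error = function(e) NULL)
    if (is.null(got)) next   # rare cyclic instance is rejected, as specified
    want <- oracle_forest(cf)
    want_ids <- ifelse(is.na(want), NA_character_, rownames(cf)[want])
    expect_equal(got$nodes$parent, unname(want_ids))
  }
})

test_that("CF monotonicity holds along root-to-tip paths", {
  set.seed(31)
  for (r in 1:10) {
    K <- sample(3:6, 1)
    cf <- matrix(runif(K * 4, 0, 0.9), K)
    rownames(cf) <- paste0("c", seq_len(K))
    cl <- list(cf_centroid = cf, vaf_centroid = cf / 2,
               clusters = data.frame(n = rep(5, K)))
    tree <- tryCatch(build_forest(cl), error = function(e) NULL)
    if (is.null(tree)) next
    for (i in seq_len(nrow(tree$nodes))) {
      p <- tree$nodes$parent[i]
      if (is.na(p)) next
      expect_true(all(cf[tree$nodes$cluster_id[i], ] <= cf[p, ] + 0.05))
    }
  }
})

test_that("pruning applies the strong-evidence and median-VAF rules", {
  nodes <- data.frame(
    cluster_id = c("A", "B", "C", "D"),
    parent = c(NA, "A", NA, NA),
    n_mutations = c(300, 100, 60, 40),
    evidence = c("none", "strong", "none", "none"),
    median_vaf = c(0.45, 0.2, 0.35, 0.25),
    stringsAsFactors = FALSE)
  cf <- matrix(0.4, 4, 2, dimnames = list(nodes$cluster_id, NULL))
  tree <- structure(list(nodes = nodes, cf = cf), class = "clone_tree")
  pruned <- prune_uncertain(tree)
  ids <- pruned$nodes$cluster_id
  expect_true("B" %in% ids)     # strong nesting retained at any VAF
  expect_true("C" %in% ids)     # un-nested, median VAF 0.35 > 0.3
  expect_false("D" %in% ids)    # un-nested, median VAF 0.25

  # weakly nested clusters are discarded and children reattach upward
  nodes2 <- nodes
  nodes2$evidence <- c("none", "weak", "none", "none")
  tree2 <- structure(list(nodes = nodes2, cf = cf), class = "clone_tree")
  pruned2 <- prune_uncertain(tree2)
  expect_false("B" %in% pruned2$nodes$cluster_id)
})

test_that("clone burdens are root-to-tip sums and pruning never raises them", {
  nodes <- data.frame(cluster_id = c("A", "B"), parent = c(NA, "A"),
                      n_mutations = c(300, 100),
                      evidence = c("none", "strong"),
                      median_vaf = c(0.4, 0.2), stringsAsFactors = FALSE)
  tree <- structure(list(nodes = nodes,
                         cf = matrix(0.5, 2, 2,
                                     dimnames = list(c("A", "B"), NULL))),
                    class = "clone_tree")
  b <- clone_burdens(tree)
  expect_equal(b$burden[b$clone_id == "B"], 400)

  single <- structure(list(nodes = data.frame(cluster_id = "X",
                                              parent = NA_character_,
                                              n_mutations = 430,
                                              evidence = "none",
                                              median_vaf = 0.4)),
                      class = "clone_tree")
  expect_equal(clone_burdens(single)$burden, 430)

  pruned <- prune_uncertain(tree)
  bp <- clone_burdens(pruned)
  for (id in bp$clone_id) {
    expect_lte(bp$burden[bp$clone_id == id],
               max(b$burden))
  }
})
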