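# Clone phylogeny by the statistical pigeonhole principle. If two mutation
# clusters' combined cellular fractions exceed 100% in some microbiopsy,
# cells must carry both, so the consistently smaller cluster is nested
# within the larger (strong evidence). Dominance without combined CF > 1
# is only weak evidence; crossing CFs mean independent clones.

#' Pigeonhole nesting relation between mutation clusters
#'
#' For every ordered cluster pair (A, B), grades the evidence that B is a
#' subclone of A: \code{strong} when some microbiopsy has
#' \code{cf_A + cf_B > 1} and B's CF never exceeds A's (within tolerance)
#' anywhere; \code{weak} when B is dominated everywhere but no microbiopsy
#' exceeds combined CF 1; \code{none} when the CFs cross. Pairs with
#' strong evidence in both directions are flagged as conflicts and left
#' unresolved.
#'
#' @param cf Matrix of cellular fractions (clusters x microbiopsies),
#'   e.g. \code{cf_centroid} from [fit_dp_clusters()].
#' @param epsilon Dominance tolerance on the CF scale (default 0.05;
#'   sampling noise at typical depths makes exact dominance brittle).
#' @return Data frame of directed edges: \code{parent}, \code{child},
#'   \code{evidence} (\code{strong}/\code{weak}), \code{conflict}.
#' @export
pigeonhole_nesting <- function(cf, epsilon = 0.05) {
  K <- nrow(cf)
  ids <- rownames(cf) %||% paste0("cluster", seq_len(K))
  rownames(cf) <- ids
  edges <- list()
  for (A in seq_len(K)) {
    for (B in seq_len(K)) {
      if (A == B) next
      dominated <- all(cf[B, ] <= cf[A, ] + epsilon)
      if (!dominated) next
      strong <- any(cf[A, ] + cf[B, ] > 1)
      edges[[length(edges) + 1L]] <- data.frame(
        parent = ids[A], child = ids[B],
        evidence = if (strong) "strong" else "weak",
        stringsAsFactors = FALSE)
    }
  }
  if (length(edges) == 0) {
    return(data.frame(parent = character(0), child = character(0),
                      evidence = character(0), conflict = logical(0)))
  }
  out <- do.call(rbind, edges)
  # bidirectional strong evidence is contradictory: flag and drop the pair
  key <- paste(out$parent, out$child)
  rev_key <- paste(out$child, out$parent)
  m <- match(rev_key, key)
  out$conflict <- !is.na(m) & out$evidence == "strong" &
    out$evidence[ifelse(is.na(m), 1L, m)] == "strong"
  out
}

#' Build a clone forest from clusters and their nesting relation
#'
#' Attaches every cluster to its tightest superset: the strong-evidence
#' parent with the smallest mean CF, falling back to the tightest weak
#' parent; clusters with no admissible parent sit at the root (germline).
#' Mutually-dominating pairs (conflicts, or weak two-way dominance of
#' near-identical clusters) are broken by attaching the cluster with the
#' smaller mean CF below the larger; flagged conflicts are not used as
#' edges at all. A residual cycle is an error.
#'
#' @param clusters A \code{dp_clusters} object, or a list with
#'   \code{cf_centroid} and \code{clusters$n}.
#' @param nesting Optional precomputed [pigeonhole_nesting()] table.
#' @param mat Optional [count_matrix()] of the clustered mutations (with
#'   \code{assignment}), used to record each cluster's median member VAF
#'   for pruning.
#' @param epsilon Dominance tolerance.
#' @return Object of class \code{clone_tree}: \code{nodes} (cluster_id,
#'   parent, n_mutations, evidence, median_vaf), \code{cf} matrix.
#' @export
build_forest <- function(clusters, nesting = NULL, mat = NULL,
                         epsilon = 0.05) {
  cf <- clusters$cf_centroid
  ids <- rownames(cf) %||% paste0("cluster", seq_len(nrow(cf)))
  rownames(cf) <- ids
  n_mut <- clusters$clusters$n %||% rep(0L, nrow(cf))
  if (is.null(nesting)) nesting <- pigeonhole_nesting(cf, epsilon)
  usable <- nesting[!nesting$conflict, , drop = FALSE]
  mean_cf <- rowMeans(cf)
  # two-way weak dominance (near-identical clusters): keep only the edge
  # from the larger-CF cluster to the smaller
  if (nrow(usable)) {
    key <- paste(usable$parent, usable$child)
    rev_key <- paste(usable$child, usable$parent)
    two_way <- key %in% rev_key
    drop <- two_way & mean_cf[usable$parent] < mean_cf[usable$child]
    usable <- usable[!drop, , drop = FALSE]
  }
  parent <- stats::setNames(rep(NA_character_, length(ids)), ids)
  evidence <- stats::setNames(rep("none", length(ids)), ids)
  for (id in ids) {
    cand <- usable[usable$child == id, , drop = FALSE]
    if (nrow(cand) == 0) next
    pick_from <- if (any(cand$evidence == "strong"))
      cand[cand$evidence == "strong", ] else cand
    best <- pick_from$parent[which.min(mean_cf[pick_from$parent])]
    parent[id] <- best
    evidence[id] <- pick_from$evidence[pick_from$parent == best][1]
  }
  # cycle check
  for (id in ids) {
    seen <- character(0); cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen)
        stop("nesting cycle: ", paste(c(seen, cur), collapse = " -> "))
      seen <- c(seen, cur)
      cur <- parent[cur]
    }
  }
  median_vaf <- rep(NA_real_, length(ids))
  if (!is.null(mat) && !is.null(clusters$assignment)) {
    v <- vaf(mat)
    for (k in seq_along(ids)) {
      rows <- clusters$assignment == k
      cols <- clusters$vaf_centroid[k, ] >= 0.05
      if (any(rows) && any(cols)) {
        median_vaf[k] <- stats::median(v[rows, cols, drop = FALSE], na.rm = TRUE)
      }
    }
  } else {
    # fall back to the largest per-sample centroid as a location summary
    median_vaf <- apply(clusters$vaf_centroid %||% cf / 2, 1, max)
  }
  nodes <- data.frame(cluster_id = ids, parent = unname(parent),
                      n_mutations = n_mut, evidence = unname(evidence),
                      median_vaf = median_vaf, stringsAsFactors = FALSE)
  structure(list(nodes = nodes, cf = cf), class = "clone_tree")
}

#' @export
print.clone_tree <- function(x, ...) {
  n_tip <- sum(!(x$nodes$cluster_id %in% x$nodes$parent))
  cat(sprintf("clone_tree: %d clusters, %d tips (clones), %d mutations\n",
              nrow(x$nodes), n_tip, sum(x$nodes$n_mutations)))
  invisible(x)
}

#' Prune branches where the pigeonhole principle is uncertain
#'
#' Nested clusters are retained only when the nesting is supported by
#' combined cellular fractions exceeding 1 (strong evidence); weakly
#' nested clusters are removed and their mutations discarded from the
#' burden set (their children are re-attached to the grandparent).
#' Root-level clusters with no retained children are kept only if the
#' cluster's median VAF exceeds \code{vaf_threshold}.
#'
#' @param tree A \code{clone_tree}.
#' @param vaf_threshold Retention threshold for un-nested clusters
#'   (default 0.3).
#' @return The pruned \code{clone_tree}; the full tree is retained in the
#'   \code{full} attribute.
#' @export
prune_uncertain <- function(tree, vaf_threshold = 0.3) {
  nodes <- tree$nodes
  # remove weakly nested clusters, reattaching children upward
  repeat {
    weak <- which(!is.na(nodes$parent) & nodes$evidence == "weak")
    if (length(weak) == 0) break
    w <- weak[1]
    wid <- nodes$cluster_id[w]
    ch <- nodes$cluster_id[!is.na(nodes$parent) & nodes$parent == wid]
    nodes$parent[nodes$cluster_id %in% ch] <- nodes$parent[w]
    nodes <- nodes[-w, , drop = FALSE]
  }
  # un-nested single-cluster branches: keep only high-VAF clusters
  is_parent <- nodes$cluster_id %in% nodes$parent
  drop <- is.na(nodes$parent) & !is_parent &
    !(ifelse(is.na(nodes$median_vaf), 0, nodes$median_vaf) > vaf_threshold)
  nodes <- nodes[!drop, , drop = FALSE]
  rownames(nodes) <- NULL
  out <- structure(list(nodes = nodes,
                        cf = tree$cf[nodes$cluster_id, , drop = FALSE]),
                   class = "clone_tree")
  attr(out, "full") <- tree
  out
}

#' Root-to-tip clone burdens
#'
#' Each tip of the clone tree is a clone; its mutation burden is the sum
#' of branch mutation counts on the path from the germline root to the
#' tip.
#'
#' @param tree A \code{clone_tree}.
#' @return Data frame: \code{clone_id} (tip), \code{burden}.
#' @export
clone_burdens <- function(tree) {
  nodes <- tree$nodes
  tips <- nodes$cluster_id[!(nodes$cluster_id %in% nodes$parent)]
  burden <- vapply(tips, function(id) {
    tot <- 0; cur <- id
    while (!is.na(cur)) {
      tot <- tot + nodes$n_mutations[nodes$cluster_id == cur]
      cur <- nodes$parent[nodes$cluster_id == cur]
    }
    tot
  }, numeric(1))
  data.frame(clone_id = tips, burden = unname(burden),
             stringsAsFactors = FALSE)
}
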