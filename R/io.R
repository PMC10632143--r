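# Readers and writers for the tabular formats the pipeline touches:
# mutation tables (VCF or TSV), count matrices (TSV with per-sample
# ALT_<id>/DEP_<id> columns) and Newick clone trees.
#
# Conventions: positions are 1-based (VCF); intervals are half-open
# [start, end) with 1-based starts.

#' Read a mutation table from VCF or TSV
#'
#' @param path File path.
#' @param format \code{"vcf"} or \code{"tsv"}. TSV needs columns
#'   \code{chrom}, \code{pos}, \code{ref}, \code{alt}; optional
#'   \code{trinucleotide} and \code{gene_id}.
#' @param contigs Optional character vector of known contigs; records on
#'   other contigs are skipped with a warning.
#' @return Data frame of mutation calls with columns \code{chrom},
#'   \code{pos} (1-based), \code{ref}, \code{alt}, \code{mut_class},
#'   \code{trinucleotide} (NA when no context is available) and
#'   \code{on_tpa}.
#' @export
read_mutation_table <- function(path, format = c("tsv", "vcf"), contigs = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "vcf") {
    if (requireNamespace("vcfR", quietly = TRUE)) {
      v <- vcfR::read.vcfR(path, verbose = FALSE)
      fix <- as.data.frame(v@fix, stringsAsFactors = FALSE)
      tab <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                        ref = fix$REF, alt = fix$ALT,
                        stringsAsFactors = FALSE)
    } else {
      lines <- readLines(path)
      body <- which(!startsWith(lines, "#"))
      parts <- strsplit(lines[body], "\t")
      bad <- which(lengths(parts) < 5)
      if (length(bad))
        stop("malformed VCF record at line ", body[bad[1]])
      tab <- data.frame(chrom = vapply(parts, `[`, "", 1),
                        pos = as.integer(vapply(parts, `[`, "", 2)),
                        ref = vapply(parts, `[`, "", 4),
                        alt = vapply(parts, `[`, "", 5),
                        stringsAsFactors = FALSE)
    }
  } else {
    tab <- utils::read.delim(path, stringsAsFactors = FALSE)
    need <- c("chrom", "pos", "ref", "alt")
    miss <- setdiff(need, names(tab))
    if (length(miss)) stop("TSV lacks columns: ", paste(miss, collapse = ", "))
    bad <- which(is.na(suppressWarnings(as.integer(tab$pos))))
    if (length(bad))
      stop("malformed record at line ", bad[1] + 1L, ": non-integer pos")
    tab$pos <- as.integer(tab$pos)
  }
  if (!is.null(contigs)) {
    drop <- !(tab$chrom %in% contigs)
    if (any(drop)) {
      warning(sum(drop), " record(s) on unknown contigs skipped")
      tab <- tab[!drop, , drop = FALSE]
    }
  }
  tab$mut_class <- mutation_class(tab$ref, tab$alt)
  if (is.null(tab$trinucleotide)) tab$trinucleotide <- NA_character_
  tab$on_tpa <- ifelse(tab$mut_class == "SBS" & !is.na(tab$trinucleotide),
                       is_tpa_site(tab$ref, tab$alt, tab$trinucleotide), NA)
  tab
}

#' Read a count matrix from TSV
#'
#' Expects columns \code{chrom}, \code{pos}, \code{ref}, \code{alt}
#' followed by per-sample pairs \code{ALT_<id>} and \code{DEP_<id>}.
#' Missing cells are treated as depth 0.
#'
#' @param path File path.
#' @return A [count_matrix()].
#' @export
read_count_matrix <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  alt_cols <- grep("^ALT_", names(tab), value = TRUE)
  dep_cols <- grep("^DEP_", names(tab), value = TRUE)
  ids <- sub("^ALT_", "", alt_cols)
  if (!setequal(ids, sub("^DEP_", "", dep_cols)))
    stop("ALT_/DEP_ sample columns do not match")
  key <- paste(tab$chrom, tab$pos, tab$ref, tab$alt, sep = ":")
  if (anyDuplicated(key)) stop("duplicated mutation key: ", key[duplicated(key)][1])
  A <- as.matrix(tab[, paste0("ALT_", ids), drop = FALSE])
  D <- as.matrix(tab[, paste0("DEP_", ids), drop = FALSE])
  A[is.na(A) | is.na(D)] <- 0L; D[is.na(D)] <- 0L  # missing cell = uncovered
  colnames(A) <- colnames(D) <- ids
  muts <- tab[, setdiff(names(tab), c(alt_cols, dep_cols)), drop = FALSE]
  muts$mut_class <- mutation_class(muts$ref, muts$alt)
  count_matrix(muts, A, D)
}

#' Write a count matrix to TSV
#'
#' Inverse of [read_count_matrix()].
#' @param x A \code{count_matrix}.
#' @param path Output path.
#' @export
write_count_matrix <- function(x, path) {
  A <- x$alt; D <- x$depth
  colnames(A) <- paste0("ALT_", x$samples)
  colnames(D) <- paste0("DEP_", x$samples)
  keep <- intersect(c("chrom", "pos", "ref", "alt", "trinucleotide", "gene_id"),
                    names(x$mutations))
  out <- cbind(x$mutations[, keep, drop = FALSE], A, D)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Recursive newick builder over a parent-child node table.
.newick_subtree <- function(nodes, id) {
  children <- nodes$cluster_id[!is.na(nodes$parent) & nodes$parent == id]
  len <- nodes$n_mutations[nodes$cluster_id == id]
  if (length(children) == 0) return(sprintf("%s:%g", id, len))
  inner <- paste(vapply(children, function(ch) .newick_subtree(nodes, ch),
                        character(1)), collapse = ",")
  sprintf("(%s)%s:%g", inner, id, len)
}

#' Write a clone forest as Newick
#'
#' Branch lengths are per-cluster mutation counts; internal nodes and tips
#' are labelled with cluster ids; the implicit root is the germline.
#'
#' @param tree A \code{clone_tree} (see [build_forest()]).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_newick <- function(tree, path) {
  nodes <- tree$nodes
  # cycle guard
  for (id in nodes$cluster_id) {
    seen <- character(0); cur <- id
    while (!is.na(cur)) {
      if (cur %in% seen) stop("cyclic nesting involving cluster ", cur)
      seen <- c(seen, cur)
      cur <- nodes$parent[nodes$cluster_id == cur]
    }
  }
  roots <- nodes$cluster_id[is.na(nodes$parent)]
  if (length(roots) == 0) stop("tree has no root-level clusters")
  inner <- paste(vapply(roots, function(r) .newick_subtree(nodes, r),
                        character(1)), collapse = ",")
  txt <- sprintf("(%s);", inner)  # unlabelled root = germline
  writeLines(txt, path)
  invisible(path)
}

#' Read a Newick clone forest written by [write_newick()]
#'
#' Clone trees routinely contain unary chains (a parent cluster with a
#' single nested subcluster and no siblings), which general phylogenetic
#' newick readers collapse or renumber; this reader preserves them
#' verbatim with a small recursive parser.
#'
#' @param path File path.
#' @return A \code{clone_tree} with the node table (cluster_id, parent,
#'   n_mutations) reconstructed.
#' @export
read_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "")
  txt <- sub(";\\s*$", "", trimws(txt))
  # strip the outer (unlabelled germline) parentheses
  if (!startsWith(txt, "(")) stop("not a newick forest: ", txt)
  inner <- sub("^\\((.*)\\)[^)]*$", "\\1", txt)
  nodes <- list()
  # split a comma-separated sibling list at depth 0
  split_siblings <- function(s) {
    depth <- 0L; cuts <- integer(0)
    chars <- strsplit(s, "")[[1]]
    for (i in seq_along(chars)) {
      if (chars[i] == "(") depth <- depth + 1L
      else if (chars[i] == ")") depth <- depth - 1L
      else if (chars[i] == "," && depth == 0L) cuts <- c(cuts, i)
    }
    starts <- c(1L, cuts + 1L); ends <- c(cuts - 1L, length(chars))
    mapply(function(a, b) substr(s, a, b), starts, ends)
  }
  parse_node <- function(s, parent) {
    if (startsWith(s, "(")) {
      close <- {
        depth <- 0L; chars <- strsplit(s, "")[[1]]; pos <- NA_integer_
        for (i in seq_along(chars)) {
          if (chars[i] == "(") depth <- depth + 1L
          if (chars[i] == ")") { depth <- depth - 1L
            if (depth == 0L) { pos <- i; break } }
        }
        pos
      }
      label_part <- substr(s, close + 1L, nchar(s))
      kids <- substr(s, 2L, close - 1L)
    } else {
      label_part <- s
      kids <- NULL
    }
    bits <- strsplit(label_part, ":", fixed = TRUE)[[1]]
    id <- bits[1]
    len <- if (length(bits) > 1) as.numeric(bits[2]) else NA_real_
    nodes[[length(nodes) + 1L]] <<- data.frame(
      cluster_id = id, parent = parent, n_mutations = len,
      stringsAsFactors = FALSE)
    if (!is.null(kids)) {
      for (k in split_siblings(kids)) parse_node(k, id)
    }
  }
  for (s in split_siblings(inner)) parse_node(s, NA_character_)
  out <- do.call(rbind, nodes)
  rownames(out) <- NULL
  structure(list(nodes = out, cf = NULL), class = "clone_tree")
}
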