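#' UPGMA tree from a distance matrix
#'
#' Standard unweighted pair group method with arithmetic mean: the closest
#' pair of clusters is merged repeatedly, the new node placed at half the
#' merge distance, and distances to the merged cluster taken as
#' size-weighted arithmetic means. Ties are broken deterministically by the
#' lexicographically smallest (label, label) pair. The result is a rooted
#' ultrametric tree.
#'
#' @param dm symmetric non-negative numeric matrix with zero diagonal and
#'   row/column labels (or a `dist` object).
#' @return list of class `upgma_tree`: `labels`, `merge` (hclust-style),
#'   `height` (ultrametric node heights, i.e. merge distance / 2), and
#'   `newick` (serialized tree with branch lengths).
#' @export
upgma <- function(dm) {
  if (inherits(dm, "dist")) dm <- as.matrix(dm)
  n <- nrow(dm)
  if (n < 2) stop("need at least 2 labels")
  if (is.null(rownames(dm))) {
    rownames(dm) <- colnames(dm) <- paste0("t", seq_len(n))
  }
  if (!isTRUE(all.equal(dm, t(dm))) || any(dm < 0) ||
      any(diag(dm) != 0)) {
    stop("distance matrix must be symmetric, non-negative, zero-diagonal")
  }
  labels <- rownames(dm)
  # active clusters: index -> member leaf indices, representative label
  # (lexicographically smallest member, used for tie-breaking), node id
  # (negative = leaf, positive = internal, hclust convention), height
  active <- lapply(seq_len(n), function(i) {
    list(members = i, lab = labels[i], node = -i, h = 0)
  })
  d <- dm
  merge <- matrix(0L, n - 1L, 2L)
  height <- numeric(n - 1L)
  subtree <- as.list(paste0(gsub("([(),:;])", "_", labels)))
  for (step in seq_len(n - 1L)) {
    m <- length(active)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in (i + 1L):m) {
        dij <- d[i, j]
        li <- sort(c(active[[i]]$lab, active[[j]]$lab))
        if (is.null(best) || dij < best$d - 1e-12 ||
            (abs(dij - best$d) <= 1e-12 &&
             (li[1] < best$lab[1] ||
              (li[1] == best$lab[1] && li[2] < best$lab[2])))) {
          best <- list(i = i, j = j, d = dij, lab = li)
        }
      }
    }
    i <- best$i; j <- best$j
    h <- best$d / 2
    height[step] <- h
    merge[step, ] <- sort(c(active[[i]]$node, active[[j]]$node))
    ni <- length(active[[i]]$members)
    nj <- length(active[[j]]$members)
    newick_ij <- sprintf("(%s:%.12g,%s:%.12g)",
                         subtree[[i]], h - active[[i]]$h,
                         subtree[[j]], h - active[[j]]$h)
    # weighted-average distances to every other cluster
    keep <- setdiff(seq_len(m), c(i, j))
    nd <- matrix(0, m - 1L, m - 1L)
    if (length(keep)) {
      dk <- (ni * d[i, keep] + nj * d[j, keep]) / (ni + nj)
      nd[seq_along(keep), seq_along(keep)] <- d[keep, keep, drop = FALSE]
      nd[length(keep) + 1L, seq_along(keep)] <- dk
      nd[seq_along(keep), length(keep) + 1L] <- dk
    }
    newc <- list(members = c(active[[i]]$members, active[[j]]$members),
                 lab = min(active[[i]]$lab, active[[j]]$lab),
                 node = step, h = h)
    active <- c(active[keep], list(newc))
    subtree <- c(subtree[keep], list(newick_ij))
    d <- nd
  }
  structure(list(labels = labels, merge = merge, height = height,
                 newick = paste0(subtree[[1]], ";")),
            class = "upgma_tree")
}

#' @export
print.upgma_tree <- function(x, ...) {
  cat(sprintf("<upgma_tree: %d leaves, root height %g>\n",
              length(x$labels), max(x$height)))
  invisible(x)
}

#' Convert a UPGMA tree to an ape "phylo" object
#' @param tree an [upgma()] result.
#' @return an `ape::phylo` rooted ultrametric tree.
#' @export
as_phylo <- function(tree) {
  stopifnot(inherits(tree, "upgma_tree"))
  ape::read.tree(text = tree$newick)
}

#' Write a UPGMA tree as newick
#' @param tree an [upgma()] result.
#' @param path output file.
#' @export
write_newick <- function(tree, path) {
  writeLines(tree$newick, path)
  invisible(path)
}

#' Cut a UPGMA tree into flat clusters
#'
#' Either at a fixed ultrametric height `h` (clusters are the connected
#' leaf sets joined strictly below or at `h`) or into a fixed number `k` of
#' clusters (the `k - 1` highest merges are removed). Exactly one of `k`
#' and `h` must be given.
#'
#' @param tree an [upgma()] result.
#' @param k desired number of clusters.
#' @param h cut height (on the node-height scale, i.e. merge distance / 2).
#' @return named integer vector: cluster id per leaf label, numbered in
#'   order of first appearance.
#' @export
cut_tree <- function(tree, k = NULL, h = NULL) {
  stopifnot(inherits(tree, "upgma_tree"))
  if (is.null(k) == is.null(h)) stop("give exactly one of k, h")
  n <- length(tree$labels)
  if (!is.null(k)) {
    if (k < 1 || k > n) stop("k must be between 1 and the leaf count")
    # merges are produced in non-decreasing height order; keep the first
    # n - k of them
    nkeep <- n - k
  } else {
    nkeep <- sum(tree$height <= h)
  }
  uf <- .union_find(n)
  if (nkeep > 0) {
    for (s in seq_len(nkeep)) {
      mem <- .merge_members(tree$merge, s)
      for (x in mem[-1]) uf$union(mem[1], x)
    }
  }
  roots <- vapply(seq_len(n), uf$find, 0L)
  cl <- match(roots, unique(roots))
  stats::setNames(cl, tree$labels)
}

# leaf members of internal node s in an hclust-style merge matrix
.merge_members <- function(merge, s) {
  out <- integer(0)
  stack <- s
  while (length(stack)) {
    node <- stack[1]
    stack <- stack[-1]
    for (child in merge[node, ]) {
      if (child < 0) out <- c(out, -child) else stack <- c(stack, child)
    }
  }
  out
}

#' Tally clusters by species sharing
#'
#' Categorizes each cluster as `singleton` (one member), `one_species`
#' (several members, one species), `two_species`, `three_species`, or
#' `all_species` (all four), and tabulates cluster counts per category.
#'
#' @param clusters named integer vector from [cut_tree()] (names = member
#'   ids).
#' @param species_of named character vector mapping member id -> species.
#' @param n_species how many species count as "all" (default 4).
#' @return list with `summary` (one row per cluster: id, size, species,
#'   category) and `tally` (clusters per category).
#' @export
species_tally <- function(clusters, species_of, n_species = 4L) {
  ids <- names(clusters)
  unmapped <- setdiff(ids, names(species_of))
  if (length(unmapped)) {
    stop("no species mapping for: ", paste(utils::head(unmapped, 5),
                                           collapse = ", "))
  }
  rows <- lapply(sort(unique(clusters)), function(cl) {
    mem <- ids[clusters == cl]
    sp <- sort(unique(unname(species_of[mem])))
    category <- if (length(mem) == 1L) "singleton"
      else if (length(sp) == 1L) "one_species"
      else if (length(sp) == 2L) "two_species"
      else if (length(sp) == 3L) "three_species"
      else if (length(sp) >= n_species) "all_species"
      else "three_species"
    data.frame(cluster = cl, size = length(mem),
               species = paste(sp, collapse = "+"),
               category = category, stringsAsFactors = FALSE)
  })
  summary <- do.call(rbind, rows)
  cats <- c("singleton", "one_species", "two_species", "three_species",
            "all_species")
  tally <- data.frame(category = cats,
                      clusters = vapply(cats, function(cc)
                        sum(summary$category == cc), 0L),
                      row.names = NULL, stringsAsFactors = FALSE)
  list(summary = summary, tally = tally)
}

#' Normalized k-mer difference distance between sequences
#'
#' A lightweight alignment-free distance for self-contained tests and
#' examples: one minus the Jaccard similarity of the two k-mer sets.
#' Alignment-based amino-acid distances from an external aligner are the
#' intended production input to [upgma()].
#'
#' @param seqs named character vector of sequences.
#' @param k k-mer size.
#' @return symmetric distance matrix with zero diagonal.
#' @export
kmer_distance <- function(seqs, k = 4L) {
  nm <- names(seqs) %||% paste0("s", seq_along(seqs))
  sets <- lapply(seqs, function(s) {
    L <- nchar(s)
    if (L < k) return(character(0))
    unique(substring(s, 1:(L - k + 1L), k:L))
  })
  n <- length(seqs)
  d <- matrix(0, n, n, dimnames = list(nm, nm))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j <= i) next
      u <- length(union(sets[[i]], sets[[j]]))
      jc <- if (u == 0) 0 else length(intersect(sets[[i]], sets[[j]])) / u
      d[i, j] <- d[j, i] <- 1 - jc
    }
  }
  d
}

#' Read a TSV distance matrix
#' @param path tab-separated file, first column = labels, header = labels.
#' @return numeric matrix.
#' @export
read_distance_tsv <- function(path) {
  tb <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                          check.names = FALSE, comment.char = "#")
  as.matrix(tb)
}
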