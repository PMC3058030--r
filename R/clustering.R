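#' @title Co-occurrence clustering of significant proteins
#' @description
#' Proteins passing the significance filter for a metal are clustered by
#' their co-occurrence across fractions: Euclidean distances between raw
#' 0/1 presence vectors, Ward (variance-minimizing) linkage, and a dynamic
#' hybrid tree cut that adapts the partition depth to the branch structure
#' instead of a single fixed height. Each resulting cluster is expected to
#' contain at least one distinct metalloprotein to explain the metal-peak
#' data, so the cluster count is the framework's per-metal metalloprotein
#' estimate. A cluster's *core region* is the set of fractions in which at
#' least half of its proteins are observed.
#' @name clustering
NULL

#' Cluster significant proteins by fraction co-occurrence
#'
#' Rows of `presence` (restricted beforehand to one metal's significant
#' proteins) are put in canonical lexicographic order, pairwise Euclidean
#' distances on the Boolean vectors are computed, the tree is built with
#' Ward linkage (`hclust(method = "ward.D2")`) and cut with
#' [cut_tree_hybrid()]. Fully deterministic for fixed input and
#' parameters; row input order never matters.
#'
#' @param presence Logical protein x fraction matrix (>= 2 rows).
#' @param min_cluster_size Smallest admissible cluster (default 3); smaller
#'   branches are left unassigned (label 0).
#' @param deep_split Integer 0-4 (default 2) controlling split sensitivity:
#'   a branch splits when its top merge height reaches `3 - deep_split/2`
#'   times the median merge height inside the branch (0 = most
#'   conservative, 4 = most aggressive).
#' @param cut_height_fraction Static cut as a fraction of the maximum merge
#'   height (default 0.99).
#' @return List with `tree` (the `hclust` object) and `assignments`
#'   (named integer vector, protein -> cluster label, 0 = unassigned).
#' @export
cluster_proteins <- function(presence, min_cluster_size = 3, deep_split = 2,
                             cut_height_fraction = 0.99) {
  if (nrow(presence) < 2) {
    value_error("clustering needs at least 2 proteins (have %d)", nrow(presence))
  }
  presence <- presence[order(rownames(presence)), , drop = FALSE]
  d <- stats::dist(presence * 1, method = "euclidean")
  hc <- stats::hclust(d, method = "ward.D2")
  labels <- cut_tree_hybrid(hc, min_cluster_size = min_cluster_size,
                            deep_split = deep_split,
                            cut_height_fraction = cut_height_fraction)
  names(labels) <- rownames(presence)
  list(tree = hc, assignments = labels)
}

#' Dynamic hybrid cut of a dendrogram
#'
#' A self-contained hybrid tree cut: (1) a static cut at
#' `cut_height_fraction` times the maximum merge height separates the
#' top-level branches; (2) each branch is then evaluated recursively and
#' split at its top merge whenever that merge stands well above the
#' branch's internal cohesion — its height must reach `3 - deep_split/2`
#' times the median of all merge heights inside the branch (a branch whose
#' interior collapses at height 0 under a positive top merge always
#' splits). This ratio criterion separates chained between-cluster merges,
#' whose local height gaps are small, from the tight within-cluster merge
#' regime. (3) Leftover branches smaller than `min_cluster_size` become
#' label 0 (unassigned). Final labels are renumbered by decreasing cluster
#' size, ties broken by the smallest leaf index, so the labelling is
#' canonical. When no branch at all reaches `min_cluster_size` but the
#' tree does, the whole tree is returned as a single cluster rather than
#' dissolving into unassigned fragments.
#'
#' @param hc An `hclust` object.
#' @inheritParams cluster_proteins
#' @return Integer vector of cluster labels in leaf (input row) order.
#' @export
cut_tree_hybrid <- function(hc, min_cluster_size = 3, deep_split = 2,
                            cut_height_fraction = 0.99) {
  if (!deep_split %in% 0:4) value_error("deep_split must be an integer in 0..4")
  n <- length(hc$order)
  merge <- hc$merge
  height <- hc$height
  split_ratio <- 3 - deep_split / 2
  h_cut <- cut_height_fraction * max(height)

  node_leaves <- vector("list", n - 1)  # leaf indices under each internal node
  node_desc <- vector("list", n - 1)    # descendant merge heights, self excluded
  for (i in seq_len(n - 1)) {
    kids <- merge[i, ]
    node_leaves[[i]] <- c(
      if (kids[1] < 0) -kids[1] else node_leaves[[kids[1]]],
      if (kids[2] < 0) -kids[2] else node_leaves[[kids[2]]])
    node_desc[[i]] <- c(
      numeric(0),
      if (kids[1] > 0) c(height[kids[1]], node_desc[[kids[1]]]),
      if (kids[2] > 0) c(height[kids[2]], node_desc[[kids[2]]]))
  }

  # recursive branch splitting; `node` < 0 is a leaf, > 0 an internal node
  split_rec <- function(node) {
    if (node < 0) return(list(-node))
    h <- height[node]
    desc <- node_desc[[node]]
    cohesion <- if (length(desc) > 0) stats::median(desc) else NA_real_
    splittable <- h > 0 && length(desc) > 0 &&
      (cohesion == 0 || h / cohesion >= split_ratio)
    if (splittable) {
      return(c(split_rec(merge[node, 1]), split_rec(merge[node, 2])))
    }
    list(node_leaves[[node]])
  }

  # descend from the root; merges above the static cut always separate
  clusters <- list()
  descend <- function(node) {
    if (node < 0) { clusters[[length(clusters) + 1]] <<- -node; return(invisible()) }
    if (height[node] > h_cut) {
      descend(merge[node, 1])
      descend(merge[node, 2])
    } else {
      for (cl in split_rec(node)) clusters[[length(clusters) + 1]] <<- cl
    }
  }
  descend(n - 1)

  labels <- integer(n)
  keep <- Filter(function(cl) length(cl) >= min_cluster_size, clusters)
  if (length(keep) > 0) {
    ord <- order(-vapply(keep, length, 1L), vapply(keep, min, 1L))
    for (lab in seq_along(ord)) labels[keep[[ord[lab]]]] <- lab
  } else if (n >= min_cluster_size) {
    # the cut found no admissible branch at all: the set as a whole is the
    # only supportable cluster (a static cut always severs the root, so
    # small homogeneous trees would otherwise dissolve into fragments)
    labels[] <- 1L
  }
  labels
}

#' Cluster core regions and their pairwise overlap
#'
#' A fraction belongs to the core of cluster `c` iff at least 50% of the
#' cluster's proteins are observed in it (boundary inclusive). Overlap
#' between two clusters' cores is their Jaccard index; low overlap
#' supports reading each cluster as at least one distinct metalloprotein.
#'
#' @param presence Logical protein x fraction matrix covering the
#'   clustered proteins.
#' @param assignments Named label vector from [cluster_proteins()].
#' @return List with `core_fractions` (label -> character vector of
#'   fraction IDs) and `pairwise_core_overlap` (symmetric matrix, Jaccard,
#'   or `NULL` when fewer than 2 clusters).
#' @export
compute_cores <- function(presence, assignments) {
  labs <- sort(unique(assignments[assignments > 0]))
  cores <- lapply(labs, function(lab) {
    members <- names(assignments)[assignments == lab]
    sub <- presence[members, , drop = FALSE]
    colnames(sub)[colMeans(sub) >= 0.5]
  })
  names(cores) <- as.character(labs)
  overlap <- NULL
  if (length(labs) >= 2) {
    overlap <- matrix(0, length(labs), length(labs),
                      dimnames = list(as.character(labs), as.character(labs)))
    diag(overlap) <- 1
    for (i in seq_along(labs)) for (j in seq_along(labs)) {
      if (i >= j) next
      u <- length(union(cores[[i]], cores[[j]]))
      jac <- if (u == 0) 0 else length(intersect(cores[[i]], cores[[j]])) / u
      overlap[i, j] <- jac
      overlap[j, i] <- jac
    }
  }
  list(core_fractions = cores, pairwise_core_overlap = overlap)
}

#' Assemble the per-metal cluster report
#'
#' Bundles assignments, cluster count, core regions, core overlaps and,
#' when a peak set is supplied, which peaks each cluster touches (a peak is
#' covered by a cluster when any member protein is observed in at least
#' one of the peak's fractions).
#'
#' @param metal Metal symbol.
#' @param presence Logical matrix over the clustered proteins.
#' @param assignments Named label vector.
#' @param peakset Optional `gmpa_peakset` for `metal`.
#' @return A list of class `gmpa_cluster_report`.
#' @export
cluster_report <- function(metal, presence, assignments, peakset = NULL) {
  cores <- compute_cores(presence, assignments)
  labs <- sort(unique(assignments[assignments > 0]))
  covered <- NULL
  if (!is.null(peakset)) {
    covered <- lapply(labs, function(lab) {
      members <- names(assignments)[assignments == lab]
      frs <- colnames(presence)[colSums(presence[members, , drop = FALSE]) > 0]
      ids <- vapply(peakset$regions, function(r)
        if (length(intersect(r$fraction_ids, frs)) > 0) r$peak_id else NA_character_,
        NA_character_)
      ids[!is.na(ids)]
    })
    names(covered) <- as.character(labs)
  }
  structure(list(metal = metal, assignments = assignments,
                 n_clusters = length(labs),
                 core_fractions = cores$core_fractions,
                 pairwise_core_overlap = cores$pairwise_core_overlap,
                 covered_peaks = covered),
            class = "gmpa_cluster_report")
}

#' @export
print.gmpa_cluster_report <- function(x, ...) {
  cat(sprintf("%s: %d proteins in %d cluster(s), %d unassigned\n",
              x$metal, sum(x$assignments > 0), x$n_clusters,
              sum(x$assignments == 0)))
  invisible(x)
}

#' Predicted number of distinct metalloproteins for a metal
#'
#' The framework's estimate: the number of co-occurrence clusters, each
#' assumed to contain at least one metalloprotein to account for the
#' observed metal peaks.
#'
#' @param report A `gmpa_cluster_report`.
#' @return Integer cluster count.
#' @export
predict_metalloprotein_count <- function(report) {
  report$n_clusters
}
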