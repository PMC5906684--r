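# Dual-evidence consensus trees for clades of small, fast-diverging domains.
#
# These domains are not amenable to conventional phylogenetic methods, so
# relationships between clades are established from two independent evidence
# channels - profile-profile E-values and structure-search Z-scores recorded
# for hits between clade representatives - each clustered by single linkage,
# with the strict consensus of the two dendrograms rendered as a tree.

#' Build an evidence channel from a similarity table
#'
#' E-value tables are transformed to similarities `s = -log10(E)` clipped to
#' \[0, 300\] (the cap absorbs underflowed E = 0); Z-score tables use
#' `s = Z` clipped at 0. The matrix is symmetrized by the mean, treating a
#' one-sided missing value as the present value; cells missing in both
#' directions get similarity 0 (absence of a reported hit is weak evidence
#' of dissimilarity in both source programs). Distances are
#' `d_ij = s_max - s'_ij` with a zero diagonal.
#'
#' @param table A [similarity_table].
#' @return An object of class `evidence_channel`: list with `table`,
#'   `transform`, `symmetrization`, `similarity` and `distances`.
#' @export
build_channel <- function(table) {
  stopifnot(inherits(table, "similarity_table"))
  v <- table$values
  n <- nrow(v)
  off <- row(v) != col(v)
  if (all(is.na(v[off]))) stop_fmt("all off-diagonal entries are missing")
  transform <- if (table$measure == "evalue") "neglog10" else "identity"
  s <- if (table$measure == "evalue") {
    pmin(pmax(-log10(v), 0), 300)
  } else {
    pmax(v, 0)
  }
  sym <- matrix(0, n, n, dimnames = dimnames(v))
  for (i in seq_len(n - 1L)) {
    for (j in seq.int(i + 1L, n)) {
      ij <- s[i, j]; ji <- s[j, i]
      val <- if (is.na(ij) && is.na(ji)) 0 else mean(c(ij, ji), na.rm = TRUE)
      sym[i, j] <- sym[j, i] <- val
    }
  }
  d <- max(sym[off]) - sym
  diag(d) <- 0
  structure(list(table = table, transform = transform, symmetrization = "mean",
                 similarity = sym, distances = d),
            class = "evidence_channel")
}

#' @export
print.evidence_channel <- function(x, ...) {
  cat(sprintf("<evidence_channel> %s (%s), %d clades\n",
              x$table$measure, x$transform, length(x$table$labels)))
  invisible(x)
}

#' Single-linkage dendrogram of an evidence channel
#'
#' Standard agglomerative single linkage on the channel's distance matrix,
#' with a deterministic tie-break: among merges of equal distance, the pair
#' whose lexicographically smallest member label is smallest wins (then the
#' smaller of the two clusters' other minimum labels). This makes the Newick
#' output reproducible across runs and platforms.
#'
#' @param channel An `evidence_channel`, or a symmetric distance matrix with
#'   dimnames.
#' @return An object of class `dendrogram_sl`: list with `labels` and
#'   `merges`, a list of `n-1` entries `(a, b, height)` where `a` and `b`
#'   are the member label sets being merged. Heights are non-decreasing.
#' @export
single_linkage <- function(channel) {
  d <- if (inherits(channel, "evidence_channel")) channel$distances
       else as.matrix(channel)
  labels <- rownames(d)
  n <- length(labels)
  if (n < 2L) stop_fmt("need >= 2 leaves")
  clusters <- as.list(labels)
  # cluster-to-cluster single-linkage distances
  cd <- d
  merges <- vector("list", n - 1L)
  for (step in seq_len(n - 1L)) {
    m <- length(clusters)
    best <- NULL
    for (i in seq_len(m - 1L)) {
      for (j in seq.int(i + 1L, m)) {
        mins <- sort(c(min(clusters[[i]]), min(clusters[[j]])))
        cand <- list(i = i, j = j, h = cd[i, j], k1 = mins[1], k2 = mins[2])
        if (is.null(best) || cand$h < best$h - 1e-12 ||
            (abs(cand$h - best$h) <= 1e-12 &&
             (cand$k1 < best$k1 ||
              (cand$k1 == best$k1 && cand$k2 < best$k2)))) {
          best <- cand
        }
      }
    }
    merges[[step]] <- list(a = sort(clusters[[best$i]]),
                           b = sort(clusters[[best$j]]), height = best$h)
    new_d <- pmin(cd[best$i, ], cd[best$j, ])[-c(best$i, best$j)]
    keep <- setdiff(seq_len(m), c(best$i, best$j))
    cd <- rbind(cbind(cd[keep, keep, drop = FALSE], new_d),
                c(new_d, 0))
    clusters <- c(clusters[keep],
                  list(c(clusters[[best$i]], clusters[[best$j]])))
  }
  structure(list(labels = labels, merges = merges), class = "dendrogram_sl")
}

#' @export
print.dendrogram_sl <- function(x, ...) {
  cat(sprintf("<dendrogram_sl> %d leaves, heights %s\n", length(x$labels),
              paste(sprintf("%.3g", vapply(x$merges, `[[`, numeric(1), "height")),
                    collapse = " <= ")))
  invisible(x)
}

#' Clades (merge clusters) of a dendrogram
#'
#' @param dend A `dendrogram_sl`.
#' @return List of sorted label vectors, one per merge (the last is the full
#'   leaf set).
#' @export
dendrogram_clades <- function(dend) {
  stopifnot(inherits(dend, "dendrogram_sl"))
  lapply(dend$merges, function(m) sort(c(m$a, m$b)))
}

#' Strict consensus of two dendrograms
#'
#' The clade set of a dendrogram is every cluster formed at any merge; the
#' strict consensus keeps the clades present in both (necessarily mutually
#' compatible) and assembles them into a rooted tree. Kept internal nodes
#' carry support 2; singleton leaves are always present. With two inputs,
#' majority rule and strict consensus coincide.
#'
#' @param d1,d2 `dendrogram_sl` objects over identical leaf sets.
#' @return A [clade_tree()].
#' @export
strict_consensus <- function(d1, d2) {
  stopifnot(inherits(d1, "dendrogram_sl"), inherits(d2, "dendrogram_sl"))
  l1 <- sort(d1$labels); l2 <- sort(d2$labels)
  if (!identical(l1, l2)) {
    stop_fmt("leaf sets differ: %s",
             paste(union(setdiff(l1, l2), setdiff(l2, l1)), collapse = ", "))
  }
  key <- function(x) paste(x, collapse = "\r")
  c1 <- dendrogram_clades(d1)
  c2 <- dendrogram_clades(d2)
  shared <- c1[key_in <- vapply(c1, key, character(1)) %in%
                 vapply(c2, key, character(1))]
  shared <- shared[!duplicated(vapply(shared, key, character(1)))]
  root_set <- l1
  if (!any(vapply(shared, identical, logical(1), root_set))) {
    shared <- c(shared, list(root_set))
  }
  build <- function(members, clades) {
    if (length(members) == 1L) return(clade_node(leaf = members))
    # maximal proper sub-clades of `members`
    inside <- clades[vapply(clades, function(cl) {
      length(cl) < length(members) && all(cl %in% members)
    }, logical(1))]
    maximal <- inside[vapply(seq_along(inside), function(k) {
      !any(vapply(inside, function(other) {
        length(other) > length(inside[[k]]) && all(inside[[k]] %in% other)
      }, logical(1)))
    }, logical(1))]
    covered <- unlist(maximal)
    children <- c(lapply(maximal, build, clades = clades),
                  lapply(sort(setdiff(members, covered)),
                         function(lf) clade_node(leaf = lf)))
    # deterministic child order: by smallest contained leaf
    children <- children[order(vapply(children, function(ch) min(tree_leaves(ch)),
                                      character(1)))]
    clade_node(children = children, support = 2L)
  }
  clade_tree(build(root_set, shared))
}

#' Dual-evidence consensus clade tree
#'
#' Composition of the full pipeline: [build_channel()] on the E-value and
#' Z-score tables, [single_linkage()] on each channel, then
#' [strict_consensus()]. Render with [write_newick()].
#'
#' @param evalue_table,zscore_table [similarity_table]s over the same label
#'   set (the Z-score table is reordered to the E-value table's label order
#'   if necessary).
#' @return A [clade_tree()].
#' @export
build_clade_tree <- function(evalue_table, zscore_table) {
  stopifnot(inherits(evalue_table, "similarity_table"),
            inherits(zscore_table, "similarity_table"))
  if (!setequal(evalue_table$labels, zscore_table$labels)) {
    stop_fmt("label sets differ between the two tables")
  }
  if (!identical(evalue_table$labels, zscore_table$labels)) {
    ord <- match(evalue_table$labels, zscore_table$labels)
    zscore_table <- similarity_table(zscore_table$values[ord, ord],
                                     measure = zscore_table$measure)
  }
  strict_consensus(single_linkage(build_channel(evalue_table)),
                   single_linkage(build_channel(zscore_table)))
}
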