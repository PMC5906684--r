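# Zinc-knuckle (CPxCG) motif scanning, chelation-state calling and
# identity-based redundancy clustering.
#
# Zinc ribbons chelate a single Zn ion with two cysteines from each of two
# beta-hairpin turns ("knuckles", consensus CPxCG: Cys at motif positions 1
# and 4). Cren7/Sul7-like sequences retain between zero and four of these
# cysteines; the scanner locates knuckle-like windows and the classifier
# calls the chelation state from the best-supported pair of knuckles.

#' Scan a sequence for CPxCG-like zinc-knuckle windows
#'
#' Every 5-residue window is scored: +2 if cysteines occupy window positions
#' 1 and 4, +1 if exactly one of the two is cysteine, plus a bonus of +1 each
#' for proline at position 2 and glycine at position 5. Windows scoring >= 1
#' are reported in order of position; overlapping windows are all reported
#' (pair selection happens in [classify_chelation()]). The proline/glycine
#' contributions are bonuses rather than requirements so that degraded
#' knuckles, which the partial/lost analysis depends on, are still detected.
#'
#' @param seq A [seq_record] (length >= 5 for any hit to be possible).
#' @return Data frame with one row per hit: `start` (1-based), `pattern_score`,
#'   `cys1`/`cys2` (logical: cysteine at motif positions 1/4) and
#'   `matched_text`.
#' @examples
#' find_knuckles(seq_record("a", "MACPKCGA"))
#' @export
find_knuckles <- function(seq) {
  stopifnot(inherits(seq, "seq_record"))
  empty <- data.frame(start = integer(), pattern_score = integer(),
                      cys1 = logical(), cys2 = logical(),
                      matched_text = character(), stringsAsFactors = FALSE)
  n <- nchar(seq$residues)
  if (n < 5L) return(empty)
  chars <- strsplit(seq$residues, "")[[1]]
  starts <- seq_len(n - 4L)
  c1 <- chars[starts] == "C"
  c2 <- chars[starts + 3L] == "C"
  score <- ifelse(c1 & c2, 2L, (c1 | c2) * 1L) +
    (chars[starts + 1L] == "P") + (chars[starts + 4L] == "G")
  keep <- score >= 1L
  if (!any(keep)) return(empty)
  data.frame(start = starts[keep], pattern_score = as.integer(score[keep]),
             cys1 = c1[keep], cys2 = c2[keep],
             matched_text = vapply(starts[keep], function(s) {
               substr(seq$residues, s, s + 4L)
             }, character(1)),
             stringsAsFactors = FALSE)
}

#' Call the zinc-chelation state of a sequence
#'
#' Chooses the pair of non-overlapping knuckle hits whose starts are separated
#' by `min_spacing`..`max_spacing` residues and whose summed pattern score is
#' maximal (ties broken by the smaller start of the first knuckle, then of the
#' second). If no valid pair exists the single best hit is used, and a missing
#' second knuckle contributes zero cysteines. The state follows the cysteine
#' count: 4 = `intact`, 2-3 = `partial`, <= 1 = `lost`. Sequences shorter than
#' 5 residues yield `lost` with no hits rather than an error.
#'
#' The spacing bounds stand in for the structural requirement that the two
#' knuckles sit in the turns of hairpins beta1/beta2 and beta4/beta5 of a
#' small domain; both are configurable.
#'
#' @param seq A [seq_record].
#' @param min_spacing,max_spacing Allowed residue separation between knuckle
#'   starts (defaults 10 and 60).
#' @return An object of class `chelation_call`: list with `state`
#'   (`"intact"`, `"partial"` or `"lost"`), `n_cys` (0-4), `knuckles` (chosen
#'   hit rows, 0-2) and `spacing` (NA when fewer than two knuckles chosen).
#' @examples
#' classify_chelation(seq_record("a", "MAACPKCGAAAAAAAAAAAACPHCGAA"))
#' @export
classify_chelation <- function(seq, min_spacing = 10L, max_spacing = 60L) {
  stopifnot(min_spacing >= 1L, max_spacing >= min_spacing)
  hits <- find_knuckles(seq)
  n_cys_of <- function(rows) sum(rows$cys1) + sum(rows$cys2)
  call_of <- function(rows, spacing) {
    n_cys <- n_cys_of(rows)
    state <- if (n_cys == 4L) "intact" else if (n_cys >= 2L) "partial" else "lost"
    structure(list(state = state, n_cys = as.integer(n_cys), knuckles = rows,
                   spacing = spacing), class = "chelation_call")
  }
  if (!nrow(hits)) return(call_of(hits, NA_integer_))
  best <- NULL
  if (nrow(hits) >= 2L) {
    idx <- which(outer(hits$start, hits$start, function(a, b) {
      sp <- b - a
      sp >= 5L & sp >= min_spacing & sp <= max_spacing
    }), arr.ind = TRUE)
    if (nrow(idx)) {
      sums <- hits$pattern_score[idx[, 1]] + hits$pattern_score[idx[, 2]]
      ord <- order(-sums, hits$start[idx[, 1]], hits$start[idx[, 2]])
      best <- idx[ord[1], ]
    }
  }
  if (is.null(best)) {
    ord <- order(-hits$pattern_score, hits$start)
    return(call_of(hits[ord[1], , drop = FALSE], NA_integer_))
  }
  rows <- hits[c(best[1], best[2]), , drop = FALSE]
  call_of(rows, as.integer(hits$start[best[2]] - hits$start[best[1]]))
}

#' @export
print.chelation_call <- function(x, ...) {
  cat(sprintf("<chelation_call> %s (%d motif cysteines%s)\n", x$state, x$n_cys,
              if (is.na(x$spacing)) "" else sprintf(", knuckle spacing %d", x$spacing)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# Global alignment and redundancy clustering

#' Global alignment identity and coverage between two sequences
#'
#' Exact Needleman-Wunsch with match +1, mismatch 0 and linear gap -1, with a
#' deterministic traceback preferring diagonal, then up (gap in `b`).
#' Identity is matches over aligned column pairs (a global pairwise alignment
#' has no double-gap columns) times 100; coverage is the number of columns in
#' which both sequences have a residue, divided by the length of the longer
#' sequence. Exact dynamic programming is used instead of search heuristics:
#' inputs are desk-scale, so exactness is affordable and reproducible.
#'
#' @param a,b [seq_record] objects (non-empty).
#' @return Named list with `identity` (percent) and `coverage` (fraction).
#' @examples
#' global_align_identity(seq_record("x", "CPKCG"), seq_record("y", "CPRCG"))
#' @export
global_align_identity <- function(a, b) {
  sa <- strsplit(a$residues, "")[[1]]
  sb <- strsplit(b$residues, "")[[1]]
  m <- length(sa); n <- length(sb)
  gap <- -1
  # F[i+1, j+1] = best score aligning a[1..i], b[1..j]; rows vectorized with a
  # cummax trick for the within-row (left-gap) dependency.
  F <- matrix(0, m + 1L, n + 1L)
  F[1, ] <- gap * (0:n)
  F[, 1] <- gap * (0:m)
  jj <- seq_len(n)
  for (i in seq_len(m)) {
    s <- as.numeric(sa[i] == sb)
    u <- pmax(F[i, jj] + s, F[i, jj + 1L] + gap)  # diag, up candidates
    # left gaps (gap = -1): F[i+1, j+1] = max_{k<=j} (v_k + k) - j, where
    # v_0 is the row boundary and v_k = u[k]; a single cummax resolves the
    # within-row dependency.
    w <- cummax(c(F[i + 1L, 1L], u + jj))
    F[i + 1L, jj + 1L] <- w[jj + 1L] - jj
  }
  # deterministic traceback: diagonal, then up, then left
  i <- m; j <- n
  matches <- 0L; both <- 0L; cols <- 0L
  while (i > 0L || j > 0L) {
    cols <- cols + 1L
    if (i > 0L && j > 0L && F[i + 1L, j + 1L] == F[i, j] + (sa[i] == sb[j])) {
      matches <- matches + (sa[i] == sb[j])
      both <- both + 1L
      i <- i - 1L; j <- j - 1L
    } else if (i > 0L && F[i + 1L, j + 1L] == F[i, j + 1L] + gap) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  list(identity = 100 * matches / cols, coverage = both / max(m, n))
}

#' Clustering parameters for identity-based redundancy reduction
#'
#' Mirrors the score (S) and length (L) controls of classic BLAST-based
#' clustering: `identity_threshold` is the percent identity (S) and
#' `coverage_threshold` the fraction of the longer sequence that must be
#' aligned (L).
#'
#' @param identity_threshold Percent identity in (0, 100].
#' @param coverage_threshold Coverage fraction in (0, 1].
#' @return An object of class `cluster_params`.
#' @export
cluster_params <- function(identity_threshold = 50, coverage_threshold = 0.9) {
  stopifnot(identity_threshold > 0, identity_threshold <= 100,
            coverage_threshold > 0, coverage_threshold <= 1)
  structure(list(identity_threshold = identity_threshold,
                 coverage_threshold = coverage_threshold),
            class = "cluster_params")
}

#' Single-linkage clustering of sequences by alignment identity
#'
#' Two sequences are connected iff their [global_align_identity()] meets both
#' thresholds; clusters are the connected components. Each cluster's
#' representative is its longest member (ties broken by lexicographically
#' smallest id); clusters are sorted by decreasing size, then representative
#' id. The output always partitions the input.
#'
#' @param seqs List of [seq_record] (length >= 1).
#' @param params A [cluster_params].
#' @return List of clusters, each a list with `representative` (id) and
#'   `members` (character vector of ids, representative included).
#' @export
cluster_by_identity <- function(seqs, params = cluster_params()) {
  stopifnot(length(seqs) >= 1L, inherits(params, "cluster_params"))
  ids <- vapply(seqs, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop_fmt("duplicate sequence id '%s'", ids[duplicated(ids)][1])
  n <- length(seqs)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (find(i) == find(j)) next
        al <- global_align_identity(seqs[[i]], seqs[[j]])
        if (al$identity >= params$identity_threshold &&
            al$coverage >= params$coverage_threshold) {
          parent[find(i)] <- find(j)
        }
      }
    }
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lens <- vapply(seqs, function(s) nchar(s$residues), integer(1))
  clusters <- lapply(split(seq_len(n), comp), function(members) {
    ord <- order(-lens[members], ids[members])
    list(representative = ids[members[ord[1]]], members = sort(ids[members]))
  })
  reps <- vapply(clusters, `[[`, character(1), "representative")
  sizes <- vapply(clusters, function(cl) length(cl$members), integer(1))
  unname(clusters[order(-sizes, reps)])
}
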