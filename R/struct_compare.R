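# Pairwise structural superposition: least-squares rigid-body fit on given
# correspondences (Kabsch), TM-score scoring, and a deterministic
# fragment-seeded alignment search in the spirit of TM-align.
#
# The TM-score of an alignment of lali residue pairs is
#   TM = (1/L_norm) * sum_i 1 / (1 + (d_i/d0)^2),
#   d0 = max(0.5, 1.24 * (L_norm - 15)^(1/3) - 1.8),
# with distances d_i taken under the superposition that maximizes the sum.
# The d0 floor of 0.5 A matters for the ~50-60 residue domains studied here.

as_ca <- function(x) {
  if (inherits(x, "structure_model")) x$ca else as.matrix(x)
}

#' TM-score normalization distance d0
#' @param l_norm Normalization length.
#' @return d0 in angstrom.
#' @export
tm_d0 <- function(l_norm) {
  stopifnot(l_norm >= 1)
  cbrt <- function(x) sign(x) * abs(x)^(1 / 3)
  max(0.5, 1.24 * cbrt(l_norm - 15) - 1.8)
}

superposition_result <- function(rotation, translation, aligned_pairs, rmsd,
                                 tm, lali, normalised_by) {
  structure(list(rotation = rotation, translation = translation,
                 aligned_pairs = aligned_pairs, rmsd = rmsd, tm_score = tm,
                 lali = lali, normalised_by = normalised_by),
            class = "superposition_result")
}

#' @export
print.superposition_result <- function(x, ...) {
  cat(sprintf("<superposition> TM = %.4f (norm. by %d), RMSD = %.3f A, lali = %d\n",
              x$tm_score, x$normalised_by, x$rmsd, x$lali))
  invisible(x)
}

# Core least-squares fit: returns R, t such that b %*% t(R) + t ~ a.
kabsch_fit <- function(a, b) {
  ca_m <- colMeans(a); cb_m <- colMeans(b)
  ac <- sweep(a, 2, ca_m); bc <- sweep(b, 2, cb_m)
  h <- t(bc) %*% ac
  sv <- svd(h)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  list(R = R, t = as.numeric(ca_m - R %*% cb_m))
}

apply_rt <- function(b, fit) {
  sweep(b %*% t(fit$R), 2, fit$t, `+`)
}

#' Optimal rigid-body superposition on given correspondences
#'
#' Least-squares (RMSD-minimizing) rotation and translation of `coords_b`
#' onto `coords_a` under the identity correspondence, computed by singular
#' value decomposition with the reflection excluded (Kabsch). Degenerate
#' input (fewer than 3 points, or collinear points) is an error.
#'
#' @param coords_a,coords_b n x 3 coordinate matrices (or
#'   [structure_model]s, whose C-alpha coordinates are used), equal n >= 3.
#' @return A `superposition_result`; its `tm_score` is evaluated at the
#'   least-squares superposition, normalized by n.
#' @export
kabsch_superpose <- function(coords_a, coords_b) {
  a <- as_ca(coords_a); b <- as_ca(coords_b)
  if (nrow(a) != nrow(b)) stop_fmt("coordinate sets differ in length")
  n <- nrow(a)
  if (n < 3L) stop_fmt("need >= 3 points to superpose (got %d)", n)
  if (!all(is.finite(a)) || !all(is.finite(b))) stop_fmt("non-finite coordinates")
  rank2 <- function(m) {
    sv <- svd(sweep(m, 2, colMeans(m)))$d
    sv[2] > 1e-8 * max(sv[1], 1)
  }
  if (!rank2(a) || !rank2(b)) stop_fmt("degenerate (collinear) point set")
  fit <- kabsch_fit(a, b)
  d <- row_norms(a - apply_rt(b, fit))
  d0 <- tm_d0(n)
  superposition_result(fit$R, fit$t,
                       data.frame(a = seq_len(n), b = seq_len(n)),
                       rmsd = sqrt(mean(d^2)),
                       tm = sum(1 / (1 + (d / d0)^2)) / n,
                       lali = n, normalised_by = n)
}

# TM-maximizing superposition for a FIXED set of aligned pairs: seeded by
# contiguous pair windows, iteratively re-fit on the close pairs. Returns
# list(tm, R, t, d).
tm_superpose <- function(a, b, pa, pb, l_norm) {
  d0 <- tm_d0(l_norm)
  A <- a[pa, , drop = FALSE]
  B <- b[pb, , drop = FALSE]
  L <- nrow(A)
  if (L == 1L) {
    return(list(tm = 1 / l_norm, R = diag(3), t = as.numeric(A - B),
                d = 0))
  }
  if (L == 2L) {
    gap <- abs(sqrt(sum((A[2, ] - A[1, ])^2)) - sqrt(sum((B[2, ] - B[1, ])^2))) / 2
    return(list(tm = 2 / (1 + (gap / d0)^2) / l_norm, R = diag(3),
                t = c(0, 0, 0), d = rep(gap, 2)))
  }
  best <- NULL
  lens <- sort(unique(pmax(3L, c(L, ceiling(L / 2), ceiling(L / 4), 4L))),
               decreasing = TRUE)
  lens <- lens[lens <= L]
  for (len in lens) {
    starts <- unique(c(seq(1L, L - len + 1L, by = max(1L, len %/% 2L)),
                       L - len + 1L))
    for (s0 in starts) {
      sel <- s0:(s0 + len - 1L)
      for (iter in 1:30) {
        fit <- tryCatch(kabsch_fit(A[sel, , drop = FALSE], B[sel, , drop = FALSE]),
                        error = function(e) NULL)
        if (is.null(fit)) break
        d <- row_norms(A - apply_rt(B, fit))
        tm <- sum(1 / (1 + (d / d0)^2)) / l_norm
        if (is.null(best) || tm > best$tm + 1e-12) {
          best <- list(tm = tm, R = fit$R, t = fit$t, d = d)
        }
        new_sel <- which(d < max(d0, 1.5))
        if (length(new_sel) < 3L) new_sel <- order(d)[1:3]
        if (identical(new_sel, sel)) break
        sel <- new_sel
      }
    }
  }
  best
}

#' TM-score of an alignment between two structures
#'
#' Evaluates the TM-score formula for the given aligned pairs, with distances
#' taken under the superposition that maximizes the score (found by seeded
#' iterative refinement on the close pairs).
#'
#' @param coords_a,coords_b Coordinate matrices or [structure_model]s.
#' @param pairs Data frame with columns `a` and `b` (residue indices);
#'   default is the identity correspondence over all residues.
#' @param normalise_length Normalization length `L_norm` (>= 1).
#' @return TM-score in (0, 1].
#' @examples
#' m <- simulate_znr_structure(znr_sim_spec("type2"))
#' tm_score(m, m)  # 1 exactly
#' @export
tm_score <- function(coords_a, coords_b, pairs = NULL,
                     normalise_length = NULL) {
  a <- as_ca(coords_a); b <- as_ca(coords_b)
  if (is.null(pairs)) {
    if (nrow(a) != nrow(b)) stop_fmt("identity pairing needs equal lengths")
    pairs <- data.frame(a = seq_len(nrow(a)), b = seq_len(nrow(a)))
  }
  if (!nrow(pairs)) stop_fmt("need at least one aligned pair")
  if (is.null(normalise_length)) normalise_length <- nrow(a)
  tm_superpose(a, b, pairs$a, pairs$b, normalise_length)$tm
}

# Vectorized global alignment with affine gaps (open cost `gap_open`,
# extension free) on a similarity matrix. Returns the aligned index pairs.
nw_affine <- function(S, gap_open = 0.6) {
  la <- nrow(S); lb <- ncol(S)
  NEG <- -1e18
  M <- matrix(NEG, la + 1L, lb + 1L)
  X <- matrix(NEG, la + 1L, lb + 1L)  # gap in b (consumes a)
  Y <- matrix(NEG, la + 1L, lb + 1L)  # gap in a (consumes b)
  M[1, 1] <- 0
  X[2:(la + 1L), 1] <- -gap_open
  Y[1, 2:(lb + 1L)] <- -gap_open
  jc <- seq_len(lb)
  for (i in seq_len(la)) {
    prev_best <- pmax(M[i, ], X[i, ], Y[i, ])
    M[i + 1L, jc + 1L] <- S[i, ] + prev_best[jc]
    X[i + 1L, ] <- pmax(M[i, ] - gap_open, X[i, ], Y[i, ] - gap_open)
    ax <- pmax(M[i + 1L, ], X[i + 1L, ]) - gap_open
    Y[i + 1L, jc + 1L] <- cummax(ax[jc])
  }
  # traceback, preferring M, then X, then Y at every tie
  tol <- 1e-9
  ii <- la + 1L; jj <- lb + 1L
  vals <- c(M[ii, jj], X[ii, jj], Y[ii, jj])
  state <- which(vals >= max(vals) - tol)[1]
  pa <- integer(0); pb <- integer(0)
  while (ii > 1L || jj > 1L) {
    if (state == 1L) {
      pa <- c(ii - 1L, pa); pb <- c(jj - 1L, pb)
      tgt <- M[ii, jj] - S[ii - 1L, jj - 1L]
      ii <- ii - 1L; jj <- jj - 1L
      cand <- c(M[ii, jj], X[ii, jj], Y[ii, jj])
      state <- which(abs(cand - tgt) <= tol)[1]
    } else if (state == 2L) {
      tgt <- X[ii, jj]
      ii <- ii - 1L
      cand <- c(M[ii, jj] - gap_open, X[ii, jj], Y[ii, jj] - gap_open)
      state <- which(abs(cand - tgt) <= tol)[1]
    } else {
      tgt <- Y[ii, jj]
      jj <- jj - 1L
      cand <- c(M[ii, jj] - gap_open, X[ii, jj] - gap_open, Y[ii, jj])
      state <- which(abs(cand - tgt) <= tol)[1]
    }
    if (ii == 1L && jj == 1L) break
    if (is.na(state)) stop_fmt("traceback failed")  # nocov
  }
  data.frame(a = pa, b = pb)
}

#' Deterministic fragment-seeded structural alignment
#'
#' TM-align-style search. Seeds are gapless threadings of fragments of `a`
#' over `b` (fragment lengths: the full common length, its half, and 20) at
#' every relative offset, plus a secondary-structure seed matching strand
#' segments from [assign_strands()] in order. Each seed is refined by
#' iterating: superpose on the current pairs, score every residue pair
#' `s_ij = 1/(1 + (d_ij/d0)^2)`, realign by global dynamic programming with
#' affine gaps (open 0.6, extension free), and re-superpose on pairs closer
#' than `2*d0`; until the alignment is unchanged (at most 30 rounds). The
#' result with the highest TM-score wins (ties: more aligned pairs, then the
#' earlier seed). Everything is deterministic: no stochastic restarts.
#'
#' @param a,b [structure_model]s with >= 10 residues each.
#' @param normalise `"first"`, `"second"` or `"shorter"`: which length
#'   normalizes the TM-score.
#' @return A `superposition_result`: TM-score and its superposition
#'   (rotation/translation), aligned pairs (indices into `a` and `b`), and
#'   the least-squares RMSD over the aligned pairs.
#' @export
align_structures <- function(a, b, normalise = c("first", "second", "shorter")) {
  normalise <- match.arg(normalise)
  A <- as_ca(a); B <- as_ca(b)
  la <- nrow(A); lb <- nrow(B)
  if (la < 10L || lb < 10L) {
    stop_fmt("both structures need >= 10 residues (got %d, %d)", la, lb)
  }
  l_norm <- switch(normalise, first = la, second = lb, shorter = min(la, lb))
  d0 <- tm_d0(l_norm)
  lmin <- min(la, lb)
  seeds <- list()
  for (len in unique(pmin(lmin, c(lmin, lmin %/% 2L, 20L)))) {
    if (len < 5L) next
    stride <- if (len == lmin) 1L else max(1L, len %/% 4L)
    for (k in seq.int(-(lb - len), la - len, by = stride)) {
      i0 <- max(1L, 1L + k); j0 <- max(1L, 1L - k)
      lk <- min(la - i0 + 1L, lb - j0 + 1L, len)
      if (lk < 5L) next
      seeds[[length(seeds) + 1L]] <-
        data.frame(a = i0:(i0 + lk - 1L), b = j0:(j0 + lk - 1L))
    }
  }
  ss_seed <- tryCatch({
    sa <- if (inherits(a, "structure_model")) assign_strands(a) else NULL
    sb <- if (inherits(b, "structure_model")) assign_strands(b) else NULL
    if (!is.null(sa) && !is.null(sb) && nrow(sa) && nrow(sb)) {
      ns <- min(nrow(sa), nrow(sb))
      pa <- integer(0); pb <- integer(0)
      for (s in seq_len(ns)) {
        l <- min(sa$end[s] - sa$start[s], sb$end[s] - sb$start[s]) + 1L
        pa <- c(pa, sa$start[s]:(sa$start[s] + l - 1L))
        pb <- c(pb, sb$start[s]:(sb$start[s] + l - 1L))
      }
      if (length(pa) >= 3L) data.frame(a = pa, b = pb) else NULL
    } else NULL
  }, error = function(e) NULL)
  if (!is.null(ss_seed)) seeds <- c(seeds, list(ss_seed))
  best <- NULL
  for (seed in seeds) {
    pairs <- seed
    fit <- tryCatch(kabsch_fit(A[pairs$a, , drop = FALSE],
                               B[pairs$b, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(fit)) next
    for (iter in 1:30) {
      Bt <- apply_rt(B, fit)
      D2 <- outer(rowSums(A^2), rep(1, lb)) +
        outer(rep(1, la), rowSums(Bt^2)) - 2 * A %*% t(Bt)
      D2[D2 < 0] <- 0
      S <- 1 / (1 + D2 / d0^2)
      new_pairs <- nw_affine(S)
      d <- row_norms(A[new_pairs$a, , drop = FALSE] -
                       Bt[new_pairs$b, , drop = FALSE])
      fit_sel <- which(d < 2 * d0)
      if (length(fit_sel) < 3L) fit_sel <- seq_len(nrow(new_pairs))
      fit2 <- tryCatch(kabsch_fit(A[new_pairs$a[fit_sel], , drop = FALSE],
                                  B[new_pairs$b[fit_sel], , drop = FALSE]),
                       error = function(e) NULL)
      if (is.null(fit2)) break
      done <- identical(new_pairs, pairs)
      pairs <- new_pairs
      fit <- fit2
      if (done) break
    }
    res <- tm_superpose(A, B, pairs$a, pairs$b, l_norm)
    if (is.null(best) || res$tm > best$res$tm + 1e-12 ||
        (abs(res$tm - best$res$tm) <= 1e-12 && nrow(pairs) > nrow(best$pairs))) {
      best <- list(res = res, pairs = pairs)
    }
  }
  if (is.null(best)) stop_fmt("alignment search failed")  # nocov
  ls_fit <- kabsch_fit(A[best$pairs$a, , drop = FALSE],
                       B[best$pairs$b, , drop = FALSE])
  rmsd <- sqrt(mean(row_norms(A[best$pairs$a, , drop = FALSE] -
                                apply_rt(B, ls_fit)[best$pairs$b, , drop = FALSE])^2))
  superposition_result(best$res$R, best$res$t, best$pairs, rmsd,
                       best$res$tm, nrow(best$pairs), l_norm)
}
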