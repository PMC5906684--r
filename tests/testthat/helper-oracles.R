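# Independent oracles used across the suite. These deliberately share no
# code with the implementation they check.

# Exhaustive 5-residue window scan for CPxCG-like knuckles.
brute_knuckles <- function(residues) {
  n <- nchar(residues)
  out <- data.frame(start = integer(), pattern_score = integer())
  if (n < 5) return(out)
  for (s in 1:(n - 4)) {
    w <- substr(residues, s, s + 4)
    c1 <- substr(w, 1, 1) == "C"
    c2 <- substr(w, 4, 4) == "C"
    score <- (if (c1 && c2) 2 else if (c1 || c2) 1 else 0) +
      (substr(w, 2, 2) == "P") + (substr(w, 5, 5) == "G")
    if (score >= 1) {
      out <- rbind(out, data.frame(start = s, pattern_score = score))
    }
  }
  out
}

# Plain cell-by-cell Needleman-Wunsch (match +1 / mismatch 0 / gap -1) with
# the same diagonal-then-up traceback preference, written as an explicit
# double loop (no vectorized tricks).
oracle_align <- function(sa, sb) {
  a <- strsplit(sa, "")[[1]]
  b <- strsplit(sb, "")[[1]]
  m <- length(a); n <- length(b)
  F <- matrix(0, m + 1, n + 1)
  F[1, ] <- -(0:n); F[, 1] <- -(0:m)
  for (i in 1:m) {
    for (j in 1:n) {
      F[i + 1, j + 1] <- max(F[i, j] + (a[i] == b[j]),
                             F[i, j + 1] - 1,
                             F[i + 1, j] - 1)
    }
  }
  i <- m; j <- n; matches <- 0; both <- 0; cols <- 0
  while (i > 0 || j > 0) {
    cols <- cols + 1
    if (i > 0 && j > 0 && F[i + 1, j + 1] == F[i, j] + (a[i] == b[j])) {
      matches <- matches + (a[i] == b[j]); both <- both + 1
      i <- i - 1; j <- j - 1
    } else if (i > 0 && F[i + 1, j + 1] == F[i, j + 1] - 1) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(identity = 100 * matches / cols, coverage = both / max(m, n))
}

# Random amino-acid sequence (optionally gap-free alphabet tweaks).
random_seq <- function(n, letters = strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]) {
  paste(sample(letters, n, replace = TRUE), collapse = "")
}

# Idealized alpha-helix C-alpha trace: rise 1.5 A, radius 2.3 A, with the
# turn angle fixed by the 3.8 A consecutive spacing.
helix_trace <- function(n) {
  omega <- 2 * asin(sqrt(3.8^2 - 1.5^2) / (2 * 2.3))
  k <- seq_len(n)
  cbind(2.3 * cos(omega * k), 2.3 * sin(omega * k), 1.5 * k)
}

# Minimum RMSD over a large sample of rotations (quaternion
# parameterization), each with its optimal translation (centroid match).
# Half the budget samples uniformly; the other half samples near the best
# quaternion found so far, so the minimum closes in on the optimum.
quat_min_rmsd <- function(a, b, n_samples = 1e6, chunk = 1e5) {
  ac <- sweep(a, 2, colMeans(a))
  bc <- sweep(b, 2, colMeans(b))
  np <- nrow(a)
  best <- Inf
  best_q <- c(1, 0, 0, 0)
  done <- 0
  while (done < n_samples) {
    k <- min(chunk, n_samples - done)
    q <- matrix(rnorm(4 * k), k, 4)
    if (done >= n_samples / 2) {  # local refinement rounds
      q <- matrix(best_q, k, 4, byrow = TRUE) + 0.02 * q
    }
    q <- q / sqrt(rowSums(q^2))
    w <- q[, 1]; v <- q[, 2:4]
    ss <- numeric(k)
    for (p in seq_len(np)) {
      pv <- bc[p, ]
      # v x p
      cr1 <- cbind(v[, 2] * pv[3] - v[, 3] * pv[2],
                   v[, 3] * pv[1] - v[, 1] * pv[3],
                   v[, 1] * pv[2] - v[, 2] * pv[1])
      # v x (v x p + w p)
      t1 <- cr1 + w * matrix(pv, k, 3, byrow = TRUE)
      cr2 <- cbind(v[, 2] * t1[, 3] - v[, 3] * t1[, 2],
                   v[, 3] * t1[, 1] - v[, 1] * t1[, 3],
                   v[, 1] * t1[, 2] - v[, 2] * t1[, 1])
      rp <- matrix(pv, k, 3, byrow = TRUE) + 2 * cr2
      ss <- ss + rowSums((rp - matrix(ac[p, ], k, 3, byrow = TRUE))^2)
    }
    if (min(ss) < best) {
      best <- min(ss)
      best_q <- q[which.min(ss), ]
    }
    done <- done + k
  }
  sqrt(best / np)
}

# All clades of a dendrogram as a canonical character set.
clade_keys <- function(dend) {
  vapply(dendrogram_clades(dend), paste, character(1), collapse = "|")
}

tree_clade_keys <- function(tree) {
  vapply(tree_clades(tree), paste, character(1), collapse = "|")
}

# Random alignment object for the cage-statistic oracle.
random_alignment <- function(n_rows, n_cols, gap_prob = 0.15) {
  letters20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  recs <- lapply(seq_len(n_rows), function(i) {
    ch <- sample(letters20, n_cols, replace = TRUE)
    ch[runif(n_cols) < gap_prob] <- "-"
    if (all(ch == "-")) ch[1] <- "A"
    seq_record(paste0("r", i), paste(ch, collapse = ""), allow_gap = TRUE)
  })
  alignment(recs, family_label = "rand")
}
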