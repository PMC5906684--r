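# Synthetic-data generators.
#
# Each generator emulates the statistical or geometric structure one analysis
# stage assumes: family MSAs with controlled aromatic composition at the cage
# columns, Cren7-like sequences carrying 0-4 knuckle cysteines, idealized
# C-alpha traces for the three zinc-ribbon topology types, and paired
# E-value/Z-score matrices with planted clade structure. All generators are
# reproducible under a fixed seed and produce objects satisfying the
# invariants of their target types.

# ---------------------------------------------------------------------------
# Cage alignments

#' Specification for a simulated cage alignment
#'
#' @param n_sequences,n_columns Alignment dimensions.
#' @param cage_columns Five distinct column indices hosting the aromatic cage.
#' @param aromatic_prob Probability that a non-gap cage-column cell is
#'   aromatic (drawn uniformly from Y/W/F/H; non-aromatic cells are uniform
#'   over the remaining 16 letters).
#' @param gap_prob Per-cell gap probability.
#' @param seed RNG seed.
#' @return An object of class `cage_sim_spec`.
#' @export
cage_sim_spec <- function(n_sequences = 200L, n_columns = 60L,
                          cage_columns = c(10L, 20L, 30L, 40L, 50L),
                          aromatic_prob = 0.8, gap_prob = 0.05, seed = 1L) {
  stopifnot(is_count(n_sequences, 2L), is_count(n_columns),
            is_prob(aromatic_prob), is_prob(gap_prob))
  cage_columns <- as.integer(cage_columns)
  if (length(cage_columns) != 5L || anyDuplicated(cage_columns) ||
      any(cage_columns < 1L) || any(cage_columns > n_columns)) {
    stop_fmt("cage_columns must be 5 distinct indices within 1..%d", n_columns)
  }
  structure(list(n_sequences = as.integer(n_sequences),
                 n_columns = as.integer(n_columns),
                 cage_columns = sort(cage_columns),
                 aromatic_prob = aromatic_prob, gap_prob = gap_prob,
                 seed = as.integer(seed)),
            class = "cage_sim_spec")
}

#' Simulate a family alignment with controlled cage-column composition
#'
#' Cage columns draw aromatic residues (uniform over Y/W/F/H) with probability
#' `aromatic_prob` and non-aromatic residues (uniform over the other 16
#' letters) otherwise; all other columns are uniform over the 20 amino acids;
#' every cell is independently gapped with probability `gap_prob`.
#'
#' @param spec A [cage_sim_spec].
#' @return An [alignment] with rows `s1..sN` and family label
#'   `"simulated-cage"`.
#' @export
simulate_cage_msa <- function(spec) {
  stopifnot(inherits(spec, "cage_sim_spec"))
  non_aromatic <- setdiff(AA20, AROMATIC)
  with_seed(spec$seed, {
    m <- matrix("", spec$n_sequences, spec$n_columns)
    for (j in seq_len(spec$n_columns)) {
      if (j %in% spec$cage_columns) {
        is_arom <- stats::runif(spec$n_sequences) < spec$aromatic_prob
        col <- ifelse(is_arom,
                      sample(AROMATIC, spec$n_sequences, replace = TRUE),
                      sample(non_aromatic, spec$n_sequences, replace = TRUE))
      } else {
        col <- sample(AA20, spec$n_sequences, replace = TRUE)
      }
      gap <- stats::runif(spec$n_sequences) < spec$gap_prob
      col[gap] <- "-"
      m[, j] <- col
    }
    recs <- lapply(seq_len(spec$n_sequences), function(i) {
      seq_record(paste0("s", i), paste(m[i, ], collapse = ""), allow_gap = TRUE)
    })
    alignment(recs, family_label = "simulated-cage")
  })
}

# ---------------------------------------------------------------------------
# Knuckle sequences

#' Specification for simulated knuckle-bearing sequences
#'
#' Each sequence is flank + knuckle1 + spacer + knuckle2 + flank, knuckles
#' templated on C-P-x-C-G. `partial` deletes 1-2 of the four cysteines
#' (replaced by serine), `lost` deletes 3-4. Flanks, spacers, the motif `x`
#' and substitutions are drawn from the 19 non-cysteine amino acids, so the
#' motif cysteines are the only cysteines and the planted state is exact.
#'
#' @param n_sequences Number of sequences.
#' @param chelation_mix Named proportions over intact/partial/lost (sum 1).
#' @param spacer_range Min/max residues between the knuckles (knuckle starts
#'   are separated by 5 + spacer, which must stay within the scanner's
#'   spacing bounds).
#' @param mutation_rate Per-position substitution probability outside the
#'   motif cysteine positions.
#' @param flank_range Min/max flank length on each side.
#' @param seed RNG seed.
#' @return An object of class `knuckle_sim_spec`.
#' @export
knuckle_sim_spec <- function(n_sequences = 300L,
                             chelation_mix = c(intact = 0.4, partial = 0.3, lost = 0.3),
                             spacer_range = c(8L, 30L),
                             mutation_rate = 0,
                             flank_range = c(3L, 12L),
                             seed = 1L) {
  stopifnot(is_count(n_sequences),
            all(sort(names(chelation_mix)) == c("intact", "lost", "partial")),
            abs(sum(chelation_mix) - 1) < 1e-9, all(chelation_mix >= 0),
            length(spacer_range) == 2L, spacer_range[1] >= 5L,
            spacer_range[2] >= spacer_range[1], spacer_range[2] + 5L <= 60L,
            is_prob(mutation_rate),
            length(flank_range) == 2L, flank_range[1] >= 0L,
            flank_range[2] >= flank_range[1])
  structure(list(n_sequences = as.integer(n_sequences),
                 chelation_mix = chelation_mix,
                 spacer_range = as.integer(spacer_range),
                 mutation_rate = mutation_rate,
                 flank_range = as.integer(flank_range),
                 seed = as.integer(seed)),
            class = "knuckle_sim_spec")
}

# Largest-remainder quota so realized counts match proportions exactly.
quota_counts <- function(n, props) {
  base <- floor(n * props)
  rem <- n - sum(base)
  if (rem > 0) {
    frac <- n * props - base
    top <- order(-frac, names(props))[seq_len(rem)]
    base[top] <- base[top] + 1
  }
  as.integer(base)
}

#' Simulate Cren7-like sequences with planted chelation states
#'
#' @param spec A [knuckle_sim_spec].
#' @return List with `records` (list of [seq_record], ids `k1..kN`) and
#'   `true_states` (character vector over intact/partial/lost, assigned by
#'   deterministic quota in sequence order).
#' @export
simulate_knuckle_sequences <- function(spec) {
  stopifnot(inherits(spec, "knuckle_sim_spec"))
  no_cys <- setdiff(AA20, "C")
  counts <- quota_counts(spec$n_sequences,
                         spec$chelation_mix[c("intact", "partial", "lost")])
  states <- rep(c("intact", "partial", "lost"), counts)
  with_seed(spec$seed, {
    records <- lapply(seq_len(spec$n_sequences), function(i) {
      f1 <- sample(no_cys, sample(spec$flank_range[1]:spec$flank_range[2], 1),
                   replace = TRUE)
      f2 <- sample(no_cys, sample(spec$flank_range[1]:spec$flank_range[2], 1),
                   replace = TRUE)
      spacer <- sample(no_cys, sample(spec$spacer_range[1]:spec$spacer_range[2], 1),
                       replace = TRUE)
      k1 <- c("C", "P", sample(no_cys, 1), "C", "G")
      k2 <- c("C", "P", sample(no_cys, 1), "C", "G")
      n_del <- switch(states[i], intact = 0L,
                      partial = sample(1:2, 1), lost = sample(3:4, 1))
      if (n_del > 0L) {
        del <- sample(4L, n_del)  # cys 1/2 in knuckle1, 3/4 in knuckle2
        k1[c(1L, 4L)[del[del <= 2L]]] <- "S"
        k2[c(1L, 4L)[del[del > 2L] - 2L]] <- "S"
      }
      chars <- c(f1, k1, spacer, k2, f2)
      cys_pos <- length(f1) + c(1L, 4L, 5L + length(spacer) + c(1L, 4L))
      if (spec$mutation_rate > 0) {
        mut <- which(stats::runif(length(chars)) < spec$mutation_rate)
        mut <- setdiff(mut, cys_pos)
        for (p in mut) chars[p] <- sample(setdiff(no_cys, chars[p]), 1)
      }
      seq_record(paste0("k", i), paste(chars, collapse = ""))
    })
    list(records = records, true_states = states)
  })
}

# ---------------------------------------------------------------------------
# Idealized zinc-ribbon structures
#
# Strands are pleated zig-zags with consecutive C-alpha spacing 3.8 A (rise
# 3.35 A along the strand axis, +-0.9 A pleat), antiparallel partners at
# 4.8 A sheet spacing: textbook beta geometry. Turns and linkers are chains
# of 3.8 A chords on tight circular arcs, curved strongly enough that their
# residues never satisfy the strand-detection distance windows.

ZNR_RISE <- 3.35
ZNR_PLEAT <- sqrt(3.8^2 - ZNR_RISE^2) / 2
ZNR_SHEET <- 4.8

# n points along +-z from z0, pleated in y (or rotated later). `phase` flips
# the pleat so that facing residues of paired antiparallel strands are in
# register (contact rungs at the 4.8 A sheet spacing, as in real sheets).
vert_strand <- function(n, x, y, z0 = 0, dir = 1, phase = 1) {
  k <- seq_len(n)
  cbind(x, y + ZNR_PLEAT * phase * (-1)^k, z0 + dir * ZNR_RISE * (k - 1))
}

# k intermediate points between P and Q, all chords exactly 3.8 A, on the
# circular arc (bulging toward `bulge`) whose chord count forces enough
# curvature that arc residues are never strand-like.
arc_points <- function(P, Q, k, bulge) {
  chord <- 3.8
  v <- Q - P
  c_len <- sqrt(sum(v^2))
  if (c_len >= chord * (k + 1)) {
    stop_fmt("cannot bridge %.1f A with %d chords of %.1f A", c_len, k + 1, chord)
  }
  e1 <- v / c_len
  b <- bulge - sum(bulge * e1) * e1
  if (sqrt(sum(b^2)) < 1e-8) stop_fmt("bulge direction parallel to chord")
  e2 <- b / sqrt(sum(b^2))
  f <- function(theta) sin((k + 1) * theta / 2) / sin(theta / 2) - c_len / chord
  theta <- stats::uniroot(f, c(1e-6, 2 * pi / (k + 1) - 1e-6), tol = 1e-12)$root
  r <- chord / 2 / sin(theta / 2)
  beta <- (k + 1) * theta / 2
  M <- (P + Q) / 2
  Cc <- M - e2 * (r * cos(beta))     # signed: major arcs put the center bulge-side
  phi_p <- atan2(r * cos(beta), -c_len / 2)
  pts_at <- function(s) {
    t(vapply(seq_len(k), function(m) {
      phi <- phi_p - s * m * theta
      Cc + r * (cos(phi) * e1 + sin(phi) * e2)
    }, numeric(3)))
  }
  ends_at <- function(s) {
    phi <- phi_p - s * (k + 1) * theta
    Cc + r * (cos(phi) * e1 + sin(phi) * e2)
  }
  for (s in c(1, -1)) {
    if (sqrt(sum((ends_at(s) - Q)^2)) < 1e-6) return(pts_at(s))
  }
  stop_fmt("arc construction failed")  # nocov
}

# Curved multi-arc path between distant points; every consecutive distance is
# exactly 3.8 A and every residue is strongly curved (never strand-like).
bridge_path <- function(P, Q, bulge, max_seg = 7) {
  c_len <- sqrt(sum((Q - P)^2))
  m <- max(1L, ceiling(c_len / max_seg))
  way <- t(sapply(0:m, function(i) P + (Q - P) * i / m))
  pts <- NULL
  for (i in seq_len(m)) {
    seg <- arc_points(way[i, ], way[i + 1, ], k = 3L,
                      bulge = bulge * (-1)^(i - 1))
    pts <- rbind(pts, seg, if (i < m) way[i + 1, ])
  }
  pts
}

rot_z90 <- function(pts, cx, cy) {
  cbind(cx - (pts[, 2] - cy), cy + (pts[, 1] - cx), pts[, 3])
}

# Assemble the chain for one topology type. Returns ca, aa, strand index
# ranges and the indices of the four knuckle cysteines.
znr_template <- function(type, n) {
  ztop <- ZNR_RISE * (n - 1)
  ez <- c(0, 0, 1); ex <- c(1, 0, 0)
  strand_aa <- function(n) rep_len(c("V", "T"), n)
  segs <- list()   # list of (pts, aa, is_strand)
  add <- function(pts, aa, is_strand = FALSE) {
    segs[[length(segs) + 1L]] <<- list(pts = pts, aa = aa, is_strand = is_strand)
  }
  fac <- (-1)^(n + 1)  # in-register pleat phase for an antiparallel partner
  hairpin <- function(x1, x2, y, knuckle) {
    a <- vert_strand(n, x1, y, dir = 1)
    b <- vert_strand(n, x2, y, z0 = ztop, dir = -1, phase = fac)
    turn <- arc_points(a[n, ], b[1, ], k = 3L, bulge = ez)
    aa_a <- strand_aa(n); aa_b <- strand_aa(n)
    aa_t <- c("G", "N", "G")
    if (knuckle) { aa_a[n] <- "C"; aa_t <- c("P", "S", "C"); aa_b[1] <- "G" }
    list(a = a, turn = turn, b = b, aa_a = aa_a, aa_t = aa_t, aa_b = aa_b)
  }
  emit_hairpin <- function(h, transform = identity) {
    add(transform(h$a), h$aa_a, TRUE)
    add(transform(h$turn), h$aa_t)
    add(transform(h$b), h$aa_b, TRUE)
  }
  if (type %in% c("type1A", "type1B")) {
    h1 <- hairpin(0, ZNR_SHEET, 0, knuckle = TRUE)
    h2 <- hairpin(0, ZNR_SHEET, 0, knuckle = TRUE)
    shift <- function(pts) {
      p <- rot_z90(pts, ZNR_SHEET / 2, 0)
      p[, 2] <- p[, 2] + 10
      p
    }
    emit_hairpin(h1)
    link <- bridge_path(h1$b[n, ], shift(h2$a)[1, ], bulge = -ez)
    add(link, rep_len(c("G", "S"), nrow(link)))
    emit_hairpin(h2, shift)
    if (type == "type1B") {
      b5 <- vert_strand(n, -ZNR_SHEET, 0, z0 = ztop, dir = -1, phase = fac)
      link2 <- bridge_path(shift(h2$b)[n, ], b5[1, ], bulge = ex)
      add(link2, rep_len(c("S", "G"), nrow(link2)))
      add(b5, strand_aa(n), TRUE)
    }
  } else if (type == "type2") {
    h1 <- hairpin(0, ZNR_SHEET, 0, knuckle = TRUE)
    emit_hairpin(h1)
    b3 <- vert_strand(n, ZNR_SHEET, 8, z0 = ztop, dir = -1, phase = fac)
    link <- bridge_path(h1$b[n, ], b3[1, ], bulge = ex)
    add(link, rep_len(c("G", "S"), nrow(link)))
    aa3 <- strand_aa(n)
    add(b3, aa3, TRUE)
    b4 <- vert_strand(n, 0, 8, dir = 1)
    add(arc_points(b3[n, ], b4[1, ], k = 3L, bulge = -ez), c("G", "N", "G"))
    aa4 <- strand_aa(n); aa4[n] <- "C"
    add(b4, aa4, TRUE)
    b5 <- vert_strand(n, -ZNR_SHEET, 8, z0 = ztop, dir = -1, phase = fac)
    add(arc_points(b4[n, ], b5[1, ], k = 3L, bulge = ez), c("P", "S", "C"))
    aa5 <- strand_aa(n); aa5[1] <- "G"
    add(b5, aa5, TRUE)
  } else {
    stop_fmt("unknown znr type '%s'", type)
  }
  ca <- do.call(rbind, lapply(segs, `[[`, "pts"))
  aa <- unlist(lapply(segs, `[[`, "aa"))
  lens <- vapply(segs, function(s) nrow(s$pts), integer(1))
  ends <- cumsum(lens)
  starts <- ends - lens + 1L
  strand_idx <- which(vapply(segs, `[[`, logical(1), "is_strand"))
  strands <- data.frame(start = starts[strand_idx], end = ends[strand_idx])
  list(ca = ca, aa = aa, strands = strands, cys = which(aa == "C"))
}

#' Specification for an idealized zinc-ribbon structure
#'
#' @param znr_type `"type1A"`, `"type1B"` or `"type2"`.
#' @param noise_sd RMS displacement (angstrom) of the isotropic Gaussian
#'   jitter applied to every atom (per-axis sd `noise_sd/sqrt(3)`).
#' @param strand_length Residues per strand (>= 3; default 8).
#' @param seed RNG seed.
#' @return An object of class `znr_sim_spec`.
#' @export
znr_sim_spec <- function(znr_type = c("type1A", "type1B", "type2"),
                         noise_sd = 0, strand_length = 8L, seed = 1L) {
  znr_type <- match.arg(znr_type)
  stopifnot(noise_sd >= 0, is_count(strand_length, 3L))
  structure(list(znr_type = znr_type, noise_sd = noise_sd,
                 strand_length = as.integer(strand_length),
                 seed = as.integer(seed)),
            class = "znr_sim_spec")
}

#' Simulate an idealized zinc-ribbon C-alpha trace
#'
#' Builds the layout template for the requested topology type: type-1A, two
#' hairpins mutually rotated/translated so there is no inter-hairpin strand
#' pairing; type-1B, the same two hairpins plus a fifth strand pairing into
#' the N-terminal hairpin's sheet; type-2, the N-terminal hairpin followed by
#' a three-stranded meander sheet (strands 3-5). The four knuckle cysteines
#' sit at the two chelating turn apices, and each cysteine is given an
#' S-gamma atom at chelating distance (2.3 A) from the implied zinc position so
#' that chelation-site geometry can be assessed. Isotropic Gaussian jitter of
#' RMS magnitude `noise_sd` is applied to all atoms.
#'
#' @param spec A [znr_sim_spec].
#' @return A [structure_model] (chain `"A"`, residues numbered from 1) with
#'   attribute `"true_strands"` (data frame of planted strand index ranges).
#' @export
simulate_znr_structure <- function(spec) {
  stopifnot(inherits(spec, "znr_sim_spec"))
  tpl <- znr_template(spec$znr_type, spec$strand_length)
  n <- nrow(tpl$ca)
  sg <- matrix(NA_real_, n, 3)
  zn <- colMeans(tpl$ca[tpl$cys, , drop = FALSE])
  for (i in tpl$cys) {
    v <- tpl$ca[i, ] - zn
    sg[i, ] <- zn + 2.3 * v / sqrt(sum(v^2))  # thiolate at chelating distance
  }
  ca <- tpl$ca
  with_seed(spec$seed, {
    if (spec$noise_sd > 0) {
      s <- spec$noise_sd / sqrt(3)
      ca <- ca + matrix(stats::rnorm(3 * n, sd = s), n, 3)
      sg <- sg + matrix(stats::rnorm(3 * n, sd = s), n, 3)  # NA rows stay NA
    }
    model <- structure_model("A", seq_len(n), tpl$aa, ca, sg = sg)
    attr(model, "true_strands") <- tpl$strands
    model
  })
}

#' Apply a random rigid transform plus jitter to a structure
#'
#' A uniformly random rotation (seeded quaternion), the given translation and
#' then isotropic Gaussian jitter of RMS magnitude `jitter_sd` per atom.
#' Residue identities are unchanged.
#'
#' @param model A [structure_model].
#' @param rotation_seed Seed for the random rotation.
#' @param translation Numeric 3-vector (angstrom).
#' @param jitter_sd RMS displacement of the per-atom jitter (angstrom).
#' @return The transformed [structure_model].
#' @export
perturb_rigid <- function(model, rotation_seed = 1L, translation = c(0, 0, 0),
                          jitter_sd = 0) {
  stopifnot(inherits(model, "structure_model"), length(translation) == 3L,
            jitter_sd >= 0)
  with_seed(rotation_seed, {
    q <- stats::rnorm(4)
    q <- q / sqrt(sum(q^2))
    R <- quat_to_rot(q)
    n <- length(model$resno)
    tf <- function(m) {
      out <- m %*% t(R) + matrix(translation, n, 3, byrow = TRUE)
      if (jitter_sd > 0) {
        out <- out + matrix(stats::rnorm(3 * n, sd = jitter_sd / sqrt(3)), n, 3)
      }
      out[is.na(m[, 1]), ] <- NA_real_
      out
    }
    structure_model(model$chain_id, model$resno, model$aa, tf(model$ca),
                    cb = tf(model$cb), sg = tf(model$sg), ins = model$ins)
  })
}

#' @noRd
quat_to_rot <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# ---------------------------------------------------------------------------
# Paired similarity matrices with planted clades

#' Specification for paired E-value/Z-score similarity matrices
#'
#' @param planted_partition List of disjoint leaf-name groups covering all
#'   leaves.
#' @param within_z,between_z Mean Z-score inside vs across groups.
#' @param within_loge,between_loge Mean -log10 E-value inside vs across
#'   groups.
#' @param noise_sd Gaussian spread of both channels.
#' @param missing_frac Fraction of off-diagonal cells blanked (each ordered
#'   cell independently).
#' @param seed RNG seed.
#' @return An object of class `clade_sim_spec`.
#' @export
clade_sim_spec <- function(planted_partition = list(c("a1", "a2", "a3"),
                                                    c("b1", "b2", "b3"),
                                                    c("c1", "c2", "c3")),
                           within_z = 8, between_z = 2,
                           within_loge = 8, between_loge = 2,
                           noise_sd = 1, missing_frac = 0.1, seed = 1L) {
  leaves <- unlist(planted_partition)
  if (anyDuplicated(leaves)) stop_fmt("planted groups must be disjoint")
  stopifnot(length(leaves) >= 2L, within_z > between_z,
            within_loge > between_loge, noise_sd >= 0, is_prob(missing_frac))
  structure(list(n_leaves = length(leaves),
                 planted_partition = planted_partition,
                 within_z = within_z, between_z = between_z,
                 within_loge = within_loge, between_loge = between_loge,
                 noise_sd = noise_sd, missing_frac = missing_frac,
                 seed = as.integer(seed)),
            class = "clade_sim_spec")
}

#' Simulate a paired E-value/Z-score evidence matrix with planted clades
#'
#' Z-score entries are Normal(within or between mean, `noise_sd`) truncated
#' at 0; E-value entries are `10^-Normal(...)` truncated to (0, 10]. Each
#' ordered off-diagonal cell is blanked independently with probability
#' `missing_frac` (so symmetric positions are blanked independently);
#' diagonals are missing (they are ignored downstream).
#'
#' @param spec A [clade_sim_spec].
#' @return List with `evalue` and `zscore` [similarity_table]s.
#' @export
simulate_similarity_pair <- function(spec) {
  stopifnot(inherits(spec, "clade_sim_spec"))
  leaves <- unlist(spec$planted_partition)
  n <- length(leaves)
  group <- rep(seq_along(spec$planted_partition),
               lengths(spec$planted_partition))
  same <- outer(group, group, `==`)
  off <- row(same) != col(same)
  with_seed(spec$seed, {
    mu_z <- ifelse(same, spec$within_z, spec$between_z)
    z <- matrix(pmax(0, stats::rnorm(n * n, mu_z, spec$noise_sd)), n, n)
    mu_e <- ifelse(same, spec$within_loge, spec$between_loge)
    e <- matrix(pmin(10, 10^(-stats::rnorm(n * n, mu_e, spec$noise_sd))), n, n)
    drop_z <- off & matrix(stats::runif(n * n) < spec$missing_frac, n, n)
    drop_e <- off & matrix(stats::runif(n * n) < spec$missing_frac, n, n)
    z[drop_z | !off] <- NA_real_
    e[drop_e | !off] <- NA_real_
    dimnames(z) <- dimnames(e) <- list(leaves, leaves)
    list(evalue = similarity_table(e, "evalue"),
         zscore = similarity_table(z, "zscore"))
  })
}
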