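# Topology-based typing of zinc-ribbon domains from C-alpha coordinates.
#
# Zinc ribbons come in two major types: type-1 keeps the two Zn-knuckle
# hairpins structurally separate (1A: nothing else; 1B: an extra C-terminal
# strand sheets with the N-terminal hairpin), whereas in type-2 the
# N-terminal hairpin extends into a strand that completes a three-stranded
# meander with the C-terminal hairpin. Strand assignment uses C-alpha
# distance windows (in the style of P-SEA) rather than hydrogen bonds: the
# typing criteria are purely topological and many deposited ribbons lack
# complete backbones.

#' Assign beta-strand segments from C-alpha geometry
#'
#' Residue `i` is strand-like if `d(CAi, CAi+2)` lies in
#' `[i2_window[1], i2_window[2]]` and `d(CAi, CAi+3)` in `i3_window`;
#' maximal runs of at least `min_run` strand-like residues become strands,
#' labelled in sequence order. Because the label at `i` attests the geometry
#' of residues `i..i+3`, a run ending at `j` yields a strand segment ending
#' at `j + 3` (capped at the next run and the chain end); an isolated ideal
#' strand is thus covered in full.
#'
#' @param model A [structure_model] with >= 6 residues.
#' @param i2_window,i3_window Distance windows (angstrom) for the i,i+2 and
#'   i,i+3 C-alpha separations.
#' @param min_run Minimum run length (default 3).
#' @return Data frame with one row per strand: `label` (`b1`, `b2`, ...),
#'   `start`, `end` (residue indices into the model) and direction cosines
#'   `dx`, `dy`, `dz`. Zero rows when no strands are found.
#' @export
assign_strands <- function(model, i2_window = c(6.1, 7.4),
                           i3_window = c(9.0, 11.1), min_run = 3L) {
  stopifnot(inherits(model, "structure_model"))
  n <- length(model$resno)
  if (n < 6L) stop_fmt("need >= 6 residues to assign strands (got %d)", n)
  ca <- model$ca
  d2 <- row_norms(ca[seq_len(n - 2L) + 2L, , drop = FALSE] -
                    ca[seq_len(n - 2L), , drop = FALSE])
  d3 <- row_norms(ca[seq_len(n - 3L) + 3L, , drop = FALSE] -
                    ca[seq_len(n - 3L), , drop = FALSE])
  lab <- logical(n)
  idx <- seq_len(n - 3L)
  lab[idx] <- d2[idx] >= i2_window[1] & d2[idx] <= i2_window[2] &
    d3 >= i3_window[1] & d3 <= i3_window[2]
  runs <- rle(lab)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- runs$values & runs$lengths >= min_run
  out <- data.frame(label = character(0), start = integer(0), end = integer(0),
                    dx = numeric(0), dy = numeric(0), dz = numeric(0),
                    stringsAsFactors = FALSE)
  if (!any(keep)) return(out)
  st <- starts[keep]; en <- ends[keep]
  en <- pmin(en + 3L, n, c(st[-1] - 1L, n))
  dirs <- t(vapply(seq_along(st), function(k) {
    v <- ca[en[k], ] - ca[st[k], ]
    v / sqrt(sum(v^2))
  }, numeric(3)))
  data.frame(label = paste0("b", seq_along(st)), start = st, end = en,
             dx = dirs[, 1], dy = dirs[, 2], dz = dirs[, 3],
             stringsAsFactors = FALSE)
}

#' Pair strands into sheets and list hairpins
#'
#' Strands are paired iff at least two residue pairs (one residue from each
#' strand) lie within `contact_cutoff` of each other and are
#' sequence-consecutive on both strands (the standard inter-strand C-alpha
#' distance is ~4.5-5.2 A; the default cutoff adds tolerance). Orientation
#' comes from the sign of the strand direction dot product. Hairpins are
#' sequence-adjacent antiparallel pairs whose connecting turn is at most
#' `max_turn` residues.
#'
#' @param model A [structure_model].
#' @param strands Data frame from [assign_strands()].
#' @param contact_cutoff C-alpha contact distance (default 5.6 A).
#' @param max_turn Maximum hairpin turn length (default 6).
#' @return An object of class `strand_topology`: list with `strands`,
#'   `pairings` (data frame: `i`, `j`, `orientation`, `n_contact_pairs`) and
#'   `hairpins` (data frame: `i`, `j`, `turn_length`).
#' @export
pair_strands <- function(model, strands, contact_cutoff = 5.6, max_turn = 6L) {
  stopifnot(inherits(model, "structure_model"))
  ns <- nrow(strands)
  pairings <- data.frame(i = integer(0), j = integer(0),
                         orientation = character(0),
                         n_contact_pairs = integer(0), stringsAsFactors = FALSE)
  if (ns >= 2L) {
    ca <- model$ca
    for (i in seq_len(ns - 1L)) {
      for (j in seq.int(i + 1L, ns)) {
        ri <- strands$start[i]:strands$end[i]
        rj <- strands$start[j]:strands$end[j]
        D <- outer(seq_along(ri), seq_along(rj), function(p, q) {
          row_norms(ca[ri[p], , drop = FALSE] - ca[rj[q], , drop = FALSE])
        })
        contact <- D <= contact_cutoff
        if (sum(contact) < 2L) next
        np <- length(ri); nq <- length(rj)
        ladder <- FALSE
        for (p in seq_len(np - 1L)) {
          qs <- which(contact[p, ])
          for (q in qs) {
            if ((q < nq && contact[p + 1L, q + 1L]) ||
                (q > 1L && contact[p + 1L, q - 1L])) {
              ladder <- TRUE
              break
            }
          }
          if (ladder) break
        }
        if (!ladder) next
        dot <- sum(unlist(strands[i, c("dx", "dy", "dz")]) *
                     unlist(strands[j, c("dx", "dy", "dz")]))
        pairings <- rbind(pairings, data.frame(
          i = i, j = j,
          orientation = if (dot >= 0) "parallel" else "antiparallel",
          n_contact_pairs = sum(contact), stringsAsFactors = FALSE))
      }
    }
  }
  hairpins <- data.frame(i = integer(0), j = integer(0),
                         turn_length = integer(0))
  if (nrow(pairings)) {
    adj <- pairings[pairings$j == pairings$i + 1L &
                      pairings$orientation == "antiparallel", , drop = FALSE]
    if (nrow(adj)) {
      turn <- strands$start[adj$j] - strands$end[adj$i] - 1L
      ok <- turn <= max_turn
      hairpins <- data.frame(i = adj$i[ok], j = adj$j[ok],
                             turn_length = turn[ok])
    }
  }
  structure(list(strands = strands, pairings = pairings, hairpins = hairpins),
            class = "strand_topology")
}

#' @export
print.strand_topology <- function(x, ...) {
  cat(sprintf("<strand_topology> %d strands, %d pairings, %d hairpins\n",
              nrow(x$strands), nrow(x$pairings), nrow(x$hairpins)))
  invisible(x)
}

# Connected components of the strand pairing graph, as a list of sorted
# integer vectors ordered by their smallest member.
sheet_components <- function(topology) {
  ns <- nrow(topology$strands)
  comp <- seq_len(ns)
  if (nrow(topology$pairings)) {
    for (k in seq_len(nrow(topology$pairings))) {
      a <- comp[topology$pairings$i[k]]
      b <- comp[topology$pairings$j[k]]
      comp[comp == b] <- a
    }
  }
  unname(lapply(split(seq_len(ns), comp), sort))
}

#' Classify zinc-ribbon topology type from strand topology
#'
#' Pure decision table over the sheet-component structure:
#' \describe{
#'   \item{type1A}{exactly 4 strands forming two disjoint hairpin components
#'     (\{b1,b2\} and \{b3,b4\}).}
#'   \item{type1B}{5 strands with the C-terminal strand pairing into the
#'     N-terminal hairpin's sheet (components \{b1,b2,b5\} and \{b3,b4\}).}
#'   \item{type2}{5 strands with the middle strand opening the C-terminal
#'     meander sheet (components \{b1,b2\} and \{b3,b4,b5\}).}
#' }
#' Anything else (including the five-stranded Cren7/SH3-like barrel, which is
#' a single sheet component) is `unclassified`, with the evidence recording
#' which row failed. The type-1B/type-2 circular-permutation relationship is
#' noted in the evidence text only, never detected automatically.
#'
#' @param topology A `strand_topology` from [pair_strands()].
#' @return An object of class `znr_type_call`: list with `znr_type`,
#'   `evidence` and `topology`.
#' @export
classify_znr_type <- function(topology) {
  stopifnot(inherits(topology, "strand_topology"))
  ns <- nrow(topology$strands)
  comps <- sheet_components(topology)
  comp_str <- paste(vapply(comps, function(cc) {
    paste0("{", paste0("b", cc, collapse = ","), "}")
  }, character(1)), collapse = " ")
  hp <- topology$hairpins
  is_hairpin <- function(i, j) any(hp$i == i & hp$j == j)
  key <- function(...) {
    target <- list(...)
    length(comps) == length(target) &&
      all(vapply(seq_along(target), function(k) {
        any(vapply(comps, identical, logical(1), as.integer(target[[k]])))
      }, logical(1)))
  }
  call <- function(type, evidence) {
    structure(list(znr_type = type, evidence = evidence, topology = topology),
              class = "znr_type_call")
  }
  if (ns == 4L && key(c(1, 2), c(3, 4)) &&
      is_hairpin(1L, 2L) && is_hairpin(3L, 4L)) {
    return(call("type1A", sprintf(
      "4 strands; two disjoint hairpins; components %s", comp_str)))
  }
  if (ns == 5L && key(c(1, 2, 5), c(3, 4))) {
    return(call("type1B", sprintf(
      "5 strands; b5 joins the N-terminal hairpin sheet; components %s (circularly permuted counterpart of type2)",
      comp_str)))
  }
  if (ns == 5L && key(c(1, 2), c(3, 4, 5))) {
    return(call("type2", sprintf(
      "5 strands; b3-b5 form the C-terminal meander sheet; components %s (circularly permuted counterpart of type1B)",
      comp_str)))
  }
  call("unclassified", sprintf(
    "%d strands; components %s; no decision row matched", ns, comp_str))
}

#' @export
print.znr_type_call <- function(x, ...) {
  cat(sprintf("<znr_type_call> %s\n  %s\n", x$znr_type, x$evidence))
  invisible(x)
}

#' Assess zinc-chelation competence from cysteine geometry
#'
#' A site is competent iff some 4-cysteine subset has all pairwise
#' ligand-atom distances within `cutoff`. The ligand atom is S-gamma when
#' present, else C-beta, else C-alpha; pairs falling back to C-alpha get
#' `cutoff + 1.5` A of slack. The best subset (minimal max pairwise
#' distance) is reported.
#'
#' @param model A [structure_model].
#' @param call Optional `chelation_call` from [classify_chelation()]; when
#'   given, candidate cysteines are restricted to the called knuckle windows.
#' @param cutoff Ligand-atom distance cutoff (default 8.0 A).
#' @return An object of class `zn_site_call`: list with `competent`,
#'   `cys_residues` (residue numbers of the best subset, or all cysteines if
#'   fewer than 4) and `max_pairwise` (A, NA if fewer than 2 cysteines).
#' @export
detect_zn_site <- function(model, call = NULL, cutoff = 8.0) {
  stopifnot(inherits(model, "structure_model"))
  cys <- which(model$aa == "C")
  if (!is.null(call) && nrow(call$knuckles)) {
    windows <- unlist(lapply(call$knuckles$start, function(s) s:(s + 4L)))
    cys <- cys[cys %in% windows]
  }
  result <- function(competent, subset, maxd) {
    structure(list(competent = competent,
                   cys_residues = model$resno[subset],
                   max_pairwise = maxd), class = "zn_site_call")
  }
  if (length(cys) < 4L) {
    maxd <- NA_real_
    return(result(FALSE, cys, maxd))
  }
  lig <- t(vapply(cys, function(i) {
    if (!anyNA(model$sg[i, ])) c(model$sg[i, ], 0)
    else if (!anyNA(model$cb[i, ])) c(model$cb[i, ], 0)
    else c(model$ca[i, ], 1)  # flag: C-alpha fallback
  }, numeric(4)))
  eff_dist <- function(a, b) {
    d <- sqrt(sum((lig[a, 1:3] - lig[b, 1:3])^2))
    d - 1.5 * (lig[a, 4] > 0 || lig[b, 4] > 0)  # slack for C-alpha fallback
  }
  best <- NULL
  combs <- utils::combn(seq_along(cys), 4L)
  for (k in seq_len(ncol(combs))) {
    sub <- combs[, k]
    pd <- utils::combn(sub, 2L)
    dmax <- max(vapply(seq_len(ncol(pd)), function(m) {
      eff_dist(pd[1, m], pd[2, m])
    }, numeric(1)))
    if (is.null(best) || dmax < best$dmax) best <- list(sub = sub, dmax = dmax)
  }
  raw_max <- max(utils::combn(best$sub, 2L, function(p) {
    sqrt(sum((lig[p[1], 1:3] - lig[p[2], 1:3])^2))
  }))
  result(best$dmax <= cutoff, cys[best$sub], raw_max)
}

#' @export
print.zn_site_call <- function(x, ...) {
  cat(sprintf("<zn_site_call> %s (cys at %s; max pairwise %.2f A)\n",
              if (x$competent) "competent" else "not competent",
              paste(x$cys_residues, collapse = ","), x$max_pairwise))
  invisible(x)
}
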