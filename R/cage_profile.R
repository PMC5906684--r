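# Aromatic-cage conservation profiling for chromo-like domain families.
#
# Chromo-like SH3-fold domains recognize methylated lysine/arginine peptides
# through a cage of ~5 aromatic residues (Y, W, F, H; histidine counts as
# aromatic). Given a family alignment and the five alignment columns hosting
# the cage, the profile reports the fraction of aromatic residues at each
# position, among rows that have a residue there.

#' Cage position specification
#'
#' Exactly five strictly increasing alignment column indices (1-based),
#' numbered 1-5 from the N- to the C-terminus. Cage positions are user input
#' (typically read off an annotated reference structure); no automatic cage
#' detection is attempted.
#'
#' @param columns Integer vector of 5 strictly increasing column indices.
#' @param source Free-text provenance note.
#' @return An object of class `cage_spec`.
#' @export
cage_spec <- function(columns, source = "") {
  columns <- as.integer(columns)
  if (length(columns) != 5L || any(columns < 1L) || any(diff(columns) <= 0L)) {
    stop_fmt("cage columns must be 5 strictly increasing positive indices")
  }
  structure(list(columns = columns, source = source), class = "cage_spec")
}

#' Map reference residue positions to alignment columns
#'
#' Converts ungapped residue positions of a reference row (e.g. the five cage
#' residues of an annotated structure) into alignment column indices.
#'
#' @param aln An [alignment].
#' @param reference_id Row id of the reference sequence.
#' @param reference_positions Five ungapped residue indices of the reference.
#' @return A [cage_spec] whose columns are alignment column indices.
#' @examples
#' aln <- alignment(list(
#'   seq_record("ref", "A-CDE-F", allow_gap = TRUE),
#'   seq_record("oth", "AWCDEYF", allow_gap = TRUE)))
#' map_cage_columns(aln, "ref", 1:5)$columns  # 1 3 4 5 7
#' @export
map_cage_columns <- function(aln, reference_id, reference_positions) {
  stopifnot(inherits(aln, "alignment"))
  ids <- vapply(aln$records, `[[`, character(1), "id")
  k <- match(reference_id, ids)
  if (is.na(k)) stop_fmt("reference id '%s' not in alignment", reference_id)
  chars <- strsplit(aln$records[[k]]$residues, "")[[1]]
  res_cols <- which(chars != "-")
  pos <- as.integer(reference_positions)
  bad <- pos[pos < 1L | pos > length(res_cols)]
  if (length(bad)) {
    stop_fmt("position %d is beyond the %d-residue reference '%s'",
             bad[1], length(res_cols), reference_id)
  }
  cage_spec(res_cols[pos],
            source = sprintf("mapped from %s positions %s", reference_id,
                             paste(pos, collapse = ",")))
}

#' Aromatic fraction at the cage positions of a family alignment
#'
#' For each cage column the fraction is the number of rows carrying Y, W, F or
#' H over the number of rows carrying any residue (gaps excluded from the
#' denominator; the per-column non-gap fraction is reported as `coverage` so
#' the choice is auditable). All-gap columns get fraction 0 and coverage 0.
#'
#' @param aln An [alignment]; its `family_label` is carried into the profile.
#' @param cage A [cage_spec] within the alignment's bounds.
#' @param include_gaps If `TRUE`, gapped rows count in the denominator
#'   (alternative mode; default `FALSE`).
#' @return An object of class `cage_profile`: list with `family_label`,
#'   `fractions` (5 values in \[0,1\]), `coverage` (5 values) and
#'   `n_sequences`.
#' @export
aromatic_fraction_profile <- function(aln, cage, include_gaps = FALSE) {
  stopifnot(inherits(aln, "alignment"), inherits(cage, "cage_spec"))
  if (any(cage$columns > aln$n_columns)) {
    stop_fmt("cage column %d beyond alignment width %d",
             max(cage$columns), aln$n_columns)
  }
  m <- alignment_matrix(aln)[, cage$columns, drop = FALSE]
  n_rows <- nrow(m)
  non_gap <- colSums(m != "-")
  arom <- colSums(matrix(m %in% AROMATIC, nrow = n_rows))
  denom <- if (include_gaps) rep(n_rows, 5L) else non_gap
  fractions <- ifelse(denom > 0, arom / denom, 0)
  structure(list(family_label = aln$family_label,
                 fractions = as.numeric(fractions),
                 coverage = as.numeric(non_gap / n_rows),
                 n_sequences = n_rows),
            class = "cage_profile")
}

#' @export
print.cage_profile <- function(x, ...) {
  cat(sprintf("<cage_profile> %s (n = %d)\n",
              if (nzchar(x$family_label)) x$family_label else "(unnamed)",
              x$n_sequences))
  print(round(rbind(fraction = x$fractions, coverage = x$coverage), 3))
  invisible(x)
}

#' Long-format comparison table of cage profiles across families
#'
#' @param profiles List of `cage_profile` objects (length >= 1).
#' @return Data frame with columns `family`, `position` (1-5), `fraction`,
#'   `coverage`, `n_sequences`; ordered by family, then position. Suitable
#'   for plotting.
#' @export
compare_families <- function(profiles) {
  if (inherits(profiles, "cage_profile")) profiles <- list(profiles)
  stopifnot(length(profiles) >= 1L,
            all(vapply(profiles, inherits, logical(1), "cage_profile")))
  do.call(rbind, lapply(profiles, function(p) {
    data.frame(family = p$family_label, position = 1:5,
               fraction = p$fractions, coverage = p$coverage,
               n_sequences = p$n_sequences, stringsAsFactors = FALSE)
  }))
}
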