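# Core data types and readers/writers for the formats every pipeline stage
# touches: FASTA, aligned FASTA, Stockholm, PDB (ATOM records), TSV similarity
# matrices and Newick trees.

# ---------------------------------------------------------------------------
# Sequence records

#' Create a protein sequence record
#'
#' A sequence record holds an identifier, an optional free-text description and
#' the residue string (upper-case one-letter amino-acid codes, `X` allowed;
#' alignment rows may additionally contain the gap character `-`).
#'
#' @param id Non-empty identifier, unique within a collection.
#' @param residues Non-empty residue string.
#' @param description Free text, defaults to `""`.
#' @param allow_gap Permit `-` in `residues` (used for alignment rows).
#' @return An object of class `seq_record` with fields `id`, `description`
#'   and `residues`.
#' @examples
#' seq_record("knuckle", "CPKCG")
#' @export
seq_record <- function(id, residues, description = "", allow_gap = FALSE) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_fmt("sequence id must be a non-empty string")
  }
  if (!is.character(residues) || length(residues) != 1L || !nzchar(residues)) {
    stop_fmt("residues of '%s' must be a non-empty string", id)
  }
  residues <- toupper(residues)
  ok <- c(AA_VALID, if (allow_gap) "-")
  bad <- setdiff(unique(strsplit(residues, "")[[1]]), ok)
  if (length(bad)) {
    stop_fmt("illegal residue character(s) %s in sequence '%s'",
             paste(sQuote(bad), collapse = ", "), id)
  }
  structure(list(id = id, description = description, residues = residues),
            class = "seq_record")
}

#' @export
print.seq_record <- function(x, ...) {
  cat(sprintf("<seq_record> %s (%d aa)\n", x$id, nchar(x$residues)))
  invisible(x)
}

#' Read protein sequences from a FASTA file
#'
#' One record per `>` header; surrounding whitespace is stripped and lower-case
#' residues are upper-cased. Duplicate identifiers, illegal residue characters
#' and empty files are rejected with an error naming the offending line.
#'
#' @param path Path to a FASTA file.
#' @param allow_gap Permit `-`/`.` gap characters (used by [read_alignment()]).
#' @return List of [seq_record] objects in file order.
#' @seealso [write_fasta()], [read_alignment()]
#' @export
read_fasta <- function(path, allow_gap = FALSE) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(trimws(lines)))) {
    stop_fmt("empty FASTA file: %s", path)
  }
  records <- list()
  ids <- character()
  id <- NULL
  desc <- ""
  chunks <- character()
  head_line <- 0L
  flush <- function() {
    if (is.null(id)) return()
    res <- paste(chunks, collapse = "")
    if (!nzchar(res)) stop_fmt("record '%s' (line %d) has no residues", id, head_line)
    if (allow_gap) res <- gsub("\\.", "-", res)
    rec <- tryCatch(seq_record(id, res, desc, allow_gap = allow_gap),
                    error = function(e) stop_fmt("line %d: %s", head_line, conditionMessage(e)))
    records[[length(records) + 1L]] <<- rec
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      flush()
      header <- sub("^>", "", ln)
      id <- sub("\\s.*$", "", header)
      if (!nzchar(id)) stop_fmt("line %d: empty FASTA header", i)
      if (id %in% ids) stop_fmt("line %d: duplicate sequence id '%s'", i, id)
      ids <- c(ids, id)
      desc <- trimws(sub("^\\S+\\s*", "", header))
      chunks <- character()
      head_line <- i
    } else {
      if (is.null(id)) stop_fmt("line %d: sequence data before first '>' header", i)
      chunks <- c(chunks, gsub("\\s", "", ln))
    }
  }
  flush()
  if (!length(records)) stop_fmt("no FASTA records in %s", path)
  records
}

#' Write sequences to a FASTA file
#'
#' @param records List of [seq_record] objects.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(records, path, width = 60L) {
  if (inherits(records, "seq_record")) records <- list(records)
  out <- unlist(lapply(records, function(r) {
    header <- if (nzchar(r$description)) paste0(">", r$id, " ", r$description) else paste0(">", r$id)
    body <- gsub(sprintf("(.{1,%d})", width), "\\1\n", r$residues)
    c(header, strsplit(body, "\n")[[1]])
  }))
  writeLines(out, path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Alignments

#' Create a multiple sequence alignment
#'
#' All rows must have equal length; the gap character is `-` (a `.` read from
#' disk is normalized to `-`). Column indices are 1-based throughout the
#' package, matching how alignment figures cite positions.
#'
#' @param records List of [seq_record] rows (gaps allowed).
#' @param family_label Optional family name carried through profiling.
#' @param reference Optional reference annotation string (e.g. Stockholm
#'   `#=GC RF`), kept as an attribute.
#' @return An object of class `alignment` with fields `records`, `n_columns`
#'   and `family_label`.
#' @export
alignment <- function(records, family_label = "", reference = NULL) {
  if (length(records) < 2L) stop_fmt("an alignment needs at least 2 rows")
  ids <- vapply(records, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop_fmt("duplicate row id '%s' in alignment", ids[duplicated(ids)][1])
  }
  widths <- vapply(records, function(r) nchar(r$residues), integer(1))
  if (length(unique(widths)) != 1L) {
    off <- ids[widths != widths[1]]
    stop_fmt("ragged alignment: row(s) %s differ in length from row '%s'",
             paste(sQuote(off), collapse = ", "), ids[1])
  }
  structure(list(records = records, n_columns = widths[1],
                 family_label = family_label, reference = reference),
            class = "alignment")
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("<alignment> %d rows x %d columns%s\n", length(x$records), x$n_columns,
              if (nzchar(x$family_label)) paste0(" [", x$family_label, "]") else ""))
  invisible(x)
}

#' Alignment as a character matrix
#'
#' @param aln An [alignment].
#' @return Character matrix, rows named by sequence id, one column per
#'   alignment column.
#' @export
alignment_matrix <- function(aln) {
  stopifnot(inherits(aln, "alignment"))
  m <- t(vapply(aln$records, function(r) strsplit(r$residues, "")[[1]],
                character(aln$n_columns)))
  rownames(m) <- vapply(aln$records, `[[`, character(1), "id")
  m
}

#' Read a multiple sequence alignment
#'
#' Supports aligned FASTA and (single- or multi-block) Stockholm. Gaps written
#' as `.` are normalized to `-`; a Stockholm `#=GC RF` reference annotation is
#' retained as the alignment's `reference` attribute, other `#=GC`/`#=GS`/
#' `#=GR` lines are ignored.
#'
#' @param path Path to the alignment file.
#' @param dialect `"aligned-fasta"` or `"stockholm"`.
#' @param family_label Optional family name to attach.
#' @return An [alignment].
#' @export
read_alignment <- function(path, dialect = c("aligned-fasta", "stockholm"),
                           family_label = "") {
  dialect <- match.arg(dialect)
  if (dialect == "aligned-fasta") {
    return(alignment(read_fasta(path, allow_gap = TRUE),
                     family_label = family_label))
  }
  lines <- readLines(path, warn = FALSE)
  seqs <- list()
  order_ids <- character()
  rf <- character()
  for (ln in lines) {
    ln <- sub("\\s+$", "", ln)
    if (!nzchar(ln) || ln == "//") next
    if (startsWith(ln, "#")) {
      if (grepl("^#=GC\\s+RF\\s+", ln)) {
        rf <- c(rf, sub("^#=GC\\s+RF\\s+", "", ln))
      }
      next
    }
    parts <- strsplit(trimws(ln), "\\s+")[[1]]
    if (length(parts) != 2L) stop_fmt("malformed Stockholm sequence line: '%s'", ln)
    id <- parts[1]
    if (!id %in% order_ids) order_ids <- c(order_ids, id)
    seqs[[id]] <- paste0(if (is.null(seqs[[id]])) "" else seqs[[id]], parts[2])
  }
  if (!length(order_ids)) stop_fmt("no sequences in Stockholm file %s", path)
  recs <- lapply(order_ids, function(id) {
    seq_record(id, gsub("\\.", "-", seqs[[id]]), allow_gap = TRUE)
  })
  alignment(recs, family_label = family_label,
            reference = if (length(rf)) paste(rf, collapse = "") else NULL)
}

#' Write an alignment as aligned FASTA
#'
#' @param aln An [alignment].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "alignment"))
  write_fasta(aln$records, path, width = max(60L, aln$n_columns))
}

# ---------------------------------------------------------------------------
# Structures

#' Create a C-alpha level structure model
#'
#' Holds, per residue: PDB residue number (with insertion-code ordering
#' preserved), one-letter amino acid, the mandatory C-alpha coordinate and
#' optional C-beta / S-gamma coordinates (rows of `NA` where absent).
#'
#' @param chain_id Chain identifier.
#' @param resno Integer residue numbers (non-decreasing; strictly increasing
#'   unless insertion codes distinguish ties).
#' @param aa One-letter amino-acid codes.
#' @param ca n x 3 matrix of C-alpha coordinates (angstrom), all finite.
#' @param cb,sg Optional n x 3 matrices (NA rows allowed).
#' @param ins Insertion codes (default `""`).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(chain_id, resno, aa, ca, cb = NULL, sg = NULL,
                            ins = NULL) {
  n <- length(resno)
  ca <- as.matrix(ca)
  if (!is.numeric(resno) || n < 1L) stop_fmt("resno must be a non-empty numeric vector")
  resno <- as.integer(resno)
  if (is.null(ins)) ins <- rep("", n)
  if (length(aa) != n || nrow(ca) != n || ncol(ca) != 3L || length(ins) != n) {
    stop_fmt("structure fields disagree in length")
  }
  key <- paste(resno, ins)
  if (anyDuplicated(key)) stop_fmt("duplicate residue number/insertion-code pair")
  if (any(diff(resno) < 0)) stop_fmt("residue numbers must be non-decreasing")
  if (any(diff(resno) == 0 & ins[-n] == ins[-1])) {
    stop_fmt("residue numbers must be strictly increasing")
  }
  if (!all(is.finite(ca))) stop_fmt("non-finite C-alpha coordinate")
  fix_opt <- function(m) {
    if (is.null(m)) return(matrix(NA_real_, n, 3))
    m <- as.matrix(m)
    stopifnot(nrow(m) == n, ncol(m) == 3L)
    m
  }
  structure(list(chain_id = chain_id, resno = resno, ins = ins,
                 aa = toupper(as.character(aa)), ca = unname(ca),
                 cb = unname(fix_opt(cb)), sg = unname(fix_opt(sg))),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> chain %s, %d residues (%d-%d)\n",
              x$chain_id, length(x$resno), min(x$resno), max(x$resno)))
  invisible(x)
}

#' Number of residues in a structure model
#' @param model A [structure_model].
#' @return Integer count.
#' @export
n_residues <- function(model) length(model$resno)

# bio3d three-letter -> one-letter, with fallback to X
aa321_safe <- function(resid) {
  one <- suppressWarnings(bio3d::aa321(resid))
  one[is.na(one) | !one %in% AA_VALID] <- "X"
  one
}

#' Read one chain of a PDB file as a C-alpha model
#'
#' Parses ATOM records via [bio3d::read.pdb()]; keeps one entry per residue
#' that has a C-alpha (first alternate location wins), skips HETATM, preserves
#' insertion-code ordering, and collects C-beta and S-gamma coordinates where
#' present. Only model 1 of multi-model files is used.
#'
#' @param path Path to a PDB-format file.
#' @param chain Chain identifier that must be present in the file.
#' @return A [structure_model].
#' @export
read_structure <- function(path, chain) {
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  pdb <- suppressWarnings(bio3d::read.pdb(path, multi = FALSE, verbose = FALSE))
  at <- pdb$atom
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop_fmt("no ATOM records in %s", path)
  if (!chain %in% at$chain) {
    stop_fmt("chain '%s' not present in %s (chains: %s)", chain, path,
             paste(sort(unique(at$chain)), collapse = ", "))
  }
  at <- at[at$chain == chain, , drop = FALSE]
  at$insert[is.na(at$insert)] <- ""
  key <- paste(at$resno, at$insert)
  # first altloc wins, per atom name within a residue
  at <- at[!duplicated(paste(key, at$elety)), , drop = FALSE]
  ca <- at[at$elety == "CA", , drop = FALSE]
  if (!nrow(ca)) stop_fmt("chain '%s' of %s has no C-alpha atoms", chain, path)
  ca_key <- paste(ca$resno, ca$insert)
  pick <- function(elety) {
    sub <- at[at$elety == elety, , drop = FALSE]
    idx <- match(ca_key, paste(sub$resno, sub$insert))
    cbind(sub$x[idx], sub$y[idx], sub$z[idx])
  }
  structure_model(chain_id = chain, resno = ca$resno, ins = ca$insert,
                  aa = aa321_safe(ca$resid),
                  ca = cbind(ca$x, ca$y, ca$z),
                  cb = pick("CB"), sg = pick("SG"))
}

#' Write a structure model as a PDB-format file
#'
#' Emits fixed-width ATOM records for CA and any present CB/SG atoms, in
#' residue order, followed by TER/END. The output round-trips through
#' [read_structure()].
#'
#' @param model A [structure_model].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_structure <- function(model, path) {
  stopifnot(inherits(model, "structure_model"))
  aa3 <- suppressWarnings(bio3d::aa123(model$aa))
  aa3[is.na(aa3)] <- "UNK"
  lines <- character()
  serial <- 0L
  for (i in seq_along(model$resno)) {
    for (atom in list(c("CA", "C"), c("CB", "C"), c("SG", "S"))) {
      xyz <- model[[tolower(atom[1])]][i, ]
      if (anyNA(xyz)) next
      serial <- serial + 1L
      lines <- c(lines, sprintf(
        "ATOM  %5d %s %3s %s%4d%s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
        serial, sprintf(" %-3s", atom[1]), aa3[i], model$chain_id,
        model$resno[i], ifelse(nzchar(model$ins[i]), model$ins[i], " "),
        xyz[1], xyz[2], xyz[3], 1, 0, atom[2]))
    }
  }
  writeLines(c(lines, "TER", "END"), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Similarity tables

#' Create a clade-by-clade similarity table
#'
#' Square matrix of nonnegative evidence values (profile-profile E-values or
#' structure-search Z-scores) between labelled clades. Entries may be missing
#' (`NA`) and the matrix may be asymmetric on input; the diagonal is ignored
#' by all consumers. Missing cells are retained as missing, never imputed at
#' read time.
#'
#' @param values Square numeric matrix (NA = missing).
#' @param measure `"evalue"` or `"zscore"`.
#' @param labels Clade names; defaults to the matrix dimnames.
#' @return An object of class `similarity_table`.
#' @export
similarity_table <- function(values, measure = c("evalue", "zscore"),
                             labels = NULL) {
  measure <- match.arg(measure)
  values <- as.matrix(values)
  if (nrow(values) != ncol(values)) {
    stop_fmt("similarity table must be square (got %d x %d)", nrow(values), ncol(values))
  }
  if (is.null(labels)) labels <- rownames(values)
  if (is.null(labels)) stop_fmt("similarity table needs labels")
  labels <- as.character(labels)
  if (anyDuplicated(labels)) stop_fmt("duplicate labels in similarity table")
  if (length(labels) != nrow(values)) stop_fmt("labels do not match matrix size")
  if (any(values < 0, na.rm = TRUE)) stop_fmt("negative similarity value")
  dimnames(values) <- list(labels, labels)
  structure(list(labels = labels, values = values, measure = measure),
            class = "similarity_table")
}

#' @export
print.similarity_table <- function(x, ...) {
  cat(sprintf("<similarity_table> %s, %d clades, %d missing off-diagonal cells\n",
              x$measure, length(x$labels),
              sum(is.na(x$values[row(x$values) != col(x$values)]))))
  invisible(x)
}

#' Read a similarity table from TSV
#'
#' Expects a header row and a first column of labels; blank cells are read as
#' missing. Row and column label sets must agree (same order); negative values
#' are rejected.
#'
#' @param path Path to a TSV file.
#' @param measure `"evalue"` or `"zscore"`.
#' @return A [similarity_table] with labels in file order.
#' @export
read_similarity_table <- function(path, measure = c("evalue", "zscore")) {
  measure <- match.arg(measure)
  if (!file.exists(path)) stop_fmt("file not found: %s", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          na.strings = c("", "NA"))
  labels <- as.character(df[[1]])
  m <- as.matrix(df[, -1, drop = FALSE])
  if (nrow(m) != ncol(m)) {
    stop_fmt("similarity table in %s is not square (%d rows, %d value columns)",
             path, nrow(m), ncol(m))
  }
  if (!identical(colnames(m), labels)) {
    stop_fmt("row and column labels differ in %s", path)
  }
  storage.mode(m) <- "double"
  similarity_table(m, measure = measure, labels = labels)
}

#' Write a similarity table as TSV
#'
#' @param table A [similarity_table].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_similarity_table <- function(table, path) {
  stopifnot(inherits(table, "similarity_table"))
  df <- data.frame(clade = table$labels, table$values, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Clade trees and Newick output

#' Construct a clade tree node
#'
#' A clade tree is a rooted tree whose leaves are clade names and whose
#' internal nodes (each with >= 2 children) may carry a support count (how
#' many evidence channels contained that clade).
#'
#' @param children List of child nodes (each a `clade_node`), or `NULL` for a
#'   leaf.
#' @param leaf Leaf label (for leaves only).
#' @param support Optional support count for internal nodes.
#' @return A `clade_node`; the root of a tree is additionally tagged
#'   `clade_tree` by [clade_tree()].
#' @export
clade_node <- function(children = NULL, leaf = NULL, support = NA_integer_) {
  if (is.null(children)) {
    stopifnot(is.character(leaf), length(leaf) == 1L, nzchar(leaf))
    node <- list(leaf = leaf)
  } else {
    if (length(children) < 2L) stop_fmt("internal node needs >= 2 children")
    node <- list(children = children, support = as.integer(support))
  }
  class(node) <- "clade_node"
  node
}

#' Mark a node as the root of a clade tree
#'
#' Validates that leaf labels are unique.
#'
#' @param root A `clade_node`.
#' @return The node, classed `clade_tree`.
#' @export
clade_tree <- function(root) {
  stopifnot(inherits(root, "clade_node"))
  lv <- tree_leaves(root)
  if (anyDuplicated(lv)) stop_fmt("duplicate leaf label '%s'", lv[duplicated(lv)][1])
  class(root) <- c("clade_tree", "clade_node")
  root
}

#' Leaf labels of a clade tree (left-to-right)
#' @param node A `clade_node` / `clade_tree`.
#' @return Character vector of leaf labels.
#' @export
tree_leaves <- function(node) {
  if (!is.null(node$leaf)) return(node$leaf)
  unlist(lapply(node$children, tree_leaves))
}

#' Enumerate the clades (leaf sets) of all internal nodes
#' @param node A `clade_node` / `clade_tree`.
#' @return List of sorted character vectors, one per internal node (root
#'   included).
#' @export
tree_clades <- function(node) {
  if (!is.null(node$leaf)) return(list())
  c(list(sort(tree_leaves(node))), unlist(lapply(node$children, tree_clades),
                                          recursive = FALSE))
}

#' @export
print.clade_tree <- function(x, ...) {
  cat(sprintf("<clade_tree> %d leaves, %d internal nodes\n",
              length(tree_leaves(x)), length(tree_clades(x))))
  cat(newick_string(x), "\n")
  invisible(x)
}

newick_quote <- function(label) {
  if (grepl("[][(),:;'\"\\s]", label, perl = TRUE)) {
    paste0("'", gsub("'", "''", label), "'")
  } else {
    label
  }
}

#' Newick string for a clade tree
#'
#' Support counts become internal node labels; no branch lengths are written;
#' labels containing Newick metacharacters or whitespace are quoted.
#'
#' @param tree A `clade_tree` (or any `clade_node`).
#' @return Newick string terminated by `;`.
#' @export
newick_string <- function(tree) {
  rec <- function(node) {
    if (!is.null(node$leaf)) return(newick_quote(node$leaf))
    inner <- paste(vapply(node$children, rec, character(1)), collapse = ",")
    lab <- if (!is.na(node$support)) as.character(node$support) else ""
    paste0("(", inner, ")", lab)
  }
  paste0(rec(tree), ";")
}

#' Write a clade tree to a Newick file
#'
#' @param tree A `clade_tree`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_newick <- function(tree, path) {
  stopifnot(inherits(tree, "clade_node"))
  writeLines(newick_string(tree), path)
  invisible(path)
}
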