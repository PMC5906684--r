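test_that("FASTA reading handles records, order, and malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "CPKCG"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs[[1]]$id, "a")
  expect_equal(recs[[1]]$residues, "CPKCG")

  writeLines(c(">a desc", "cpk", "CG", ">b", "MKV", ">c", "WW"), f)
  recs <- read_fasta(f)
  expect_equal(vapply(recs, `[[`, character(1), "id"), c("a", "b", "c"))
  expect_equal(recs[[1]]$residues, "CPKCG")  # wrapped + upper-cased
  expect_equal(recs[[1]]$description, "desc")

  writeLines(c(">a", "MK", ">a", "WV"), f)
  expect_error(read_fasta(f), "duplicate")
  writeLines(c(">a", "MK1V"), f)
  expect_error(read_fasta(f), "illegal")
  writeLines(character(), f)
  expect_error(read_fasta(f), "empty")
})

test_that("FASTA writing round-trips sequence content exactly", {
  recs <- list(seq_record("id1", "CPKCGAAWWY", "some desc"),
               seq_record("id2", paste(rep("MKV", 50), collapse = "")))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(lapply(back, `[[`, "residues"), lapply(recs, `[[`, "residues"))
  expect_equal(back[[1]]$description, "some desc")
})

test_that("alignment reading enforces equal rows and normalizes gaps", {
  f <- withr::local_tempfile(fileext = ".afa")
  writeLines(c(">x", "AC-DE", ">y", "ACWDE"), f)
  aln <- read_alignment(f)
  expect_s3_class(aln, "alignment")
  expect_equal(aln$n_columns, 5L)

  writeLines(c(">x", "AC-DE", ">y", "ACW"), f)
  expect_error(read_alignment(f), "ragged.*'?y'?")
})

test_that("Stockholm input equals the equivalent aligned FASTA", {
  fa <- withr::local_tempfile(fileext = ".afa")
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c(">x", "AC-DE", ">y", "ACWDE"), fa)
  writeLines(c("# STOCKHOLM 1.0", "#=GF ID test", "x AC.DE", "y ACWDE",
               "#=GC RF xxXXx", "//"), sto)
  a1 <- read_alignment(fa, "aligned-fasta")
  a2 <- read_alignment(sto, "stockholm")
  expect_equal(lapply(a2$records, `[[`, "residues"),
               lapply(a1$records, `[[`, "residues"))
  expect_equal(a2$n_columns, a1$n_columns)
  expect_equal(a2$reference, "xxXXx")  # reference annotation retained
})

test_that("alignments round-trip through aligned FASTA", {
  aln <- simulate_cage_msa(cage_sim_spec(n_sequences = 8, n_columns = 30,
                                         cage_columns = c(3L, 8L, 15L, 22L, 28L),
                                         seed = 13))
  f <- withr::local_tempfile(fileext = ".afa")
  write_alignment(aln, f)
  back <- read_alignment(f)
  expect_equal(alignment_matrix(back), alignment_matrix(aln))
  expect_equal(back$n_columns, aln$n_columns)
})

test_that("multi-block Stockholm concatenates sequence blocks", {
  sto <- withr::local_tempfile(fileext = ".sto")
  writeLines(c("# STOCKHOLM 1.0", "x AC-", "y ACW", "", "x DE", "y DE", "//"), sto)
  aln <- read_alignment(sto, "stockholm")
  expect_equal(aln$records[[1]]$residues, "AC-DE")
  expect_equal(aln$n_columns, 5L)
})

test_that("PDB reading keeps one CA per residue, first altloc, no HETATM", {
  pdb <- withr::local_tempfile(fileext = ".pdb")
  mkatom <- function(serial, name, res, chain, resno, x, alt = " ") {
    sprintf("ATOM  %5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, sprintf(" %-3s", name), alt, res, chain, resno,
            x, 0, 0, 1, 0, substr(name, 1, 1))
  }
  lines <- vapply(1:10, function(i) mkatom(i, "CA", "ALA", "A", i, i * 3.8),
                  character(1))
  writeLines(c(lines, "TER", "END"), pdb)
  m <- read_structure(pdb, "A")
  expect_equal(n_residues(m), 10L)
  expect_true(all(is.finite(m$ca)))
  expect_equal(m$resno, 1:10)
  expect_error(read_structure(pdb, "Z"), "chain 'Z'")

  # altloc A/B on one atom: exactly one coordinate kept (the first)
  lines2 <- c(mkatom(1, "CA", "ALA", "A", 1, 0, alt = "A"),
              mkatom(2, "CA", "ALA", "A", 1, 99, alt = "B"),
              mkatom(3, "CA", "GLY", "A", 2, 3.8),
              "HETATM    4  O   HOH A   3      20.000   0.000   0.000  1.00  0.00           O",
              "END")
  writeLines(lines2, pdb)
  m2 <- read_structure(pdb, "A")
  expect_equal(n_residues(m2), 2L)     # water skipped
  expect_equal(m2$ca[1, 1], 0)         # first altloc wins
})

test_that("structure writing round-trips through the PDB reader", {
  m <- simulate_znr_structure(znr_sim_spec("type2", seed = 11))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(m, f)
  back <- read_structure(f, "A")
  expect_equal(n_residues(back), n_residues(m))
  expect_equal(back$resno, m$resno)
  expect_equal(back$aa, m$aa)
  expect_lt(max(abs(back$ca - m$ca)), 1e-3 + 1e-9)  # %8.3f precision
  expect_equal(is.na(back$sg[, 1]), is.na(m$sg[, 1]))
})

test_that("similarity tables read labels in file order and reject bad input", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("clade\tgamma\talpha\tbeta",
               "gamma\t\t3.5\t2.0",
               "alpha\t3.1\t\t8.2",
               "beta\t2.2\t7.9\t"), f)
  tab <- read_similarity_table(f, "zscore")
  expect_equal(tab$labels, c("gamma", "alpha", "beta"))
  expect_true(is.na(tab$values["gamma", "gamma"]))
  expect_equal(tab$values["alpha", "beta"], 8.2)

  writeLines(c("clade\ta\tb", "a\t1\t-2", "b\t1\t1"), f)
  expect_error(read_similarity_table(f, "zscore"), "negative")
  writeLines(c("clade\ta\tb\tc", "a\t1\t2\t3", "b\t1\t2\t3"), f)
  expect_error(read_similarity_table(f, "zscore"), "square")
  expect_error(read_similarity_table(f, "fancy"))
})

test_that("similarity tables round-trip including missing cells", {
  pair <- simulate_similarity_pair(clade_sim_spec(seed = 3))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_similarity_table(pair$evalue, f)
  back <- read_similarity_table(f, "evalue")
  expect_equal(back$labels, pair$evalue$labels)
  expect_equal(is.na(back$values), is.na(pair$evalue$values))
  expect_equal(back$values, pair$evalue$values, tolerance = 1e-12)
})

test_that("Newick output matches expectations and survives a parser round-trip", {
  cherry <- clade_tree(clade_node(children = list(clade_node(leaf = "a"),
                                                  clade_node(leaf = "b"))))
  expect_equal(newick_string(cherry), "(a,b);")

  spaced <- clade_tree(clade_node(children = list(clade_node(leaf = "x y"),
                                                  clade_node(leaf = "b"))))
  expect_match(newick_string(spaced), "'x y'", fixed = TRUE)

  tree <- clade_tree(clade_node(children = list(
    clade_node(children = list(clade_node(leaf = "a"), clade_node(leaf = "b")),
               support = 2L),
    clade_node(leaf = "c")), support = 2L))
  f <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, f)
  skip_if_not_installed("ape")
  ap <- ape::read.tree(f)
  expect_setequal(ap$tip.label, c("a", "b", "c"))
  # the {a,b} bipartition survives the round trip
  part <- ape::prop.part(ap)
  key <- vapply(part, function(p) paste(sort(ap$tip.label[p]), collapse = "|"),
                character(1))
  expect_true("a|b" %in% key)
})

test_that("core type constructors enforce their invariants", {
  expect_error(seq_record("", "MKV"), "non-empty")
  expect_error(seq_record("a", "M-K"), "illegal")
  expect_silent(seq_record("a", "M-K", allow_gap = TRUE))
  expect_error(alignment(list(seq_record("a", "MK"))), "2 rows")
  expect_error(structure_model("A", c(1, 1), c("A", "G"),
                               rbind(c(0, 0, 0), c(1, 0, 0))),
               "strictly increasing|duplicate")
  expect_error(structure_model("A", 1, "A", rbind(c(0, 0, Inf))), "finite")
  expect_error(similarity_table(matrix(1, 2, 3), "zscore"), "square")
  expect_error(cage_spec(c(1, 2, 3, 4)), "5 strictly increasing")
  expect_error(cage_spec(c(5, 4, 6, 7, 8)), "5 strictly increasing")
})
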