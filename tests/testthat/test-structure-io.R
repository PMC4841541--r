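test_that("hand-written ATOM records parse field by field", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER B   7      11.104  -2.500   3.000  1.00 14.80           N",
    "ATOM      2  CA  SER B   7      12.560  -2.400   3.100  0.50 20.00           C",
    "HETATM    3 MG    MG C 601       0.000   1.250  -9.999  1.00  5.00          MG",
    "END"), tf)
  s <- read_pdb(tf)
  expect_s3_class(s, "pdb_structure")
  a <- s$atoms
  expect_identical(a$name, c("N", "CA", "MG"))
  expect_identical(a$type, c("ATOM", "ATOM", "HETATM"))
  expect_identical(a$resname, c("SER", "SER", "MG"))
  expect_identical(a$chain, c("B", "B", "C"))
  expect_identical(a$resno, c(7L, 7L, 601L))
  expect_equal(a$x, c(11.104, 12.560, 0.0))
  expect_equal(a$z, c(3.0, 3.1, -9.999))
  expect_equal(a$occ, c(1, 0.5, 1))
  expect_equal(a$b, c(14.8, 20, 5))
  expect_identical(a$element, c("N", "C", "MG"))
})

test_that("write/read round trip is lossless at the declared precision", {
  base <- as_structure(small_complex())
  ens <- gaussian_ensemble(base, sigma = 1.5, n_frames = 100, seed = 5)
  for (i in c(1L, 50L, 100L)) {
    fr <- ens_frame(ens, i)
    tf <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(fr, tf)
    back <- read_pdb(tf)
    expect_lt(max(abs(coords(back) - coords(fr))), 5.0001e-4)
    expect_lt(max(abs(back$atoms$b - fr$atoms$b)), 5.0001e-3)
    cols <- c("type", "name", "resname", "chain", "resno", "element")
    expect_identical(back$atoms[, cols], fr$atoms[, cols])
    # a second round trip is exact: values are already on the output grid
    tf2 <- withr::local_tempfile(fileext = ".pdb")
    write_pdb(back, tf2)
    expect_identical(readLines(tf), readLines(tf2))
  }
})

test_that("multi-MODEL files become roster-checked ensembles", {
  base <- as_structure(small_complex())
  ens <- gaussian_ensemble(base, sigma = 0.7, n_frames = 5, seed = 9)
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(ens, tf)
  back <- read_pdb(tf)
  expect_s3_class(back, "pdb_ensemble")
  expect_identical(n_frames(back), 5L)
  expect_identical(nrow(back$atoms), nrow(base$atoms))
  expect_lt(max(abs(back$xyz - ens$xyz)), 5.0001e-4)
  # chain order is preserved
  expect_identical(unique(back$atoms$chain), unique(base$atoms$chain))
})

test_that("parse and roster errors are reported with context", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER B   7      11.104  -2.500   3.000  1.00 14.80           N",
    "ATOM      2  CA  SER B   7      12.5xy  -2.400   3.100  1.00 20.00           C"),
    tf)
  expect_error(read_pdb(tf), "line 2", class = "phosready_parse_error")

  tf2 <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "MODEL        1",
    "ATOM      1  N   SER B   7       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA  SER B   7       1.000   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   SER B   7       2.000   0.000   0.000  1.00 10.00           C",
    "ENDMDL",
    "MODEL        2",
    "ATOM      1  N   SER B   7       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CB  SER B   7       1.000   0.000   0.000  1.00 10.00           C",
    "ATOM      3  C   SER B   7       2.000   0.000   0.000  1.00 10.00           C",
    "ENDMDL", "END"), tf2)
  expect_error(read_pdb(tf2), class = "phosready_ensemble_error")
})

test_that("alternate locations beyond blank/'A' are dropped", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    "ATOM      1  N   SER B   7       0.000   0.000   0.000  1.00 10.00           N",
    "ATOM      2  CA ASER B   7       1.000   0.000   0.000  0.60 10.00           C",
    "ATOM      3  CA BSER B   7       1.200   0.000   0.000  0.40 10.00           C",
    "END"), tf)
  s <- read_pdb(tf)
  expect_identical(nrow(s$atoms), 2L)
  expect_identical(s$atoms$alt, c(" ", "A"))
})

test_that("coordinates too large for the fixed-width format are refused", {
  s <- as_structure(small_complex())
  xyz <- coords(s)
  xyz[1, 1] <- 12345.0
  coords(s) <- xyz
  expect_error(write_pdb(s, withr::local_tempfile(fileext = ".pdb")),
               class = "phosready_format_error")
})

test_that("template extraction partitions atoms without loss or duplication", {
  s <- synthetic_template()
  model <- extract_template(s, kinase_chain = "A", peptide_chain = "B",
                            tail_span = c(466, 479), cofactor_name = "ANP",
                            metal_name = "MN", water_cutoff = 3.0)
  parts <- c(nrow(model$kinase$atoms), nrow(model$peptide$atoms),
             nrow(model$tail$atoms), nrow(model$cofactor$atoms),
             nrow(model$metals$atoms), nrow(model$waters$atoms))
  expect_identical(sum(parts) + model$meta$discarded_atoms, nrow(s$atoms))
  # component serial sets are disjoint
  serials <- c(model$kinase$atoms$serial, model$peptide$atoms$serial,
               model$tail$atoms$serial, model$cofactor$atoms$serial,
               model$metals$atoms$serial, model$waters$atoms$serial)
  expect_identical(anyDuplicated(serials), 0L)
  expect_identical(length(unique(model$peptide$atoms$resno)), 10L)
  expect_identical(nrow(model$metals$atoms), 2L)
  expect_identical(nrow(model$waters$atoms), 3L)
  expect_identical(range(model$tail$atoms$resno), c(466L, 479L))
  # zero cutoff keeps no waters
  m0 <- extract_template(s, tail_span = c(466, 479), water_cutoff = 0)
  expect_identical(nrow(m0$waters$atoms), 0L)
  # missing components are named
  expect_error(extract_template(s, cofactor_name = "GTP"),
               "GTP", class = "phosready_extraction_error")
  expect_error(extract_template(s, peptide_chain = "Q"),
               class = "phosready_extraction_error")
})

test_that("toy-complex extraction returns exactly the generated components", {
  model <- make_toy_complex("RRSRSRSRSR", 3.2, seed = 4, name = "truth")
  s <- as_structure(model)
  back <- extract_template(s, tail_span = NULL, cofactor_name = "ATP",
                           metal_name = "MG")
  for (comp in c("kinase", "peptide", "cofactor", "metals")) {
    expect_identical(nrow(back[[comp]]$atoms), nrow(model[[comp]]$atoms))
  }
  # only the three first-shell waters survive the coordination cutoff
  expect_identical(back$waters$atoms$resno, model$waters$atoms$resno[1:3])
})

test_that("cofactor relabelling changes names, not geometry", {
  tmpl <- extract_template(synthetic_template(), tail_span = c(466, 479))
  rl <- relabel_cofactor(tmpl)
  expect_identical(nrow(rl$cofactor$atoms), nrow(tmpl$cofactor$atoms))
  pg_before <- tmpl$cofactor$atoms[tmpl$cofactor$atoms$name == "PG",
                                   c("x", "y", "z")]
  pg_after <- rl$cofactor$atoms[rl$cofactor$atoms$name == "PG",
                                c("x", "y", "z")]
  expect_identical(pg_before, pg_after)
  # element multiset changes by exactly one N -> O and two Mn -> Mg
  before <- table(c(tmpl$cofactor$atoms$element, tmpl$metals$atoms$element))
  after <- table(c(rl$cofactor$atoms$element, rl$metals$atoms$element))
  expect_identical(unname(before[["N"]] - 0L), 1L)
  expect_false("N" %in% names(after))
  expect_identical(unname(after[["O"]]) - unname(before[["O"]]), 1L)
  expect_identical(unname(after[["MG"]]), 2L)
  expect_false("MN" %in% names(after))
  # idempotent (second call warns and leaves everything unchanged)
  expect_warning(rl2 <- relabel_cofactor(rl), "already ATP")
  expect_identical(rl2$cofactor$atoms, rl$cofactor$atoms)
  expect_identical(rl2$metals$atoms, rl$metals$atoms)
})

test_that("an independent PDB reader agrees with ours", {
  tf <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(synthetic_template(), tf)
  ours <- read_pdb(tf)
  theirs <- bio3d::read.pdb(tf)
  expect_identical(nrow(theirs$atom), nrow(ours$atoms))
  expect_equal(unname(cbind(theirs$atom$x, theirs$atom$y, theirs$atom$z)),
               unname(coords(ours)))
  expect_equal(theirs$atom$b, ours$atoms$b)
  expect_identical(theirs$atom$elety, ours$atoms$name)
})
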