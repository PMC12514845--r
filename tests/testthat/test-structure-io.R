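minimal_cif <- function(extra_rows = character()) {
  c("data_TEST",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "ATOM 1 C CA . ALA A 97 1.000 2.000 3.000 1.00 10.00",
    "HETATM 2 CL CL14 . TCL A 371 4.500 5.250 6.125 1.00 20.00",
    "ATOM 3 O O . ALA A 97 7.000 8.000 9.000 0.50 30.00",
    extra_rows)
}

test_that("a minimal mmCIF reads back identically", {
  path <- tempfile(fileext = ".cif")
  writeLines(minimal_cif(), path)
  st <- read_structure(path)
  expect_s3_class(st$atoms, "tbl_df")
  expect_equal(nrow(st$atoms), 3)
  expect_equal(st$atoms$atom_name, c("CA", "CL14", "O"))
  expect_equal(st$atoms$x, c(1, 4.5, 7))
  expect_equal(st$atoms$y, c(2, 5.25, 8))
  expect_equal(st$atoms$z, c(3, 6.125, 9))
  expect_equal(st$atoms$element, c("C", "CL", "O"))
  expect_equal(st$atoms$occupancy, c(1, 1, 0.5))
  expect_equal(st$atoms$residue_seq, c(97L, 371L, 97L))
  # absent metadata is missing, not zero
  expect_true(is.na(st$metadata$resolution))
  expect_true(is.na(st$metadata$r_factor))
})

test_that("alternate locations are both returned with altloc populated", {
  path <- tempfile(fileext = ".cif")
  writeLines(minimal_cif(c(
    "ATOM 4 O OG A SER A 98 1.000 1.000 1.000 0.50 12.00",
    "ATOM 5 O OG B SER A 98 1.200 1.000 1.000 0.50 12.00")), path)
  st <- read_structure(path)
  og <- dplyr::filter(st$atoms, atom_name == "OG")
  expect_equal(nrow(og), 2)
  expect_setequal(og$altloc, c("A", "B"))
})

test_that("label_*-only mmCIF dialect resolves to the same model", {
  lines <- c("data_L",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "ATOM C CA . ALA A 97 1.0 2.0 3.0")
  path <- tempfile(fileext = ".cif")
  writeLines(lines, path)
  st <- read_structure(path)
  expect_equal(st$atoms$chain_id, "A")
  expect_equal(st$atoms$residue_seq, 97L)
  expect_equal(st$atoms$atom_name, "CA")
  expect_equal(st$atoms$occupancy, 1) # defaulted, not zero
})

test_that("write-then-read round trip preserves the model to 3 decimals", {
  fx <- fixture_structure("I", "Tyr", d = 5.2, theta1 = 150)
  path <- tempfile(fileext = ".cif")
  write_structure(fx$structure, path)
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), nrow(fx$atoms))
  expect_equal(st$atoms$atom_name, fx$atoms$atom_name)
  expect_equal(st$atoms$residue_name, fx$atoms$residue_name)
  expect_equal(st$atoms$x, fx$atoms$x, tolerance = 1e-3)
  expect_equal(st$atoms$y, fx$atoms$y, tolerance = 1e-3)
  expect_equal(st$atoms$z, fx$atoms$z, tolerance = 1e-3)
})

test_that("legacy PDB and mmCIF renderings of one fixture agree", {
  fx <- fixture_structure("CL", "O-C", d = 3.3, theta1 = 165, theta2 = 100)
  cif_path <- write_fx(fx)
  pdb_path <- tempfile(fileext = ".pdb")
  write_fixture_pdb(fx, pdb_path)
  st_cif <- read_structure(cif_path)
  st_pdb <- read_structure(pdb_path)
  expect_equal(st_pdb$atoms$atom_name, st_cif$atoms$atom_name)
  expect_equal(st_pdb$atoms$element, st_cif$atoms$element)
  expect_equal(st_pdb$atoms$x, st_cif$atoms$x, tolerance = 1e-3)
  expect_equal(st_pdb$atoms$residue_seq, st_cif$atoms$residue_seq)
})

test_that("an independent mmCIF reader agrees on a canonical-layout file", {
  # bio3d's reader needs the full canonical atom_site item layout
  fx <- fixture_structure("BR", "Phe", d = 4.8, theta1 = 160)
  at <- fx$atoms
  rows <- sprintf(
    "%s %d %s %s . %s %s 1 %d ? %.4f %.4f %.4f %.2f %.2f ? %d %s %s %s 1",
    at$record, seq_len(nrow(at)), at$element, at$atom_name, at$residue_name,
    at$chain_id, at$residue_seq, at$x, at$y, at$z, at$occupancy, at$b_factor,
    at$residue_seq, at$residue_name, at$chain_id, at$atom_name)
  items <- paste0("_atom_site.", c(
    "group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
    "label_comp_id", "label_asym_id", "label_entity_id", "label_seq_id",
    "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z", "occupancy",
    "B_iso_or_equiv", "pdbx_formal_charge", "auth_seq_id", "auth_comp_id",
    "auth_asym_id", "auth_atom_id", "pdbx_PDB_model_num"))
  path <- tempfile(fileext = ".cif")
  writeLines(c("data_XC", "#", "loop_", items, rows, "#"), path)
  ref <- suppressWarnings(bio3d::read.cif(path))
  st <- read_structure(path)
  expect_equal(nrow(st$atoms), nrow(ref$atom))
  expect_equal(st$atoms$x, ref$atom$x, tolerance = 1e-6)
  expect_equal(st$atoms$atom_name, ref$atom$elety)
  expect_equal(st$atoms$residue_seq, ref$atom$resno)
})

test_that("unknown element symbols warn and are inferred from atom names", {
  path <- tempfile(fileext = ".cif")
  writeLines(minimal_cif(c(
    "HETATM 6 Q BR2 . XYZ A 400 1.0 1.0 1.0 1.00 10.00")), path)
  expect_warning(st <- read_structure(path), "unknown element")
  expect_equal(st$atoms$element[st$atoms$atom_name == "BR2"], "BR")
})

test_that("unparseable input raises a parse error naming the file", {
  path <- tempfile(fileext = ".cif")
  writeLines(c("data_X", "loop_", "_atom_site.id", "_atom_site.Cartn_x", "1 2 3"),
             path)
  expect_error(read_structure(path), "parse error")
  expect_error(read_structure(tempfile(fileext = ".cif")), "not found")
})

test_that("multi-model files score model 1 by default, all models on request", {
  fx <- fixture_structure("BR", "O-C", d = 3.4, theta1 = 170, theta2 = 110)
  atoms2 <- dplyr::mutate(fx$atoms, model_number = 2L,
                          x = x + 0.3)
  both <- dplyr::bind_rows(fx$atoms, atoms2)
  path <- tempfile(fileext = ".cif")
  write_structure(both, path, digits = 6)
  st1 <- read_structure(path)
  expect_true(all(st1$atoms$model_number == 1L))
  st_all <- read_structure(path, all_models = TRUE)
  expect_equal(sort(unique(st_all$atoms$model_number)), c(1L, 2L))
})
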