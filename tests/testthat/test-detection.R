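test_that("halogen sites honour the dictionary, exclusion list and altlocs", {
  # a ligand with three chlorines on ring carbons -> three sites
  base <- fixture_structure("CL", "O-C", d = 3.4, theta1 = 160, theta2 = 105)
  atoms <- base$atoms
  lig <- atoms[atoms$residue_name == "LIG", ]
  extra <- dplyr::bind_rows(
    dplyr::mutate(lig, atom_name = dplyr::recode(atom_name, C1 = "C2", CL1 = "CL2"),
                  y = y + 3.2),
    dplyr::mutate(lig, atom_name = dplyr::recode(atom_name, C1 = "C3", CL1 = "CL3"),
                  z = z + 3.2))
  atoms3 <- dplyr::bind_rows(atoms, extra)
  dict <- tibble::tibble(
    ccd_id = "LIG", component_type = "non-polymer",
    halogen_atom = c("CL1", "CL2", "CL3"), halogen_element = "CL",
    parent_atom = c("C1", "C2", "C3"), on_carbon = TRUE, excluded = FALSE)
  sites <- find_halogen_sites(atoms3, dict)
  expect_equal(nrow(sites), 3)
  expect_setequal(sites$atom_name, c("CL1", "CL2", "CL3"))
  expect_equal(unique(sites$parent_atom[sites$atom_name == "CL2"]), "C2")

  # iodide ions only -> no sites
  iod <- tibble::tibble(model_number = 1L, record = "HETATM", chain_id = "A",
                        residue_name = "IOD", residue_seq = 500L, ins_code = "",
                        atom_name = "I", element = "I", x = 0, y = 0, z = 0,
                        occupancy = 1, b_factor = 20, altloc = "")
  s0 <- find_halogen_sites(iod, NULL)
  expect_equal(nrow(s0), 0)
  expect_equal(attr(s0, "skipped")$reason, "excluded_compound")

  # alternate-conformation halogen -> no sites
  fx_alt <- fixture_structure("BR", "O-C", d = 3.4, theta1 = 170, theta2 = 110,
                              altloc_halogen = TRUE)
  s_alt <- find_halogen_sites(fx_alt$structure)
  expect_equal(nrow(s_alt), 0)
  expect_true("altloc" %in% attr(s_alt, "skipped")$reason)
})

test_that("atomic acceptor discovery applies the 4 A shell and water rule", {
  ok <- detect_halogen_bonds(
    fixture_structure("BR", "O-C", d = 3.5, theta1 = 160, theta2 = 105)$structure)
  expect_equal(nrow(ok), 1)
  expect_equal(ok$acceptor_class, "O-C")

  at_shell <- detect_halogen_bonds(
    fixture_structure("BR", "O-C", d = 4.0, theta1 = 160, theta2 = 105)$structure)
  expect_equal(nrow(at_shell), 1) # inclusive cutoff

  beyond <- detect_halogen_bonds(
    fixture_structure("BR", "O-C", d = 4.1, theta1 = 160, theta2 = 105)$structure)
  expect_equal(nrow(beyond), 0)

  # a water oxygen 3 A away never becomes an acceptor
  watered <- fixture_structure("BR", "O-C", d = 4.1, theta1 = 160, theta2 = 105,
                               water_near = TRUE)
  cand <- detect_halogen_bonds(watered$structure)
  expect_equal(nrow(cand), 0)
})

test_that("pi acceptor discovery applies the 6 A centroid shell", {
  one <- detect_halogen_bonds(
    fixture_structure("CL", "Phe", d = 4.8, theta1 = 150)$structure)
  expect_equal(nrow(one), 1)
  expect_equal(one$acceptor_class, "Phe")
  expect_equal(one$d, 4.8, tolerance = 1e-6)
  expect_true(is.na(one$theta2) && is.na(one$vdw_overlap))

  none <- detect_halogen_bonds(
    fixture_structure("CL", "Phe", d = 6.2, theta1 = 150)$structure)
  expect_equal(nrow(none), 0)

  his <- detect_halogen_bonds(
    fixture_structure("BR", "His", d = 5.0, theta1 = 155)$structure)
  expect_equal(nrow(his), 1)
  expect_equal(his$acceptor_class, "His") # 5-atom imidazole centroid
  expect_equal(his$d, 5.0, tolerance = 1e-6)
})

test_that("the sigma-hole filter removes theta1 <= 90 strictly", {
  cand <- tibble::tibble(theta1 = c(160, 89, 90, 90.0000001))
  kept <- apply_theta1_filter(cand)
  expect_equal(kept$theta1, c(160, 90.0000001))

  # end to end: a fixture built at theta1 = 85 is generated then culled
  fx <- fixture_structure("BR", "O-C", d = 3.4, theta1 = 85, theta2 = 110)
  sites <- find_halogen_sites(fx$structure)
  expect_equal(nrow(sites), 1)
  pre <- find_atomic_acceptors(sites, fx$structure)
  expect_equal(nrow(pre), 1)
  expect_equal(nrow(apply_theta1_filter(pre)), 0)
})

test_that("mining selection keeps theta1 closest to 180 with deterministic ties", {
  fx <- fixture_structure("I", "O-C", d = 3.5, theta1 = 120, theta2 = 100,
                          extra_acceptors = list(
                            list(kind = "O-C", d = 3.8, theta1 = 175, theta2 = 110)))
  cand <- detect_halogen_bonds(fx$structure)
  expect_equal(nrow(cand), 2)
  sel <- select_mining_acceptor(cand)
  expect_equal(nrow(sel), 1)
  expect_equal(sel$theta1, 175, tolerance = 1e-6)

  single <- select_mining_acceptor(cand[1, ])
  expect_equal(nrow(single), 1)

  # exact theta1 tie: the shorter distance wins, under both input orders
  tie <- cand
  tie$theta1 <- 150
  tie$d <- c(3.2, 3.9)
  for (perm in list(1:2, 2:1)) {
    got <- select_mining_acceptor(tie[perm, ])
    expect_equal(got$d, 3.2)
  }
})

test_that("detection is order-independent", {
  fx <- random_fixture(101)
  cand1 <- detect_halogen_bonds(fx$structure)
  set.seed(7)
  shuffled <- fx$structure
  shuffled$atoms <- shuffled$atoms[sample(nrow(shuffled$atoms)), ]
  cand2 <- detect_halogen_bonds(shuffled)
  expect_equal(as.data.frame(cand1), as.data.frame(cand2), ignore_attr = TRUE)
})

test_that("candidate sets equal an O(n^2) brute-force scan on fuzzed fixtures", {
  for (seed in 1:25) {
    fx <- random_fixture(seed)
    cand <- detect_halogen_bonds(fx$structure)
    got <- candidate_key_frame(cand)
    want <- brute_force_scan(fx$atoms, load_compound_dictionary(fx$structure))
    expect_equal(nrow(got), nrow(want), info = sprintf("seed %d", seed))
    if (nrow(got)) {
      expect_equal(got$hal, want$hal, info = sprintf("seed %d", seed))
      expect_equal(got$acc, want$acc, info = sprintf("seed %d", seed))
      expect_equal(got$d, want$d, tolerance = 1e-9)
      expect_equal(got$theta1, want$theta1, tolerance = 1e-9)
      expect_equal(got$theta2, want$theta2, tolerance = 1e-9)
    }
    # type invariants on every emitted candidate
    if (nrow(cand)) {
      expect_true(all(cand$theta1 > 90))
      expect_true(all(cand$d[cand$acceptor_kind == "atomic"] <= 4.0))
      expect_true(all(cand$d[cand$acceptor_kind == "pi"] <= 6.0))
      expect_false(any(cand$acc_residue_name %in% c("HOH", "WAT", "DOD")))
      expect_true(all(is.na(cand$theta2[cand$acceptor_kind == "pi"])))
      expect_true(all(!is.na(cand$theta2[cand$acceptor_kind == "atomic"])))
    }
  }
})
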