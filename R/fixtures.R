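# Synthetic mmCIF fixtures with exactly prescribed halogen-bond geometry.
#
# Construction places the halogen X at a fixed origin offset, its parent
# carbon along -x, the acceptor point at distance d and angle theta1 from
# the parent direction, and (atomic acceptors) the covalent neighbour at
# angle theta2. Rings are ideal planar polygons (1.39/1.37 A edges)
# perpendicular to the halogen-centroid axis, so the recomputed geometry
# equals the prescription to coordinate-rounding precision (8 decimals).

.FIX_ORIGIN <- c(20, 20, 20)

unit3 <- function(v) v / sqrt(sum(v^2))

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

# acceptor point at distance d, angle theta1 from the X->parent direction,
# azimuth phi around that axis
acceptor_point <- function(x, p_hat, d, theta1, phi = 0) {
  e1 <- if (abs(p_hat[3]) < 0.9) unit3(cross3(p_hat, c(0, 0, 1))) else unit3(cross3(p_hat, c(0, 1, 0)))
  e2 <- cross3(p_hat, e1)
  t1 <- theta1 * pi / 180
  x + d * (cos(t1) * p_hat + sin(t1) * (cos(phi) * e1 + sin(phi) * e2))
}

neighbor_point <- function(x, a, theta2, bond = 1.23) {
  u <- unit3(x - a)
  w <- if (abs(u[3]) < 0.9) unit3(cross3(u, c(0, 0, 1))) else unit3(cross3(u, c(0, 1, 0)))
  t2 <- theta2 * pi / 180
  a + bond * (cos(t2) * u + sin(t2) * w)
}

fixture_atom <- function(record, chain, resname, resseq, name, element,
                         pos, altloc = "", occupancy = 1, b = 20) {
  tibble(model_number = 1L, record = record, chain_id = chain,
         residue_name = resname, residue_seq = as.integer(resseq),
         ins_code = "", atom_name = name, element = element,
         x = pos[1], y = pos[2], z = pos[3],
         occupancy = occupancy, b_factor = b, altloc = altloc)
}

halogen_atom_name <- function(halogen) {
  c(F = "F1", CL = "CL1", BR = "BR1", I = "I1")[[halogen]]
}

#' Generate a structure fixture with prescribed halogen-bond geometry
#'
#' Emits a small, parseable mmCIF structure containing a minimal
#' halogen-bearing ligand (`LIG`: parent carbon + halogen, with embedded
#' chemical-component connectivity) and a protein fragment carrying the
#' requested acceptor — a backbone carbonyl (`O-C`, alanine), a thiol
#' sulfur (`S-C`, cysteine) or a complete aromatic ring (`His`, `Phe`,
#' `Tyr`, `Trp`) — positioned so that the recomputed bond geometry equals
#' the prescription. For tryptophan the 6-membered indole ring is built.
#'
#' @param halogen `"F"`, `"CL"`, `"BR"` or `"I"`.
#' @param acceptor_kind `"O-C"`, `"S-C"`, `"His"`, `"Phe"`, `"Tyr"` or
#'   `"Trp"`.
#' @param d Halogen–acceptor (or –centroid) distance, Å (> 0; π ≥ ring
#'   clearance).
#' @param theta1 Angle at the halogen, degrees, in (0, 180).
#' @param theta2 Angle at the acceptor atom, degrees, in (0, 180); atomic
#'   acceptors only.
#' @param altloc_halogen Give the halogen alternate conformation `"A"`
#'   (it must then be excluded from detection).
#' @param water_near Add a water oxygen 3 Å from the halogen (water must
#'   never become an acceptor).
#' @param extra_acceptors A list of `list(kind =, d =, theta1 =,
#'   theta2 =)` specs for additional acceptors around the same halogen
#'   (placed at distinct azimuths).
#' @param hal_b B-factor of the halogen atom (Å²).
#' @param resolution Resolution written into the file's refinement
#'   metadata (Å); `NA` omits it.
#' @param block_name mmCIF data block name.
#' @return A list: `cif` (character vector of mmCIF lines), `structure`
#'   (the equivalent in-memory `halbs_structure`), `truth` (tibble of the
#'   prescribed geometry per acceptor), `atoms`.
#' @examples
#' fx <- fixture_structure("BR", "O-C", d = 3.4, theta1 = 170, theta2 = 110)
#' fx$truth
#' @export
fixture_structure <- function(halogen = c("BR", "F", "CL", "I"),
                              acceptor_kind = c("O-C", "S-C", "His", "Phe", "Tyr", "Trp"),
                              d, theta1, theta2 = NULL,
                              altloc_halogen = FALSE, water_near = FALSE,
                              extra_acceptors = list(),
                              hal_b = 20, resolution = 2.0,
                              block_name = "fixture") {
  halogen <- match.arg(toupper(halogen), c("BR", "F", "CL", "I"))
  acceptor_kind <- match.arg(acceptor_kind)
  atomic <- acceptor_kind %in% c("O-C", "S-C")
  if (!is.finite(d) || d <= 0) abort("fixture_structure(): d must be > 0")
  if (!is.finite(theta1) || theta1 <= 0 || theta1 >= 180) {
    abort("fixture_structure(): theta1 must lie in (0, 180)")
  }
  if (atomic) {
    if (is.null(theta2)) abort("fixture_structure(): atomic acceptors need theta2")
    if (!is.finite(theta2) || theta2 <= 0 || theta2 >= 180) {
      abort("fixture_structure(): theta2 must lie in (0, 180)")
    }
  } else if (d < 1.5) {
    abort("fixture_structure(): pi centroid distance below ring clearance")
  }

  x_pos <- .FIX_ORIGIN
  p_hat <- c(-1, 0, 0)
  parent_pos <- x_pos + 1.80 * p_hat
  hal_name <- halogen_atom_name(halogen)

  atoms <- bind_rows(
    fixture_atom("HETATM", "L", "LIG", 501L, "C1", "C", parent_pos),
    fixture_atom("HETATM", "L", "LIG", 501L, hal_name, halogen, x_pos,
                 altloc = if (altloc_halogen) "A" else "", b = hal_b)
  )

  specs <- c(list(list(kind = acceptor_kind, d = d, theta1 = theta1,
                       theta2 = theta2)),
             extra_acceptors)
  phis <- seq(0, by = 2 * pi / 5, length.out = length(specs))

  truth <- list()
  for (i in seq_along(specs)) {
    sp <- specs[[i]]
    built <- build_acceptor(sp, x_pos, p_hat, phis[i], resseq = 96L + i)
    atoms <- bind_rows(atoms, built$atoms)
    truth[[i]] <- built$truth
  }
  truth <- list_rbind(truth)

  if (water_near) {
    w <- acceptor_point(x_pos, p_hat, 3.0, 135, phi = pi)
    atoms <- bind_rows(atoms, fixture_atom("HETATM", "W", "HOH", 601L, "O", "O", w))
  }

  cif <- fixture_cif(atoms, halogen, hal_name, resolution, block_name)
  st <- new_halbs_structure(
    atoms,
    tibble(resolution = if (is.finite(resolution)) resolution else NA_real_,
           r_factor = NA_real_, r_free = NA_real_,
           mean_b = mean(atoms$b_factor)),
    fixture_chem_comp(halogen, hal_name), paste0("<fixture:", block_name, ">"))
  list(cif = cif, structure = st, truth = truth, atoms = atoms)
}

build_acceptor <- function(sp, x_pos, p_hat, phi, resseq) {
  kind <- sp$kind
  if (kind == "O-C") {
    a <- acceptor_point(x_pos, p_hat, sp$d, sp$theta1, phi)
    nb <- neighbor_point(x_pos, a, sp$theta2, bond = 1.23)
    atoms <- bind_rows(
      fixture_atom("ATOM", "A", "ALA", resseq, "C", "C", nb),
      fixture_atom("ATOM", "A", "ALA", resseq, "O", "O", a)
    )
    truth <- tibble(acceptor_kind = "atomic", acceptor_class = "O-C",
                    acc_residue_name = "ALA", acc_residue_seq = resseq,
                    acc_atom = "O", d = sp$d, theta1 = sp$theta1,
                    theta2 = sp$theta2)
  } else if (kind == "S-C") {
    a <- acceptor_point(x_pos, p_hat, sp$d, sp$theta1, phi)
    nb <- neighbor_point(x_pos, a, sp$theta2, bond = 1.81)
    atoms <- bind_rows(
      fixture_atom("ATOM", "A", "CYS", resseq, "CB", "C", nb),
      fixture_atom("ATOM", "A", "CYS", resseq, "SG", "S", a)
    )
    truth <- tibble(acceptor_kind = "atomic", acceptor_class = "S-C",
                    acc_residue_name = "CYS", acc_residue_seq = resseq,
                    acc_atom = "SG", d = sp$d, theta1 = sp$theta1,
                    theta2 = sp$theta2)
  } else {
    resname <- toupper(kind)
    resname <- c(HIS = "HIS", PHE = "PHE", TYR = "TYR", TRP = "TRP")[[resname]]
    cen <- acceptor_point(x_pos, p_hat, sp$d, sp$theta1, phi)
    ring <- switch(resname,
      HIS = list(names = .PI_RINGS$HIS$ring, edge = 1.37, label = "ring"),
      PHE = list(names = .PI_RINGS$PHE$ring, edge = 1.39, label = "ring"),
      TYR = list(names = .PI_RINGS$TYR$ring, edge = 1.39, label = "ring"),
      TRP = list(names = .PI_RINGS$TRP$ring6, edge = 1.39, label = "ring6")
    )
    nring <- length(ring$names)
    r_circ <- ring$edge / (2 * sin(pi / nring))
    u <- unit3(cen - x_pos)
    f1 <- if (abs(u[3]) < 0.9) unit3(cross3(u, c(0, 0, 1))) else unit3(cross3(u, c(0, 1, 0)))
    f2 <- cross3(u, f1)
    elems <- ifelse(startsWith(ring$names, "N"), "N", "C")
    ring_atoms <- purrr::imap(ring$names, function(nm, k) {
      ang <- 2 * pi * (k - 1) / nring
      fixture_atom("ATOM", "A", resname, resseq, nm,
                   elems[k], cen + r_circ * (cos(ang) * f1 + sin(ang) * f2))
    }) |> list_rbind()
    atoms <- ring_atoms
    truth <- tibble(acceptor_kind = "pi", acceptor_class = .PI_CLASS[[resname]],
                    acc_residue_name = resname, acc_residue_seq = resseq,
                    acc_atom = ring$label, d = sp$d, theta1 = sp$theta1,
                    theta2 = NA_real_)
  }
  list(atoms = atoms, truth = truth)
}

fixture_chem_comp <- function(halogen, hal_name) {
  list(
    comp = tibble(id = "LIG", type = "non-polymer"),
    atoms = tibble(comp_id = c("LIG", "LIG"), atom_id = c("C1", hal_name),
                   type_symbol = c("C", halogen)),
    bonds = tibble(comp_id = "LIG", atom_id_1 = "C1", atom_id_2 = hal_name)
  )
}

fixture_cif <- function(atoms, halogen, hal_name, resolution, block_name) {
  fmt <- function(v) sprintf("%.8f", v)
  rows <- sprintf(
    "%s %d %s %s %s %s %s %d ? %s %s %s %.2f %.2f %d %s %s %s %d",
    atoms$record, seq_len(nrow(atoms)), cif_quote(atoms$element),
    cif_quote(atoms$atom_name),
    ifelse(atoms$altloc == "", ".", atoms$altloc),
    cif_quote(atoms$residue_name), cif_quote(atoms$chain_id),
    atoms$residue_seq,
    fmt(atoms$x), fmt(atoms$y), fmt(atoms$z),
    atoms$occupancy, atoms$b_factor,
    atoms$residue_seq, cif_quote(atoms$residue_name),
    cif_quote(atoms$chain_id), cif_quote(atoms$atom_name),
    atoms$model_number
  )
  lines <- c(
    paste0("data_", block_name),
    "#",
    if (is.finite(resolution)) c(
      sprintf("_refine.ls_d_res_high %.2f", resolution), "#"),
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.label_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.label_comp_id",
    "_atom_site.label_asym_id",
    "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.auth_seq_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num",
    rows,
    "#",
    "loop_",
    "_chem_comp.id",
    "_chem_comp.type",
    "LIG non-polymer",
    "#",
    "loop_",
    "_chem_comp_atom.comp_id",
    "_chem_comp_atom.atom_id",
    "_chem_comp_atom.type_symbol",
    "LIG C1 C",
    sprintf("LIG %s %s", hal_name, halogen),
    "#",
    "loop_",
    "_chem_comp_bond.comp_id",
    "_chem_comp_bond.atom_id_1",
    "_chem_comp_bond.atom_id_2",
    sprintf("LIG C1 %s", hal_name),
    "#"
  )
  lines
}

#' Write a fixture as a legacy PDB file
#'
#' Companion to [fixture_structure()] for the dual-format reader test:
#' renders the fixture's atoms as fixed-width ATOM/HETATM records
#' (coordinates at PDB's 3-decimal precision).
#'
#' @param fx A fixture from [fixture_structure()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fixture_pdb <- function(fx, path) {
  at <- fx$atoms
  lines <- sprintf(
    "%-6s%5d %-4s%1s%3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    at$record, seq_len(nrow(at)),
    ifelse(nchar(at$atom_name) < 4, paste0(" ", at$atom_name), at$atom_name),
    ifelse(at$altloc == "", " ", at$altloc),
    at$residue_name, at$chain_id, at$residue_seq,
    at$x, at$y, at$z, at$occupancy, at$b_factor, at$element
  )
  writeLines(c(lines, "END"), path)
  invisible(path)
}

#' Generate a synthetic calibration corpus
#'
#' Draws `n` independent halogen-bond geometries from stated parametric
#' laws — normal distance truncated to (0, shell], normal angles truncated
#' to (90, 180) for theta1 and (0, 180) for theta2 — and builds one
#' fixture structure per draw, together with the sidecar metadata and
#' RSCC tables [calibrate()] consumes and the quartiles of the generating
#' laws. Deterministic under `seed`, using R's default Mersenne-Twister
#' generator.
#'
#' @param n Number of bonds (≥ 1).
#' @param halogen,acceptor_kind Category of every bond.
#' @param d_mean,d_sd Distance law (Å).
#' @param theta1_mean,theta1_sd theta1 law (degrees).
#' @param theta2_mean,theta2_sd theta2 law (degrees; atomic only).
#' @param seed Integer seed.
#' @param resolution,rscc_value,hal_b Quality metadata given to every
#'   entry (defaults pass the calibration filter).
#' @return A list: `structures` (named list of `halbs_structure`),
#'   `draws` (tibble of the generated parameter values), `metadata`,
#'   `rscc` (sidecar tibbles for [calibrate()]), `law_quartiles`
#'   (analytic Q1/median/Q3 of the untruncated laws), `sample_quartiles`
#'   (type-7 quartiles of the drawn values).
#' @export
fixture_corpus <- function(n, halogen = "BR", acceptor_kind = "O-C",
                           d_mean = 3.5, d_sd = 0.2,
                           theta1_mean = 155, theta1_sd = 12,
                           theta2_mean = 105, theta2_sd = 10,
                           seed = 1L, resolution = 2.0, rscc_value = 0.95,
                           hal_b = 20) {
  stopifnot(n >= 1)
  atomic <- acceptor_kind %in% c("O-C", "S-C")
  shell <- if (atomic) 4.0 else 6.0
  set.seed(seed)
  rtrunc <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
      x <- rnorm(n, mean, sd)
      out <- c(out, x[x > lo & x < hi])
    }
    out[seq_len(n)]
  }
  d <- rtrunc(n, d_mean, d_sd, 0, shell)
  theta1 <- rtrunc(n, theta1_mean, theta1_sd, 90, 180)
  theta2 <- if (atomic) rtrunc(n, theta2_mean, theta2_sd, 0, 180) else rep(NA_real_, n)

  ids <- sprintf("entry%04d", seq_len(n))
  structures <- setNames(vector("list", n), ids)
  for (i in seq_len(n)) {
    fx <- fixture_structure(halogen, acceptor_kind, d = d[i],
                            theta1 = theta1[i],
                            theta2 = if (atomic) theta2[i] else NULL,
                            hal_b = hal_b, resolution = resolution,
                            block_name = ids[i])
    structures[[i]] <- fx$structure
  }
  draws <- tibble(entry_id = ids, d = d, theta1 = theta1, theta2 = theta2)

  metadata <- tibble(entry_id = ids, resolution = resolution)
  rscc <- bind_rows(
    tibble(entry_id = ids, chain_id = "L", residue_seq = 501L, rscc = rscc_value),
    tibble(entry_id = ids, chain_id = "A", residue_seq = 97L, rscc = rscc_value)
  )

  law_q <- function(mean, sd) qnorm(c(0.25, 0.5, 0.75), mean, sd)
  samp_q <- function(v) unname(quantile(v, c(0.25, 0.5, 0.75), type = 7))
  params <- c("distance", "theta1", if (atomic) "theta2")
  law_quartiles <- list_rbind(list(
    tibble(parameter = "distance", q1 = law_q(d_mean, d_sd)[1],
           median = law_q(d_mean, d_sd)[2], q3 = law_q(d_mean, d_sd)[3]),
    tibble(parameter = "theta1", q1 = law_q(theta1_mean, theta1_sd)[1],
           median = law_q(theta1_mean, theta1_sd)[2],
           q3 = law_q(theta1_mean, theta1_sd)[3]),
    if (atomic) tibble(parameter = "theta2", q1 = law_q(theta2_mean, theta2_sd)[1],
                       median = law_q(theta2_mean, theta2_sd)[2],
                       q3 = law_q(theta2_mean, theta2_sd)[3])
  ))
  sample_quartiles <- list_rbind(list(
    tibble(parameter = "distance", q1 = samp_q(d)[1], median = samp_q(d)[2],
           q3 = samp_q(d)[3]),
    tibble(parameter = "theta1", q1 = samp_q(theta1)[1],
           median = samp_q(theta1)[2], q3 = samp_q(theta1)[3]),
    if (atomic) tibble(parameter = "theta2", q1 = samp_q(theta2)[1],
                       median = samp_q(theta2)[2], q3 = samp_q(theta2)[3])
  ))
  list(structures = structures, draws = draws, metadata = metadata,
       rscc = rscc, law_quartiles = law_quartiles,
       sample_quartiles = sample_quartiles, seed = seed,
       halogen = toupper(halogen), acceptor_kind = acceptor_kind)
}
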