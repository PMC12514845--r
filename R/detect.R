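# Candidate enumeration: halogen sites, atomic acceptors, pi acceptors,
# geometric filters. All functions are deterministic and order-independent:
# outputs are sorted on identity columns before return.

residue_key <- function(df, prefix = "") {
  paste(df[[paste0(prefix, "model_number")]] %||% df$model_number,
        df[[paste0(prefix, "chain_id")]], df[[paste0(prefix, "residue_seq")]],
        df[[paste0(prefix, "ins_code")]], df[[paste0(prefix, "residue_name")]],
        sep = "|")
}

#' Find halogen sites in a structure
#'
#' A halogen site is a F/Cl/Br/I atom in a non-excluded halogen-containing
#' compound, covalently bonded to a carbon atom, and not in an alternate
#' conformation. The parent carbon is resolved from the compound dictionary
#' when one is available and otherwise by a bond-distance heuristic
#' (nearest carbon in the same residue within 1.9 Å).
#'
#' @param x A `halbs_structure` or atom tibble.
#' @param dictionary Compound dictionary tibble from
#'   [load_compound_dictionary()], or `NULL` to use only what is embedded
#'   in `x` (falling back to the distance heuristic).
#' @return A tibble of halogen sites: halogen identity and coordinates,
#'   `parent_atom` and its coordinates (`px`, `py`, `pz`),
#'   `compound_class` (`ligand`, `non-canonical-residue`, `nucleotide`,
#'   `other`). Sites that had to be skipped (excluded compound, altloc,
#'   non-carbon halogen, unresolvable parent) are recorded in the
#'   `"skipped"` attribute with a reason code.
#' @export
find_halogen_sites <- function(x, dictionary = NULL) {
  atoms <- as_atom_table(x)
  if (inherits(x, "halbs_structure") && !is.null(x$chem_comp)) {
    embedded <- load_compound_dictionary(x)
    dictionary <- merge_dictionaries(dictionary, embedded)
  }
  if (is.null(dictionary)) dictionary <- empty_dictionary()

  skipped <- tibble(chain_id = character(), residue_name = character(),
                    residue_seq = integer(), atom_name = character(),
                    reason = character())
  note_skip <- function(rows, reason) {
    if (!nrow(rows)) return()
    skipped <<- bind_rows(skipped, tibble(
      chain_id = rows$chain_id, residue_name = rows$residue_name,
      residue_seq = rows$residue_seq, atom_name = rows$atom_name,
      reason = reason))
  }

  hal <- dplyr::filter(atoms, .data$element %in% .HALOGENS)
  note_skip(dplyr::filter(hal, .data$altloc != ""), "altloc")
  hal <- dplyr::filter(hal, .data$altloc == "")
  note_skip(dplyr::filter(hal, .data$residue_name %in% excluded_compound_ids()),
            "excluded_compound")
  hal <- dplyr::filter(hal, !(.data$residue_name %in% excluded_compound_ids()))
  if (!nrow(hal)) {
    return(structure(empty_sites(), skipped = skipped))
  }

  dict_excluded <- unique(dictionary$ccd_id[dictionary$excluded])
  note_skip(dplyr::filter(hal, .data$residue_name %in% dict_excluded),
            "excluded_compound")
  hal <- dplyr::filter(hal, !(.data$residue_name %in% dict_excluded))

  akey <- residue_key(atoms)
  sites <- pmap(hal, function(...) {
    h <- tibble(...)
    dent <- dplyr::filter(dictionary, .data$ccd_id == h$residue_name,
                          .data$halogen_atom == h$atom_name)
    parent_name <- NA_character_
    ctype <- NA_character_
    if (nrow(dent)) {
      dent <- dent[1, ]
      ctype <- dent$component_type
      if (isFALSE(dent$on_carbon)) {
        note_skip(h, "halogen_not_on_carbon")
        return(NULL)
      }
      parent_name <- dent$parent_atom
    }
    same_res <- atoms[akey == residue_key(h) & atoms$atom_name != h$atom_name, ]
    parent <- NULL
    if (!is.na(parent_name)) {
      parent <- dplyr::filter(same_res, .data$atom_name == parent_name)
      parent <- head(parent, 1L)
    }
    if (is.null(parent) || !nrow(parent)) {
      # bond-distance fallback: nearest carbon within 1.9 A
      cs <- dplyr::filter(same_res, .data$element == "C")
      if (nrow(cs)) {
        dd <- sqrt((cs$x - h$x)^2 + (cs$y - h$y)^2 + (cs$z - h$z)^2)
        if (min(dd) <= 1.9) parent <- cs[which.min(dd), ] else parent <- NULL
      } else parent <- NULL
    }
    if (is.null(parent) || !nrow(parent)) {
      note_skip(h, "no_parent_carbon")
      return(NULL)
    }
    mutate(h,
           parent_atom = parent$atom_name,
           px = parent$x, py = parent$y, pz = parent$z,
           compound_class = classify_compound(ctype, h$residue_name, h$record))
  })
  sites <- list_rbind(keep(sites, Negate(is.null)))
  if (!nrow(sites)) return(structure(empty_sites(), skipped = skipped))
  sites <- arrange(sites, .data$model_number, .data$chain_id,
                   .data$residue_seq, .data$ins_code, .data$atom_name)
  structure(sites, skipped = skipped)
}

empty_sites <- function() {
  tibble(model_number = integer(), record = character(), chain_id = character(),
         residue_name = character(), residue_seq = integer(),
         ins_code = character(), atom_name = character(), element = character(),
         x = double(), y = double(), z = double(), occupancy = double(),
         b_factor = double(), altloc = character(), parent_atom = character(),
         px = double(), py = double(), pz = double(),
         compound_class = character())
}

classify_compound <- function(component_type, residue_name, record) {
  if (!is.na(component_type)) {
    ct <- tolower(component_type)
    if (grepl("non-polymer", ct)) return("ligand")
    if (grepl("peptide", ct)) return("non-canonical-residue")
    if (grepl("dna|rna|nucleotide|linking", ct)) return("nucleotide")
    return("other")
  }
  if (identical(record, "HETATM")) return("ligand")
  if (residue_name %in% .CANONICAL_AA) return("other")
  "non-canonical-residue"
}

acceptor_table_for <- function(residue_name) {
  side <- dplyr::filter(.SIDECHAIN_ACCEPTORS, .data$residue_name == !!residue_name)
  bind_rows(.BACKBONE_ACCEPTORS, select(side, -"residue_name"))
}

#' Find atomic acceptors for halogen sites
#'
#' Scans for C–X··Y candidates: oxygen or sulfur atoms of canonical amino
#' acids within `max_d` of each halogen, whose covalent heavy-atom
#' neighbours are all carbon (acceptor classes `O-C` / `S-C`). Water is
#' never an acceptor, alternate-conformation atoms and atoms of the
#' halogen's own residue are skipped, and an acceptor whose covalent
#' neighbour is missing from the coordinates is rejected (theta2 would be
#' undefined). Acceptors with several covalent neighbours (methionine SD)
#' yield one candidate row per neighbour; scoring keeps the lower
#' theta2-score row.
#'
#' With `survey = TRUE` the scan widens to the discovery rule used for
#' mining surveys — any O/N/S/P/Se atom of any organic (non-water)
#' compound — without the neighbour requirement; such rows carry
#' `acceptor_class = "other"` and no theta2.
#'
#' @param sites Halogen-site tibble from [find_halogen_sites()].
#' @param x The structure (`halbs_structure` or atom tibble).
#' @param max_d Distance shell in Å (default 4.0, inclusive).
#' @param survey Widen to the O/N/S/P/Se discovery rule.
#' @param radii Van der Waals radius table.
#' @return A candidate tibble (see [detect_halogen_bonds()]).
#' @export
find_atomic_acceptors <- function(sites, x, max_d = 4.0, survey = FALSE,
                                  radii = vdw_radii()) {
  atoms <- as_atom_table(x)
  if (!nrow(sites)) return(empty_candidates())
  acc_pool <- dplyr::filter(atoms,
    .data$altloc == "",
    !(.data$residue_name %in% .WATER_NAMES))
  if (survey) {
    acc_pool <- dplyr::filter(acc_pool, .data$element %in% c("O", "N", "S", "P", "SE"))
  } else {
    acc_pool <- dplyr::filter(acc_pool,
      .data$residue_name %in% .CANONICAL_AA,
      .data$element %in% c("O", "S"))
  }
  if (!nrow(acc_pool)) return(empty_candidates())

  pool_key <- residue_key(acc_pool)
  atoms_key <- residue_key(atoms)

  out <- pmap(sites, function(...) {
    h <- tibble(...)
    hkey <- residue_key(h)
    dd <- sqrt((acc_pool$x - h$x)^2 + (acc_pool$y - h$y)^2 + (acc_pool$z - h$z)^2)
    sel <- acc_pool[dd <= max_d & pool_key != hkey &
                      acc_pool$model_number == h$model_number, ]
    if (!nrow(sel)) return(NULL)
    rows <- pmap(sel, function(...) {
      a <- tibble(...)
      if (survey) {
        geom <- compute_bond_geometry(
          c(h$x, h$y, h$z), c(h$px, h$py, h$pz), c(a$x, a$y, a$z),
          neighbor = NULL, pi_acceptor = TRUE)
        geom$vdw_overlap <- vdw_overlap(geom$d, h$element, a$element, radii)
        return(candidate_row(h, a, geom, neighbor_atom = NA_character_,
                             neighbor_rank = NA_integer_,
                             acceptor_class = "other", kind = "atomic"))
      }
      tab <- acceptor_table_for(a$residue_name)
      tab <- dplyr::filter(tab, .data$atom_name == a$atom_name,
                           .data$element == a$element)
      if (!nrow(tab)) return(NULL)
      neighbors <- tab$neighbors[[1]]
      res_atoms <- atoms[atoms_key == residue_key(a) & atoms$altloc == "", ]
      found <- purrr::imap(neighbors, function(nb_name, rank) {
        nb <- dplyr::filter(res_atoms, .data$atom_name == nb_name)
        if (!nrow(nb)) return(NULL)
        nb <- nb[1, ]
        geom <- compute_bond_geometry(
          c(h$x, h$y, h$z), c(h$px, h$py, h$pz), c(a$x, a$y, a$z),
          neighbor = c(nb$x, nb$y, nb$z),
          element_x = h$element, element_y = a$element, radii = radii)
        candidate_row(h, a, geom, neighbor_atom = nb_name,
                      neighbor_rank = as.integer(rank),
                      acceptor_class = if (a$element == "S") "S-C" else "O-C",
                      kind = "atomic")
      })
      found <- keep(found, Negate(is.null))
      if (!length(found)) return(NULL) # neighbour missing: theta2 undefined
      list_rbind(found)
    })
    rows <- keep(rows, Negate(is.null))
    if (!length(rows)) return(NULL)
    list_rbind(rows)
  })
  finish_candidates(out)
}

#' Find π acceptors for halogen sites
#'
#' Scans for C–X···Π candidates: aromatic side-chain rings of His, Phe,
#' Tyr and Trp whose centroid is within `max_d` of the halogen. theta1 is
#' measured to the centroid; theta2 and the Van der Waals overlap are not
#' defined for π acceptors. Tryptophan contributes one candidate per
#' indole ring by default (`trp_rings = "each"`: 5- and 6-membered;
#' downstream selection keeps the better-scoring one) or a single
#' whole-indole centroid (`trp_rings = "indole"`). Residues with
#' incomplete rings are skipped.
#'
#' @param sites Halogen-site tibble.
#' @param x The structure.
#' @param max_d Centroid distance shell in Å (default 6.0, inclusive).
#' @param trp_rings `"each"` or `"indole"`.
#' @return A candidate tibble (see [detect_halogen_bonds()]).
#' @export
find_pi_acceptors <- function(sites, x, max_d = 6.0,
                              trp_rings = c("each", "indole")) {
  trp_rings <- match.arg(trp_rings)
  atoms <- as_atom_table(x)
  if (!nrow(sites)) return(empty_candidates())
  aro <- dplyr::filter(atoms, .data$residue_name %in% names(.PI_RINGS),
                       .data$altloc == "")
  if (!nrow(aro)) return(empty_candidates())
  rings <- aro |>
    group_by(.data$model_number, .data$chain_id, .data$residue_seq,
             .data$ins_code, .data$residue_name) |>
    tidyr::nest(.key = "res_atoms") |>
    ungroup()

  ring_defs <- function(resname) {
    defs <- .PI_RINGS[[resname]]
    if (resname == "TRP") {
      if (trp_rings == "indole") defs <- defs["indole"] else defs <- defs[c("ring5", "ring6")]
    }
    defs
  }

  centroids <- pmap(rings, function(model_number, chain_id, residue_seq,
                                    ins_code, residue_name, res_atoms) {
    defs <- ring_defs(residue_name)
    rows <- purrr::imap(defs, function(names_needed, label) {
      got <- res_atoms[match(names_needed, res_atoms$atom_name), ]
      if (anyNA(got$atom_name)) return(NULL) # incomplete ring
      cen <- ring_centroid(got)
      tibble(model_number = model_number, chain_id = chain_id,
             residue_seq = residue_seq, ins_code = ins_code,
             residue_name = residue_name, ring = label,
             cx = cen[1], cy = cen[2], cz = cen[3])
    })
    rows <- keep(rows, Negate(is.null))
    if (!length(rows)) return(NULL)
    list_rbind(rows)
  })
  centroids <- keep(centroids, Negate(is.null))
  if (!length(centroids)) return(empty_candidates())
  centroids <- list_rbind(centroids)

  out <- pmap(sites, function(...) {
    h <- tibble(...)
    hkey <- residue_key(h)
    dd <- sqrt((centroids$cx - h$x)^2 + (centroids$cy - h$y)^2 + (centroids$cz - h$z)^2)
    sel <- centroids[dd <= max_d & centroids$model_number == h$model_number &
                       residue_key(centroids) != hkey, ]
    if (!nrow(sel)) return(NULL)
    rows <- pmap(sel, function(...) {
      r <- tibble(...)
      geom <- compute_bond_geometry(
        c(h$x, h$y, h$z), c(h$px, h$py, h$pz), c(r$cx, r$cy, r$cz),
        pi_acceptor = TRUE)
      a <- tibble(model_number = r$model_number, chain_id = r$chain_id,
                  residue_name = r$residue_name, residue_seq = r$residue_seq,
                  ins_code = r$ins_code, atom_name = r$ring)
      candidate_row(h, a, geom, neighbor_atom = NA_character_,
                    neighbor_rank = NA_integer_,
                    acceptor_class = .PI_CLASS[[r$residue_name]], kind = "pi")
    })
    list_rbind(rows)
  })
  finish_candidates(out)
}

candidate_row <- function(h, a, geom, neighbor_atom, neighbor_rank,
                          acceptor_class, kind) {
  tibble(
    model_number = h$model_number,
    hal_chain = h$chain_id, hal_residue_name = h$residue_name,
    hal_residue_seq = h$residue_seq, hal_ins_code = h$ins_code,
    hal_atom = h$atom_name, hal_element = h$element,
    hal_b_factor = h$b_factor, compound_class = h$compound_class,
    acceptor_kind = kind,
    acc_chain = a$chain_id, acc_residue_name = a$residue_name,
    acc_residue_seq = a$residue_seq, acc_ins_code = a$ins_code,
    acc_atom = a$atom_name,
    neighbor_atom = neighbor_atom, neighbor_rank = neighbor_rank,
    acceptor_class = acceptor_class,
    d = geom$d, vdw_overlap = geom$vdw_overlap,
    theta1 = geom$theta1, theta2 = geom$theta2
  )
}

empty_candidates <- function() {
  candidate_row(
    tibble(model_number = integer(), chain_id = character(),
           residue_name = character(), residue_seq = integer(),
           ins_code = character(), atom_name = character(),
           element = character(), b_factor = double(),
           compound_class = character()),
    tibble(chain_id = character(), residue_name = character(),
           residue_seq = integer(), ins_code = character(),
           atom_name = character()),
    tibble(d = double(), vdw_overlap = double(), theta1 = double(),
           theta2 = double()),
    neighbor_atom = character(), neighbor_rank = integer(),
    acceptor_class = character(), kind = character()
  )
}

finish_candidates <- function(rows) {
  rows <- keep(rows, Negate(is.null))
  if (!length(rows)) return(empty_candidates())
  arrange(list_rbind(rows),
          .data$model_number, .data$hal_chain, .data$hal_residue_seq,
          .data$hal_ins_code, .data$hal_atom, .data$acceptor_kind,
          .data$acc_chain, .data$acc_residue_seq, .data$acc_ins_code,
          .data$acc_atom, .data$neighbor_rank)
}

#' Remove candidates whose σ-hole is unreachable
#'
#' Keeps only candidates with theta1 strictly greater than 90°: smaller
#' angles place the acceptor on the covalent-bond side of the halogen,
#' where the σ-hole cannot be reached. The boundary value 90.0° is
#' rejected.
#'
#' @param candidates Candidate tibble.
#' @return The filtered tibble.
#' @export
apply_theta1_filter <- function(candidates) {
  dplyr::filter(candidates, .data$theta1 > 90)
}

#' Select one acceptor per halogen for mining/calibration
#'
#' When a halogen has several possible acceptors, calibration keeps the one
#' whose theta1 is closest to 180° (the most σ-hole-aligned geometry).
#' Exact theta1 ties are broken by smaller distance, then by acceptor
#' chain/residue/atom order, so the choice is deterministic. Multiple
#' neighbour rows of one acceptor (methionine SD) collapse to the
#' first-listed neighbour.
#'
#' @param candidates Candidate tibble (typically theta1-filtered).
#' @return A tibble with one row per halogen site; zero rows for empty
#'   input.
#' @export
select_mining_acceptor <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  candidates |>
    group_by(across(dplyr::any_of(c(
      "entry_id", "model_number", "hal_chain", "hal_residue_name",
      "hal_residue_seq", "hal_ins_code", "hal_atom")))) |>
    arrange(dplyr::desc(.data$theta1), .data$d, .data$acc_chain,
            .data$acc_residue_seq, .data$acc_ins_code, .data$acc_atom,
            .data$neighbor_rank, .by_group = TRUE) |>
    slice(1L) |>
    ungroup()
}

#' Detect halogen-bond candidates in a structure
#'
#' End-to-end enumeration: finds halogen sites ([find_halogen_sites()]),
#' their atomic acceptors within 4 Å ([find_atomic_acceptors()]) and π
#' acceptors within 6 Å of a ring centroid ([find_pi_acceptors()]),
#' computes all geometric descriptors, and removes candidates with
#' theta1 ≤ 90° ([apply_theta1_filter()]).
#'
#' @param x A `halbs_structure` (from [read_structure()]) or atom tibble.
#' @param dictionary Optional compound dictionary
#'   ([load_compound_dictionary()]); connectivity embedded in `x` wins on
#'   conflict.
#' @param max_d,max_d_pi Distance shells (Å, inclusive) for atomic and π
#'   acceptors.
#' @param trp_rings Tryptophan ring handling, see [find_pi_acceptors()].
#' @param survey Widen atomic-acceptor discovery, see
#'   [find_atomic_acceptors()].
#' @param radii Van der Waals radius table.
#' @return A candidate tibble, one row per (halogen, acceptor, neighbour):
#'   halogen and acceptor identities, `acceptor_kind` (`atomic`/`pi`),
#'   `acceptor_class` (`O-C`, `S-C`, `His`, `Phe`, `Tyr`, `Trp`), and the
#'   geometry columns `d`, `vdw_overlap`, `theta1`, `theta2` (the last two
#'   `NA` for π acceptors). The `"skipped"` attribute carries the
#'   halogen-site skip log.
#' @examples
#' fx <- fixture_structure("BR", "O-C", d = 3.4, theta1 = 170, theta2 = 110)
#' path <- tempfile(fileext = ".cif")
#' writeLines(fx$cif, path)
#' detect_halogen_bonds(read_structure(path))
#' @export
detect_halogen_bonds <- function(x, dictionary = NULL, max_d = 4.0,
                                 max_d_pi = 6.0,
                                 trp_rings = c("each", "indole"),
                                 survey = FALSE, radii = vdw_radii()) {
  trp_rings <- match.arg(trp_rings)
  sites <- find_halogen_sites(x, dictionary)
  atomic <- find_atomic_acceptors(sites, x, max_d = max_d, survey = survey,
                                  radii = radii)
  pis <- find_pi_acceptors(sites, x, max_d = max_d_pi, trp_rings = trp_rings)
  cand <- finish_candidates(list(atomic, pis))
  cand <- apply_theta1_filter(cand)
  structure(cand, skipped = attr(sites, "skipped"))
}
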