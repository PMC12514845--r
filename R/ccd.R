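#' Load a chemical-component dictionary
#'
#' Builds a per-compound table of halogen atoms and their covalent carbon
#' parents from Chemical Component Dictionary (CCD) style definitions. The
#' source can be a path to a CCD-style mmCIF file (one or more `data_`
#' blocks with `chem_comp_atom` / `chem_comp_bond` categories) or a
#' `halbs_structure` whose file embedded those categories; when both a full
#' dictionary and embedded blocks describe the same component, the embedded
#' definition wins.
#'
#' Only components containing at least one F/Cl/Br/I atom are indexed.
#' Components on [excluded_compound_ids()] are marked `excluded`. A halogen
#' whose single covalent neighbour is not a carbon — or whose component has
#' no bond records at all — is retained but flagged unscorable
#' (`on_carbon = FALSE` / `NA`), never dropped silently.
#'
#' @param source Path to a CCD-style mmCIF file, or a `halbs_structure`.
#' @return A tibble with one row per (compound, halogen atom):
#'   `ccd_id`, `component_type`, `halogen_atom`, `halogen_element`,
#'   `parent_atom` (name of the bonded carbon, `NA` if unresolvable),
#'   `on_carbon` (logical; `NA` when the component has no bond records),
#'   `excluded`.
#' @examples
#' fx <- fixture_structure("CL", "O-C", d = 3.3, theta1 = 165, theta2 = 100)
#' path <- tempfile(fileext = ".cif")
#' writeLines(fx$cif, path)
#' load_compound_dictionary(read_structure(path))
#' @export
load_compound_dictionary <- function(source) {
  if (inherits(source, "halbs_structure")) {
    cc <- source$chem_comp
    if (is.null(cc)) {
      return(empty_dictionary())
    }
    atoms <- cc$atoms
    bonds <- cc$bonds
    types <- cc$comp
  } else {
    blocks <- cif_read(source)
    atoms <- bonds <- types <- NULL
    for (b in blocks) {
      if ("chem_comp_atom" %in% names(b)) {
        ca <- b$chem_comp_atom
        # per-entry CCD blocks may omit comp_id in favour of the block name
        atoms <- bind_rows(atoms, ca)
        if ("chem_comp_bond" %in% names(b)) bonds <- bind_rows(bonds, b$chem_comp_bond)
        if ("chem_comp" %in% names(b)) types <- bind_rows(types, b$chem_comp)
      }
    }
    if (is.null(atoms)) return(empty_dictionary())
  }
  build_dictionary(atoms, bonds, types)
}

empty_dictionary <- function() {
  tibble(ccd_id = character(), component_type = character(),
         halogen_atom = character(), halogen_element = character(),
         parent_atom = character(), on_carbon = logical(),
         excluded = logical())
}

build_dictionary <- function(atoms, bonds, types) {
  at <- tibble(
    ccd_id = cif_clean(cif_col(atoms, "comp_id")),
    atom_id = cif_clean(cif_col(atoms, "atom_id")),
    element = toupper(cif_clean(cif_col(atoms, "type_symbol")))
  )
  bd <- if (!is.null(bonds) && nrow(bonds)) {
    tibble(
      ccd_id = cif_clean(cif_col(bonds, "comp_id")),
      atom_1 = cif_clean(cif_col(bonds, "atom_id_1")),
      atom_2 = cif_clean(cif_col(bonds, "atom_id_2"))
    )
  } else {
    tibble(ccd_id = character(), atom_1 = character(), atom_2 = character())
  }
  ty <- if (!is.null(types) && nrow(types)) {
    tibble(ccd_id = cif_clean(cif_col(types, "id")),
           component_type = tolower(cif_clean(cif_col(types, "type")))) |>
      distinct(.data$ccd_id, .keep_all = TRUE)
  } else {
    tibble(ccd_id = character(), component_type = character())
  }

  hal <- dplyr::filter(at, .data$element %in% .HALOGENS)
  if (!nrow(hal)) return(empty_dictionary())

  element_of <- function(comp, atom) {
    hit <- at$element[at$ccd_id == comp & at$atom_id == atom]
    if (length(hit)) hit[1] else NA_character_
  }

  out <- pmap(list(hal$ccd_id, hal$atom_id, hal$element), function(comp, atom, elem) {
    b <- dplyr::filter(bd, .data$ccd_id == comp,
                       .data$atom_1 == atom | .data$atom_2 == atom)
    comp_has_bonds <- any(bd$ccd_id == comp)
    if (!comp_has_bonds) {
      return(tibble(ccd_id = comp, halogen_atom = atom, halogen_element = elem,
                    parent_atom = NA_character_, on_carbon = NA))
    }
    partners <- ifelse(b$atom_1 == atom, b$atom_2, b$atom_1)
    # drop hydrogens: a halogen bound to H only is a halogen acid
    p_elem <- map_chr(partners, function(p) element_of(comp, p) %||% NA_character_)
    heavy <- partners[!(p_elem %in% c("H", "D"))]
    heavy_elem <- p_elem[!(p_elem %in% c("H", "D"))]
    carbon <- heavy[heavy_elem == "C"]
    tibble(ccd_id = comp, halogen_atom = atom, halogen_element = elem,
           parent_atom = if (length(carbon) == 1L) carbon else NA_character_,
           on_carbon = length(carbon) == 1L && length(heavy) == 1L)
  }) |> list_rbind()

  out <- left_join(out, ty, by = "ccd_id")
  out$component_type <- ifelse(is.na(out$component_type), "non-polymer", out$component_type)
  out$excluded <- out$ccd_id %in% excluded_compound_ids()
  select(out, "ccd_id", "component_type", "halogen_atom", "halogen_element",
         "parent_atom", "on_carbon", "excluded")
}

#' Merge compound dictionaries, embedded definitions winning
#'
#' @param full Dictionary tibble from a full CCD dump (may be `NULL`).
#' @param embedded Dictionary tibble from blocks embedded in a structure
#'   file (may be `NULL`). On conflict the embedded definition replaces the
#'   full-dictionary one.
#' @return A merged dictionary tibble.
#' @export
merge_dictionaries <- function(full, embedded) {
  if (is.null(full) || !nrow(full)) return(embedded %||% empty_dictionary())
  if (is.null(embedded) || !nrow(embedded)) return(full)
  bind_rows(embedded, anti_join(full, embedded, by = "ccd_id"))
}
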