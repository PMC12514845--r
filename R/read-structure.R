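#' Read a macromolecular structure model
#'
#' Reads an mmCIF (PDBx) or legacy PDB file into a uniform tabular model: one
#' row per atom site, with author-facing chain/residue identifiers, element,
#' Cartesian coordinates, occupancy, B-factor and alternate-location code.
#' Model metadata (resolution, R-factors) is read when the file records it
#' and marked missing (`NA`) otherwise, never zero.
#'
#' mmCIF reading is dialect-tolerant: `auth_*` identifiers are used when
#' present and `label_*` identifiers otherwise. Chemical-component
#' connectivity embedded in the file (`chem_comp_atom` / `chem_comp_bond`
#' categories) is retained and can seed [load_compound_dictionary()].
#'
#' @param path Path to the structure file.
#' @param format `"auto"` (default; decided from the extension, then file
#'   content), `"mmcif"`, or `"pdb"`.
#' @param model Model number to keep (default 1, the crystallographic
#'   convention). Use `all_models = TRUE` to keep every model.
#' @param all_models Keep all models of a multi-model file.
#' @return An object of class `halbs_structure`: a list with
#'   \describe{
#'     \item{atoms}{tibble of atom sites (`model_number`, `record`,
#'       `chain_id`, `residue_name`, `residue_seq`, `ins_code`, `atom_name`,
#'       `element`, `x`, `y`, `z`, `occupancy`, `b_factor`, `altloc`).}
#'     \item{metadata}{one-row tibble: `resolution`, `r_factor`, `r_free`,
#'       `mean_b` (Å², mean over atoms).}
#'     \item{chem_comp}{embedded component connectivity
#'       (`list(atoms =, bonds =)`) or `NULL`.}
#'   }
#' @examples
#' fx <- fixture_structure(halogen = "BR", acceptor_kind = "O-C",
#'                         d = 3.4, theta1 = 170, theta2 = 110)
#' path <- tempfile(fileext = ".cif")
#' writeLines(fx$cif, path)
#' st <- read_structure(path)
#' st$atoms
#' @export
read_structure <- function(path, format = c("auto", "mmcif", "pdb"),
                           model = 1L, all_models = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path)) abort(sprintf("structure file not found: '%s'", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif"
      else if (ext %in% c("pdb", "ent")) "pdb"
      else {
        first <- head(grep("\\S", readLines(path, n = 50L, warn = FALSE), value = TRUE), 1L)
        if (length(first) && grepl("^data_", first)) "mmcif" else "pdb"
      }
  }
  st <- switch(format,
    mmcif = read_structure_mmcif(path),
    pdb = read_structure_pdb(path)
  )
  if (!all_models) {
    st$atoms <- dplyr::filter(st$atoms, .data$model_number == model)
  }
  st$metadata$mean_b <- if (nrow(st$atoms)) mean(st$atoms$b_factor, na.rm = TRUE) else NA_real_
  st
}

read_structure_mmcif <- function(path) {
  blocks <- cif_read(path)
  blk <- NULL
  for (b in blocks) if ("atom_site" %in% names(b)) { blk <- b; break }
  if (is.null(blk)) abort(sprintf("mmCIF parse error in '%s': no atom_site category", path))
  a <- blk$atom_site
  atoms <- tibble(
    model_number = {
      mn <- cif_num(cif_col(a, "pdbx_PDB_model_num"))
      as.integer(ifelse(is.na(mn), 1L, mn))
    },
    record = {
      g <- cif_clean(cif_col(a, "group_PDB"))
      ifelse(is.na(g), "HETATM", g)
    },
    chain_id = cif_clean(cif_col(a, c("auth_asym_id", "label_asym_id"))),
    residue_name = cif_clean(cif_col(a, c("auth_comp_id", "label_comp_id"))),
    residue_seq = as.integer(cif_num(cif_col(a, c("auth_seq_id", "label_seq_id")))),
    ins_code = {
      ic <- cif_clean(cif_col(a, "pdbx_PDB_ins_code"))
      ifelse(is.na(ic), "", ic)
    },
    atom_name = cif_clean(cif_col(a, c("auth_atom_id", "label_atom_id"))),
    element = toupper(cif_clean(cif_col(a, "type_symbol"))),
    x = cif_num(cif_col(a, "Cartn_x")),
    y = cif_num(cif_col(a, "Cartn_y")),
    z = cif_num(cif_col(a, "Cartn_z")),
    occupancy = {
      o <- cif_num(cif_col(a, "occupancy"))
      ifelse(is.na(o), 1, o)
    },
    b_factor = cif_num(cif_col(a, "B_iso_or_equiv")),
    altloc = {
      al <- cif_clean(cif_col(a, "label_alt_id"))
      ifelse(is.na(al), "", al)
    }
  )
  atoms <- fix_elements(atoms, path)

  meta <- tibble(resolution = NA_real_, r_factor = NA_real_, r_free = NA_real_,
                 mean_b = NA_real_)
  if ("refine" %in% names(blk)) {
    r <- blk$refine
    meta$resolution <- cif_num(cif_col(r, "ls_d_res_high"))[1]
    meta$r_factor <- cif_num(cif_col(r, c("ls_R_factor_R_work", "ls_R_factor_obs")))[1]
    meta$r_free <- cif_num(cif_col(r, "ls_R_factor_R_free"))[1]
  }

  chem_comp <- NULL
  if ("chem_comp_atom" %in% names(blk)) {
    chem_comp <- list(
      comp = blk$chem_comp %||% NULL,
      atoms = blk$chem_comp_atom,
      bonds = blk$chem_comp_bond %||% NULL
    )
  }

  new_halbs_structure(atoms, meta, chem_comp, path)
}

read_structure_pdb <- function(path) {
  pdb <- suppressWarnings(bio3d::read.pdb(path, rm.alt = FALSE, verbose = FALSE,
                                          multi = FALSE))
  a <- pdb$atom
  atoms <- tibble(
    model_number = 1L,
    record = a$type,
    chain_id = a$chain,
    residue_name = a$resid,
    residue_seq = as.integer(a$resno),
    ins_code = ifelse(is.na(a$insert), "", a$insert),
    atom_name = a$elety,
    element = toupper(ifelse(is.na(a$elesy), "", a$elesy)),
    x = a$x, y = a$y, z = a$z,
    occupancy = ifelse(is.na(a$o), 1, a$o),
    b_factor = a$b,
    altloc = ifelse(is.na(a$alt), "", a$alt)
  )
  atoms$element[atoms$element == ""] <- NA_character_
  atoms <- fix_elements(atoms, path)
  meta <- tibble(resolution = NA_real_, r_factor = NA_real_, r_free = NA_real_,
                 mean_b = NA_real_)
  new_halbs_structure(atoms, meta, NULL, path)
}

# unknown element symbols: warn, then infer from the atom name when possible
fix_elements <- function(atoms, path) {
  bad <- !is.na(atoms$element) & !(atoms$element %in% .ELEMENTS)
  missing <- is.na(atoms$element)
  if (any(bad)) {
    warn(sprintf("'%s': %d atom(s) with unknown element symbol (%s); inferring from atom names",
                 path, sum(bad), paste(unique(atoms$element[bad]), collapse = ", ")))
  }
  idx <- which(bad | missing)
  if (length(idx)) {
    atoms$element[idx] <- map_chr(atoms$atom_name[idx], infer_element)
  }
  atoms
}

infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name %||% ""))
  if (nchar(nm) >= 2L && substr(nm, 1L, 2L) %in% .ELEMENTS) return(substr(nm, 1L, 2L))
  if (nchar(nm) >= 1L && substr(nm, 1L, 1L) %in% .ELEMENTS) return(substr(nm, 1L, 1L))
  NA_character_
}

new_halbs_structure <- function(atoms, metadata, chem_comp, path) {
  structure(
    list(atoms = atoms, metadata = metadata, chem_comp = chem_comp,
         source = path),
    class = "halbs_structure"
  )
}

#' @export
print.halbs_structure <- function(x, ...) {
  cat(sprintf("<halbs_structure> %s\n", x$source %||% "<in memory>"))
  cat(sprintf("  %d atom sites, %d model(s)\n", nrow(x$atoms),
              dplyr::n_distinct(x$atoms$model_number)))
  if (!is.na(x$metadata$resolution))
    cat(sprintf("  resolution %.2f A\n", x$metadata$resolution))
  invisible(x)
}

# accept either a halbs_structure or a bare atom tibble
as_atom_table <- function(x) {
  if (inherits(x, "halbs_structure")) return(x$atoms)
  if (is.data.frame(x)) return(as_tibble(x))
  abort("expected a `halbs_structure` or an atom data frame")
}

#' Write an atom table as a minimal mmCIF file
#'
#' Writes the internal atom model back to a PDBx/mmCIF `atom_site` loop
#' (author identifiers, element, coordinates, occupancy, B-factor, altloc),
#' suitable for round-tripping through [read_structure()].
#'
#' @param atoms A `halbs_structure` or atom tibble.
#' @param path Output file path.
#' @param block_name Data block name.
#' @param digits Decimal places for coordinates (default 4).
#' @return `path`, invisibly.
#' @export
write_structure <- function(atoms, path, block_name = "model", digits = 4L) {
  at <- as_atom_table(atoms)
  fmt <- sprintf("%%.%df", digits)
  rows <- sprintf(
    "%s %d %s %s %s %s %s %d %s %s %s %s %.2f %.2f %d",
    at$record, seq_len(nrow(at)), cif_quote(at$element), cif_quote(at$atom_name),
    ifelse(at$altloc == "", ".", at$altloc), cif_quote(at$residue_name),
    cif_quote(at$chain_id), at$residue_seq,
    ifelse(at$ins_code == "" | is.na(at$ins_code), "?", at$ins_code),
    sprintf(fmt, at$x), sprintf(fmt, at$y), sprintf(fmt, at$z),
    at$occupancy, at$b_factor, at$model_number
  )
  writeLines(c(
    paste0("data_", block_name),
    "#",
    "loop_",
    "_atom_site.group_PDB",
    "_atom_site.id",
    "_atom_site.type_symbol",
    "_atom_site.auth_atom_id",
    "_atom_site.label_alt_id",
    "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id",
    "_atom_site.auth_seq_id",
    "_atom_site.pdbx_PDB_ins_code",
    "_atom_site.Cartn_x",
    "_atom_site.Cartn_y",
    "_atom_site.Cartn_z",
    "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv",
    "_atom_site.pdbx_PDB_model_num",
    rows,
    "#"
  ), path)
  invisible(path)
}

cif_quote <- function(x) {
  x <- ifelse(is.na(x) | x == "", ".", x)
  ifelse(grepl("\\s|'", x), paste0('"', x, '"'), x)
}
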