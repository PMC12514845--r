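# Independent oracles: plain scalar arithmetic and O(n^2) loops, kept free
# of the package's vectorised/joined code paths.

write_fx <- function(fx) {
  path <- tempfile(fileext = ".cif")
  writeLines(fx$cif, path)
  path
}

oracle_angle <- function(a, v, c) {
  u <- a - v; w <- c - v
  cosang <- sum(u * w) / sqrt(sum(u^2) * sum(w^2))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

oracle_score <- function(value, q1, q3) {
  iqr <- q3 - q1
  max((value - q3) / iqr, (q1 - value) / iqr, 0)
}

# Scalar HalBS recomputation from a geometry triple and a stats table
oracle_halbs <- function(halogen, acceptor_class, d, theta1, theta2, stats) {
  cell <- function(par) {
    row <- stats[stats$halogen == halogen &
                   stats$acceptor_class == acceptor_class &
                   stats$parameter == par, ]
    if (nrow(row) != 1L) return(NULL)
    row
  }
  sd_ <- cell("distance"); st1 <- cell("theta1")
  if (is.null(sd_) || is.null(st1)) return(NA_real_)
  scores <- c(oracle_score(d, sd_$q1, sd_$q3),
              oracle_score(theta1, st1$q1, st1$q3))
  if (!is.na(theta2)) {
    st2 <- cell("theta2")
    if (is.null(st2)) return(NA_real_)
    scores <- c(scores, oracle_score(theta2, st2$q1, st2$q3))
  }
  max(scores)
}

# Residue-level acceptor map, restated independently of the package constants
oracle_acceptor_map <- function(resname) {
  side <- switch(resname,
    SER = list(c("OG", "CB")), THR = list(c("OG1", "CB")),
    TYR = list(c("OH", "CZ")), ASP = list(c("OD1", "CG"), c("OD2", "CG")),
    GLU = list(c("OE1", "CD"), c("OE2", "CD")), ASN = list(c("OD1", "CG")),
    GLN = list(c("OE1", "CD")), CYS = list(c("SG", "CB")),
    MET = list(c("SD", "CG"), c("SD", "CE")),
    list())
  c(list(c("O", "C"), c("OXT", "C")), side)
}

oracle_rings <- list(
  HIS = list(ring = c("CG", "ND1", "CD2", "CE1", "NE2")),
  PHE = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TYR = list(ring = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ")),
  TRP = list(ring5 = c("CG", "CD1", "NE1", "CE2", "CD2"),
             ring6 = c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2"))
)

aa20 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")

# Brute-force candidate scan: nested loops over every atom pair, applying
# the 4 A / 6 A shells, theta1 > 90, water/altloc/intra-residue exclusions.
brute_force_scan <- function(atoms, dictionary = NULL) {
  atoms <- as.data.frame(atoms)
  rkey <- paste(atoms$chain_id, atoms$residue_seq, atoms$ins_code,
                atoms$residue_name)
  out <- list()
  for (i in seq_len(nrow(atoms))) {
    h <- atoms[i, ]
    if (!(h$element %in% c("F", "CL", "BR", "I"))) next
    if (h$altloc != "") next
    if (h$residue_name %in% halbs::excluded_compound_ids()) next
    # parent carbon
    parent <- NULL
    if (!is.null(dictionary)) {
      dent <- dictionary[dictionary$ccd_id == h$residue_name &
                           dictionary$halogen_atom == h$atom_name, ]
      if (nrow(dent) && !is.na(dent$parent_atom[1])) {
        hit <- atoms[rkey == rkey[i] & atoms$atom_name == dent$parent_atom[1], ]
        if (nrow(hit)) parent <- hit[1, ]
      }
    }
    if (is.null(parent)) {
      best <- NULL; bestd <- 1.9
      for (j in seq_len(nrow(atoms))) {
        if (rkey[j] != rkey[i] || atoms$element[j] != "C") next
        dj <- sqrt(sum((c(h$x, h$y, h$z) - c(atoms$x[j], atoms$y[j], atoms$z[j]))^2))
        if (dj <= bestd) { bestd <- dj; best <- atoms[j, ] }
      }
      parent <- best
    }
    if (is.null(parent)) next
    hx <- c(h$x, h$y, h$z); px <- c(parent$x, parent$y, parent$z)

    # atomic acceptors
    for (j in seq_len(nrow(atoms))) {
      a <- atoms[j, ]
      if (rkey[j] == rkey[i]) next
      if (a$altloc != "") next
      if (!(a$residue_name %in% aa20)) next
      if (!(a$element %in% c("O", "S"))) next
      pairs <- oracle_acceptor_map(a$residue_name)
      pairs <- Filter(function(p) p[1] == a$atom_name, pairs)
      if (!length(pairs)) next
      ax <- c(a$x, a$y, a$z)
      d <- sqrt(sum((hx - ax)^2))
      if (d > 4.0) next
      t1 <- oracle_angle(px, hx, ax)
      if (t1 <= 90) next
      for (p in pairs) {
        nb <- atoms[rkey == rkey[j] & atoms$atom_name == p[2] & atoms$altloc == "", ]
        if (!nrow(nb)) next
        t2 <- oracle_angle(hx, ax, c(nb$x[1], nb$y[1], nb$z[1]))
        out[[length(out) + 1L]] <- data.frame(
          hal = paste(h$chain_id, h$residue_seq, h$atom_name),
          acc = paste(a$chain_id, a$residue_seq, a$atom_name, p[2]),
          kind = "atomic", d = d, theta1 = t1, theta2 = t2)
      }
    }

    # pi acceptors
    res_ids <- unique(rkey[atoms$residue_name %in% names(oracle_rings)])
    for (rid in res_ids) {
      if (rid == rkey[i]) next
      res <- atoms[rkey == rid & atoms$altloc == "", ]
      if (!nrow(res)) next
      rings <- oracle_rings[[res$residue_name[1]]]
      for (lab in names(rings)) {
        nms <- rings[[lab]]
        got <- res[match(nms, res$atom_name), ]
        if (anyNA(got$atom_name)) next
        cen <- c(mean(got$x), mean(got$y), mean(got$z))
        d <- sqrt(sum((hx - cen)^2))
        if (d > 6.0) next
        t1 <- oracle_angle(px, hx, cen)
        if (t1 <= 90) next
        out[[length(out) + 1L]] <- data.frame(
          hal = paste(h$chain_id, h$residue_seq, h$atom_name),
          acc = paste(res$chain_id[1], res$residue_seq[1], lab, ""),
          kind = "pi", d = d, theta1 = t1, theta2 = NA_real_)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(hal = character(), acc = character(), kind = character(),
                      d = double(), theta1 = double(), theta2 = double()))
  }
  res <- do.call(rbind, out)
  res[order(res$hal, res$kind, res$acc), , drop = FALSE]
}

candidate_key_frame <- function(cand) {
  df <- data.frame(
    hal = paste(cand$hal_chain, cand$hal_residue_seq, cand$hal_atom),
    acc = paste(cand$acc_chain, cand$acc_residue_seq, cand$acc_atom,
                ifelse(is.na(cand$neighbor_atom), "", cand$neighbor_atom)),
    kind = cand$acceptor_kind, d = cand$d, theta1 = cand$theta1,
    theta2 = cand$theta2)
  df[order(df$hal, df$kind, df$acc), , drop = FALSE]
}

# A random multi-acceptor fixture for fuzzed detection tests
random_fixture <- function(seed) {
  set.seed(seed)
  hal <- sample(c("F", "CL", "BR", "I"), 1)
  kinds <- c("O-C", "S-C", "His", "Phe", "Tyr", "Trp")
  n_extra <- sample(0:3, 1)
  mk <- function() {
    kind <- sample(kinds, 1)
    atomic <- kind %in% c("O-C", "S-C")
    list(kind = kind,
         d = if (atomic) runif(1, 2.8, 4.4) else runif(1, 3.8, 6.5),
         theta1 = runif(1, 70, 179),
         theta2 = if (atomic) runif(1, 80, 150) else NULL)
  }
  main <- mk()
  fixture_structure(hal, main$kind, d = main$d, theta1 = main$theta1,
                    theta2 = main$theta2,
                    water_near = runif(1) < 0.3,
                    altloc_halogen = runif(1) < 0.15,
                    extra_acceptors = replicate(n_extra, mk(), simplify = FALSE))
}
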