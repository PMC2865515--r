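# Geometric census of stabilizing interactions in gas-phase conformers:
# hydrogen bonds (neutral / ionized / salt-bridge classes), salt bridges,
# per-group coordination and radius of gyration.

ATOMIC_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                   S = 32.06, P = 30.974)

# Heavy atoms defining each ionizable group, PDB atom-name conventions.
GROUP_HEAVY <- list(
  NTER_amine    = c("N"),
  CTER_carboxyl = c("C", "O", "OXT"),
  ARG_side      = c("NE", "NH1", "NH2", "CZ"),
  LYS_side      = c("NZ"),
  HIS_side      = c("ND1", "NE2", "CE1", "CD2", "CG"),
  ASP_side      = c("OD1", "OD2", "CG"),
  GLU_side      = c("OE1", "OE2", "CD"),
  GLN_side      = c("NE2", "OE1", "CD"))

# Protonatable nitrogens (salt-bridge base side) and acid oxygens.
GROUP_BASE_N <- list(
  NTER_amine = "N", ARG_side = c("NE", "NH1", "NH2"), LYS_side = "NZ",
  HIS_side = c("ND1", "NE2"), GLN_side = "NE2")
GROUP_ACID_O <- list(
  CTER_carboxyl = c("O", "OXT"), ASP_side = c("OD1", "OD2"),
  GLU_side = c("OE1", "OE2"))

#' Construct a conformer
#'
#' A conformer couples a 3-D structure (atom table in angstroms, hydrogens
#' present on donor groups) with the protomer it realizes, an optional
#' energy, and a provenance level.
#'
#' @param peptide A [peptide_definition()].
#' @param p The `protomer` realized by the structure.
#' @param atoms Data frame with columns `elety` (atom name), `resid`
#'   (residue name), `resno` (residue number), `element`, `x`, `y`, `z`
#'   (angstrom) and optionally `mass` (Da; filled from `element` when
#'   missing).
#' @param energy Optional energy in kJ/mol.
#' @param level `"forcefield"` or `"refined"`.
#' @return An object of class `conformer`.
#' @export
conformer <- function(peptide, p, atoms, energy = NULL,
                      level = c("forcefield", "refined")) {
  level <- match.arg(level)
  need <- c("elety", "resid", "resno", "element", "x", "y", "z")
  if (!all(need %in% names(atoms))) {
    stopf("atoms must have columns %s", paste(need, collapse = ", "))
  }
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (any(!is.finite(xyz))) stopf("non-finite coordinates")
  if (is.null(atoms$mass)) {
    atoms$mass <- unname(ATOMIC_MASSES[atoms$element])
    atoms$mass[is.na(atoms$mass)] <- 12.011
  }
  obj <- structure(
    list(peptide = peptide, protomer = p, atoms = atoms,
         energy = energy, level = level),
    class = "conformer")
  # every ionized site must be represented by at least one atom
  for (id in names(p$charges)[p$charges != 0L]) {
    if (length(site_atom_indices(obj, id)) == 0L) {
      stopf("ionized site '%s' maps to no atoms of the structure", id)
    }
  }
  obj
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s: %d atoms, protomer %s, level %s%s>\n",
              x$peptide$peptide_id, nrow(x$atoms),
              protomer_pattern(x$protomer), x$level,
              if (is.null(x$energy)) "" else
                sprintf(", E = %.1f kJ/mol", x$energy)))
  invisible(x)
}

# Residue number a site maps to within this structure. Terminal groups map
# to the first / last residue present.
site_resno <- function(conf, site) {
  resnos <- conf$atoms$resno
  switch(site$site_id,
         NTER = min(resnos),
         CTER = max(resnos),
         site$residue_index)
}

find_site <- function(conf, site_id) {
  for (s in conf$peptide$sites) if (s$site_id == site_id) return(s)
  stopf("unknown site '%s'", site_id)
}

# Indices of a hydrogen's covalent parent: nearest N/O within 1.3 A.
hydrogen_parents <- function(atoms) {
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  is_h <- atoms$element == "H"
  heavy <- which(atoms$element %in% c("N", "O"))
  parent <- rep(NA_integer_, nrow(atoms))
  for (h in which(is_h)) {
    if (length(heavy) == 0L) next
    d <- sqrt(colSums((t(xyz[heavy, , drop = FALSE]) - xyz[h, ])^2))
    j <- which.min(d)
    if (d[j] <= 1.3) parent[h] <- heavy[j]
  }
  parent
}

#' Atom indices of an ionizable group
#'
#' Heavy atoms of the group (atom-name lookup keyed to the site type) plus
#' any hydrogens covalently attached to them.
#'
#' @param conf A `conformer`.
#' @param site_id Site identifier.
#' @return Integer vector of row indices into `conf$atoms`.
#' @export
site_atom_indices <- function(conf, site_id) {
  site <- find_site(conf, site_id)
  heavies <- GROUP_HEAVY[[site$site_type]]
  if (is.null(heavies)) return(integer(0))
  rn <- site_resno(conf, site)
  idx <- which(conf$atoms$resno == rn & conf$atoms$elety %in% heavies)
  if (length(idx) == 0L) return(integer(0))
  par <- hydrogen_parents(conf$atoms)
  c(idx, which(!is.na(par) & par %in% idx))
}

#' Detect hydrogen bonds by a distance/angle criterion
#'
#' A hydrogen bond is a (donor, hydrogen, acceptor) triple where the donor
#' is an N or O atom with a covalently attached hydrogen, the acceptor any
#' other N or O atom, the donor-acceptor distance is at most `d_max` and the
#' D-H...A angle (at the hydrogen) is at least `angle_min`. Intra-residue
#' pairs are excluded by default. Donor-capable nitrogens of ionized basic
#' groups lacking hydrogens are skipped with a warning and recorded in the
#' `qc` attribute of the result.
#'
#' @param conf A `conformer` (hydrogens present).
#' @param d_max Donor-acceptor distance cutoff in angstrom.
#' @param angle_min Minimum D-H...A angle in degrees.
#' @param exclude_intra Exclude pairs within one residue.
#' @return Data frame with columns `d_idx`, `h_idx`, `a_idx`, `donor`,
#'   `acceptor`, `d_DA`, `angle` and a placeholder `klass` column.
#' @export
detect_hbonds <- function(conf, d_max = 3.5, angle_min = 120,
                          exclude_intra = TRUE) {
  atoms <- conf$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  par <- hydrogen_parents(atoms)
  hs <- which(atoms$element == "H" & !is.na(par))
  acc <- which(atoms$element %in% c("N", "O"))

  # QC: protonatable N of an ionized basic site with no attached hydrogen
  qc <- list()
  pr <- conf$protomer
  for (id in names(pr$charges)[pr$charges > 0L]) {
    site <- find_site(conf, id)
    nn <- GROUP_BASE_N[[site$site_type]]
    rn <- site_resno(conf, site)
    for (a in which(atoms$resno == rn & atoms$elety %in% nn)) {
      if (!any(par == a, na.rm = TRUE)) {
        qc[[length(qc) + 1L]] <- data.frame(site_id = id,
                                            atom = atoms$elety[a],
                                            resno = atoms$resno[a])
      }
    }
  }
  qc <- if (length(qc)) do.call(rbind, qc) else
    data.frame(site_id = character(0), atom = character(0),
               resno = integer(0))
  if (nrow(qc) > 0L) {
    warning(sprintf("donor group(s) without hydrogens skipped: %s",
                    paste(unique(qc$site_id), collapse = ", ")),
            call. = FALSE)
  }

  rows <- list()
  for (h in hs) {
    d <- par[h]
    for (a in acc) {
      if (a == d) next
      if (exclude_intra && atoms$resno[a] == atoms$resno[d]) next
      dda <- sqrt(sum((xyz[d, ] - xyz[a, ])^2))
      if (dda > d_max) next
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
      ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      if (ang < angle_min) next
      rows[[length(rows) + 1L]] <- data.frame(
        d_idx = d, h_idx = h, a_idx = a,
        donor = atoms$elety[d], acceptor = atoms$elety[a],
        d_DA = dda, angle = ang, klass = NA_character_,
        stringsAsFactors = FALSE)
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(d_idx = integer(0), h_idx = integer(0), a_idx = integer(0),
               donor = character(0), acceptor = character(0),
               d_DA = numeric(0), angle = numeric(0),
               klass = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "qc") <- qc
  attr(out, "criteria") <- c(d_max = d_max, angle_min = angle_min)
  out
}

#' Detect salt bridges between ionized acid/base site pairs
#'
#' A bridge is reported for each (ionized acidic, ionized basic) site pair
#' whose minimum distance between any acid oxygen and any protonatable base
#' nitrogen is strictly below the cutoff.
#'
#' @param conf A `conformer`.
#' @param cutoff O...N distance cutoff in angstrom (strict `<`).
#' @return Data frame with columns `acid_site`, `base_site`,
#'   `min_ON_distance`.
#' @export
detect_salt_bridges <- function(conf, cutoff = 4.0) {
  atoms <- conf$atoms
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  pr <- conf$protomer
  acids <- names(pr$charges)[pr$charges < 0L]
  bases <- names(pr$charges)[pr$charges > 0L]
  rows <- list()
  for (aid in acids) {
    asite <- find_site(conf, aid)
    oat <- which(atoms$resno == site_resno(conf, asite) &
                 atoms$elety %in% GROUP_ACID_O[[asite$site_type]])
    if (length(oat) == 0L) next
    for (bid in bases) {
      bsite <- find_site(conf, bid)
      nat <- which(atoms$resno == site_resno(conf, bsite) &
                   atoms$elety %in% GROUP_BASE_N[[bsite$site_type]])
      if (length(nat) == 0L) next
      dmin <- min(vapply(oat, function(o) {
        min(sqrt(colSums((t(xyz[nat, , drop = FALSE]) - xyz[o, ])^2)))
      }, 0))
      if (dmin < cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          acid_site = aid, base_site = bid, min_ON_distance = dmin,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(acid_site = character(0), base_site = character(0),
               min_ON_distance = numeric(0), stringsAsFactors = FALSE)
}

#' Classify interactions and build the census of a conformer
#'
#' Every detected hydrogen bond is assigned exactly one class, with
#' precedence salt-bridge H-bond > ionized H-bond > neutral H-bond:
#' \describe{
#'   \item{sHB}{donor group and acceptor group are the two sites of a
#'     detected salt-bridge pair (decided at the site-pair level, whichever
#'     atoms realize it);}
#'   \item{iHB}{the donor or the acceptor atom belongs to an ionized group;}
#'   \item{HB}{all remaining (neutral) hydrogen bonds.}
#' }
#'
#' @param conf A `conformer`.
#' @param hbonds Result of [detect_hbonds()]; computed with defaults when
#'   `NULL`.
#' @param bridges Result of [detect_salt_bridges()]; computed with defaults
#'   when `NULL`.
#' @return An object of class `interaction_census` with counts `IR`, `SB`,
#'   `sHB`, `iHB`, `HB`, a `per_group` coordination table (hydrogen bonds
#'   donated/accepted per site), `Rg` and the classified `hbonds` and
#'   `bridges` tables.
#' @export
classify_interactions <- function(conf, hbonds = NULL, bridges = NULL) {
  if (is.null(hbonds)) hbonds <- detect_hbonds(conf)
  if (is.null(bridges)) bridges <- detect_salt_bridges(conf)
  pr <- conf$protomer
  ids <- names(pr$charges)
  membership <- lapply(ids, function(id) site_atom_indices(conf, id))
  names(membership) <- ids
  ionized <- ids[pr$charges != 0L]

  site_of <- function(atom_idx) {
    for (id in ids) if (atom_idx %in% membership[[id]]) return(id)
    NA_character_
  }
  bridged_pairs <- if (nrow(bridges)) {
    paste(pmin(bridges$acid_site, bridges$base_site),
          pmax(bridges$acid_site, bridges$base_site))
  } else character(0)

  if (nrow(hbonds)) {
    for (k in seq_len(nrow(hbonds))) {
      ds <- site_of(hbonds$d_idx[k])
      as_ <- site_of(hbonds$a_idx[k])
      key <- if (!is.na(ds) && !is.na(as_))
        paste(pmin(ds, as_), pmax(ds, as_)) else ""
      hbonds$klass[k] <- if (nzchar(key) && key %in% bridged_pairs) {
        "sHB"
      } else if ((!is.na(ds) && ds %in% ionized) ||
                 (!is.na(as_) && as_ %in% ionized)) {
        "iHB"
      } else "HB"
    }
  }
  per_group <- data.frame(
    site_id = ids,
    donated = vapply(ids, function(id) {
      sum(hbonds$d_idx %in% membership[[id]])
    }, 0L),
    accepted = vapply(ids, function(id) {
      sum(hbonds$a_idx %in% membership[[id]])
    }, 0L),
    row.names = NULL, stringsAsFactors = FALSE)

  structure(
    list(IR = count_ionized(pr),
         SB = nrow(bridges),
         sHB = sum(hbonds$klass == "sHB"),
         iHB = sum(hbonds$klass == "iHB"),
         HB = sum(hbonds$klass == "HB"),
         per_group = per_group,
         Rg = radius_of_gyration(conf),
         hbonds = hbonds, bridges = bridges),
    class = "interaction_census")
}

#' @export
print.interaction_census <- function(x, ...) {
  cat(sprintf("Interaction census: IR=%d SB=%d sHB=%d iHB=%d HB=%d Rg=%.2f A\n",
              x$IR, x$SB, x$sHB, x$iHB, x$HB, x$Rg))
  invisible(x)
}

#' Mass-weighted radius of gyration
#'
#' @param conf A `conformer` (atoms carry masses in Da).
#' @return Rg in angstrom.
#' @export
radius_of_gyration <- function(conf) {
  atoms <- conf$atoms
  m <- atoms$mass
  if (sum(m) <= 0) stopf("zero total mass")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums((xyz - matrix(com, nrow(xyz), 3, byrow = TRUE))^2)) /
         sum(m))
}

#' Write a conformer to a PDB file
#'
#' @param conf A `conformer`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conformer_pdb <- function(conf, path) {
  a <- conf$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, resid = a$resid, elety = a$elety,
                   eleno = seq_len(nrow(a)), chain = rep("A", nrow(a)),
                   elesy = a$element)
  invisible(path)
}

# Infer the protonation-state label of one site from residue naming and
# hydrogen counts of the structure.
infer_state <- function(site, atoms, par) {
  rn_site <- switch(site$site_id, NTER = min(atoms$resno),
                    CTER = max(atoms$resno), site$residue_index)
  sel <- atoms$resno == rn_site
  resid <- unique(atoms$resid[sel])[1]
  n_h_on <- function(names) {
    heavy <- which(sel & atoms$elety %in% names)
    sum(!is.na(par) & par %in% heavy)
  }
  ty <- site$site_type
  if (ty == "HIS_side") {
    hd1 <- n_h_on("ND1") > 0; he2 <- n_h_on("NE2") > 0
    if (resid %in% c("HIP")) return("HIP")
    if (resid %in% c("HID", "HSD")) return("HID")
    if (resid %in% c("HIE", "HSE")) return("HIE")
    if (hd1 && he2) return("HIP")
    return(if (hd1) "HID" else "HIE")
  }
  if (ty == "ASP_side") {
    return(if (resid == "ASH" || n_h_on(c("OD1", "OD2")) > 0) "ASH" else "-")
  }
  if (ty == "GLU_side") {
    return(if (resid == "GLH" || n_h_on(c("OE1", "OE2")) > 0) "GLH" else "-")
  }
  if (ty == "LYS_side") {
    return(if (resid == "LYN" || n_h_on("NZ") < 3) "0" else "+")
  }
  if (ty == "ARG_side") {
    return(if (n_h_on(c("NE", "NH1", "NH2")) >= 5) "+" else "0")
  }
  if (ty == "GLN_side") {
    return(if (n_h_on("NE2") >= 3) "+" else "0")
  }
  if (ty == "NTER_amine") {
    return(if (n_h_on("N") >= 3) "+" else "0")
  }
  if (ty == "CTER_carboxyl") {
    return(if (n_h_on(c("O", "OXT")) > 0) "0" else "-")
  }
  "0"
}

#' Read a conformer from a PDB file
#'
#' Protonation states are inferred from residue names (HID/HIE/HIP, ASH,
#' GLH, LYN conventions) and hydrogen counts, or overridden by an explicit
#' protomer sidecar: a TSV with columns `site_id`, `state_label`.
#'
#' @param path PDB file, one model, hydrogens present.
#' @param peptide The [peptide_definition()] the structure realizes.
#' @param sidecar Optional path to a protomer sidecar TSV.
#' @param energy,level Passed to [conformer()].
#' @return A `conformer`.
#' @export
read_conformer_pdb <- function(path, peptide, sidecar = NULL,
                               energy = NULL, level = "forcefield") {
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  a <- pdb$atom
  element <- if (!is.null(a$elesy)) trimws(a$elesy) else rep("", nrow(a))
  miss <- is.na(element) | !nzchar(element)
  if (any(miss)) {
    guess <- tryCatch(suppressWarnings(bio3d::atom2ele(pdb)),
                      error = function(e) rep(NA_character_, nrow(a)))
    element[miss] <- guess[miss]
    miss <- is.na(element) | !nzchar(element)
    element[miss] <- substr(gsub("^[0-9]+", "", a$elety[miss]), 1, 1)
  }
  atoms <- data.frame(elety = a$elety, resid = a$resid, resno = a$resno,
                      element = toupper(element),
                      x = a$x, y = a$y, z = a$z,
                      stringsAsFactors = FALSE)
  if (!is.null(sidecar)) {
    sc <- read_tsv_file(sidecar)
    assignment <- stats::setNames(as.character(sc$state_label),
                                  as.character(sc$site_id))
  } else {
    par <- hydrogen_parents(atoms)
    assignment <- vapply(peptide$sites, function(s) {
      infer_state(s, atoms, par)
    }, "")
    names(assignment) <- vapply(peptide$sites, function(s) s$site_id, "")
  }
  conformer(peptide, protomer(peptide, assignment), atoms,
            energy = energy, level = level)
}

#' Write an interaction census as TSV
#'
#' Columns mirror the per-protomer report tables: protonation pattern,
#' counts and radius of gyration; detection criteria are recorded in a
#' header comment.
#'
#' @param censuses Named list (pattern -> `interaction_census`) or a single
#'   census.
#' @param path Output path.
#' @param criteria Optional named vector of detection criteria recorded in
#'   the header.
#' @return `path`, invisibly.
#' @export
write_census_tsv <- function(censuses, path, criteria = NULL) {
  if (inherits(censuses, "interaction_census")) {
    censuses <- list(censuses)
    names(censuses) <- "conformer"
  }
  df <- data.frame(
    pattern = names(censuses),
    IR = vapply(censuses, function(x) x$IR, 0L),
    SB = vapply(censuses, function(x) x$SB, 0L),
    sHB = vapply(censuses, function(x) x$sHB, 0L),
    iHB = vapply(censuses, function(x) x$iHB, 0L),
    HB = vapply(censuses, function(x) x$HB, 0L),
    Rg = vapply(censuses, function(x) x$Rg, 0),
    row.names = NULL, stringsAsFactors = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(criteria)) {
    writeLines(sprintf("# criteria: %s",
                       paste(names(criteria), criteria, sep = "=",
                             collapse = " ")), con)
  }
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
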