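#' Declare one ionizable site of a peptide
#'
#' An ionizable site is a titratable group: a side chain, the N-terminal
#' amine or the C-terminal carboxyl. Each site carries an ordered list of
#' protonation states (possibly several neutral tautomers, as for histidine)
#' with their formal charges, and an optional gating set restricting the
#' charged state to particular net charges of the whole peptide.
#'
#' @param site_id Canonical identifier: `"NTER"`, `"CTER"` or
#'   `"<RES><index>"` with a 1-based residue index (e.g. `"ARG2"`).
#' @param residue_index 1-based index into the sequence; 0 denotes the
#'   N-terminus and `nchar(sequence) + 1` the C-terminus.
#' @param kind `"basic"` (states with charge 0/+1) or `"acidic"`
#'   (states with charge -1/0).
#' @param states Ordered list of states, each `list(label, charge)`, or a
#'   two-column data frame with columns `label` and `charge`. The order given
#'   here fixes the deterministic enumeration order of
#'   [enumerate_protomers()].
#' @param gating Optional integer vector of net charges at which the charged
#'   (non-reference) state of this site is allowed. `NULL` (default) means
#'   the charged state is always available.
#' @param site_type Thermodynamic type used to join intrinsic basicity
#'   tables (e.g. `"ARG_side"`, `"NTER_amine"`). Derived from `site_id`
#'   when missing.
#' @return An object of class `ionizable_site`.
#' @seealso [peptide_definition()], [enumerate_protomers()]
#' @export
ionizable_site <- function(site_id, residue_index, kind,
                           states, gating = NULL, site_type = NULL) {
  kind <- match.arg(kind, c("basic", "acidic"))
  if (is.data.frame(states)) {
    states <- data.frame(label = as.character(states$label),
                         charge = as.integer(states$charge),
                         stringsAsFactors = FALSE)
  } else {
    states <- data.frame(
      label = vapply(states, function(s) as.character(s[[1]]), ""),
      charge = vapply(states, function(s) as.integer(s[[2]]), 0L),
      stringsAsFactors = FALSE)
  }
  allowed <- if (kind == "basic") c(0L, 1L) else c(-1L, 0L)
  if (!all(states$charge %in% allowed)) {
    stopf("site '%s': state charge outside the allowed set for a %s site",
          site_id, kind)
  }
  if (!any(states$charge == 0L)) {
    stopf("site '%s': at least one neutral state is required", site_id)
  }
  if (anyDuplicated(states$label)) {
    stopf("site '%s': state labels must be unique", site_id)
  }
  structure(
    list(site_id = as.character(site_id),
         residue_index = as.integer(residue_index),
         kind = kind,
         states = states,
         gating = if (is.null(gating)) NULL else as.integer(gating),
         site_type = site_type %||% default_site_type(site_id)),
    class = "ionizable_site")
}

# Map a canonical site id to the thermodynamic site type used by the
# intrinsic tables.
default_site_type <- function(site_id) {
  if (site_id == "NTER") return("NTER_amine")
  if (site_id == "CTER") return("CTER_carboxyl")
  res <- sub("[0-9]+$", "", site_id)
  paste0(res, "_side")
}

# Convenience constructors for the common residue types. `index` is the
# 1-based residue index in the sequence.
site_nter <- function() {
  ionizable_site("NTER", 0L, "basic",
                 list(list("0", 0L), list("+", 1L)))
}
site_cter <- function(seq_length) {
  ionizable_site("CTER", seq_length + 1L, "acidic",
                 list(list("0", 0L), list("-", -1L)))
}
site_basic <- function(res, index, gating = NULL) {
  ionizable_site(paste0(res, index), index, "basic",
                 list(list("0", 0L), list("+", 1L)), gating = gating)
}
site_his <- function(index) {
  # Two neutral tautomers (proton on N-delta or N-epsilon) plus the
  # protonated imidazolium; labels follow force-field nomenclature.
  ionizable_site(paste0("HIS", index), index, "basic",
                 list(list("HID", 0L), list("HIE", 0L), list("HIP", 1L)))
}
site_acidic <- function(res, index) {
  neutral <- switch(res, ASP = "ASH", GLU = "GLH", "0")
  ionizable_site(paste0(res, index), index, "acidic",
                 list(list(neutral, 0L), list("-", -1L)))
}

#' Define a peptide with its ionizable sites and considered charge states
#'
#' @param peptide_id Short identifier (e.g. `"BK"`).
#' @param sequence One-letter amino-acid sequence.
#' @param sites List of [ionizable_site()] objects, in the column order used
#'   for protonation-pattern tables.
#' @param charge_states Integer vector of net charges under study.
#' @return An object of class `peptide_definition`.
#' @export
peptide_definition <- function(peptide_id, sequence, sites, charge_states) {
  sequence <- toupper(as.character(sequence))
  one2three <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS",
                 Q = "GLN", E = "GLU", G = "GLY", H = "HIS", I = "ILE",
                 L = "LEU", K = "LYS", M = "MET", F = "PHE", P = "PRO",
                 S = "SER", T = "THR", W = "TRP", Y = "TYR", V = "VAL")
  ids <- vapply(sites, function(s) s$site_id, "")
  if (anyDuplicated(ids)) stopf("duplicated site ids: %s",
                                paste(ids[duplicated(ids)], collapse = ", "))
  for (s in sites) {
    if (!inherits(s, "ionizable_site")) stopf("all sites must be ionizable_site objects")
    idx <- s$residue_index
    if (idx >= 1L && idx <= nchar(sequence)) {
      res <- sub("[0-9]+$", "", s$site_id)
      letter <- substr(sequence, idx, idx)
      if (!(s$site_id %in% c("NTER", "CTER")) &&
          !identical(one2three[[letter]], res)) {
        stopf("site '%s' does not match residue %d ('%s') of the sequence",
              s$site_id, idx, letter)
      }
    }
  }
  structure(
    list(peptide_id = as.character(peptide_id),
         sequence = sequence,
         sites = sites,
         charge_states = as.integer(charge_states)),
    class = "peptide_definition")
}

#' @export
print.peptide_definition <- function(x, ...) {
  cat(sprintf("Peptide '%s' (%d residues): %s\n", x$peptide_id,
              nchar(x$sequence), x$sequence))
  cat(sprintf("  charge states considered: %s\n",
              paste(x$charge_states, collapse = ", ")))
  for (s in x$sites) {
    gate <- if (is.null(s$gating)) "" else
      sprintf(" [charged state only at z = %s]",
              paste(s$gating, collapse = ", "))
    cat(sprintf("  %-6s %-6s states: %s%s\n", s$site_id, s$kind,
                paste(s$states$label, collapse = "/"), gate))
  }
  invisible(x)
}

#' Packaged peptide systems
#'
#' Definitions of the three benchmark systems: bradykinin (BK, RPPGFSPFR;
#' sites N-ter, Arg1, Arg9, C-ter; z = 0..+2), angiotensin II (AN, DRVYIHPF;
#' sites N-ter, Asp1, Arg2, His6 with both neutral tautomers, C-ter;
#' z = -1..+2) and the Trp-cage mini-protein (NLYIQWLKDGGPSSGRPPPS; sites
#' N-ter, Gln5 with its protonated form allowed only at z = +2 and +3, Lys8,
#' Asp9, Arg16, C-ter; z = 0..+3).
#'
#' @return A `peptide_definition`.
#' @export
bradykinin <- function() {
  seqc <- "RPPGFSPFR"
  peptide_definition("BK", seqc,
                     list(site_nter(),
                          site_basic("ARG", 1L),
                          site_basic("ARG", 9L),
                          site_cter(nchar(seqc))),
                     charge_states = 0:2)
}

#' @rdname bradykinin
#' @export
angiotensin_ii <- function() {
  seqc <- "DRVYIHPF"
  peptide_definition("AN", seqc,
                     list(site_nter(),
                          site_acidic("ASP", 1L),
                          site_basic("ARG", 2L),
                          site_his(6L),
                          site_cter(nchar(seqc))),
                     charge_states = -1:2)
}

#' @rdname bradykinin
#' @export
trp_cage <- function() {
  seqc <- "NLYIQWLKDGGPSSGRPPPS"
  peptide_definition("TC", seqc,
                     list(site_nter(),
                          site_basic("GLN", 5L, gating = c(2L, 3L)),
                          site_basic("LYS", 8L),
                          site_acidic("ASP", 9L),
                          site_basic("ARG", 16L),
                          site_cter(nchar(seqc))),
                     charge_states = 0:3)
}

#' Packaged systems as a named list
#' @return Named list of the three `peptide_definition`s.
#' @export
packaged_systems <- function() {
  list(BK = bradykinin(), AN = angiotensin_ii(), TC = trp_cage())
}

#' Read a peptide definition from a YAML or JSON config
#'
#' The config mirrors [peptide_definition()]: fields `peptide_id`,
#' `sequence`, `charge_states` and a list `sites`, each site with `site_id`,
#' `residue_index`, `kind`, `states` (list of `[label, charge]` pairs) and
#' optional `gating`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `peptide_definition`.
#' @export
read_peptide_config <- function(path) {
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  sites <- lapply(cfg$sites, function(s) {
    ionizable_site(s$site_id, s$residue_index, s$kind,
                   lapply(s$states, function(st) list(st[[1]], st[[2]])),
                   gating = unlist(s$gating),
                   site_type = s$site_type %||% NULL)
  })
  peptide_definition(cfg$peptide_id, cfg$sequence, sites,
                     unlist(cfg$charge_states))
}

#' Write a peptide definition to a YAML config
#' @param peptide A `peptide_definition`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peptide_config <- function(peptide, path) {
  cfg <- list(
    peptide_id = peptide$peptide_id,
    sequence = peptide$sequence,
    charge_states = peptide$charge_states,
    sites = lapply(peptide$sites, function(s) {
      out <- list(site_id = s$site_id, residue_index = s$residue_index,
                  kind = s$kind,
                  states = lapply(seq_len(nrow(s$states)), function(i) {
                    list(s$states$label[i], s$states$charge[i])
                  }),
                  site_type = s$site_type)
      if (!is.null(s$gating)) out$gating <- s$gating
      out
    }))
  yaml::write_yaml(cfg, path)
  invisible(path)
}
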