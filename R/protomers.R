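#' Construct a protomer
#'
#' A protomer is a full assignment of protonation states to the ionizable
#' sites of a peptide at a fixed net charge. Protomers are self-contained:
#' they carry, per site, the assigned state label, its formal charge and the
#' thermodynamic site type, so downstream scoring does not need the peptide
#' definition again.
#'
#' @param peptide A [peptide_definition()].
#' @param assignment Named character vector `site_id -> state_label`, one
#'   entry per declared site.
#' @return An object of class `protomer` with fields `peptide_id`,
#'   `assignment`, `charges`, `site_types`, `site_kinds` and `net_charge`.
#' @export
protomer <- function(peptide, assignment) {
  ids <- vapply(peptide$sites, function(s) s$site_id, "")
  if (!setequal(names(assignment), ids) || length(assignment) != length(ids)) {
    stopf("assignment must name every declared site exactly once")
  }
  assignment <- assignment[ids]  # canonical site order
  charges <- integer(length(ids))
  types <- kinds <- character(length(ids))
  for (i in seq_along(peptide$sites)) {
    s <- peptide$sites[[i]]
    j <- match(assignment[[i]], s$states$label)
    if (is.na(j)) stopf("site '%s': unknown state label '%s'",
                        s$site_id, assignment[[i]])
    charges[i] <- s$states$charge[j]
    types[i] <- s$site_type
    kinds[i] <- s$kind
  }
  names(charges) <- names(types) <- names(kinds) <- ids
  structure(
    list(peptide_id = peptide$peptide_id,
         assignment = assignment,
         charges = charges,
         site_types = types,
         site_kinds = kinds,
         net_charge = sum(charges)),
    class = "protomer")
}

#' Protonation pattern of a protomer
#'
#' One symbol per site in declared site order: `"+"`, `"0"`, `"-"` or a
#' tautomer label, matching the layout of per-protomer report tables.
#'
#' @param p A `protomer`.
#' @param collapse Separator between site symbols.
#' @return A character scalar.
#' @export
protomer_pattern <- function(p, collapse = " ") {
  paste(p$assignment, collapse = collapse)
}

#' @export
format.protomer <- function(x, ...) {
  sprintf("<protomer %s z=%+d: %s>", x$peptide_id, x$net_charge,
          protomer_pattern(x))
}

#' @export
print.protomer <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

#' Parse a protonation pattern into a protomer
#'
#' @param peptide A [peptide_definition()].
#' @param pattern Space-separated state labels, one per site in declared
#'   order (e.g. `"0 + 0 -"`).
#' @return A `protomer`.
#' @export
parse_pattern <- function(peptide, pattern) {
  labs <- strsplit(trimws(pattern), "[[:space:]]+")[[1]]
  ids <- vapply(peptide$sites, function(s) s$site_id, "")
  if (length(labs) != length(ids)) {
    stopf("pattern '%s' has %d fields; peptide '%s' declares %d sites",
          pattern, length(labs), peptide$peptide_id, length(ids))
  }
  protomer(peptide, stats::setNames(labs, ids))
}

#' Enumerate every protomer of a peptide at a given net charge
#'
#' Returns every distinct assignment of states to sites whose formal charges
#' sum to `z`. Two assignments differing only in a neutral tautomer label
#' (e.g. His N-delta-H vs N-epsilon-H) are distinct protomers. A site whose
#' charged state is gated contributes that state only when `z` belongs to its
#' gating set. The result is ordered lexicographically, the first declared
#' site most significant and states in their declared order, so output order
#' is deterministic and reproducible.
#'
#' @param peptide A [peptide_definition()].
#' @param z Target net charge.
#' @return List of `protomer` objects (empty if `z` is unreachable).
#' @examples
#' length(enumerate_protomers(angiotensin_ii(), 1))  # 14
#' length(enumerate_protomers(trp_cage(), 2))        # 15
#' @export
enumerate_protomers <- function(peptide, z) {
  z <- as.integer(z)
  # per-site admissible states at this z (gating applied to charged states)
  state_sets <- lapply(peptide$sites, function(s) {
    st <- s$states
    if (!is.null(s$gating) && !(z %in% s$gating)) {
      st <- st[st$charge == 0L, , drop = FALSE]
    }
    st
  })
  # depth-first in declared site/state order => lexicographic output
  n <- length(state_sets)
  out <- list()
  labs <- character(n)
  recurse <- function(i, acc) {
    # prune: remaining sites bound the reachable charge window
    if (i > n) {
      if (acc == z) out[[length(out) + 1L]] <<- labs
      return(invisible())
    }
    rest <- state_sets[i:n]
    lo <- acc + sum(vapply(rest, function(st) min(st$charge), 0L))
    hi <- acc + sum(vapply(rest, function(st) max(st$charge), 0L))
    if (z < lo || z > hi) return(invisible())
    st <- state_sets[[i]]
    for (j in seq_len(nrow(st))) {
      labs[i] <<- st$label[j]
      recurse(i + 1L, acc + st$charge[j])
    }
  }
  recurse(1L, 0L)
  ids <- vapply(peptide$sites, function(s) s$site_id, "")
  lapply(out, function(v) protomer(peptide, stats::setNames(v, ids)))
}

#' Total protomer-space size over peptides and their charge states
#'
#' @param peptides List of [peptide_definition()]s, each carrying its
#'   `charge_states`.
#' @return Integer: the summed number of protomers.
#' @examples
#' protomer_space_size(packaged_systems())  # 100
#' @export
protomer_space_size <- function(peptides) {
  if (length(peptides) == 0L) return(0L)
  sum(vapply(peptides, function(p) {
    sum(vapply(p$charge_states,
               function(z) length(enumerate_protomers(p, z)), 0L))
  }, 0L))
}

#' Number of ionized sites of a protomer
#'
#' @param p A `protomer`.
#' @return Integer count of sites whose assigned state has nonzero charge.
#' @export
count_ionized <- function(p) {
  sum(p$charges != 0L)
}

#' Tabulate a list of protomers as a protonation-pattern data frame
#'
#' One column per site (state labels) plus `z` and `IR` columns; layout
#' matches the per-protomer report tables.
#'
#' @param protomers List of `protomer` objects for one peptide.
#' @return A data frame.
#' @export
protomer_table <- function(protomers) {
  if (length(protomers) == 0L) {
    return(data.frame())
  }
  ids <- names(protomers[[1]]$assignment)
  df <- as.data.frame(do.call(rbind, lapply(protomers, function(p) {
    p$assignment
  })), stringsAsFactors = FALSE)
  names(df) <- ids
  df$z <- vapply(protomers, function(p) p$net_charge, 0L)
  df$IR <- vapply(protomers, count_ionized, 0L)
  rownames(df) <- NULL
  df
}

#' Write protomer lists as TSV
#' @param protomers List of `protomer` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_protomer_tsv <- function(protomers, path) {
  write_tsv_file(protomer_table(protomers), path)
}
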