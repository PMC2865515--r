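#' Intrinsic gas-phase thermochemistry tables
#'
#' An intrinsic table stores, per thermodynamic site type and conformational
#' context, the internal-energy change of protonation (`dU`), the proton
#' affinity (`PA`, negative protonation enthalpy) and the gas-phase basicity
#' (`GPB`, negative protonation free energy), all in kJ/mol. For an acidic
#' site the stored values are those of the conjugate base, i.e. the gas-phase
#' acidity (GA) of the acid.
#'
#' `intrinsic_free_amino_acids()` returns the packaged free-amino-acid side
#' chain values in both the lowest-energy ("folded") and extended, all-trans
#' ("linear") conformations. `intrinsic_peptide_scale()` returns the default
#' scale used for peptide penalty work: the folded side-chain values plus
#' reconstructed terminal-group entries (column `source` distinguishes them).
#'
#' @param path Path to a TSV with columns `site_type`, `context`, `dU`,
#'   `PA`, `GPB` (and optionally `source`).
#' @return A data frame with those columns.
#' @export
read_intrinsic_table <- function(path) {
  df <- read_tsv_file(path)
  need <- c("site_type", "context", "dU", "PA", "GPB")
  if (!all(need %in% names(df))) {
    stopf("intrinsic table must have columns %s", paste(need, collapse = ", "))
  }
  for (col in c("dU", "PA", "GPB")) {
    df[[col]] <- as.numeric(df[[col]])
    if (any(!is.finite(df[[col]]))) stopf("non-finite %s values", col)
  }
  df
}

#' @rdname read_intrinsic_table
#' @export
intrinsic_free_amino_acids <- function() {
  read_intrinsic_table(system.file("extdata", "intrinsic_free_amino_acids.tsv",
                                   package = "protomerscan", mustWork = TRUE))
}

#' @rdname read_intrinsic_table
#' @export
intrinsic_peptide_scale <- function() {
  read_intrinsic_table(system.file("extdata", "intrinsic_peptide_scale.tsv",
                                   package = "protomerscan", mustWork = TRUE))
}

# Resolve a site_type -> value lookup for one quantity from an intrinsic
# table (data frame) or a plain named numeric vector.
thermo_lookup <- function(table, quantity) {
  if (is.numeric(table) && !is.null(names(table))) return(table)
  if (!is.data.frame(table)) stopf("table must be a data frame or named vector")
  if (!quantity %in% names(table)) stopf("table has no '%s' column", quantity)
  stats::setNames(table[[quantity]], table$site_type)
}

#' Packaged single-pair anchor rows
#'
#' Printed relative gas-phase-basicity penalties of the single-pair
#' (two-ion) protomers of the neutral-charge blocks of the three packaged
#' systems. These rows pin down every acid/base pair penalty needed to
#' reconstruct the full relative-penalty columns additively, and are the
#' standard input of [calibrate_anchors()].
#'
#' @return Data frame with columns `peptide` (`BK`/`AN`/`TC`), `pattern`,
#'   `pair`, `dGPB` (kJ/mol).
#' @export
packaged_anchor_rows <- function() {
  read_tsv_file(system.file("extdata", "anchor_rows_gpb.tsv",
                            package = "protomerscan", mustWork = TRUE))
}

#' Turn anchor rows into calibration input
#'
#' @param peptide A [peptide_definition()].
#' @param rows Subset of [packaged_anchor_rows()] (or a data frame with
#'   `pattern` and `dGPB` columns) for that peptide. The rows' reference is
#'   the all-neutral protomer (zero raw penalty), as in neutral-charge
#'   blocks.
#' @return List of rows suitable for [calibrate_anchors()].
#' @export
anchor_calibration_rows <- function(peptide, rows) {
  lapply(seq_len(nrow(rows)), function(i) {
    list(protomer = parse_pattern(peptide, rows$pattern[i]),
         relative_penalty = rows$dGPB[i])
  })
}

#' Additive intrinsic charge-separation penalty of a protomer
#'
#' Creating a charge-separated (zwitterionic) pair from an acid AH and a
#' base B costs, to first approximation, `GA(AH) - GPB(B)` in the gas phase.
#' The raw penalty of a protomer is the additive generalization: the sum of
#' the stored acidity values of its deprotonated acids minus the sum of the
#' basicity values of its protonated bases. The same bookkeeping applies to
#' the `PA` and `dU` columns.
#'
#' @param p A `protomer`.
#' @param table Intrinsic table (data frame) or named numeric vector of
#'   site-type values.
#' @param quantity One of `"GPB"`, `"PA"`, `"dU"`.
#' @param context Context rows to use when `table` has several (default
#'   `"folded"`).
#' @return Scalar penalty in kJ/mol, with attribute `components`: the signed
#'   per-site contributions.
#' @export
separation_penalty <- function(p, table, quantity = c("GPB", "PA", "dU"),
                               context = "folded") {
  quantity <- match.arg(quantity)
  if (is.data.frame(table) && "context" %in% names(table)) {
    table <- table[table$context == context, , drop = FALSE]
  }
  vals <- thermo_lookup(table, quantity)
  ion <- which(p$charges != 0L)
  comp <- numeric(0)
  for (i in ion) {
    ty <- p$site_types[i]
    if (!ty %in% names(vals)) {
      stopf("no intrinsic %s entry for site '%s' (type '%s')",
            quantity, names(p$charges)[i], ty)
    }
    comp[names(p$charges)[i]] <-
      if (p$charges[i] < 0L) vals[[ty]] else -vals[[ty]]
  }
  structure(sum(comp), components = comp)
}

#' Normalize penalties of the protomers of one charge state
#'
#' Relative penalties are reported against the protomer with the lowest raw
#' charge-separation penalty of the set, whose relative value is set to
#' zero; ties all receive zero.
#'
#' @param protomers List of `protomer` objects sharing one net charge.
#' @param table,quantity,context As in [separation_penalty()].
#' @return A data frame of class `penalty_table` with columns `pattern`,
#'   `z`, `IR`, `raw` and `relative` (kJ/mol); attribute `components` holds
#'   the per-protomer signed site contributions.
#' @export
normalize_penalties <- function(protomers, table,
                                quantity = c("GPB", "PA", "dU"),
                                context = "folded") {
  quantity <- match.arg(quantity)
  if (length(protomers) == 0L) stopf("empty protomer set")
  zs <- vapply(protomers, function(p) p$net_charge, 0L)
  if (length(unique(zs)) != 1L) {
    stopf("all protomers must share one net charge (got %s)",
          paste(sort(unique(zs)), collapse = ", "))
  }
  pens <- lapply(protomers, separation_penalty, table = table,
                 quantity = quantity, context = context)
  raw <- vapply(pens, as.numeric, 0)
  out <- data.frame(
    pattern = vapply(protomers, protomer_pattern, ""),
    z = zs,
    IR = vapply(protomers, count_ionized, 0L),
    raw = raw,
    relative = raw - min(raw),
    stringsAsFactors = FALSE)
  attr(out, "components") <- lapply(pens, attr, "components")
  attr(out, "quantity") <- quantity
  class(out) <- c("penalty_table", "data.frame")
  out
}

#' Penalty report across all three intrinsic quantities
#'
#' Convenience wrapper running [normalize_penalties()] for `dU`, `PA` and
#' `GPB`, mirroring the relative-penalty columns of per-protomer report
#' tables.
#'
#' @inheritParams normalize_penalties
#' @return Data frame with columns `pattern`, `z`, `IR`, `ddU`, `dPA`,
#'   `dGPB`.
#' @export
penalty_report <- function(protomers, table, context = "folded") {
  base <- normalize_penalties(protomers, table, "dU", context)
  out <- base[c("pattern", "z", "IR")]
  out$ddU <- base$relative
  out$dPA <- normalize_penalties(protomers, table, "PA", context)$relative
  out$dGPB <- normalize_penalties(protomers, table, "GPB", context)$relative
  out
}

#' Calibrate intrinsic site values from printed relative-penalty rows
#'
#' Solves, by least squares, for per-site-type intrinsic values (acidity for
#' acids, basicity for bases) that reproduce a set of relative penalties
#' under the additive charge-separation model. Each row contributes one
#' linear equation `sum GA(acids) - sum GPB(bases) - (same for reference) =
#' relative_penalty`. The absolute scale is not identifiable: within each
#' connected component of site types co-occurring in rows, one site type is
#' pinned to a reference value (0 by default, or a value supplied via
#' `pin`), which leaves all relative penalties of any fixed-charge protomer
#' set unchanged.
#'
#' @param rows List of `list(protomer =, relative_penalty =, reference =)`;
#'   `reference` is the reference protomer of the row's charge state and may
#'   be omitted when the reference carries no ionized sites (raw penalty 0),
#'   as for neutral-charge blocks normalized to the all-neutral protomer.
#' @param pin Optional named numeric vector of site-type values used to pin
#'   one gauge site per connected component.
#' @return Object of class `anchor_fit` with `coefficients` (named
#'   site-type values), `residuals`, `fitted`, `pinned`.
#' @export
calibrate_anchors <- function(rows, pin = NULL) {
  if (length(rows) == 0L) stopf("no rows to calibrate from")
  # signed incidence of each row over site types
  row_coef <- function(p, ref = NULL) {
    co <- numeric(0)
    add <- function(pp, sign) {
      ion <- which(pp$charges != 0L)
      for (i in ion) {
        ty <- pp$site_types[i]
        s <- sign * (if (pp$charges[i] < 0L) 1 else -1)
        co[ty] <<- (if (ty %in% names(co)) co[[ty]] else 0) + s
      }
    }
    add(p, 1)
    if (!is.null(ref)) add(ref, -1)
    co
  }
  coefs <- lapply(rows, function(r) {
    row_coef(r$protomer, r$reference %||% NULL)
  })
  types <- sort(unique(unlist(lapply(coefs, names))))
  if (length(types) == 0L) stopf("rows involve no ionized sites")
  A <- matrix(0, nrow = length(rows), ncol = length(types),
              dimnames = list(NULL, types))
  for (i in seq_along(coefs)) A[i, names(coefs[[i]])] <- coefs[[i]]
  b <- vapply(rows, function(r) as.numeric(r$relative_penalty), 0)

  # connected components of the type co-occurrence graph; pin one type each
  comp <- stats::setNames(seq_along(types), types)
  for (co in coefs) {
    nm <- names(co)
    if (length(nm) > 1L) {
      ids <- unique(comp[nm])
      comp[comp %in% ids] <- min(ids)
    }
  }
  pinned <- numeric(0)
  for (cid in unique(comp)) {
    members <- names(comp)[comp == cid]
    g <- members[1L]
    pinned[g] <- if (!is.null(pin) && g %in% names(pin)) pin[[g]] else 0
  }
  # augment with gauge equations (exact pins, large weight not needed: we
  # solve the reduced system with pinned columns moved to the RHS)
  free <- setdiff(types, names(pinned))
  b_adj <- b - A[, names(pinned), drop = FALSE] %*% unlist(pinned)
  Af <- A[, free, drop = FALSE]
  if (length(free) > 0L) {
    qrA <- qr(Af)
    if (qrA$rank < length(free)) {
      null_types <- free[qrA$pivot[(qrA$rank + 1L):length(free)]]
      stopf("underdetermined system: cannot resolve site type(s) %s",
            paste(null_types, collapse = ", "))
    }
    x <- qr.coef(qrA, b_adj)
  } else {
    x <- numeric(0)
  }
  est <- c(unlist(pinned), stats::setNames(as.numeric(x), free))[types]
  names(est) <- types
  fitted <- as.numeric(A %*% est)
  structure(
    list(coefficients = est, residuals = b - fitted, fitted = fitted,
         pinned = pinned, design = A, target = b),
    class = "anchor_fit")
}

#' @export
coef.anchor_fit <- function(object, ...) object$coefficients

#' @export
residuals.anchor_fit <- function(object, ...) object$residuals

#' @export
print.anchor_fit <- function(x, ...) {
  cat("Anchor calibration (additive charge-separation model)\n")
  cat("  site values (kJ/mol; acids: acidity, bases: basicity):\n")
  for (nm in names(x$coefficients)) {
    tag <- if (nm %in% names(x$pinned)) "  [gauge pin]" else ""
    cat(sprintf("    %-14s %8.2f%s\n", nm, x$coefficients[[nm]], tag))
  }
  cat(sprintf("  max |residual|: %.3f kJ/mol over %d rows\n",
              max(abs(x$residuals)), length(x$residuals)))
  invisible(x)
}

#' Site values of an anchor fit as an intrinsic table
#'
#' @param fit An `anchor_fit`.
#' @param quantity Column to fill with the calibrated values.
#' @param context Context label for the rows.
#' @return Data frame usable as the `table` argument of
#'   [separation_penalty()] for that quantity.
#' @export
anchor_table <- function(fit, quantity = "GPB", context = "folded") {
  df <- data.frame(site_type = names(coef(fit)), context = context,
                   dU = NA_real_, PA = NA_real_, GPB = NA_real_,
                   stringsAsFactors = FALSE)
  df[[quantity]] <- as.numeric(coef(fit))
  df
}

#' Conformational shift of intrinsic protonation thermochemistry
#'
#' Component-wise `linear - folded` differences of `dU`, `PA` and `GPB` for
#' one site type, quantifying how much internal hydrogen bonding in the
#' folded conformer raises (bases) or lowers (acid conjugate bases) the
#' intrinsic protonation thermochemistry.
#'
#' @param folded,linear Single entries (one-row data frames or named
#'   lists/vectors with `site_type`, `context`, `dU`, `PA`, `GPB`).
#' @return Named numeric vector `c(dU_shift, PA_shift, GPB_shift)` in
#'   kJ/mol.
#' @export
conformer_shift <- function(folded, linear) {
  as_entry <- function(e) {
    if (is.data.frame(e)) {
      if (nrow(e) != 1L) stopf("expected a single intrinsic entry")
      e <- as.list(e)
    }
    e
  }
  folded <- as_entry(folded); linear <- as_entry(linear)
  if (!identical(as.character(folded$site_type),
                 as.character(linear$site_type))) {
    stopf("site_type mismatch: '%s' vs '%s'",
          folded$site_type, linear$site_type)
  }
  if (!identical(as.character(folded$context), "folded") ||
      !identical(as.character(linear$context), "linear")) {
    stopf("contexts must be 'folded' and 'linear'")
  }
  c(dU_shift = as.numeric(linear$dU) - as.numeric(folded$dU),
    PA_shift = as.numeric(linear$PA) - as.numeric(folded$PA),
    GPB_shift = as.numeric(linear$GPB) - as.numeric(folded$GPB))
}

#' Dispersion of the entropic term across intrinsic entries
#'
#' The difference `GPB - PA` isolates the (temperature-weighted) entropic
#' contribution to gas-phase protonation. Its standard deviation across a
#' set of intrinsic entries measures how transferable a constant entropic
#' term is between site types and conformations.
#'
#' @param entries Intrinsic table (data frame) with `GPB` and `PA` columns,
#'   at least two rows.
#' @return Named numeric vector with the `population` and `sample` standard
#'   deviation conventions, in kJ/mol.
#' @export
entropic_dispersion <- function(entries) {
  if (!is.data.frame(entries) || nrow(entries) < 2L) {
    stopf("need at least two intrinsic entries")
  }
  x <- as.numeric(entries$GPB) - as.numeric(entries$PA)
  n <- length(x)
  s2 <- stats::var(x)
  c(population = sqrt(s2 * (n - 1) / n), sample = sqrt(s2))
}
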