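# Per-protomer report rows (energetics + structural counts) and binned
# energy/structure maps.

#' Build the per-protomer report of one charge state
#'
#' Joins the refined energy ranking, the relative intrinsic penalties and
#' the interaction censuses of the lowest-energy conformers into rows that
#' mirror the standard per-protomer tables: protonation pattern, energy
#' difference to the most stable protomer, relative intrinsic `ddU`, `dPA`,
#' `dGPB`, and the interaction counts.
#'
#' @param peptide A [peptide_definition()].
#' @param z The charge state reported.
#' @param ranking Result of [rank_protomers()] (patterns in `protomer`).
#' @param penalties Result of [penalty_report()] for the same protomers.
#' @param censuses Named list: pattern -> `interaction_census` of that
#'   protomer's lowest-energy conformer.
#' @return Data frame of class `protomer_report`, rows sorted by `dE`
#'   ascending; serialization via [write_report_tsv()] is byte-stable for
#'   fixed inputs.
#' @export
build_report <- function(peptide, z, ranking, penalties, censuses) {
  missing_cen <- setdiff(ranking$protomer, names(censuses))
  if (length(missing_cen)) {
    stopf("no census for protomer(s): %s",
          paste(missing_cen, collapse = "; "))
  }
  pi <- match(ranking$protomer, penalties$pattern)
  if (any(is.na(pi))) {
    stopf("no penalties for protomer(s): %s",
          paste(ranking$protomer[is.na(pi)], collapse = "; "))
  }
  cen <- censuses[ranking$protomer]
  out <- data.frame(
    pattern = ranking$protomer,
    dE = ranking$dE,
    ddU = penalties$ddU[pi],
    dPA = penalties$dPA[pi],
    dGPB = penalties$dGPB[pi],
    IR = vapply(cen, function(x) x$IR, 0L),
    SB = vapply(cen, function(x) x$SB, 0L),
    sHB = vapply(cen, function(x) x$sHB, 0L),
    iHB = vapply(cen, function(x) x$iHB, 0L),
    HB = vapply(cen, function(x) x$HB, 0L),
    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[order(out$dE, out$pattern), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "peptide_id") <- peptide$peptide_id
  attr(out, "z") <- z
  class(out) <- c("protomer_report", "data.frame")
  out
}

#' Write a protomer report as TSV
#'
#' Energies are printed as integers (kJ/mol), matching the table
#' conventions of the field; full precision is kept in a machine-readable
#' JSON sidecar when `sidecar = TRUE`.
#'
#' @param report A `protomer_report`.
#' @param path Output path.
#' @param sidecar Also write `<path>.json` with full-precision values.
#' @return `path`, invisibly.
#' @export
write_report_tsv <- function(report, path, sidecar = FALSE) {
  fmt <- report
  for (col in c("dE", "ddU", "dPA", "dGPB")) {
    fmt[[col]] <- sprintf("%.0f", fmt[[col]])
  }
  con <- file(path, "w")
  writeLines(sprintf("# peptide=%s z=%+d",
                     attr(report, "peptide_id") %||% "NA",
                     attr(report, "z") %||% NA_integer_), con)
  utils::write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  if (sidecar) {
    jsonlite::write_json(as.data.frame(report), paste0(path, ".json"),
                         digits = NA, auto_unbox = TRUE)
  }
  invisible(path)
}

report_axis <- function(rows, axis) {
  ax <- switch(axis,
               penalty = rows$dGPB,
               IR = rows$IR, SB = rows$SB, iHB = rows$iHB, HB = rows$HB,
               stopf("unknown axis '%s' (use penalty, IR, SB, iHB or HB)",
                     axis))
  as.numeric(ax)
}

#' Bin report rows on two structure/energy axes
#'
#' Builds the binned energy/structure relationship map: cells are mean
#' energy differences (`dE`, kJ/mol) of the protomers falling in each
#' (x, y) bin; empty cells are `NA`, never zero. The cell containing the
#' lowest-energy protomer is flagged.
#'
#' @param rows A `protomer_report` (or data frame with the same columns).
#' @param x_axis,y_axis One of `"penalty"` (relative intrinsic GPB
#'   penalty), `"IR"`, `"SB"`, `"iHB"`, `"HB"`.
#' @param bins Number of bins per axis (integer-valued axes are binned on
#'   integers when their range is smaller).
#' @return Object of class `binned_map`: list with `mean_dE` and `count`
#'   matrices, bin `x_edges`/`y_edges`, and `min_cell`, the (row, col) of
#'   the cell holding the minimum-`dE` row.
#' @export
build_binned_map <- function(rows, x_axis = "penalty", y_axis = "SB",
                             bins = 10L) {
  if (nrow(rows) == 0L) stopf("no rows")
  x <- report_axis(rows, x_axis)
  y <- report_axis(rows, y_axis)
  edges <- function(v) {
    if (min(v) == max(v)) return(c(min(v) - 0.5, max(v) + 0.5))
    if (all(v == round(v)) && diff(range(v)) + 1 <= bins) {
      seq(min(v) - 0.5, max(v) + 0.5, by = 1)  # integer axis: unit bins
    } else {
      seq(min(v), max(v), length.out = bins + 1L)
    }
  }
  xe <- edges(x); ye <- edges(y)
  xi <- pmin(findInterval(x, xe, rightmost.closed = TRUE), length(xe) - 1L)
  yi <- pmin(findInterval(y, ye, rightmost.closed = TRUE), length(ye) - 1L)
  nx <- length(xe) - 1L; ny <- length(ye) - 1L
  mean_dE <- matrix(NA_real_, nx, ny)
  count <- matrix(0L, nx, ny)
  for (k in seq_along(x)) {
    count[xi[k], yi[k]] <- count[xi[k], yi[k]] + 1L
    cur <- mean_dE[xi[k], yi[k]]
    mean_dE[xi[k], yi[k]] <- if (is.na(cur)) rows$dE[k] else cur + rows$dE[k]
  }
  nz <- count > 0L
  mean_dE[nz] <- mean_dE[nz] / count[nz]
  kmin <- which.min(rows$dE)
  structure(list(x_axis = x_axis, y_axis = y_axis,
                 x_edges = xe, y_edges = ye,
                 mean_dE = mean_dE, count = count,
                 min_cell = c(xi[kmin], yi[kmin])),
            class = "binned_map")
}

#' @export
print.binned_map <- function(x, ...) {
  cat(sprintf("Binned map: %s x %s, %d x %d cells (%d occupied)\n",
              x$x_axis, x$y_axis, nrow(x$mean_dE), ncol(x$mean_dE),
              sum(x$count > 0)))
  cat(sprintf("  lowest-energy protomer in cell (%d, %d)\n",
              x$min_cell[1], x$min_cell[2]))
  invisible(x)
}

#' Write a run manifest
#'
#' Records configuration, seeds, thresholds and input digests of a run to a
#' JSON file, for reproducibility of reports.
#'
#' @param path Output path.
#' @param config A [protocol_config()] or arbitrary named list.
#' @param inputs Named character vector of input file paths (digested by
#'   file size and md5).
#' @return `path`, invisibly.
#' @export
write_run_manifest <- function(path, config = list(), inputs = character(0)) {
  digests <- lapply(inputs, function(f) {
    list(path = f, size = file.info(f)$size,
         md5 = unname(tools::md5sum(f)))
  })
  jsonlite::write_json(
    list(timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
         config = unclass(config), inputs = digests),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
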