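# Hierarchical conformer-selection protocol over externally supplied energy
# lists: (i) window-minimum harvesting from an annealing-style trajectory,
# (ii) energy-threshold filtering, (iii) stratified random selection for
# refinement, (iv) ranking of refined energies; plus the cross-level
# threshold validation statistic.

#' Selection-protocol configuration
#'
#' Defaults follow common practice for this protocol: 5-ps non-overlapping
#' trajectory windows, a 100 kJ/mol force-field energy threshold (60 kJ/mol
#' for compact folded systems such as Trp-cage), 60 conformers selected for
#' refinement (35 for Trp-cage) and a 10 kJ/mol near-minimum window for the
#' cross-level check. The MD temperature is carried as metadata only.
#'
#' @param window_ps Trajectory window length, ps.
#' @param delta_threshold Energy threshold above the force-field minimum,
#'   kJ/mol.
#' @param n_select Number of stratified-selection bins.
#' @param qm_window Near-minimum window at the refined level, kJ/mol.
#' @param seed Seed for the stratified random choice.
#' @param md_temperature_K Metadata: simulation temperature.
#' @return An object of class `protocol_config`.
#' @export
protocol_config <- function(window_ps = 5, delta_threshold = 100,
                            n_select = 60, qm_window = 10, seed = 1L,
                            md_temperature_K = 700) {
  if (any(c(window_ps, delta_threshold, n_select, qm_window) <= 0)) {
    stopf("window_ps, delta_threshold, n_select and qm_window must be positive")
  }
  structure(list(window_ps = window_ps, delta_threshold = delta_threshold,
                 n_select = as.integer(n_select), qm_window = qm_window,
                 seed = as.integer(seed),
                 md_temperature_K = md_temperature_K),
            class = "protocol_config")
}

check_records <- function(records, need_time = FALSE) {
  need <- c("conformer_id", "protomer", "energy", "level")
  if (need_time) need <- c(need, "time_ps")
  if (!is.data.frame(records) || !all(need %in% names(records))) {
    stopf("energy records must have columns %s", paste(need, collapse = ", "))
  }
  if (any(!is.finite(records$energy))) stopf("non-finite energies")
  if (length(unique(records$level)) > 1L) {
    stopf("level tags must not be mixed within one record set")
  }
  invisible(records)
}

#' Read / write energy-record TSV files
#'
#' Columns: `conformer_id`, `protomer` (protonation pattern), `time_ps`
#' (optional), `energy` (kJ/mol), `level` (`forcefield` or `refined`).
#'
#' @param path File path.
#' @return A data frame of energy records.
#' @export
read_energy_tsv <- function(path) {
  df <- read_tsv_file(path)
  check_records(df)
  df
}

#' @rdname read_energy_tsv
#' @param records Data frame of energy records.
#' @export
write_energy_tsv <- function(records, path) {
  write_tsv_file(records, path)
}

#' Per-window energy minima of a trajectory
#'
#' Splits a time-sorted trajectory into non-overlapping windows
#' `[k*w, (k+1)*w)` and keeps, for each non-empty window, the lowest-energy
#' record (ties broken by earliest time), emulating the harvesting of one
#' annealing candidate per window.
#'
#' @param trajectory Energy records with a `time_ps` column.
#' @param window_ps Window length, ps.
#' @return The selected records, one per non-empty window, in time order.
#' @export
window_minima <- function(trajectory, window_ps = 5) {
  check_records(trajectory, need_time = TRUE)
  if (any(trajectory$time_ps < 0)) stopf("negative times")
  trajectory <- trajectory[order(trajectory$time_ps), , drop = FALSE]
  win <- floor(trajectory$time_ps / window_ps)
  picks <- vapply(split(seq_len(nrow(trajectory)), win), function(idx) {
    idx[which.min(trajectory$energy[idx])]  # first minimum = earliest time
  }, 0L)
  out <- trajectory[sort(picks), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Keep conformers within an energy threshold of the minimum
#'
#' @param conformers Energy records.
#' @param delta_threshold Threshold above the minimum, kJ/mol (boundary
#'   inclusive); the minimum itself is always retained.
#' @return The filtered records.
#' @export
threshold_filter <- function(conformers, delta_threshold = 100) {
  check_records(conformers)
  if (nrow(conformers) == 0L) stopf("empty input")
  keep <- conformers$energy - min(conformers$energy) <= delta_threshold
  out <- conformers[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified random selection from equally spaced energy windows
#'
#' Divides the energy span into `n_select` equal-width bins
#' `[min + k*D/n, min + (k+1)*D/n)` (last bin closed) and draws one
#' uniformly random member from each non-empty bin. By default the span is
#' the threshold width `delta_threshold`; with `span = "range"` it is the
#' range of the filtered set. Deterministic for a fixed seed; empty bins
#' contribute nothing, so the result has at most `n_select` records.
#'
#' @param conformers Energy records, already threshold-filtered.
#' @param n_select Number of bins.
#' @param seed Seed for the random draws.
#' @param delta_threshold Span width when `span = "threshold"`.
#' @param span `"threshold"` (default) or `"range"`.
#' @return The selected records, in input row order.
#' @export
stratified_select <- function(conformers, n_select = 60, seed = 1L,
                              delta_threshold = 100,
                              span = c("threshold", "range")) {
  check_records(conformers)
  span <- match.arg(span)
  if (n_select <= 0L) stopf("n_select must be positive")
  if (nrow(conformers) == 0L) stopf("empty input")
  emin <- min(conformers$energy)
  width <- if (span == "threshold") delta_threshold else
    max(conformers$energy) - emin
  if (width <= 0) {  # degenerate flat set: all in one bin
    return(with_seed(seed, {
      conformers[sample.int(nrow(conformers), 1L), , drop = FALSE]
    }))
  }
  bin <- pmin(floor((conformers$energy - emin) / (width / n_select)),
              n_select - 1L)  # last bin closed
  with_seed(seed, {
    picks <- vapply(split(seq_len(nrow(conformers)), bin), function(idx) {
      idx[sample.int(length(idx), 1L)]
    }, 0L)
    out <- conformers[sort(unname(picks)), , drop = FALSE]
    rownames(out) <- NULL
    out
  })
}

#' Rank protomers by their refined minimum energies
#'
#' Groups records by protomer, takes the per-protomer minimum energy and
#' reports it relative to the lowest minimum of the charge state.
#'
#' @param refined Energy records of one charge state (a `z` column, when
#'   present, must be constant).
#' @return Data frame with columns `protomer`, `min_energy`, `dE`, sorted
#'   by `dE` ascending (ties by protomer pattern for a stable order).
#' @export
rank_protomers <- function(refined) {
  check_records(refined)
  if (nrow(refined) == 0L) stopf("empty input")
  if ("z" %in% names(refined) && length(unique(refined$z)) > 1L) {
    stopf("mixed charge states: %s",
          paste(sort(unique(refined$z)), collapse = ", "))
  }
  mins <- vapply(split(refined$energy, refined$protomer), min, 0)
  out <- data.frame(protomer = names(mins),
                    min_energy = as.numeric(mins),
                    dE = as.numeric(mins) - min(mins),
                    stringsAsFactors = FALSE)
  out <- out[order(out$dE, out$protomer), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Cross-level retention statistic of the energy threshold
#'
#' Validates the force-field threshold against refined energies: among
#' refined records within `qm_window` of the refined minimum, the fraction
#' whose matched force-field energy lies more than `delta_threshold` above
#' the force-field minimum. A small value (a few percent) certifies that
#' the threshold filtering loses almost none of the refined near-minimum
#' conformers.
#'
#' @param ff Force-field-level energy records.
#' @param refined Refined-level energy records; `conformer_id`s must match
#'   records in `ff`.
#' @param qm_window Near-minimum window at the refined level, kJ/mol.
#' @param delta_threshold Force-field threshold, kJ/mol.
#' @return Fraction in `[0, 1]`.
#' @export
cross_level_retention <- function(ff, refined, qm_window = 10,
                                  delta_threshold = 100) {
  check_records(ff)
  check_records(refined)
  unmatched <- setdiff(refined$conformer_id, ff$conformer_id)
  if (length(unmatched)) {
    stopf("refined conformer_id(s) missing from the force-field set: %s",
          paste(unmatched, collapse = ", "))
  }
  near <- refined[refined$energy - min(refined$energy) <= qm_window, ,
                  drop = FALSE]
  ff_e <- ff$energy[match(near$conformer_id, ff$conformer_id)]
  mean(ff_e - min(ff$energy) > delta_threshold)
}

#' Run the full selection pipeline on a trajectory set
#'
#' Convenience composition of the protocol: per-protomer window minima,
#' threshold filtering over the pooled candidates, stratified selection,
#' refinement through a caller-supplied adapter, and final ranking.
#'
#' @param trajectory Force-field energy records with `time_ps`.
#' @param config A [protocol_config()].
#' @param refine Function mapping the selected force-field records to
#'   refined-level records (an adapter to an external engine's energies);
#'   the identity-with-relabel default ranks on force-field energies.
#' @return List with elements `candidates`, `filtered`, `selected`,
#'   `refined`, `ranking`.
#' @export
run_selection <- function(trajectory, config = protocol_config(),
                          refine = NULL) {
  cands <- do.call(rbind, lapply(split(trajectory, trajectory$protomer),
                                 window_minima,
                                 window_ps = config$window_ps))
  rownames(cands) <- NULL
  filt <- threshold_filter(cands, config$delta_threshold)
  sel <- do.call(rbind, lapply(split(filt, filt$protomer), function(g) {
    stratified_select(g, config$n_select, seed = config$seed,
                      delta_threshold = config$delta_threshold)
  }))
  rownames(sel) <- NULL
  refined <- if (is.null(refine)) {
    r <- sel
    r$level <- "refined"
    r
  } else {
    refine(sel)
  }
  list(candidates = cands, filtered = filt, selected = sel,
       refined = refined, ranking = rank_protomers(refined))
}
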