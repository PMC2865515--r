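# Synthetic fixtures: conformers with prescribed interaction patterns and
# mock per-protomer energy landscapes. Fixtures use simplified residue
# geometries (ideal ammonium / carboxylate / carbonyl templates on a
# glycine scaffold): the classifier only needs correct atom names, elements
# and distances, not rotamer-accurate side chains.

#' Specify a synthetic conformer fixture
#'
#' Prescribes an interaction census to realize geometrically: `sb` salt
#' bridges (each an ionized ammonium/carboxylate pair), with `shb[i]`
#' hydrogen bonds inside bridge `i` (0-2: one per carboxylate oxygen),
#' `ihb` ionized hydrogen bonds (charged ammonium donating to a neutral
#' carbonyl), `donate3` ionized ammonium groups donating one hydrogen bond
#' per N-H to three carbonyls, and `hb` neutral amide-to-carbonyl hydrogen
#' bonds. Contacts are placed with at least 0.25 angstrom margin to the
#' default detection thresholds, so a positional jitter of amplitude
#' `noise_A` up to 0.05 angstrom preserves the prescribed census.
#'
#' @param sb Number of salt bridges.
#' @param shb Integer vector (length `sb`, recycled from a scalar) of
#'   salt-bridge hydrogen bonds per bridge, each 0-2.
#' @param ihb Number of ionized hydrogen bonds (single-donor units).
#' @param donate3 Number of triply donating ionized ammonium units (each
#'   adds 3 ionized hydrogen bonds).
#' @param hb Number of neutral hydrogen bonds.
#' @param noise_A Uniform positional jitter amplitude, angstrom.
#' @param seed Seed for the jitter.
#' @param peptide_id Identifier given to the synthetic peptide.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(sb = 0L, shb = 0L, ihb = 0L, donate3 = 0L,
                         hb = 0L, noise_A = 0, seed = 1L,
                         peptide_id = "FIX") {
  sb <- as.integer(sb)
  shb <- rep_len(as.integer(shb), max(sb, 1L))[seq_len(sb)]
  if (any(c(sb, ihb, donate3, hb) < 0L)) stopf("counts must be non-negative")
  if (sb > 0L && any(shb < 0L | shb > 2L)) {
    stopf("unrealizable prescription: shb per bridge must be 0, 1 or 2 (one per carboxylate oxygen)")
  }
  if (noise_A < 0 || noise_A > 0.05) {
    stopf("noise_A must be in [0, 0.05] to preserve prescribed contacts")
  }
  structure(list(sb = sb, shb = shb, ihb = as.integer(ihb),
                 donate3 = as.integer(donate3), hb = as.integer(hb),
                 noise_A = noise_A, seed = as.integer(seed),
                 peptide_id = peptide_id),
            class = "fixture_spec")
}

# One residue worth of atoms at given positions (matrix with rownames =
# atom names), all shifted by `origin`.
fixture_residue <- function(resid, elety_xyz, origin) {
  xyz <- sweep(elety_xyz, 2, origin, "+")
  elety <- rownames(elety_xyz)
  data.frame(elety = elety, resid = resid, resno = NA_integer_,
             element = substr(elety, 1, 1),
             x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
             stringsAsFactors = FALSE)
}

mat3 <- function(...) {
  m <- rbind(...)
  colnames(m) <- c("x", "y", "z")
  m
}

# Ideal ionized ammonium (lysine-like) template: N-H bonds 1.0 A, roughly
# tetrahedral, pointing +x, (+x rotated 110 deg in xy), and up-z.
LYS_TEMPLATE <- mat3(
  NZ = c(0, 0, 0), HZ1 = c(1, 0, 0), HZ2 = c(-0.333, 0.943, 0),
  HZ3 = c(-0.333, -0.471, 0.816), CE = c(-0.6, -0.85, -1.47),
  CA = c(-1.8, -0.85, -1.47))
H_DIRS <- rbind(c(1, 0, 0), c(-0.333, 0.943, 0), c(-0.333, -0.471, 0.816))

#' Build a synthetic conformer realizing a fixture specification
#'
#' Atoms are placed so that [classify_interactions()] at default criteria
#' recovers exactly the prescribed census; the construction is deterministic
#' given the seed. Interaction units are separated by 25 angstrom so they
#' cannot interact with each other. By default the census is verified
#' against the prescription before the conformer is returned.
#'
#' @param spec A [fixture_spec()].
#' @param check Verify the realized census against the prescription
#'   (default `TRUE`).
#' @return A `conformer`; its attribute `prescribed` carries the requested
#'   `(SB, sHB, iHB, HB)` counts.
#' @export
build_conformer <- function(spec, check = TRUE) {
  stopifnot(inherits(spec, "fixture_spec"))
  residues <- list()   # list of (resid, seq_letter, site_kind, atoms)
  add_residue <- function(resid, letter, ion, atoms) {
    residues[[length(residues) + 1L]] <<-
      list(resid = resid, letter = letter, ion = ion, atoms = atoms)
  }
  unit_origin <- function(k) c(25 * (k - 1), 0, 0)
  k <- 0L

  for (i in seq_len(spec$sb)) {
    k <- k + 1L; o <- unit_origin(k); s <- spec$shb[i]
    add_residue("LYS", "K", "+", fixture_residue("LYS", LYS_TEMPLATE, o))
    asp <- if (s == 2L) {
      mat3(OD1 = c(2.9, 0, 0), OD2 = 2.9 * H_DIRS[2, ],
           CG = c(1.0, 1.4, 0), CA = c(1.0, 1.4, 1.5))
    } else if (s == 1L) {
      mat3(OD1 = c(2.9, 0, 0), OD2 = c(3.9, 1.9, 0),
           CG = c(3.4, 0.95, 0), CA = c(3.4, 0.95, 1.5))
    } else {
      # bridge without hydrogen bonds: O...N at 3.75 A, off every N-H axis
      mat3(OD1 = c(0, 0, -3.75), OD2 = c(1.0, 0, -4.3),
           CG = c(0.5, 0, -4.8), CA = c(0.5, 1.5, -4.8))
    }
    add_residue("ASP", "D", "-", fixture_residue("ASP", asp, o))
  }
  for (i in seq_len(spec$ihb)) {
    k <- k + 1L; o <- unit_origin(k)
    add_residue("LYS", "K", "+", fixture_residue("LYS", LYS_TEMPLATE, o))
    gly <- mat3(O = c(2.9, 0, 0), C = c(4.13, 0, 0), CA = c(4.8, 1.1, 0),
                N = c(6.8, 0, 0), H = c(7.8, 0, 0))
    add_residue("GLY", "G", NA, fixture_residue("GLY", gly, o))
  }
  for (i in seq_len(spec$donate3)) {
    k <- k + 1L; o <- unit_origin(k)
    add_residue("LYS", "K", "+", fixture_residue("LYS", LYS_TEMPLATE, o))
    for (j in 1:3) {
      gly <- mat3(O = 2.9 * H_DIRS[j, ], C = 4.13 * H_DIRS[j, ],
                  CA = 4.13 * H_DIRS[j, ] + c(0, 0, -1.5))
      add_residue("GLY", "G", NA, fixture_residue("GLY", gly, o))
    }
  }
  for (i in seq_len(spec$hb)) {
    k <- k + 1L; o <- unit_origin(k)
    donor <- mat3(N = c(0, 0, 0), H = c(1, 0, 0), CA = c(-0.7, -1.2, 0))
    accep <- mat3(O = c(2.9, 0, 0), C = c(4.13, 0, 0), CA = c(4.8, 1.1, 0))
    add_residue("GLY", "G", NA, fixture_residue("GLY", donor, o))
    add_residue("GLY", "G", NA, fixture_residue("GLY", accep, o))
  }
  if (length(residues) == 0L) {
    # degenerate all-zero fixture: one lone glycine
    add_residue("GLY", "G", NA,
                fixture_residue("GLY", mat3(CA = c(0, 0, 0), C = c(1.5, 0, 0),
                                            O = c(2.1, 1.0, 0)), c(0, 0, 0)))
  }

  atoms <- do.call(rbind, lapply(seq_along(residues), function(i) {
    a <- residues[[i]]$atoms
    a$resno <- i
    a
  }))
  rownames(atoms) <- NULL
  if (spec$noise_A > 0) {
    atoms[, c("x", "y", "z")] <- with_seed(spec$seed, {
      atoms[, c("x", "y", "z")] +
        matrix(stats::runif(3 * nrow(atoms), -spec$noise_A, spec$noise_A),
               ncol = 3)
    })
  }

  seqc <- paste(vapply(residues, function(r) r$letter, ""), collapse = "")
  sites <- list()
  assignment <- character(0)
  for (i in seq_along(residues)) {
    r <- residues[[i]]
    if (is.na(r$ion)) next
    if (r$ion == "+") {
      s <- site_basic("LYS", i)
      assignment[s$site_id] <- "+"
    } else {
      s <- site_acidic("ASP", i)
      assignment[s$site_id] <- "-"
    }
    sites[[length(sites) + 1L]] <- s
  }
  pep <- peptide_definition(spec$peptide_id, seqc, sites,
                            charge_states = sum(assignment == "+") -
                              sum(assignment == "-"))
  pr <- if (length(sites)) protomer(pep, assignment) else {
    structure(list(peptide_id = pep$peptide_id,
                   assignment = character(0), charges = integer(0),
                   site_types = character(0), site_kinds = character(0),
                   net_charge = 0L), class = "protomer")
  }
  conf <- conformer(pep, pr, atoms)
  prescribed <- c(SB = spec$sb, sHB = sum(spec$shb),
                  iHB = spec$ihb + 3L * spec$donate3, HB = spec$hb)
  if (check) {
    cen <- classify_interactions(conf)
    got <- c(SB = cen$SB, sHB = cen$sHB, iHB = cen$iHB, HB = cen$HB)
    if (!identical(unname(got), unname(as.integer(prescribed)))) {
      stopf("fixture failed verification: prescribed (%s), realized (%s)",
            paste(prescribed, collapse = ","), paste(got, collapse = ","))
    }
  }
  attr(conf, "prescribed") <- prescribed
  conf
}

#' Specify a mock per-protomer energy landscape
#'
#' Emulates the energy time series of independent high-temperature MD runs,
#' one per protomer: each series is a protomer-specific energy floor plus
#' smooth, strictly non-negative seeded noise (half a scaled squared AR(1)
#' process with autocorrelation time `tau_ps`). For long durations the
#' series minimum approaches the floor.
#'
#' @param floors Named numeric vector: energy floor (kJ/mol) per protomer
#'   pattern.
#' @param roughness Noise amplitude scale, kJ/mol.
#' @param tau_ps Autocorrelation time, ps.
#' @param duration_ns Trajectory length, ns.
#' @param interval_ps Sampling interval, ps.
#' @param seed Seed for the noise.
#' @return An object of class `landscape_spec`.
#' @export
landscape_spec <- function(floors, roughness = 50, tau_ps = 2,
                           duration_ns = 8, interval_ps = 0.5, seed = 1L) {
  if (is.null(names(floors)) || any(!nzchar(names(floors)))) {
    stopf("floors must be a named vector (protomer patterns)")
  }
  if (any(!is.finite(floors))) stopf("floors must be finite")
  if (duration_ns <= 0 || interval_ps <= 0 ||
      interval_ps > duration_ns * 1000) {
    stopf("inconsistent duration/interval")
  }
  if (roughness < 0 || tau_ps <= 0) stopf("invalid roughness or tau_ps")
  structure(list(floors = floors, roughness = roughness, tau_ps = tau_ps,
                 duration_ns = duration_ns, interval_ps = interval_ps,
                 seed = as.integer(seed)),
            class = "landscape_spec")
}

#' Generate a mock energy trajectory from a landscape specification
#'
#' @param spec A [landscape_spec()].
#' @return Energy records: a data frame with columns `conformer_id`,
#'   `protomer`, `time_ps`, `energy`, `level` (`"forcefield"`),
#'   bit-identical for a fixed seed.
#' @export
build_landscape <- function(spec) {
  stopifnot(inherits(spec, "landscape_spec"))
  n <- floor(spec$duration_ns * 1000 / spec$interval_ps)
  times <- (seq_len(n) - 1L) * spec$interval_ps
  rho <- exp(-spec$interval_ps / spec$tau_ps)
  with_seed(spec$seed, {
    out <- lapply(seq_along(spec$floors), function(i) {
      x <- numeric(n)
      x[1] <- stats::rnorm(1)
      innov <- stats::rnorm(n - 1)
      for (t in seq_len(n - 1L)) {
        x[t + 1L] <- rho * x[t] + sqrt(1 - rho^2) * innov[t]
      }
      data.frame(
        conformer_id = sprintf("p%d_%06d", i, seq_len(n)),
        protomer = names(spec$floors)[i],
        time_ps = times,
        energy = spec$floors[[i]] + spec$roughness * x^2 / 2,
        level = "forcefield",
        stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
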