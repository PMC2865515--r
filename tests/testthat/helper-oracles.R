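# Independent brute-force oracles and small generators used across tests.

# Closed-form protomer count for b ungated single-tautomer basic sites and
# a acidic sites at net charge z.
closed_form_count <- function(b, a, z) {
  ks <- 0:b
  sum(vapply(ks, function(k) {
    j <- k - z
    if (j < 0 || j > a) 0 else choose(b, k) * choose(a, j)
  }, 0))
}

# A peptide with b generic basic sites and a generic acidic sites on a
# poly-K/poly-D sequence (no gating, no tautomers).
generic_peptide <- function(b, a) {
  seqc <- paste0(strrep("K", b), strrep("D", a))
  sites <- c(
    lapply(seq_len(b), function(i) protomerscan:::site_basic("LYS", i)),
    lapply(seq_len(a), function(i) protomerscan:::site_acidic("ASP", b + i)))
  peptide_definition(paste0("G", b, a), seqc, sites,
                     charge_states = (-a):b)
}

# Direct, independent evaluation of the additive separation penalty.
oracle_penalty <- function(p, values) {
  tot <- 0
  for (id in names(p$charges)) {
    ch <- p$charges[[id]]
    if (ch == 0L) next
    v <- values[[p$site_types[[id]]]]
    tot <- tot + if (ch < 0) v else -v
  }
  tot
}

# Exhaustive all-triples hydrogen-bond scan, written independently of the
# package implementation (plain nested loops, explicit formulas).
oracle_hbonds <- function(atoms, d_max = 3.5, angle_min = 120,
                          exclude_intra = TRUE) {
  n <- nrow(atoms)
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  dist2 <- function(i, j) sum((xyz[i, ] - xyz[j, ])^2)
  found <- character(0)
  for (h in seq_len(n)) {
    if (atoms$element[h] != "H") next
    # covalent parent: nearest N/O within 1.3 A
    best <- NA_integer_; bestd <- Inf
    for (d in seq_len(n)) {
      if (!(atoms$element[d] %in% c("N", "O"))) next
      dd <- sqrt(dist2(h, d))
      if (dd < bestd) { bestd <- dd; best <- d }
    }
    if (is.na(best) || bestd > 1.3) next
    d <- best
    for (a in seq_len(n)) {
      if (a == d || !(atoms$element[a] %in% c("N", "O"))) next
      if (exclude_intra && atoms$resno[a] == atoms$resno[d]) next
      if (sqrt(dist2(d, a)) > d_max) next
      v1 <- xyz[d, ] - xyz[h, ]
      v2 <- xyz[a, ] - xyz[h, ]
      ct <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
      ang <- acos(min(1, max(-1, ct))) * 180 / pi
      if (ang >= angle_min) found <- c(found, paste(d, h, a))
    }
  }
  sort(found)
}

# Random atom cloud wrapped into a site-less conformer.
random_cloud_conformer <- function(n_atoms, seed, box = 8) {
  set.seed(seed)
  elements <- sample(c("N", "O", "C", "H"), n_atoms, replace = TRUE,
                     prob = c(0.2, 0.2, 0.25, 0.35))
  atoms <- data.frame(
    elety = paste0(elements, seq_len(n_atoms)),
    resid = "GLY",
    resno = sample.int(max(2L, n_atoms %/% 5L), n_atoms, replace = TRUE),
    element = elements,
    x = runif(n_atoms, 0, box), y = runif(n_atoms, 0, box),
    z = runif(n_atoms, 0, box),
    stringsAsFactors = FALSE)
  empty_protomer <- structure(
    list(peptide_id = "CLOUD", assignment = character(0),
         charges = integer(0), site_types = character(0),
         site_kinds = character(0), net_charge = 0L),
    class = "protomer")
  pep <- peptide_definition("CLOUD", "G", list(), 0)
  conformer(pep, empty_protomer, atoms)
}

# Random rigid motion (proper rotation + translation).
apply_rigid_motion <- function(conf, seed) {
  set.seed(seed)
  th <- runif(3, 0, 2 * pi)
  Rx <- rbind(c(1, 0, 0), c(0, cos(th[1]), -sin(th[1])),
              c(0, sin(th[1]), cos(th[1])))
  Ry <- rbind(c(cos(th[2]), 0, sin(th[2])), c(0, 1, 0),
              c(-sin(th[2]), 0, cos(th[2])))
  Rz <- rbind(c(cos(th[3]), -sin(th[3]), 0),
              c(sin(th[3]), cos(th[3]), 0), c(0, 0, 1))
  R <- Rx %*% Ry %*% Rz
  tr <- runif(3, -20, 20)
  xyz <- as.matrix(conf$atoms[, c("x", "y", "z")]) %*% t(R)
  conf$atoms$x <- xyz[, 1] + tr[1]
  conf$atoms$y <- xyz[, 2] + tr[2]
  conf$atoms$z <- xyz[, 3] + tr[3]
  conf
}

# Canonical key set of a detected hbond table, for oracle comparison.
hbond_keys <- function(hb) sort(paste(hb$d_idx, hb$h_idx, hb$a_idx))

# Energy records helper.
make_records <- function(energy, protomer = "p", time_ps = NULL,
                         level = "forcefield", id_prefix = "c") {
  data.frame(
    conformer_id = paste0(id_prefix, seq_along(energy)),
    protomer = rep_len(protomer, length(energy)),
    time_ps = if (is.null(time_ps)) seq_along(energy) - 1 else time_ps,
    energy = energy, level = level, stringsAsFactors = FALSE)
}
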