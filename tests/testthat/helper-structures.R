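# Shared hand-built structures and report inputs.

# One ionized Lys ammonium and one Asp carboxylate, with controllable
# O...N separation along x (collinear N-H...O geometry when reachable).
two_site_conformer <- function(d_ON, acid_state = "-") {
  atoms <- data.frame(
    elety = c("NZ", "HZ1", "HZ2", "HZ3", "CA",
              "OD1", "OD2", "CG", "CA"),
    resid = c(rep("LYS", 5), rep(if (acid_state == "-") "ASP" else "ASH", 4)),
    resno = c(rep(1L, 5), rep(2L, 4)),
    element = c("N", "H", "H", "H", "C", "O", "O", "C", "C"),
    x = c(0, 1, -0.333, -0.333, -1.5, d_ON, d_ON + 1, d_ON + 0.5, d_ON + 0.5),
    y = c(0, 0, 0.943, -0.471, 0, 0, 1.8, 0.9, 0.9),
    z = c(0, 0, 0, 0.816, -1, 0, 0, 0, 1.5),
    stringsAsFactors = FALSE)
  sites <- list(protomerscan:::site_basic("LYS", 1L),
                protomerscan:::site_acidic("ASP", 2L))
  pep <- peptide_definition("T", "KD", sites, 0)
  conformer(pep, protomer(pep, c(LYS1 = "+", ASP2 = acid_state)), atoms)
}

# Census stub carrying only the count fields the report layer reads.
stub_census <- function(IR = 0L, SB = 0L, sHB = 0L, iHB = 0L, HB = 0L) {
  structure(list(IR = IR, SB = SB, sHB = sHB, iHB = iHB, HB = HB,
                 per_group = data.frame(), Rg = 0,
                 hbonds = data.frame(), bridges = data.frame()),
            class = "interaction_census")
}

# Reconstructed neutral-bradykinin report inputs (ranking gaps and
# structural counts as a fixture, penalties computed by the package).
bk_fixture_inputs <- function() {
  bk <- bradykinin()
  z0 <- enumerate_protomers(bk, 0)
  pens <- penalty_report(z0, intrinsic_peptide_scale())
  dE <- c("0 + 0 -" = 0, "0 0 + -" = 10, "+ 0 0 -" = 49, "0 0 0 0" = 57)
  ranking <- data.frame(protomer = names(dE), min_energy = -1000 + dE,
                        dE = unname(dE), stringsAsFactors = FALSE)
  censuses <- list(
    "0 + 0 -" = stub_census(2L, 1L, 2L, 5L, 1L),
    "0 0 + -" = stub_census(2L, 1L, 2L, 4L, 3L),
    "+ 0 0 -" = stub_census(2L, 1L, 1L, 5L, 0L),
    "0 0 0 0" = stub_census(0L, 0L, 0L, 0L, 4L))
  list(bk = bk, ranking = ranking, pens = pens, censuses = censuses)
}
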