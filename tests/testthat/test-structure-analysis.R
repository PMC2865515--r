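test_that("hydrogen-bond detection honours the distance/angle criterion", {
  conf <- two_site_conformer(2.9)
  hb <- detect_hbonds(conf)
  expect_identical(nrow(hb), 1L)           # collinear N-H...O at 2.9 A
  expect_equal(hb$d_DA, 2.9, tolerance = 1e-9)
  expect_equal(hb$angle, 180, tolerance = 1e-6)
  # just past the cutoff: gone
  expect_identical(nrow(detect_hbonds(two_site_conformer(4.0))), 0L)
  # larger cutoff admits it again (monotonicity in d_max)
  expect_identical(nrow(detect_hbonds(two_site_conformer(4.0), d_max = 4.5)), 1L)
})

test_that("detection equals the exhaustive all-triples oracle on random clouds", {
  for (seed in 1:12) {
    n <- sample(50:200, 1)
    conf <- random_cloud_conformer(n, seed = seed)
    hb <- detect_hbonds(conf)
    expect_identical(hbond_keys(hb), oracle_hbonds(conf$atoms),
                     info = paste("seed", seed))
    # monotonicity: enlarging d_max never loses bonds
    hb_wide <- detect_hbonds(conf, d_max = 4.5)
    expect_true(all(hbond_keys(hb) %in% hbond_keys(hb_wide)))
  }
})

test_that("salt bridges require ionization and a strict 4.0 A cutoff", {
  expect_identical(nrow(detect_salt_bridges(two_site_conformer(3.9))), 1L)
  # same geometry, neutral acid: no bridge
  expect_identical(nrow(detect_salt_bridges(
    two_site_conformer(3.9, acid_state = "ASH"))), 0L)
  # O...N exactly 4.0 A: excluded (strict less-than)
  expect_identical(nrow(detect_salt_bridges(two_site_conformer(4.0))), 0L)
  expect_identical(nrow(detect_salt_bridges(two_site_conformer(3.9999999))), 1L)
  # shrinking the cutoff never adds bridges
  expect_identical(nrow(detect_salt_bridges(two_site_conformer(3.9),
                                            cutoff = 3.0)), 0L)
})

test_that("classification partitions hydrogen bonds with sHB > iHB > HB precedence", {
  conf <- build_conformer(fixture_spec(sb = 1, shb = 2, ihb = 1, hb = 2,
                                       seed = 1))
  cen <- classify_interactions(conf)
  expect_identical(c(cen$SB, cen$sHB, cen$iHB, cen$HB), c(1L, 2L, 1L, 2L))
  expect_identical(cen$sHB + cen$iHB + cen$HB, nrow(cen$hbonds))
  expect_true(all(cen$hbonds$klass %in% c("sHB", "iHB", "HB")))
  expect_lte(cen$SB, choose(cen$IR, 2))
  # all-neutral conformer: no ionized classes
  cen0 <- classify_interactions(build_conformer(fixture_spec(hb = 3, seed = 2)))
  expect_identical(c(cen0$IR, cen0$SB, cen0$sHB, cen0$iHB), c(0L, 0L, 0L, 0L))
  expect_identical(cen0$HB, 3L)
})

test_that("a protonated ammonium donating three hydrogen bonds is fully counted", {
  conf <- build_conformer(fixture_spec(donate3 = 1, seed = 4))
  cen <- classify_interactions(conf)
  expect_identical(cen$iHB, 3L)
  don <- cen$per_group$donated[cen$per_group$site_id == "LYS1"]
  expect_identical(don, 3L)
})

test_that("the census is invariant under rigid motions", {
  conf <- build_conformer(fixture_spec(sb = 2, shb = c(1, 2), ihb = 2,
                                       hb = 1, seed = 5))
  cen <- classify_interactions(conf)
  for (seed in 1:5) {
    conf2 <- apply_rigid_motion(conf, seed)
    cen2 <- classify_interactions(conf2)
    expect_identical(c(cen2$IR, cen2$SB, cen2$sHB, cen2$iHB, cen2$HB),
                     c(cen$IR, cen$SB, cen$sHB, cen$iHB, cen$HB))
    expect_equal(cen2$Rg, cen$Rg, tolerance = 1e-6)
    expect_equal(cen2$hbonds$d_DA, cen$hbonds$d_DA, tolerance = 1e-6)
    expect_equal(cen2$hbonds$angle, cen$hbonds$angle, tolerance = 1e-6)
  }
})

test_that("radius of gyration matches the mass-weighted formula", {
  pep <- peptide_definition("X", "G", list(), 0)
  pr <- structure(list(peptide_id = "X", assignment = character(0),
                       charges = integer(0), site_types = character(0),
                       site_kinds = character(0), net_charge = 0L),
                  class = "protomer")
  one <- conformer(pep, pr, data.frame(
    elety = "CA", resid = "GLY", resno = 1L, element = "C",
    x = 3, y = -2, z = 7, stringsAsFactors = FALSE))
  expect_equal(radius_of_gyration(one), 0)
  two <- conformer(pep, pr, data.frame(
    elety = c("CA", "CA"), resid = "GLY", resno = 1:2, element = "C",
    x = c(0, 2), y = 0, z = 0, stringsAsFactors = FALSE))
  expect_equal(radius_of_gyration(two), 1)
  set.seed(9)
  n <- 80
  atoms <- data.frame(elety = "CA", resid = "GLY", resno = seq_len(n),
                      element = sample(c("C", "N", "O", "H"), n, TRUE),
                      x = rnorm(n), y = rnorm(n), z = rnorm(n),
                      stringsAsFactors = FALSE)
  conf <- conformer(pep, pr, atoms)
  m <- conf$atoms$mass
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  com <- colSums(xyz * m) / sum(m)
  direct <- sqrt(sum(m * ((xyz[, 1] - com[1])^2 + (xyz[, 2] - com[2])^2 +
                            (xyz[, 3] - com[3])^2)) / sum(m))
  expect_equal(radius_of_gyration(conf), direct, tolerance = 1e-9)
})

test_that("donor groups without hydrogens are skipped with a QC record", {
  conf <- two_site_conformer(2.9)
  conf$atoms <- conf$atoms[conf$atoms$element != "H", ]
  expect_warning(hb <- detect_hbonds(conf), "without hydrogens")
  expect_identical(nrow(hb), 0L)
  qc <- attr(hb, "qc")
  expect_identical(qc$site_id, "LYS1")
})

test_that("PDB round trips preserve the census and inferred protomer", {
  conf <- build_conformer(fixture_spec(sb = 1, shb = 1, ihb = 1, hb = 1,
                                       seed = 6))
  path <- withr::local_tempfile(fileext = ".pdb")
  write_conformer_pdb(conf, path)
  back <- read_conformer_pdb(path, conf$peptide)
  expect_identical(back$protomer$assignment, conf$protomer$assignment)
  cen <- classify_interactions(conf)
  cen2 <- classify_interactions(back)
  expect_identical(c(cen2$SB, cen2$sHB, cen2$iHB, cen2$HB),
                   c(cen$SB, cen$sHB, cen$iHB, cen$HB))
  # explicit sidecar overrides inference
  sc <- withr::local_tempfile(fileext = ".tsv")
  write.table(data.frame(site_id = names(conf$protomer$assignment),
                         state_label = c("0", "ASH", "0")),
              sc, sep = "\t", quote = FALSE, row.names = FALSE)
  neutral <- read_conformer_pdb(path, conf$peptide, sidecar = sc)
  expect_identical(count_ionized(neutral$protomer), 0L)
})
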