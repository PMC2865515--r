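scale_tab <- intrinsic_peptide_scale()

test_that("separation penalty is the acid-base basicity gap", {
  # single acid/base pair: GA 1394, GPB 1026 -> 368
  pep <- generic_peptide(1, 1)
  vals <- c(LYS_side = 1026, ASP_side = 1394)
  p <- parse_pattern(pep, "+ -")
  expect_equal(as.numeric(separation_penalty(p, vals)), 1394 - 1026)
  expect_equal(as.numeric(separation_penalty(parse_pattern(pep, "0 ASH"),
                                             vals)), 0)
  expect_error(separation_penalty(p, c(LYS_side = 1026)), "ASP2")
})

test_that("penalty is additive over independent acid/base pairs", {
  pep <- generic_peptide(2, 2)
  set.seed(42)
  for (rep in 1:20) {
    vals <- c(LYS_side = runif(1, 800, 1100), ASP_side = runif(1, 1200, 1500))
    pair1 <- as.numeric(separation_penalty(parse_pattern(pep, "+ 0 - ASH"), vals))
    pair2 <- as.numeric(separation_penalty(parse_pattern(pep, "0 + ASH -"), vals))
    both <- as.numeric(separation_penalty(parse_pattern(pep, "+ + - -"), vals))
    expect_equal(both, pair1 + pair2)
  }
  # brute-force decomposition on the packaged systems
  for (pep2 in packaged_systems()) {
    vals <- stats::setNames(runif(nrow(scale_tab), 800, 1500),
                            scale_tab$site_type)
    for (z in pep2$charge_states) {
      for (p in enumerate_protomers(pep2, z)) {
        expect_equal(as.numeric(separation_penalty(p, vals)),
                     oracle_penalty(p, vals))
      }
    }
  }
})

test_that("normalization references the lowest-separation protomer, ties at zero", {
  bk <- bradykinin()
  z1 <- normalize_penalties(enumerate_protomers(bk, 1), scale_tab, "GPB")
  # the two single-Arg protomers share the reference
  expect_equal(z1$relative[z1$pattern == "0 + 0 0"], 0)
  expect_equal(z1$relative[z1$pattern == "0 0 + 0"], 0)
  expect_true(all(z1$relative >= 0))
  expect_equal(sum(z1$relative == 0), 2L)
  # idempotence: re-normalizing relative penalties changes nothing
  expect_equal(z1$relative - min(z1$relative), z1$relative)
  expect_error(normalize_penalties(list(), scale_tab), "empty")
  expect_error(normalize_penalties(unlist(lapply(0:1, function(z)
    enumerate_protomers(bk, z)), recursive = FALSE), scale_tab),
    "share one net charge")
})

test_that("frozen relative-GPB column of the bradykinin table is reproduced", {
  bk <- bradykinin()
  printed <- list(
    "0" = c("0 + 0 -" = 368, "0 0 + -" = 368, "+ 0 0 -" = 540,
            "0 0 0 0" = 0),
    "1" = c("0 + + -" = 368, "0 + 0 0" = 0, "0 0 + 0" = 0,
            "+ 0 + -" = 540, "+ + 0 -" = 540, "+ 0 0 0" = 172),
    "2" = c("+ + + -" = 540, "0 + + 0" = 0, "+ + 0 0" = 172,
            "+ 0 + 0" = 172))
  for (z in names(printed)) {
    tab <- normalize_penalties(enumerate_protomers(bk, as.integer(z)),
                               scale_tab, "GPB")
    got <- stats::setNames(tab$relative, tab$pattern)
    expect_equal(got[names(printed[[z]])], printed[[z]],
                 tolerance = 1e-9, info = paste("z =", z))
  }
})

test_that("four-ion zwitterions of the larger systems get their printed penalties", {
  an <- angiotensin_ii()
  rep_an <- penalty_report(enumerate_protomers(an, 0), scale_tab)
  expect_equal(rep_an$dGPB[rep_an$pattern == "0 - + HIP -"], 725)
  expect_equal(rep_an$ddU[rep_an$pattern == "0 - + HIP -"], 732)
  expect_equal(rep_an$dPA[rep_an$pattern == "0 - + HIP -"], 756)
  expect_equal(rep_an$dGPB[rep_an$pattern == "+ - 0 HIP -"], 897)
  expect_equal(rep_an$dGPB[rep_an$pattern == "+ - + HID -"], 842)
  expect_equal(rep_an$dGPB[rep_an$pattern == "+ - + HIE -"], 842)

  tc <- trp_cage()
  tz0 <- normalize_penalties(enumerate_protomers(tc, 0), scale_tab, "GPB")
  got <- stats::setNames(tz0$relative, tz0$pattern)
  expect_equal(got[["+ 0 0 - + -"]], 842)
  expect_equal(got[["+ 0 + - 0 -"]], 890)
  expect_equal(got[["0 0 + - + -"]], 718)
  tz2 <- normalize_penalties(enumerate_protomers(tc, 2), scale_tab, "GPB")
  got2 <- stats::setNames(tz2$relative, tz2$pattern)
  expect_equal(got2[["+ + + - + -"]], 949)
  expect_equal(got2[["+ + + ASH 0 -"]], 647)
  expect_equal(got2[["+ 0 + ASH + -"]], 540)
})

test_that("uniform shifts of the scale move relatives only through ion counts", {
  bk <- bradykinin()
  z2 <- enumerate_protomers(bk, 2)
  vals <- stats::setNames(scale_tab$GPB, scale_tab$site_type)
  base <- normalize_penalties(z2, vals, "GPB")$relative
  # shifting acids and bases together: raw shift is -c*z, constant in a
  # fixed-z set, so relatives are invariant even with unequal ion counts
  shifted_all <- vals + 100
  expect_equal(normalize_penalties(z2, shifted_all, "GPB")$relative, base)
  # shifting bases only changes relatives between protomers with unequal
  # numbers of ionized bases (IR 2 vs 4 here)
  shifted_bases <- vals
  basics <- c("NTER_amine", "ARG_side", "LYS_side", "HIS_side", "GLN_side")
  shifted_bases[basics] <- shifted_bases[basics] + 100
  rel2 <- normalize_penalties(z2, shifted_bases, "GPB")$relative
  expect_false(isTRUE(all.equal(rel2, base)))
})

test_that("anchor calibration recovers pair offsets and round-trips", {
  bk <- bradykinin()
  rows <- packaged_anchor_rows()
  fit <- calibrate_anchors(anchor_calibration_rows(bk,
                                                   rows[rows$peptide == "BK", ]))
  expect_equal(max(abs(residuals(fit))), 0, tolerance = 1e-9)
  # offsets imply GPB(Arg) - GPB(N-ter) = 540 - 368 = 172
  co <- coef(fit)
  expect_equal(co[["ARG_side"]] - co[["NTER_amine"]], 172)
  # single row: that pair's offset exactly, residual 0
  f1 <- calibrate_anchors(anchor_calibration_rows(bk, rows[1, ]))
  expect_equal(as.numeric(residuals(f1)), 0)
  expect_equal(coef(f1)[["CTER_carboxyl"]] - coef(f1)[["ARG_side"]], 368)
})

test_that("calibration on generated columns recovers the model up to gauge", {
  tc <- trp_cage()
  set.seed(7)
  acid_types <- c("CTER_carboxyl", "ASP_side", "GLU_side")
  for (rep in 1:5) {
    # acids above bases so every pair penalty is positive and the z = 0
    # reference is the all-neutral protomer, as the rows assume
    vals <- stats::setNames(
      ifelse(scale_tab$site_type %in% acid_types,
             runif(nrow(scale_tab), 1250, 1500),
             runif(nrow(scale_tab), 800, 1100)),
      scale_tab$site_type)
    z0 <- enumerate_protomers(tc, 0)
    col <- normalize_penalties(z0, vals, "GPB")
    rows <- lapply(seq_along(z0), function(i) {
      list(protomer = z0[[i]], relative_penalty = col$relative[i])
    })
    fit <- calibrate_anchors(rows)
    expect_lt(max(abs(residuals(fit))), 1e-8)
    # predictions transfer to a different charge state (z = +1 involves
    # the same site types as the calibration rows)
    z1 <- normalize_penalties(enumerate_protomers(tc, 1),
                              coef(fit), "GPB")$relative
    ref <- normalize_penalties(enumerate_protomers(tc, 1),
                               vals, "GPB")$relative
    expect_equal(z1, ref, tolerance = 1e-8)
  }
})

test_that("underdetermined calibration fails loudly", {
  bk <- bradykinin()
  # one row cannot separate three site types on one connected component
  rows <- list(list(protomer = parse_pattern(bk, "+ + 0 -"),
                    relative_penalty = 908))
  expect_error(calibrate_anchors(rows), "underdetermined")
})

test_that("conformational shifts reproduce the linear-minus-folded columns", {
  tab4 <- intrinsic_free_amino_acids()
  entry <- function(ty, ctx) tab4[tab4$site_type == ty & tab4$context == ctx, ]
  expect_equal(conformer_shift(entry("LYS_side", "folded"),
                               entry("LYS_side", "linear")),
               c(dU_shift = -63, PA_shift = -54, GPB_shift = -53))
  expect_equal(conformer_shift(entry("ARG_side", "folded"),
                               entry("ARG_side", "linear"))[["GPB_shift"]],
               -11)
  same <- entry("HIS_side", "folded")
  same2 <- same; same2$context <- "linear"
  expect_equal(unname(conformer_shift(same, same2)), c(0, 0, 0))
  expect_error(conformer_shift(entry("LYS_side", "linear"),
                               entry("LYS_side", "folded")), "context")
  expect_error(conformer_shift(entry("LYS_side", "folded"),
                               entry("ARG_side", "linear")), "mismatch")
})

test_that("entropic dispersion matches a direct computation and stays small", {
  tab4 <- intrinsic_free_amino_acids()
  disp <- entropic_dispersion(tab4)
  x <- tab4$GPB - tab4$PA
  n <- length(x)
  expect_equal(disp[["sample"]], sqrt(sum((x - mean(x))^2) / (n - 1)))
  expect_equal(disp[["population"]], sqrt(sum((x - mean(x))^2) / n))
  expect_lt(disp[["sample"]], 6)
  expect_lt(disp[["population"]], 6)
  const <- data.frame(GPB = c(10, 20, 30), PA = c(5, 15, 25))
  expect_equal(unname(entropic_dispersion(const)), c(0, 0))
  expect_error(entropic_dispersion(tab4[1, ]), "at least two")
  set.seed(3)
  rnd <- data.frame(GPB = rnorm(50, 1000, 30), PA = rnorm(50, 990, 30))
  d <- rnd$GPB - rnd$PA
  expect_equal(entropic_dispersion(rnd)[["sample"]], sd(d))
})
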