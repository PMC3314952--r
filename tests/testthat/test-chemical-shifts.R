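test_that("NMR-STAR reader maps atoms onto the nucleus vocabulary", {
  path <- system.file("extdata", "synthetic_shifts.str", package = "ucoil")
  expect_message(tab <- read_nmrstar_shifts(path), "outside the backbone nucleus")
  expect_s3_class(tab, "shift_table")
  expect_equal(nrow(tab), 8L)   # the CG row is outside the vocabulary
  expect_setequal(unique(tab$nucleus), c("CA", "CB", "CO", "HA", "N", "HN"))
  expect_equal(tab$shift_ppm[tab$index == 2 & tab$nucleus == "CO"], 176.55)
  expect_equal(tab$residue[tab$index == 1][1], "M")
})

test_that("NMR-STAR reader rejects duplicates and files without a shift loop", {
  dup <- tempfile(fileext = ".str")
  writeLines(c("data_x", "loop_",
               "_Atom_chem_shift.ID", "_Atom_chem_shift.Seq_ID",
               "_Atom_chem_shift.Comp_ID", "_Atom_chem_shift.Atom_ID",
               "_Atom_chem_shift.Val",
               "1 5 ALA CA 52.1", "2 5 ALA CA 52.3", "stop_"), dup)
  expect_error(read_nmrstar_shifts(dup), "duplicate shift for residue 5")

  empty <- tempfile(fileext = ".str")
  writeLines(c("data_y", "loop_", "_Other.Tag", "1", "stop_"), empty)
  expect_error(read_nmrstar_shifts(empty), "no assigned-chemical-shift loop")
})

test_that("random-coil prediction equals base values for zeroed corrections", {
  seq <- protein_sequence(strrep("L", 10))
  ref <- random_coil_reference()
  rc <- random_coil_shifts(seq, ref)
  base_ca <- ref$base$shift_ppm[ref$base$residue == "L" & ref$base$nucleus == "CA"]
  expect_true(all(rc$shift_ppm[rc$nucleus == "CA"] == base_ca))

  # zero temperature coefficients: prediction independent of T
  rc_hot <- random_coil_shifts(seq, ref, temperature_K = 310)
  expect_equal(rc$shift_ppm, rc_hot$shift_ppm)

  # nonzero coefficient shifts every value linearly
  ref_t <- ref
  ref_t$temp_coef$coef_ppm_per_K[ref_t$temp_coef$nucleus == "CA"] <- 0.01
  rc_t <- random_coil_shifts(seq, ref_t, temperature_K = ref$t_ref + 10)
  expect_equal(rc_t$shift_ppm[rc_t$nucleus == "CA"],
               rc$shift_ppm[rc$nucleus == "CA"] + 0.1)
})

test_that("a neighbour flip changes predictions only within two positions", {
  ref <- random_coil_reference(
    neighbor = tibble::tibble(nucleus = "CA", offset = c(-2L, -1L, 1L, 2L),
                              neighbor = "W", delta_ppm = c(0.05, 0.2, 0.3, 0.1)))
  res <- strsplit(strrep("L", 15), "")[[1]]
  seq1 <- protein_sequence(res)
  res[8] <- "W"
  seq2 <- protein_sequence(res)
  d <- secondary_shifts(random_coil_shifts(seq2, ref),
                        random_coil_shifts(seq1, ref))
  changed <- d$index[d$nucleus == "CA" & abs(d$delta_ppm) > 1e-12]
  expect_true(all(abs(changed - 8) <= 2))
  # position 8 itself changes through the base table (W vs L), neighbours
  # through the correction terms
  expect_setequal(changed, 6:10)
})

test_that("secondary shifts are zero on a round trip and shift with the input", {
  seq <- im7_sequence()
  rc <- random_coil_shifts(seq)
  expect_true(all(secondary_shifts(rc, rc)$delta_ppm == 0))

  obs <- rc
  obs$shift_ppm[obs$nucleus == "CA"] <- obs$shift_ppm[obs$nucleus == "CA"] + 0.5
  d <- secondary_shifts(obs, rc)
  expect_true(all(d$delta_ppm[d$nucleus == "CA"] == 0.5))
  expect_true(all(d$delta_ppm[d$nucleus != "CA"] == 0))
})

test_that("simulated helix regions give positive CA secondary shifts only there", {
  seq <- im7_sequence(c("L18A", "L19A", "L37A"))
  sim <- simulate_shift_dataset(seq, fractions = data.frame(start = 31, end = 45,
                                                            fraction = 1))
  d <- secondary_shifts(sim, random_coil_shifts(seq))
  ca <- d[d$nucleus == "CA", ]
  expect_true(all(abs(ca$delta_ppm[ca$index >= 31 & ca$index <= 45] - 2.6) < 1e-9))
  expect_true(all(ca$delta_ppm[ca$index < 31 | ca$index > 45] == 0))
})

test_that("denaturant-difference shifts cancel the reference and are antisymmetric", {
  seq <- im7_sequence()
  a <- simulate_shift_dataset(seq, seed = 1)
  expect_true(all(urea_difference_shifts(a, a)$delta_ppm == 0))

  b <- simulate_shift_dataset(seq, fractions = data.frame(start = 12, end = 25,
                                                          fraction = 0.12))
  d_ab <- urea_difference_shifts(b, a)
  d_ba <- urea_difference_shifts(a, b)
  expect_equal(d_ab$delta_ppm, -d_ba$delta_ppm)
  ca <- d_ab[d_ab$nucleus == "CA", ]
  expect_true(all(ca$delta_ppm[ca$index >= 12 & ca$index <= 25] > 0))
  expect_false(any(ca$atypical))  # fractional helicity stays within 1 ppm
})

test_that("SSP scores scale with the injected fraction and stay in [-1, 1]", {
  seq <- protein_sequence(strrep("L", 31))
  rc <- random_coil_shifts(seq)

  zero <- ssp_profile(secondary_shifts(rc, rc))
  expect_true(all(zero$ssp[!is.na(zero$ssp)] == 0))

  for (f in c(1, 0.15)) {
    sim <- simulate_shift_dataset(seq, fractions = data.frame(start = 1, end = 31,
                                                              fraction = f))
    ssp <- ssp_profile(secondary_shifts(sim, rc))
    expect_equal(ssp$ssp[16], f, tolerance = 1e-9)
  }

  expect_true(all(abs(ssp_profile(secondary_shifts(rc, rc))$ssp) <= 1,
                  na.rm = TRUE))
})

test_that("SSP is invariant under translation along the sequence", {
  d <- tibble::tibble(index = rep(1:20, each = 2),
                      residue = "L",
                      nucleus = rep(c("CA", "CB"), 20),
                      delta_ppm = rep(c(0.9, -0.4), 20))
  s1 <- ssp_profile(d)
  d2 <- d
  d2$index <- d2$index + 100L
  s2 <- ssp_profile(d2)
  expect_equal(s1$ssp, s2$ssp)
})

test_that("region helicity averages SSP scores as percent helix", {
  ssp <- tibble::tibble(index = 1:87, ssp = 0, n_shifts = 2L)
  ssp$ssp[65:79] <- 0.163
  reg <- region_helicity(ssp)
  expect_equal(reg$helicity_pct[reg$region == "IV"], 16.3)
  expect_equal(reg$helicity_pct[reg$region == "I"], 0)
  expect_error(region_helicity(tibble::tibble(index = 1:5, ssp = 0.1)),
               "overlaps only")
})

test_that("injected region propensity is recovered within two percentage points", {
  seq <- im7_sequence(c("L18A", "L19A", "L37A"))
  rc <- random_coil_shifts(seq)
  sim <- simulate_shift_dataset(seq,
                                fractions = data.frame(start = 12, end = 25,
                                                       fraction = 0.13),
                                noise = 0.05, seed = 11)
  ssp <- ssp_profile(secondary_shifts(sim, rc))
  reg <- region_helicity(ssp)
  expect_equal(reg$helicity_pct[reg$region == "I"], 13, tolerance = 2 / 13)
  expect_lt(abs(reg$helicity_pct[reg$region == "III"]), 2)
})
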