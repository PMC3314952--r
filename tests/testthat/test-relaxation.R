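test_that("intrinsic R2 matches the direct-summation oracle on small chains", {
  props <- residue_properties()
  # 5-mer of identical non-Ala/Gly residues, per-residue term normalised to 1
  rgL <- props$rg_A[props$residue == "L"]
  seqL <- protein_sequence("LLLLL")
  prof <- intrinsic_r2_profile(seqL, scale = 1 / rgL^3, properties = props)
  expect_equal(prof$rate[3], 4.2367, tolerance = 1e-4)
  expect_equal(prof$rate[1], 3.8345, tolerance = 1e-4)

  rgA <- props$rg_A[props$residue == "A"]
  seqA <- protein_sequence("AAAAA")
  profA <- intrinsic_r2_profile(seqA, scale = 1 / rgA^3, properties = props)
  expect_equal(profA$rate[3], 2.9488, tolerance = 1e-4)
})

test_that("intrinsic R2 is linear in the scale coefficient", {
  seq <- im7_sequence()
  expect_equal(intrinsic_r2_profile(seq, scale = 2)$rate,
               2 * intrinsic_r2_profile(seq, scale = 1)$rate)
})

test_that("vectorised baseline equals the naive double loop on random sequences", {
  set.seed(42)
  for (n in c(5, 30, 200)) {
    seq <- random_sequence(n)
    fast <- intrinsic_r2_profile(seq, scale = 0.05)$rate
    slow <- brute_force_r2(seq, scale = 0.05)
    expect_equal(fast, slow, tolerance = 1e-12)
  }
})

test_that("homopolymer baseline is palindromic and maximal at the centre", {
  prof <- intrinsic_r2_profile(protein_sequence(strrep("V", 21)))$rate
  expect_equal(prof, rev(prof))
  expect_equal(which.max(prof), 11L)
  expect_lt(prof[1], prof[11])
  expect_lt(prof[21], prof[11])
})

test_that("substituting by glycine never increases any baseline rate", {
  set.seed(7)
  seq <- random_sequence(50)
  base <- intrinsic_r2_profile(seq)$rate
  non_ag <- which(!seq$residue %in% c("A", "G"))
  for (pos in sample(non_ag, 5)) {
    res <- seq$residue
    res[pos] <- "G"
    mut <- intrinsic_r2_profile(protein_sequence(res))$rate
    expect_true(all(mut <= base + 1e-12))
  }
})

test_that("scale fitting recovers exact proportionality and resists outliers", {
  seq <- im7_sequence(c("L18A", "L19A", "L37A"))
  shape <- intrinsic_r2_profile(seq, scale = 1)
  obs <- tibble::tibble(index = shape$index, rate = shape$rate * 2.5)
  expect_equal(fit_scale_factor(obs, seq)$scale, 2.5, tolerance = 1e-12)

  obs_out <- obs
  obs_out$rate[40] <- obs_out$rate[40] * 5
  fitted <- fit_scale_factor(obs_out, seq)$scale
  # independent grid-search oracle over the L1 objective
  grid <- seq(2, 3, by = 1e-4)
  sh <- shape$rate[match(obs_out$index, shape$index)]
  loss <- vapply(grid, function(s) sum(abs(obs_out$rate - s * sh)), numeric(1))
  expect_equal(fitted, grid[which.min(loss)], tolerance = 2e-4)
  expect_equal(fitted, 2.5, tolerance = 0.01)

  expect_error(fit_scale_factor(obs[1, ], seq), "overlap")
})

test_that("exponential decay fitting round-trips the noiseless case", {
  t <- r2_delay_schedule()
  expect_length(t, 11L)
  expect_equal(range(t), c(1.60e-3, 191.6e-3))

  fit <- fit_exponential_decay(t, 10 * exp(-5 * t))
  expect_equal(fit$rate, 5, tolerance = 1e-6)
  expect_equal(fit$flag, "ok")

  flat <- fit_exponential_decay(t, rep(3, length(t)))
  expect_equal(flat$rate, 0, tolerance = 1e-6)
  expect_equal(flat$flag, "nonpositive_rate")

  expect_error(fit_exponential_decay(t[1:2], c(1, 0.5)), "3 time points")
})

test_that("decay-rate recovery is unbiased at 2% noise", {
  rates <- vapply(1:200, function(s) {
    sim <- simulate_decay_series(8, noise = 2, seed = s)  # i0 = 100 -> 2%
    fit_exponential_decay(sim$time_s, sim$intensity, noise = 2)$rate
  }, numeric(1))
  expect_equal(mean(rates), 8, tolerance = 0.01)
})

test_that("cluster detection flags constructed runs and nothing else", {
  idx <- 1:60
  base <- tibble::tibble(index = idx, rate = 2.0)
  obs <- base
  obs$rate[40:44] <- 4.0
  obs$err <- 0.5   # z = 2 -> threshold 1.0
  cl <- detect_clusters(obs, base, min_run = 3, z = 2)
  expect_equal(nrow(cl), 1L)
  expect_equal(cl$start, 40L)
  expect_equal(cl$end, 44L)
  expect_equal(cl$center, 42L)  # flat-top excess: middle of the plateau

  expect_equal(nrow(detect_clusters(base, base)), 0L)
  expect_error(detect_clusters(base, tibble::tibble(index = 100:120, rate = 1)),
               "share no residues")
})

test_that("runs broken by missing residues are not merged across the gap", {
  idx <- c(1:10, 21:30)   # coverage gap between 10 and 21
  base <- tibble::tibble(index = idx, rate = 1, err = 0.1)
  obs <- base
  obs$rate[idx %in% c(8:10, 21:23)] <- 3
  cl <- detect_clusters(obs, base, min_run = 3, z = 2)
  expect_equal(nrow(cl), 2L)
  expect_equal(cl$start, c(8L, 21L))
})

test_that("heteronuclear NOE ratios propagate noise and flag the rigid limit", {
  rec <- het_noe(0.29, 1.0, noise_sat = 0.01, noise_ref = 0.02)
  expect_equal(rec$noe, 0.29)
  expect_equal(rec$err, 0.29 * sqrt((0.01 / 0.29)^2 + (0.02 / 1)^2))
  expect_false(rec$above_rigid_limit)

  same <- het_noe(1, 1, 0.05, 0.05)
  expect_equal(same$noe, 1)
  expect_true(same$above_rigid_limit)

  expect_error(het_noe(0.5, 0), "zero")
})
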