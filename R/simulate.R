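#' Simulate an R2 profile with hydrophobic-cluster elevations
#'
#' Builds the intrinsic random-coil baseline for a sequence, adds Gaussian
#' (in residue index) cluster bumps at the requested centres, and corrupts
#' the result with homoscedastic Gaussian noise. The defaults emulate the
#' phenomenology of an unfolded four-helix chain: four clusters centred at
#' residues 18, 42, 56 and 73.
#'
#' @param seq a [protein_sequence()]; default the triply substituted Im7
#'   chain whose unfolded state is populated without denaturant.
#' @param scale baseline scale factor (s^-1 per cubic Angstrom).
#' @param centers,amplitudes,widths cluster bump parameters: centre residue
#'   index, peak height (s^-1) and Gaussian sigma (residues).
#' @param noise rate noise standard deviation (s^-1).
#' @param seed integer seed; the generator is a pure function of its inputs.
#' @param properties per-residue property table.
#' @return list with `observed` (tibble `index`, `residue`, `rate`, `err`),
#'   `baseline` (noise-free scaled baseline) and `truth` (bump table).
#' @export
#' @examples
#' sim <- simulate_r2_dataset(seed = 1)
#' detect_clusters(sim$observed, sim$baseline)
simulate_r2_dataset <- function(seq = im7_sequence(c("L18A", "L19A", "L37A")),
                                scale = 0.05,
                                centers = c(18, 42, 56, 73),
                                amplitudes = rep(1.5, length(centers)),
                                widths = rep(2.5, length(centers)),
                                noise = 0.1, seed = 1L,
                                properties = residue_properties()) {
  if (length(centers) > 0 &&
      (any(centers < min(seq$index)) || any(centers > max(seq$index)))) {
    abort("cluster bump centre outside the sequence")
  }
  baseline <- intrinsic_r2_profile(seq, scale = scale, properties = properties)
  bumps <- rep(0, nrow(baseline))
  for (k in seq_along(centers)) {
    bumps <- bumps + amplitudes[k] *
      exp(-((baseline$index - centers[k])^2) / (2 * widths[k]^2))
  }
  .set_seed(seed)
  observed <- baseline
  observed$rate <- baseline$rate + bumps + rnorm(nrow(baseline), 0, noise)
  observed$err <- rep(noise, nrow(baseline))
  list(observed = observed, baseline = baseline,
       truth = tibble(center = centers, amplitude = amplitudes, width = widths))
}

# local seeded RNG without touching the caller's stream state thereafter
.set_seed <- function(seed) {
  set.seed(as.integer(seed) %% .Machine$integer.max)
}

#' Simulate a chemical-shift table with region-wise helical propensity
#'
#' Shifts equal the random-coil reference plus a fractional-helix offset
#' (fraction times the full-helix secondary-shift magnitude; Cbeta moves
#' upfield, i.e. with inverted sign) plus Gaussian noise.
#'
#' @param seq a [protein_sequence()].
#' @param fractions named-by-nothing tibble or data frame with columns
#'   `start`, `end`, `fraction` (helix fraction in \[0, 1\] per region), or
#'   `NULL` for a pure coil.
#' @param nuclei nuclei to simulate.
#' @param noise shift noise sd (ppm).
#' @param seed integer seed.
#' @param ref random-coil reference.
#' @param expected full-structure magnitudes from [ssp_expected()].
#' @param temperature_K,pH conditions passed to the reference.
#' @return a [shift_table()]; the injected per-residue fraction is attached
#'   as attribute `truth`.
#' @export
simulate_shift_dataset <- function(seq, fractions = NULL,
                                   nuclei = c("CA", "CB"), noise = 0,
                                   seed = 1L, ref = random_coil_reference(),
                                   expected = ssp_expected(),
                                   temperature_K = 283.15, pH = 7.0) {
  rc <- random_coil_shifts(seq, ref, temperature_K = temperature_K, pH = pH,
                           nuclei = nuclei)
  frac <- rep(0, nrow(seq))
  if (!is.null(fractions)) {
    fractions <- as_tibble(fractions)
    if (any(fractions$fraction < 0) || any(fractions$fraction > 1)) {
      abort("helix fractions must lie in [0, 1]")
    }
    for (k in seq_len(nrow(fractions))) {
      sel <- seq$index >= fractions$start[k] & seq$index <= fractions$end[k]
      frac[sel] <- fractions$fraction[k]
    }
  }
  exp_h <- setNames(expected$helix_ppm, expected$nucleus)
  tab <- as_tibble(rc)
  f_i <- frac[match(tab$index, seq$index)]
  sgn <- ifelse(tab$nucleus == "CB", -1, 1)
  .set_seed(seed)
  tab$shift_ppm <- tab$shift_ppm + sgn * f_i * exp_h[tab$nucleus] +
    rnorm(nrow(tab), 0, noise)
  out <- shift_table(tab, temperature_K = temperature_K, pH = pH,
                     label = "simulated")
  attr(out, "truth") <- tibble(index = seq$index, fraction = frac)
  out
}

#' Simulate HNHA cross/diagonal intensity pairs from known couplings
#'
#' @param j true couplings (Hz), each inside `(0, 1/(4*delta))`.
#' @param delta delay (s).
#' @param i_diag diagonal-peak intensity scale.
#' @param noise Gaussian intensity noise sd applied to both peaks.
#' @param seed integer seed.
#' @param index residue indices.
#' @return tibble `index`, `j_true`, `i_cross`, `i_diag`, `noise`.
#' @export
simulate_hnha <- function(j, delta = 0.01254, i_diag = 100, noise = 0,
                          seed = 1L, index = seq_along(j)) {
  ratio <- hnha_ratio(j, delta)   # errors at/above the singularity
  .set_seed(seed)
  tibble(index = index, j_true = j,
         i_cross = ratio * i_diag + rnorm(length(j), 0, noise),
         i_diag = i_diag + rnorm(length(j), 0, noise),
         noise = noise)
}

#' Simulate a two-state denaturation curve
#'
#' @param dG,m,a,b,c,d,temperature_K model parameters, see
#'   [two_state_signal()].
#' @param urea denaturant grid (M), default 0-8 M in 0.2 M steps.
#' @param noise Gaussian signal noise sd.
#' @param seed integer seed.
#' @return tibble `urea`, `signal`; true parameters attached as attribute
#'   `truth`.
#' @export
simulate_denaturation <- function(dG = 24.9, m = 6, a = 0, b = 1, c = 0,
                                  d = 0, temperature_K = 283.15,
                                  urea = seq(0, 8, by = 0.2), noise = 0,
                                  seed = 1L) {
  clean <- two_state_signal(urea, dG, m, a, b, c, d, temperature_K)
  .set_seed(seed)
  out <- tibble(urea = urea, signal = clean + rnorm(length(urea), 0, noise))
  attr(out, "truth") <- tibble(dG = dG, m = m, a = a, b = b, c = c, d = d,
                               temperature_K = temperature_K, noise = noise)
  out
}

#' Simulate per-residue monoexponential relaxation decay series
#'
#' @param rates true R2 rates (s^-1), one per residue.
#' @param times delay schedule (s), default [r2_delay_schedule()].
#' @param i0 initial intensity.
#' @param noise Gaussian intensity noise sd.
#' @param duplicates indices into `times` to re-acquire (duplicate points
#'   exercise the error-inflation path of the decay fit).
#' @param seed integer seed.
#' @param index residue indices.
#' @return tibble `index`, `rate_true`, `time_s`, `intensity`, `noise`.
#' @export
simulate_decay_series <- function(rates, times = r2_delay_schedule(),
                                  i0 = 100, noise = 0, duplicates = integer(),
                                  seed = 1L, index = seq_along(rates)) {
  if (any(rates <= 0)) abort("rates must be positive")
  t_all <- c(times, times[duplicates])
  .set_seed(seed)
  out <- purrr::map2(index, rates, function(ix, r) {
    tibble(index = ix, rate_true = r, time_s = t_all,
           intensity = i0 * exp(-r * t_all) + rnorm(length(t_all), 0, noise),
           noise = noise)
  })
  bind_rows(out)
}
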