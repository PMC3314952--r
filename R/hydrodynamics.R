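#' Density and viscosity of pure water
#'
#' Standard empirical correlations used when correcting sedimentation
#' coefficients to water at 20 degrees C: the Kell polynomial for density and
#' a CRC-style log-ratio correlation (anchored at 1.002 mPa s at 20 C) for
#' viscosity. Valid over roughly 0-40 C.
#'
#' @param temperature_K temperature in kelvin.
#' @return `water_density`: g/mL; `water_viscosity`: mPa s.
#' @export
#' @examples
#' water_density(293.15)    # 0.99821 g/mL
#' water_viscosity(283.15)  # about 1.306 mPa s
water_density <- function(temperature_K) {
  t <- temperature_K - 273.15
  if (any(t < 0) || any(t > 45)) abort("water correlations valid for 0-45 C")
  (999.83952 + 16.945176 * t - 7.9870401e-3 * t^2 - 46.170461e-6 * t^3 +
     105.56302e-9 * t^4 - 280.54253e-12 * t^5) / (1 + 16.897850e-3 * t) / 1000
}

#' @rdname water_density
#' @export
water_viscosity <- function(temperature_K) {
  t <- temperature_K - 273.15
  if (any(t < 0) || any(t > 45)) abort("water correlations valid for 0-45 C")
  d <- 20 - t
  1.002 * 10^((d / (t + 96)) * (1.2364 - 1.37e-3 * d + 5.7e-6 * d^2))
}

#' Correct an observed sedimentation coefficient to water at 20 C
#'
#' `s20w = s_obs * (eta_buffer/eta_20w) * (1 - vbar*rho_20w) /
#' (1 - vbar*rho_buffer)`, with water properties at 20 C from the packaged
#' correlations. Buffer density and viscosity at the experimental temperature
#' are user inputs.
#'
#' @param s_obs observed sedimentation coefficient (Svedberg units).
#' @param temperature_K experimental temperature (K); recorded only.
#' @param buffer_density buffer density at the experimental temperature (g/mL).
#' @param buffer_viscosity buffer viscosity at the experimental temperature
#'   (mPa s).
#' @param vbar protein partial specific volume (mL/g), in (0.5, 0.9).
#' @return s20,w in Svedberg units.
#' @export
standardize_s20w <- function(s_obs, temperature_K, buffer_density,
                             buffer_viscosity, vbar) {
  if (any(s_obs <= 0)) abort("s_obs must be positive")
  if (any(vbar <= 0.5) || any(vbar >= 0.9)) abort("vbar outside physical range (0.5, 0.9) mL/g")
  rho20 <- water_density(293.15)
  eta20 <- water_viscosity(293.15)
  buoy20 <- 1 - vbar * rho20
  buoyT <- 1 - vbar * buffer_density
  if (any(buoyT <= 0) || any(buoy20 <= 0)) {
    abort("non-positive buoyancy term (1 - vbar * rho): particle would float")
  }
  s_obs * (buffer_viscosity / eta20) * buoy20 / buoyT
}

#' Translational friction coefficient from the Svedberg equation
#'
#' `f = M * (1 - vbar * rho_20w) / (N_A * s20w)` with the sedimentation
#' coefficient converted from Svedberg units (1 S = 1e-13 s); cgs output.
#'
#' @param s20w sedimentation coefficient in water at 20 C (S).
#' @param molar_mass molar mass (g/mol).
#' @param vbar partial specific volume (mL/g).
#' @param rho water density at 20 C (g/mL).
#' @return friction coefficient f (g/s).
#' @export
#' @examples
#' svedberg_friction(1.45, 10600, 0.73)   # about 3.29e-8 g/s
svedberg_friction <- function(s20w, molar_mass, vbar,
                              rho = water_density(293.15)) {
  if (any(s20w <= 0)) abort("s20w must be positive")
  buoy <- 1 - vbar * rho
  if (any(buoy <= 0)) abort("non-positive buoyancy term: particle would float")
  molar_mass * buoy / (.avogadro * s20w * .svedberg_s)
}

#' Radius and friction of the equal-volume rigid sphere
#'
#' The Stokes reference sphere has the anhydrous volume of the protein,
#' `V = M * vbar / N_A`, so `R0 = (3 M vbar / (4 pi N_A))^(1/3)` and
#' `f0 = 6 pi eta R0`. An optional hydration parameter `delta_hydration`
#' (g water per g protein) inflates the sphere volume by the bound-water
#' shell; it defaults to 0 because the Svedberg-Stokes chain as used here
#' closes exactly only with the equal-volume (anhydrous) sphere.
#'
#' @param molar_mass molar mass (g/mol).
#' @param vbar partial specific volume (mL/g).
#' @param eta solvent viscosity (mPa s), default water at 20 C.
#' @param delta_hydration g water / g protein added to the sphere volume.
#' @return one-row tibble: `r0_A` (Angstrom), `f0_g_s` (g/s).
#' @export
#' @examples
#' stokes_sphere(10600, 0.73)   # r0 about 14.5 A
stokes_sphere <- function(molar_mass, vbar, eta = water_viscosity(293.15),
                          delta_hydration = 0) {
  if (any(molar_mass <= 0) || any(vbar <= 0)) abort("inputs must be positive")
  v_spec <- vbar + delta_hydration / water_density(293.15)  # mL/g
  r0_cm <- (3 * molar_mass * v_spec / (4 * pi * .avogadro))^(1 / 3)
  eta_poise <- eta / 100   # mPa s -> poise (g cm^-1 s^-1)
  f0 <- 6 * pi * eta_poise * r0_cm
  tibble(r0_A = r0_cm * 1e8, f0_g_s = f0)
}

#' Frictional ratio and hydrodynamic radius
#'
#' `f/f0` measures departure from the compact sphere; the hydrodynamic radius
#' is `Rh = (f/f0) * R0`. A frictional ratio below 1 is unphysical for a
#' rigid particle and triggers a warning.
#'
#' @param f measured friction coefficient (g/s).
#' @param f0 sphere friction coefficient (g/s).
#' @param r0 sphere radius (Angstrom).
#' @return one-row tibble: `f_ratio`, `rh_A`.
#' @export
hydrodynamic_radius <- function(f, f0, r0) {
  if (any(f <= 0) || any(f0 <= 0)) abort("friction coefficients must be positive")
  f_ratio <- f / f0
  if (any(f_ratio < 1)) {
    warn("frictional ratio below 1: unphysical for a rigid particle")
  }
  tibble(f_ratio = f_ratio, rh_A = f_ratio * r0)
}

#' Full sedimentation-to-hydrodynamic-radius chain for one record
#'
#' Convenience wrapper running [standardize_s20w()], [svedberg_friction()],
#' [stokes_sphere()] and [hydrodynamic_radius()] on one AUC measurement.
#'
#' @inheritParams standardize_s20w
#' @inheritParams svedberg_friction
#' @param delta_hydration passed to [stokes_sphere()].
#' @return one-row tibble with the inputs and the derived `s20w`, `f_g_s`,
#'   `r0_A`, `f0_g_s`, `f_ratio`, `rh_A`.
#' @export
#' @examples
#' sedimentation_chain(1.45, 293.15, water_density(293.15),
#'                     water_viscosity(293.15), 0.73, 10600)
sedimentation_chain <- function(s_obs, temperature_K, buffer_density,
                                buffer_viscosity, vbar, molar_mass,
                                delta_hydration = 0) {
  s20w <- standardize_s20w(s_obs, temperature_K, buffer_density,
                           buffer_viscosity, vbar)
  f <- svedberg_friction(s20w, molar_mass, vbar)
  sph <- stokes_sphere(molar_mass, vbar, delta_hydration = delta_hydration)
  hr <- hydrodynamic_radius(f, sph$f0_g_s, sph$r0_A)
  tibble(s_obs = s_obs, temperature_K = temperature_K,
         buffer_density = buffer_density, buffer_viscosity = buffer_viscosity,
         vbar = vbar, molar_mass = molar_mass,
         s20w = s20w, f_g_s = f, r0_A = sph$r0_A, f0_g_s = sph$f0_g_s,
         f_ratio = hr$f_ratio, rh_A = hr$rh_A)
}

#' Empirical hydrodynamic radius from chain length
#'
#' Power-law predictions of the hydrodynamic radius of a polypeptide from the
#' number of residues N, following the empirical pulsed-field-gradient NMR
#' calibration of Wilkins and colleagues: `4.75 * N^0.29` Angstrom for a
#' compact folded protein and `2.21 * N^0.57` for a highly denatured chain.
#'
#' @param n_residues chain length (>= 1); include any expression-tag residues.
#' @param state `"folded"` or `"denatured"`.
#' @return predicted Rh (Angstrom).
#' @export
#' @examples
#' wilkins_rh(94, "folded")      # 17.7 A
#' wilkins_rh(94, "denatured")   # 29.4 A
wilkins_rh <- function(n_residues, state = c("folded", "denatured")) {
  if (any(n_residues < 1)) abort("n_residues must be >= 1")
  state <- match.arg(state)
  switch(state,
         folded = 4.75 * n_residues^0.29,
         denatured = 2.21 * n_residues^0.57)
}

#' Compaction metrics between two hydrodynamic radii
#'
#' @param rh_a,rh_b radii (Angstrom); the ratio is `rh_a / rh_b` and
#'   `percent_more_compact = 100 * (1 - rh_a / rh_b)` (negative when `rh_a`
#'   is the larger, i.e. expansion).
#' @return one-row tibble: `ratio`, `percent_more_compact`.
#' @export
#' @examples
#' compaction_metrics(24.6, 34.0)
compaction_metrics <- function(rh_a, rh_b) {
  if (any(rh_b <= 0)) abort("reference radius must be positive")
  tibble(ratio = rh_a / rh_b,
         percent_more_compact = 100 * (1 - rh_a / rh_b))
}
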