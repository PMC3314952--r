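#' Helical content from mean residue ellipticity at 222 nm
#'
#' Scales the variant-to-wild-type ratio of the 222 nm mean residue
#' ellipticity by 50, the percentage of wild-type Im7 residues in helical
#' conformation in the native crystal structure. Both MREs are negative at
#' 222 nm for helical proteins; the ratio handles the sign.
#'
#' @param mre_variant,mre_wt mean residue ellipticity at 222 nm
#'   (deg cm^2 dmol^-1 per peptide bond); `mre_wt != 0`.
#' @param wt_helix_pct helicity of the reference protein (default 50).
#' @return percent helix.
#' @export
#' @examples
#' helical_content(-11000, -11000)   # 50
helical_content <- function(mre_variant, mre_wt, wt_helix_pct = 50) {
  if (any(mre_wt == 0)) abort("wild-type reference MRE is zero")
  (mre_variant / mre_wt) * wt_helix_pct
}

#' Evaluate the two-state equilibrium unfolding model
#'
#' Signal of a protein in a two-state folded/unfolded equilibrium as a
#' function of denaturant concentration, with linear folded and unfolded
#' baselines:
#'
#' \deqn{S(u) = \frac{(a u + b)\,e^{(\Delta G^\circ_{UF} - m u)/RT} + (c u + d)}
#'                   {1 + e^{(\Delta G^\circ_{UF} - m u)/RT}}}
#'
#' `dG` is the unfolding free energy (kJ/mol, positive for a stable fold) and
#' `m` its denaturant dependence (kJ/mol/M); the transition midpoint is
#' `dG/m`. As `u -> 0` with a large positive `dG` the signal tends to the
#' folded baseline intercept `b`; at high denaturant it tends to `c*u + d`.
#'
#' @param urea denaturant concentrations (M).
#' @param dG unfolding free energy (kJ/mol).
#' @param m m-value (kJ/mol/M).
#' @param a,b folded-baseline slope and intercept.
#' @param c,d unfolded-baseline slope and intercept.
#' @param temperature_K temperature (K).
#' @return signal values.
#' @export
two_state_signal <- function(urea, dG, m, a = 0, b = 1, c = 0, d = 0,
                             temperature_K = 283.15) {
  k <- exp((dG - m * urea) / (.R_kJ * temperature_K))
  ((a * urea + b) * k + (c * urea + d)) / (1 + k)
}

#' Fit a two-state denaturation curve
#'
#' Nonlinear least-squares fit of [two_state_signal()] to a titration,
#' estimating the unfolding free energy `dG` (kJ/mol), the m-value
#' (kJ/mol/M) and the four baseline parameters. Starting values: baselines
#' from straight-line fits to the first and last three points, `m` = 5
#' kJ/mol/M, and `dG` from the concentration where the signal crosses midway
#' between the baselines. Before parameters are reported, an F-test (default
#' alpha 0.01) compares the six-parameter transition model against a straight
#' line; data without a detectable cooperative transition raise a classed
#' error (`ucoil_no_transition`) rather than returning meaningless estimates.
#'
#' The fitted `dG` follows the unfolding convention (positive for a stable
#' protein); the folding free energy `-dG` is reported alongside it.
#'
#' @param curve data frame with columns `urea` (M, >= 8 unique values) and
#'   `signal`.
#' @param temperature_K temperature (K).
#' @param normalise divide the signal by its value at the highest denaturant
#'   point before fitting (baselines transform accordingly).
#' @param gate_alpha significance level of the transition F-test; `NULL`
#'   disables the gate.
#' @return object of class `two_state_fit`: list with `estimates` (tibble of
#'   `term`, `estimate`, `std_error`), `midpoint_M`, `dG_fold`, `fitted`,
#'   `data`, `temperature_K`, `converged`.
#' @export
#' @examples
#' u <- seq(0, 8, by = 0.2)
#' curve <- data.frame(urea = u,
#'                     signal = two_state_signal(u, dG = 24.9, m = 6))
#' fit <- fit_two_state(curve)
#' tidy(fit)
fit_two_state <- function(curve, temperature_K = 283.15, normalise = FALSE,
                          gate_alpha = 0.01) {
  curve <- as_tibble(curve)
  if (!all(c("urea", "signal") %in% names(curve))) {
    abort("curve needs columns: urea, signal")
  }
  curve <- arrange(curve, .data$urea)
  if (length(unique(curve$urea)) < 8L) abort("need >= 8 denaturant points")
  if (normalise) {
    ref <- curve$signal[which.max(curve$urea)]
    if (ref == 0) abort("cannot normalise: zero signal at highest denaturant")
    curve$signal <- curve$signal / ref
  }
  u <- curve$urea; y <- curve$signal
  n <- length(u)
  lo <- lm(y ~ u, data = data.frame(u = head(u, 3), y = head(y, 3)))
  hi <- lm(y ~ u, data = data.frame(u = tail(u, 3), y = tail(y, 3)))
  b0 <- coef(lo)[[1]]; a0 <- coef(lo)[[2]]
  d0 <- coef(hi)[[1]]; c0 <- coef(hi)[[2]]
  mid_sig <- (predict(lo, data.frame(u = u)) + predict(hi, data.frame(u = u))) / 2
  cross <- which.min(abs(y - mid_sig))
  m0 <- 5
  dG0 <- max(m0 * u[cross], 1)
  RT <- .R_kJ * temperature_K

  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ ((a * u + b) * exp((dG - m * u) / RT) + (c * u + d)) /
        (1 + exp((dG - m * u) / RT)),
      data = data.frame(u = u, y = y),
      start = list(dG = dG0, m = m0, a = a0, b = b0, c = c0, d = d0),
      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(e) {
      abort(sprintf("two-state fit did not converge: %s", conditionMessage(e)),
            class = "ucoil_no_transition")
    })

  if (!is.null(gate_alpha)) {
    rss2 <- sum(stats::resid(fit)^2)
    line <- lm(y ~ u)
    rss1 <- sum(stats::resid(line)^2)
    tss <- sum((y - mean(y))^2)
    # a straight line that already explains the data leaves no transition to fit
    if (tss == 0 || rss1 <= 1e-12 * tss) {
      abort("no detectable cooperative unfolding transition (signal is linear in denaturant)",
            class = "ucoil_no_transition")
    }
    df2 <- n - 6L
    fstat <- ((rss1 - rss2) / 4) / (rss2 / df2)
    pval <- pf(fstat, 4, df2, lower.tail = FALSE)
    if (!is.finite(fstat)) pval <- if (rss2 <= 1e-12 * rss1) 0 else 1
    if (is.na(pval) || pval > gate_alpha) {
      abort(paste("no detectable cooperative unfolding transition",
                  sprintf("(F-test p = %.3g)", pval)),
            class = "ucoil_no_transition")
    }
  }

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  estimates <- tibble(term = names(est), estimate = unname(est),
                      std_error = unname(se))
  structure(list(
    estimates = estimates,
    midpoint_M = est[["dG"]] / est[["m"]],
    dG_fold = -est[["dG"]],
    fitted = tibble(urea = u, signal = y, fit = stats::fitted(fit)),
    data = curve,
    temperature_K = temperature_K,
    converged = TRUE
  ), class = "two_state_fit")
}

#' @export
print.two_state_fit <- function(x, ...) {
  dg <- x$estimates[x$estimates$term == "dG", ]
  m <- x$estimates[x$estimates$term == "m", ]
  cat("<two_state_fit>\n")
  cat(sprintf("  dG(unfold) = %.2f +/- %.2f kJ/mol (folding: %.2f)\n",
              dg$estimate, dg$std_error, -dg$estimate))
  cat(sprintf("  m-value    = %.2f +/- %.2f kJ/mol/M\n", m$estimate, m$std_error))
  cat(sprintf("  midpoint   = %.2f M, T = %.2f K, n = %d\n",
              x$midpoint_M, x$temperature_K, nrow(x$data)))
  invisible(x)
}

#' @rdname fit_two_state
#' @param x a `two_state_fit` object.
#' @param ... unused.
#' @method tidy two_state_fit
#' @export
tidy.two_state_fit <- function(x, ...) {
  x$estimates
}

#' @rdname fit_two_state
#' @method glance two_state_fit
#' @export
glance.two_state_fit <- function(x, ...) {
  rss <- sum((x$fitted$signal - x$fitted$fit)^2)
  tibble(dG_unfold = x$estimates$estimate[x$estimates$term == "dG"],
         dG_fold = x$dG_fold,
         m_value = x$estimates$estimate[x$estimates$term == "m"],
         midpoint_M = x$midpoint_M,
         temperature_K = x$temperature_K,
         rss = rss, n = nrow(x$data), converged = x$converged)
}

#' Fluorescence emission maximum by parabolic interpolation
#'
#' Finds the grid maximum of an emission spectrum and refines it to sub-grid
#' resolution with a parabola through the maximum and its two neighbours.
#' A maximum at the spectrum edge cannot be interpolated and is flagged.
#'
#' @param wavelength wavelengths (nm), >= 5 points.
#' @param intensity emission intensities.
#' @return one-row tibble: `lambda_max_nm`, `intensity_max`, `at_edge`.
#' @export
#' @examples
#' wl <- 300:400
#' lambda_max(wl, exp(-(wl - 350)^2 / 200))
lambda_max <- function(wavelength, intensity) {
  if (length(wavelength) < 5L) abort("need >= 5 spectral points")
  o <- order(wavelength)
  wl <- wavelength[o]; y <- intensity[o]
  k <- which.max(y)
  if (k == 1L || k == length(y)) {
    return(tibble(lambda_max_nm = wl[k], intensity_max = y[k], at_edge = TRUE))
  }
  # vertex of the parabola through (wl[k-1..k+1], y[k-1..k+1])
  x1 <- wl[k - 1]; x2 <- wl[k]; x3 <- wl[k + 1]
  y1 <- y[k - 1]; y2 <- y[k]; y3 <- y[k + 1]
  denom <- (x1 - x2) * (x1 - x3) * (x2 - x3)
  A <- (x3 * (y2 - y1) + x2 * (y1 - y3) + x1 * (y3 - y2)) / denom
  B <- (x3^2 * (y1 - y2) + x2^2 * (y3 - y1) + x1^2 * (y2 - y3)) / denom
  vx <- -B / (2 * A)
  vy <- A * vx^2 + B * vx + (y1 - A * x1^2 - B * x1)
  tibble(lambda_max_nm = vx, intensity_max = vy, at_edge = FALSE)
}

#' Colicin-protection gamma statistic
#'
#' Relative increase of density-corrected luminescence of challenged cells
#' over unchallenged controls: `gamma = (L_sample - L_control) / L_control`.
#'
#' @param l_sample,l_control density-corrected luminescence; `l_control > 0`.
#' @return one-row tibble: `l_sample`, `l_control`, `gamma`.
#' @export
#' @examples
#' gamma_value(3, 1)   # gamma = 2
gamma_value <- function(l_sample, l_control) {
  if (any(l_control <= 0)) abort("control luminescence must be positive")
  tibble(l_sample = l_sample, l_control = l_control,
         gamma = (l_sample - l_control) / l_control)
}
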