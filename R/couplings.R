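#' Forward HNHA intensity ratio for a given coupling
#'
#' In the HNHA experiment the cross- to diagonal-peak intensity ratio is
#' `-tan^2(2*pi*J*delta)`, where `delta` is the pulse-sequence delay (half the
#' mixing time). The ratio is defined for couplings below the tangent
#' singularity at `J = 1/(4*delta)`.
#'
#' @param j coupling constant (Hz), `0 <= j < 1/(4*delta)`.
#' @param delta delay (s); the default corresponds to a 25.08 ms mixing time.
#' @return intensity ratio (<= 0).
#' @export
#' @examples
#' hnha_ratio(6)          # about -0.262
hnha_ratio <- function(j, delta = 0.01254) {
  jmax <- 1 / (4 * delta)
  if (any(j < 0) || any(j >= jmax)) {
    abort(sprintf("j must lie in [0, %.3f) Hz for delta = %g s", jmax, delta))
  }
  -tan(2 * pi * j * delta)^2
}

#' Extract 3J(HN-HA) couplings from HNHA peak intensities
#'
#' Inverts the HNHA intensity relation: `J = atan(sqrt(-Icross/Idiag)) /
#' (2*pi*delta)`. The construction bounds J inside `(0, 1/(4*delta))`, so the
#' tangent singularity is unreachable. Uncertainties follow by first-order
#' propagation of the two (independent) peak-height noises through the
#' inverse formula. Positive intensity ratios indicate a phase or assignment
#' artefact and raise an error rather than being clipped.
#'
#' @param i_cross,i_diag cross- and diagonal-peak intensities; a valid pair
#'   has `i_cross / i_diag <= 0`.
#' @param delta delay (s).
#' @param noise peak-height noise estimate (intensity units), applied to both
#'   peaks; may be a vector.
#' @param index optional residue indices.
#' @param helix_max,sheet_min classification bounds (Hz): couplings at or
#'   below `helix_max` are called helical, at or above `sheet_min` extended.
#' @return tibble `index`, `i_cross`, `i_diag`, `ratio`, `j_Hz`, `sigma_j_Hz`,
#'   `class`.
#' @export
#' @examples
#' j_from_hnha(-0.262, 1.0)
j_from_hnha <- function(i_cross, i_diag, delta = 0.01254, noise = 0,
                        index = seq_along(i_cross),
                        helix_max = 6, sheet_min = 8) {
  if (any(i_diag == 0)) abort("diagonal intensity is zero")
  ratio <- i_cross / i_diag
  if (any(ratio > 0)) {
    abort(sprintf("positive intensity ratio at position %d: phase or assignment artefact",
                  index[which(ratio > 0)[1]]))
  }
  j <- atan(sqrt(-ratio)) / (2 * pi * delta)
  # dJ/dratio through J = atan(sqrt(-r))/(2 pi delta); singular at r = 0
  djdr <- -1 / (2 * pi * delta) / (1 - ratio) / (2 * sqrt(-ratio))
  sigma_r <- abs(ratio) * sqrt((noise / i_cross)^2 + (noise / i_diag)^2)
  sigma_j <- abs(djdr) * sigma_r
  sigma_j[ratio == 0] <- if (all(noise == 0)) 0 else NA_real_
  tibble(index = index, i_cross = i_cross, i_diag = i_diag, ratio = ratio,
         j_Hz = j, sigma_j_Hz = sigma_j,
         class = classify_j(j, helix_max = helix_max, sheet_min = sheet_min))
}

#' Classify a coupling as helical, intermediate or extended
#'
#' Backbone 3J(HN-HA) couplings at or below 6 Hz are consistent with helical
#' phi angles, those at or above 8 Hz with extended structure.
#'
#' @param j coupling (Hz), >= 0.
#' @param helix_max,sheet_min class boundaries (Hz).
#' @return character vector in `{"helical", "intermediate", "extended"}`.
#' @export
#' @examples
#' classify_j(c(4.96, 7, 9.54))
classify_j <- function(j, helix_max = 6, sheet_min = 8) {
  if (any(j < 0)) abort("couplings must be non-negative")
  dplyr::case_when(
    j <= helix_max ~ "helical",
    j >= sheet_min ~ "extended",
    TRUE ~ "intermediate"
  )
}
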