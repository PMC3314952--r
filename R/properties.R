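#' Per-residue property table
#'
#' Loads the packaged per-amino-acid property scale: side-chain radius of
#' gyration (Angstrom), segmental-motion persistence length (residues, 2 for
#' alanine and glycine, 7 otherwise), and the average-area-buried-upon-folding
#' (AABUF) hydrophobicity scale. The proline radius of gyration is raised
#' from its tabulated 1.25 A to `proline_rg` (default 2.0 A) at construction
#' time, reflecting the reduced conformational space of the closed pyrrolidine
#' ring; reloading is idempotent.
#'
#' @param path optional TSV with columns `residue`, `rg_A`, `lambda`, `aabuf`
#'   to replace the packaged defaults.
#' @param proline_rg value (A) the proline side-chain Rg is set to; use `NULL`
#'   to keep the tabulated value.
#' @return a tibble with columns `residue`, `rg_A`, `lambda`, `aabuf`,
#'   covering all 20 amino acids.
#' @export
#' @examples
#' residue_properties()
residue_properties <- function(path = NULL, proline_rg = 2.0) {
  if (is.null(path)) {
    path <- system.file("extdata", "residue_properties.tsv", package = "ucoil")
  }
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("residue", "rg_A", "lambda", "aabuf")
  if (!all(need %in% names(tab))) {
    abort(sprintf("property table must have columns: %s",
                  paste(need, collapse = ", ")))
  }
  missing <- setdiff(.aa_alphabet, tab$residue)
  if (length(missing) > 0L) {
    abort(sprintf("property table lacks entries for: %s",
                  paste(missing, collapse = ", ")))
  }
  if (any(tab$rg_A <= 0)) abort("all side-chain Rg values must be positive")
  if (!is.null(proline_rg)) {
    tab$rg_A[tab$residue == "P"] <- proline_rg
  }
  as_tibble(tab)
}

#' Smoothed, normalised AABUF profile along a sequence
#'
#' Computes the sliding-window mean of the average-area-buried-upon-folding
#' scale over the sequence, then rescales linearly so the profile minimum maps
#' to 0 and the maximum to 10. A constant profile (e.g. a homopolymer) maps to
#' 0 everywhere. Windows are truncated at the chain termini.
#'
#' @param seq a [protein_sequence()].
#' @param properties property table from [residue_properties()].
#' @param window odd window width (residues), at most the sequence length.
#' @return tibble with columns `index`, `residue`, `aabuf_raw`,
#'   `aabuf_smoothed`, `aabuf_norm` (0-10).
#' @export
#' @examples
#' aabuf_profile(im7_sequence(), window = 9)
aabuf_profile <- function(seq, properties = residue_properties(), window = 9L) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("window must be a positive odd integer")
  if (window > nrow(seq)) abort("window larger than the sequence")
  raw <- properties$aabuf[match(seq$residue, properties$residue)]
  half <- window %/% 2L
  n <- length(raw)
  smoothed <- vapply(seq_len(n), function(i) {
    mean(raw[max(1L, i - half):min(n, i + half)])
  }, numeric(1))
  rng <- range(smoothed)
  norm <- if (diff(rng) == 0) rep(0, n) else 10 * (smoothed - rng[1]) / diff(rng)
  tibble(index = seq$index, residue = seq$residue,
         aabuf_raw = raw, aabuf_smoothed = smoothed, aabuf_norm = norm)
}

#' Native helix regions of Im7 in wild-type numbering
#'
#' Default inclusive intervals for the four helices: I 12-25, II 31-45,
#' III 51-56, IV 65-79. Individual regions can be overridden.
#'
#' @param overrides optional named list of length-2 integer vectors
#'   `c(start, end)` replacing the default interval for that region.
#' @param n_residues optional chain length; intervals are checked to lie
#'   within `1..n_residues` when given.
#' @return tibble with columns `region`, `start`, `end`.
#' @export
#' @examples
#' helix_regions()
#' helix_regions(list(I = c(10, 20)))
helix_regions <- function(overrides = NULL, n_residues = NULL) {
  regions <- tibble(
    region = c("I", "II", "III", "IV"),
    start = c(12L, 31L, 51L, 65L),
    end = c(25L, 45L, 56L, 79L)
  )
  if (!is.null(overrides)) {
    for (nm in names(overrides)) {
      iv <- as.integer(overrides[[nm]])
      if (length(iv) != 2L || iv[1] > iv[2]) {
        abort(sprintf("region '%s': interval must be c(start, end) with start <= end", nm))
      }
      if (nm %in% regions$region) {
        regions$start[regions$region == nm] <- iv[1]
        regions$end[regions$region == nm] <- iv[2]
      } else {
        regions <- bind_rows(regions, tibble(region = nm, start = iv[1], end = iv[2]))
      }
    }
  }
  regions <- arrange(regions, .data$start)
  if (nrow(regions) > 1L && any(regions$start[-1] <= regions$end[-nrow(regions)])) {
    abort("helix regions overlap")
  }
  if (!is.null(n_residues) &&
      (any(regions$start < 1L) || any(regions$end > n_residues))) {
    abort("helix region outside sequence bounds")
  }
  regions
}
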