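.nucleus_vocab <- c("CA", "CB", "CO", "HA", "N", "HN")

#' Assemble and validate a chemical-shift table
#'
#' A shift table is a tibble with one row per (residue, nucleus) observation
#' and columns `index`, `residue`, `nucleus`, `shift_ppm`, plus solution
#' conditions stored as attributes. Nuclei are restricted to the backbone
#' vocabulary CA, CB, CO, HA, N, HN.
#'
#' @param x data frame with the four columns above (`residue` optional).
#' @param temperature_K,pH,urea_M,na2so4_M solution conditions.
#' @param label provenance label recorded with the table.
#' @return a validated tibble of class `shift_table`.
#' @export
shift_table <- function(x, temperature_K = 283.15, pH = 7.0, urea_M = 0,
                        na2so4_M = 0, label = "unlabelled") {
  x <- as_tibble(x)
  if (!all(c("index", "nucleus", "shift_ppm") %in% names(x))) {
    abort("shift table needs columns: index, nucleus, shift_ppm")
  }
  if (!"residue" %in% names(x)) x$residue <- NA_character_
  bad <- setdiff(unique(x$nucleus), .nucleus_vocab)
  if (length(bad) > 0L) {
    abort(sprintf("unknown nucleus: %s (expected %s)",
                  paste(bad, collapse = ", "),
                  paste(.nucleus_vocab, collapse = ", ")))
  }
  if (any(!is.finite(x$shift_ppm))) abort("shifts must be finite")
  dup <- duplicated(x[, c("index", "nucleus")])
  if (any(dup)) {
    d <- x[dup, ][1, ]
    abort(sprintf("duplicate shift for residue %d nucleus %s", d$index, d$nucleus))
  }
  x <- x[, c("index", "residue", "nucleus", "shift_ppm")]
  structure(x, class = c("shift_table", class(x)),
            temperature_K = temperature_K, pH = pH,
            urea_M = urea_M, na2so4_M = na2so4_M, label = label)
}

#' Read assigned chemical shifts from an NMR-STAR v3 file
#'
#' Extracts the assigned-chemical-shift loop (`_Atom_chem_shift` tags) of an
#' NMR-STAR v3 file, maps atom names onto the backbone nucleus vocabulary
#' (C -> CO, H -> HN, HA2/HA3 -> HA) and returns a [shift_table()]. Rows for
#' atoms outside the vocabulary are skipped, as are rows that fail to parse;
#' the number skipped is reported via a message.
#'
#' @param path NMR-STAR v3 file containing an assigned-chemical-shift loop.
#' @inheritParams shift_table
#' @return a [shift_table()] tibble.
#' @export
read_nmrstar_shifts <- function(path, temperature_K = 283.15, pH = 7.0,
                                urea_M = 0, na2so4_M = 0,
                                label = basename(path)) {
  lines <- readr::read_lines(path)
  loops <- which(stringr::str_trim(lines) == "loop_")
  if (length(loops) == 0L) abort("no loop_ block found")
  tab <- NULL
  for (lp in loops) {
    i <- lp + 1L
    tags <- character()
    while (i <= length(lines) && stringr::str_detect(stringr::str_trim(lines[i]), "^_")) {
      tags <- c(tags, stringr::str_trim(lines[i]))
      i <- i + 1L
    }
    if (!any(stringr::str_detect(tags, "^_Atom_chem_shift\\."))) next
    cols <- stringr::str_remove(tags, "^_Atom_chem_shift\\.")
    rows <- list()
    while (i <= length(lines)) {
      ln <- stringr::str_trim(lines[i])
      if (ln == "stop_" || ln == "" && i == length(lines)) break
      if (ln != "" && !stringr::str_starts(ln, "#")) {
        rows[[length(rows) + 1L]] <- stringr::str_split_1(ln, "\\s+")
      }
      i <- i + 1L
    }
    need <- c("Seq_ID", "Comp_ID", "Atom_ID", "Val")
    if (!all(need %in% cols)) {
      abort(sprintf("chemical-shift loop lacks tags: %s",
                    paste(setdiff(need, cols), collapse = ", ")))
    }
    ok <- vapply(rows, function(r) length(r) == length(cols), logical(1))
    skipped <- sum(!ok)
    rows <- rows[ok]
    m <- do.call(rbind, rows)
    colnames(m) <- cols
    df <- tibble(
      index = suppressWarnings(as.integer(m[, "Seq_ID"])),
      residue = .three_to_one(m[, "Comp_ID"]),
      atom = m[, "Atom_ID"],
      shift_ppm = suppressWarnings(as.numeric(m[, "Val"]))
    )
    bad <- !is.finite(df$shift_ppm) | is.na(df$index)
    skipped <- skipped + sum(bad)
    df <- df[!bad, ]
    df$nucleus <- dplyr::case_match(df$atom,
                                    "CA" ~ "CA", "CB" ~ "CB", "C" ~ "CO",
                                    "HA" ~ "HA", "HA2" ~ "HA", "HA3" ~ NA_character_,
                                    "N" ~ "N", "H" ~ "HN", "HN" ~ "HN",
                                    .default = NA_character_)
    dropped <- sum(is.na(df$nucleus))
    df <- df[!is.na(df$nucleus), c("index", "residue", "nucleus", "shift_ppm")]
    if (skipped > 0L) inform(sprintf("skipped %d unparseable rows", skipped))
    if (dropped > 0L) {
      inform(sprintf("dropped %d shifts outside the backbone nucleus vocabulary",
                     dropped))
    }
    tab <- df
    break
  }
  if (is.null(tab)) abort("no assigned-chemical-shift loop in file")
  shift_table(tab, temperature_K = temperature_K, pH = pH,
              urea_M = urea_M, na2so4_M = na2so4_M, label = label)
}

.aa3 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
          GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
          MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
          TYR = "Y", VAL = "V")

.three_to_one <- function(x) {
  out <- unname(.aa3[toupper(x)])
  out[is.na(out) & toupper(x) %in% .aa_alphabet] <- toupper(x)[is.na(out) & toupper(x) %in% .aa_alphabet]
  out
}

#' Random-coil chemical-shift reference
#'
#' Loads the packaged random-coil base shifts (per residue type and nucleus),
#' optionally with neighbour-correction, temperature-coefficient and pH terms.
#' The packaged defaults carry base values only; all correction terms default
#' to zero and can be supplied by the user as replacement tables.
#'
#' @param path optional base-table TSV (`residue`, `nucleus`, `shift_ppm`).
#' @param neighbor optional tibble `nucleus`, `offset` (-2..2, not 0),
#'   `neighbor` (residue type), `delta_ppm`.
#' @param temp_coef optional tibble `nucleus`, `coef_ppm_per_K`.
#' @param t_ref reference temperature (K) of the base table.
#' @return a list of class `rc_reference` with elements `base`, `neighbor`,
#'   `temp_coef`, `t_ref`, `label`.
#' @export
random_coil_reference <- function(path = NULL, neighbor = NULL,
                                  temp_coef = NULL, t_ref = 298.15) {
  if (is.null(path)) {
    path <- system.file("extdata", "random_coil_shifts.tsv", package = "ucoil")
  }
  base <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  for (nuc in c("CA", "CB")) {
    have <- base$residue[base$nucleus == nuc]
    expected <- if (nuc == "CB") setdiff(.aa_alphabet, "G") else .aa_alphabet
    miss <- setdiff(expected, have)
    if (length(miss) > 0L) {
      abort(sprintf("random-coil base table lacks %s entries for: %s",
                    nuc, paste(miss, collapse = ", ")))
    }
  }
  if (is.null(neighbor)) {
    neighbor <- tibble(nucleus = character(), offset = integer(),
                       neighbor = character(), delta_ppm = numeric())
  }
  if (is.null(temp_coef)) {
    temp_coef <- tibble(nucleus = unique(base$nucleus), coef_ppm_per_K = 0)
  }
  structure(list(base = as_tibble(base), neighbor = as_tibble(neighbor),
                 temp_coef = as_tibble(temp_coef), t_ref = t_ref,
                 label = basename(path)),
            class = "rc_reference")
}

#' Predict random-coil shifts for a sequence
#'
#' Evaluates the sequence-, temperature- and pH-corrected random-coil shift
#' for every residue and every nucleus present in the reference base table:
#' base value of the residue type, plus neighbour corrections from residues
#' at offsets -2..+2 (edge residues use only the neighbours that exist), plus
#' a linear temperature term relative to the reference temperature.
#'
#' @param seq a [protein_sequence()].
#' @param ref a [random_coil_reference()].
#' @param temperature_K,pH solution conditions of the prediction.
#' @param nuclei nuclei to predict (default: all in the base table).
#' @return a [shift_table()] of predicted random-coil shifts.
#' @export
random_coil_shifts <- function(seq, ref = random_coil_reference(),
                               temperature_K = 283.15, pH = 7.0,
                               nuclei = unique(ref$base$nucleus)) {
  miss <- setdiff(unique(seq$residue), unique(ref$base$residue))
  if (length(miss) > 0L) {
    abort(sprintf("residue type(s) absent from base table: %s",
                  paste(miss, collapse = ", ")))
  }
  n <- nrow(seq)
  rows <- tidyr::expand_grid(pos = seq_len(n), nucleus = nuclei)
  rows$index <- seq$index[rows$pos]
  rows$residue <- seq$residue[rows$pos]
  rows <- dplyr::left_join(rows, ref$base,
                           by = c("residue", "nucleus")) |>
    dplyr::rename(shift = "shift_ppm")
  rows <- rows[!is.na(rows$shift), ]   # e.g. Gly has no CB
  if (nrow(ref$neighbor) > 0L) {
    for (k in seq_len(nrow(ref$neighbor))) {
      nb <- ref$neighbor[k, ]
      jpos <- rows$pos + nb$offset
      hit <- rows$nucleus == nb$nucleus & jpos >= 1L & jpos <= n &
        seq$residue[pmax(pmin(jpos, n), 1L)] == nb$neighbor
      rows$shift[hit] <- rows$shift[hit] + nb$delta_ppm
    }
  }
  tc <- setNames(ref$temp_coef$coef_ppm_per_K, ref$temp_coef$nucleus)
  coefs <- tc[rows$nucleus]
  coefs[is.na(coefs)] <- 0
  rows$shift <- rows$shift + (temperature_K - ref$t_ref) * coefs
  shift_table(tibble(index = rows$index, residue = rows$residue,
                     nucleus = rows$nucleus, shift_ppm = rows$shift),
              temperature_K = temperature_K, pH = pH,
              label = paste0("random-coil:", ref$label))
}

#' Secondary chemical shifts (observed minus random coil)
#'
#' @param obs observed [shift_table()].
#' @param rc random-coil [shift_table()] (e.g. from [random_coil_shifts()]).
#' @return tibble `index`, `residue`, `nucleus`, `delta_ppm`, with attribute
#'   `n_dropped` counting observations without a random-coil counterpart.
#' @export
secondary_shifts <- function(obs, rc) {
  j <- dplyr::inner_join(
    as_tibble(obs)[, c("index", "residue", "nucleus", "shift_ppm")],
    as_tibble(rc)[, c("index", "nucleus", "shift_ppm")],
    by = c("index", "nucleus"), suffix = c("_obs", "_rc"))
  if (nrow(j) == 0L) abort("no (residue, nucleus) overlap between tables")
  out <- tibble(index = j$index, residue = j$residue, nucleus = j$nucleus,
                delta_ppm = j$shift_ppm_obs - j$shift_ppm_rc)
  attr(out, "n_dropped") <- nrow(obs) - nrow(j)
  out
}

#' Denaturant-difference shifts (reference-free secondary shifts)
#'
#' Subtracts shifts measured in concentrated denaturant from those in its
#' absence; the random-coil contribution cancels, so the difference reports
#' structure formed on removing the denaturant. Calpha differences larger
#' than 1 ppm in magnitude are flagged as atypical for a residually
#' structured unfolded state (full helix formation shifts Calpha by ~2.6 ppm).
#'
#' @param shifts_0M,shifts_6M [shift_table()]s for the same sequence.
#' @return tibble `index`, `residue`, `nucleus`, `delta_ppm`
#'   (= native-buffer minus denaturant), `atypical`.
#' @export
urea_difference_shifts <- function(shifts_0M, shifts_6M) {
  j <- dplyr::inner_join(
    as_tibble(shifts_0M)[, c("index", "residue", "nucleus", "shift_ppm")],
    as_tibble(shifts_6M)[, c("index", "nucleus", "shift_ppm")],
    by = c("index", "nucleus"), suffix = c("_0", "_6"))
  if (nrow(j) == 0L) abort("no (residue, nucleus) overlap between tables")
  tibble(index = j$index, residue = j$residue, nucleus = j$nucleus,
         delta_ppm = j$shift_ppm_0 - j$shift_ppm_6,
         atypical = j$nucleus == "CA" & abs(j$shift_ppm_0 - j$shift_ppm_6) > 1)
}

#' Expected full-structure secondary-shift magnitudes
#'
#' @param path optional replacement TSV (`nucleus`, `helix_ppm`, `sheet_ppm`).
#' @return tibble of per-nucleus expected magnitudes (ppm).
#' @export
ssp_expected <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "ssp_expected.tsv", package = "ucoil")
  }
  readr::read_tsv(path, comment = "#", show_col_types = FALSE)
}

#' Secondary structure propensity (SSP) profile
#'
#' Windowed, helix-positive propensity score: within each window the observed
#' secondary shifts (Cbeta entering with inverted sign, since helical
#' sampling moves Cbeta upfield) are summed and divided by the sum of the
#' expected full-structure magnitudes — full-helix magnitudes when the window
#' consensus is helical (positive), full-sheet when it is extended. A score of
#' +1 therefore means 100% helix propensity and -1 means 100% strand; scores
#' are clamped to [-1, 1]. Shifts whose magnitude exceeds
#' `outlier_factor` times the expected full-structure value are excluded as
#' likely referencing or assignment outliers. Positions whose window holds
#' fewer than two usable shifts are returned as `NA`.
#'
#' @param deltas secondary shifts from [secondary_shifts()].
#' @param expected per-nucleus expected magnitudes from [ssp_expected()].
#' @param window odd window width (residues), default 5.
#' @param nuclei nuclei included in the score (default CA and CB).
#' @param outlier_factor exclusion threshold multiplier (default 3).
#' @return tibble `index`, `ssp`, `n_shifts`; attributes `window`, `nuclei`.
#' @export
ssp_profile <- function(deltas, expected = ssp_expected(), window = 5L,
                        nuclei = c("CA", "CB"), outlier_factor = 3) {
  window <- as.integer(window)
  if (window < 1L || window %% 2L == 0L) abort("window must be a positive odd integer")
  d <- deltas[deltas$nucleus %in% nuclei & is.finite(deltas$delta_ppm), ]
  if (nrow(d) == 0L) abort("no usable shifts for the requested nuclei")
  exp_h <- setNames(expected$helix_ppm, expected$nucleus)
  exp_s <- setNames(expected$sheet_ppm, expected$nucleus)
  keep <- abs(d$delta_ppm) <= outlier_factor * pmax(exp_h[d$nucleus], exp_s[d$nucleus])
  d <- d[keep, ]
  sign_eff <- ifelse(d$nucleus == "CB", -1, 1)
  d$eff <- sign_eff * d$delta_ppm
  half <- window %/% 2L
  idx <- sort(unique(deltas$index))
  scores <- vapply(idx, function(i) {
    w <- d[d$index >= i - half & d$index <= i + half, ]
    if (nrow(w) < 2L) return(NA_real_)
    num <- sum(w$eff)
    denom <- if (num >= 0) sum(exp_h[w$nucleus]) else sum(exp_s[w$nucleus])
    max(-1, min(1, num / denom))
  }, numeric(1))
  counts <- vapply(idx, function(i) {
    sum(d$index >= i - half & d$index <= i + half)
  }, numeric(1))
  out <- tibble(index = idx, ssp = scores, n_shifts = as.integer(counts))
  attr(out, "window") <- window
  attr(out, "nuclei") <- nuclei
  out
}

#' Mean helicity per helix region
#'
#' Arithmetic mean of the defined SSP scores inside each inclusive region
#' interval, expressed as percent helix.
#'
#' @param ssp profile from [ssp_profile()].
#' @param regions tibble from [helix_regions()].
#' @param min_scored minimum number of scored residues a region must overlap.
#' @return tibble `region`, `start`, `end`, `n_scored`, `helicity_pct`.
#' @export
region_helicity <- function(ssp, regions = helix_regions(), min_scored = 2L) {
  out <- purrr::pmap(regions, function(region, start, end) {
    s <- ssp$ssp[ssp$index >= start & ssp$index <= end]
    s <- s[!is.na(s)]
    if (length(s) < min_scored) {
      abort(sprintf("region %s overlaps only %d scored residues", region, length(s)))
    }
    tibble(region = region, start = start, end = end,
           n_scored = length(s), helicity_pct = 100 * mean(s))
  })
  bind_rows(out)
}
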