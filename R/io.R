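#' Read and write tab-separated tables with metadata headers
#'
#' The package's TSV dialect: tab-separated values, UTF-8, '.' decimal
#' separator, with optional leading metadata lines of the form `#key=value`.
#' Metadata are returned (and written) as a named list attribute `meta`.
#'
#' @param path file path.
#' @return `read_ucoil_tsv`: a tibble with attribute `meta`.
#' @export
read_ucoil_tsv <- function(path) {
  lines <- readr::read_lines(path)
  is_meta <- stringr::str_starts(lines, "#")
  meta_lines <- lines[cumsum(!is_meta) == 0]
  meta <- list()
  for (ml in meta_lines) {
    kv <- stringr::str_match(ml, "^#\\s*([^=]+)=(.*)$")
    if (!is.na(kv[1, 1])) {
      val <- stringr::str_trim(kv[1, 3])
      num <- suppressWarnings(as.numeric(val))
      meta[[stringr::str_trim(kv[1, 2])]] <- if (!is.na(num)) num else val
    }
  }
  tab <- readr::read_tsv(I(lines[!is_meta & nzchar(lines)]),
                         show_col_types = FALSE)
  attr(tab, "meta") <- meta
  tab
}

#' @rdname read_ucoil_tsv
#' @param x data frame to write.
#' @param meta named list of scalar metadata written as `#key=value` lines.
#' @return `write_ucoil_tsv`: `path`, invisibly.
#' @export
write_ucoil_tsv <- function(x, path, meta = list()) {
  header <- purrr::imap_chr(meta, function(v, k) sprintf("#%s=%s", k, format(v, scientific = FALSE)))
  body <- readr::format_tsv(x)
  readr::write_lines(c(header, sub("\n$", "", body)), path)
  invisible(path)
}

#' Run a multi-stage analysis from a configuration
#'
#' Executes the requested analysis stages in dependency order on a set of
#' input files and writes every stage's result (TSV for tables, JSON for
#' scalars) plus an echo of the configuration and a log to `out_dir`.
#' Supported stages: `simulate` (seeded R2 dataset), `r2-baseline` (scale
#' fit + baseline), `clusters`, `jcoupling`, `hydro`, `unfold-fit`,
#' `helicity`, `gamma`. Any stage failure aborts with the stage name.
#'
#' @param config named list (or path to a JSON file) with elements `stages`
#'   (character vector), `out_dir`, `seed`, plus per-stage parameter lists
#'   (`sequence`, `r2_tsv`, `hnha_tsv`, `hydro`, `curve_tsv`, `helicity`,
#'   `gamma` as applicable). Unknown top-level keys are rejected.
#' @return named list of per-stage results, invisibly; side effect: files in
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  known <- c("stages", "out_dir", "seed", "sequence", "simulate", "r2_tsv",
             "hnha_tsv", "hydro", "curve_tsv", "helicity", "gamma",
             "cluster_min_run", "cluster_z")
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0L) {
    abort(sprintf("unknown configuration keys: %s", paste(unknown, collapse = ", ")))
  }
  out_dir <- config$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(config$seed %||% 1L)
  log <- c(sprintf("ucoil %s", as.character(utils::packageVersion("ucoil"))),
           sprintf("seed=%d", seed))
  results <- list()

  seq <- if (!is.null(config$sequence)) {
    do.call(load_sequence, as.list(config$sequence))
  } else {
    im7_sequence(c("L18A", "L19A", "L37A"))
  }

  run_stage <- function(name, fn) {
    tryCatch(fn(), error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  for (stage in config$stages) {
    if (stage == "simulate") {
      results$simulate <- run_stage("simulate", function() {
        args <- c(list(seq = seq, seed = seed), config$simulate)
        sim <- do.call(simulate_r2_dataset, args)
        write_ucoil_tsv(sim$observed, file.path(out_dir, "simulated_r2.tsv"),
                        meta = list(seed = seed))
        sim
      })
    } else if (stage == "r2-baseline") {
      results$r2_baseline <- run_stage("r2-baseline", function() {
        obs <- if (!is.null(config$r2_tsv)) read_ucoil_tsv(config$r2_tsv)
               else results$simulate$observed
        if (is.null(obs)) abort("no observed R2 input (r2_tsv or simulate stage)")
        fit <- fit_scale_factor(obs, seq)
        write_ucoil_tsv(fit$baseline, file.path(out_dir, "r2_baseline.tsv"),
                        meta = list(scale = fit$scale, n_used = fit$n_used))
        c(fit, list(observed = obs))
      })
    } else if (stage == "clusters") {
      results$clusters <- run_stage("clusters", function() {
        if (is.null(results$r2_baseline)) abort("clusters requires the r2-baseline stage")
        cl <- detect_clusters(results$r2_baseline$observed,
                              results$r2_baseline$baseline,
                              min_run = config$cluster_min_run %||% 3L,
                              z = config$cluster_z %||% 2)
        write_ucoil_tsv(cl, file.path(out_dir, "clusters.tsv"))
        cl
      })
    } else if (stage == "jcoupling") {
      results$jcoupling <- run_stage("jcoupling", function() {
        if (is.null(config$hnha_tsv)) abort("jcoupling requires hnha_tsv")
        tab <- read_ucoil_tsv(config$hnha_tsv)
        meta <- attr(tab, "meta")
        rec <- j_from_hnha(tab$i_cross, tab$i_diag,
                           delta = meta$delta_s %||% 0.01254,
                           noise = tab$noise %||% 0, index = tab$index)
        write_ucoil_tsv(rec, file.path(out_dir, "jcouplings.tsv"))
        rec
      })
    } else if (stage == "hydro") {
      results$hydro <- run_stage("hydro", function() {
        if (is.null(config$hydro)) abort("hydro requires a 'hydro' parameter block")
        rec <- do.call(sedimentation_chain, as.list(config$hydro))
        jsonlite::write_json(as.list(rec), file.path(out_dir, "hydro.json"),
                             auto_unbox = TRUE, digits = NA)
        rec
      })
    } else if (stage == "unfold-fit") {
      results$unfold_fit <- run_stage("unfold-fit", function() {
        if (is.null(config$curve_tsv)) abort("unfold-fit requires curve_tsv")
        curve <- read_ucoil_tsv(config$curve_tsv)
        fit <- fit_two_state(curve)
        write_ucoil_tsv(tidy(fit), file.path(out_dir, "two_state_fit.tsv"))
        fit
      })
    } else if (stage == "helicity") {
      results$helicity <- run_stage("helicity", function() {
        p <- config$helicity
        if (is.null(p)) abort("helicity requires a 'helicity' parameter block")
        val <- helical_content(p$mre_variant, p$mre_wt)
        jsonlite::write_json(list(helix_pct = val),
                             file.path(out_dir, "helicity.json"),
                             auto_unbox = TRUE, digits = NA)
        val
      })
    } else if (stage == "gamma") {
      results$gamma <- run_stage("gamma", function() {
        p <- config$gamma
        if (is.null(p)) abort("gamma requires a 'gamma' parameter block")
        g <- gamma_value(p$l_sample, p$l_control)
        jsonlite::write_json(as.list(g), file.path(out_dir, "gamma.json"),
                             auto_unbox = TRUE, digits = NA)
        g
      })
    } else {
      abort(sprintf("unknown stage '%s'", stage))
    }
    log <- c(log, sprintf("stage %s: ok", stage))
  }
  jsonlite::write_json(config, file.path(out_dir, "config_echo.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  readr::write_lines(log, file.path(out_dir, "run.log"))
  invisible(results)
}
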