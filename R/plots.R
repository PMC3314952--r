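#' Diagnostic plots
#'
#' Simple ggplot2 diagnostics for the main result types: observed R2 rates
#' against the intrinsic baseline with detected clusters shaded, the SSP
#' profile with helix regions shaded, and a denaturation curve with its
#' two-state fit.
#'
#' @param observed,baseline R2 profile tibbles (`index`, `rate`, opt. `err`).
#' @param clusters optional cluster table from [detect_clusters()].
#' @return a ggplot object.
#' @export
plot_r2_profile <- function(observed, baseline = NULL, clusters = NULL) {
  p <- ggplot(observed, aes(x = .data$index, y = .data$rate))
  if (!is.null(clusters) && nrow(clusters) > 0) {
    p <- p + geom_rect(data = clusters,
                       aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
                       ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "firebrick",
                       inherit.aes = FALSE)
  }
  if ("err" %in% names(observed)) {
    p <- p + geom_errorbar(aes(ymin = .data$rate - .data$err,
                               ymax = .data$rate + .data$err), width = 0)
  }
  p <- p + geom_point()
  if (!is.null(baseline)) {
    p <- p + geom_line(data = baseline, linetype = "dashed", colour = "grey30")
  }
  p + labs(x = "residue", y = expression(R[2] ~ (s^-1)))
}

#' @rdname plot_r2_profile
#' @param ssp profile from [ssp_profile()].
#' @param regions helix regions from [helix_regions()].
#' @export
plot_ssp_profile <- function(ssp, regions = NULL) {
  p <- ggplot(ssp, aes(x = .data$index, y = .data$ssp))
  if (!is.null(regions)) {
    p <- p + geom_rect(data = regions,
                       aes(xmin = .data$start - 0.5, xmax = .data$end + 0.5),
                       ymin = -Inf, ymax = Inf, alpha = 0.15, fill = "steelblue",
                       inherit.aes = FALSE)
  }
  p + geom_hline(yintercept = 0, colour = "grey60") +
    geom_col() +
    labs(x = "residue", y = "SSP (helix-positive)")
}

#' @rdname plot_r2_profile
#' @param object a `two_state_fit`.
#' @param ... unused.
#' @method autoplot two_state_fit
#' @export
autoplot.two_state_fit <- function(object, ...) {
  ggplot(object$fitted, aes(x = .data$urea)) +
    geom_point(aes(y = .data$signal)) +
    geom_line(aes(y = .data$fit), colour = "firebrick") +
    labs(x = "[urea] (M)", y = "signal",
         subtitle = sprintf("dG(unfold) = %.1f kJ/mol, m = %.2f kJ/mol/M, midpoint %.2f M",
                            object$estimates$estimate[object$estimates$term == "dG"],
                            object$estimates$estimate[object$estimates$term == "m"],
                            object$midpoint_M))
}
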