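#' Plot an intensity trace with its binarization
#'
#' @param tr an [build_intensity_trace()] trace.
#' @param bt optional [binarize_otsu()] result; RBC intervals are shaded and
#'   the threshold drawn.
#' @return a ggplot.
#' @export
plot_intensity_trace <- function(tr, bt = NULL) {
  p <- ggplot2::ggplot(tr, ggplot2::aes(x = .data$time_s, y = .data$counts)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)", y = "photons / cycle")
  if (!is.null(bt)) {
    if (nrow(bt$rbc_intervals) > 0) {
      p <- p + ggplot2::geom_rect(
        data = bt$rbc_intervals,
        ggplot2::aes(xmin = .data$start_s, xmax = .data$end_s),
        ymin = -Inf, ymax = Inf, alpha = 0.2, fill = "red",
        inherit.aes = FALSE
      )
    }
    if (is.finite(bt$threshold)) {
      p <- p + ggplot2::geom_hline(yintercept = bt$threshold,
                                   linetype = "dashed", colour = "grey40")
    }
  }
  p
}

#' Plot flux and pO2 of one capillary over a session
#'
#' @param ts an [analyze_session()] table.
#' @param capillary_id capillary to plot.
#' @return a ggplot (pO2 and flux stacked on a free y scale).
#' @export
plot_capillary_series <- function(ts, capillary_id) {
  d <- ts[ts$capillary_id == capillary_id, ]
  long <- tidyr::pivot_longer(
    d[, c("visit_time_s", "po2", "flux")],
    cols = c("po2", "flux"), names_to = "measure", values_to = "value"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$visit_time_s, y = .data$value)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(po2 = "pO2 (mmHg)", flux = "flux (RBC/s)"))) +
    ggplot2::labs(x = "session time (s)", y = NULL, title = capillary_id)
}

#' Plot peri-stall aligned dynamics
#'
#' @param summary a [summarize_peri_stall()] table.
#' @return a ggplot of mean +/- SD pO2 and flux against visit offset
#'   (stall at 0).
#' @export
plot_peri_stall <- function(summary) {
  long <- dplyr::bind_rows(
    tb(offset = summary$offset, mean = summary$po2_mean,
       sd = summary$po2_sd, measure = "pO2 (mmHg)"),
    tb(offset = summary$offset, mean = summary$flux_mean,
       sd = summary$flux_sd, measure = "flux (RBC/s)")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset, y = .data$mean)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~measure, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "visits relative to stall (stall at 0)", y = NULL)
}

#' Plot an EAT oxygen profile
#'
#' @param prof an [build_eat_profile()] result.
#' @param tissue optional [estimate_tissue_po2()] row to draw as a plateau
#'   reference.
#' @return a ggplot of per-bin pO2 against distance to the nearest RBC.
#' @export
plot_eat_profile <- function(prof, tissue = NULL) {
  d <- prof[prof$sufficient, ]
  p <- ggplot2::ggplot(d, ggplot2::aes(
    x = (.data$bin_lo_um + .data$bin_hi_um) / 2, y = .data$po2)) +
    ggplot2::geom_line() + ggplot2::geom_point(ggplot2::aes(size = .data$n_photons)) +
    ggplot2::scale_size_continuous(range = c(0.5, 2.5), guide = "none") +
    ggplot2::labs(x = "distance to nearest RBC (um)", y = "pO2 (mmHg)")
  if (!is.null(tissue) && isTRUE(tissue$sufficient)) {
    p <- p +
      ggplot2::geom_hline(yintercept = tissue$tissue_po2, linetype = "dashed") +
      ggplot2::geom_vline(xintercept = tissue$plateau_cutoff_um,
                          linetype = "dotted", colour = "grey40")
  }
  p
}

#' Plot stall pO2 against estimated tissue pO2 with per-group fits
#'
#' @param cmp the event comparison table handed to [fit_stall_vs_tissue()].
#' @param fit the resulting `stall_tissue_fit`.
#' @return a ggplot with the identity line and the per-group OLS fits.
#' @export
plot_stall_vs_tissue <- function(cmp, fit) {
  if (!"group" %in% names(cmp)) cmp$group <- "all"
  ggplot2::ggplot(cmp, ggplot2::aes(x = .data$tissue_po2, y = .data$stall_po2,
                                    colour = .data$group)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = fit,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept,
                   colour = .data$group),
      linetype = "dashed"
    ) +
    ggplot2::labs(x = "estimated tissue pO2 (mmHg)", y = "stall pO2 (mmHg)")
}

#' Plot mean vessel-density curves by hypoxia class
#'
#' @param cmp a [compare_density_by_class()] table.
#' @return a ggplot of mean density counts against distance.
#' @export
plot_density_by_class <- function(cmp) {
  ggplot2::ggplot(cmp, ggplot2::aes(
    x = (.data$bin_lo_um + .data$bin_hi_um) / 2, y = .data$mean_count,
    colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance from stall (um)",
                  y = "vessel density (voxel counts, a.u.)")
}
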