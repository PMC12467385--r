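#' Plot the training loss history
#'
#' Log-log decay of the per-vessel physics losses, per-vessel data
#' losses, the bifurcation interface loss and the total.
#'
#' @param object A [train_pinn()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pinn_model <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                  colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "epoch", y = "loss",
                  title = "Composite loss decay") +
    ggplot2::theme_minimal()
}

#' Plot junction conservation of a reference solution
#'
#' Volume flux of the parent against the summed daughter fluxes, and the
#' total pressure of the three vessels, at the bifurcation over one
#' cycle.
#'
#' @param object A [solve_bifurcation()] result.
#' @param ... Unused.
#' @return A ggplot object (two stacked panels).
#' @exportS3Method ggplot2::autoplot
autoplot.bifurcation_solution <- function(object, ...) {
  jn <- object$junction
  rho <- object$problem$fluid$rho
  d <- dplyr::bind_rows(
    tibble(t_s = jn$t_s, value = jn$A1 * jn$u1 * 1e6,
           series = "parent flow", panel = "flow (mL/s)"),
    tibble(t_s = jn$t_s, value = (jn$A2 * jn$u2 + jn$A3 * jn$u3) * 1e6,
           series = "daughters flow", panel = "flow (mL/s)"),
    tibble(t_s = jn$t_s, value = pa_to_mmhg(jn$p1 + 0.5 * rho * jn$u1^2),
           series = "parent", panel = "total pressure (mmHg)"),
    tibble(t_s = jn$t_s, value = pa_to_mmhg(jn$p2 + 0.5 * rho * jn$u2^2),
           series = "daughter 1", panel = "total pressure (mmHg)"),
    tibble(t_s = jn$t_s, value = pa_to_mmhg(jn$p3 + 0.5 * rho * jn$u3^2),
           series = "daughter 2", panel = "total pressure (mmHg)"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$t_s, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~panel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL,
                  title = "Junction conservation over one cycle") +
    ggplot2::theme_minimal()
}

#' Space-time surface plot of one predicted or solved field
#'
#' @param fields Field tibble (`x_m`, `t_s`, plus the value column), e.g.
#'   from [predict_fields()] or [solution_fields()].
#' @param field One of `"pressure_pa"`, `"area_m2"`, `"velocity_m_s"`.
#' @return A ggplot raster, faceted by vessel when several are present.
#' @export
plot_field_surface <- function(fields, field = "pressure_pa") {
  if (!field %in% names(fields))
    abort(paste0("column `", field, "` not found."))
  p <- ggplot2::ggplot(fields,
                       ggplot2::aes(x = .data$x_m * 100, y = .data$t_s,
                                    fill = .data[[field]])) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "x (cm)", y = "t (s)", fill = field) +
    ggplot2::theme_minimal()
  if ("vessel_id" %in% names(fields) &&
      length(unique(fields$vessel_id)) > 1L)
    p <- p + ggplot2::facet_wrap(~vessel_id, scales = "free_x")
  p
}
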