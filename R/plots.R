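#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-step summary of a quasi-static solution
#'
#' @param x an `aaa_solution`.
#' @param ... unused.
#' @return A tibble with one row per recorded state: pressure, maximum first
#'   principal stress, maximum equivalent strain, maximum displacement
#'   magnitude, iteration count and convergence flag.
#' @export
tidy.aaa_solution <- function(x, ...) {
  dplyr::bind_rows(lapply(seq_along(x$states), function(k) {
    st <- x$states[[k]]
    tibble::tibble(
      step = k,
      pressure_mmHg = st$pressure,
      load_factor = st$load_factor,
      max_sigma1 = max(field_sigma1(st$cauchy_stress)),
      max_eq_strain = max(field_eq_strain(st$green_strain)),
      max_displacement = max(sqrt(rowSums(st$displacements^2))),
      iterations = st$iterations,
      converged = st$converged
    )
  }))
}

#' One-row summary of a quasi-static solution
#' @inheritParams tidy.aaa_solution
#' @return A one-row tibble describing the final state and the model size.
#' @export
glance.aaa_solution <- function(x, ...) {
  st <- x$states[[length(x$states)]]
  tibble::tibble(
    final_pressure_mmHg = st$pressure,
    max_sigma1 = max(field_sigma1(st$cauchy_stress)),
    max_eq_strain = max(field_eq_strain(st$green_strain)),
    n_elements = nrow(x$mesh$tets),
    n_nodes = nrow(x$mesh$nodes),
    n_states = length(x$states),
    converged = all(vapply(x$states, function(s) s$converged, logical(1)))
  )
}

#' Bar plot of the regional stress/strain summary
#'
#' Mirrors the ILT-free versus ILT-covered wall comparison: average and
#' maximum first principal stress and equivalent strain per region.
#'
#' @param object a [regional_summary()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.regional_summary <- function(object, ...) {
  df <- dplyr::filter(object, .data$region != "ILT")
  long <- dplyr::bind_rows(
    tibble::tibble(region = df$region, stat = "avg sigma1 (MPa)",
                   value = df$avg_sigma1),
    tibble::tibble(region = df$region, stat = "max sigma1 (MPa)",
                   value = df$max_sigma1),
    tibble::tibble(region = df$region, stat = "avg eq. strain",
                   value = df$avg_eq_strain),
    tibble::tibble(region = df$region, stat = "max eq. strain",
                   value = df$max_eq_strain)
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$stat, y = .data$value,
                                     fill = .data$region)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~stat, scales = "free") +
    ggplot2::scale_fill_manual(values = c(WALL_ILT_FREE = "#3366cc",
                                          WALL_ILT_COVERED = "#cc3333")) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = "Wall loading by thrombus coverage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}

#' Stress evolution with pressure
#'
#' Maximum first principal wall stress per recorded step, with the wall
#' tensile-strength limit for reference.
#'
#' @param object an `aaa_solution`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.aaa_solution <- function(object, ...) {
  df <- tidy(object)
  uts <- uts_wall(0.0593, 0.0895)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pressure_mmHg,
                                   y = .data$max_sigma1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = uts, linetype = 2, colour = "darkgreen") +
    ggplot2::annotate("text", x = min(df$pressure_mmHg), y = uts,
                      label = "wall UTS", vjust = -0.5, hjust = 0, size = 3) +
    ggplot2::labs(x = "intraluminal pressure (mmHg)",
                  y = "max principal stress (MPa)") +
    ggplot2::theme_minimal()
}

#' Mesh-sensitivity deviation plot
#'
#' @param report a [mesh_sensitivity_report()] tibble.
#' @return A ggplot object.
#' @export
plot_mesh_sensitivity <- function(report) {
  ggplot2::ggplot(report, ggplot2::aes(x = .data$level,
                                       y = .data$max_sigma1, group = 1)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "resolution level", y = "max principal stress (MPa)") +
    ggplot2::theme_minimal()
}
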