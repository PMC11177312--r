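#' Stacked yield/fidelity barplot for a fidelity report
#'
#' Position-wise frequencies of complementary incorporation, mismatched
#' incorporation and no extension, stacked so each bar sums to 1.
#'
#' @param object A [fidelity_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fidelity_report <- function(object, ...) {
  df <- object$position_frequencies |>
    tidyr::pivot_longer(-"position", names_to = "class",
                        values_to = "frequency") |>
    dplyr::mutate(class = factor(
      .data$class,
      levels = c("f_unextended", "f_mismatch", "f_comp"),
      labels = c("unextended", "mismatch", "complementary")
    ))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position), y = .data$frequency, fill = .data$class
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(
      unextended = "grey85", mismatch = "#d95f02", complementary = "#1b9e77"
    )) +
    ggplot2::labs(
      x = "position", y = "frequency", fill = NULL,
      title = paste0(object$system, " system (", object$n_reads, " reads)")
    ) +
    ggplot2::theme_minimal()
}

#' Product-base distribution heatmap
#'
#' @param report A [fidelity_report()].
#' @return A ggplot object.
#' @export
plot_product_distribution <- function(report) {
  sys <- chemistry_system(report$system)
  df <- report$product_base_distribution |>
    dplyr::select(-"n_reads") |>
    tidyr::pivot_longer(-"position", names_to = "base",
                        values_to = "frequency") |>
    dplyr::mutate(base = factor(.data$base, levels = sys$alphabet))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position), y = .data$base, fill = .data$frequency
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$frequency)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, NA)) +
    ggplot2::labs(x = "position", y = "product base",
                  title = paste(report$system, "product base distribution")) +
    ggplot2::theme_minimal()
}

#' Frequency-ratio heatmap between two systems
#'
#' Ratios above 1 (enriched in the numerator system) in red, below 1 in
#' blue, mirroring the usual two-system comparison display.
#'
#' @param ratios A [system_ratio()] object.
#' @return A ggplot object.
#' @export
plot_system_ratio <- function(ratios) {
  sys <- chemistry_system(ratios$system_num)
  df <- ratios$product_base |>
    dplyr::mutate(base = factor(.data$base, levels = sys$alphabet))
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$position), y = .data$base, fill = log2(.data$ratio)
  )) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = ifelse(.data$undefined, "NA", sprintf("%.2f", .data$ratio))),
      size = 3) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(
      x = "position", y = "product base",
      fill = "log2 ratio",
      title = paste0(ratios$system_num, " / ", ratios$system_den,
                     " product-base frequency ratio")
    ) +
    ggplot2::theme_minimal()
}

#' Fitted-curve plots for kinetic fits
#'
#' @param object A `first_order_fit` or `mm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot_kinetics
#' @export
autoplot.first_order_fit <- function(object, ...) {
  grid <- tibble::tibble(
    time = seq(0, max(object$data$time), length.out = 200)
  )
  grid$fraction <- object$plateau * (1 - exp(-object$kobs * grid$time))
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$time, y = .data$fraction)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "time (h)", y = "fraction extended",
      title = sprintf("kobs = %.3g h⁻¹, plateau = %.2f",
                      object$kobs, object$plateau)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot_kinetics
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(
    concentration = seq(min(object$data$concentration) / 2,
                        max(object$data$concentration), length.out = 200)
  )
  grid$kobs <- object$kobs_max * grid$concentration /
    (object$Km + grid$concentration)
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$concentration, y = .data$kobs)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "#2c7fb8") +
    ggplot2::labs(
      x = "concentration (mM)", y = expression(k[obs] ~ (h^-1)),
      title = sprintf("kobs_max = %.3g h⁻¹, Km = %.3g mM",
                      object$kobs_max, object$Km)
    ) +
    ggplot2::theme_minimal()
}
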