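#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Trace and density plots for a Gibbs fit
#'
#' Faceted trace plots (and marginal densities) of the retained
#' variance-component draws, the standard convergence check for this
#' sampler.
#'
#' @param object An [fit_multibreed()] object.
#' @param type `"trace"` or `"density"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swt_fit
#' @export
autoplot.swt_fit <- function(object, type = c("trace", "density"), ...) {
  type <- match.arg(type)
  df <- as_tibble(object$draws)
  df$iteration <- seq_len(nrow(df))
  long <- tidyr::pivot_longer(df, -"iteration",
    names_to = "component", values_to = "value"
  )
  if (type == "trace") {
    ggplot2::ggplot(long, ggplot2::aes(.data$iteration, .data$value)) +
      ggplot2::geom_line(linewidth = 0.2) +
      ggplot2::facet_wrap(~component, scales = "free_y") +
      ggplot2::labs(
        x = "retained iteration", y = "variance draw",
        title = "Variance-component traces"
      )
  } else {
    ggplot2::ggplot(long, ggplot2::aes(.data$value)) +
      ggplot2::geom_density() +
      ggplot2::facet_wrap(~component, scales = "free") +
      ggplot2::labs(x = "variance", y = "posterior density")
  }
}

#' Empirical versus predicted covariances from the gene-dropping oracle
#'
#' Scatter of Monte-Carlo covariances against tabular-method predictions
#' with 3-standard-error bars; pairs affected by the synthetic-doubling
#' scoring ambiguity are highlighted.
#'
#' @param object A [gene_drop()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot swt_genedrop
#' @export
autoplot.swt_genedrop <- function(object, ...) {
  rep <- object$report
  ggplot2::ggplot(
    rep,
    ggplot2::aes(.data$predicted, .data$empirical, colour = .data$s_affected)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$empirical - 3 * .data$se,
        ymax = .data$empirical + 3 * .data$se
      ),
      width = 0
    ) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "tabular-method prediction", y = "gene-dropping covariance",
      colour = "doubling-affected"
    )
}

#' Variance decomposition across backcross generations
#'
#' Bar chart of additive versus segregation variance by percent synthetic
#' genome, the package's analogue of the per-cross variance table.
#'
#' @param object A [group_variances()] tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_group_variances <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object[, c("cross", "pct_synthetic", "additive", "segregation")],
    c("additive", "segregation"),
    names_to = "part", values_to = "variance"
  )
  ggplot2::ggplot(
    long,
    ggplot2::aes(factor(.data$pct_synthetic), .data$variance,
      fill = .data$part
    )
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "% synthetic genome", y = "variance (trait units squared)",
      fill = NULL
    )
}
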