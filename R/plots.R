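#' Plot group-mean biomarker profiles
#'
#' Group means (with standard-error bars) of each age/sex-corrected,
#' z-scaled biomarker across the four severity groups, alongside the group
#' mean symptom severity — the layout of the group-separation figure.
#'
#' @param summary A `group_summary` from [group_profile()].
#' @return A ggplot object.
#' @export
plot_group_profile <- function(summary) {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$group, y = .data$mean,
                               group = .data$biomarker)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.15) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::facet_wrap(~biomarker) +
    ggplot2::labs(x = NULL, y = "group mean (z, age/sex-corrected)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.group_summary <- function(object, ...) plot_group_profile(object)

#' Scatter plot of two association-profile t vectors
#'
#' Per-test t-scores of one profile against another (e.g. a biomarker's
#' cognition profile versus the case-control deficit profile), annotated with
#' the pattern correlation.
#'
#' @param a,b `association_profile` tibbles over the same tests.
#' @return A ggplot object.
#' @export
plot_profile_comparison <- function(a, b) {
  cmp <- compare_profiles(a, b)
  dat <- tibble(test = a$test, t_a = a$t, t_b = b$t)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$t_b, y = .data$t_a)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey70", linewidth = 0.5) +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$test), vjust = -0.7,
                       size = 3) +
    ggplot2::labs(
      x = paste0("t (", cmp$profile_b, ")"),
      y = paste0("t (", cmp$profile_a, ")"),
      subtitle = sprintf("pattern r = %.2f (df = %d)", cmp$pattern_r, cmp$df)) +
    ggplot2::theme_minimal()
}

#' Bar chart of an association profile
#'
#' Per-test t-scores of a single profile, the layout of the cognitive-deficit
#' figure.
#'
#' @param profile An `association_profile`.
#' @param alpha Significance threshold used to highlight tests.
#' @return A ggplot object.
#' @export
plot_association_profile <- function(profile, alpha = 0.05) {
  dat <- mutate(as_tibble(unclass(profile)),
                significant = !is.na(.data$p) & .data$p < alpha)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$test, y = .data$t,
                                    fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "goldenrod",
                                          `FALSE` = "grey65"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "t",
                  title = attr(profile, "profile")) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @export
autoplot.association_profile <- function(object, ...) {
  plot_association_profile(object, ...)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
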