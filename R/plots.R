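#' Plot per-group error patterns
#'
#' Dot-and-summary plot of the three error-type percentages by diagnostic
#' group, the standard way variant-specific error profiles are displayed.
#'
#' @param profiles Subject profile tibble (see [subject_profiles()]).
#' @return A ggplot object.
#' @export
plot_error_patterns <- function(profiles) {
  long <- profiles %>%
    filter(.data$group != "HC") %>%
    tidyr::pivot_longer(
      c("pct_not_verb", "pct_unrelated_verb", "pct_missing"),
      names_to = "error_type", values_to = "pct"
    ) %>%
    mutate(error_type = factor(
      .data$error_type,
      levels = c("pct_not_verb", "pct_unrelated_verb", "pct_missing"),
      labels = c("not a verb", "unrelated verb", "missing")
    ))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$group, y = .data$pct)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.5, size = 1) +
    ggplot2::stat_summary(fun = mean, geom = "crossbar",
                          width = 0.5, colour = "darkorange") +
    ggplot2::facet_wrap(~error_type) +
    ggplot2::labs(x = NULL, y = "% of trials") +
    ggplot2::theme_minimal()
}

#' Plot per-noun agreement profiles
#'
#' Entropy against ASI for every noun; low-entropy, high-ASI nouns have one
#' dominant verb associate, high-entropy nouns many competing ones.
#'
#' @param agreement Output of [agreement_profiles()].
#' @return A ggplot object.
#' @export
plot_agreement_profiles <- function(agreement) {
  ggplot2::ggplot(
    agreement,
    ggplot2::aes(x = .data$asi, y = .data$entropy, size = .data$csi)
  ) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "Association Strength Index (%)",
      y = "response entropy (bits)",
      size = "CSI"
    ) +
    ggplot2::theme_minimal()
}
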