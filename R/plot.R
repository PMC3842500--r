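## Simple QC figures (ggplot2, suggested dependency).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
}

#' Heatmap of a connectivity matrix
#' @param cm a `connectivity_matrix`.
#' @return a ggplot object.
#' @export
plot_connectivity <- function(cm) {
  need_ggplot()
  df <- as.data.frame(cm)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$seed,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, cm$n_initiated)) +
    ggplot2::labs(x = "target region", y = "seed ROI",
                  fill = "max\nconnectivity") +
    ggplot2::theme_minimal()
}

#' Participant-count map of a group profile
#' @param profile a `group_profile`.
#' @return a ggplot object.
#' @export
plot_group_profile <- function(profile) {
  need_ggplot()
  df <- as.data.frame(profile)
  df$criterion <- ifelse(df$strict_pass, "strict",
                         ifelse(df$relaxed_pass, "relaxed", "none"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$target, y = .data$seed)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$participant_count)) +
    ggplot2::geom_text(ggplot2::aes(label = paste0(
      .data$participant_count,
      ifelse(df$criterion == "strict", "*",
             ifelse(df$criterion == "relaxed", "+", ""))))) +
    ggplot2::scale_fill_viridis_c(
      limits = c(0, attr(profile, "n_participants"))) +
    ggplot2::labs(x = "target region", y = "seed ROI",
                  fill = "participants\nabove threshold",
                  caption = "* strict criterion, + relaxed criterion") +
    ggplot2::theme_minimal()
}
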