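methylmap_class_colors <- c(
  strong = "#8b0000", slight = "#e06666", unaffected = "grey55",
  excluded = "black", "no-data" = "black", extension = "#e6c229"
)

#' Plot a methyl classification profile
#'
#' Relative signal intensity per residue at the evaluation point, with the
#' mean (dashed) and the strong/slight thresholds drawn as horizontal
#' lines - the per-residue view used to read off affected methyls.
#'
#' @param object A `methyl_classification` from [classify_methyls()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.methyl_classification <- function(object, ...) {
  d <- object$probes |> filter(.data$class != "excluded")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$resno, y = .data$r)) +
    ggplot2::geom_hline(yintercept = object$mu, linetype = "dashed") +
    ggplot2::geom_hline(yintercept = object$t_slight,
                        colour = methylmap_class_colors["slight"]) +
    ggplot2::geom_hline(yintercept = object$t_strong,
                        colour = methylmap_class_colors["strong"]) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$resno, yend = 0,
                                       colour = .data$class)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 1.6) +
    ggplot2::scale_colour_manual(values = methylmap_class_colors) +
    ggplot2::labs(x = "residue number", y = "relative signal intensity",
                  colour = NULL,
                  title = sprintf("Methyl classification at %s", object$point),
                  subtitle = sprintf(
                    "mean %.2f; thresholds %.2f (strong) / %.2f (slight)",
                    object$mu, object$t_strong, object$t_slight)) +
    ggplot2::theme_minimal()
}

#' Plot a residue classification map
#'
#' One tile per residue along the sequence, colored by class with
#' extension-flagged residues in yellow - a flat rendering of the colored
#' surface view.
#'
#' @param rc Residue classification tibble (after
#'   [extend_classification()]).
#' @return A ggplot object.
#' @export
plot_residue_classification <- function(rc) {
  d <- as_tibble(rc) |>
    mutate(shown = ifelse(.data$extension & !(.data$class %in%
                                                c("strong", "slight")),
                          "extension", as.character(.data$class)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$resno, y = .data$chain,
                                  fill = .data$shown)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.2) +
    ggplot2::scale_fill_manual(values = methylmap_class_colors) +
    ggplot2::labs(x = "residue number", y = "chain", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot restraint violations across an ensemble
#'
#' @param object A `restraint_validation` from [violation_stats()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.restraint_validation <- function(object, ...) {
  ggplot2::ggplot(object$per_restraint,
                  ggplot2::aes(x = .data$restraint, y = .data$violation,
                               group = .data$restraint)) +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$model)),
                        alpha = 0.6, size = 1) +
    ggplot2::labs(x = "restraint index", y = "violation (Å)",
                  colour = "model",
                  subtitle = sprintf("rms %.4f ± %.4f Å, max %.3f Å",
                                     object$rms, object$rms_sd,
                                     object$max_violation)) +
    ggplot2::theme_minimal()
}
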