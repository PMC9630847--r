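# ggplot2 helpers for the main result types.

#' Kaplan-Meier curves for a two-group comparison
#'
#' Step curves of the per-group KM estimates attached to a [km_logrank()]
#' result, annotated with the log-rank p-value.
#'
#' @param logrank Result of [km_logrank()] (carries the `km_fit` attribute).
#' @return A ggplot object.
#' @export
plot_km_curves <- function(logrank) {
  km <- attr(logrank, "km_fit")
  if (is.null(km)) abort("No KM fit attached; run km_logrank() first.")
  strata <- rep(names(km$strata), km$strata)
  df <- tibble(time = km$time, surv = km$surv,
               group = sub("^groups=", "", strata))
  anchor <- df |> group_by(.data$group) |>
    summarise(time = 0, surv = 1, .groups = "drop")
  ggplot2::ggplot(bind_rows(anchor, df),
                  ggplot2::aes(x = .data$time, y = .data$surv,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::annotate("text", x = Inf, y = 1, hjust = 1.1, vjust = 1,
                      label = sprintf("log-rank p = %.2g",
                                      logrank$p_value)) +
    ggplot2::labs(x = "Time", y = "Survival probability",
                  colour = "Score group") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Score distribution split at the selected cut-point
#'
#' @param object A `ptp_score_result`.
#' @param cutpoint One-row tibble from [optimal_cutpoint()] (optional).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ptp_score_result <- function(object, cutpoint = NULL, ...) {
  p <- ggplot2::ggplot(tidy(object), ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::labs(x = "Hazard-weighted score", y = "Patients") +
    ggplot2::theme_minimal()
  if (!is.null(cutpoint)) {
    p <- p + ggplot2::geom_vline(xintercept = cutpoint$cutpoint,
                                 linetype = "dashed", colour = "red")
  }
  p
}

#' Volcano-style view of a drug-association screen
#'
#' Tested feature-drug pairs as Rs versus -log10(FDR), colored by the
#' sensitive/resistant call of the retained pairs.
#'
#' @param assoc Result of [gene_drug_screen()] or [score_drug_screen()].
#' @param rs_threshold,fdr_threshold Thresholds to draw as guides.
#' @return A ggplot object.
#' @export
plot_drug_associations <- function(assoc, rs_threshold = 0.25,
                                   fdr_threshold = 0.05) {
  tested <- attr(assoc, "tested")
  if (is.null(tested)) abort("`assoc` must come from a drug screen call.")
  tested <- tested |>
    left_join(select(assoc, "feature", "drug", "label"),
              by = c("feature", "drug")) |>
    mutate(label = dplyr::coalesce(.data$label, "not retained"))
  ggplot2::ggplot(tested,
                  ggplot2::aes(x = .data$rho, y = -log10(.data$fdr),
                               colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = c(-rs_threshold, rs_threshold),
                        linetype = "dotted") +
    ggplot2::geom_hline(yintercept = -log10(fdr_threshold),
                        linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(sensitive = "#2166AC",
                                            resistant = "#B2182B",
                                            `not retained` = "grey70")) +
    ggplot2::labs(x = "Spearman Rs", y = "-log10 FDR", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Bar chart of the top MCC hub nodes
#'
#' @param scores Tibble from [mcc_scores()].
#' @param k Number of top nodes to show.
#' @return A ggplot object.
#' @export
plot_mcc_hubs <- function(scores, k = 20L) {
  top <- scores |>
    arrange(dplyr::desc(.data$mcc), .data$node) |>
    head(k) |>
    mutate(node = factor(.data$node, levels = rev(.data$node)))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$mcc, y = .data$node)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "Maximal Clique Centrality", y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
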