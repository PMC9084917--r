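#' Plot predicted vs. actual heavy-atom RMSD
#'
#' Scatter of model predictions against true HA RMSD for a set of decoys,
#' with the identity line; the tighter the cloud hugs the diagonal, the
#' better the function ranks decoys.
#'
#' @param model a `decoy_model`.
#' @param fm a `feature_matrix` with `target_ha_rmsd`.
#' @return a ggplot object.
#' @export
plot_predictions <- function(model, fm) {
  df <- tibble(actual = fm$target_ha_rmsd, predicted = predict(model, fm))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "red") +
    ggplot2::labs(x = "actual HA RMSD (Å)", y = "predicted HA RMSD (Å)",
                  title = paste0(model$kind, " prediction"))
}

#' @rdname rank_decoys
#' @param object a `ranking_result`.
#' @param ... unused.
#' @export
autoplot.ranking_result <- function(object, ...) {
  rho <- attr(object, "spearman_vs_true")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$rank, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::labs(
      x = "rank (1 = best)", y = attr(object, "criterion"),
      title = if (is.na(rho)) "decoy ranking (degenerate criterion)"
              else sprintf("decoy ranking (Spearman vs true = %.2f)", rho)
    )
}

#' @rdname compare_methods
#' @param object a `selection_comparison`.
#' @export
autoplot.selection_comparison <- function(object, ...) {
  lv <- object$summary$method  # ascending mean HA RMSD
  df <- object$selections
  df$method <- factor(df$method, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$method, y = .data$true_ha_rmsd)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = NULL, y = "true HA RMSD of selected decoy (Å)",
                  title = "selection-method comparison") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @rdname stratify_errors
#' @param object a `stratified_error_table`.
#' @export
autoplot.stratified_error_table <- function(object, ...) {
  ggplot2::ggplot(object$by_residue,
                  ggplot2::aes(x = factor(.data$position), y = .data$aa,
                               fill = .data$mean_ha_rmsd)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean HA RMSD (Å)") +
    ggplot2::labs(x = "peptide position", y = "amino acid",
                  title = "selected-decoy error by position and amino acid")
}

#' @rdname stratified_rmsd
#' @param object an `rmsd_report`.
#' @export
autoplot.rmsd_report <- function(object, ...) {
  ggplot2::ggplot(object$per_position,
                  ggplot2::aes(x = factor(.data$position), y = .data$rmsd)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~atom_class) +
    ggplot2::labs(x = "peptide position", y = "RMSD (Å)", title = object$id)
}
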