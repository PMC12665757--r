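# broom-style tidiers and ggplot2 autoplot methods for the fitted objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy cross-validation results
#'
#' @param x A `gat_cv` object.
#' @param ... Unused.
#' @return Per-fold, per-receptor metric tibble.
#' @export
tidy.gat_cv <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, -c(fold, receptor, n_pos, n_neg),
                      names_to = "metric")
}

#' @rdname tidy.gat_cv
#' @return `glance`: one row with per-receptor mean and sd of AUC-ROC and F1.
#' @export
glance.gat_cv <- function(x, ...) {
  s <- x$metrics |>
    dplyr::group_by(receptor) |>
    dplyr::summarise(
      auc_roc_mean = mean(auc_roc, na.rm = TRUE),
      auc_roc_sd = stats::sd(auc_roc, na.rm = TRUE),
      f1_mean = mean(f1, na.rm = TRUE),
      f1_sd = stats::sd(f1, na.rm = TRUE),
      .groups = "drop"
    )
  wide <- tidyr::pivot_wider(
    tidyr::pivot_longer(s, -receptor, names_to = "metric"),
    names_from = c(receptor, metric), values_from = value,
    names_glue = "{metric}_{receptor}"
  )
  dplyr::bind_cols(tibble::tibble(k_folds = x$tc$k_folds), wide)
}

#' Plot per-fold AUC-ROC by receptor
#'
#' @param object A `gat_cv` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gat_cv <- function(object, ...) {
  ggplot2::ggplot(object$metrics,
                  ggplot2::aes(x = receptor, y = auc_roc, fill = receptor)) +
    ggplot2::geom_boxplot(alpha = 0.6, outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0) +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(y = "AUC-ROC", x = NULL,
                  title = "Cross-validated discrimination by receptor") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Tidy a trained model's loss history
#'
#' @param x A `gat_model` with training history.
#' @param ... Unused.
#' @return Tibble: stage, epoch, train and validation loss.
#' @export
tidy.gat_model <- function(x, ...) {
  if (is.null(x$history)) return(tibble::tibble())
  purrr::imap(x$history, function(log, stage) {
    if (is.null(log)) return(NULL)
    tibble::tibble(stage = stage, epoch = seq_len(nrow(log)),
                   train_loss = log[, "train"], val_loss = log[, "val"])
  }) |> dplyr::bind_rows()
}

#' @rdname tidy.gat_model
#' @export
glance.gat_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers,
    n_heads = x$config$n_heads,
    hidden_dim = x$config$hidden_dim,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    final_val_loss = if (is.null(x$history)) NA_real_ else {
      utils::tail(x$history[[length(x$history)]][, "val"], 1)
    }
  )
}

#' Plot training loss curves by stage
#'
#' @param object A `gat_model` with history.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.gat_model <- function(object, ...) {
  df <- tidy.gat_model(object)
  df <- tidyr::pivot_longer(df, c(train_loss, val_loss), names_to = "series")
  ggplot2::ggplot(df, ggplot2::aes(epoch, value, colour = series)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~stage, scales = "free_x") +
    ggplot2::labs(y = "loss", title = "Transfer-learning loss by stage") +
    ggplot2::theme_minimal()
}

#' Tidy a genetic-algorithm run
#'
#' @param x A `ga_result`.
#' @param ... Unused.
#' @return The per-generation history tibble.
#' @export
tidy.ga_result <- function(x, ...) {
  x$history
}

#' @rdname tidy.ga_result
#' @export
glance.ga_result <- function(x, ...) {
  tibble::tibble(
    generations = nrow(x$history) - 1L,
    best_fitness = x$best_fitness,
    final_mean_fitness = utils::tail(x$history$mean_fitness, 1),
    final_mean_diversity = utils::tail(x$history$mean_diversity, 1),
    stop_reason = x$stop_reason
  )
}

#' Plot the fitness trajectory of a GA run
#'
#' @param object A `ga_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ga_result <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(generation)) +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = mean_fitness - sd_fitness, ymax = mean_fitness + sd_fitness
    ), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = mean_fitness, colour = "mean")) +
    ggplot2::geom_line(ggplot2::aes(y = best_fitness, colour = "best")) +
    ggplot2::labs(y = "fitness", colour = NULL,
                  title = "Population fitness evolution") +
    ggplot2::theme_minimal()
}
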