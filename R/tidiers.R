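#' @export
print.hs_experiment_spec <- function(x, ...) {
  cat("<experiment spec: ", x$protocol, ">\n", sep = "")
  scalars <- x[vapply(x, function(f) is.atomic(f) && length(f) <= 4, TRUE)]
  for (nm in names(scalars)) {
    cat("  ", nm, ": ", paste(scalars[[nm]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' @export
print.hs_run <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  g <- glance(x)
  cat(paste0("  ", names(g), " = ", signif(unlist(g), 4), collapse = "\n"),
      "\n")
  invisible(x)
}

#' Tidy per-trial records of a protocol run
#'
#' Returns the run's per-trial tibble (one row per trial, or per
#' replicate x trial for replicated protocols).
#'
#' @param x A protocol result object.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.hs_run <- function(x, ...) {
  out <- if (!is.null(x$trials)) x$trials else x$tests
  tibble::as_tibble(out)
}

#' One-row summary of an acquisition run
#'
#' Final learned parameters and the mean planned intensity over the last
#' tenth of training.
#'
#' @param x An `hs_acquisition` object.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.hs_acquisition <- function(x, ...) {
  tr <- x$trials
  late <- tr[tr$trial > max(tr$trial) * 0.9, ]
  tibble::tibble(
    n_trials = nrow(tr), w1 = x$final$td$w[1], q = x$final$params$q,
    h = x$final$params$h, sigma_g = x$final$params$sigma_g,
    sigma_h = x$final$params$sigma_h,
    late_planned = mean(late$planned)
  )
}

#' @export
glance.hs_depletion <- function(x, ...) {
  p <- x$probes
  tibble::tibble(
    n_trials = nrow(x$trials),
    probe_early = p$planned_depleted[1],
    probe_late = p$planned_depleted[nrow(p)],
    intact_early = p$planned_intact[1],
    intact_late = p$planned_intact[nrow(p)]
  )
}

#' @export
glance.hs_devaluation <- function(x, ...) {
  s <- x$summary
  first_bin <- function(g, n) {
    v <- s$mean[s$group == g & s$n_train == n & s$bin == 1]
    if (length(v)) v else NA_real_
  }
  tibble::tibble(
    replicates = max(x$tests$replicate),
    ratio_120 = first_bin("devalued", 120) / first_bin("control", 120),
    ratio_360 = first_bin("devalued", 360) / first_bin("control", 360)
  )
}

#' @export
glance.hs_pit <- function(x, ...) {
  s <- x$summary
  tibble::tibble(
    replicates = max(x$tests$replicate),
    cs_mean = mean(s$mean[s$cs]),
    noncs_mean = mean(s$mean[!s$cs & s$bin > 1 & s$bin < max(s$bin)]),
    first_bin = s$mean[s$bin == 1],
    last_bin = s$mean[s$bin == max(s$bin)]
  )
}

#' @export
glance.hs_reversal <- function(x, ...) {
  tr <- x$trials
  n_pre <- x$spec$n_pre
  tibble::tibble(
    n_trials = nrow(tr),
    acc_pre = mean(tr$correct[tr$trial > n_pre - 50 & tr$trial <= n_pre]),
    acc_post = mean(tr$correct[tr$trial > nrow(tr) - 50]),
    persev_10 = mean(!tr$correct[tr$trial > n_pre & tr$trial <= n_pre + 10])
  )
}

#' Plot parameter learning curves of an acquisition run
#'
#' Mirrors the standard presentation: learned parameters and planned
#' intensity across trials, and the variance parameters on a log scale.
#'
#' @param object An `hs_acquisition` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_acquisition <- function(object, ...) {
  tr <- tidy(object) |>
    dplyr::select("trial", "w1", "q", "h", "planned", "sigma_g", "sigma_h") |>
    tidyr::pivot_longer(-"trial", names_to = "quantity")
  ggplot2::ggplot(tr, ggplot2::aes(.data$trial, .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_wrap(~.data$quantity, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot within-trial dynamics of recorded probe trials
#'
#' @param run A run with a `trajectories` tibble.
#' @param quantities Trajectory columns to show.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(run,
                              quantities = c("a", "delta_v", "delta_g",
                                             "delta_h", "v")) {
  stopifnot(!is.null(run$trajectories))
  tr <- run$trajectories |>
    tidyr::pivot_longer(dplyr::all_of(quantities), names_to = "quantity")
  ggplot2::ggplot(tr, ggplot2::aes(.data$t, .data$value,
                                   colour = .data$quantity)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::facet_grid(.data$quantity ~ .data$trial, scales = "free_y") +
    ggplot2::labs(x = "time within trial", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' Plot binned test intensities of a devaluation run
#'
#' @param object An `hs_devaluation` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_devaluation <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$bin, .data$mean,
                                  linetype = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd)) +
    ggplot2::facet_wrap(~.data$n_train,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "bin of test trials", y = "mean planned intensity") +
    ggplot2::theme_minimal()
}

#' Plot binned test intensities of a transfer run
#'
#' @param object An `hs_pit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_pit <- function(object, ...) {
  s <- object$summary
  ggplot2::ggplot(s, ggplot2::aes(.data$bin, .data$mean)) +
    ggplot2::geom_col(ggplot2::aes(fill = .data$cs)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2) +
    ggplot2::labs(x = "bin of test trials", y = "mean planned intensity",
                  fill = "CS present") +
    ggplot2::theme_minimal()
}

#' Plot learning and prediction-error trajectories of a reversal run
#'
#' @param object An `hs_reversal` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hs_reversal <- function(object, ...) {
  tr <- tidy(object) |>
    dplyr::select("trial", "Q11", "Q21", "H11", "H21", "sigma_h",
                  "max_dg_plan", "max_dh_plan") |>
    tidyr::pivot_longer(-"trial", names_to = "quantity")
  ggplot2::ggplot(tr, ggplot2::aes(.data$trial, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::geom_vline(xintercept = object$spec$n_pre, linetype = 2) +
    ggplot2::facet_wrap(~.data$quantity, scales = "free_y") +
    ggplot2::labs(x = "trial", y = NULL) +
    ggplot2::theme_minimal()
}
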