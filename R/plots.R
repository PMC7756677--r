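#' Mean-difference (Bland-Altman) plot with tolerance intervals
#'
#' Scatter of per-subject means against differences (or geometric means
#' against ratios after back-transformation), with horizontal lines at the
#' bounds of the selected intervals and, when an acceptance specification
#' is attached, the acceptance band: constant lines, sloped lines for a
#' percentage band, or a step for a two-threshold band.  By default the
#' two tolerance intervals are drawn; the agreement interval is opt-in and
#' drawn dotted, reflecting its approximate nature.
#'
#' @param result an `"md_result"` from [md_analyze()] (optionally passed
#'   through [antilog_intervals()]).
#' @param which_intervals subset of `c("bTI", "bgTI", "AI")`; default the
#'   two tolerance intervals.
#' @param acceptance draw the acceptance band if present; default `TRUE`.
#' @param path optional output file (png/svg/pdf chosen by extension).
#' @param title,xlab,ylab optional labels.
#' @param width,height device size in inches when writing a file.
#' @return The ggplot object, invisibly when written to file.
#' @export
md_plot <- function(result, which_intervals = c("bTI", "bgTI"),
                    acceptance = TRUE, path = NULL,
                    title = NULL, xlab = NULL, ylab = NULL,
                    width = 7, height = 5) {
  if (!inherits(result, "md_result"))
    stop("`result` must be an `md_result`", call. = FALSE)
  if (!length(result$md$diffs))
    stop("empty result: nothing to plot", call. = FALSE)
  which_intervals <- match.arg(which_intervals,
                               c("bTI", "bgTI", "AI"), several.ok = TRUE)

  iv_map <- list(bTI = "PI_bTI", bgTI = "bgTI_exact", AI = "AI")
  if (is.null(result$intervals$bgTI_exact) &&
      !is.null(result$intervals$bgTI_approx))
    iv_map$bgTI <- "bgTI_approx"
  missing_iv <- which_intervals[vapply(
    which_intervals, function(w) is.null(result$intervals[[iv_map[[w]]]]),
    logical(1))]
  if (length(missing_iv))
    stop("requested interval(s) not present in the result: ",
         paste(missing_iv, collapse = ", "), call. = FALSE)

  df <- data.frame(m = result$md$means, d = result$md$diffs)
  ratio_scale <- isTRUE(result$back_transformed)
  ref <- if (ratio_scale) 1 else 0

  lines <- do.call(rbind, lapply(which_intervals, function(w) {
    iv <- result$intervals[[iv_map[[w]]]]
    lab <- switch(w,
      bTI  = sprintf("%g%% βTI", 100 * iv$beta),
      bgTI = sprintf("%g%% βγTI (γ=%g%%)",
                     100 * iv$beta, 100 * iv$gamma),
      AI   = sprintf("%g%% AI", 100 * iv$beta))
    data.frame(y = c(iv$lower, iv$upper), interval = lab, kind = w)
  }))
  lines$interval <- factor(lines$interval, levels = unique(lines$interval))

  lty <- c(bTI = "solid", bgTI = "dashed", AI = "dotted")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$m, y = .data$d)) +
    ggplot2::geom_hline(yintercept = ref, colour = "grey60") +
    ggplot2::geom_point() +
    ggplot2::geom_hline(
      data = lines,
      ggplot2::aes(yintercept = .data$y, colour = .data$interval,
                   linetype = .data$interval)) +
    ggplot2::scale_linetype_manual(
      values = stats::setNames(lty[lines$kind], lines$interval)) +
    ggplot2::labs(
      x = if (!is.null(xlab)) xlab
          else if (ratio_scale) "Geometric mean" else "Mean of methods (M)",
      y = if (!is.null(ylab)) ylab
          else if (ratio_scale)
            sprintf("Ratio %s / %s", result$md$method_names[1],
                    result$md$method_names[2])
          else sprintf("Difference %s - %s", result$md$method_names[1],
                       result$md$method_names[2]),
      title = title, colour = "Interval", linetype = "Interval") +
    ggplot2::theme_bw()

  if (acceptance && !is.null(result$acceptance)) {
    acc <- result$acceptance
    if (!is.null(acc$ratio_fraction) && ratio_scale) {
      f <- acc$ratio_fraction
      p <- p + ggplot2::geom_hline(yintercept = c(1 - f, 1 / (1 - f)),
                                   colour = "red3")
    } else if (is.null(acc$ratio_fraction) && !ratio_scale &&
               result$scale == "none") {
      if (acc$percent) {
        slope <- acc$delta1 / 100
        p <- p + ggplot2::geom_abline(slope = c(slope, -slope),
                                      intercept = 0, colour = "red3")
      } else {
        grid_m <- seq(min(df$m), max(df$m), length.out = 200)
        band <- acceptance_band(acc, grid_m)
        band_df <- data.frame(m = rep(grid_m, 2),
                              y = c(band[, "lower"], band[, "upper"]),
                              side = rep(c("lo", "hi"), each = 200))
        p <- p + ggplot2::geom_step(
          data = band_df,
          ggplot2::aes(x = .data$m, y = .data$y, group = .data$side),
          colour = "red3")
      }
    }
  }

  if (!is.null(path)) {
    save_plot_file(p, path, width, height)
    return(invisible(p))
  }
  p
}

#' Plot a coverage study
#'
#' Two panels against sample size: the mean effective predictive level of
#' each interval, and the effective confidence level of the content
#' tolerance intervals.  The beta-expectation TI traces a flat line at the
#' nominal level.
#'
#' @param grid a `"coverage_grid"` from [run_coverage_study()].
#' @param path optional output file (png/svg/pdf by extension).
#' @param log_x draw the sample-size axis on a log scale.
#' @param width,height device size in inches when writing a file.
#' @return The ggplot object, invisibly when written to file.
#' @export
coverage_plot <- function(grid, path = NULL, log_x = FALSE,
                          width = 8, height = 4.5) {
  if (!inherits(grid, "coverage_grid"))
    stop("`grid` must be a `coverage_grid`", call. = FALSE)
  if (!nrow(grid))
    stop("empty coverage grid", call. = FALSE)
  df <- as.data.frame(grid)
  df$series <- ifelse(is.na(df$gamma), df$interval,
                      sprintf("%s γ=%g", df$interval, df$gamma))
  beta <- df$beta[1]

  pred <- df
  pred$metric <- "Mean effective predictive level"
  pred$value <- pred$mean_effective_level
  conf <- df[!is.na(df$gamma), ]
  if (nrow(conf)) {
    conf$metric <- "Effective confidence level"
    conf$value <- conf$effective_confidence
  }
  both <- rbind(pred, conf)

  p <- ggplot2::ggplot(both, ggplot2::aes(x = .data$n, y = .data$value,
                                          colour = .data$series)) +
    ggplot2::geom_hline(yintercept = beta, colour = "grey70",
                        linetype = "dashed") +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "Sample size (n)", y = "Level", colour = NULL) +
    ggplot2::theme_bw()
  if (log_x) p <- p + ggplot2::scale_x_log10()

  if (!is.null(path)) {
    save_plot_file(p, path, width, height)
    return(invisible(p))
  }
  p
}

save_plot_file <- function(p, path, width, height) {
  dir <- dirname(path)
  if (!dir.exists(dir))
    stop("directory does not exist: ", dir, call. = FALSE)
  ggplot2::ggsave(path, plot = p, width = width, height = height)
  invisible(path)
}
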