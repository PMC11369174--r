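# broom-style tidiers and ggplot2 autoplot methods for the package's
# result objects.

#' Tidy a polarisation curve fit
#'
#' @param x a `ppd_fp_fit` from [fit_saturation()] or [fit_displacement()].
#' @param ... unused.
#' @return one-row tibble of the fitted parameters and flags.
#' @export
tidy.ppd_fp_fit <- function(x, ...) {
  if (x$type == "saturation") {
    tibble(
      type = "saturation", kd = x$kd, mp_free = x$mp_free, mp_max = x$mp_max,
      flagged = x$flagged
    )
  } else {
    tibble(
      type = "displacement", ic50 = x$ic50, top = x$top, bottom = x$bottom,
      hill = x$hill, non_binder = x$non_binder, anomalous = x$anomalous,
      flagged = x$flagged
    )
  }
}

#' Fit-quality summary of a polarisation curve fit
#'
#' @inheritParams tidy.ppd_fp_fit
#' @return one-row tibble with residual standard deviation, number of
#'   points and convergence flag.
#' @export
glance.ppd_fp_fit <- function(x, ...) {
  tibble(
    n_points = nrow(x$data),
    sigma = if (!is.null(x$fit)) stats::sigma(x$fit) else NA_real_,
    converged = !is.null(x$fit),
    flagged = x$flagged
  )
}

#' @export
print.ppd_fp_fit <- function(x, ...) {
  cat(sprintf("<ppd_fp_fit: %s>\n", x$type))
  print(tidy.ppd_fp_fit(x))
  invisible(x)
}

#' Tidy a mutation scan
#'
#' @param x a `ppd_mutscan` tibble from [mutation_scan()].
#' @param ... unused.
#' @return the underlying tibble.
#' @export
tidy.ppd_mutscan <- function(x, ...) {
  out <- x
  class(out) <- setdiff(class(out), "ppd_mutscan")
  out
}

#' One-row summary of a mutation scan
#'
#' @inheritParams tidy.ppd_mutscan
#' @return tibble with counts of scanned and significant domain-mutation
#'   pairs per direction at the scan's cut-off.
#' @export
glance.ppd_mutscan <- function(x, ...) {
  tibble(
    n_pairs = nrow(x),
    n_enhancing = sum(x$direction == "enhancing"),
    n_diminishing = sum(x$direction == "diminishing"),
    n_neutral = sum(x$direction == "neutral"),
    p_cutoff = attr(x, "p_cutoff")
  )
}

#' V-shaped plot of a mutation scan
#'
#' Mutation enrichment score against -log10 Mann-Whitney p value; the left
#' arm holds mutation-diminished, the right arm mutation-enhanced
#' interactions; pairs failing the cut-off are grey.
#'
#' @param object a `ppd_mutscan` tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ppd_mutscan <- function(object, ...) {
  dat <- tidy.ppd_mutscan(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$enrichment_score, y = -log10(.data$p_value),
    colour = .data$direction
  )) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(
      diminishing = "#2166AC", neutral = "grey60", enhancing = "#B2182B"
    ), drop = FALSE) +
    ggplot2::geom_hline(
      yintercept = -log10(attr(object, "p_cutoff")), linetype = "dashed",
      colour = "grey40"
    ) +
    ggplot2::labs(
      x = "mutation enrichment score",
      y = expression(-log[10] ~ italic(p)),
      colour = "mutation effect"
    ) +
    ggplot2::theme_minimal()
}

#' Affinity fold-change versus phage enrichment score
#'
#' @param object a `ppd_affinity` tibble from [score_agreement()].
#' @param threshold fold-change threshold drawn as dotted guides.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ppd_affinity <- function(object, threshold = 2, ...) {
  dat <- as_tibble(object)
  ggplot2::ggplot(dat, ggplot2::aes(
    x = .data$enrichment_score, y = .data$log2_fold,
    colour = .data$agreement, shape = .data$capped
  )) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(
      yintercept = c(-log2(threshold), log2(threshold)),
      linetype = "dotted", colour = "grey40"
    ) +
    ggplot2::labs(
      x = "mutation enrichment score",
      y = expression(log[2] ~ "fold-change in affinity (mutant tighter > 0)"),
      colour = "agrees with selection", shape = "capped (non-binder)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a polarisation curve fit
#'
#' @param object a `ppd_fp_fit`.
#' @param ... unused.
#' @return a ggplot object with data points and the fitted curve.
#' @export
autoplot.ppd_fp_fit <- function(object, ...) {
  xcol <- if (object$type == "saturation") "protein_conc" else "competitor_conc"
  dat <- object$data
  dat$x <- dat[[xcol]]
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$x, y = .data$mp)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = paste(xcol, "(M)"), y = "polarisation (mP)") +
    ggplot2::theme_minimal()
  if (!is.null(object$fit)) {
    grid <- tibble(x = 10^seq(log10(min(dat$x)), log10(max(dat$x)),
                              length.out = 200))
    if (object$type == "saturation") {
      grid$mp <- object$mp_free + (object$mp_max - object$mp_free) *
        bound_fraction(grid$x, object$probe_conc, object$kd)
    } else {
      grid$mp <- object$bottom + (object$top - object$bottom) /
        (1 + 10^((log10(grid$x) - log10(10^coef(object$fit)[["logic50"]])) *
                   object$hill))
    }
    p <- p + ggplot2::geom_line(data = grid, colour = "#B2182B")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Turn a fitted object into a tidy tibble
#'
#' Generic in the broom style; methods exist for the package's result
#' objects.
#'
#' @param x object to tidy.
#' @param ... passed to methods.
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' One-row model/result summary
#'
#' Generic in the broom style; methods exist for the package's result
#' objects.
#'
#' @param x object to summarise.
#' @param ... passed to methods.
#' @export
glance <- function(x, ...) UseMethod("glance")
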