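#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot ggplot aes geom_col geom_point geom_smooth
#'   geom_hline geom_vline labs theme_minimal position_dodge geom_abline
#' @export
ggplot2::autoplot

#' @rdname fit_sge
#' @param x,object An `"sge_fit"` object.
#' @export
tidy.sge_fit <- function(x, ...) {
  x$vc %>% mutate(trait = x$trait, pct_variation = 100 * .data$proportion)
}

#' @rdname fit_sge
#' @export
glance.sge_fit <- function(x, ...) {
  tibble(trait = x$trait, constraint = x$constraint,
         logLik = x$fit$loglik, converged = x$fit$converged,
         iterations = x$fit$iterations, n_rows = x$n_rows,
         n_pots = x$n_pots, n_excluded = x$n_excluded)
}

#' @rdname fit_sge
#' @param ... Unused.
#' @export
autoplot.sge_fit <- function(object, ...) {
  ggplot(tidy(object),
         aes(x = stats::reorder(.data$component, -.data$pct_variation),
             y = .data$pct_variation)) +
    geom_col(fill = "steelblue") +
    labs(x = NULL, y = "% of phenotypic variance",
         title = sprintf("Variance partition: %s", object$trait)) +
    theme_minimal()
}

#' @rdname fit_means_regression
#' @param x,object A `"means_reg"` object.
#' @param ... Unused.
#' @export
tidy.means_reg <- function(x, ...) {
  sm <- summary(x$lm)$coefficients
  tibble(term = rownames(sm), estimate = sm[, 1], std.error = sm[, 2],
         statistic = sm[, 3], p.value = sm[, 4])
}

#' @rdname fit_means_regression
#' @export
glance.means_reg <- function(x, ...) {
  tibble(r.squared = x$r_squared, statistic = x$f_statistic,
         df = x$df1, df.residual = x$df2, p.value = x$p_value,
         nobs = x$n)
}

#' @rdname fit_means_regression
#' @export
autoplot.means_reg <- function(object, ...) {
  ggplot(object$data, aes(x = .data$x, y = .data$y)) +
    geom_point(size = 2) +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "firebrick") +
    labs(x = object$x, y = object$y,
         title = sprintf("F(%d,%d) = %.2f, p = %.3g", object$df1,
                         object$df2, object$f_statistic,
                         object$p_value)) +
    theme_minimal()
}

#' @rdname fit_deviation_model
#' @param x,object A `"deviation_fit"` object.
#' @param ... Unused.
#' @export
tidy.deviation_fit <- function(x, ...) {
  tibble(term = c("(Intercept)", "prop_beneficial"),
         estimate = c(x$intercept, x$slope),
         statistic = c(NA_real_, x$chisq),
         df = c(NA_integer_, x$df),
         p.value = c(NA_real_, x$p_value))
}

#' @rdname fit_deviation_model
#' @export
glance.deviation_fit <- function(x, ...) {
  tibble(statistic = x$chisq, df = x$df, p.value = x$p_value,
         logLik = as.numeric(logLik(x$model)), nobs = x$n)
}

#' @rdname fit_deviation_model
#' @export
autoplot.deviation_fit <- function(object, ...) {
  ggplot(object$records,
         aes(x = .data$prop_beneficial, y = .data$deviation)) +
    geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    geom_vline(xintercept = 0.5, linetype = 2, colour = "grey50") +
    geom_point(alpha = 0.6) +
    geom_abline(intercept = object$intercept, slope = object$slope,
                colour = "firebrick") +
    labs(x = "proportion of nodules from the more beneficial strain",
         y = "deviation from neutral host fitness",
         title = sprintf("slope = %.3g, chisq(1) = %.2f, p = %.3g",
                         object$slope, object$chisq, object$p_value)) +
    theme_minimal()
}

#' Grouped bar chart of a cross-trait variance partition
#'
#' @param vt Output of [variance_table()].
#' @return A ggplot object.
#' @export
plot_variance_partition <- function(vt) {
  ggplot(vt, aes(x = .data$component, y = .data$pct_variation,
                 fill = .data$trait)) +
    geom_col(position = position_dodge(width = 0.8), width = 0.7) +
    labs(x = NULL, y = "% of phenotypic variance", fill = "trait") +
    theme_minimal()
}
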