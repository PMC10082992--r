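#' Scatter plot of a harmonized instrument with fitted MR lines
#'
#' SNP-outcome against SNP-exposure effects with +/- 1 SE error bars and
#' the fitted line(s).  For an `mr_rucker` object both the IVW line
#' (through the origin) and the Egger line (with intercept) are drawn,
#' the chosen method solid.
#'
#' @param x an `mr_fit` or `mr_rucker` object (fitted with the data kept)
#'   together with `h`, or call as `plot(fit, h)`.
#' @param h the `harmonized_set` the model was fitted to.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
plot.mr_rucker <- function(x, h, ...) {
  r <- retained(h)
  s <- ifelse(r$beta_exp < 0, -1, 1)
  bx <- s * r$beta_exp; by <- s * r$beta_out
  graphics::plot(bx, by, pch = 19, col = "grey30",
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", ...)
  graphics::segments(bx, by - r$se_out, bx, by + r$se_out,
                     col = "grey70")
  graphics::segments(bx - r$se_exp, by, bx + r$se_exp, by,
                     col = "grey70")
  ivw_lty <- if (x$chosen_method == "IVW") 1L else 2L
  graphics::abline(0, x$ivw$beta, col = "steelblue", lwd = 2,
                   lty = ivw_lty)
  graphics::abline(x$egger$intercept, x$egger$beta, col = "firebrick",
                   lwd = 2, lty = 3L - ivw_lty)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("steelblue", "firebrick"),
                   lty = c(ivw_lty, 3L - ivw_lty),
                   legend = c(sprintf("IVW (%.3g)", x$ivw$beta),
                              sprintf("MR-Egger (%.3g)", x$egger$beta)))
  invisible(x)
}

#' @rdname plot.mr_rucker
#' @export
plot.mr_fit <- function(x, h, ...) {
  r <- retained(h)
  graphics::plot(r$beta_exp, r$beta_out, pch = 19, col = "grey30",
                 xlab = "SNP effect on exposure",
                 ylab = "SNP effect on outcome", ...)
  graphics::segments(r$beta_exp, r$beta_out - r$se_out, r$beta_exp,
                     r$beta_out + r$se_out, col = "grey70")
  if (!is.na(x$intercept))
    graphics::abline(x$intercept, x$beta, col = "firebrick", lwd = 2)
  else graphics::abline(0, x$beta, col = "steelblue", lwd = 2)
  invisible(x)
}

#' Funnel plot of per-SNP Wald ratios
#'
#' Instrument precision (1/se of the ratio) against the per-SNP causal
#' estimate; asymmetry suggests directional pleiotropy.
#'
#' @param h a `harmonized_set`.
#' @param fit optional `mr_fit` whose estimate is drawn as a vertical
#'   line.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the [wald_ratios()] table.
#' @export
funnel_plot <- function(h, fit = NULL, ...) {
  wr <- wald_ratios(h)
  graphics::plot(wr$beta, 1 / wr$se, pch = 19, col = "grey30",
                 xlab = "per-SNP causal estimate (Wald ratio)",
                 ylab = "precision (1/SE)", ...)
  if (!is.null(fit))
    graphics::abline(v = fit$beta, col = "steelblue", lwd = 2)
  invisible(wr)
}

#' Forest plot of per-SNP or leave-one-out estimates
#'
#' @param x a [wald_ratios()] table, an `mr_loo` object, or any data
#'   frame with `snp`, `beta`, `ci_low`, `ci_high`.
#' @param overall optional `mr_fit` drawn as a reference line and bottom
#'   row.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `x`.
#' @export
forest_plot <- function(x, overall = NULL, ...) {
  n <- nrow(x)
  ys <- rev(seq_len(n))
  xlim <- range(c(x$ci_low, x$ci_high,
                  if (!is.null(overall)) c(overall$ci_low,
                                           overall$ci_high)))
  graphics::plot(x$beta, ys, pch = 15, xlim = xlim,
                 ylim = c(0, n + 1), yaxt = "n",
                 xlab = "causal estimate", ylab = "", ...)
  graphics::axis(2, at = ys, labels = x$snp, las = 1, cex.axis = 0.7)
  graphics::segments(x$ci_low, ys, x$ci_high, ys)
  if (!is.null(overall)) {
    graphics::abline(v = overall$beta, lty = 2, col = "steelblue")
    graphics::points(overall$beta, 0, pch = 18, col = "steelblue",
                     cex = 1.5)
    graphics::segments(overall$ci_low, 0, overall$ci_high, 0,
                       col = "steelblue", lwd = 2)
  }
  graphics::abline(v = 0, col = "grey60")
  invisible(x)
}

#' @export
plot.mr_loo <- function(x, ...) {
  forest_plot(x, overall = attr(x, "full_fit"), ...)
}

#' @export
residuals.mr_fit <- function(object, h, ...) {
  if (missing(h))
    stop("supply the harmonized_set the model was fitted to",
         call. = FALSE)
  r <- retained(h)
  if (!is.na(object$intercept)) {
    s <- ifelse(r$beta_exp < 0, -1, 1)
    s * r$beta_out - object$intercept - object$beta * (s * r$beta_exp)
  } else {
    r$beta_out - object$beta * r$beta_exp
  }
}
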