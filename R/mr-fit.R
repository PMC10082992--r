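# Run expr with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Oriented, retained effect vectors; Egger-style orientation flips each
# SNP so the exposure effect is non-negative (both betas together).
.mr_data <- function(h, orient = FALSE, drop_null_exposure = FALSE) {
  r <- retained(h)
  if (drop_null_exposure && any(r$beta_exp == 0)) {
    warning(sprintf("excluding %d SNP(s) with zero exposure effect",
                    sum(r$beta_exp == 0)), call. = FALSE)
    r <- r[r$beta_exp != 0, , drop = FALSE]
  }
  bx <- r$beta_exp; by <- r$beta_out
  if (orient) {
    s <- ifelse(bx < 0, -1, 1)
    bx <- s * bx; by <- s * by
  }
  list(snp = r$snp, bx = bx, bxse = r$se_exp, by = by, byse = r$se_out,
       J = nrow(r))
}

.mk_estimate <- function(method, beta, se, pvalue, n_snps, df = Inf,
                         overdispersion = NA_real_, intercept = NA_real_,
                         intercept_se = NA_real_, intercept_p = NA_real_,
                         exposure = NULL, outcome = NULL) {
  crit <- if (is.finite(df)) stats::qt(0.975, df) else stats::qnorm(0.975)
  structure(list(method = method, beta = beta, se = se,
                 ci_low = beta - crit * se, ci_high = beta + crit * se,
                 pvalue = pvalue, n_snps = n_snps, df = df,
                 overdispersion = overdispersion, intercept = intercept,
                 intercept_se = intercept_se, intercept_p = intercept_p,
                 exposure = exposure, outcome = outcome,
                 odds_scale = FALSE),
            class = "mr_fit")
}

.ivw_core <- function(bx, by, byse, random_effects = TRUE) {
  J <- length(bx)
  w <- 1 / byse^2
  sxx <- sum(w * bx^2)
  beta <- sum(w * bx * by) / sxx
  q <- sum(w * (by - beta * bx)^2)
  phi <- if (J > 1L) q / (J - 1) else NA_real_
  se <- sqrt(1 / sxx)
  if (random_effects && J > 1L) se <- se * sqrt(max(1, phi))
  list(beta = beta, se = se, q = q, phi = phi,
       pvalue = 2 * stats::pnorm(-abs(beta / se)))
}

.egger_core <- function(bx, by, byse, random_effects = TRUE) {
  J <- length(bx)
  w <- 1 / byse^2
  # weighted normal equations for [intercept, slope]
  sw <- sum(w); swx <- sum(w * bx); swxx <- sum(w * bx^2)
  swy <- sum(w * by); swxy <- sum(w * bx * by)
  A <- matrix(c(sw, swx, swx, swxx), 2L, 2L)
  coef <- solve(A, c(swy, swxy))
  resid <- by - coef[1L] - coef[2L] * bx
  qp <- sum(w * resid^2)
  phi <- qp / (J - 2)
  vc <- solve(A)
  infl <- if (random_effects) max(1, phi) else 1
  se <- sqrt(diag(vc) * infl)
  tt <- coef / se
  p <- 2 * stats::pt(-abs(tt), df = J - 2)
  list(intercept = coef[1L], slope = coef[2L], intercept_se = se[1L],
       slope_se = se[2L], intercept_p = p[1L], slope_p = p[2L], qp = qp,
       phi = phi)
}

.wald_core <- function(bx, by, byse) {
  list(beta = by / bx, se = byse / abs(bx))
}

.weighted_median_point <- function(ratio, weight) {
  ord <- order(ratio)
  r <- ratio[ord]; w <- weight[ord] / sum(weight)
  cum <- cumsum(w)
  pj <- cum - w / 2
  stats::approx(pj, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Fit a two-sample Mendelian randomization model
#'
#' The central fitting function: estimates the causal effect of the
#' exposure on the outcome from a harmonized set of SNP association
#' summaries, by one of four methods.
#'
#' \describe{
#'   \item{`"ivw"`}{Inverse-variance weighted: weighted regression of the
#'     SNP-outcome effects on the SNP-exposure effects through the origin
#'     with weights 1/se_out^2.  With `random_effects = TRUE` (the
#'     default, the multiplicative random-effects model) the standard
#'     error is inflated by sqrt(max(1, Q/(J-1))), never deflated below
#'     the fixed-effect value.  Inference is normal-theory.}
#'   \item{`"egger"`}{MR-Egger: the same weighted regression with an
#'     intercept, after orienting every SNP so its exposure effect is
#'     non-negative.  The slope is the causal estimate; the intercept
#'     estimates directional pleiotropy.  Inference uses the t
#'     distribution on J-2 degrees of freedom (small-J intercept tests are
#'     anticonservative under normal theory); random-effects inflation by
#'     sqrt(max(1, Q'/(J-2))).}
#'   \item{`"weighted_median"`}{Weighted median of the per-SNP Wald
#'     ratios: consistent when at least half the weight comes from valid
#'     instruments.  The point estimate interpolates the inverse-variance-
#'     weighted ratio distribution at probability 0.5; the standard error
#'     comes from a parametric bootstrap (`n_boot` draws, seeded).}
#'   \item{`"wald"`}{Single-SNP Wald ratio (J = 1): Gamma/gamma with the
#'     first-order delta-method standard error se_out/|gamma|.}
#' }
#'
#' @param h a `harmonized_set` (see [harmonize()] / [harmonized_set()]).
#'   Dropped rows are ignored.
#' @param method one of `"ivw"`, `"egger"`, `"weighted_median"`, `"wald"`.
#' @param random_effects multiplicative random-effects standard errors for
#'   IVW/Egger (default `TRUE`).
#' @param n_boot bootstrap replicates for the weighted-median standard
#'   error (default 1000; fewer than 100 warns).
#' @param seed RNG seed for the bootstrap; the caller's RNG state is
#'   restored afterwards.
#' @return an object of class `mr_fit` with components `method`, `beta`,
#'   `se`, `ci_low`, `ci_high` (95\%), `pvalue`, `n_snps`,
#'   `overdispersion` and, for Egger, `intercept`, `intercept_se`,
#'   `intercept_p`.
#' @examples
#' h <- harmonized_set(beta_exp = c(0.1, 0.2, 0.15, 0.3),
#'                     se_exp = rep(0.01, 4),
#'                     beta_out = c(0.05, 0.1, 0.075, 0.15),
#'                     se_out = rep(0.01, 4))
#' mr_fit(h, "ivw")
#' @seealso [mr_rucker()] for model selection, [mr_presso()],
#'   [leave_one_out()], [wald_ratios()], [heterogeneity()]
#' @export
mr_fit <- function(h, method = c("ivw", "egger", "weighted_median", "wald"),
                   random_effects = TRUE, n_boot = 1000, seed = NULL) {
  method <- match.arg(method)
  exposure <- attr(h, "exposure"); outcome <- attr(h, "outcome")
  d <- .mr_data(h, orient = method %in% c("egger", "weighted_median"),
                drop_null_exposure = method %in% c("weighted_median",
                                                   "wald"))
  fit <- switch(method,
    ivw = {
      if (d$J < 2L)
        stop("IVW requires at least 2 SNPs; use method = 'wald' for a ",
             "single-SNP instrument", call. = FALSE)
      f <- .ivw_core(d$bx, d$by, d$byse, random_effects)
      .mk_estimate("IVW", f$beta, f$se, f$pvalue, d$J,
                   overdispersion = f$phi, exposure = exposure,
                   outcome = outcome)
    },
    egger = {
      if (d$J < 3L)
        stop("insufficient SNPs for Egger (need J >= 3)", call. = FALSE)
      f <- .egger_core(d$bx, d$by, d$byse, random_effects)
      .mk_estimate("MR-Egger", f$slope, f$slope_se, f$slope_p, d$J,
                   df = d$J - 2, overdispersion = f$phi,
                   intercept = f$intercept, intercept_se = f$intercept_se,
                   intercept_p = f$intercept_p, exposure = exposure,
                   outcome = outcome)
    },
    weighted_median = {
      if (d$J < 3L)
        stop("weighted median requires at least 3 SNPs", call. = FALSE)
      if (n_boot < 100) warning("n_boot < 100 gives unstable standard ",
                                "errors", call. = FALSE)
      ratio <- d$by / d$bx
      w <- (d$bx / d$byse)^2     # inverse variance of the Wald ratio
      est <- .weighted_median_point(ratio, w)
      boots <- .with_seed(seed, {
        vapply(seq_len(n_boot), function(b) {
          bxb <- stats::rnorm(d$J, d$bx, d$bxse)
          byb <- stats::rnorm(d$J, d$by, d$byse)
          ok <- bxb != 0
          .weighted_median_point(byb[ok] / bxb[ok],
                                 (bxb[ok] / d$byse[ok])^2)
        }, numeric(1L))
      })
      se <- stats::sd(boots)
      .mk_estimate("Weighted median", est, se,
                   2 * stats::pnorm(-abs(est / se)), d$J,
                   exposure = exposure, outcome = outcome)
    },
    wald = {
      if (d$J != 1L)
        stop("method 'wald' is for single-SNP instruments; see ",
             "wald_ratios() for per-SNP estimates", call. = FALSE)
      f <- .wald_core(d$bx, d$by, d$byse)
      .mk_estimate("Wald ratio", f$beta, f$se,
                   2 * stats::pnorm(-abs(f$beta / f$se)), 1L,
                   exposure = exposure, outcome = outcome)
    })
  fit$call <- match.call()
  fit
}

#' Per-SNP Wald ratio estimates
#'
#' beta_j = Gamma_j / gamma_j with first-order delta-method standard error
#' se_j = se_Gamma_j / |gamma_j| (the second-order term is omitted), plus
#' normal-theory confidence limits and p-values.  SNPs with a zero
#' exposure effect are excluded with a warning.
#'
#' @param h a `harmonized_set`.
#' @return data frame with columns `snp`, `beta`, `se`, `ci_low`,
#'   `ci_high`, `pvalue`.
#' @export
wald_ratios <- function(h) {
  d <- .mr_data(h, drop_null_exposure = TRUE)
  f <- .wald_core(d$bx, d$by, d$byse)
  z <- stats::qnorm(0.975)
  data.frame(snp = d$snp, beta = f$beta, se = f$se,
             ci_low = f$beta - z * f$se, ci_high = f$beta + z * f$se,
             pvalue = 2 * stats::pnorm(-abs(f$beta / f$se)),
             stringsAsFactors = FALSE)
}

#' Heterogeneity statistics for IVW and MR-Egger
#'
#' Cochran's Q for the IVW fit and Ruecker's Q' for the Egger fit (both
#' with weights 1/se_out^2, Egger after orientation), with chi-squared
#' p-values on J-1 and J-2 degrees of freedom, and the 1-df test of the
#' difference Q - Q' used by the Ruecker model-selection framework.
#'
#' @param h a `harmonized_set` with at least 3 retained SNPs.
#' @return object of class `mr_heterogeneity`: list with `q`, `q_prime`,
#'   `df_q`, `df_qp`, `p_q`, `p_qp`, `p_diff`.
#' @export
heterogeneity <- function(h) {
  d <- .mr_data(h)
  if (d$J < 3L) stop("heterogeneity requires at least 3 SNPs",
                     call. = FALSE)
  ivw <- .ivw_core(d$bx, d$by, d$byse)
  o <- .mr_data(h, orient = TRUE)
  egg <- .egger_core(o$bx, o$by, o$byse)
  q <- ivw$q; qp <- egg$qp
  structure(list(q = q, q_prime = qp, df_q = d$J - 1, df_qp = d$J - 2,
                 p_q = stats::pchisq(q, d$J - 1, lower.tail = FALSE),
                 p_qp = stats::pchisq(qp, d$J - 2, lower.tail = FALSE),
                 p_diff = stats::pchisq(max(0, q - qp), 1,
                                        lower.tail = FALSE)),
            class = "mr_heterogeneity")
}

#' @export
print.mr_heterogeneity <- function(x, ...) {
  cat("Heterogeneity statistics\n")
  cat(sprintf("  Cochran's Q  = %.3f on %d df (p = %.3g)\n", x$q, x$df_q,
              x$p_q))
  cat(sprintf("  Ruecker's Q' = %.3f on %d df (p = %.3g)\n", x$q_prime,
              x$df_qp, x$p_qp))
  cat(sprintf("  Q - Q' = %.3f, chi2(1) p = %.3g\n", x$q - x$q_prime,
              x$p_diff))
  invisible(x)
}

#' Ruecker model selection between IVW and MR-Egger
#'
#' Fits both the multiplicative random-effects IVW model and MR-Egger and
#' applies the Ruecker decision rule: MR-Egger is reported as the primary
#' method only when the heterogeneity difference Q - Q' is significant
#' (chi-squared 1 df, p < 0.05) *and* the Egger intercept differs from
#' zero (p < 0.1); otherwise IVW, which has the best power when all SNPs
#' are valid instruments, is retained.
#'
#' @param h a `harmonized_set` with at least 3 retained SNPs.
#' @param p_diff_threshold,intercept_threshold the two components of the
#'   switching rule (defaults 0.05 and 0.1).
#' @param random_effects passed to both fits.
#' @return object of class `mr_rucker`: list with `chosen_method`
#'   (`"IVW"` or `"MR-Egger"`), `estimate` (the chosen `mr_fit`), `ivw`,
#'   `egger`, `heterogeneity`, `rationale`.
#' @export
mr_rucker <- function(h, p_diff_threshold = 0.05, intercept_threshold = 0.1,
                      random_effects = TRUE) {
  ivw <- mr_fit(h, "ivw", random_effects = random_effects)
  egger <- mr_fit(h, "egger", random_effects = random_effects)
  het <- heterogeneity(h)
  switch_to_egger <- het$p_diff < p_diff_threshold &&
    egger$intercept_p < intercept_threshold
  chosen <- if (switch_to_egger) "MR-Egger" else "IVW"
  rationale <- sprintf(paste0(
    "Q - Q' difference p = %.3g (threshold %.2g) and Egger intercept ",
    "p = %.3g (threshold %.2g): %s"),
    het$p_diff, p_diff_threshold, egger$intercept_p, intercept_threshold,
    if (switch_to_egger)
      "directional pleiotropy with a better Egger fit; MR-Egger selected"
    else "no significant improvement from the Egger intercept; IVW retained")
  structure(list(chosen_method = chosen,
                 estimate = if (switch_to_egger) egger else ivw,
                 ivw = ivw, egger = egger, heterogeneity = het,
                 p_diff = het$p_diff, intercept_p = egger$intercept_p,
                 rationale = rationale),
            class = "mr_rucker")
}

#' @export
print.mr_rucker <- function(x, ...) {
  cat("Ruecker model selection\n")
  cat(sprintf("  chosen method: %s\n", x$chosen_method))
  cat(sprintf("  %s\n", x$rationale))
  cat("\nSelected estimate:\n")
  print(x$estimate)
  invisible(x)
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the causal effect J times, each time excluding one SNP,
#' to reveal whether a single variant drives the association.
#'
#' @param h a `harmonized_set` with at least 3 retained SNPs.
#' @param method estimation method passed to [mr_fit()].
#' @param ... further arguments to [mr_fit()].
#' @return object of class `mr_loo`: data frame with one row per excluded
#'   SNP (`snp`, `beta`, `se`, `ci_low`, `ci_high`, `pvalue`) and the full-
#'   instrument fit in attribute `full_fit`.
#' @export
leave_one_out <- function(h, method = "ivw", ...) {
  r <- retained(h)
  if (nrow(r) < 3L) stop("leave-one-out requires at least 3 SNPs",
                         call. = FALSE)
  full <- mr_fit(h, method, ...)
  rows <- lapply(seq_len(nrow(r)), function(j) {
    fit <- mr_fit(r[-j, , drop = FALSE], method, ...)
    data.frame(snp = r$snp[j], beta = fit$beta, se = fit$se,
               ci_low = fit$ci_low, ci_high = fit$ci_high,
               pvalue = fit$pvalue, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "full_fit") <- full
  class(out) <- c("mr_loo", "data.frame")
  out
}

#' Aggregate Steiger directionality test
#'
#' Sums the per-SNP variance explained over the instrument for the
#' exposure and for the outcome and tests the implied aggregate
#' correlations with the Fisher-z statistic of [steiger_stats()].  The
#' verdict is `"valid"` when the instrument explains more variance in the
#' exposure than in the outcome, i.e. the assumed causal direction is
#' supported.
#'
#' @param h a `harmonized_set` with per-SNP sample sizes.
#' @return object of class `steiger_test`: list with `r2_exp`, `r2_out`
#'   (instrument totals), `verdict` (`"valid"`/`"reversed"`), `z`, `p`
#'   (two-sided), and the per-SNP table `per_snp`.
#' @export
steiger_directionality <- function(h) {
  st <- steiger_stats(h)
  r <- retained(h)
  r2x <- min(sum(st$r2_exp), 1 - 1e-12)
  r2y <- min(sum(st$r2_out), 1 - 1e-12)
  nx <- mean(r$n_exp); ny <- mean(r$n_out)
  z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
    sqrt(1 / (nx - 3) + 1 / (ny - 3))
  structure(list(r2_exp = r2x, r2_out = r2y,
                 verdict = if (r2x > r2y) "valid" else "reversed",
                 z = z, p = 2 * stats::pnorm(-abs(z)), per_snp = st),
            class = "steiger_test")
}

#' @export
print.steiger_test <- function(x, ...) {
  cat("Steiger directionality test\n")
  cat(sprintf("  instrument r2: exposure %.4f vs outcome %.6f\n",
              x$r2_exp, x$r2_out))
  cat(sprintf("  verdict: %s (z = %.2f, p = %.3g)\n", x$verdict, x$z, x$p))
  invisible(x)
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("Two-sample MR estimate (%s)\n", x$method))
  if (!is.null(x$exposure))
    cat(sprintf("  %s -> %s\n", x$exposure, x$outcome))
  unit <- if (isTRUE(x$odds_scale)) "OR" else "beta"
  cat(sprintf("  %s = %.4g (95%% CI %.4g to %.4g), p = %.3g, J = %d\n",
              unit, x$beta, x$ci_low, x$ci_high, x$pvalue, x$n_snps))
  if (!is.na(x$intercept))
    cat(sprintf("  Egger intercept = %.4g (se %.3g), p = %.3g\n",
                x$intercept, x$intercept_se, x$intercept_p))
  if (!is.na(x$overdispersion))
    cat(sprintf("  overdispersion phi = %.3g\n", x$overdispersion))
  invisible(x)
}

#' @export
summary.mr_fit <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.mr_fit <- function(object, ...) {
  if (is.na(object$intercept)) c(beta = object$beta)
  else c(intercept = object$intercept, beta = object$beta)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  crit <- if (is.finite(object$df)) stats::qt(1 - (1 - level) / 2,
                                              object$df)
          else stats::qnorm(1 - (1 - level) / 2)
  out <- matrix(c(object$beta - crit * object$se,
                  object$beta + crit * object$se), 1L, 2L,
                dimnames = list("beta",
                                sprintf("%.1f %%",
                                        c((1 - level) / 2,
                                          1 - (1 - level) / 2) * 100)))
  out
}
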