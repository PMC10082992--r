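#' Harmonize exposure, mediator and outcome onto one allele frame
#'
#' Builds the input for multivariable MR: per SNP the exposure effect
#' gamma_j, the mediator association delta_j and the outcome effect
#' Gamma_j, all on a single effect-allele orientation.  Pairwise
#' harmonization reuses [harmonize()] (exposure vs outcome and exposure vs
#' mediator), then all three betas are jointly oriented toward increasing
#' exposure.  Only SNPs retained in both pairwise harmonizations are kept.
#'
#' @param exposure,mediator,outcome [summary_table()] objects.
#' @param palindrome_eaf_window as in [harmonize()].
#' @return object of class `mvmr_set`: data frame with `snp`, `beta_exp`,
#'   `se_exp`, `beta_med`, `se_med`, `beta_out`, `se_out`, `n_exp`,
#'   `n_out`.
#' @export
harmonize_mv <- function(exposure, mediator, outcome,
                         palindrome_eaf_window = 0.08) {
  hxy <- harmonize(exposure, outcome, palindrome_eaf_window,
                   orient_increasing = FALSE)
  hxm <- harmonize(exposure, mediator, palindrome_eaf_window,
                   orient_increasing = FALSE)
  rxy <- retained(hxy); rxm <- retained(hxm)
  common <- intersect(rxy$snp, rxm$snp)
  if (length(common) == 0L)
    stop("no SNPs retained in both pairwise harmonizations", call. = FALSE)
  rxy <- rxy[match(common, rxy$snp), ]
  rxm <- rxm[match(common, rxm$snp), ]
  s <- ifelse(rxy$beta_exp < 0, -1, 1)   # joint orientation
  mv <- data.frame(snp = common,
                   beta_exp = s * rxy$beta_exp, se_exp = rxy$se_exp,
                   beta_med = s * rxm$beta_out, se_med = rxm$se_out,
                   beta_out = s * rxy$beta_out, se_out = rxy$se_out,
                   n_exp = rxy$n_exp, n_out = rxy$n_out,
                   stringsAsFactors = FALSE)
  structure(mv, exposure = attr(exposure, "trait_label"),
            mediator = attr(mediator, "trait_label"),
            outcome = attr(outcome, "trait_label"),
            class = c("mvmr_set", "data.frame"))
}

#' Construct a multivariable-MR set from aligned vectors
#'
#' @param beta_exp,se_exp,beta_med,se_med,beta_out,se_out aligned per-SNP
#'   effects and standard errors for exposure, mediator and outcome.
#' @param snp SNP ids (generated if omitted).
#' @return an `mvmr_set`.
#' @export
mvmr_set <- function(beta_exp, se_exp, beta_med, se_med, beta_out,
                     se_out, snp = NULL) {
  J <- length(beta_exp)
  stopifnot(all(se_exp > 0), all(se_med > 0), all(se_out > 0),
            length(beta_med) == J, length(beta_out) == J)
  if (is.null(snp)) snp <- sprintf("snp%03d", seq_len(J))
  structure(data.frame(snp = as.character(snp), beta_exp = beta_exp,
                       se_exp = se_exp, beta_med = beta_med,
                       se_med = se_med, beta_out = beta_out,
                       se_out = se_out, n_exp = NA_real_,
                       n_out = NA_real_, stringsAsFactors = FALSE),
            class = c("mvmr_set", "data.frame"))
}

#' Multivariable MR by the IVW method
#'
#' Weighted regression of the SNP-outcome effects on the SNP-exposure and
#' SNP-mediator effects jointly, without intercept and with weights
#' 1/se_out^2.  The coefficient on the exposure is its direct effect
#' conditional on the mediator; the coefficient on the mediator is the
#' mediator's conditional effect.  Standard errors come from the weighted
#' normal equations, inflated by sqrt(max(1, RSS_w/(J-2))) (multiplicative
#' random effects, floored at the fixed-effect value).
#'
#' @param mv an `mvmr_set` with at least 3 SNPs.
#' @return object of class `mvmr_fit`: list with `exposure` and
#'   `mediator` components (each an `mr_fit`-like estimate), `n_snps`,
#'   `overdispersion`.
#' @export
mvmr_fit <- function(mv) {
  stopifnot(inherits(mv, "mvmr_set"))
  J <- nrow(mv)
  if (J < 3L) stop("multivariable MR requires at least 3 SNPs",
                   call. = FALSE)
  X <- cbind(exposure = mv$beta_exp, mediator = mv$beta_med)
  w <- 1 / mv$se_out^2
  if (all(mv$beta_med == 0)) {
    # degenerate mediator column: the model reduces to univariable IVW
    h <- harmonized_set(mv$beta_exp, mv$se_exp, mv$beta_out, mv$se_out,
                        snp = mv$snp)
    uni <- mr_fit(h, "ivw")
    uni$method <- "MVMR-IVW (direct effect of exposure; null mediator)"
    none <- .mk_estimate("MVMR-IVW (conditional effect of mediator)",
                         NA_real_, NA_real_, NA_real_, J)
    return(structure(list(exposure = uni, mediator = none, n_snps = J,
                          overdispersion = uni$overdispersion,
                          vcov = NULL),
                     class = "mvmr_fit"))
  }
  Xw <- X * sqrt(w)
  A <- crossprod(Xw)
  d <- sqrt(diag(A))
  if (any(d == 0) || rcond(A / tcrossprod(d)) < 1e-10)
    stop("mediator instrument collinear with exposure", call. = FALSE)
  b <- crossprod(X * w, mv$beta_out)
  coef <- as.vector(solve(A, b))
  resid <- mv$beta_out - drop(X %*% coef)
  rss_w <- sum(w * resid^2)
  phi <- rss_w / (J - 2)
  vc <- solve(A) * max(1, phi)
  se <- unname(sqrt(diag(vc)))
  p <- 2 * stats::pnorm(-abs(coef / se))
  mk <- function(i, label) .mk_estimate(
    sprintf("MVMR-IVW (%s)", label), coef[i], se[i], p[i], J,
    overdispersion = phi, exposure = attr(mv, "exposure"),
    outcome = attr(mv, "outcome"))
  structure(list(exposure = mk(1L, "direct effect of exposure"),
                 mediator = mk(2L, "conditional effect of mediator"),
                 n_snps = J, overdispersion = phi,
                 vcov = vc),
            class = "mvmr_fit")
}

#' @export
print.mvmr_fit <- function(x, ...) {
  cat(sprintf("Multivariable MR (IVW), J = %d\n", x$n_snps))
  cat(sprintf("  exposure (direct):  beta = %.4g (se %.3g), p = %.3g\n",
              x$exposure$beta, x$exposure$se, x$exposure$pvalue))
  cat(sprintf("  mediator:           beta = %.4g (se %.3g), p = %.3g\n",
              x$mediator$beta, x$mediator$se, x$mediator$pvalue))
  invisible(x)
}

#' Difference-method mediation decomposition
#'
#' Combines the total effect of the exposure on the outcome (univariable
#' MR) with its direct effect conditional on the mediator (multivariable
#' MR): indirect = total - direct, and the proportion mediated is
#' indirect / total.  The indirect-effect standard error uses the
#' independence approximation sqrt(se_total^2 + se_direct^2) (the
#' covariance between the two estimates, whose samples overlap, is
#' ignored); a parametric bootstrap for the proportion's interval is
#' available via `n_boot`.
#'
#' @param total the total-effect estimate: an `mr_fit`, or a length-2
#'   numeric `c(beta, se)`.
#' @param direct the direct-effect estimate: an `mvmr_fit` (its exposure
#'   component is used), an `mr_fit`, or `c(beta, se)`.
#' @param n_boot if > 0, parametric bootstrap draws for a percentile CI of
#'   the proportion mediated.
#' @param seed RNG seed for the bootstrap.
#' @param tol proportion reported as `NA` when `|total beta| < tol`.
#' @return object of class `mr_mediation`: list with `total`, `direct`,
#'   `indirect` (each beta/se/ci), `proportion` (fraction of the total
#'   effect that is mediated; `proportion_ci` when bootstrapped).
#' @examples
#' # worked example: total effect -3.14 years per unit log-eGFR, direct
#' # effect -1.95 after conditioning on the mediator
#' med <- mediation_difference(c(-3.14, 1.07), c(-1.95, 1.20))
#' round(100 * med$proportion)   # 38 (% mediated)
#' @export
mediation_difference <- function(total, direct, n_boot = 0, seed = NULL,
                                 tol = 1e-12) {
  get_bs <- function(x, which = "total") {
    if (inherits(x, "mvmr_fit")) x <- x$exposure
    if (inherits(x, "mr_fit")) c(x$beta, x$se)
    else if (is.numeric(x) && length(x) == 2L) x
    else stop("cannot interpret the ", which, " estimate", call. = FALSE)
  }
  tt <- get_bs(total, "total"); dd <- get_bs(direct, "direct")
  z <- stats::qnorm(0.975)
  ind_beta <- tt[1L] - dd[1L]
  ind_se <- sqrt(tt[2L]^2 + dd[2L]^2)
  proportion <- if (abs(tt[1L]) < tol) NA_real_ else ind_beta / tt[1L]
  out <- list(
    total = list(beta = tt[1L], se = tt[2L],
                 ci = tt[1L] + c(-1, 1) * z * tt[2L]),
    direct = list(beta = dd[1L], se = dd[2L],
                  ci = dd[1L] + c(-1, 1) * z * dd[2L]),
    indirect = list(beta = ind_beta, se = ind_se,
                    ci = ind_beta + c(-1, 1) * z * ind_se),
    proportion = proportion, proportion_ci = NULL)
  if (n_boot > 0 && !is.na(proportion)) {
    props <- .with_seed(seed, {
      tb <- stats::rnorm(n_boot, tt[1L], tt[2L])
      db <- stats::rnorm(n_boot, dd[1L], dd[2L])
      (tb - db) / tb
    })
    out$proportion_ci <- stats::quantile(props, c(0.025, 0.975),
                                         names = FALSE)
  }
  structure(out, class = "mr_mediation")
}

#' @export
print.mr_mediation <- function(x, ...) {
  cat("Difference-method mediation decomposition\n")
  line <- function(label, e)
    cat(sprintf("  %-9s %8.4g (95%% CI %.4g to %.4g)\n", label, e$beta,
                e$ci[1L], e$ci[2L]))
  line("total:", x$total); line("direct:", x$direct)
  line("indirect:", x$indirect)
  if (!is.na(x$proportion))
    cat(sprintf("  proportion mediated: %.0f%%%s\n", 100 * x$proportion,
                if (!is.null(x$proportion_ci))
                  sprintf(" (bootstrap 95%% CI %.0f%% to %.0f%%)",
                          100 * x$proportion_ci[1L],
                          100 * x$proportion_ci[2L]) else ""))
  else cat("  proportion mediated: undefined (total effect ~ 0)\n")
  invisible(x)
}
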