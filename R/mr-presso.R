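#' MR-PRESSO: pleiotropy residual sum and outlier test
#'
#' Detects horizontal-pleiotropy outliers among instrument SNPs by
#' comparing each SNP's contribution to the leave-one-out weighted
#' residual sum of squares against a parametric simulation of the
#' no-pleiotropy null, then re-estimates the causal effect without the
#' flagged SNPs.
#'
#' For each SNP j the leave-one-out IVW slope beta(-j) is computed and the
#' observed residual contribution is e_j = w_j (Gamma_j - gamma_j
#' beta(-j))^2 with w_j = 1/se_out_j^2; RSS_obs is their sum.  The null
#' distribution is built by drawing, `n_sim` times, Gamma*_j ~
#' N(gamma_j beta(-j), se_out_j) and gamma*_j ~ N(gamma_j, se_exp_j) and
#' recomputing the same quantities.  The global test p-value is the
#' add-one empirical tail probability (1 + #\{RSS* >= RSS_obs\}) /
#' (n_sim + 1), which cannot be exactly zero.  Per-SNP outlier p-values
#' come from each SNP's simulated contribution distribution and are
#' Bonferroni-adjusted by J; SNPs below `outlier_alpha` are flagged.  The
#' outlier-corrected estimate is the IVW fit on the remaining SNPs, and
#' the distortion test compares the observed change in estimate with the
#' change produced by removing random subsets of the same size.
#'
#' @param h a `harmonized_set` with at least 4 retained SNPs.
#' @param n_sim number of simulated datasets (>= 1000 recommended).
#' @param outlier_alpha significance level applied to the
#'   Bonferroni-adjusted per-SNP p-values.  Default 0.05.
#' @param seed RNG seed; identical inputs, seed and `n_sim` give a
#'   bit-identical result.  The caller's RNG state is restored.
#' @param random_effects passed to the raw/corrected IVW fits.
#' @return object of class `mr_presso`: list with `rss_obs`, `global_p`,
#'   `outlier_p` (adjusted, named by SNP), `outlier_ids`, `beta_raw` and
#'   `beta_corrected` (both `mr_fit` objects; `beta_corrected` is `NULL`
#'   when no outlier is found), `distortion_p` (`NA` without outliers),
#'   `n_sim`, `seed`.
#' @export
mr_presso <- function(h, n_sim = 2000, outlier_alpha = 0.05, seed = NULL,
                      random_effects = TRUE) {
  d <- .mr_data(h)
  J <- d$J
  if (J < 4L) stop("MR-PRESSO requires at least 4 SNPs", call. = FALSE)
  w <- 1 / d$byse^2

  loo_beta <- function(bx, by) {
    sxy <- sum(w * bx * by); sxx <- sum(w * bx^2)
    (sxy - w * bx * by) / (sxx - w * bx^2)
  }
  bl <- loo_beta(d$bx, d$by)
  e_obs <- w * (d$by - d$bx * bl)^2
  rss_obs <- sum(e_obs)

  .with_seed(seed, {
    bx_sim <- matrix(stats::rnorm(J * n_sim, d$bx, d$bxse), J, n_sim)
    by_sim <- matrix(stats::rnorm(J * n_sim, d$bx * bl, d$byse), J, n_sim)
    sxy <- colSums(w * bx_sim * by_sim)
    sxx <- colSums(w * bx_sim^2)
    bl_sim <- (rep(sxy, each = J) - w * bx_sim * by_sim) /
      (rep(sxx, each = J) - w * bx_sim^2)
    e_sim <- w * (by_sim - bx_sim * bl_sim)^2
    rss_sim <- colSums(e_sim)

    global_p <- (1 + sum(rss_sim >= rss_obs)) / (n_sim + 1)
    outlier_raw <- (1 + rowSums(e_sim >= e_obs)) / (n_sim + 1)
    outlier_p <- pmin(1, outlier_raw * J)
    names(outlier_p) <- d$snp
    outliers <- d$snp[outlier_p < outlier_alpha]

    beta_raw <- mr_fit(h, "ivw", random_effects = random_effects)
    beta_corrected <- NULL; distortion_p <- NA_real_
    if (length(outliers) > 0L) {
      if (length(outliers) == J)
        stop("no SNPs remain after outlier removal", call. = FALSE)
      r <- retained(h)
      beta_corrected <- mr_fit(r[!(r$snp %in% outliers), , drop = FALSE],
                               "ivw", random_effects = random_effects)
      d_obs <- beta_raw$beta - beta_corrected$beta
      k <- length(outliers)
      n_d <- min(n_sim, 1000L)
      d_sim <- vapply(seq_len(n_d), function(b) {
        drop_idx <- sample.int(J, k)
        f <- .ivw_core(d$bx[-drop_idx], d$by[-drop_idx], d$byse[-drop_idx],
                       random_effects)
        beta_raw$beta - f$beta
      }, numeric(1L))
      distortion_p <- (1 + sum(abs(d_sim) >= abs(d_obs))) / (n_d + 1)
    }
    structure(list(rss_obs = rss_obs, global_p = global_p,
                   outlier_p = outlier_p, outlier_ids = outliers,
                   beta_raw = beta_raw, beta_corrected = beta_corrected,
                   distortion_p = distortion_p, n_sim = n_sim,
                   seed = seed),
              class = "mr_presso")
  })
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO\n")
  cat(sprintf("  global test: RSS_obs = %.4g, p = %.4g (%d simulations)\n",
              x$rss_obs, x$global_p, x$n_sim))
  if (length(x$outlier_ids) > 0L) {
    cat(sprintf("  outliers (%d): %s\n", length(x$outlier_ids),
                paste(x$outlier_ids, collapse = ", ")))
    cat(sprintf("  raw beta = %.4g; outlier-corrected beta = %.4g; ",
                x$beta_raw$beta, x$beta_corrected$beta))
    cat(sprintf("distortion p = %.3g\n", x$distortion_p))
  } else {
    cat("  no outliers detected\n")
    cat(sprintf("  raw beta = %.4g\n", x$beta_raw$beta))
  }
  invisible(x)
}
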