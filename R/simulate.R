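#' Configuration for the synthetic two-sample MR generator
#'
#' Collects the generative parameters for simulated GWAS summary
#' statistics and individual-level cohorts with known ground truth.  The
#' generative model is
#'
#'   X = sum_j gamma_j G_j + e_x,
#'   Y = beta_true X + sum_j alpha_j G_j + e_y
#'
#' (continuous outcomes; variances normalized so var(X) = 1), with
#' optional horizontal pleiotropy alpha_j on a fraction of SNPs, an
#' optional mediator path X -> M -> Y, and binary outcomes generated
#' through a logistic link whose intercept is solved numerically for the
#' target prevalence.  Summary statistics are obtained either from two
#' disjoint simulated samples (`mode = "individual"`) or drawn directly
#' from their asymptotic sampling distributions (`mode = "asymptotic"`,
#' the fast default for calibration experiments).
#'
#' @param J number of biallelic SNPs.
#' @param n_exp,n_out exposure- and outcome-GWAS sample sizes.
#' @param beta_true causal effect of exposure on outcome (the *direct*
#'   effect when a mediator is configured; log odds per unit exposure for
#'   binary outcomes).
#' @param r2_gx total variance in the exposure explained by the J SNPs.
#' @param maf_range range of minor-allele frequencies, within (0, 0.5].
#' @param prop_invalid fraction of SNPs with horizontal pleiotropy.
#' @param mean_alpha,sd_alpha mean and SD of the pleiotropic effects of
#'   invalid SNPs (mean 0 = balanced, nonzero = directional).
#' @param correlated if `TRUE`, pleiotropic effects are routed through a
#'   heritable confounder so they correlate with instrument strength
#'   (violating the InSIDE assumption).
#' @param outcome_type `"continuous"` or `"binary"`.
#' @param case_fraction target prevalence K for binary outcomes.
#' @param mediator `NULL`, or `list(beta_xm =, beta_med_out =, r2_med =,
#'   n_med =)`: exposure-to-mediator effect, mediator-to-outcome effect,
#'   variance in the mediator explained by its own (SNP-level) effects,
#'   and the mediator-GWAS sample size.
#' @param ld_blocks `NULL`, or `list(size =, rho =)`: dosages generated in
#'   blocks of `size` SNPs with within-block latent correlation `rho`
#'   (individual-level data only).
#' @param mode `"asymptotic"` or `"individual"`.
#' @param sample_overlap fraction of outcome-sample individuals shared
#'   with the exposure sample (individual mode; two-sample independence
#'   corresponds to 0).
#' @param n_ind cohort size for [simulate_individual()].
#' @param score_beta planted effect of the standardized allele score on
#'   log-eGFR (per SD), for the individual-level cohort.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(J = 50, n_exp = 50000, n_out = 50000,
                       beta_true = 0, r2_gx = 0.03,
                       maf_range = c(0.05, 0.5), prop_invalid = 0,
                       mean_alpha = 0, sd_alpha = 0, correlated = FALSE,
                       outcome_type = c("continuous", "binary"),
                       case_fraction = 0.1, mediator = NULL,
                       ld_blocks = NULL,
                       mode = c("asymptotic", "individual"),
                       sample_overlap = 0, n_ind = 10000,
                       score_beta = -0.001) {
  outcome_type <- match.arg(outcome_type)
  mode <- match.arg(mode)
  stopifnot(J >= 1, n_exp > 10, n_out > 10, r2_gx > 0, r2_gx < 1,
            length(maf_range) == 2L, maf_range[1L] > 0,
            maf_range[2L] <= 0.5, prop_invalid >= 0, prop_invalid <= 1,
            sd_alpha >= 0, sample_overlap >= 0, sample_overlap <= 1)
  if (outcome_type == "binary" &&
      (case_fraction <= 0 || case_fraction >= 1))
    stop("case_fraction must lie in (0, 1)", call. = FALSE)
  if (!is.null(mediator)) {
    stopifnot(is.list(mediator),
              all(c("beta_xm", "beta_med_out") %in% names(mediator)))
    if (is.null(mediator$r2_med)) mediator$r2_med <- 0.05
    if (is.null(mediator$n_med)) mediator$n_med <- n_exp
  }
  if (!is.null(ld_blocks))
    stopifnot(is.list(ld_blocks), ld_blocks$size >= 1,
              ld_blocks$rho >= 0, ld_blocks$rho < 1)
  structure(list(J = J, n_exp = n_exp, n_out = n_out,
                 beta_true = beta_true, r2_gx = r2_gx,
                 maf_range = maf_range, prop_invalid = prop_invalid,
                 mean_alpha = mean_alpha, sd_alpha = sd_alpha,
                 correlated = correlated, outcome_type = outcome_type,
                 case_fraction = case_fraction, mediator = mediator,
                 ld_blocks = ld_blocks, mode = mode,
                 sample_overlap = sample_overlap, n_ind = n_ind,
                 score_beta = score_beta),
            class = "sim_config")
}

# Draw the genetic architecture shared by both simulation modes.
.sim_truth <- function(config) {
  J <- config$J
  f <- stats::runif(J, config$maf_range[1L], config$maf_range[2L])
  varg <- 2 * f * (1 - f)
  # aligned (non-negative) per-allele exposure effects, rescaled so the
  # instrument explains exactly r2_gx of the exposure variance
  g <- abs(stats::rnorm(J))
  gamma <- g * sqrt(config$r2_gx / sum(g^2 * varg))
  n_invalid <- round(config$prop_invalid * J)
  invalid <- sort(sample.int(J, n_invalid))
  alpha <- numeric(J)
  if (n_invalid > 0L) {
    if (config$correlated) {
      alpha[invalid] <- config$mean_alpha * gamma[invalid] /
        mean(gamma[invalid]) +
        stats::rnorm(n_invalid, 0, config$sd_alpha)
    } else {
      alpha[invalid] <- stats::rnorm(n_invalid, config$mean_alpha,
                                     config$sd_alpha)
    }
  }
  med <- config$mediator
  eta <- delta <- NULL
  total <- config$beta_true
  mediated_fraction <- NA_real_
  if (!is.null(med)) {
    # mediator-specific effects are sign-symmetric: alleles aligned
    # toward increasing exposure carry no systematic mediator direction
    e <- stats::rnorm(J)
    eta <- e * sqrt(med$r2_med / sum(e^2 * varg))
    delta <- med$beta_xm * gamma + eta
    total <- config$beta_true + med$beta_xm * med$beta_med_out
    mediated_fraction <- if (total != 0)
      med$beta_xm * med$beta_med_out / total else NA_real_
  }
  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), 2L)
  al <- pairs[, sample.int(4L, J, replace = TRUE), drop = FALSE]
  chr <- as.character(rep(1:22, length.out = J))
  # SNPs 1 Mb apart within a chromosome: outside any clumping window
  pos <- stats::ave(seq_len(J), chr, FUN = seq_along) * 1e6
  structure(list(snp = sprintf("rs%05d", seq_len(J)), maf = f,
                 varg = varg, gamma = gamma, alpha = alpha,
                 invalid = seq_len(J) %in% invalid, eta = eta,
                 delta = delta, beta_true = config$beta_true,
                 total_effect = total,
                 mediated_fraction = mediated_fraction,
                 chr = chr, pos = pos, ea = al[1L, ], oa = al[2L, ]),
            class = "simulation_truth")
}

.sim_table <- function(truth, beta, se, n, label, type = "continuous",
                       eaf = truth$maf, n_cases = NA) {
  z <- beta / se
  summary_table(data.frame(
    snp = truth$snp, chr = truth$chr, pos = truth$pos, ea = truth$ea,
    oa = truth$oa, eaf = pmin(pmax(eaf, 1e-6), 1 - 1e-6), beta = beta,
    se = se, p = pmax(2 * stats::pnorm(-abs(z)), 1e-300), n = n,
    n_cases = n_cases, stringsAsFactors = FALSE),
    trait_label = label, trait_type = type)
}

#' Simulate two-sample GWAS summary statistics with known truth
#'
#' Generates an exposure summary table, an outcome summary table (and a
#' mediator table when configured) under the generative model of
#' [sim_config()], plus the ground truth used to plant them.  Fully
#' seeded: the same config and seed give identical tables.
#'
#' @param config a [sim_config()].
#' @param seed integer RNG seed (the caller's RNG state is restored).
#' @return list with `exposure`, `outcome` (and `mediator` if configured)
#'   as [summary_table()] objects, and `truth` (a `simulation_truth`).
#' @export
simulate_two_sample <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    truth <- .sim_truth(config)
    if (config$mode == "asymptotic")
      .sim_asymptotic(config, truth)
    else
      .sim_individual_two_sample(config, truth)
  })
}

.sim_asymptotic <- function(config, truth) {
  J <- config$J; varg <- truth$varg
  med <- config$mediator
  gamma_med_path <- if (!is.null(med)) med$beta_med_out * truth$delta
                    else 0
  Gamma <- truth$beta_true * truth$gamma + gamma_med_path + truth$alpha

  se_x <- sqrt(pmax(1 - truth$gamma^2 * varg, 0.1) / (config$n_exp * varg))
  bx <- stats::rnorm(J, truth$gamma, se_x)
  exposure <- .sim_table(truth, bx, se_x, config$n_exp, "exposure")

  if (config$outcome_type == "binary") {
    K <- config$case_fraction
    se_y <- sqrt(1 / (config$n_out * K * (1 - K) * varg))
    by <- stats::rnorm(J, Gamma, se_y)
    outcome <- .sim_table(truth, by, se_y, config$n_out, "outcome",
                          type = "binary",
                          n_cases = round(K * config$n_out))
  } else {
    sigma2_y <- truth$total_effect^2 + sum(truth$alpha^2 * varg) + 1
    se_y <- sqrt(sigma2_y / (config$n_out * varg))
    by <- stats::rnorm(J, Gamma, se_y)
    outcome <- .sim_table(truth, by, se_y, config$n_out, "outcome")
  }
  out <- list(exposure = exposure, outcome = outcome, truth = truth)
  if (!is.null(med)) {
    sigma2_m <- med$beta_xm^2 + 1
    se_m <- sqrt(sigma2_m / (med$n_med * varg))
    bm <- stats::rnorm(J, truth$delta, se_m)
    out$mediator <- .sim_table(truth, bm, se_m, med$n_med, "mediator")
  }
  out
}

# Per-SNP simple regressions, vectorized over SNPs.
.gwas_scan <- function(G, y) {
  n <- nrow(G)
  gc <- scale(G, scale = FALSE)
  yc <- y - mean(y)
  sxx <- colSums(gc^2)
  beta <- colSums(gc * yc) / sxx
  rss <- sum(yc^2) - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / ((n - 2) * sxx))
  list(beta = beta, se = se)
}

.sim_dosages <- function(n, truth, ld_blocks = NULL) {
  J <- length(truth$maf)
  if (is.null(ld_blocks)) {
    G <- matrix(stats::rbinom(n * J, 2L, rep(truth$maf, each = n)), n, J)
  } else {
    # Gaussian-copula blocks: a shared latent factor per block induces
    # within-block dosage correlation about ld_blocks$rho
    size <- ld_blocks$size; rho <- ld_blocks$rho
    block <- rep(seq_len(ceiling(J / size)), each = size)[seq_len(J)]
    B <- matrix(stats::rnorm(n * max(block)), n)
    Z <- sqrt(rho) * B[, block, drop = FALSE] +
      sqrt(1 - rho) * matrix(stats::rnorm(n * J), n, J)
    U <- stats::pnorm(Z)
    G <- vapply(seq_len(J), function(j)
      stats::qbinom(U[, j], 2L, truth$maf[j]), numeric(n))
  }
  colnames(G) <- truth$snp
  G
}

.sim_individual_two_sample <- function(config, truth) {
  J <- config$J
  n_x <- config$n_exp; n_y <- config$n_out
  n_shared <- round(config$sample_overlap * min(n_x, n_y))

  Gx <- .sim_dosages(n_x, truth, config$ld_blocks)
  ex <- stats::rnorm(n_x, 0, sqrt(1 - config$r2_gx))
  X1 <- drop(Gx %*% truth$gamma) + ex
  sx <- .gwas_scan(Gx, X1)
  exposure <- .sim_table(truth, sx$beta, sx$se, n_x, "exposure",
                         eaf = colMeans(Gx) / 2)

  # outcome sample shares the first n_shared individuals with the
  # exposure sample (two-sample independence when sample_overlap = 0)
  if (n_shared > 0L) {
    Gy <- rbind(Gx[seq_len(n_shared), , drop = FALSE],
                .sim_dosages(n_y - n_shared, truth, config$ld_blocks))
    Xy <- c(X1[seq_len(n_shared)],
            drop(Gy[-seq_len(n_shared), , drop = FALSE] %*% truth$gamma) +
              stats::rnorm(n_y - n_shared, 0, sqrt(1 - config$r2_gx)))
  } else {
    Gy <- .sim_dosages(n_y, truth, config$ld_blocks)
    Xy <- drop(Gy %*% truth$gamma) +
      stats::rnorm(n_y, 0, sqrt(1 - config$r2_gx))
  }
  med <- config$mediator
  My <- if (!is.null(med))
    med$beta_xm * Xy + drop(Gy %*% truth$eta) + stats::rnorm(n_y)
  else NULL
  lin <- config$beta_true * Xy + drop(Gy %*% truth$alpha) +
    (if (!is.null(med)) med$beta_med_out * My else 0)

  if (config$outcome_type == "binary") {
    K <- config$case_fraction
    a0 <- stats::uniroot(function(a)
      mean(stats::plogis(a + lin)) - K, c(-30, 30))$root
    y <- stats::rbinom(n_y, 1L, stats::plogis(a0 + lin))
    res <- .logistic_scan(Gy, y)
    outcome <- .sim_table(truth, res$beta, res$se, n_y, "outcome",
                          type = "binary", eaf = colMeans(Gy) / 2,
                          n_cases = sum(y))
  } else {
    y <- lin + stats::rnorm(n_y)
    sy <- .gwas_scan(Gy, y)
    outcome <- .sim_table(truth, sy$beta, sy$se, n_y, "outcome",
                          eaf = colMeans(Gy) / 2)
  }
  out <- list(exposure = exposure, outcome = outcome, truth = truth)
  if (!is.null(med)) {
    sm <- .gwas_scan(Gy, My)
    out$mediator <- .sim_table(truth, sm$beta, sm$se, n_y, "mediator",
                               eaf = colMeans(Gy) / 2)
  }
  out
}

.logistic_scan <- function(G, y) {
  J <- ncol(G)
  beta <- se <- numeric(J)
  for (j in seq_len(J)) {
    fit <- stats::glm(y ~ G[, j], family = stats::binomial())
    cf <- summary(fit)$coefficients
    beta[j] <- cf[2L, 1L]; se[j] <- cf[2L, 2L]
  }
  list(beta = beta, se = se)
}

#' Simulate an individual-level cohort for allele-score MR
#'
#' Generates dosages (optionally in correlated LD blocks), demographics,
#' clinical covariates, 10 synthetic ancestry principal components, and
#' serum creatinine / cystatin C values constructed so that the derived
#' CKD-EPI eGFR carries a planted effect of the standardized allele score
#' (`config$score_beta` per SD on log-eGFR).  Creatinine is obtained by
#' exact inversion of the CKD-EPI creatinine-cystatin equation at the
#' target eGFR, so derived phenotypes are internally consistent; CKD
#' status follows the eGFR < 60 rule.
#'
#' @param config a [sim_config()] (`n_ind`, `J`, `maf_range`, `r2_gx`,
#'   `ld_blocks`, `score_beta` are used).
#' @param seed integer RNG seed.
#' @return list with `data` (an [individual_dataset()] with derived
#'   phenotypes), `instrument` (the generating per-allele weights as a
#'   [summary_table()]) and `truth`.
#' @export
simulate_individual <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    truth <- .sim_truth(config)
    n <- config$n_ind
    G <- .sim_dosages(n, truth, config$ld_blocks)
    raw <- drop(G %*% truth$gamma)
    zscore <- (raw - mean(raw)) / stats::sd(raw)

    age <- stats::runif(n, 40, 70)
    sex <- ifelse(stats::runif(n) < 0.5, "female", "male")
    bmi <- stats::rnorm(n, 27, 4)
    hypertension <- stats::rbinom(n, 1L, 0.30)
    diabetes <- stats::rbinom(n, 1L, 0.08)
    hypercholesterolemia <- stats::rbinom(n, 1L, 0.20)
    ldl <- stats::rnorm(n, 3.5, 0.9)
    hdl <- stats::rnorm(n, 1.4, 0.35)
    smoking <- stats::rbinom(n, 1L, 0.45)
    pcs <- matrix(stats::rnorm(n * 10L), n,
                  dimnames = list(NULL, paste0("pc", 1:10)))

    log_egfr <- log(80) - 0.005 * (age - 55) - 0.002 * (bmi - 27) -
      0.02 * hypertension - 0.03 * diabetes +
      config$score_beta * zscore + stats::rnorm(n, 0, 0.18)
    target <- exp(log_egfr)

    scys <- stats::rlnorm(n, log(0.9), 0.12)
    scr <- .invert_ckd_epi(target, scys, age, sex)

    pheno <- data.frame(scr = scr, scys = scys, age = age, sex = sex,
                        bmi = bmi, hypertension = hypertension,
                        diabetes = diabetes,
                        hypercholesterolemia = hypercholesterolemia,
                        ldl = ldl, hdl = hdl, smoking = smoking,
                        stringsAsFactors = FALSE)
    pheno <- cbind(pheno, as.data.frame(pcs))
    snp_info <- data.frame(snp = truth$snp, ea = truth$ea, oa = truth$oa,
                           stringsAsFactors = FALSE)
    data <- individual_dataset(G, pheno, snp_info)
    data <- derive_kidney_phenotypes(data)
    instrument <- summary_table(data.frame(
      snp = truth$snp, chr = truth$chr, pos = truth$pos, ea = truth$ea,
      oa = truth$oa, eaf = truth$maf, beta = truth$gamma,
      se = pmax(truth$gamma / 10, 1e-4), p = 1e-10,
      n = n, stringsAsFactors = FALSE), trait_label = "score weights")
    list(data = data, instrument = instrument, truth = truth)
  })
}

# Solve the CKD-EPI creatinine-cystatin equation for creatinine given a
# target eGFR and the remaining inputs (the creatinine factor is strictly
# decreasing in scr, so the inverse is closed-form and piecewise).
.invert_ckd_epi <- function(egfr_target, scys, age, sex) {
  female <- tolower(sex) == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.248, -0.207)
  cys_fac <- pmin(scys / 0.8, 1)^-0.375 * pmax(scys / 0.8, 1)^-0.711
  f_cr <- egfr_target / (135 * cys_fac * 0.995^age *
                           ifelse(female, 0.969, 1))
  ifelse(f_cr >= 1, kappa * f_cr^(1 / alpha),
         kappa * f_cr^(-1 / 0.601))
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat(sprintf("  J = %d SNPs, n_exp = %d, n_out = %d, mode = %s\n",
              x$J, x$n_exp, x$n_out, x$mode))
  cat(sprintf("  beta_true = %g, r2_gx = %g, outcome = %s\n",
              x$beta_true, x$r2_gx, x$outcome_type))
  if (x$prop_invalid > 0)
    cat(sprintf("  pleiotropy: %.0f%% invalid, alpha ~ N(%g, %g)%s\n",
                100 * x$prop_invalid, x$mean_alpha, x$sd_alpha,
                if (x$correlated) " (correlated / InSIDE-violating)"
                else ""))
  if (!is.null(x$mediator))
    cat(sprintf("  mediator: beta_xm = %g, beta_med_out = %g\n",
                x$mediator$beta_xm, x$mediator$beta_med_out))
  invisible(x)
}
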