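#' CKD-EPI creatinine-cystatin C estimated GFR (2012 combined equation)
#'
#' Estimated glomerular filtration rate from serum creatinine and serum
#' cystatin C, age and sex, using the 2012 combined creatinine-cystatin C
#' estimating equation:
#'
#' eGFR = 135 x min(Scr/k, 1)^a x max(Scr/k, 1)^-0.601
#'            x min(Scys/0.8, 1)^-0.375 x max(Scys/0.8, 1)^-0.711
#'            x 0.995^age x 0.969\[if female\] x 1.08\[if Black\]
#'
#' with k = 0.7 (female) / 0.9 (male) and a = -0.248 (female) / -0.207
#' (male).  The race coefficient is not applied by default (configurable
#' via `race_black`).
#'
#' @param scr serum creatinine, mg/dL (> 0).
#' @param scys serum cystatin C, mg/L (> 0).
#' @param age age in years (>= 18; the equation is for adults).
#' @param sex `"male"`/`"female"` (or a factor/character vector thereof).
#' @param race_black logical, apply the 1.08 coefficient.  Default FALSE.
#' @return eGFR in ml/min/1.73 m^2 (vectorized).
#' @examples
#' ckd_epi_egfr(0.9, 0.8, 50, "male")
#' @export
ckd_epi_egfr <- function(scr, scys, age, sex, race_black = FALSE) {
  sex <- tolower(as.character(sex))
  if (!all(sex %in% c("male", "female")))
    stop("sex must be 'male' or 'female'", call. = FALSE)
  if (any(!is.finite(scr) | scr <= 0) || any(!is.finite(scys) | scys <= 0))
    stop("serum creatinine and cystatin C must be positive", call. = FALSE)
  if (any(!is.finite(age) | age < 18))
    stop("the equation applies to adults (age >= 18)", call. = FALSE)
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.248, -0.207)
  ratio_cr <- scr / kappa
  ratio_cys <- scys / 0.8
  egfr <- 135 *
    pmin(ratio_cr, 1)^alpha * pmax(ratio_cr, 1)^-0.601 *
    pmin(ratio_cys, 1)^-0.375 * pmax(ratio_cys, 1)^-0.711 *
    0.995^age * ifelse(female, 0.969, 1)
  if (any(race_black)) egfr <- egfr * ifelse(race_black, 1.08, 1)
  egfr
}

#' Derive kidney phenotypes for an individual-level dataset
#'
#' Computes eGFR via [ckd_epi_egfr()], its natural-log transform, and CKD
#' status (strictly `egfr < 60` ml/min/1.73 m^2).
#'
#' @param data an `individual_dataset` (see [individual_dataset()]), or a
#'   data frame with columns `scr`, `scys`, `age`, `sex`.
#' @return the input with columns `egfr`, `log_egfr`, `ckd`
#'   added/overwritten.
#' @export
derive_kidney_phenotypes <- function(data) {
  ph <- if (inherits(data, "individual_dataset")) data$pheno else data
  ph$egfr <- ckd_epi_egfr(ph$scr, ph$scys, ph$age, ph$sex)
  ph$log_egfr <- log(ph$egfr)
  ph$ckd <- ph$egfr < 60
  if (inherits(data, "individual_dataset")) { data$pheno <- ph; data }
  else ph
}

#' Individual-level dataset for allele-score MR
#'
#' Bundles a dosage matrix (participants x SNPs, additively coded in
#' \[0, 2\]), a phenotype/covariate table and the SNP annotation (effect
#' and other allele per dosage column).
#'
#' @param dosage numeric matrix, rows = participants, columns = SNPs
#'   (column names are SNP ids), entries in \[0, 2\].
#' @param pheno data frame with one row per participant; expected columns
#'   include `scr`, `scys`, `age`, `sex`, covariates (`bmi`,
#'   `hypertension`, `diabetes`, `hypercholesterolemia`, `ldl`, `hdl`,
#'   `smoking`) and `pc1` ... `pc10`.
#' @param snp_info data frame with columns `snp`, `ea`, `oa` (the dosage
#'   counts copies of `ea`).
#' @return object of class `individual_dataset`.
#' @export
individual_dataset <- function(dosage, pheno, snp_info) {
  stopifnot(is.matrix(dosage), nrow(dosage) == nrow(pheno),
            ncol(dosage) == nrow(snp_info),
            identical(colnames(dosage), snp_info$snp))
  if (any(dosage < 0 | dosage > 2))
    stop("dosages must lie in [0, 2]", call. = FALSE)
  structure(list(dosage = dosage, pheno = pheno, snp_info = snp_info),
            class = "individual_dataset")
}

#' @export
print.individual_dataset <- function(x, ...) {
  cat(sprintf("Individual-level dataset: %d participants, %d SNPs\n",
              nrow(x$dosage), ncol(x$dosage)))
  if (!is.null(x$pheno$ckd))
    cat(sprintf("  CKD cases: %d (%.1f%%)\n", sum(x$pheno$ckd),
                100 * mean(x$pheno$ckd)))
  invisible(x)
}

#' Read a PLINK .raw-style additive dosage matrix
#'
#' Expects a whitespace- or tab-delimited header of `FID IID` (any further
#' non-SNP columns such as `PAT MAT SEX PHENOTYPE` are ignored) followed
#' by one column per SNP named `<snpid>_<effect allele>`.
#'
#' @param path file path.
#' @return list with `dosage` (matrix, SNP ids as column names) and
#'   `snp_info` (data frame `snp`, `ea`).
#' @export
read_dosage <- function(path) {
  raw <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                           check.names = FALSE)
  drop_cols <- intersect(c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE"),
                         names(raw))
  snp_cols <- setdiff(names(raw), drop_cols)
  m <- regmatches(snp_cols, regexec("^(.*)_([ACGT])$", snp_cols))
  bad <- vapply(m, length, integer(1L)) != 3L
  if (any(bad))
    stop("dosage columns must be named <snpid>_<allele>: ",
         paste(snp_cols[bad], collapse = ", "), call. = FALSE)
  snp <- vapply(m, `[`, character(1L), 2L)
  ea <- vapply(m, `[`, character(1L), 3L)
  dosage <- as.matrix(raw[, snp_cols, drop = FALSE])
  colnames(dosage) <- snp
  list(dosage = dosage, snp_info = data.frame(snp = snp, ea = ea,
                                              stringsAsFactors = FALSE))
}

#' Build a weighted allele score from an instrument
#'
#' For each participant the per-SNP effect size is multiplied by the
#' participant's dosage of the effect allele and summed across the
#' instrument; the raw score is then z-score standardized (mean 0,
#' variance 1).  Dosage columns whose effect allele is the instrument's
#' other allele are flipped (`2 - d`) and logged; a SNP missing from the
#' dosage matrix is an error.
#'
#' @param data an `individual_dataset`.
#' @param instrument a [summary_table()] of instrument SNPs (`beta` is the
#'   per-allele weight; `ea`/`oa` define orientation).
#' @return object of class `allele_score`: list with `raw`, `z`
#'   (standardized), `snps` (used ids), `flipped` (ids flipped to match).
#' @export
build_allele_score <- function(data, instrument) {
  stopifnot(inherits(data, "individual_dataset"),
            inherits(instrument, "summary_table"))
  idx <- match(instrument$snp, colnames(data$dosage))
  if (any(is.na(idx)))
    stop("instrument SNP(s) missing from dosage matrix: ",
         paste(instrument$snp[is.na(idx)], collapse = ", "),
         call. = FALSE)
  info <- data$snp_info[idx, , drop = FALSE]
  d <- data$dosage[, idx, drop = FALSE]
  same <- info$ea == instrument$ea
  flip <- !same & (is.na(info$oa) | info$oa == instrument$ea |
                     info$ea == instrument$oa)
  mismatch <- !same & !flip
  if (any(mismatch))
    stop("allele mismatch between instrument and dosage data for: ",
         paste(instrument$snp[mismatch], collapse = ", "), call. = FALSE)
  if (any(flip)) d[, flip] <- 2 - d[, flip, drop = FALSE]
  raw <- drop(d %*% instrument$beta)
  sdr <- stats::sd(raw)
  if (!is.finite(sdr) || sdr == 0)
    stop("allele score has zero variance", call. = FALSE)
  structure(list(raw = raw, z = (raw - mean(raw)) / sdr,
                 snps = instrument$snp, flipped = instrument$snp[flip]),
            class = "allele_score")
}

#' Rank-based inverse-normal transform (optional score standardization)
#'
#' Blom-offset rank inverse-normal transform, offered as an alternative to
#' z-score standardization of the raw allele score.
#'
#' @param x numeric vector.
#' @return transformed vector with a standard-normal marginal.
#' @export
rank_inverse_normal <- function(x) {
  stats::qnorm((rank(x, ties.method = "average") - 3 / 8) /
                 (length(x) + 1 / 4))
}

#' Association of an allele score with kidney phenotypes
#'
#' One-sample MR association models: a linear model of log-eGFR (effect
#' per 1 SD of the score) or a logistic model of CKD status (reported on
#' the odds-ratio scale), with covariate adjustment.  Model 1 adjusts for
#' age, sex and 10 ancestry principal components; Model 2 additionally
#' adjusts for hypertension, diabetes, hypercholesterolemia, lipid
#' measures, BMI and smoking.
#'
#' @param score an [build_allele_score()] result (its standardized score
#'   is used), or a numeric vector already standardized.
#' @param data an `individual_dataset` whose phenotypes include the
#'   outcome (run [derive_kidney_phenotypes()] first if needed).
#' @param outcome `"log_egfr"` (linear) or `"ckd"` (logistic).
#' @param model covariate set, `1` or `2`.
#' @return object of class `score_mr`: list with `beta` (per 1 SD; log
#'   odds for CKD), `se`, `ci_low`, `ci_high`, `pvalue`, `or`/`or_ci`
#'   (binary only), `outcome`, `model`, `n`, and the underlying `fit`.
#' @export
score_association <- function(score, data, outcome = c("log_egfr", "ckd"),
                              model = 1) {
  outcome <- match.arg(outcome)
  stopifnot(inherits(data, "individual_dataset"), model %in% c(1, 2))
  z <- if (inherits(score, "allele_score")) score$z else as.numeric(score)
  ph <- data$pheno
  if (is.null(ph[[outcome]]))
    stop("outcome '", outcome, "' not present; run ",
         "derive_kidney_phenotypes() first", call. = FALSE)
  covars <- c("age", "sex", paste0("pc", 1:10))
  if (model == 2)
    covars <- c(covars, intersect(c("hypertension", "diabetes",
                                    "hypercholesterolemia", "ldl", "hdl",
                                    "triglycerides", "bmi", "smoking"),
                                  names(ph)))
  missing_cov <- setdiff(covars, names(ph))
  if (length(missing_cov) > 0L)
    stop("missing covariate column(s): ",
         paste(missing_cov, collapse = ", "), call. = FALSE)
  df <- cbind(data.frame(.y = ph[[outcome]], .score = z),
              ph[, covars, drop = FALSE])
  form <- stats::as.formula(paste(".y ~ .score +",
                                  paste(covars, collapse = " + ")))
  fit <- if (outcome == "ckd")
    stats::glm(form, data = df, family = stats::binomial())
  else stats::lm(form, data = df)
  aliased <- is.na(stats::coef(fit))
  if (any(aliased))
    stop("singular design; aliased column(s): ",
         paste(names(stats::coef(fit))[aliased], collapse = ", "),
         call. = FALSE)
  sm <- summary(fit)$coefficients
  est <- sm[".score", 1L]; se <- sm[".score", 2L]; p <- sm[".score", 4L]
  zc <- stats::qnorm(0.975)
  out <- list(beta = est, se = se, ci_low = est - zc * se,
              ci_high = est + zc * se, pvalue = p, outcome = outcome,
              model = model, n = nrow(df), fit = fit)
  if (outcome == "ckd") {
    out$or <- exp(est)
    out$or_ci <- exp(c(out$ci_low, out$ci_high))
  }
  structure(out, class = "score_mr")
}

#' @export
print.score_mr <- function(x, ...) {
  cat(sprintf("Allele-score MR association (Model %d, n = %d)\n",
              x$model, x$n))
  if (x$outcome == "ckd")
    cat(sprintf("  CKD: OR per 1 SD = %.3f (95%% CI %.3f to %.3f), p = %.3g\n",
                x$or, x$or_ci[1L], x$or_ci[2L], x$pvalue))
  else
    cat(sprintf("  log-eGFR: beta per 1 SD = %.5f (95%% CI %.5f to %.5f), p = %.3g\n",
                x$beta, x$ci_low, x$ci_high, x$pvalue))
  invisible(x)
}
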