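#' Harmonize exposure and outcome summary statistics
#'
#' Places SNP-exposure and SNP-outcome association summaries on a common
#' effect-allele frame so that the Wald ratio Gamma_j / gamma_j is
#' meaningful.  Variants are matched by SNP id.  If the outcome's alleles
#' are swapped relative to the exposure the outcome beta is sign-flipped
#' and its effect-allele frequency complemented; for non-palindromic
#' variants a strand flip (A<->T, C<->G complement) is attempted before a
#' pair is declared irreconcilable.  Palindromic variants (A/T or C/G),
#' whose strand cannot be resolved from allele labels, are aligned by
#' comparing allele frequencies — but only when both frequencies are away
#' from 0.5; a palindromic variant with either frequency inside
#' `0.5 +/- palindrome_eaf_window` (or with a missing frequency) is dropped
#' as ambiguous.  Finally, with `orient_increasing = TRUE` every retained
#' variant is oriented so that the exposure effect is non-negative (both
#' betas flipped together), the convention of aligning instruments toward
#' increasing exposure.
#'
#' Dropped variants stay in the returned set, flagged with a reason
#' (`"palindromic-ambiguous"` or `"allele-mismatch"`), so the harmonization
#' is fully auditable and retained + dropped always equals matched.
#'
#' @param exposure,outcome [summary_table()] objects sharing SNP ids.
#' @param palindrome_eaf_window half-width w of the ambiguity window: a
#'   palindromic SNP is only frequency-alignable when both eafs lie outside
#'   `[0.5 - w, 0.5 + w]`.  Default 0.08 (ambiguous in `[0.42, 0.58]`), the
#'   conventional choice.
#' @param orient_increasing orient all pairs so `beta_exp >= 0`.
#' @return object of class `harmonized_set`: a data frame with one row per
#'   matched SNP and columns `snp`, `chr`, `pos`, `ea`, `oa`, `beta_exp`,
#'   `se_exp`, `eaf_exp`, `p_exp`, `n_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `p_out`, `n_out`, `palindromic`, `allele_flipped`,
#'   `dropped`, `drop_reason`.
#' @examples
#' exp <- summary_table(data.frame(
#'   snp = c("rs1", "rs2"), ea = c("A", "A"), oa = c("G", "T"),
#'   eaf = c(0.3, 0.1), beta = c(0.1, 0.1), se = c(0.01, 0.01),
#'   p = c(1e-20, 1e-20), n = 30000))
#' out <- summary_table(data.frame(
#'   snp = c("rs1", "rs2"), ea = c("G", "A"), oa = c("A", "T"),
#'   eaf = c(0.7, 0.88), beta = c(-0.05, 0.02), se = c(0.01, 0.01),
#'   p = c(1e-6, 0.05), n = 50000))
#' h <- harmonize(exp, out)
#' h$beta_out    # rs1 swapped to +0.05; rs2 frequency-aligned
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      orient_increasing = TRUE) {
  stopifnot(inherits(exposure, "summary_table"),
            inherits(outcome, "summary_table"),
            palindrome_eaf_window >= 0, palindrome_eaf_window < 0.5)
  common <- intersect(exposure$snp, outcome$snp)
  if (length(common) == 0L)
    stop("no SNPs shared between exposure and outcome tables",
         call. = FALSE)
  ex <- exposure[match(common, exposure$snp), ]
  ou <- outcome[match(common, outcome$snp), ]

  comp <- c(A = "T", T = "A", C = "G", G = "C")
  pal <- ex$ea == comp[ex$oa]            # A/T or C/G on the exposure side

  beta_out <- ou$beta
  eaf_out <- ou$eaf
  flipped <- logical(length(common))
  dropped <- logical(length(common))
  reason <- rep(NA_character_, length(common))

  same <- ou$ea == ex$ea & ou$oa == ex$oa
  swap <- ou$ea == ex$oa & ou$oa == ex$ea
  strand_same <- !pal & comp[ou$ea] == ex$ea & comp[ou$oa] == ex$oa
  strand_swap <- !pal & comp[ou$ea] == ex$oa & comp[ou$oa] == ex$ea

  mismatch <- !(same | swap | strand_same | strand_swap)
  dropped[mismatch] <- TRUE
  reason[mismatch] <- "allele-mismatch"

  do_flip <- (swap | strand_swap) & !mismatch
  beta_out[do_flip] <- -beta_out[do_flip]
  eaf_out[do_flip] <- 1 - eaf_out[do_flip]
  flipped[do_flip] <- TRUE

  # palindromic resolution by allele frequency
  w <- palindrome_eaf_window
  near_half <- function(f) !is.na(f) & f >= 0.5 - w & f <= 0.5 + w
  pal_idx <- which(pal & !dropped)
  for (i in pal_idx) {
    fe <- ex$eaf[i]; fo <- eaf_out[i]
    if (is.na(fe) || is.na(fo) || near_half(fe) || near_half(fo)) {
      dropped[i] <- TRUE
      reason[i] <- "palindromic-ambiguous"
    } else if ((fe < 0.5) != (fo < 0.5)) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
      flipped[i] <- !flipped[i]
    }
  }

  h <- data.frame(
    snp = common, chr = ex$chr, pos = ex$pos, ea = ex$ea, oa = ex$oa,
    beta_exp = ex$beta, se_exp = ex$se, eaf_exp = ex$eaf, p_exp = ex$p,
    n_exp = ex$n, beta_out = beta_out, se_out = ou$se, eaf_out = eaf_out,
    p_out = ou$p, n_out = ou$n, palindromic = pal,
    allele_flipped = flipped, dropped = dropped, drop_reason = reason,
    stringsAsFactors = FALSE)

  if (orient_increasing) {
    neg <- !h$dropped & h$beta_exp < 0
    if (any(neg)) {
      tmp <- h$ea[neg]; h$ea[neg] <- h$oa[neg]; h$oa[neg] <- tmp
      h$beta_exp[neg] <- -h$beta_exp[neg]
      h$beta_out[neg] <- -h$beta_out[neg]
      h$eaf_exp[neg] <- 1 - h$eaf_exp[neg]
      h$eaf_out[neg] <- 1 - h$eaf_out[neg]
    }
  }
  rownames(h) <- NULL
  structure(h,
            exposure = attr(exposure, "trait_label"),
            outcome = attr(outcome, "trait_label"),
            outcome_type = attr(outcome, "trait_type"),
            palindrome_eaf_window = palindrome_eaf_window,
            orient_increasing = orient_increasing,
            class = c("harmonized_set", "data.frame"))
}

#' Construct a harmonized set directly from aligned effect vectors
#'
#' Convenience constructor for simulation studies and tests where both
#' traits are already on a common allele frame.
#'
#' @param beta_exp,se_exp SNP-exposure effects and standard errors.
#' @param beta_out,se_out SNP-outcome effects and standard errors.
#' @param snp SNP ids (generated if omitted).
#' @param n_exp,n_out per-SNP sample sizes (optional, needed for Steiger).
#' @param eaf_exp,eaf_out effect-allele frequencies (optional).
#' @param exposure,outcome trait labels.
#' @param outcome_type `"continuous"` or `"binary"`.
#' @return a `harmonized_set`.
#' @export
harmonized_set <- function(beta_exp, se_exp, beta_out, se_out, snp = NULL,
                           n_exp = NA, n_out = NA, eaf_exp = NA,
                           eaf_out = NA, exposure = "exposure",
                           outcome = "outcome",
                           outcome_type = "continuous") {
  J <- length(beta_exp)
  stopifnot(length(se_exp) == J, length(beta_out) == J,
            length(se_out) == J, all(se_exp > 0), all(se_out > 0))
  if (is.null(snp)) snp <- sprintf("snp%03d", seq_len(J))
  h <- data.frame(snp = as.character(snp), chr = NA_character_,
                  pos = NA_real_, ea = NA_character_, oa = NA_character_,
                  beta_exp = beta_exp, se_exp = se_exp,
                  eaf_exp = as.numeric(eaf_exp), p_exp = NA_real_,
                  n_exp = as.numeric(n_exp), beta_out = beta_out,
                  se_out = se_out, eaf_out = as.numeric(eaf_out),
                  p_out = NA_real_, n_out = as.numeric(n_out),
                  palindromic = FALSE, allele_flipped = FALSE,
                  dropped = FALSE, drop_reason = NA_character_,
                  stringsAsFactors = FALSE)
  structure(h, exposure = exposure, outcome = outcome,
            outcome_type = outcome_type,
            class = c("harmonized_set", "data.frame"))
}

#' Retained (non-dropped) rows of a harmonized set
#' @param h a `harmonized_set`.
#' @return the subset of rows with `dropped == FALSE`, same class.
#' @export
retained <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  out <- h[!h$dropped, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat(sprintf("Harmonized set: %s -> %s; %d matched SNPs (%d retained, %d dropped)\n",
              attr(x, "exposure") %||% "exposure",
              attr(x, "outcome") %||% "outcome",
              nrow(x), sum(!x$dropped), sum(x$dropped)))
  if (any(x$dropped)) {
    tb <- table(x$drop_reason[x$dropped])
    cat("  drop reasons:",
        paste(sprintf("%s (%d)", names(tb), tb), collapse = ", "), "\n")
  }
  print(as.data.frame(utils::head(x[, c("snp", "beta_exp", "se_exp",
                                        "beta_out", "se_out", "dropped")],
                                  10L)), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Keep subclass on subsetting so retained()/estimators keep working.
#' @export
`[.harmonized_set` <- function(x, ...) {
  out <- NextMethod()
  if (is.data.frame(out) && all(c("beta_exp", "beta_out") %in% names(out))) {
    attributes(out)[c("exposure", "outcome", "outcome_type")] <-
      attributes(x)[c("exposure", "outcome", "outcome_type")]
    class(out) <- c("harmonized_set", "data.frame")
  }
  out
}
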