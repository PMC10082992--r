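#' Pairwise linkage-disequilibrium information
#'
#' Holds user-supplied pairwise r-squared values between SNPs, as produced
#' by reference-panel LD calculations.  Stored sparsely: any pair not
#' listed is treated as r-squared 0 (with a warning from the consumer),
#' since sparse LD inputs are the norm.
#'
#' @param pairs data frame with columns `snp_a`, `snp_b`, `r2` (in
#'   \[0, 1\]).  Order of the two ids is immaterial; self pairs are
#'   implicit (r2 = 1).
#' @return object of class `ld_info`.
#' @export
ld_info <- function(pairs = NULL) {
  if (is.null(pairs))
    pairs <- data.frame(snp_a = character(), snp_b = character(),
                        r2 = numeric())
  stopifnot(all(c("snp_a", "snp_b", "r2") %in% names(pairs)))
  pairs$snp_a <- as.character(pairs$snp_a)
  pairs$snp_b <- as.character(pairs$snp_b)
  pairs$r2 <- as.numeric(pairs$r2)
  if (any(is.na(pairs$r2)) || any(pairs$r2 < 0 | pairs$r2 > 1))
    stop("r2 values must lie in [0, 1]", call. = FALSE)
  key <- ifelse(pairs$snp_a < pairs$snp_b,
                paste(pairs$snp_a, pairs$snp_b, sep = "\r"),
                paste(pairs$snp_b, pairs$snp_a, sep = "\r"))
  dup <- duplicated(key)
  if (any(dup)) { pairs <- pairs[!dup, , drop = FALSE]; key <- key[!dup] }
  structure(list(pairs = pairs,
                 map = stats::setNames(pairs$r2, key)),
            class = "ld_info")
}

#' Read LD pairs from a 3-column TSV (snp_a, snp_b, r2)
#' @param path file path.
#' @return an [ld_info()] object.
#' @export
read_ld <- function(path) {
  ld <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  ld_info(ld)
}

# r2 lookup; NA when the pair is absent (caller decides how to treat it).
.ld_r2 <- function(ld, a, b) {
  if (a == b) return(1)
  key <- if (a < b) paste(a, b, sep = "\r") else paste(b, a, sep = "\r")
  val <- ld$map[key]
  unname(val)
}

#' Greedy LD clumping of genome-wide significant SNPs
#'
#' Selects an approximately independent instrument: SNPs passing the
#' significance threshold are ranked by p-value and greedily retained,
#' each retained SNP discarding weaker SNPs on the same chromosome within
#' `window_kb` whose r-squared with it reaches `r2_max`.  This mirrors the
#' conventional construction of genome-wide significant, independent
#' instruments (500-kb window, r2 < 0.1, P < 5e-8).
#'
#' Ties in p-value are broken by (chr, pos, snp) lexical order so the
#' result does not depend on input row order.  LD pairs absent from `ld`
#' are treated as r2 = 0, with a single warning giving the count.
#'
#' @param table a [summary_table()]; `chr` and `pos` must be present for
#'   every SNP passing `p_threshold`.
#' @param ld an [ld_info()] object (or `NULL` for distance-only clumping).
#' @param p_threshold significance level, default genome-wide `5e-8`
#'   (strictly `p < p_threshold`).
#' @param window_kb clumping window in kilobases, default 500.
#' @param r2_max LD ceiling: SNPs with `r2 >= r2_max` to a better SNP
#'   within the window are discarded.  Default 0.1.
#' @return a [summary_table()] of retained SNPs, with attribute
#'   `clump_log` (data frame: discarded snp, the index snp that removed
#'   it, r2, distance in kb).
#' @export
select_and_clump <- function(table, ld = NULL, p_threshold = 5e-8,
                             window_kb = 500, r2_max = 0.1) {
  stopifnot(inherits(table, "summary_table"))
  if (is.null(ld)) ld <- ld_info()
  stopifnot(inherits(ld, "ld_info"))
  qual <- table[!is.na(table$p) & table$p < p_threshold, , drop = FALSE]
  if (nrow(qual) == 0L) {
    warning("no SNP passes the significance threshold; empty instrument",
            call. = FALSE)
    out <- table[0L, , drop = FALSE]
    attr(out, "clump_log") <- data.frame(snp = character(),
                                         removed_by = character(),
                                         r2 = numeric(), dist_kb = numeric())
    return(out)
  }
  if (any(is.na(qual$chr)) || any(is.na(qual$pos)))
    stop("chr and pos are required for clumping and are missing for: ",
         paste(qual$snp[is.na(qual$chr) | is.na(qual$pos)], collapse = ", "),
         call. = FALSE)

  ord <- order(qual$p, qual$chr, qual$pos, qual$snp)
  qual <- qual[ord, , drop = FALSE]
  keep <- character(); log <- list(); missing_pairs <- 0L
  remaining <- seq_len(nrow(qual))
  while (length(remaining) > 0L) {
    i <- remaining[1L]
    keep <- c(keep, qual$snp[i])
    remaining <- remaining[-1L]
    if (length(remaining) == 0L) break
    drop_here <- logical(length(remaining))
    for (k in seq_along(remaining)) {
      j <- remaining[k]
      if (qual$chr[j] != qual$chr[i]) next
      dist_kb <- abs(qual$pos[j] - qual$pos[i]) / 1000
      if (dist_kb > window_kb) next
      r2 <- .ld_r2(ld, qual$snp[i], qual$snp[j])
      if (is.na(r2)) { missing_pairs <- missing_pairs + 1L; r2 <- 0 }
      if (r2 >= r2_max) {
        drop_here[k] <- TRUE
        log[[length(log) + 1L]] <- data.frame(
          snp = qual$snp[j], removed_by = qual$snp[i], r2 = r2,
          dist_kb = dist_kb, stringsAsFactors = FALSE)
      }
    }
    remaining <- remaining[!drop_here]
  }
  if (missing_pairs > 0L)
    warning(sprintf("%d SNP pair(s) absent from LD info treated as r2 = 0",
                    missing_pairs), call. = FALSE)
  out <- table[table$snp %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clump_log") <- if (length(log) > 0L) do.call(rbind, log) else
    data.frame(snp = character(), removed_by = character(), r2 = numeric(),
               dist_kb = numeric())
  out
}

#' Remove SNPs on (or in high LD with) an exclusion list
#'
#' Implements confounder/pleiotropy exclusion from user-supplied lists
#' (e.g. SNPs robustly associated with blood pressure, diabetes, BMI or
#' smoking): any instrument SNP that is itself listed, or that has
#' `r2 > r2_proxy` with a listed SNP, is removed.
#'
#' @param table a [summary_table()].
#' @param excluded_snps character vector of SNP ids to exclude.
#' @param ld an [ld_info()] covering instrument-by-excluded pairs
#'   (optional; without it only exact id matches are removed).
#' @param r2_proxy LD ceiling above which a SNP is treated as a proxy for
#'   an excluded SNP; default 0.8 (removal requires `r2 > r2_proxy`).
#' @return filtered [summary_table()] with attribute `exclusion_log`
#'   (snp, trigger, r2).
#' @export
apply_exclusion_list <- function(table, excluded_snps, ld = NULL,
                                 r2_proxy = 0.8) {
  stopifnot(inherits(table, "summary_table"))
  excluded_snps <- as.character(excluded_snps)
  log <- list()
  drop <- rep(FALSE, nrow(table))
  for (i in seq_len(nrow(table))) {
    id <- table$snp[i]
    if (id %in% excluded_snps) {
      drop[i] <- TRUE
      log[[length(log) + 1L]] <- data.frame(snp = id, trigger = id, r2 = 1,
                                            stringsAsFactors = FALSE)
    } else if (!is.null(ld)) {
      for (ex in excluded_snps) {
        r2 <- .ld_r2(ld, id, ex)
        if (!is.na(r2) && r2 > r2_proxy) {
          drop[i] <- TRUE
          log[[length(log) + 1L]] <- data.frame(snp = id, trigger = ex,
                                                r2 = r2,
                                                stringsAsFactors = FALSE)
          break
        }
      }
    }
  }
  out <- table[!drop, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusion_log") <- if (length(log) > 0L) do.call(rbind, log)
    else data.frame(snp = character(), trigger = character(), r2 = numeric())
  out
}

#' Refine an instrument against a second marker of the same trait
#'
#' For composite kidney-function instruments, index SNPs for the primary
#' marker (creatinine-based eGFR) are retained only when they also show a
#' Bonferroni-significant association with a second marker of kidney
#' function (cystatin-C-based eGFR, or blood urea nitrogen as an inverse
#' marker), guarding against instruments that reflect creatinine
#' metabolism rather than kidney function.
#'
#' @param primary [summary_table()] of index SNPs for the primary marker.
#' @param secondary [summary_table()] of the same SNPs for the second
#'   marker; index SNPs absent from it are removed with reason
#'   `"no-secondary-data"`.
#' @param n_index number of index SNPs entering refinement (Bonferroni
#'   denominator); defaults to `nrow(primary)`.
#' @param require_direction also require the secondary effect to have the
#'   expected sign.  Default `TRUE`.
#' @param marker `"concordant"` (secondary beta must share the primary
#'   sign, e.g. cystatin-based eGFR) or `"discordant"` (opposite sign,
#'   e.g. BUN).
#' @return filtered [summary_table()] (primary-trait records) with
#'   attribute `refine_log` (snp, reason).
#' @export
dual_marker_refine <- function(primary, secondary, n_index = nrow(primary),
                               require_direction = TRUE,
                               marker = c("concordant", "discordant")) {
  marker <- match.arg(marker)
  stopifnot(inherits(primary, "summary_table"),
            inherits(secondary, "summary_table"))
  if (n_index <= 0) stop("n_index must be positive", call. = FALSE)
  thr <- 0.05 / n_index
  idx <- match(primary$snp, secondary$snp)
  reason <- rep(NA_character_, nrow(primary))
  reason[is.na(idx)] <- "no-secondary-data"
  p_sec <- secondary$p[idx]
  b_sec <- secondary$beta[idx]
  weak <- !is.na(idx) & p_sec >= thr
  reason[weak] <- "secondary-not-significant"
  if (require_direction) {
    ok_dir <- if (marker == "concordant") sign(b_sec) == sign(primary$beta)
              else sign(b_sec) == -sign(primary$beta)
    bad_dir <- !is.na(idx) & !weak & !ok_dir
    reason[bad_dir] <- "secondary-direction"
  }
  keep <- is.na(reason)
  out <- primary[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "refine_log") <- data.frame(snp = primary$snp[!keep],
                                        reason = reason[!keep],
                                        stringsAsFactors = FALSE)
  out
}

# Per-trait variance explained by one SNP from its t-statistic:
# r2 = t^2 / (t^2 + n - 2), with t = beta / se.
.r2_from_t <- function(beta, se, n) {
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Per-SNP Steiger directionality computations
#'
#' For each retained SNP, the variance explained in the exposure and in
#' the outcome is computed from the t-statistic, r2 = t^2/(t^2 + n - 2),
#' and the two implied correlations are compared with a Fisher-z test:
#' z = (atanh r_exp - atanh r_out) / sqrt(1/(n_exp - 3) + 1/(n_out - 3)).
#' A SNP supports the assumed exposure-to-outcome direction when it
#' explains more variance in the exposure than in the outcome.
#'
#' @param h a `harmonized_set` with `n_exp` and `n_out` present.
#' @return data frame with columns `snp`, `r2_exp`, `r2_out`,
#'   `direction_ok`, `steiger_z`, `steiger_p` (two-sided).
#' @export
steiger_stats <- function(h) {
  stopifnot(inherits(h, "harmonized_set"))
  r <- retained(h)
  if (any(is.na(r$n_exp)) || any(is.na(r$n_out)))
    stop("n_exp and n_out are required for Steiger computations",
         call. = FALSE)
  if (any(r$n_exp <= 3) || any(r$n_out <= 3))
    stop("sample sizes must exceed 3 for the Fisher-z variance",
         call. = FALSE)
  r2_exp <- .r2_from_t(r$beta_exp, r$se_exp, r$n_exp)
  r2_out <- .r2_from_t(r$beta_out, r$se_out, r$n_out)
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (r$n_exp - 3) + 1 / (r$n_out - 3))
  data.frame(snp = r$snp, r2_exp = r2_exp, r2_out = r2_out,
             direction_ok = r2_exp > r2_out, steiger_z = z,
             steiger_p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}

#' Steiger filtering of a harmonized instrument
#'
#' Removes SNPs that fail to explain more variance in the exposure than in
#' the outcome, confirming the directionality of the instrument.  In mode
#' `"point"` (default) the point comparison `r2_exp > r2_out` decides; in
#' mode `"significance"` a SNP must additionally have a Fisher-z p-value
#' below `alpha`.
#'
#' @param h a `harmonized_set` with per-SNP sample sizes.
#' @param mode `"point"` or `"significance"`.
#' @param alpha significance level for mode `"significance"`; the per-SNP
#'   p-value is always reported.  Default 0.05.
#' @return list with `h` (the set with failing SNPs flagged dropped,
#'   reason `"steiger-direction"`) and `steiger` (the [steiger_stats()]
#'   table).
#' @export
steiger_filter <- function(h, mode = c("point", "significance"),
                           alpha = 0.05) {
  mode <- match.arg(mode)
  st <- steiger_stats(h)
  fail <- !st$direction_ok
  if (mode == "significance") fail <- fail | st$steiger_p >= alpha
  bad <- st$snp[fail]
  idx <- h$snp %in% bad & !h$dropped
  h$dropped[idx] <- TRUE
  h$drop_reason[idx] <- "steiger-direction"
  list(h = h, steiger = st)
}

#' Instrument-strength diagnostics
#'
#' Computes the per-SNP F-statistic F_j = (beta_exp/se_exp)^2 (with mean
#' and minimum), the heterogeneity of the SNP-exposure effects Q_GX and
#' its I2 (the I2_GX statistic quantifying violation of the no-measurement-
#' error assumption relevant for MR-Egger), and the total variance in the
#' exposure explained by the instrument.  A mean F below 10 is flagged as
#' a weak instrument by convention.
#'
#' @param h a `harmonized_set`.
#' @return object of class `strength_stats`: list with `f_per_snp`,
#'   `f_mean`, `f_min`, `q_gx`, `i2_gx` (clamped to \[0, 1\]; `NA` with a
#'   single SNP), `r2_instrument` (`NA` without sample sizes), `n_snps`,
#'   `weak_instrument` flag.
#' @export
instrument_strength <- function(h) {
  r <- retained(h)
  J <- nrow(r)
  if (J < 1L) stop("no retained SNPs", call. = FALSE)
  f <- (r$beta_exp / r$se_exp)^2
  if (J >= 2L) {
    v <- 1 / r$se_exp^2
    gbar <- sum(v * r$beta_exp) / sum(v)
    q_gx <- sum(v * (r$beta_exp - gbar)^2)
    i2 <- max(0, (q_gx - (J - 1)) / q_gx)
  } else {
    q_gx <- NA_real_; i2 <- NA_real_
  }
  r2 <- if (all(!is.na(r$n_exp))) sum(.r2_from_t(r$beta_exp, r$se_exp,
                                                 r$n_exp)) else NA_real_
  structure(list(f_per_snp = stats::setNames(f, r$snp), f_mean = mean(f),
                 f_min = min(f), q_gx = q_gx, i2_gx = i2,
                 r2_instrument = r2, n_snps = J,
                 weak_instrument = mean(f) < 10),
            class = "strength_stats")
}

#' @export
print.strength_stats <- function(x, ...) {
  cat("Instrument strength diagnostics\n")
  cat(sprintf("  SNPs: %d\n", x$n_snps))
  cat(sprintf("  F-statistic: mean %.1f, min %.1f%s\n", x$f_mean, x$f_min,
              if (x$weak_instrument) "  [weak instrument: mean F < 10]"
              else ""))
  if (!is.na(x$i2_gx))
    cat(sprintf("  I2_GX: %.1f%% (Q_GX = %.2f)\n", 100 * x$i2_gx, x$q_gx))
  if (!is.na(x$r2_instrument))
    cat(sprintf("  Variance explained in exposure: %.2f%%\n",
                100 * x$r2_instrument))
  invisible(x)
}

#' Read a one-id-per-line exclusion list
#' @param path text file with one SNP id per line (blank lines and lines
#'   starting with `#` ignored).
#' @return character vector of ids.
#' @export
read_exclusion_list <- function(path) {
  x <- readLines(path, warn = FALSE)
  x <- trimws(x)
  x[nzchar(x) & !startsWith(x, "#")]
}
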