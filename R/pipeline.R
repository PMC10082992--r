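#' Rescale an MR estimate to a different exposure unit or the odds scale
#'
#' Multiplies the point estimate, standard error and confidence limits by
#' `factor` (e.g. 5 to report effects per 5-year increase in genetically
#' predicted epigenetic age acceleration), and optionally exponentiates
#' the point estimate and limits to the odds-ratio scale for binary
#' outcomes.  The p-value is unchanged in both cases.
#'
#' @param est an `mr_fit`.
#' @param factor positive exposure-unit multiple.
#' @param odds_scale exponentiate after scaling (binary outcomes).
#' @return the rescaled `mr_fit` (field `odds_scale` records the scale;
#'   `se` stays on the log-odds scale when exponentiated).
#' @export
scale_effect <- function(est, factor = 1, odds_scale = FALSE) {
  stopifnot(inherits(est, "mr_fit"), factor > 0)
  est$beta <- est$beta * factor
  est$se <- est$se * factor
  est$ci_low <- est$ci_low * factor
  est$ci_high <- est$ci_high * factor
  if (odds_scale) {
    est$beta <- exp(est$beta)
    est$ci_low <- exp(est$ci_low)
    est$ci_high <- exp(est$ci_high)
    est$odds_scale <- TRUE
  }
  est
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1, original order
#' restored), as used to account for multiple testing across the four
#' epigenetic-clock measures.  Thin wrapper over [stats::p.adjust()].
#'
#' @param pvalues numeric vector of p-values in (0, 1].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(pvalues) {
  if (length(pvalues) == 0L) return(numeric(0))
  if (any(!is.na(pvalues) & (pvalues <= 0 | pvalues > 1)))
    stop("p-values must lie in (0, 1]", call. = FALSE)
  stats::p.adjust(pvalues, method = "BH")
}

.as_table <- function(x, what) {
  if (inherits(x, "summary_table")) return(x)
  if (is.character(x) && length(x) == 1L)
    return(read_summary_stats(x, trait_label = what))
  stop("cannot interpret ", what, " input (need a summary_table or path)",
       call. = FALSE)
}

# Small deterministic config fingerprint (polynomial rolling hash over
# the deparsed list, kept within 31 bits).
.config_hash <- function(x) {
  s <- paste(deparse(x), collapse = "")
  h <- 0
  for (b in utf8ToInt(s)) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

# One exposure-outcome pair through the full analysis stack.
.run_pair <- function(exposure, outcome, settings, ld, exclusions,
                      pair_seed) {
  instr <- exposure
  if (isTRUE(settings$clump))
    instr <- suppressWarnings(select_and_clump(
      instr, ld, settings$p_threshold, settings$window_kb,
      settings$r2_max))
  if (length(exclusions) > 0L)
    instr <- apply_exclusion_list(instr, exclusions, ld,
                                  settings$r2_proxy)
  if (nrow(instr) == 0L) stop("empty instrument after filtering",
                              call. = FALSE)
  h <- harmonize(instr, outcome, settings$palindrome_eaf_window)
  steiger_tab <- NULL
  if (isTRUE(settings$steiger_filter) &&
      all(!is.na(retained(h)$n_exp)) && all(!is.na(retained(h)$n_out))) {
    sf <- steiger_filter(h)
    h <- sf$h; steiger_tab <- sf$steiger
  }
  J <- nrow(retained(h))
  if (J == 0L) stop("no SNPs retained after harmonization", call. = FALSE)

  odds <- identical(attr(h, "outcome_type"), "binary")
  out <- list(J = J, harmonized = h, steiger = steiger_tab)
  if (J >= 3L) {
    rk <- mr_rucker(h)
    out$rucker <- rk
    out$primary <- rk$estimate
    out$weighted_median <- mr_fit(h, "weighted_median",
                                  n_boot = settings$n_boot,
                                  seed = pair_seed)
    out$loo <- leave_one_out(h)
  } else {
    out$primary <- mr_fit(h, if (J == 1L) "wald" else "ivw")
  }
  if (J >= 4L)
    out$presso <- mr_presso(h, n_sim = settings$n_sim,
                            outlier_alpha = settings$outlier_alpha,
                            seed = pair_seed + 1L)
  out$strength <- instrument_strength(h)
  if (all(!is.na(retained(h)$n_exp)) && all(!is.na(retained(h)$n_out)))
    out$directionality <- steiger_directionality(h)
  out$scaled <- scale_effect(out$primary, settings$scale_factor,
                             odds_scale = odds)
  out
}

.pair_row <- function(direction, exp_name, out_name, res) {
  num <- function(x) if (is.null(x)) NA_real_ else x
  chr <- function(x) if (is.null(x)) NA_character_ else x
  data.frame(
    direction = direction, exposure = exp_name, outcome = out_name,
    status = "ok", n_snps = res$J,
    primary_method = res$primary$method,
    beta = res$scaled$beta, ci_low = res$scaled$ci_low,
    ci_high = res$scaled$ci_high, se = res$scaled$se,
    pvalue = res$primary$pvalue,
    odds_scale = isTRUE(res$scaled$odds_scale),
    egger_intercept_p = num(res$rucker$egger$intercept_p),
    q = num(res$rucker$heterogeneity$q),
    q_prime = num(res$rucker$heterogeneity$q_prime),
    p_diff = num(res$rucker$heterogeneity$p_diff),
    wm_beta = num(res$weighted_median$beta),
    wm_p = num(res$weighted_median$pvalue),
    presso_global_p = num(res$presso$global_p),
    presso_outliers = chr(if (!is.null(res$presso))
      paste(res$presso$outlier_ids, collapse = ",") else NULL),
    f_mean = res$strength$f_mean, i2_gx = num(res$strength$i2_gx),
    steiger_verdict = chr(res$directionality$verdict),
    stringsAsFactors = FALSE)
}

.failed_row <- function(direction, exp_name, out_name, msg) {
  row <- .pair_row(direction, exp_name, out_name,
                   list(J = NA_integer_,
                        primary = list(method = NA_character_,
                                       pvalue = NA_real_),
                        scaled = list(beta = NA_real_, ci_low = NA_real_,
                                      ci_high = NA_real_, se = NA_real_,
                                      odds_scale = NA),
                        strength = list(f_mean = NA_real_)))
  row$status <- paste0("failed: ", msg)
  row
}

#' Run a bidirectional two-sample MR analysis
#'
#' Orchestrates every configured exposure-outcome pair through instrument
#' filtering, harmonization, Steiger filtering, Ruecker model selection,
#' the sensitivity suite (weighted median, MR-PRESSO, leave-one-out),
#' strength and directionality diagnostics, effect scaling, and
#' false-discovery-rate adjustment within the configured family.  A
#' failing pair is recorded and does not stop the remaining pairs.
#' Identical config and seed give an identical results bundle.
#'
#' @param config a list with elements
#'   \describe{
#'     \item{`forward`/`reverse`}{each a list with `exposures` and
#'       `outcomes`: named lists of [summary_table()] objects or file
#'       paths.  Either direction may be omitted.}
#'     \item{`ld`}{optional [ld_info()] or LD TSV path.}
#'     \item{`exclusions`}{optional character vector of SNP ids or a
#'       one-id-per-line file path.}
#'     \item{`settings`}{optional overrides of the defaults: `clump`
#'       (TRUE), `p_threshold` (5e-8), `window_kb` (500), `r2_max` (0.1),
#'       `r2_proxy` (0.8), `palindrome_eaf_window` (0.08),
#'       `steiger_filter` (TRUE), `n_boot` (1000), `n_sim` (2000),
#'       `outlier_alpha` (0.05), `scale_factor` (1).}
#'     \item{`fdr_family`}{`"per-outcome"` (default: the adjustment family
#'       is the set of exposures for each outcome within each direction)
#'       or `"pooled"` (all pairs together).}
#'   }
#' @param seed integer master seed; per-pair seeds are derived
#'   deterministically from it.
#' @return object of class `mr_results_bundle`: list with `results` (one
#'   row per pair, including `fdr_p`), `pairs` (detailed per-pair
#'   objects), `meta` (seed, config hash, package version).
#' @seealso [write_results()]
#' @export
run_bidirectional <- function(config, seed = 1L) {
  defaults <- list(clump = TRUE, p_threshold = 5e-8, window_kb = 500,
                   r2_max = 0.1, r2_proxy = 0.8,
                   palindrome_eaf_window = 0.08, steiger_filter = TRUE,
                   n_boot = 1000, n_sim = 2000, outlier_alpha = 0.05,
                   scale_factor = 1)
  settings <- utils::modifyList(defaults, config$settings %||% list())
  fdr_family <- config$fdr_family %||% "per-outcome"
  ld <- config$ld
  if (is.character(ld)) ld <- read_ld(ld)
  exclusions <- config$exclusions %||% character()
  if (length(exclusions) == 1L && file.exists(exclusions))
    exclusions <- read_exclusion_list(exclusions)

  rows <- list(); pairs <- list(); k <- 0L
  for (direction in intersect(c("forward", "reverse"), names(config))) {
    blk <- config[[direction]]
    exposures <- blk$exposures; outcomes <- blk$outcomes
    for (out_name in names(outcomes)) for (exp_name in names(exposures)) {
      k <- k + 1L
      pair_seed <- as.integer((seed + 7919 * k) %% 2147483647)
      res <- tryCatch({
        ex <- .as_table(exposures[[exp_name]], exp_name)
        ou <- .as_table(outcomes[[out_name]], out_name)
        attr(ex, "trait_label") <- exp_name
        attr(ou, "trait_label") <- out_name
        .run_pair(ex, ou, settings, ld, exclusions, pair_seed)
      }, error = function(e) e)
      key <- paste(direction, exp_name, out_name, sep = ".")
      if (inherits(res, "error")) {
        rows[[key]] <- .failed_row(direction, exp_name, out_name,
                                   conditionMessage(res))
      } else {
        rows[[key]] <- .pair_row(direction, exp_name, out_name, res)
        pairs[[key]] <- res
      }
    }
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  ok <- results$status == "ok"
  results$fdr_p <- NA_real_
  fam <- if (identical(fdr_family, "pooled")) rep("all", nrow(results))
         else paste(results$direction, results$outcome)
  for (f in unique(fam[ok])) {
    idx <- ok & fam == f
    results$fdr_p[idx] <- fdr_adjust(results$pvalue[idx])
  }
  results$nominal_sig <- !is.na(results$pvalue) & results$pvalue < 0.05
  results$fdr_sig <- !is.na(results$fdr_p) & results$fdr_p < 0.05

  structure(list(results = results, pairs = pairs,
                 meta = list(seed = seed,
                             config_hash = .config_hash(
                               list(settings = settings,
                                    fdr_family = fdr_family)),
                             package_version =
                               as.character(utils::packageVersion("clockmr")))),
            class = "mr_results_bundle")
}

#' @export
print.mr_results_bundle <- function(x, ...) {
  r <- x$results
  cat(sprintf("MR results bundle: %d pair(s), seed %s, config %s\n",
              nrow(r), x$meta$seed, x$meta$config_hash))
  show <- r[, c("direction", "exposure", "outcome", "n_snps",
                "primary_method", "beta", "pvalue", "fdr_p", "status")]
  print(show, digits = 3, row.names = FALSE)
  invisible(x)
}

#' Write a results bundle to disk (TSV + JSON)
#'
#' Emits `results.tsv` (the per-pair table) and `results.json` (table
#' plus run metadata) into `dir`.  Output is deterministic: two runs with
#' the same config and seed produce byte-identical files.
#'
#' @param bundle an `mr_results_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_results <- function(bundle, dir) {
  stopifnot(inherits(bundle, "mr_results_bundle"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(bundle$results, file.path(dir, "results.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  jsonlite::write_json(list(meta = bundle$meta, results = bundle$results),
                       file.path(dir, "results.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(dir)
}

#' Read an analysis configuration from YAML
#'
#' The YAML mirrors the config list of [run_bidirectional()]: named
#' exposure/outcome file paths under `forward:`/`reverse:`, optional
#' `ld`, `exclusions`, `settings`, `fdr_family`.  Relative paths are
#' resolved against the YAML file's directory.
#'
#' @param path YAML file path.
#' @return config list for [run_bidirectional()].
#' @export
read_analysis_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  fix <- function(p) if (is.character(p) && !file.exists(p) &&
                           file.exists(file.path(base, p)))
    file.path(base, p) else p
  for (dir in intersect(c("forward", "reverse"), names(cfg)))
    for (side in c("exposures", "outcomes"))
      cfg[[dir]][[side]] <- lapply(cfg[[dir]][[side]], fix)
  for (fld in intersect(c("ld", "exclusions"), names(cfg)))
    cfg[[fld]] <- fix(cfg[[fld]])
  cfg
}
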