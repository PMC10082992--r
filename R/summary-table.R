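#' GWAS summary-statistic tables
#'
#' A `summary_table` is a validated data frame of per-SNP association
#' summaries for one trait: one row per variant with effect/other allele,
#' effect-allele frequency, effect size, standard error, p-value and sample
#' size.  It is the raw material of both directions of a two-sample MR
#' analysis: the SNP-exposure associations (gamma_j) and the SNP-outcome
#' associations (Gamma_j) are each held in one of these tables.
#'
#' Canonical column names are `snp`, `chr`, `pos`, `ea`, `oa`, `eaf`,
#' `beta`, `se`, `p`, `n`, `n_cases`.  Only `snp`, `ea`, `oa`, `beta`,
#' `se` and `p` are mandatory; the rest may be `NA` (some operations, e.g.
#' clumping or Steiger filtering, require `chr`/`pos` or `n` and say so).
#'
#' @param x data frame with at least the mandatory canonical columns.
#' @param trait_label short human-readable trait name, e.g. `"IEAA"` or
#'   `"log-eGFR"`.
#' @param trait_type `"continuous"` or `"binary"`.  Binary traits (e.g. CKD
#'   status) report effects on the log-odds scale and may carry `n_cases`.
#' @return an object of class `summary_table` (a data frame with the
#'   canonical columns, plus attributes `trait_label` and `trait_type`).
#' @examples
#' tab <- summary_table(data.frame(
#'   snp = c("rs1", "rs2"), ea = c("A", "C"), oa = c("G", "T"),
#'   beta = c(0.12, -0.08), se = c(0.02, 0.02), p = c(1e-9, 4e-8)),
#'   trait_label = "IEAA")
#' tab
#' @seealso [read_summary_stats()], [harmonize()]
#' @export
summary_table <- function(x, trait_label = "trait",
                          trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  stopifnot(is.data.frame(x))
  mandatory <- c("snp", "ea", "oa", "beta", "se", "p")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0L)
    stop("summary table is missing mandatory column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  optional <- c("chr", "pos", "eaf", "n", "n_cases")
  for (col in optional) if (is.null(x[[col]])) x[[col]] <- NA
  x <- x[, c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p",
             "n", "n_cases")]
  x$snp <- as.character(x$snp)
  x$chr <- as.character(x$chr)
  x$ea <- toupper(as.character(x$ea))
  x$oa <- toupper(as.character(x$oa))
  for (col in c("pos", "eaf", "beta", "se", "p", "n", "n_cases"))
    x[[col]] <- as.numeric(x[[col]])

  bad <- .invalid_record_reasons(x)
  if (any(nzchar(bad))) {
    idx <- which(nzchar(bad))
    stop("invalid summary records at row(s) ",
         paste0(idx, " (", bad[idx], ")", collapse = "; "), call. = FALSE)
  }
  dup <- unique(x$snp[duplicated(x$snp)])
  if (length(dup) > 0L)
    stop("duplicate snp id(s): ", paste(dup, collapse = ", "), call. = FALSE)

  rownames(x) <- NULL
  structure(x, trait_label = trait_label, trait_type = trait_type,
            class = c("summary_table", "data.frame"))
}

# One reason string per row; "" where the row is valid.  Used both by the
# strict constructor and by the forgiving reader (which drops bad rows).
.invalid_record_reasons <- function(x) {
  reasons <- character(nrow(x))
  add <- function(cond, msg) {
    cond[is.na(cond)] <- FALSE
    reasons[cond] <<- ifelse(nzchar(reasons[cond]),
                             paste(reasons[cond], msg, sep = "; "), msg)
  }
  valid_allele <- function(a) !is.na(a) & a %in% c("A", "C", "G", "T")
  add(is.na(x$snp) | !nzchar(x$snp), "missing snp id")
  add(!valid_allele(x$ea), "effect allele not one of A/C/G/T")
  add(!valid_allele(x$oa), "other allele not one of A/C/G/T")
  add(valid_allele(x$ea) & valid_allele(x$oa) & x$ea == x$oa,
      "effect and other allele identical")
  add(is.na(x$beta) | !is.finite(x$beta), "non-numeric beta")
  add(is.na(x$se) | !is.finite(x$se) | x$se <= 0, "se not > 0")
  add(is.na(x$p) | x$p <= 0 | x$p > 1, "pvalue outside (0, 1]")
  add(!is.na(x$eaf) & (x$eaf < 0 | x$eaf > 1), "eaf outside [0, 1]")
  add(!is.na(x$n) & x$n <= 0, "n not positive")
  reasons
}

#' @export
print.summary_table <- function(x, ...) {
  cat(sprintf("GWAS summary table: %s (%s), %d SNP%s\n",
              attr(x, "trait_label"), attr(x, "trait_type"), nrow(x),
              if (nrow(x) == 1L) "" else "s"))
  print(as.data.frame(utils::head(x, 10L)), ...)
  if (nrow(x) > 10L) cat(sprintf("... and %d more rows\n", nrow(x) - 10L))
  invisible(x)
}

#' @export
trait_label <- function(x) attr(x, "trait_label")

#' @export
trait_type <- function(x) attr(x, "trait_type")

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- (or otherwise-) delimited summary-statistics file with a
#' header and returns a validated [summary_table()].  Column-name dialects
#' (e.g. the CKDGen-style `RSID`/`Effect_allele`/`Freq` headers) are
#' handled through `column_map`; unmapped canonical names are matched to
#' identical header names.  Rows that fail record validation (non-numeric
#' beta or SE, p outside (0,1], identical alleles, ...) are dropped with a
#' warning reporting their file line numbers; a missing mandatory column or
#' a duplicated SNP id is a hard error.
#'
#' @param path file path of the delimited text file.
#' @param column_map named character vector mapping canonical column names
#'   (`snp`, `chr`, `pos`, `ea`, `oa`, `eaf`, `beta`, `se`, `p`, `n`,
#'   `n_cases`) to header names in the file, e.g.
#'   `c(snp = "RSID", ea = "Effect_allele", eaf = "Freq")`.
#' @param trait_type,trait_label as in [summary_table()].
#' @param sep field separator, default tab.
#' @return a [summary_table()].  Dropped rows (if any) are recorded in the
#'   attribute `invalid_rows` (data frame of file line and reason).
#' @export
read_summary_stats <- function(path, column_map = NULL,
                               trait_type = c("continuous", "binary"),
                               trait_label = NULL, sep = "\t") {
  trait_type <- match.arg(trait_type)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(trait_label))
    trait_label <- sub("\\.[^.]*$", "", basename(path))
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           quote = "", comment.char = "")
  canonical <- c("snp", "chr", "pos", "ea", "oa", "eaf", "beta", "se", "p",
                 "n", "n_cases")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(column_map)) {
    unknown <- setdiff(names(column_map), canonical)
    if (length(unknown) > 0L)
      stop("column_map names must be canonical column names; unknown: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    map[names(column_map)] <- column_map
  }
  mandatory <- c("snp", "ea", "oa", "beta", "se", "p")
  absent <- mandatory[!(map[mandatory] %in% names(raw))]
  if (length(absent) > 0L)
    stop("input lacks mandatory column(s): ",
         paste(sprintf("%s (expected header '%s')", absent, map[absent]),
               collapse = ", "), call. = FALSE)

  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in canonical)
    out[[col]] <- if (map[[col]] %in% names(raw)) raw[[map[[col]]]] else NA
  out$snp <- as.character(out$snp)
  out$chr <- as.character(out$chr)
  out$ea <- toupper(as.character(out$ea))
  out$oa <- toupper(as.character(out$oa))
  for (col in c("pos", "eaf", "beta", "se", "p", "n", "n_cases"))
    out[[col]] <- suppressWarnings(as.numeric(out[[col]]))

  reasons <- .invalid_record_reasons(out)
  invalid <- which(nzchar(reasons))
  if (length(invalid) > 0L) {
    # +1 for the header line
    warning(sprintf("dropping %d invalid row(s) from %s: %s",
                    length(invalid), basename(path),
                    paste0("line ", invalid + 1L, " (", reasons[invalid],
                           ")", collapse = "; ")), call. = FALSE)
    out <- out[-invalid, , drop = FALSE]
  }
  tab <- summary_table(out, trait_label = trait_label,
                       trait_type = trait_type)
  if (length(invalid) > 0L)
    attr(tab, "invalid_rows") <- data.frame(line = invalid + 1L,
                                            reason = reasons[invalid])
  tab
}

#' Write a summary table (or harmonized set) to tab-delimited text
#'
#' Writes with the canonical header so the file round-trips through
#' [read_summary_stats()] unchanged.
#'
#' @param x a `summary_table` or any data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_summary_stats <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
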