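# Shared fixtures and independent oracles for the test suite.

mk_tab <- function(snp, ea, oa, beta, se, p = 1e-10, eaf = NA, chr = "1",
                   pos = seq_along(snp) * 1e6, n = 30000,
                   label = "trait", type = "continuous") {
  summary_table(data.frame(snp = snp, chr = chr, pos = pos, ea = ea,
                           oa = oa, eaf = eaf, beta = beta, se = se,
                           p = p, n = n, stringsAsFactors = FALSE),
                trait_label = label, trait_type = type)
}

# Rebuild exposure/outcome summary tables from a harmonized set (for
# idempotence checks).
tables_from_h <- function(h) {
  r <- retained(h)
  list(exposure = mk_tab(r$snp, r$ea, r$oa, r$beta_exp, r$se_exp,
                         eaf = r$eaf_exp, n = r$n_exp),
       outcome = mk_tab(r$snp, r$ea, r$oa, r$beta_out, r$se_out,
                        eaf = r$eaf_out, n = r$n_out))
}

# Independent weighted-least-squares oracle (QR path via stats::lm).
wls_oracle <- function(bx, by, byse, intercept = FALSE) {
  w <- 1 / byse^2
  if (intercept) stats::lm(by ~ bx, weights = w)
  else stats::lm(by ~ 0 + bx, weights = w)
}

# A well-behaved random instrument on a common allele frame.
random_h <- function(J, seed, beta = 0.3, het = 0) {
  set.seed(seed)
  bx <- abs(rnorm(J, 0.1, 0.05)) + 0.02
  bxse <- runif(J, 0.005, 0.02)
  byse <- runif(J, 0.005, 0.02)
  by <- beta * bx + rnorm(J, 0, sqrt(byse^2 + het^2))
  harmonized_set(bx, bxse, by, byse, n_exp = 30000, n_out = 50000)
}
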