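clump_tab <- function(p, pos, chr = "1", snp = sprintf("rs%d", seq_along(p))) {
  mk_tab(snp, rep("A", length(p)), rep("G", length(p)),
         beta = rep(0.1, length(p)), se = rep(0.01, length(p)),
         p = p, chr = chr, pos = pos)
}

# independent brute-force greedy clumping oracle
clump_oracle <- function(tab, ld_pairs, window_kb, r2_max) {
  get_r2 <- function(a, b) {
    hit <- (ld_pairs$snp_a == a & ld_pairs$snp_b == b) |
      (ld_pairs$snp_a == b & ld_pairs$snp_b == a)
    if (any(hit)) ld_pairs$r2[which(hit)[1]] else 0
  }
  df <- as.data.frame(tab)
  df <- df[order(df$p, df$chr, df$pos, df$snp), ]
  kept <- character()
  while (nrow(df) > 0) {
    top <- df[1, ]
    kept <- c(kept, top$snp)
    df <- df[-1, , drop = FALSE]
    if (nrow(df) == 0) break
    near <- df$chr == top$chr & abs(df$pos - top$pos) / 1000 <= window_kb
    r2s <- vapply(df$snp, get_r2, numeric(1), b = top$snp)
    df <- df[!(near & r2s >= r2_max), , drop = FALSE]
  }
  sort(kept)
}

test_that("clumping keeps the stronger of two linked SNPs", {
  tab <- clump_tab(p = c(1e-10, 1e-9), pos = c(1e6, 1.1e6))
  ld <- ld_info(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.5))
  got <- select_and_clump(tab, ld)
  expect_equal(got$snp, "rs1")
  expect_equal(attr(got, "clump_log")$snp, "rs2")
})

test_that("SNPs outside the window are kept regardless of LD", {
  tab <- clump_tab(p = c(1e-10, 1e-9), pos = c(1e6, 1.6e6 + 1000))
  ld <- ld_info(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  expect_equal(sort(select_and_clump(tab, ld)$snp), c("rs1", "rs2"))
})

test_that("greedy clumping matches a brute-force oracle on a 5-SNP chain", {
  tab <- clump_tab(p = c(1e-12, 5e-12, 1e-10, 2e-9, 4e-8),
                   pos = c(1e6, 1.3e6, 1.45e6, 1.9e6, 2.2e6))
  pairs <- data.frame(
    snp_a = c("rs1", "rs1", "rs2", "rs2", "rs3", "rs4"),
    snp_b = c("rs2", "rs3", "rs3", "rs4", "rs4", "rs5"),
    r2 = c(0.5, 0.05, 0.3, 0.15, 0.6, 0.2))
  got <- select_and_clump(tab, ld_info(pairs))
  expect_equal(sort(got$snp), clump_oracle(tab, pairs, 500, 0.1))
})

test_that("clumping is invariant to input row order", {
  set.seed(7)
  J <- 15
  tab <- clump_tab(p = 10^runif(J, -12, -8), pos = sort(runif(J, 1e6, 4e6)),
                   snp = sprintf("rs%02d", 1:J))
  combos <- t(combn(tab$snp, 2))
  pairs <- data.frame(snp_a = combos[, 1], snp_b = combos[, 2],
                      r2 = runif(nrow(combos)))
  ld <- ld_info(pairs)
  ref <- select_and_clump(tab, ld)$snp
  for (rep in 1:3) {
    shuffled <- summary_table(as.data.frame(tab)[sample.int(J), ],
                              trait_label = "t")
    expect_equal(sort(select_and_clump(shuffled, ld)$snp), sort(ref))
  }
})

test_that("sub-threshold tables give an empty instrument with a warning", {
  tab <- clump_tab(p = c(1e-6, 1e-7), pos = c(1e6, 2e6))
  expect_warning(got <- select_and_clump(tab, ld_info()), "no SNP passes")
  expect_equal(nrow(got), 0L)
})

test_that("missing LD pairs are treated as unlinked, with a warning", {
  tab <- clump_tab(p = c(1e-10, 1e-9), pos = c(1e6, 1.1e6))
  expect_warning(got <- select_and_clump(tab, ld_info()), "treated as r2 = 0")
  expect_equal(sort(got$snp), c("rs1", "rs2"))
})

test_that("exclusion lists remove listed SNPs and their close proxies", {
  tab <- clump_tab(p = rep(1e-10, 3), pos = c(1e6, 2e6, 3e6),
                   snp = c("rs1598856", "rs2", "rs3"))
  ld <- ld_info(data.frame(snp_a = c("rs2", "rs3"),
                           snp_b = c("rsX", "rsX"), r2 = c(0.85, 0.75)))
  got <- apply_exclusion_list(tab, c("rs1598856", "rsX"), ld)
  expect_equal(got$snp, "rs3")
  log <- attr(got, "exclusion_log")
  expect_setequal(log$snp, c("rs1598856", "rs2"))
  # empty exclusion list is a no-op
  expect_equal(apply_exclusion_list(tab, character())$snp, tab$snp)
})

test_that("dual-marker refinement applies Bonferroni and sign rules", {
  # Bonferroni threshold with 256 index SNPs is 0.05/256 ~ 1.95e-4
  prim <- mk_tab(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                 beta = c(0.1, 0.1), se = c(0.01, 0.01))
  sec <- mk_tab(c("rs1", "rs2"), c("A", "A"), c("G", "G"),
                beta = c(0.08, 0.09), se = c(0.01, 0.01),
                p = c(1e-6, 0.01))
  got <- dual_marker_refine(prim, sec, n_index = 256)
  expect_equal(got$snp, "rs1")
  expect_equal(attr(got, "refine_log")$reason, "secondary-not-significant")
  # inverse marker (BUN-like): concordant sign now fails
  got2 <- dual_marker_refine(prim, sec, n_index = 256,
                             marker = "discordant")
  expect_equal(nrow(got2), 0L)
  expect_error(dual_marker_refine(prim, sec, n_index = 0), "n_index")
})

test_that("dual-marker refinement matches hand enumeration on 10 SNPs", {
  snp <- sprintf("rs%02d", 1:10)
  prim <- mk_tab(snp, rep("A", 10), rep("G", 10), beta = rep(0.1, 10),
                 se = rep(0.01, 10))
  # secondary: rs01..rs05 significant (p = 1e-6); of those rs04, rs05
  # discordant; rs09 missing entirely
  sec <- mk_tab(snp[-9], rep("A", 9), rep("G", 9),
                beta = c(0.1, 0.1, 0.1, -0.1, -0.1, 0.1, 0.1, 0.1, 0.1),
                se = rep(0.01, 9),
                p = c(rep(1e-6, 5), 0.2, 0.3, 0.5, 0.9))
  got <- dual_marker_refine(prim, sec, n_index = 10,
                            require_direction = TRUE)
  expect_equal(got$snp, c("rs01", "rs02", "rs03"))
  got2 <- dual_marker_refine(prim, sec, n_index = 10,
                             require_direction = FALSE)
  expect_equal(got2$snp, c("rs01", "rs02", "rs03", "rs04", "rs05"))
})

test_that("Steiger z matches a direct evaluation of the Fisher formula", {
  h <- harmonized_set(beta_exp = c(0.10, 0.05, 0.02),
                      se_exp = c(0.01, 0.01, 0.01),
                      beta_out = c(0.02, 0.01, 0.03),
                      se_out = c(0.005, 0.004, 0.006),
                      n_exp = 30000, n_out = c(50000, 45000, 40000))
  st <- steiger_stats(h)
  for (j in 1:3) {
    tx <- h$beta_exp[j] / h$se_exp[j]
    ty <- h$beta_out[j] / h$se_out[j]
    r2x <- tx^2 / (tx^2 + h$n_exp[j] - 2)
    r2y <- ty^2 / (ty^2 + h$n_out[j] - 2)
    z <- (atanh(sqrt(r2x)) - atanh(sqrt(r2y))) /
      sqrt(1 / (h$n_exp[j] - 3) + 1 / (h$n_out[j] - 3))
    expect_equal(st$r2_exp[j], r2x)
    expect_equal(st$steiger_z[j], z)
    expect_equal(st$direction_ok[j], r2x > r2y)
  }
})

test_that("Steiger filtering drops SNPs by mode and handles edge cases", {
  # equal r2 on both sides: z = 0, p = 1, dropped even in point mode
  h <- harmonized_set(beta_exp = c(0.1, 0.1), se_exp = c(0.01, 0.01),
                      beta_out = c(0.1, 0.001), se_out = c(0.01, 0.01),
                      n_exp = 30000, n_out = 30000)
  st <- steiger_stats(h)
  expect_equal(st$steiger_z[1], 0)
  expect_equal(st$steiger_p[1], 1)
  expect_false(st$direction_ok[1])
  sf <- steiger_filter(h)
  expect_equal(retained(sf$h)$snp, "snp002")
  expect_equal(sf$h$drop_reason[1], "steiger-direction")
  # a zero outcome beta explains zero variance: direction valid
  h2 <- harmonized_set(0.1, 0.01, 0, 0.01, n_exp = 1000, n_out = 1000)
  expect_true(steiger_stats(h2)$direction_ok)
  # tiny samples are rejected
  h3 <- harmonized_set(0.1, 0.01, 0, 0.01, n_exp = 3, n_out = 1000)
  expect_error(steiger_stats(h3), "exceed 3")
})

test_that("instrument strength statistics match direct summation", {
  h <- harmonized_set(beta_exp = c(0.10, 0.12, 0.08, 0.20),
                      se_exp = c(0.010, 0.015, 0.012, 0.020),
                      beta_out = rep(0.01, 4), se_out = rep(0.01, 4),
                      n_exp = 30000, n_out = 50000)
  ss <- instrument_strength(h)
  expect_equal(unname(ss$f_per_snp), (h$beta_exp / h$se_exp)^2)
  v <- 1 / h$se_exp^2
  gbar <- sum(v * h$beta_exp) / sum(v)
  q <- sum(v * (h$beta_exp - gbar)^2)
  expect_equal(ss$q_gx, q)
  expect_equal(ss$i2_gx, max(0, (q - 3) / q))
  t2 <- (h$beta_exp / h$se_exp)^2
  expect_equal(ss$r2_instrument, sum(t2 / (t2 + h$n_exp - 2)))
  # single SNP: F defined, I2 undefined
  h1 <- harmonized_set(0.1, 0.01, 0.01, 0.01)
  s1 <- instrument_strength(h1)
  expect_equal(unname(s1$f_per_snp), 100)
  expect_true(is.na(s1$i2_gx))
  # identical effects: Q = 0, I2 clamped to 0
  h0 <- harmonized_set(rep(0.1, 4), rep(0.01, 4), rep(0.01, 4),
                       rep(0.01, 4))
  expect_equal(instrument_strength(h0)$i2_gx, 0)
})

test_that("clumping and exclusion commute for disjoint criteria", {
  tab <- clump_tab(p = c(1e-10, 1e-9, 1e-8 * 0.5, 1e-11),
                   pos = c(1e6, 1.2e6, 5e6, 9e6),
                   snp = c("rs1", "rs2", "rs3", "rs4"))
  ld <- ld_info(data.frame(snp_a = "rs1", snp_b = "rs2", r2 = 0.9))
  excl <- "rs3"
  a <- apply_exclusion_list(select_and_clump(tab, ld), excl)
  b <- select_and_clump(apply_exclusion_list(tab, excl), ld)
  expect_equal(sort(a$snp), sort(b$snp))
})
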