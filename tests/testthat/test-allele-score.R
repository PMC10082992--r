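# Independently coded CKD-EPI 2012 creatinine-cystatin oracle (explicit
# branch structure rather than pmin/pmax vectorization).
ckd_epi_oracle <- function(scr, scys, age, female) {
  kappa <- if (female) 0.7 else 0.9
  alpha <- if (female) -0.248 else -0.207
  cr <- scr / kappa
  cr_term <- if (cr < 1) cr^alpha else cr^-0.601
  cys <- scys / 0.8
  cys_term <- if (cys < 1) cys^-0.375 else cys^-0.711
  out <- 135 * cr_term * cys_term * 0.995^age
  if (female) out <- out * 0.969
  out
}

test_that("the CKD-EPI equation matches an independent implementation", {
  grid <- expand.grid(scr = c(0.5, 0.9, 1.4, 2.5),
                      scys = c(0.6, 0.8, 1.1, 1.9),
                      age = c(25, 50, 75),
                      sex = c("male", "female"),
                      stringsAsFactors = FALSE)
  got <- ckd_epi_egfr(grid$scr, grid$scys, grid$age, grid$sex)
  want <- mapply(ckd_epi_oracle, grid$scr, grid$scys, grid$age,
                 grid$sex == "female")
  expect_equal(got, unname(want), tolerance = 1e-12)
  # the specific spot value used throughout examples
  expect_equal(ckd_epi_egfr(0.9, 0.8, 50, "male"),
               ckd_epi_oracle(0.9, 0.8, 50, FALSE))
})

test_that("eGFR decreases with age and rejects invalid inputs", {
  ages <- seq(20, 80, by = 5)
  vals <- ckd_epi_egfr(rep(0.9, length(ages)), rep(0.8, length(ages)),
                       ages, rep("female", length(ages)))
  expect_true(all(diff(vals) < 0))
  expect_error(ckd_epi_egfr(-0.1, 0.8, 50, "male"), "positive")
  expect_error(ckd_epi_egfr(0.9, 0.8, 10, "male"), "adult")
  expect_error(ckd_epi_egfr(0.9, 0.8, 50, "unknown"), "sex")
})

test_that("CKD status uses a strict threshold at 60", {
  df <- data.frame(scr = c(1, 1), scys = c(1, 1), age = c(50, 50),
                   sex = "male", egfr = c(59.9, 60.0))
  df$log_egfr <- log(df$egfr)
  ckd <- df$egfr < 60
  expect_identical(ckd, c(TRUE, FALSE))
  # derive_kidney_phenotypes computes all three derived columns
  ph <- derive_kidney_phenotypes(data.frame(scr = 2.4, scys = 2.1,
                                            age = 70, sex = "female"))
  expect_equal(ph$log_egfr, log(ph$egfr))
  expect_true(ph$ckd)
  expect_lt(ph$egfr, 60)
})

toy_dataset <- function() {
  dosage <- matrix(c(0, 1, 2, 1,
                     2, 0, 1, 1,
                     1, 1, 0, 2), nrow = 4,
                   dimnames = list(NULL, c("rs1", "rs2", "rs3")))
  pheno <- data.frame(scr = rep(0.9, 4), scys = rep(0.8, 4),
                      age = rep(50, 4),
                      sex = c("male", "female", "male", "female"))
  snp_info <- data.frame(snp = c("rs1", "rs2", "rs3"),
                         ea = c("A", "C", "G"), oa = c("G", "T", "A"),
                         stringsAsFactors = FALSE)
  individual_dataset(dosage, pheno, snp_info)
}

test_that("allele scores are dosage-weighted sums of effect sizes", {
  data <- toy_dataset()
  instr <- mk_tab(c("rs1", "rs2", "rs3"), c("A", "C", "G"),
                  c("G", "T", "A"), beta = c(0.5, -0.25, 1),
                  se = rep(0.01, 3))
  sc <- build_allele_score(data, instr)
  manual <- data$dosage %*% c(0.5, -0.25, 1)
  expect_equal(sc$raw, drop(manual))
  expect_lt(abs(mean(sc$z)), 1e-10)
  expect_lt(abs(var(sc$z) - 1), 1e-8)
  # single SNP with beta 1: raw score is the dosage column
  instr1 <- mk_tab("rs2", "C", "T", 1, 0.01)
  expect_equal(build_allele_score(data, instr1)$raw,
               unname(data$dosage[, "rs2"]))
  # zero weights: zero variance error
  instr0 <- mk_tab(c("rs1", "rs2"), c("A", "C"), c("G", "T"),
                   beta = c(0, 0), se = rep(0.01, 2))
  expect_error(build_allele_score(data, instr0), "zero variance")
  # missing SNP errors with the id
  instr_miss <- mk_tab("rs99", "A", "G", 0.5, 0.01)
  expect_error(build_allele_score(data, instr_miss), "rs99")
})

test_that("flipping an effect allele leaves standardized scores unchanged", {
  data <- toy_dataset()
  instr <- mk_tab(c("rs1", "rs2", "rs3"), c("A", "C", "G"),
                  c("G", "T", "A"), beta = c(0.5, -0.25, 1),
                  se = rep(0.01, 3))
  # same instrument with rs2 reported on the other allele
  instr_flip <- mk_tab(c("rs1", "rs2", "rs3"), c("A", "T", "G"),
                       c("G", "C", "A"), beta = c(0.5, 0.25, 1),
                       se = rep(0.01, 3))
  a <- build_allele_score(data, instr)
  b <- build_allele_score(data, instr_flip)
  expect_equal(b$z, a$z)
  expect_equal(b$flipped, "rs2")
  # raw scores differ only by the additive constant 2*beta
  expect_equal(b$raw - a$raw, rep(2 * 0.25, 4))
})

test_that("score associations recover a planted effect and flag singularity", {
  cfg <- sim_config(J = 15, n_ind = 12000, score_beta = -0.01)
  sim <- simulate_individual(cfg, seed = 61)
  sc <- build_allele_score(sim$data, sim$instrument)
  fit <- score_association(sc, sim$data, "log_egfr", model = 1)
  expect_lt(abs(fit$beta - (-0.01)), 3 * fit$se)
  expect_lt(fit$pvalue, 0.05)
  # model 2 includes the clinical covariates and still recovers it
  fit2 <- score_association(sc, sim$data, "ckd", model = 2)
  expect_true(fit2$or > 0)
  # duplicated covariate column: singular design is reported
  sim$data$pheno$pc10 <- sim$data$pheno$pc9
  expect_error(score_association(sc, sim$data, "log_egfr"), "singular|aliased")
})

test_that("score associations are calibrated under the null", {
  pvals <- vapply(1:60, function(s) {
    cfg <- sim_config(J = 10, n_ind = 1500, score_beta = 0)
    sim <- simulate_individual(cfg, seed = 6000 + s)
    sc <- build_allele_score(sim$data, sim$instrument)
    score_association(sc, sim$data, "log_egfr")$pvalue
  }, numeric(1))
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("rank inverse-normal transform yields a standard-normal margin", {
  set.seed(8)
  x <- rexp(500)
  z <- rank_inverse_normal(x)
  expect_lt(abs(mean(z)), 0.01)
  expect_lt(abs(sd(z) - 1), 0.05)
  expect_equal(order(z), order(x))
})

test_that("PLINK .raw-style dosage files round-trip", {
  path <- withr::local_tempfile(fileext = ".raw")
  writeLines(c("FID IID rs1_A rs2_C",
               "f1 i1 0 2", "f2 i2 1 1", "f3 i3 2 0"), path)
  got <- read_dosage(path)
  expect_equal(colnames(got$dosage), c("rs1", "rs2"))
  expect_equal(got$snp_info$ea, c("A", "C"))
  expect_equal(got$dosage[, "rs1"], c(0, 1, 2))
})
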