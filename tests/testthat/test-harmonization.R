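# build an outcome table from an exposure table by reporting the same
# underlying associations under a transformed allele coding
recode <- function(tb, swap = FALSE, flip_strand = FALSE) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  out <- tb
  if (swap) {
    out$effect_allele <- tb$other_allele
    out$other_allele <- tb$effect_allele
    out$beta <- -tb$beta
    out$eaf <- 1 - tb$eaf
  }
  if (flip_strand) {
    out$effect_allele <- unname(comp[out$effect_allele])
    out$other_allele <- unname(comp[out$other_allele])
  }
  out
}

test_that("matching alleles pass through unchanged", {
  tb <- make_sumstats(3)
  hd <- harmonize(tb, tb)
  expect_equal(unique(hd$action), "none")
  expect_equal(hd$beta_out, tb$beta, tolerance = 1e-12)
  expect_equal(nrow(hd), 3)
})

test_that("swapped outcome coding negates beta and complements eaf", {
  tb <- make_sumstats(3)
  hd <- harmonize(tb, recode(tb, swap = TRUE))
  expect_equal(unique(hd$action), "outcome_flipped")
  expect_equal(hd$beta_out, tb$beta, tolerance = 1e-12)
  expect_equal(hd$eaf_out, tb$eaf, tolerance = 1e-12)
  expect_equal(hd$effect_allele, tb$effect_allele)
})

test_that("strand complements are relabelled, with and without swap", {
  tb <- make_sumstats(3)
  hd1 <- harmonize(tb, recode(tb, flip_strand = TRUE))
  expect_equal(unique(hd1$action), "strand_complemented")
  expect_equal(hd1$beta_out, tb$beta, tolerance = 1e-12)
  hd2 <- harmonize(tb, recode(tb, swap = TRUE, flip_strand = TRUE))
  expect_equal(unique(hd2$action), "strand_complemented_and_flipped")
  expect_equal(hd2$beta_out, tb$beta, tolerance = 1e-12)
})

test_that("palindromes inside the eaf ambiguity window are dropped", {
  tb <- make_sumstats(2)
  tb$effect_allele <- c("A", "C")
  tb$other_allele <- c("T", "G")
  tb$eaf <- c(0.50, 0.20)
  hd <- harmonize(tb, tb, palindrome_eaf_window = 0.08)
  expect_equal(hd$snp_id, "rs2") # the orientable C/G SNP survives
  expect_equal(attr(hd, "n_dropped_palindromic"), 1L)

  # window = 0.5 drops every palindrome
  hd_all <- harmonize(tb, tb, palindrome_eaf_window = 0.5)
  expect_equal(nrow(hd_all), 0)
  expect_equal(attr(hd_all, "n_dropped_palindromic"), 2L)
})

test_that("orientable palindromes are aligned by minor-allele frequency", {
  tb <- make_sumstats(1)
  tb$effect_allele <- "A"
  tb$other_allele <- "T"
  tb$eaf <- 0.2
  # outcome reported for the other strand/orientation: eaf on the other side
  out <- tb
  out$beta <- -tb$beta
  out$eaf <- 0.8
  hd <- harmonize(tb, out)
  expect_equal(hd$action, "outcome_flipped")
  expect_equal(hd$beta_out, tb$beta, tolerance = 1e-12)
})

test_that("mismatched positions for a shared id are dropped, not fatal", {
  tb <- make_sumstats(3)
  out <- tb
  out$pos[2] <- out$pos[2] + 5L
  hd <- harmonize(tb, out)
  expect_equal(nrow(hd), 2)
  expect_equal(attr(hd, "n_dropped_unmatched"), 1L)
})

test_that("no shared SNPs is a hard error", {
  a <- make_sumstats(3)
  b <- make_sumstats(3)
  b$snp_id <- paste0("x", b$snp_id)
  expect_error(harmonize(a, b), "no shared SNPs")
})

test_that("harmonization is idempotent", {
  sim <- sim_study(n_snps = 25, frac_allele_swapped = 0.5,
                   frac_strand_flipped = 0.3, seed = 11)
  hd <- harmonize(sim$exposure, sim$outcome)
  # feed the harmonized outcome back in as an outcome table
  out2 <- tibble::tibble(
    snp_id = hd$snp_id, chrom = hd$chrom, pos = hd$pos,
    effect_allele = hd$effect_allele, other_allele = hd$other_allele,
    eaf = hd$eaf_out, beta = hd$beta_out, se = hd$se_out,
    pvalue = 2 * stats::pnorm(-abs(hd$beta_out / hd$se_out)), n = hd$n_out)
  exp2 <- tibble::as_tibble(sim$exposure)[
    match(hd$snp_id, sim$exposure$snp_id), ]
  hd2 <- harmonize(exp2, out2)
  expect_equal(hd2$beta_out, hd$beta_out, tolerance = 1e-12)
  expect_equal(hd2$effect_allele, hd$effect_allele)
  expect_true(all(hd2$action == "none"))
})

test_that("globally flipping the outcome's reported coding changes nothing", {
  sim <- sim_study(n_snps = 25, seed = 5)
  out_flipped <- recode(tibble::as_tibble(sim$outcome), swap = TRUE)
  hd1 <- harmonize(sim$exposure, sim$outcome)
  hd2 <- harmonize(sim$exposure, out_flipped)
  expect_equal(hd2$beta_out, hd1$beta_out, tolerance = 1e-12)
  expect_equal(hd2$snp_id, hd1$snp_id)
})

test_that("estimates after harmonizing corrupted codings equal the clean twin", {
  for (seed in c(2, 13, 77)) {
    sim <- sim_study(n_snps = 30, frac_allele_swapped = 0.5,
                     frac_strand_flipped = 0.3, seed = seed)
    hd_corrupt <- harmonize(sim$exposure, sim$outcome)
    hd_clean <- harmonize(sim$exposure, sim$clean$outcome)
    expect_equal(nrow(hd_corrupt), nrow(hd_clean))
    expect_equal(mr_ivw(hd_corrupt)$beta, mr_ivw(hd_clean)$beta,
                 tolerance = 1e-9)
    expect_equal(mr_egger(hd_corrupt)$beta, mr_egger(hd_clean)$beta,
                 tolerance = 1e-9)
  }
})
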