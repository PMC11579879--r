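test_that("wald ratio arithmetic, null case and joint sign symmetry", {
  d <- make_harmonized(0.5, 0.25, 0.1)
  r <- mr_wald_ratio(d)
  expect_equal(r$beta, 0.5)
  expect_equal(r$se, 0.2)
  expect_equal(r$nsnp, 1L)

  null <- mr_wald_ratio(make_harmonized(0.5, 0, 0.1))
  expect_equal(null$beta, 0)
  expect_equal(null$pvalue, 1)

  flipped <- mr_wald_ratio(make_harmonized(-0.5, -0.25, 0.1))
  expect_equal(flipped$beta, r$beta)
  expect_equal(flipped$se, r$se)

  expect_error(mr_wald_ratio(make_harmonized(0, 0.1, 0.1)), "undefined ratio")
})

test_that("IVW reduces to the Wald ratio for one SNP and pools duplicates", {
  d1 <- make_harmonized(0.4, 0.2, 0.05)
  expect_equal(mr_ivw(d1)$beta, mr_wald_ratio(d1)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(d1)$se, mr_wald_ratio(d1)$se, tolerance = 1e-12)

  d2 <- dplyr::bind_rows(d1, d1)
  expect_equal(mr_ivw(d2)$beta, mr_ivw(d1)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(d2)$se, mr_ivw(d1)$se / sqrt(2), tolerance = 1e-12)

  expect_error(mr_ivw(d1[0, ]), "no SNPs")
})

test_that("IVW equals the generic origin-constrained WLS oracle", {
  for (seed in 1:20) {
    d <- random_harmonized(6, seed)
    fit <- stats::lm(beta_out ~ 0 + beta_exp, data = d,
                     weights = 1 / d$se_out^2)
    sm <- summary(fit)$coefficients
    got <- mr_ivw(d, "fixed")
    expect_equal(got$beta, unname(sm[1, 1]), tolerance = 1e-9)
    # fixed-effects SE strips the residual scale the regression applies
    expect_equal(got$se, unname(sm[1, 2]) / summary(fit)$sigma,
                 tolerance = 1e-9)
  }
})

test_that("random-effects IVW inflates the SE only under excess heterogeneity", {
  d <- random_harmonized(8, 99)
  q <- cochran_q(d)
  fx <- mr_ivw(d, "fixed")
  rd <- mr_ivw(d, "random")
  expect_equal(rd$beta, fx$beta, tolerance = 1e-12)
  expect_equal(rd$se, fx$se * sqrt(max(1, q$q / q$df)), tolerance = 1e-12)

  homog <- make_harmonized(c(0.2, 0.3, 0.4), c(0.1, 0.15, 0.2),
                           c(0.05, 0.05, 0.05))
  expect_gte(mr_ivw(homog, "random")$se, mr_ivw(homog, "fixed")$se - 1e-15)
})

test_that("Egger recovers exact linear and affine generating models", {
  bx <- c(0.1, 0.2, 0.3, 0.4)
  line <- make_harmonized(bx, 0.7 * bx, rep(0.05, 4))
  r1 <- mr_egger(line)
  expect_equal(r1$beta, 0.7, tolerance = 1e-9)
  expect_equal(r1$egger_intercept, 0, tolerance = 1e-9)

  affine <- make_harmonized(bx, 0.02 + 0.7 * bx, rep(0.05, 4))
  r2 <- mr_egger(affine)
  expect_equal(r2$beta, 0.7, tolerance = 1e-9)
  expect_equal(r2$egger_intercept, 0.02, tolerance = 1e-9)
})

test_that("Egger equals the generic WLS-with-intercept oracle", {
  for (seed in 1:20) {
    d <- random_harmonized(8, seed)
    sgn <- ifelse(d$beta_exp < 0, -1, 1) # orientation convention
    od <- data.frame(bx = sgn * d$beta_exp, by = sgn * d$beta_out)
    fit <- stats::lm(by ~ bx, data = od, weights = 1 / d$se_out^2)
    sm <- summary(fit)
    got <- mr_egger(d)
    expect_equal(got$beta, unname(stats::coef(fit)[2]), tolerance = 1e-9)
    expect_equal(got$egger_intercept, unname(stats::coef(fit)[1]),
                 tolerance = 1e-9)
    scale <- max(1, sm$sigma) / sm$sigma
    expect_equal(got$se, unname(sm$coefficients[2, 2]) * scale,
                 tolerance = 1e-9)
  }
})

test_that("Egger needs three variants and reports not-applicable below that", {
  r <- mr_egger(random_harmonized(2, 1))
  expect_true(is.na(r$beta))
  expect_equal(r$note, "not applicable")
})

test_that("weighted median handles symmetric, degenerate and random cases", {
  d <- make_harmonized(c(1, 1, 1), c(0.1, 0.5, 0.9), c(0.1, 0.1, 0.1))
  expect_equal(mr_weighted_median(d, n_boot = 0)$beta, 0.5, tolerance = 1e-12)

  same <- make_harmonized(c(1, 1, 1), c(0.3, 0.3, 0.3), c(0.1, 0.2, 0.3))
  r <- mr_weighted_median(same, n_boot = 200, seed = 4)
  expect_equal(r$beta, 0.3, tolerance = 1e-12)
  expect_gt(r$se, 0)
  expect_lt(r$se, 0.5)
})


test_that("weighted median equals the brute-force cumulative-weight oracle", {
  for (seed in 1:25) {
    d <- random_harmonized(5, seed + 100)
    ratio <- d$beta_out / d$beta_exp
    w <- (d$beta_exp / d$se_out)^2
    expect_equal(mr_weighted_median(d, n_boot = 0)$beta,
                 weighted_median_oracle(ratio, w), tolerance = 1e-12)
  }
})

test_that("mode estimators find the dominant cluster and honour weights", {
  d <- make_harmonized(c(1, 1, 1, 1), c(0.5, 0.5, 0.5, 5), rep(0.1, 4))
  md <- mr_modes(d, n_boot = 0)
  expect_equal(md$beta[md$method == "simple_mode"], 0.5, tolerance = 1e-12)

  # weight concentrated on the upper cluster moves only the weighted mode
  d2 <- make_harmonized(c(1, 1, 1, 1), c(0.2, 0.21, 0.8, 0.81),
                        c(0.5, 0.5, 0.01, 0.01))
  md2 <- mr_modes(d2, n_boot = 0)
  expect_equal(md2$beta[md2$method == "weighted_mode"], 0.805, tolerance = 0.05)
  expect_lt(md2$beta[md2$method == "simple_mode"], 0.6)
})

test_that("symmetric bimodal ties resolve to the smaller ratio", {
  d <- make_harmonized(c(1, 1, 1, 1), c(0.2, 0.2, 0.8, 0.8), rep(0.1, 4))
  md <- mr_modes(d, n_boot = 0)
  expect_lt(md$beta[md$method == "simple_mode"], 0.5)
})

test_that("modes equal a dense-grid argmax oracle", {
  for (seed in 1:10) {
    d <- random_harmonized(7, seed + 300)
    ratio <- d$beta_out / d$beta_exp
    w <- (d$beta_exp / d$se_out)^2
    h <- stats::mad(ratio)
    grid <- seq(min(ratio) - 3 * h, max(ratio) + 3 * h, length.out = 512)
    dens_s <- sapply(grid, function(g) sum(stats::dnorm((g - ratio) / h)))
    dens_w <- sapply(grid, function(g) sum(w * stats::dnorm((g - ratio) / h)))
    md <- mr_modes(d, n_boot = 0)
    expect_equal(md$beta[md$method == "simple_mode"], grid[which.max(dens_s)],
                 tolerance = 1e-9)
    expect_equal(md$beta[md$method == "weighted_mode"], grid[which.max(dens_w)],
                 tolerance = 1e-9)
  }
})

test_that("estimators are scale-equivariant in the exposure units", {
  d <- random_harmonized(8, 7)
  c_ <- 2.5
  d2 <- d
  d2$beta_exp <- d$beta_exp * c_
  d2$se_exp <- d$se_exp * c_
  expect_equal(mr_ivw(d2)$beta, mr_ivw(d)$beta / c_, tolerance = 1e-9)
  expect_equal(mr_egger(d2)$beta, mr_egger(d)$beta / c_, tolerance = 1e-9)
  expect_equal(mr_weighted_median(d2, n_boot = 0)$beta,
               mr_weighted_median(d, n_boot = 0)$beta / c_, tolerance = 1e-9)
})

test_that("negating one record's orientation leaves estimators unchanged", {
  d <- random_harmonized(8, 8)
  d2 <- d
  d2$beta_exp[3] <- -d$beta_exp[3]
  d2$beta_out[3] <- -d$beta_out[3]
  expect_equal(mr_ivw(d2)$beta, mr_ivw(d)$beta, tolerance = 1e-12)
  expect_equal(mr_ivw(d2)$se, mr_ivw(d)$se, tolerance = 1e-12)
  expect_equal(mr_egger(d2)$beta, mr_egger(d)$beta, tolerance = 1e-12)
  expect_equal(mr_weighted_median(d2, n_boot = 0)$beta,
               mr_weighted_median(d, n_boot = 0)$beta, tolerance = 1e-12)
})

test_that("results satisfy the CI and p-value identities", {
  d <- random_harmonized(6, 21)
  res <- dplyr::bind_rows(mr_ivw(d), mr_egger(d),
                          mr_weighted_median(d, n_boot = 50, seed = 1))
  expect_equal(res$ci_low, res$beta - stats::qnorm(0.975) * res$se,
               tolerance = 1e-9)
  expect_equal(res$ci_high, res$beta + stats::qnorm(0.975) * res$se,
               tolerance = 1e-9)
  expect_equal(res$pvalue, 2 * stats::pnorm(-abs(res$beta / res$se)),
               tolerance = 1e-9)
})
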