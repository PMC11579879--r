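# Minimal harmonized dataset built directly from effect vectors, for
# estimator tests that do not need the full simulation machinery.
make_harmonized <- function(beta_exp, beta_out, se_out,
                            se_exp = rep(0.01, length(beta_exp)),
                            eaf = rep(0.3, length(beta_exp)),
                            n_exp = 10000L, n_out = 10000L) {
  k <- length(beta_exp)
  tibble::tibble(
    snp_id = paste0("rs", seq_len(k)),
    chrom = "1", pos = seq_len(k) * 30000000L,
    effect_allele = "A", other_allele = "G",
    beta_exp = beta_exp, se_exp = se_exp, eaf_exp = eaf, n_exp = n_exp,
    beta_out = beta_out, se_out = se_out, eaf_out = eaf, n_out = n_out,
    action = "none", palindromic = FALSE
  )
}

# random estimator test instances under a fixed seed
random_harmonized <- function(k, seed) {
  withr::with_seed(seed, {
    make_harmonized(
      beta_exp = stats::runif(k, 0.05, 0.4) * sample(c(-1, 1), k, TRUE),
      beta_out = stats::rnorm(k, 0, 0.1),
      se_out = stats::runif(k, 0.01, 0.1),
      se_exp = stats::runif(k, 0.005, 0.02)
    )
  })
}

# canonical summary-stats tibble for IO and instrument tests
make_sumstats <- function(n = 3, pvalue = NULL, trait = "trait", seed = 42) {
  withr::with_seed(seed, {
    tb <- tibble::tibble(
      snp_id = paste0("rs", seq_len(n)),
      chrom = as.character(rep_len(1:2, n)),
      pos = seq_len(n) * 25000000L,
      effect_allele = rep_len(c("A", "C", "G"), n),
      other_allele = rep_len(c("G", "T", "A"), n),
      eaf = stats::runif(n, 0.1, 0.45),
      beta = stats::rnorm(n, 0, 0.2),
      se = stats::runif(n, 0.01, 0.05),
      n = 10000L
    )
    tb$pvalue <- if (is.null(pvalue)) {
      2 * stats::pnorm(-abs(tb$beta / tb$se))
    } else {
      rep_len(pvalue, n)
    }
    tb[, c("snp_id", "chrom", "pos", "effect_allele", "other_allele",
           "eaf", "beta", "se", "pvalue", "n")]
  })
}

# independent re-implementation of greedy clumping, written plainly:
# exhaustively check every retained SNP against every earlier retained SNP
clump_oracle <- function(tb, r2_threshold, window_kb, ld) {
  tb <- tb[order(tb$pvalue, tb$chrom, tb$pos, tb$snp_id), ]
  retained <- tb[0, ]
  for (i in seq_len(nrow(tb))) {
    conflict <- FALSE
    if (nrow(retained) > 0) {
      for (j in seq_len(nrow(retained))) {
        same_chr <- retained$chrom[j] == tb$chrom[i]
        near <- abs(retained$pos[j] - tb$pos[i]) <= window_kb * 1000
        if (same_chr && near) {
          if (is.null(ld)) {
            conflict <- TRUE
          } else if (ld$r2[tb$snp_id[i], retained$snp_id[j]] >= r2_threshold) {
            conflict <- TRUE
          }
        }
      }
    }
    if (!conflict) retained <- rbind(retained, tb[i, ])
  }
  sort(retained$snp_id)
}

# literal cumulative-weight scan over sorted ratios
weighted_median_oracle <- function(ratio, w) {
  o <- order(ratio)
  ratio <- ratio[o]
  w <- w[o] / sum(w)
  cum <- cumsum(w) - w / 2
  if (cum[1] >= 0.5) return(ratio[1])
  for (k in seq_along(ratio)) {
    if (cum[k] >= 0.5) {
      return(ratio[k - 1] + (ratio[k] - ratio[k - 1]) *
               (0.5 - cum[k - 1]) / (cum[k] - cum[k - 1]))
    }
  }
  ratio[length(ratio)]
}
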