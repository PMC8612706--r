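# Synthetic generator: mixture identities, determinism, parameter recovery.

.default_means_for_test <- function() synthetic_config()$celltype_means

test_that("config validation rejects bad worlds", {
  expect_error(synthetic_config(n_participants = 1), "n_participants")
  expect_error(synthetic_config(composition_concentration = -5), "Dirichlet")
  expect_error(synthetic_config(weekly_autocorrelation = 1.2), "autocorrelation")
  m <- .default_means_for_test()
  m[1, 1] <- -1
  expect_error(synthetic_config(celltype_means = m), "positive")
})

test_that("degenerate mixture: single subtype, zero noise, zero platelet term", {
  co <- generate_cohort(noiseless_config())
  s <- co$samples
  for (f in c("CS", "CI", "CII", "CIV", "mtDNAcn")) {
    pb <- s[[f]][s$subtype == "PBMC"]
    mono <- s[[f]][s$subtype == "monocytes"]
    expect_equal(pb, mono, tolerance = 1e-12)
  }
})

test_that("PBMC rows equal mixture + platelet term exactly (zero feature noise)", {
  cfg <- synthetic_config(n_participants = 8, celltype_cv = 0, platelet_cv = 0,
                          seed = 41)
  co <- generate_cohort(cfg)
  s <- co$samples
  w_all <- co$truth$mixture_weights
  mono_sub <- setdiff(cfg$subtypes, "neutrophils")
  for (i in seq_len(nrow(co$participants))) {
    pid <- co$participants$participant[i]
    w <- w_all[i, mono_sub] / sum(w_all[i, mono_sub])
    for (f in c("CS", "CI", "CII", "CIV", "mtDNAcn")) {
      sub_vals <- vapply(mono_sub, function(st)
        s[[f]][s$participant == pid & s$subtype == st], numeric(1))
      expected <- unname(sum(w * sub_vals) + co$truth$platelet_term[i, f])
      expect_equal(s[[f]][s$participant == pid & s$subtype == "PBMC"],
                   expected, tolerance = 1e-12)
    }
  }
})

test_that("determinism: identical seeds identical cohorts, distinct seeds differ", {
  a <- generate_cohort(synthetic_config(n_participants = 6, seed = 99))
  b <- generate_cohort(synthetic_config(n_participants = 6, seed = 99))
  expect_identical(a$samples, b$samples)
  expect_identical(a$participants, b$participants)
  c2 <- generate_cohort(synthetic_config(n_participants = 6, seed = 100))
  expect_false(identical(a$samples$CS, c2$samples$CS))
  # generators restore the caller's RNG stream
  set.seed(1); before <- runif(1)
  set.seed(1); invisible(generate_cohort(synthetic_config(n_participants = 3)))
  expect_identical(runif(1), before)
})

test_that("age-slope recovery: fitted fractional slope within 2%/decade of truth", {
  co <- generate_cohort(synthetic_config(n_participants = 500, celltype_cv = 0.1,
                                         sex_effects = 1, seed = 12))
  s <- co$samples[co$samples$subtype == "monocytes", ]
  fit <- lm(mtDNAcn ~ I((age - 20) / 10), data = s)
  frac_slope <- coef(fit)[2] / coef(fit)[1]
  expect_lt(abs(unname(frac_slope) - 0.10), 0.02)  # +-2%/decade
})

test_that("sex-effect recovery on a large cohort", {
  co <- generate_cohort(synthetic_config(n_participants = 500, celltype_cv = 0.1,
                                         age_slopes = 0, seed = 13))
  s <- co$samples[co$samples$subtype == "CD8_CMEM", ]
  ratio <- mean(s$CS[s$sex == "F"]) / mean(s$CS[s$sex == "M"])
  expect_lt(abs(ratio - 1.29), 0.03)
})

test_that("weekly series: degenerate, autocorrelation and CV calibration", {
  cfg0 <- synthetic_config(weekly_cv = 0, seed = 1)
  w0 <- generate_repeat_series(cfg0, n_weeks = 5)
  one <- w0[w0$subtype == "NK" & w0$feature == "CS", ]
  expect_equal(length(unique(one$value)), 1)
  expect_equal(rmssd(one$value), 0)

  cfg <- synthetic_config(weekly_autocorrelation = 0, weekly_cv = 0.2, seed = 14)
  w <- generate_repeat_series(cfg, n_weeks = 10000, subtypes = "NK")
  x <- w$value[w$feature == "CS"]
  lag1 <- cor(log(x[-1]), log(x[-length(x)]))
  expect_lt(abs(lag1), 0.03)                       # Monte-Carlo error at n = 1e4
  expect_true(series_cv(x) > 0.19 && series_cv(x) < 0.21)

  expect_error(generate_repeat_series(cfg, n_weeks = 1), "n_weeks")
})

test_that("depletion triplets obey the closed-form mixture identities", {
  cfg <- synthetic_config(seed = 15)
  # efficiency 1, carryover 0, zero noise -> depleted is the pure leukocyte
  tr <- generate_depletion_triplets(cfg, n_subjects = 4, depletion_efficiency = 1,
                                    carryover = 0, noise_cv = 0, subject_cv = 0)
  truth <- attr(tr, "truth")
  tot <- tr[tr$fraction == "total", ]; dep <- tr[tr$fraction == "depleted", ]
  for (f in c("CS", "CI", "CII", "mtDNAcn")) {
    share <- truth$share[, f]
    expect_equal((dep[[f]] - tot[[f]]) / tot[[f]], -unname(share), tolerance = 1e-12)
  }
  # efficiency 0 -> depleted equals total
  tr0 <- generate_depletion_triplets(cfg, n_subjects = 3, depletion_efficiency = 0,
                                     noise_cv = 0)
  expect_equal(tr0[tr0$fraction == "depleted", "CS"],
               tr0[tr0$fraction == "total", "CS"], tolerance = 1e-12)
  # efficiency 0.8 -> percent change is -0.8 * platelet share, analytically
  tr8 <- generate_depletion_triplets(cfg, n_subjects = 5, depletion_efficiency = 0.8,
                                     noise_cv = 0, subject_cv = 0)
  sh <- attr(tr8, "truth")$share[, "CS"]
  tot8 <- tr8[tr8$fraction == "total", "CS"]; dep8 <- tr8[tr8$fraction == "depleted", "CS"]
  expect_equal((dep8 - tot8) / tot8, -0.8 * unname(sh), tolerance = 1e-12)
  expect_error(generate_depletion_triplets(cfg, depletion_efficiency = 1.4),
               "efficiency")
})

test_that("raw tables invert the ingest formulas", {
  co <- small_cohort(seed = 16, n = 4)
  raw <- generate_raw_tables(co)
  # mtDNAcn 256 would imply dCt 7; check the emitted dCt for actual samples
  ct <- raw$ct
  one <- ct[ct$sample_id == ct$sample_id[1] & ct$assay == "ND1/B2M", ]
  truth <- co$samples$mtDNAcn[paste(co$samples$participant, co$samples$subtype,
                                    sep = "_") == ct$sample_id[1]]
  expect_equal(mean(one$ct_nuc) - mean(one$ct_mt), log2(truth / 2), tolerance = 1e-12)
  # both duplex assays emit the same dCt at zero noise
  two <- ct[ct$sample_id == ct$sample_id[1] & ct$assay == "COX1/RNaseP", ]
  expect_equal(mean(two$ct_nuc) - mean(two$ct_mt),
               mean(one$ct_nuc) - mean(one$ct_mt), tolerance = 1e-12)
  # plate layout: references bracket the run, run_order unique per enzyme
  pl <- raw$plate[raw$plate$enzyme == "CS" & raw$plate$well == 1, ]
  expect_true(pl$is_reference[which.min(pl$run_order)])
  expect_true(pl$is_reference[which.max(pl$run_order)])
  expect_false(any(duplicated(pl$run_order)))
})
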