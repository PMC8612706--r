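# Synthetic cohort generator: a stated world with the statistical structure
# the downstream analysis assumes — cell-type-specific feature means with
# log-normal dispersion, configured sex and age effects, Dirichlet cell
# composition, an age-declining platelet count that contaminates the PBMC
# mixture, AR(1) weekly dynamics, and platelet-depletion triplets. Every
# generated object carries its generating parameters (`truth`) so estimators
# can be validated by parameter recovery.

.subtypes <- c("neutrophils", "monocytes", "NK", "B",
               "CD4_naive", "CD4_CMEM", "CD8_naive", "CD8_CMEM")
.mononuclear <- setdiff(.subtypes, "neutrophils")
.repeat_subtypes <- c("neutrophils", "NK", "monocytes",
                      "CD4_naive", "CD4_CMEM", "CD8_naive")

# PBMCs contain no granulocytes; the mixture runs over mononuclear subtypes
# (all subtypes when the configured world has no mononuclear label)
.pbmc_constituents <- function(subtypes) {
  mono <- intersect(.mononuclear, subtypes)
  if (length(mono)) mono else subtypes
}

# Default per-subtype feature means. mtDNAcn uses the printed per-cell-type
# values (B 451, CD8+ naive 427, neutrophils 128, NK 205, ~300 for the other
# T subtypes); enzyme activities (nominal units per 1e6 cells) follow the
# qualitative ordering: CS and RC highest in monocytes/B cells, lowest in
# neutrophils (RC) and CD4+ naive (CS).
.default_means <- function() {
  m <- rbind(
    neutrophils = c(CS = 4.0, CI = 1.8, CII = 1.4, CIV = 2.8, mtDNAcn = 128),
    monocytes   = c(CS = 8.8, CI = 6.0, CII = 4.0, CIV = 9.0, mtDNAcn = 300),
    NK          = c(CS = 4.4, CI = 3.0, CII = 2.2, CIV = 5.0, mtDNAcn = 205),
    B           = c(CS = 8.4, CI = 3.6, CII = 2.8, CIV = 6.0, mtDNAcn = 451),
    CD4_naive   = c(CS = 3.2, CI = 2.4, CII = 2.0, CIV = 4.0, mtDNAcn = 300),
    CD4_CMEM    = c(CS = 5.6, CI = 3.2, CII = 2.6, CIV = 5.2, mtDNAcn = 300),
    CD8_naive   = c(CS = 5.2, CI = 2.6, CII = 2.1, CIV = 4.4, mtDNAcn = 427),
    CD8_CMEM    = c(CS = 6.0, CI = 3.4, CII = 2.7, CIV = 5.6, mtDNAcn = 300))
  m
}

.default_composition <- c(neutrophils = 0.45, monocytes = 0.08, NK = 0.07,
                          B = 0.04, CD4_naive = 0.14, CD4_CMEM = 0.10,
                          CD8_naive = 0.06, CD8_CMEM = 0.06)

# matrix of F/M ratios, 1 = no effect
.default_sex_effects <- function() {
  m <- matrix(1, nrow = length(.subtypes), ncol = 5,
              dimnames = list(.subtypes, .feature_names))
  m["CD8_CMEM", "CS"] <- 1.29   # women 29% higher CS in CD8+ CM-EM
  m["monocytes", "CI"] <- 1.26  # women 26% higher CI in monocytes
  m
}

# fractional change per decade of age (from age 20)
.default_age_slopes <- function() {
  m <- matrix(0, nrow = length(.subtypes), ncol = 5,
              dimnames = list(.subtypes, .feature_names))
  m["CD4_naive", "mtDNAcn"] <- 0.10
  m["monocytes", "mtDNAcn"] <- 0.10
  m["neutrophils", "CS"] <- -0.07
  m
}

#' Configuration for the synthetic cohort generator
#'
#' Bundles and validates all generating parameters. Defaults encode the
#' stated study world: 21 participants aged 20-60 (11 women, 10 men),
#' printed per-cell-type mtDNAcn means, a 29% female CS excess in CD8+ CM-EM
#' cells and 26% CI excess in monocytes, +10%/decade mtDNAcn in CD4+ naive
#' cells and monocytes, -7%/decade neutrophil CS, a ~6%-per-decade platelet
#' decline, and platelet contamination contributing about 20% of the PBMC CS
#' signal (0 for CIV) at the reference platelet count.
#'
#' @param n_participants Cohort size (>= 2; default 21).
#' @param age_range Years, default c(20, 60).
#' @param sex_ratio Fraction female (default 11/21).
#' @param celltype_means Subtype x feature matrix of positive means.
#' @param celltype_cv Log-normal coefficient of variation per subtype x
#'   feature; scalar recycled (default 0.25).
#' @param sex_effects Subtype x feature matrix of multiplicative female/male
#'   ratios.
#' @param age_slopes Subtype x feature matrix of fractional change per decade
#'   of age (from age 20).
#' @param composition_mean Mean circulating proportions per subtype (sums
#'   to 1).
#' @param composition_concentration Dirichlet concentration (sum of alphas;
#'   default 60). All alphas must be positive.
#' @param platelet_baseline Platelet count at age 20, 1e9/L (default 260).
#' @param platelet_decline_per_decade Fractional decline per decade,
#'   compounded (default 0.06).
#' @param platelet_sex_ratio Female/male platelet ratio (default 1.2).
#' @param platelet_cv Log-normal CV of platelet counts (default 0.15).
#' @param platelet_share Per-feature fraction of the PBMC signal contributed
#'   by platelets at the reference platelet count; converted internally to
#'   `platelet_signal_coefficient` (signal per unit platelet count). CIV
#'   defaults to 0 (platelet CIV contribution is not platelet-sensitive in
#'   the depletion data).
#' @param weekly_autocorrelation Lag-1 autocorrelation of weekly dynamics, in
#'   (-1, 1) (default 0.3).
#' @param weekly_cv Weekly log-normal CV per feature; scalar recycled
#'   (default 0.2).
#' @param seed Integer seed; identical seeds give bit-identical output.
#' @return Object of class `"synthetic_config"` (a validated list; also holds
#'   the derived `platelet_signal_coefficient` and the reference platelet
#'   count of 250).
#' @export
synthetic_config <- function(n_participants = 21,
                             age_range = c(20, 60),
                             sex_ratio = 11 / 21,
                             celltype_means = .default_means(),
                             celltype_cv = 0.25,
                             sex_effects = .default_sex_effects(),
                             age_slopes = .default_age_slopes(),
                             composition_mean = .default_composition,
                             composition_concentration = 60,
                             platelet_baseline = 260,
                             platelet_decline_per_decade = 0.06,
                             platelet_sex_ratio = 1.2,
                             platelet_cv = 0.15,
                             platelet_share = c(CS = 0.20, CI = 0.15, CII = 0.12,
                                                CIV = 0, mtDNAcn = 0.15),
                             weekly_autocorrelation = 0.3,
                             weekly_cv = 0.2,
                             seed = 1L) {
  subtypes <- rownames(celltype_means)
  assert_that(!is.null(subtypes) && all(.feature_names %in% colnames(celltype_means)),
              "celltype_means must be a subtype x feature matrix (CS, CI, CII, CIV, mtDNAcn)")
  celltype_means <- celltype_means[, .feature_names, drop = FALSE]
  assert_that(all(is.finite(celltype_means) & celltype_means > 0),
              "all feature means must be strictly positive")
  expand <- function(x, what) {
    if (is.matrix(x)) {
      assert_that(all(subtypes %in% rownames(x)) && all(.feature_names %in% colnames(x)),
                  paste(what, "matrix must cover all subtypes and features"))
      return(x[subtypes, .feature_names, drop = FALSE])
    }
    matrix(x, nrow = length(subtypes), ncol = 5,
           dimnames = list(subtypes, .feature_names))
  }
  celltype_cv <- expand(celltype_cv, "celltype_cv")
  sex_effects <- expand(sex_effects, "sex_effects")
  age_slopes <- expand(age_slopes, "age_slopes")
  assert_that(all(celltype_cv >= 0), "celltype_cv must be non-negative")
  assert_that(all(sex_effects > 0), "sex_effects must be positive ratios")
  assert_that(n_participants >= 2, "n_participants must be >= 2")
  assert_that(sex_ratio >= 0 && sex_ratio <= 1, "sex_ratio must be in [0, 1]")
  assert_that(length(age_range) == 2 && age_range[1] < age_range[2],
              "age_range must be increasing")
  assert_that(all(names(composition_mean) == subtypes) || setequal(names(composition_mean), subtypes),
              "composition_mean must name every subtype")
  composition_mean <- composition_mean[subtypes]
  assert_that(all(composition_mean > 0), "composition proportions must be positive")
  composition_mean <- composition_mean / sum(composition_mean)
  alpha <- composition_mean * composition_concentration
  assert_that(all(alpha > 0), "Dirichlet parameters must be > 0")
  assert_that(platelet_decline_per_decade >= 0 && platelet_decline_per_decade < 1,
              "platelet_decline_per_decade must be a fraction in [0, 1)")
  assert_that(abs(weekly_autocorrelation) < 1,
              "weekly_autocorrelation must lie in (-1, 1)")
  ws <- if (length(weekly_cv) == 1)
    stats::setNames(rep(weekly_cv, 5), .feature_names) else weekly_cv[.feature_names]
  assert_that(all(ws >= 0), "weekly_cv must be >= 0")
  platelet_share <- platelet_share[.feature_names]
  assert_that(all(platelet_share >= 0 & platelet_share < 1),
              "platelet_share fractions must lie in [0, 1)")
  # leukocyte-only PBMC mean signal (mononuclear mixture at mean composition)
  mono <- .pbmc_constituents(subtypes)
  w <- composition_mean[mono] / sum(composition_mean[mono])
  pbmc_leuk_mean <- as.numeric(w %*% celltype_means[mono, , drop = FALSE])
  names(pbmc_leuk_mean) <- .feature_names
  ref_count <- 250
  coef <- platelet_share / (1 - platelet_share) * pbmc_leuk_mean / ref_count
  cfg <- list(n_participants = as.integer(n_participants), age_range = age_range,
              sex_ratio = sex_ratio, subtypes = subtypes,
              celltype_means = celltype_means, celltype_cv = celltype_cv,
              sex_effects = sex_effects, age_slopes = age_slopes,
              composition_mean = composition_mean, alpha = alpha,
              platelet_baseline = platelet_baseline,
              platelet_decline_per_decade = platelet_decline_per_decade,
              platelet_sex_ratio = platelet_sex_ratio, platelet_cv = platelet_cv,
              platelet_share = platelet_share,
              platelet_signal_coefficient = coef,
              platelet_reference_count = ref_count,
              weekly_autocorrelation = weekly_autocorrelation,
              weekly_cv = ws, seed = as.integer(seed))
  class(cfg) <- "synthetic_config"
  cfg
}

# mean-unbiased log-normal multiplier with coefficient of variation cv
.lnorm_noise <- function(n, cv) {
  if (all(cv == 0)) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  exp(stats::rnorm(n, -sdlog^2 / 2, sdlog))
}

.rdirichlet <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  g / sum(g)
}

#' Generate a synthetic cohort
#'
#' Draws participants (sex, age, cell composition, platelet count), per
#' subtype feature vectors `mean x sexfactor x (1 + slope * decades) x
#' log-normal noise`, and PBMC rows as the composition-weighted mixture of the
#' mononuclear subtype vectors plus the platelet contamination term. Platelets
#' add mtDNA but no nuclear genomes, so the platelet term enters the mtDNAcn
#' numerator only.
#'
#' @param config A [synthetic_config()].
#' @return Object of class `"synthetic_cohort"`: list with `participants`
#'   (id, sex, age, platelet_count, composition columns `prop_*`), `samples`
#'   (tidy: sample_id, participant, subtype, sex, age, five features), and
#'   `truth` (the config plus per-participant latent values: mixture weights,
#'   PBMC leukocyte-only vectors, platelet terms).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  assert_that(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  .with_seed(config$seed, {
    n <- config$n_participants
    ids <- sprintf("P%03d", seq_len(n))
    n_f <- round(n * config$sex_ratio)
    sex <- sample(c(rep("F", n_f), rep("M", n - n_f)))
    age <- stats::runif(n, config$age_range[1], config$age_range[2])
    decades <- (age - 20) / 10
    comp <- matrix(NA_real_, n, length(config$alpha),
                   dimnames = list(NULL, config$subtypes))
    for (i in seq_len(n)) comp[i, ] <- .rdirichlet(config$alpha)
    plt_sexfac <- ifelse(sex == "F", sqrt(config$platelet_sex_ratio),
                         1 / sqrt(config$platelet_sex_ratio))
    platelet <- config$platelet_baseline *
      (1 - config$platelet_decline_per_decade)^decades *
      plt_sexfac * .lnorm_noise(n, config$platelet_cv)
    participants <- data.frame(participant = ids, sex = sex, age = age,
                               platelet_count = platelet, stringsAsFactors = FALSE)
    for (st in config$subtypes) participants[[paste0("prop_", st)]] <- comp[, st]

    samples <- list(); leuk_pbmc <- matrix(NA_real_, n, 5,
                                           dimnames = list(ids, .feature_names))
    plt_term <- outer(platelet, config$platelet_signal_coefficient)
    colnames(plt_term) <- .feature_names
    for (i in seq_len(n)) {
      vals <- matrix(NA_real_, length(config$subtypes), 5,
                     dimnames = list(config$subtypes, .feature_names))
      for (st in config$subtypes) {
        sexfac <- if (sex[i] == "F") config$sex_effects[st, ] else rep(1, 5)
        agefac <- 1 + config$age_slopes[st, ] * decades[i]
        vals[st, ] <- config$celltype_means[st, ] * sexfac * agefac *
          .lnorm_noise(5, config$celltype_cv[st, ])
      }
      mono <- .pbmc_constituents(config$subtypes)
      w <- comp[i, mono] / sum(comp[i, mono])
      leuk <- as.numeric(w %*% vals[mono, , drop = FALSE])
      names(leuk) <- .feature_names
      leuk_pbmc[i, ] <- leuk
      pbmc <- leuk + plt_term[i, ]
      samples[[i]] <- cbind(
        data.frame(sample_id = paste(ids[i], c(config$subtypes, "PBMC"), sep = "_"),
                   participant = ids[i],
                   subtype = c(config$subtypes, "PBMC"),
                   sex = sex[i], age = age[i], stringsAsFactors = FALSE),
        as.data.frame(rbind(vals, PBMC = pbmc)))
    }
    samples <- do.call(rbind, samples)
    rownames(samples) <- NULL
    out <- list(participants = participants, samples = samples,
                truth = list(config = config, leukocyte_pbmc = leuk_pbmc,
                             platelet_term = plt_term,
                             mixture_weights = comp))
    class(out) <- "synthetic_cohort"
    out
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants, %d samples (%d subtypes + PBMC)\n",
              nrow(x$participants), nrow(x$samples),
              length(x$truth$config$subtypes)))
  invisible(x)
}

#' Generate weekly repeat-participant series
#'
#' Multiplicative AR(1) fluctuations around one person's subtype feature
#' means: `value_t = mean * exp(sigma * z_t - sigma^2/2)` where `z` is a
#' stationary AR(1) with the configured lag-1 autocorrelation, and `sigma`
#' reproduces the configured weekly CV exactly for the log-normal marginal.
#' Covers the six subtypes collected from the repeat participant
#' (neutrophils, NK, monocytes, CD4+ naive, CD4+ CM-EM, CD8+ naive).
#'
#' @param config A [synthetic_config()].
#' @param n_weeks Number of weekly time points (>= 2; default 9).
#' @param person Person id (default "R01").
#' @param subtypes Subtypes to simulate (default the repeat-participant six).
#' @return Tidy data.frame: person, subtype, feature, week, value.
#' @export
generate_repeat_series <- function(config = synthetic_config(), n_weeks = 9,
                                   person = "R01",
                                   subtypes = intersect(.repeat_subtypes,
                                                        config$subtypes)) {
  assert_that(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  assert_that(n_weeks >= 2, "n_weeks must be >= 2")
  rho <- config$weekly_autocorrelation
  assert_that(abs(rho) < 1, "weekly autocorrelation must lie in (-1, 1)")
  .with_seed(config$seed + 1L, {
    rows <- list()
    for (st in subtypes) for (f in .feature_names) {
      cv <- config$weekly_cv[[f]]
      if (cv == 0) {
        vals <- rep(config$celltype_means[st, f], n_weeks)
      } else {
        sdlog <- sqrt(log(1 + cv^2))
        z <- numeric(n_weeks)
        z[1] <- stats::rnorm(1)
        if (n_weeks > 1) {
          e <- stats::rnorm(n_weeks - 1)
          for (t in 2:n_weeks) z[t] <- rho * z[t - 1] + sqrt(1 - rho^2) * e[t - 1]
        }
        vals <- config$celltype_means[st, f] * exp(sdlog * z - sdlog^2 / 2)
      }
      rows[[length(rows) + 1]] <- data.frame(
        person = person, subtype = st, feature = f,
        week = seq_len(n_weeks), value = vals, stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Generate platelet-depletion triplets
#'
#' Per subject: a leukocyte signal vector and a platelet contamination term;
#' total PBMC = leukocyte + platelet term, depleted = leukocyte +
#' (1 - efficiency) * platelet term, eluate = platelet term + carryover *
#' leukocyte term. Measurement noise is multiplicative log-normal.
#'
#' @param config A [synthetic_config()].
#' @param n_subjects Number of subjects (default 9).
#' @param depletion_efficiency Fraction of platelet signal removed by the
#'   depletion, in [0, 1] (default 1).
#' @param carryover Fraction of leukocyte signal carried into the eluate
#'   (default 0.1).
#' @param noise_cv Measurement log-normal CV (default 0.05).
#' @param subject_cv Between-subject log-normal CV of the leukocyte signal
#'   (default 0.2).
#' @return Tidy data.frame: subject, fraction (total/depleted/eluate), five
#'   feature columns; attribute `"truth"` holds per-subject platelet shares
#'   of the total signal and the generating parameters.
#' @export
generate_depletion_triplets <- function(config = synthetic_config(),
                                        n_subjects = 9,
                                        depletion_efficiency = 1,
                                        carryover = 0.1,
                                        noise_cv = 0.05,
                                        subject_cv = 0.2) {
  assert_that(inherits(config, "synthetic_config"), "config must be a synthetic_config")
  assert_that(depletion_efficiency >= 0 && depletion_efficiency <= 1,
              "depletion_efficiency must lie in [0, 1]")
  assert_that(n_subjects >= 1, "n_subjects must be >= 1")
  .with_seed(config$seed + 2L, {
    mono <- .pbmc_constituents(config$subtypes)
    w <- config$composition_mean[mono] / sum(config$composition_mean[mono])
    leuk_mean <- as.numeric(w %*% config$celltype_means[mono, , drop = FALSE])
    names(leuk_mean) <- .feature_names
    ids <- sprintf("D%02d", seq_len(n_subjects))
    rows <- list(); share <- matrix(NA_real_, n_subjects, 5,
                                    dimnames = list(ids, .feature_names))
    for (i in seq_len(n_subjects)) {
      leuk <- leuk_mean * .lnorm_noise(5, subject_cv)
      plt_count <- config$platelet_reference_count * .lnorm_noise(1, config$platelet_cv)
      plt <- config$platelet_signal_coefficient * plt_count
      total <- leuk + plt
      depl <- leuk + (1 - depletion_efficiency) * plt
      elu <- plt + carryover * leuk
      share[i, ] <- plt / total
      meas <- function(v) v * .lnorm_noise(5, noise_cv)
      rows[[length(rows) + 1]] <- cbind(
        data.frame(subject = ids[i],
                   fraction = c("total", "depleted", "eluate"),
                   stringsAsFactors = FALSE),
        as.data.frame(rbind(meas(total), meas(depl), meas(elu))))
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    attr(out, "truth") <- list(share = share,
                               depletion_efficiency = depletion_efficiency,
                               carryover = carryover, noise_cv = noise_cv)
    out
  })
}

#' Emit raw plate and Ct tables for a cohort
#'
#' Inverts the ingestion path: triplicate wells per sample x enzyme with
#' optional multiplicative well noise and an injected additive linear
#' run-order drift, plus reference replicates (a pooled sample at the true
#' enzyme grand mean) spaced through the run; and duplex Ct pairs such that
#' `2 * 2^(Ct_nuc - Ct_mt)` recovers each sample's mtDNAcn exactly at zero
#' noise.
#'
#' @param cohort A [generate_cohort()] result.
#' @param well_cv Multiplicative log-normal well noise CV (default 0).
#' @param drift_per_position Additive activity drift per run position
#'   (default 0).
#' @param ct_sd Gaussian noise sd on each Ct value, cycles (default 0).
#' @param ref_every Insert a reference replicate every this many sample
#'   positions (default 16); references always occupy the first and last
#'   positions.
#' @param ct_nuc Nominal nuclear-probe Ct (default 25).
#' @param samples_per_plate Plate size used to assign plate ids (default 31).
#' @return List with `plate` (sample_id, participant, subtype, enzyme, well,
#'   activity, plate, run_order, is_reference) and `ct` (sample_id, assay,
#'   ct_mt, ct_nuc, replicate).
#' @export
generate_raw_tables <- function(cohort, well_cv = 0, drift_per_position = 0,
                                ct_sd = 0, ref_every = 16, ct_nuc = 25,
                                samples_per_plate = 31) {
  assert_that(inherits(cohort, "synthetic_cohort"), "cohort must be a synthetic_cohort")
  s <- cohort$samples
  .with_seed(cohort$truth$config$seed + 3L, {
    n <- nrow(s)
    # run layout shared across enzymes: reference positions (NA) interleaved
    # between samples, always at the very start and end of the run
    mid <- if (n - 1 >= ref_every) seq(ref_every, n - 1, by = ref_every) else integer(0)
    ref_after <- unique(c(0L, mid, n))
    order_idx <- integer(0)
    for (i in 0:n) {
      if (i %in% ref_after) order_idx <- c(order_idx, NA_integer_)
      if (i < n) order_idx <- c(order_idx, i + 1L)
    }
    run_order <- seq_along(order_idx)
    plate_rows <- list()
    for (enz in c("CS", "CI", "CII", "CIV")) {
      grand <- mean(s[[enz]])
      true_vals <- ifelse(is.na(order_idx), grand, s[[enz]][order_idx])
      drifted <- true_vals + drift_per_position * (run_order - 1)
      for (w in 1:3) {
        noise <- .lnorm_noise(length(drifted), well_cv)
        plate_rows[[paste(enz, w)]] <- data.frame(
          sample_id = ifelse(is.na(order_idx), "REFERENCE",
                             paste(s$participant[order_idx], s$subtype[order_idx], sep = "_")),
          participant = ifelse(is.na(order_idx), NA_character_, s$participant[order_idx]),
          subtype = ifelse(is.na(order_idx), NA_character_, s$subtype[order_idx]),
          enzyme = enz, well = w,
          activity = drifted * noise,
          plate = ceiling(run_order / samples_per_plate),
          run_order = run_order,
          is_reference = is.na(order_idx),
          stringsAsFactors = FALSE)
      }
    }
    plate <- do.call(rbind, plate_rows)
    rownames(plate) <- NULL
    # reference rows must stay distinguishable per run position
    plate$sample_id[plate$is_reference] <-
      paste0("REF_", plate$run_order[plate$is_reference])
    ct_rows <- list()
    dct <- log2(s$mtDNAcn / 2)
    for (assay in c("ND1/B2M", "COX1/RNaseP")) for (rep_i in 1:2) {
      ct_rows[[paste(assay, rep_i)]] <- data.frame(
        sample_id = paste(s$participant, s$subtype, sep = "_"),
        assay = assay,
        ct_mt = ct_nuc - dct + stats::rnorm(n, 0, ct_sd),
        ct_nuc = ct_nuc + stats::rnorm(n, 0, ct_sd),
        replicate = rep_i, stringsAsFactors = FALSE)
    }
    ct <- do.call(rbind, ct_rows)
    rownames(ct) <- NULL
    list(plate = plate, ct = ct)
  })
}
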