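# Repeated-measures dynamics for the weekly series: scaling, CV, rMSSD,
# within-person co-regulation, and cohort-vs-repeat mitotype conservation.

#' Center and scale a weekly series in SD units
#'
#' `(x - mean) / sd` with the sample (n-1) sd, so one unit is one standard
#' deviation. Constant series return all zeros with a flag attribute.
#'
#' @param values Numeric series (ordered by week).
#' @return Scaled series; attribute `"constant"` TRUE when the input was
#'   constant.
#' @export
scale_series <- function(values) {
  v <- values[is.finite(values)]
  assert_that(length(v) >= 2, "scale_series needs >= 2 observed points")
  s <- .sd_conv(values[is.finite(values)])
  if (!is.finite(s) || s == 0) {
    out <- ifelse(is.finite(values), 0, NA_real_)
    attr(out, "constant") <- TRUE
    return(out)
  }
  out <- (values - mean(v)) / s
  attr(out, "constant") <- FALSE
  out
}

#' Root mean square of successive differences (rMSSD)
#'
#' `sqrt(mean((x[t+1] - x[t])^2))` over consecutive observed weeks. Missing
#' weeks break the chain: a pair is only "successive" when the week indices
#' are adjacent.
#'
#' @param values Numeric series.
#' @param weeks Integer week indices (default `seq_along(values)`).
#' @return rMSSD, or NA with a warning when no consecutive observed pair
#'   exists.
#' @examples
#' rmssd(c(1, -1, 1))  # 2
#' @export
rmssd <- function(values, weeks = seq_along(values)) {
  assert_that(length(values) == length(weeks), "values and weeks differ in length")
  ok <- is.finite(values)
  values <- values[ok]; weeks <- weeks[ok]
  o <- order(weeks)
  values <- values[o]; weeks <- weeks[o]
  succ <- which(diff(weeks) == 1)
  if (length(succ) == 0) {
    warning("no consecutive observed weeks: rMSSD undefined")
    return(NA_real_)
  }
  d <- values[succ + 1] - values[succ]
  sqrt(mean(d^2))
}

#' Coefficient of variation of a series
#'
#' `sd / mean` with the sample (n-1) sd; requires positive values.
#'
#' @param values Numeric series (positive).
#' @return CV as a fraction, NA when the mean is not positive.
#' @examples
#' series_cv(c(8, 12))  # 0.2828
#' @export
series_cv <- function(values) {
  v <- values[is.finite(values)]
  assert_that(length(v) >= 2, "series_cv needs >= 2 points")
  if (mean(v) <= 0) {
    warning("non-positive mean: CV undefined")
    return(NA_real_)
  }
  .sd_conv(v) / mean(v)
}

#' Weekly variability metrics for a set of series
#'
#' Applies [series_cv()] and [rmssd()] (the latter on the SD-scaled series,
#' so rMSSD is in SD units) to each (subtype, feature) series of a tidy
#' weekly table.
#'
#' @param weekly Tidy data.frame: person, subtype, feature, week, value.
#' @return Data.frame: person, subtype, feature, n_weeks, cv, rmssd_sd_units.
#' @export
weekly_metrics <- function(weekly) {
  need <- c("person", "subtype", "feature", "week", "value")
  assert_that(all(need %in% names(weekly)), "weekly table needs person/subtype/feature/week/value")
  key <- interaction(weekly$person, weekly$subtype, weekly$feature, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(weekly)), key), function(idx) {
    d <- weekly[idx, ]
    d <- d[order(d$week), ]
    sc <- suppressWarnings(scale_series(d$value))
    data.frame(person = d$person[1], subtype = d$subtype[1], feature = d$feature[1],
               n_weeks = sum(is.finite(d$value)),
               cv = suppressWarnings(series_cv(d$value)),
               rmssd_sd_units = suppressWarnings(rmssd(sc, d$week)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Within-person co-regulation across cell subtypes
#'
#' Week-wise Spearman correlations between subtypes for one feature in one
#' person's weekly series, Fisher-averaged over the off-diagonal. Subtype
#' pairs with fewer than `min_n` shared weeks are excluded.
#'
#' @param weekly Tidy weekly table (person, subtype, feature, week, value).
#' @param feature Feature (or mitotype) name to analyze.
#' @param min_n Minimum shared weeks per pair (default 4).
#' @param absolute Average absolute correlations (default FALSE).
#' @return A `"coregulation_summary"` (see [coregulation()]).
#' @export
within_person_coregulation <- function(weekly, feature, min_n = 4, absolute = FALSE) {
  d <- weekly[weekly$feature == feature, , drop = FALSE]
  assert_that(nrow(d) > 0, paste0("no rows for feature '", feature, "'"))
  wide <- .pivot_ps(d, "week", "subtype", "value")
  .coregulation_core(wide, feature, min_n = min_n, absolute = absolute)
}

#' Conservation of mitotypes between a cohort and a repeat participant
#'
#' Quantifies how much larger between-cell-subtype mitotype differences are
#' than cohort-vs-repeat differences within a subtype. Per mitotype, the
#' dominant between-subtype effect is the largest pairwise |Hedges' g| across
#' subtypes within the cohort; the within-subtype effect is |g| of cohort vs
#' repeat values for the same subtype. The conservation ratio aggregates the
#' two sets (mean by default, median optionally).
#'
#' @param cohort_mitotypes,repeat_mitotypes Outputs of [compute_mitotypes()]
#'   with a `subtype` column; only subtypes present in both are used.
#' @param aggregate `"mean"` (default) or `"median"`.
#' @return List with `ratio`, `between` (per-mitotype dominant |g|), `within`
#'   (per mitotype x subtype |g|), and `subtypes` used. `ratio` is Inf with a
#'   flag when the within-subtype differences are all zero.
#' @export
mitotype_conservation <- function(cohort_mitotypes, repeat_mitotypes,
                                  aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  registry <- attr(cohort_mitotypes, "registry")
  assert_that(!is.null(registry), "inputs must come from compute_mitotypes()")
  shared <- intersect(unique(cohort_mitotypes$subtype), unique(repeat_mitotypes$subtype))
  dropped <- setdiff(unique(cohort_mitotypes$subtype), shared)
  if (length(dropped)) warning("subtypes missing from repeat data excluded: ",
                               paste(dropped, collapse = ", "))
  assert_that(length(shared) >= 2, "need >= 2 shared subtypes")
  between <- numeric(0); within <- list()
  for (mt in registry$name) {
    vals <- lapply(shared, function(st)
      cohort_mitotypes[[mt]][cohort_mitotypes$subtype == st &
                               is.finite(cohort_mitotypes[[mt]])])
    names(vals) <- shared
    gmax <- 0
    for (i in seq_along(shared)[-length(shared)]) for (j in (i + 1):length(shared)) {
      if (length(vals[[i]]) >= 2 && length(vals[[j]]) >= 2) {
        g <- abs(suppressWarnings(hedges_g(vals[[i]], vals[[j]])$g))
        if (is.finite(g)) gmax <- max(gmax, g)
      }
    }
    between[mt] <- gmax
    for (st in shared) {
      rep_v <- repeat_mitotypes[[mt]][repeat_mitotypes$subtype == st &
                                        is.finite(repeat_mitotypes[[mt]])]
      if (length(vals[[st]]) >= 2 && length(rep_v) >= 2) {
        g <- suppressWarnings(hedges_g(vals[[st]], rep_v)$g)
        within[[paste(mt, st, sep = "|")]] <- abs(g)
      }
    }
  }
  within <- unlist(within)
  aggfun <- if (aggregate == "mean") mean else stats::median
  wagg <- aggfun(within[is.finite(within)])
  ratio <- if (!is.finite(wagg) || wagg == 0) Inf else aggfun(between) / wagg
  if (!is.finite(ratio)) warning("within-subtype differences are zero: ratio infinite")
  list(ratio = ratio, between = between, within = within, subtypes = shared,
       aggregate = aggregate)
}
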