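# Feature assembly: reference statistics and the mitochondrial health index
# (MHI), a composite of respiratory-chain capacity per unit of mitochondrial
# content.

#' Reference statistics for feature normalization
#'
#' Per-feature mean and sd within a stratum (default: per cell subtype across
#' participants). These are the centering references used by [compute_mhi()].
#' Strata with fewer than 3 samples fall back to global statistics with a
#' warning.
#'
#' @param features Tidy feature table with columns CS, CI, CII, CIV, mtDNAcn.
#' @param stratum Name of the grouping column (default `"subtype"`), or NULL
#'   for a single global stratum.
#' @return Object of class `"reference_stats"`: data.frame with columns
#'   stratum, feature, mean, sd, n.
#' @export
compute_reference_stats <- function(features, stratum = "subtype") {
  feats <- intersect(.feature_names, names(features))
  assert_that(length(feats) == 5, "features table must contain CS, CI, CII, CIV, mtDNAcn")
  grp <- if (is.null(stratum)) rep("(all)", nrow(features)) else {
    assert_that(stratum %in% names(features), "stratum column not found")
    as.character(features[[stratum]])
  }
  global <- lapply(feats, function(f) {
    x <- features[[f]][is.finite(features[[f]])]
    c(mean = mean(x), sd = .sd_conv(x), n = length(x))
  })
  names(global) <- feats
  rows <- list()
  for (g in sort(unique(grp))) {
    idx <- grp == g
    for (f in feats) {
      x <- features[[f]][idx]
      x <- x[is.finite(x)]
      if (length(x) < 3) {
        warning("stratum '", g, "' has < 3 samples for ", f,
                ": falling back to global stats")
        st <- global[[f]]
      } else {
        st <- c(mean = mean(x), sd = .sd_conv(x), n = length(x))
      }
      rows[[length(rows) + 1]] <- data.frame(
        stratum = g, feature = f, mean = st[["mean"]], sd = st[["sd"]],
        n = st[["n"]], stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  attr(out, "stratum_col") <- stratum
  class(out) <- c("reference_stats", class(out))
  out
}

# look up reference means for one stratum as a named vector
.ref_means <- function(ref, stratum) {
  d <- ref[ref$stratum == stratum, ]
  if (nrow(d) == 0) d <- ref[ref$stratum == "(all)", ]
  assert_that(nrow(d) == 5, paste0("no reference stats for stratum '", stratum, "'"))
  stats::setNames(d$mean, d$feature)
}

#' Mitochondrial health index (MHI)
#'
#' Composite index of respiratory-chain capacity per mitochondrion: the three
#' RC activities (CI, CII, CIV) over the two content features (CS, mtDNAcn).
#' Each feature is first normalized to its reference mean (ratio form, which
#' keeps the denominator positive — literal mean-subtraction would let it
#' cross zero), then
#' \deqn{MHI = \frac{(CI' + CII' + CIV')/3}{(CS' + mtDNAcn')/2} \times 100}
#' so that a sample sitting exactly at the reference means scores 100. MHI is
#' invariant to rescaling all five features together, increases with each RC
#' feature, and decreases with each content feature.
#'
#' @param fv Named numeric vector or one-row list with CS, CI, CII, CIV,
#'   mtDNAcn.
#' @param ref_means Named numeric vector of reference means for the same five
#'   features (e.g. from [compute_reference_stats()] via the `stratum`).
#' @return MHI value (dimensionless, 100 at the reference point); NA with a
#'   warning when any feature is missing.
#' @examples
#' m <- c(CS = 5, CI = 3, CII = 2, CIV = 6, mtDNAcn = 300)
#' compute_mhi(m, m)  # 100
#' up <- m; up[c("CI", "CII", "CIV")] <- up[c("CI", "CII", "CIV")] * 1.1
#' compute_mhi(up, m)  # 110
#' @export
compute_mhi <- function(fv, ref_means) {
  fv <- unlist(fv)[.feature_names]
  ref_means <- unlist(ref_means)[.feature_names]
  if (any(!is.finite(fv))) {
    warning("missing feature: MHI undefined")
    return(NA_real_)
  }
  assert_that(all(is.finite(ref_means) & ref_means > 0), "reference means must be positive")
  pr <- fv / ref_means
  num <- (pr[["CI"]] + pr[["CII"]] + pr[["CIV"]]) / 3
  den <- (pr[["CS"]] + pr[["mtDNAcn"]]) / 2
  num / den * 100
}

#' Add an MHI column to a tidy feature table
#'
#' @param features Tidy feature table (columns subtype, CS, CI, CII, CIV,
#'   mtDNAcn).
#' @param ref Reference stats from [compute_reference_stats()]; computed from
#'   `features` itself when NULL.
#' @return `features` with an `MHI` column appended.
#' @export
add_mhi <- function(features, ref = NULL) {
  if (is.null(ref)) ref <- compute_reference_stats(features)
  stratum_col <- attr(ref, "stratum_col")
  features$MHI <- vapply(seq_len(nrow(features)), function(i) {
    strat <- if (is.null(stratum_col)) "(all)" else as.character(features[[stratum_col]][i])
    suppressWarnings(compute_mhi(features[i, .feature_names], .ref_means(ref, strat)))
  }, numeric(1))
  features
}

#' Retain the most abundant cell subtypes per participant
#'
#' Mirrors the sampling design in which only the six most abundant subtypes
#' per participant yield enough cells for phenotyping.
#'
#' @param features Tidy feature table with `participant` and `subtype`.
#' @param composition Data.frame with columns `participant`, `subtype`,
#'   `proportion`.
#' @param n Number of subtypes retained per participant (default 6).
#' @param keep Labels always retained regardless of abundance (default
#'   `"PBMC"`).
#' @return Filtered feature table.
#' @export
filter_top_subtypes <- function(features, composition, n = 6, keep = "PBMC") {
  assert_that(all(c("participant", "subtype", "proportion") %in% names(composition)),
              "composition needs participant, subtype, proportion")
  keep_rows <- logical(nrow(features))
  for (p in unique(features$participant)) {
    comp <- composition[composition$participant == p, ]
    top <- comp$subtype[order(-comp$proportion)][seq_len(min(n, nrow(comp)))]
    keep_rows <- keep_rows |
      (features$participant == p & features$subtype %in% c(top, keep))
  }
  features[keep_rows, , drop = FALSE]
}
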