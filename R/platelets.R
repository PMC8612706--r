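# Platelet-depletion decomposition: fold changes of the three matched
# fractions (total PBMCs, platelet-depleted PBMCs, platelet-enriched eluate),
# Friedman/Dunn testing, and the platelet contribution share.

#' Analyze platelet-depletion triplets
#'
#' Per mitochondrial feature: fold change of each fraction relative to total
#' PBMCs (per subject, summarized by the median by default), percent change of
#' the depleted fraction, and a tie-corrected Friedman test across the three
#' matched fractions with Dunn's comparisons against total PBMCs.
#'
#' @param triplets Tidy data.frame: `subject`, `fraction` (one of `"total"`,
#'   `"depleted"`, `"eluate"`), and the five feature columns (optionally also
#'   `MHI`). Subjects with incomplete triplets are excluded with a warning.
#' @param summary `"median"` (default) or `"mean"` for the fold-change
#'   summary.
#' @return List with `per_feature` (data.frame: feature, fold_depleted,
#'   fold_eluate, pct_change_depleted, friedman_chisq, friedman_p,
#'   dunn_p_depleted, dunn_p_eluate), `n_subjects`, and `folds` (per-subject
#'   fold changes, long).
#' @export
depletion_analysis <- function(triplets, summary = c("median", "mean")) {
  summary <- match.arg(summary)
  need <- c("subject", "fraction")
  assert_that(all(need %in% names(triplets)), "triplets need subject and fraction columns")
  assert_that(all(triplets$fraction %in% c("total", "depleted", "eluate")),
              "fraction must be total/depleted/eluate")
  feats <- intersect(c(.feature_names, "MHI"), names(triplets))
  assert_that(length(feats) > 0, "no feature columns found")
  complete <- names(which(tapply(triplets$fraction, triplets$subject,
                                 function(f) all(c("total", "depleted", "eluate") %in% f))))
  dropped <- setdiff(unique(triplets$subject), complete)
  if (length(dropped)) warning("subjects with incomplete triplets excluded: ",
                               paste(dropped, collapse = ", "))
  assert_that(length(complete) >= 3, "need >= 3 complete triplets")
  tr <- triplets[triplets$subject %in% complete, ]
  sumfun <- if (summary == "median") stats::median else mean
  per_feature <- list(); folds <- list()
  for (f in feats) {
    m <- .pivot_ps(tr, "subject", "fraction", f)[, c("total", "depleted", "eluate")]
    fd <- m[, "depleted"] / m[, "total"]
    fe <- m[, "eluate"] / m[, "total"]
    fr <- friedman_dunn(m, reference = "total")
    per_feature[[f]] <- data.frame(
      feature = f,
      fold_depleted = sumfun(fd), fold_eluate = sumfun(fe),
      pct_change_depleted = sumfun((m[, "depleted"] - m[, "total"]) / m[, "total"] * 100),
      friedman_chisq = fr$chisq, friedman_p = fr$p,
      dunn_p_depleted = fr$dunn$p_adj[fr$dunn$condition == "depleted"],
      dunn_p_eluate = fr$dunn$p_adj[fr$dunn$condition == "eluate"],
      stringsAsFactors = FALSE)
    folds[[f]] <- data.frame(subject = rownames(m), feature = f,
                             fold_depleted = unname(fd), fold_eluate = unname(fe),
                             stringsAsFactors = FALSE)
  }
  list(per_feature = do.call(rbind, c(per_feature, list(make.row.names = FALSE))),
       n_subjects = length(complete),
       folds = do.call(rbind, c(folds, list(make.row.names = FALSE))))
}

#' Platelet contribution share of the total PBMC signal
#'
#' Fraction of the total PBMC measurement attributable to contaminating
#' platelets, estimated per feature from the depletion-induced drop:
#' `share = ((total - depleted) / total) / efficiency`, clipped to [0, 1].
#' With imperfect depletion (efficiency < 1) the unclipped value corrects the
#' drop upward; the default assumes perfect depletion and therefore yields a
#' lower bound.
#'
#' @param triplets Tidy triplet table (see [depletion_analysis()]).
#' @param efficiency Assumed depletion efficiency in (0, 1] (default 1).
#' @param summary `"median"` (default) or `"mean"` across subjects.
#' @return Data.frame: feature, share, share_raw (unclipped), n, efficiency.
#' @export
platelet_share_estimate <- function(triplets, efficiency = 1,
                                    summary = c("median", "mean")) {
  summary <- match.arg(summary)
  assert_that(is.numeric(efficiency) && efficiency > 0 && efficiency <= 1,
              "efficiency must be in (0, 1]")
  feats <- intersect(c(.feature_names, "MHI"), names(triplets))
  sumfun <- if (summary == "median") stats::median else mean
  rows <- lapply(feats, function(f) {
    m <- .pivot_ps(triplets, "subject", "fraction", f)
    ok <- stats::complete.cases(m[, c("total", "depleted")])
    raw <- (m[ok, "total"] - m[ok, "depleted"]) / m[ok, "total"] / efficiency
    clipped <- pmin(1, pmax(0, raw))
    if (any(raw < 0)) warning("negative raw share clipped to 0 for ", f)
    data.frame(feature = f, share = sumfun(clipped), share_raw = sumfun(raw),
               n = sum(ok), efficiency = efficiency, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
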