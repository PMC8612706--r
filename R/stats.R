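# Cross-sectional statistics: effect sizes, rank tests, correlations,
# co-regulation matrices with Fisher-z averaging.

#' Hedges' g standardized mean difference
#'
#' Bias-corrected standardized mean difference between two groups, with a 95%
#' confidence interval, the fold change of group means, and a Mann-Whitney
#' p-value. The sign convention is `g > 0` when `x` has the larger mean.
#'
#' The small-sample correction is `J = 1 - 3 / (4 df - 1)` with
#' `df = n1 + n2 - 2`; the pooled standard deviation is df-weighted. The
#' standard error of g is `sqrt((n1 + n2) / (n1 n2) + g^2 / (2 df))`.
#'
#' @param x,y Numeric vectors for the two groups (e.g. women, men).
#' @param conf Confidence level for the interval (default 0.95).
#' @return An object of class `"hedges_g"`: a list with elements `g`, `ci95`
#'   (length-2), `fold_change` (`mean(x)/mean(y)`), `p` (Mann-Whitney,
#'   two-sided), `n1`, `n2`, and `degenerate` (TRUE when the pooled sd is 0).
#' @examples
#' hedges_g(c(1, 2, 3), c(4, 5, 6))
#' @export
hedges_g <- function(x, y, conf = 0.95) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  n1 <- length(x); n2 <- length(y)
  assert_that(n1 >= 2 && n2 >= 2, "hedges_g needs at least 2 finite values per group")
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df)
  J <- 1 - 3 / (4 * df - 1)
  diff <- mean(x) - mean(y)
  degenerate <- FALSE
  if (sp == 0) {
    degenerate <- diff != 0
    g <- if (diff == 0) 0 else sign(diff) * Inf
    if (degenerate) warning("zero pooled sd with unequal means: g is infinite")
  } else {
    g <- J * diff / sp
  }
  se <- if (is.finite(g)) sqrt((n1 + n2) / (n1 * n2) + g^2 / (2 * df)) else NA_real_
  zq <- stats::qnorm(1 - (1 - conf) / 2)
  ci <- if (is.finite(g)) c(g - zq * se, g + zq * se) else c(-Inf, Inf)
  out <- list(g = g, ci95 = ci, se = se,
              fold_change = mean(x) / mean(y),
              p = mann_whitney_p(x, y),
              n1 = n1, n2 = n2, degenerate = degenerate)
  class(out) <- "hedges_g"
  out
}

#' @export
print.hedges_g <- function(x, ...) {
  cat(sprintf("Hedges' g = %.3f [%.3f, %.3f], fold change = %.3f, p = %.4g (n1=%d, n2=%d)\n",
              x$g, x$ci95[1], x$ci95[2], x$fold_change, x$p, x$n1, x$n2))
  invisible(x)
}

#' Two-sided Mann-Whitney p-value
#'
#' Exact (via the null distribution of the U statistic) when `n1 + n2 <= 20`
#' and there are no ties; otherwise a normal approximation with tie and
#' continuity correction.
#'
#' @param x,y Numeric vectors.
#' @return Two-sided p-value.
#' @export
mann_whitney_p <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  has_ties <- any(ties > 1)
  if (!has_ties && n1 + n2 <= 20) {
    p <- 2 * min(stats::pwilcox(U, n1, n2),
                 stats::pwilcox(U - 1, n1, n2, lower.tail = FALSE))
    return(min(1, p))
  }
  mu <- n1 * n2 / 2
  N <- n1 + n2
  sig2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (sig2 <= 0) return(1)
  z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Spearman rank correlation
#'
#' Rho on mid-ranks (average ranks for ties) with a two-sided p-value from the
#' t approximation `t = r sqrt((n - 2) / (1 - r^2))`.
#'
#' @param x,y Paired numeric vectors (pairs with missing values dropped).
#' @return An object of class `"correlation_result"`: list with `r`, `p`, `n`,
#'   `covariates` (empty character vector here).
#' @examples
#' spearman_cor(1:5, c(1, 3, 2, 5, 4))  # r = 0.8
#' @export
spearman_cor <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  assert_that(n >= 3, "spearman_cor needs at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman correlation undefined")
    out <- list(r = NA_real_, p = NA_real_, n = n, covariates = character(0))
    class(out) <- "correlation_result"
    return(out)
  }
  r <- stats::cor(rank(x), rank(y))
  p <- .cor_t_p(r, df = n - 2)
  out <- list(r = r, p = p, n = n, covariates = character(0))
  class(out) <- "correlation_result"
  out
}

.cor_t_p <- function(r, df) {
  if (!is.finite(r) || df < 1) return(NA_real_)
  if (abs(r) >= 1) return(0)
  tt <- r * sqrt(df / (1 - r^2))
  2 * stats::pt(-abs(tt), df)
}

#' @export
print.correlation_result <- function(x, ...) {
  adj <- if (length(x$covariates)) paste0(" | ", paste(x$covariates, collapse = ", ")) else ""
  cat(sprintf("Spearman r%s = %.3f, p = %.4g, n = %d\n", adj, x$r, x$p, x$n))
  invisible(x)
}

#' Partial Spearman correlation
#'
#' Rank-transforms `x` and `y`, residualizes both on the covariates by least
#' squares, and correlates the residuals (Pearson on rank residuals). Used for
#' sex- and age-adjusted biomarker associations.
#'
#' @param x,y Paired numeric vectors.
#' @param covariates A data.frame or matrix of covariates (e.g. sex, age).
#'   Collinear columns are dropped with a warning.
#' @return A `"correlation_result"` with the adjusted correlation, a p-value on
#'   `n - 2 - q` degrees of freedom (q = covariates used), and the covariate
#'   names recorded.
#' @export
partial_spearman <- function(x, y, covariates) {
  covariates <- as.data.frame(covariates)
  ok <- is.finite(x) & is.finite(y) & stats::complete.cases(covariates)
  x <- x[ok]; y <- y[ok]
  covariates <- covariates[ok, , drop = FALSE]
  n <- length(x)
  assert_that(n >= ncol(covariates) + 4,
              "partial_spearman needs n >= number of covariates + 4")
  mm <- stats::model.matrix(~ ., data = covariates)
  q <- qr(mm)
  if (q$rank < ncol(mm)) {
    dropped <- colnames(mm)[q$pivot[(q$rank + 1):ncol(mm)]]
    warning("collinear covariates dropped: ", paste(dropped, collapse = ", "))
    mm <- mm[, q$pivot[seq_len(q$rank)], drop = FALSE]
  }
  rx <- stats::lm.fit(mm, rank(x))$residuals
  ry <- stats::lm.fit(mm, rank(y))$residuals
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    warning("degenerate residuals: partial correlation undefined")
    r <- NA_real_; p <- NA_real_
  } else {
    r <- stats::cor(rx, ry)
    p <- .cor_t_p(r, df = n - 2 - (ncol(mm) - 1))
  }
  out <- list(r = r, p = p, n = n, covariates = colnames(covariates))
  class(out) <- "correlation_result"
  out
}

#' Fisher-z average of correlations
#'
#' Transforms each correlation to Fisher's z', averages, and back-transforms:
#' `tanh(mean(atanh(r)))`. Correlations at +-1 are clipped to +-0.999999 with
#' a warning.
#'
#' @param rs Numeric vector of correlations, all in (-1, 1).
#' @param na.rm Drop missing entries (default TRUE).
#' @return The averaged correlation (r_z').
#' @examples
#' fisher_average(c(0.3, 0.7))  # 0.529
#' @export
fisher_average <- function(rs, na.rm = TRUE) {
  if (na.rm) rs <- rs[is.finite(rs)]
  assert_that(length(rs) >= 1, "fisher_average needs at least one correlation")
  rs <- .clip_r(rs)
  tanh(mean(atanh(rs)))
}

#' Average absolute correlation strength and group comparison
#'
#' `abs_correlation_strength()` Fisher-averages absolute correlation values —
#' the summary used to compare overall biomarker-mitochondria coupling between
#' designs. `compare_correlation_strength()` additionally reports the percent
#' difference between two sets and a Mann-Whitney p-value on the absolute
#' values.
#'
#' @param rs Numeric vector of correlations (or `correlation_result` list).
#' @return For `abs_correlation_strength`, the Fisher-averaged mean of `|r|`.
#' @export
abs_correlation_strength <- function(rs) {
  if (is.list(rs)) rs <- vapply(rs, function(z) z$r, numeric(1))
  fisher_average(abs(rs))
}

#' @rdname abs_correlation_strength
#' @param rs_ref,rs_cmp Correlation vectors for the reference (e.g. cohort) and
#'   comparison (e.g. repeat participant) sets.
#' @return For `compare_correlation_strength`, a list with the two averages,
#'   `percent_difference` (of `rs_cmp` relative to `rs_ref`), and `p`.
#' @export
compare_correlation_strength <- function(rs_ref, rs_cmp) {
  a <- abs_correlation_strength(rs_ref)
  b <- abs_correlation_strength(rs_cmp)
  if (is.list(rs_ref)) rs_ref <- vapply(rs_ref, function(z) z$r, numeric(1))
  if (is.list(rs_cmp)) rs_cmp <- vapply(rs_cmp, function(z) z$r, numeric(1))
  list(avg_ref = a, avg_cmp = b,
       percent_difference = (b - a) / a * 100,
       p = mann_whitney_p(abs(rs_cmp[is.finite(rs_cmp)]), abs(rs_ref[is.finite(rs_ref)])))
}

#' Kruskal-Wallis test with Dunn's comparisons against a reference group
#'
#' Tie-corrected Kruskal-Wallis H across k groups, then Dunn's pairwise z
#' statistics of every group against the reference group (the design used to
#' compare purified subtypes against PBMCs), Bonferroni-adjusted over those
#' reference comparisons only.
#'
#' @param values Numeric vector of observations.
#' @param groups Grouping vector (coerced to factor).
#' @param reference Group label used as the comparison anchor.
#' @return List with `H`, `df`, `p`, and a data.frame `dunn` (group, z,
#'   p_unadj, p_adj).
#' @export
kruskal_dunn <- function(values, groups, reference) {
  groups <- factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  k <- nlevels(groups)
  assert_that(k >= 3, "kruskal_dunn needs at least 3 groups")
  assert_that(reference %in% levels(groups), "reference group not present")
  assert_that(all(table(groups) >= 2), "each group needs n >= 2")
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tiecorr <- 1 - sum(ties^3 - ties) / (N^3 - N)
  Rj <- tapply(r, groups, sum)
  nj <- tabulate(groups)
  H0 <- 12 / (N * (N + 1)) * sum(Rj^2 / nj) - 3 * (N + 1)
  if (tiecorr <= 0) {            # everything tied
    H <- 0
  } else {
    H <- H0 / tiecorr
  }
  p <- stats::pchisq(H, df = k - 1, lower.tail = FALSE)
  # Dunn z against reference; pooled-rank variance with tie correction
  meanr <- Rj / nj
  sig2 <- (N * (N + 1) / 12 - sum(ties^3 - ties) / (12 * (N - 1)))
  others <- setdiff(levels(groups), reference)
  iref <- which(levels(groups) == reference)
  z <- vapply(others, function(g) {
    i <- which(levels(groups) == g)
    (meanr[i] - meanr[iref]) / sqrt(sig2 * (1 / nj[i] + 1 / nj[iref]))
  }, numeric(1))
  p_un <- 2 * stats::pnorm(-abs(z))
  list(H = unname(H), df = k - 1, p = unname(p),
       dunn = data.frame(group = others, z = unname(z),
                         p_unadj = unname(p_un),
                         p_adj = pmin(1, unname(p_un) * length(others)),
                         row.names = NULL))
}

#' Friedman test with Dunn's comparisons against a reference condition
#'
#' Tie-corrected Friedman chi-square over matched conditions (columns) within
#' subjects (rows), with Dunn's post hoc z of each condition against the
#' reference condition, Bonferroni-adjusted.
#'
#' @param mat Numeric matrix, subjects x conditions, complete cases only.
#' @param reference Column name (or index) of the reference condition.
#' @return List with `chisq`, `df`, `p`, and data.frame `dunn`.
#' @export
friedman_dunn <- function(mat, reference = 1) {
  mat <- as.matrix(mat)
  mat <- mat[stats::complete.cases(mat), , drop = FALSE]
  n <- nrow(mat); k <- ncol(mat)
  assert_that(n >= 3 && k >= 2, "friedman_dunn needs >= 3 complete subjects and >= 2 conditions")
  if (is.character(reference)) reference <- match(reference, colnames(mat))
  assert_that(is.finite(reference) && reference >= 1 && reference <= k,
              "reference condition not found")
  r <- t(apply(mat, 1, rank))
  Sj <- colSums(r)
  num <- (k - 1) * sum((Sj - n * (k + 1) / 2)^2)
  den <- sum(r^2) - n * k * (k + 1)^2 / 4
  chisq <- if (den <= 0) 0 else num / den
  p <- stats::pchisq(chisq, df = k - 1, lower.tail = FALSE)
  meanr <- Sj / n
  se <- sqrt(k * (k + 1) / (6 * n))
  others <- setdiff(seq_len(k), reference)
  z <- (meanr[others] - meanr[reference]) / se
  p_un <- 2 * stats::pnorm(-abs(z))
  nm <- colnames(mat) %||% as.character(seq_len(k))
  list(chisq = chisq, df = k - 1, p = p,
       dunn = data.frame(condition = nm[others], z = unname(z),
                         p_unadj = unname(p_un),
                         p_adj = pmin(1, unname(p_un) * length(others)),
                         row.names = NULL))
}

#' Cross-cell-type co-regulation of one mitochondrial feature
#'
#' Pivots a tidy feature table to participant x subtype, computes all pairwise
#' Spearman correlations over participants present in both subtypes
#' (pairwise-complete), and Fisher-averages the off-diagonal entries. Answers
#' whether e.g. a person with high mtDNAcn in B cells also has high mtDNAcn in
#' their other cell types.
#'
#' @param features Tidy data.frame with columns `participant`, `subtype`, and
#'   the feature column named by `feature`.
#' @param feature Name of the feature column (e.g. `"CS"`).
#' @param min_n Minimum shared participants per subtype pair (default 4);
#'   pairs below this are missing and excluded from the average.
#' @param absolute Average absolute correlations instead of signed (default
#'   FALSE).
#' @return Object of class `"coregulation_summary"`: list with `matrix`
#'   (subtype x subtype Spearman), `average_rz`, `feature`, `n_pairs`.
#' @export
coregulation <- function(features, feature, min_n = 4, absolute = FALSE) {
  assert_that(all(c("participant", "subtype", feature) %in% names(features)),
              "features must have participant, subtype and the feature column")
  wide <- .pivot_ps(features, "participant", "subtype", feature)
  .coregulation_core(wide, feature, min_n = min_n, absolute = absolute)
}

.coregulation_core <- function(wide, feature, min_n = 4, absolute = FALSE) {
  subs <- colnames(wide)
  k <- length(subs)
  assert_that(k >= 2, "need at least 2 subtypes")
  m <- matrix(NA_real_, k, k, dimnames = list(subs, subs))
  diag(m) <- 1
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    ok <- is.finite(wide[, i]) & is.finite(wide[, j])
    if (sum(ok) >= min_n) {
      r <- suppressWarnings(stats::cor(rank(wide[ok, i]), rank(wide[ok, j])))
      m[i, j] <- m[j, i] <- r
    }
  }
  off <- m[upper.tri(m)]
  off <- off[is.finite(off)]
  avg <- if (length(off)) fisher_average(if (absolute) abs(off) else off) else NA_real_
  out <- list(matrix = m, average_rz = avg, feature = feature,
              n_pairs = length(off), absolute = absolute)
  class(out) <- "coregulation_summary"
  out
}

#' @export
print.coregulation_summary <- function(x, ...) {
  cat(sprintf("Co-regulation of %s across %d subtype pairs: average r_z' = %.3f\n",
              x$feature, x$n_pairs, x$average_rz))
  invisible(x)
}

# participant x subtype wide matrix of one value column (mean if duplicated)
.pivot_ps <- function(df, row, col, value) {
  rows <- sort(unique(df[[row]]))
  cols <- sort(unique(df[[col]]))
  m <- matrix(NA_real_, length(rows), length(cols), dimnames = list(rows, cols))
  agg <- stats::aggregate(df[[value]], by = list(r = df[[row]], c = df[[col]]),
                          FUN = mean)
  m[cbind(match(agg$r, rows), match(agg$c, cols))] <- agg$x
  m
}
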