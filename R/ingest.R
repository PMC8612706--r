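# Ingestion of raw measurement tables: triplicate-well aggregation, run-order
# drift correction anchored on reference replicates, and mtDNAcn from duplex
# qPCR Ct values.

#' Aggregate technical replicate wells
#'
#' Mean and coefficient of variation across replicate wells of one sample x
#' enzyme. Samples are expected in triplicate; the CV (sd/mean, sample sd by
#' default) is flagged when it exceeds the QC threshold.
#'
#' @param wells Numeric vector of well activities for one sample x enzyme.
#' @param cv_threshold QC flag threshold on the CV (default 0.15).
#' @param sd_type `"sample"` (n-1, default) or `"population"`.
#' @return List with `activity` (mean), `cv` (NA with a warning for a single
#'   well), and `qc_flag`.
#' @examples
#' aggregate_replicates(c(8, 10, 12))  # mean 10, cv 0.2
#' @export
aggregate_replicates <- function(wells, cv_threshold = 0.15, sd_type = "sample") {
  wells <- wells[is.finite(wells)]
  assert_that(length(wells) >= 1, "no finite wells")
  m <- mean(wells)
  assert_that(m != 0, "zero mean across wells")
  if (length(wells) == 1) {
    warning("single well: CV undefined")
    return(list(activity = m, cv = NA_real_, qc_flag = FALSE))
  }
  cv <- .sd_conv(wells, sd_type) / m
  list(activity = m, cv = cv, qc_flag = is.finite(cv) && cv > cv_threshold)
}

#' Aggregate a plate table to per-sample activities
#'
#' Collapses replicate wells of a plate-level activity table (columns
#' `sample_id`, `subtype`, `enzyme`, `well`, `activity`, `plate`, `run_order`,
#' `is_reference`) to one row per sample x enzyme, carrying run order and
#' reference status through for drift correction.
#'
#' @param plate Data.frame in the plate schema.
#' @inheritParams aggregate_replicates
#' @return Data.frame: sample_id, subtype, enzyme, activity, cv, qc_flag,
#'   plate, run_order, is_reference (plus `participant` if present).
#' @export
aggregate_plate <- function(plate, cv_threshold = 0.15, sd_type = "sample") {
  need <- c("sample_id", "enzyme", "activity", "run_order")
  assert_that(all(need %in% names(plate)),
              paste("plate table must have columns:", paste(need, collapse = ", ")))
  key <- interaction(plate$sample_id, plate$enzyme, drop = TRUE)
  rows <- lapply(split(seq_len(nrow(plate)), key), function(idx) {
    d <- plate[idx, , drop = FALSE]
    agg <- suppressWarnings(aggregate_replicates(d$activity, cv_threshold, sd_type))
    out <- d[1, setdiff(names(d), c("well", "activity")), drop = FALSE]
    out$activity <- agg$activity
    out$cv <- agg$cv
    out$qc_flag <- agg$qc_flag
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Linear run-order drift correction
#'
#' Fits a linear drift of activity against run order on the reference
#' replicates (per enzyme, across the whole run by default or per plate) and
#' subtracts it, anchored at the first reference position, so that the first
#' and last reference replicates agree. Non-reference samples are corrected by
#' interpolation of the fitted drift. Negative adjusted values are clipped to
#' zero and flagged.
#'
#' @param samples Per-sample activity table (e.g. from [aggregate_plate()])
#'   with columns `enzyme`, `activity`, `run_order`, `is_reference`.
#' @param per_plate Fit the drift per plate instead of across the whole run
#'   (default FALSE).
#' @param method `"additive"` (default): subtract the fitted linear drift;
#'   `"multiplicative"`: divide by the fitted relative drift.
#' @return The table with `activity` replaced by adjusted values and a
#'   `clipped` logical column.
#' @export
batch_order_adjust <- function(samples, per_plate = FALSE,
                               method = c("additive", "multiplicative")) {
  method <- match.arg(method)
  need <- c("enzyme", "activity", "run_order", "is_reference")
  assert_that(all(need %in% names(samples)),
              paste("samples must have columns:", paste(need, collapse = ", ")))
  grp <- if (per_plate && "plate" %in% names(samples))
    interaction(samples$enzyme, samples$plate, drop = TRUE)
  else factor(samples$enzyme)
  samples$clipped <- FALSE
  for (g in levels(grp)) {
    idx <- which(grp == g)
    d <- samples[idx, ]
    ref <- d[d$is_reference & is.finite(d$activity), ]
    if (nrow(ref) < 2 || length(unique(ref$run_order)) < 2) {
      warning("no usable reference replicates for ", g, ": identity transform")
      next
    }
    fit <- stats::lm(activity ~ run_order, data = ref)
    b <- stats::coef(fit)[["run_order"]]
    anchor <- min(ref$run_order)
    if (method == "additive") {
      adj <- d$activity - b * (d$run_order - anchor)
    } else {
      a0 <- stats::coef(fit)[["(Intercept)"]] + b * anchor
      rel <- (stats::coef(fit)[["(Intercept)"]] + b * d$run_order) / a0
      adj <- d$activity / rel
    }
    clip <- is.finite(adj) & adj < 0
    if (any(clip)) {
      warning(sum(clip), " adjusted values clipped at 0 for ", g)
      adj[clip] <- 0
    }
    samples$activity[idx] <- adj
    samples$clipped[idx] <- clip
  }
  samples
}

#' Mitochondrial DNA copy number from duplex qPCR Ct values
#'
#' Per duplex assay, replicate Cts are averaged, `dCt = Ct_nuc - Ct_mt`, and
#' copies per cell are `2 * 2^dCt` (the factor 2 reflects the diploid nuclear
#' reference locus). The final value is the arithmetic mean across the two
#' assays (ND1/B2M 'and COX1/RNaseP'); if only one assay is available it is
#' used alone with a warning.
#'
#' @param ct Data.frame with columns `assay`, `ct_mt`, `ct_nuc` (and
#'   optionally `replicate`) for one sample.
#' @param contamination_threshold Copies-per-cell value above which the result
#'   is flagged as probable platelet/plasma contamination (default 1e5).
#' @return List with `mtDNAcn`, per-assay values `by_assay`, and `flag`.
#' @examples
#' compute_mtdnacn(data.frame(assay = c("ND1/B2M", "COX1/RNaseP"),
#'                            ct_mt = c(18, 18), ct_nuc = c(25, 25)))
#' @export
compute_mtdnacn <- function(ct, contamination_threshold = 1e5) {
  need <- c("assay", "ct_mt", "ct_nuc")
  assert_that(all(need %in% names(ct)), "ct table needs assay, ct_mt, ct_nuc")
  ct <- ct[is.finite(ct$ct_mt) & is.finite(ct$ct_nuc), ]
  assert_that(nrow(ct) >= 1, "no complete Ct pairs")
  assert_that(all(ct$ct_mt > 0 & ct$ct_mt < 45 & ct$ct_nuc > 0 & ct$ct_nuc < 45),
              "Ct values must lie in (0, 45) cycles")
  by_assay <- vapply(split(ct, ct$assay, drop = TRUE), function(d) {
    dct <- mean(d$ct_nuc) - mean(d$ct_mt)
    2 * 2^dct
  }, numeric(1))
  if (length(by_assay) == 1)
    warning("only one duplex assay available: no cross-assay averaging")
  value <- mean(by_assay)
  flag <- value > contamination_threshold
  if (flag) warning("mtDNAcn > ", contamination_threshold,
                    ": probable platelet/plasma contamination")
  list(mtDNAcn = value, by_assay = by_assay, flag = flag)
}

#' Ingest raw tables into a tidy per-sample feature table
#'
#' Full ingestion path: aggregate replicate wells, correct run-order drift,
#' pivot enzymes wide, and merge mtDNAcn computed per sample from the Ct
#' table.
#'
#' @param plate Plate activity table (schema of [aggregate_plate()]); may be a
#'   path to a CSV file.
#' @param ct Ct table with columns `sample_id`, `assay`, `ct_mt`, `ct_nuc`,
#'   `replicate`; may be a CSV path.
#' @param adjust Apply [batch_order_adjust()] (default TRUE).
#' @param ... Passed to [batch_order_adjust()].
#' @return Tidy data.frame: sample_id, participant (if present), subtype, CS,
#'   CI, CII, CIV, mtDNAcn, plus per-enzyme technical CV columns `cv_*`.
#' @export
ingest_features <- function(plate, ct, adjust = TRUE, ...) {
  if (is.character(plate)) plate <- utils::read.csv(plate)
  if (is.character(ct)) ct <- utils::read.csv(ct)
  agg <- aggregate_plate(plate)
  if (adjust) agg <- batch_order_adjust(agg, ...)
  agg <- agg[!agg$is_reference, , drop = FALSE]
  ids <- unique(agg$sample_id)
  meta_cols <- intersect(c("participant", "subtype"), names(agg))
  rows <- lapply(ids, function(id) {
    d <- agg[agg$sample_id == id, ]
    out <- data.frame(sample_id = id, stringsAsFactors = FALSE)
    for (mc in meta_cols) out[[mc]] <- d[[mc]][1]
    for (enz in c("CS", "CI", "CII", "CIV")) {
      i <- which(d$enzyme == enz)
      out[[enz]] <- if (length(i)) d$activity[i[1]] else NA_real_
      out[[paste0("cv_", enz)]] <- if (length(i)) d$cv[i[1]] else NA_real_
    }
    cti <- ct[ct$sample_id == id, , drop = FALSE]
    out$mtDNAcn <- if (nrow(cti)) suppressWarnings(compute_mtdnacn(cti)$mtDNAcn) else NA_real_
    out
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
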