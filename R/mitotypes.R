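# Mitotype engine: the registry of ratio indices over the five mitochondrial
# features, per-cell-type summaries, sex/age effect-size ranking across the
# mitotype x subtype grid, and category enrichment tests.

.mitotype_categories <- c(
  "enzyme activity per CS",
  "enzyme ratios",
  "enzyme per mtDNA",
  "enzyme per mtDNA density",
  "enzyme per mtDNA relative to mtDNA density")

#' Default mitotype registry
#'
#' The 16 mathematically distinct mitotype ratio indices over
#' \{CS, CI, CII, CIV, mtDNAcn\}, organized in five categories:
#' enzyme activity per CS (4), enzyme ratios (3), enzyme per mtDNA (4),
#' enzyme per mtDNA density (3), and enzyme per mtDNA relative to mtDNA
#' density (2). `mtDNAcn/CS` is the mtDNA-density axis quantity used inside
#' the last two categories. The registry can be extended or replaced via
#' [read_registry()].
#'
#' @return Object of class `"mitotype_registry"`: data.frame with columns
#'   `name`, `numerator`, `denominator`, `category`.
#' @examples
#' nrow(default_registry())  # 16
#' @export
default_registry <- function() {
  def <- function(name, num, den, cat) data.frame(
    name = name, numerator = num, denominator = den, category = cat,
    stringsAsFactors = FALSE)
  reg <- rbind(
    def("CI/CS",               "CI",             "CS",                 .mitotype_categories[1]),
    def("CII/CS",              "CII",            "CS",                 .mitotype_categories[1]),
    def("CIV/CS",              "CIV",            "CS",                 .mitotype_categories[1]),
    def("(CI+CII+CIV)/CS",     "CI + CII + CIV", "CS",                 .mitotype_categories[1]),
    def("CI/CII",              "CI",             "CII",                .mitotype_categories[2]),
    def("CI/CIV",              "CI",             "CIV",                .mitotype_categories[2]),
    def("CII/CIV",             "CII",            "CIV",                .mitotype_categories[2]),
    def("CI/mtDNAcn",          "CI",             "mtDNAcn",            .mitotype_categories[3]),
    def("CII/mtDNAcn",         "CII",            "mtDNAcn",            .mitotype_categories[3]),
    def("CIV/mtDNAcn",         "CIV",            "mtDNAcn",            .mitotype_categories[3]),
    def("(CI+CII+CIV)/mtDNAcn","CI + CII + CIV", "mtDNAcn",            .mitotype_categories[3]),
    def("CI/(mtDNAcn/CS)",     "CI",             "mtDNAcn / CS",       .mitotype_categories[4]),
    def("CII/(mtDNAcn/CS)",    "CII",            "mtDNAcn / CS",       .mitotype_categories[4]),
    def("CIV/(mtDNAcn/CS)",    "CIV",            "mtDNAcn / CS",       .mitotype_categories[4]),
    def("(CI/mtDNAcn)/(mtDNAcn/CS)", "CI / mtDNAcn",  "mtDNAcn / CS",  .mitotype_categories[5]),
    def("(CII/mtDNAcn)/(mtDNAcn/CS)","CII / mtDNAcn", "mtDNAcn / CS",  .mitotype_categories[5]))
  class(reg) <- c("mitotype_registry", class(reg))
  validate_registry(reg)
  reg
}

#' Validate a mitotype registry
#'
#' Checks schema, category labels, expression symbols, and positivity of each
#' denominator on positive features.
#'
#' @param registry A registry data.frame.
#' @return The registry, invisibly, or an error.
#' @export
validate_registry <- function(registry) {
  need <- c("name", "numerator", "denominator", "category")
  assert_that(all(need %in% names(registry)), "registry needs name/numerator/denominator/category")
  assert_that(!anyDuplicated(registry$name), "duplicate mitotype names")
  assert_that(all(registry$category %in% .mitotype_categories),
              paste("categories must be among:", paste(.mitotype_categories, collapse = "; ")))
  probe <- data.frame(CS = 1.3, CI = 0.7, CII = 2.1, CIV = 0.9, mtDNAcn = 311)
  for (i in seq_len(nrow(registry))) {
    num <- .eval_feature_expr(registry$numerator[i], probe)
    den <- .eval_feature_expr(registry$denominator[i], probe)
    assert_that(is.finite(num) && is.finite(den) && den > 0,
                paste0("definition '", registry$name[i], "' invalid on positive features"))
  }
  invisible(registry)
}

#' Read a mitotype registry from JSON
#'
#' JSON array of objects with fields `name`, `numerator`, `denominator`,
#' `category`; `"default"` returns [default_registry()].
#'
#' @param path File path or `"default"`.
#' @return A validated `mitotype_registry`.
#' @export
read_registry <- function(path = "default") {
  if (identical(path, "default")) return(default_registry())
  reg <- as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  class(reg) <- c("mitotype_registry", class(reg))
  validate_registry(reg)
  reg
}

#' Homogeneity degree of a mitotype definition
#'
#' Numeric degree d such that scaling all five features by k scales the
#' mitotype by k^d. Pure ratios are degree 0; the 'enzyme per mtDNA density'
#' entries are degree 1 (the density denominator is itself scale-free).
#'
#' @param registry A mitotype registry.
#' @return Named numeric vector of degrees.
#' @export
scale_degree <- function(registry) {
  base <- data.frame(CS = 1.7, CI = 0.9, CII = 1.1, CIV = 2.3, mtDNAcn = 57)
  k <- 2
  vapply(seq_len(nrow(registry)), function(i) {
    v1 <- .eval_feature_expr(registry$numerator[i], base) /
      .eval_feature_expr(registry$denominator[i], base)
    v2 <- .eval_feature_expr(registry$numerator[i], base * k) /
      .eval_feature_expr(registry$denominator[i], base * k)
    log(v2 / v1, base = k)
  }, numeric(1), USE.NAMES = FALSE) |> stats::setNames(registry$name)
}

#' Evaluate mitotypes for every sample
#'
#' Evaluates each registry definition on a tidy feature table and appends the
#' standalone mtDNA-density axis `mtDNAcn/CS`.
#'
#' @param features Tidy feature table with positive CS, CI, CII, CIV, mtDNAcn.
#' @param registry Registry (default [default_registry()]).
#' @return Data.frame with the id columns of `features` (sample_id,
#'   participant, subtype where present), one column per mitotype (backtick
#'   names as in the registry), and `mtDNA_density`. The registry travels in
#'   attribute `"registry"`.
#' @export
compute_mitotypes <- function(features, registry = default_registry()) {
  validate_registry(registry)
  id_cols <- intersect(c("sample_id", "participant", "subtype", "sex", "age", "week"),
                       names(features))
  out <- features[, id_cols, drop = FALSE]
  for (i in seq_len(nrow(registry))) {
    num <- .eval_feature_expr(registry$numerator[i], features)
    den <- .eval_feature_expr(registry$denominator[i], features)
    v <- num / den
    v[!is.finite(v)] <- NA_real_
    out[[registry$name[i]]] <- v
  }
  out$mtDNA_density <- features$mtDNAcn / features$CS
  attr(out, "registry") <- registry
  out
}

#' Group means and SEM per (subtype, mitotype)
#'
#' @param mitotypes Output of [compute_mitotypes()].
#' @param grouping Grouping column (default `"subtype"`).
#' @return Tidy data.frame: group, mitotype, mean, sem, n. SEM = sd/sqrt(n);
#'   groups of n = 1 report the mean with a warning and missing SEM.
#' @export
celltype_summary <- function(mitotypes, grouping = "subtype") {
  registry <- attr(mitotypes, "registry")
  vars <- if (!is.null(registry)) registry$name else
    setdiff(names(mitotypes), c("sample_id", "participant", "subtype", "sex", "age", "week"))
  rows <- list()
  for (g in sort(unique(as.character(mitotypes[[grouping]])))) {
    d <- mitotypes[mitotypes[[grouping]] == g, , drop = FALSE]
    for (v in vars) {
      x <- d[[v]][is.finite(d[[v]])]
      n <- length(x)
      if (n == 0) next
      if (n == 1) warning("group '", g, "' has a single sample for ", v, ": SEM undefined")
      rows[[length(rows) + 1]] <- data.frame(
        group = g, mitotype = v, mean = mean(x),
        sem = if (n > 1) .sd_conv(x) / sqrt(n) else NA_real_, n = n,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Rank mitotype x cell-subtype combinations by sex or age effect
#'
#' For sex: Hedges' g of women vs men per (mitotype, subtype), positive g
#' meaning higher in women. For age: Spearman r of mitotype vs age. Rows are
#' sorted by effect (descending), ties broken by (category, name). With 9
#' subtypes and the 16-index registry the grid has 144 combinations.
#'
#' @param mitotypes Output of [compute_mitotypes()]; must carry `subtype` plus
#'   `sex` (levels containing "F"/"M" or "female"/"male") or `age`.
#' @param grouping `"sex"` or `"age"`.
#' @param min_age_n Minimum distinct ages per subtype for the age ranking
#'   (default 5).
#' @return Data.frame: mitotype, category, subtype, effect (g or r), p, n (or
#'   n1/n2), sorted by effect descending.
#' @export
effect_ranking <- function(mitotypes, grouping = c("sex", "age"), min_age_n = 5) {
  grouping <- match.arg(grouping)
  registry <- attr(mitotypes, "registry")
  assert_that(!is.null(registry), "mitotypes must come from compute_mitotypes()")
  assert_that("subtype" %in% names(mitotypes), "mitotypes must carry a subtype column")
  assert_that(grouping %in% names(mitotypes),
              paste0("mitotypes must carry a '", grouping, "' column"))
  rows <- list()
  for (st in sort(unique(as.character(mitotypes$subtype)))) {
    d <- mitotypes[mitotypes$subtype == st, , drop = FALSE]
    if (grouping == "sex") {
      sx <- .norm_sex(d$sex)
      if (length(unique(stats::na.omit(sx))) < 2) {
        warning("subtype '", st, "' has one sex only: excluded from ranking")
        next
      }
      for (i in seq_len(nrow(registry))) {
        v <- d[[registry$name[i]]]
        f <- v[sx == "F" & is.finite(v)]; m <- v[sx == "M" & is.finite(v)]
        if (length(f) < 2 || length(m) < 2) next
        hg <- suppressWarnings(hedges_g(f, m))
        rows[[length(rows) + 1]] <- data.frame(
          mitotype = registry$name[i], category = registry$category[i],
          subtype = st, effect = hg$g, p = hg$p, n1 = hg$n1, n2 = hg$n2,
          stringsAsFactors = FALSE)
      }
    } else {
      if (length(unique(stats::na.omit(d$age))) < min_age_n) {
        warning("subtype '", st, "' has < ", min_age_n, " distinct ages: excluded")
        next
      }
      for (i in seq_len(nrow(registry))) {
        v <- d[[registry$name[i]]]
        ok <- is.finite(v) & is.finite(d$age)
        if (sum(ok) < 4) next
        sc <- suppressWarnings(spearman_cor(d$age[ok], v[ok]))
        rows[[length(rows) + 1]] <- data.frame(
          mitotype = registry$name[i], category = registry$category[i],
          subtype = st, effect = sc$r, p = sc$p, n = sc$n,
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  assert_that(!is.null(out) && nrow(out) > 0, "no rankable combinations")
  ord <- order(-out$effect, out$category, out$mitotype, out$subtype)
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "grouping") <- grouping
  attr(out, "registry") <- registry
  out
}

.norm_sex <- function(x) {
  x <- toupper(substr(as.character(x), 1, 1))
  out <- rep(NA_character_, length(x))
  out[x %in% c("F", "W")] <- "F"
  out[x == "M"] <- "M"
  out
}

#' Category enrichment of effect directions
#'
#' Per mitotype category, counts combinations with positive vs negative effect
#' (higher in women vs men for sex; positive vs negative with age) and tests
#' the split against 50:50 with a chi-square goodness-of-fit test (df = 1).
#' Zero-effect combinations are excluded from the counts.
#'
#' @param ranking Output of [effect_ranking()].
#' @return Data.frame: category, n_pos, n_neg, chisq, df, p, flagged (TRUE
#'   when a category had no nonzero effects, reported with p = 1).
#' @export
category_enrichment <- function(ranking) {
  registry <- attr(ranking, "registry")
  cats <- if (!is.null(registry)) unique(registry$category) else unique(ranking$category)
  rows <- lapply(cats, function(cat) {
    e <- ranking$effect[ranking$category == cat]
    e <- e[is.finite(e) & e != 0]
    a <- sum(e > 0); b <- sum(e < 0)
    if (a + b == 0) {
      return(data.frame(category = cat, n_pos = 0L, n_neg = 0L,
                        chisq = 0, df = 1L, p = 1, flagged = TRUE,
                        stringsAsFactors = FALSE))
    }
    chisq <- (a - b)^2 / (a + b)
    data.frame(category = cat, n_pos = a, n_neg = b, chisq = chisq, df = 1L,
               p = stats::pchisq(chisq, 1, lower.tail = FALSE), flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
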