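# Mitotype registry, evaluation, effect ranking and category enrichment.

test_that("default registry: 16 definitions, 5 categories, valid expressions", {
  reg <- default_registry()
  expect_equal(nrow(reg), 16)
  expect_equal(length(unique(reg$category)), 5)
  expect_equal(as.integer(table(reg$category)[unique(reg$category)]),
               c(4L, 3L, 4L, 3L, 2L))
  # pure ratio definitions evaluate to 1 at an all-ones feature vector
  ones <- data.frame(CS = 1, CI = 1, CII = 1, CIV = 1, mtDNAcn = 1)
  vals <- compute_mitotypes(cbind(data.frame(sample_id = "s"), ones), reg)
  pure <- c("CI/CS", "CI/CII", "CI/mtDNAcn", "CII/CIV")
  for (p in pure) expect_equal(vals[[p]], 1)
  expect_equal(vals[["(CI+CII+CIV)/CS"]], 3)
})

test_that("registry homogeneity degrees are 0 except per-mtDNA-density (1)", {
  reg <- default_registry()
  deg <- scale_degree(reg)
  dens <- reg$name[reg$category == "enzyme per mtDNA density"]
  expect_equal(unname(deg[dens]), rep(1, 3), tolerance = 1e-10)
  expect_equal(unname(deg[setdiff(reg$name, dens)]), rep(0, 13), tolerance = 1e-10)
  # property: each mitotype scales as k^degree over random positive vectors
  set.seed(8)
  for (i in 1:20) {
    fv <- as.data.frame(as.list(setNames(rlnorm(5, 1), c("CS", "CI", "CII", "CIV", "mtDNAcn"))))
    fv$sample_id <- "s"
    k <- runif(1, 0.5, 4)
    v1 <- compute_mitotypes(fv, reg)
    fv2 <- fv; fv2[c("CS", "CI", "CII", "CIV", "mtDNAcn")] <-
      fv[c("CS", "CI", "CII", "CIV", "mtDNAcn")] * k
    v2 <- compute_mitotypes(fv2, reg)
    for (nm in reg$name)
      expect_equal(v2[[nm]], v1[[nm]] * k^deg[[nm]], tolerance = 1e-10)
  }
})

test_that("compute_mitotypes arithmetic and the mtDNA-density axis", {
  f <- data.frame(sample_id = "s", CS = 4, CI = 3, CII = 3, CIV = 6, mtDNAcn = 400)
  v <- compute_mitotypes(f)
  expect_equal(v$mtDNA_density, 100)       # 400 / 4 copies per CS unit
  expect_equal(v[["CI/CII"]], 1)           # CI = CII
  expect_equal(v[["CI/(mtDNAcn/CS)"]], 3 / 100)
  expect_error(validate_registry(data.frame(name = "bad", numerator = "CI + x",
                                            denominator = "CS", category = "enzyme ratios")),
               "undefined symbols")
})

test_that("celltype_summary computes mean and SEM per group", {
  f <- data.frame(sample_id = paste0("s", 1:4),
                  subtype = c("A", "A", "B", "B"),
                  CS = c(1, 1, 2, 2), CI = c(2, 4, 3, 3),
                  CII = c(1, 1, 1, 1), CIV = c(1, 1, 1, 1),
                  mtDNAcn = c(100, 100, 100, 100))
  mt <- compute_mitotypes(f)
  s <- celltype_summary(mt)
  # CI/CS in A: values {2, 4} -> mean 3, SEM 1
  row <- s[s$group == "A" & s$mitotype == "CI/CS", ]
  expect_equal(row$mean, 3)
  expect_equal(row$sem, 1)
  # identical values -> SEM 0
  rowb <- s[s$group == "B" & s$mitotype == "CI/CS", ]
  expect_equal(rowb$sem, 0)
})

test_that("celltype_summary recovers generator mitotype means on synthetic data", {
  co <- generate_cohort(synthetic_config(n_participants = 200, celltype_cv = 0.15,
                                         sex_effects = 1, age_slopes = 0, seed = 2))
  mt <- compute_mitotypes(co$samples[co$samples$subtype != "PBMC", ])
  s <- celltype_summary(mt)
  means <- co$truth$config$celltype_means
  for (st in c("monocytes", "B")) {
    row <- s[s$group == st & s$mitotype == "CI/CS", ]
    # noise is multiplicative so the ratio mean is slightly above the ratio of
    # means; 3 SEM around the observed mean must cover the generating ratio
    truth <- means[st, "CI"] / means[st, "CS"]
    expect_lt(abs(row$mean - truth), 3 * row$sem + 0.05 * truth)
  }
})

test_that("effect_ranking covers the grid, flips under label swap, ranks injected effects", {
  sx <- .default_sex_matrix <- matrix(1, 8, 5,
                                      dimnames = list(rownames(synthetic_config()$celltype_means),
                                                      c("CS", "CI", "CII", "CIV", "mtDNAcn")))
  sx["monocytes", "CI"] <- 1.4
  co <- generate_cohort(synthetic_config(n_participants = 80, celltype_cv = 0.1,
                                         sex_effects = sx, age_slopes = 0, seed = 4))
  mt <- compute_mitotypes(co$samples)  # includes PBMC: 9 subtypes
  rk <- effect_ranking(mt, "sex")
  expect_equal(nrow(rk), 16 * 9)  # 144 combinations
  top <- rk[which.max(abs(rk$effect)), ]
  expect_equal(top$subtype, "monocytes")
  expect_match(top$mitotype, "CI")
  expect_gt(top$effect, 0)  # higher in women by sign convention

  # swapping the sex labels negates every effect
  mt2 <- mt
  mt2$sex <- ifelse(mt$sex == "F", "M", "F")
  attr(mt2, "registry") <- attr(mt, "registry")
  rk2 <- effect_ranking(mt2, "sex")
  key <- paste(rk$mitotype, rk$subtype)
  key2 <- paste(rk2$mitotype, rk2$subtype)
  expect_equal(rk2$effect[match(key, key2)], -rk$effect, tolerance = 1e-12)

  # age ranking: injected age trend on mtDNAcn surfaces in mtDNAcn mitotypes
  rka <- effect_ranking(mt, "age")
  expect_equal(nrow(rka), 144)
  expect_true(all(abs(rka$effect) <= 1))
})

test_that("category_enrichment chi-square goodness of fit against 50:50", {
  mk_ranking <- function(effects, cats) {
    r <- data.frame(mitotype = paste0("m", seq_along(effects)), category = cats,
                    subtype = "A", effect = effects)
    attr(r, "registry") <- data.frame(name = r$mitotype, numerator = "CI",
                                      denominator = "CS", category = cats)
    r
  }
  # 8 vs 8 -> chisq 0, p 1
  e <- category_enrichment(mk_ranking(rep(c(1, -1), 8), rep("enzyme ratios", 16)))
  expect_equal(e$chisq[e$category == "enzyme ratios"], 0)
  expect_equal(e$p[e$category == "enzyme ratios"], 1)
  # 16 vs 0 -> chisq 16, p ~ 6.3e-5
  e2 <- category_enrichment(mk_ranking(rep(1, 16), rep("enzyme ratios", 16)))
  expect_equal(e2$chisq[1], 16)
  expect_equal(e2$p[1], 6.3e-5, tolerance = 0.01)
  # zero effects excluded; all-zero category flagged with p = 1
  e3 <- category_enrichment(mk_ranking(rep(0, 4), rep("enzyme ratios", 4)))
  expect_true(e3$flagged[1])
  expect_equal(e3$p[1], 1)
})

test_that("uniformly male-shifted per-CS mitotypes enrich 'higher in men'", {
  sx <- matrix(1, 8, 5, dimnames = list(rownames(synthetic_config()$celltype_means),
                                        c("CS", "CI", "CII", "CIV", "mtDNAcn")))
  sx[, "CS"] <- 1.35  # women higher CS everywhere -> RC/CS lower in women
  co <- generate_cohort(synthetic_config(n_participants = 100, celltype_cv = 0.1,
                                         sex_effects = sx, age_slopes = 0, seed = 6))
  mt <- compute_mitotypes(co$samples[co$samples$subtype != "PBMC", ])
  rk <- effect_ranking(mt, "sex")
  en <- category_enrichment(rk)
  percs <- en[en$category == "enzyme activity per CS", ]
  expect_gt(percs$n_neg, percs$n_pos)  # negative g = higher in men
  expect_lt(percs$p, 0.01)
})

test_that("registry JSON round trip preserves definitions", {
  reg <- default_registry()
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(as.data.frame(reg), path)
  reg2 <- read_registry(path)
  expect_equal(reg2$name, reg$name)
  expect_equal(reg2$category, reg$category)
  expect_equal(nrow(read_registry("default")), 16)
})
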