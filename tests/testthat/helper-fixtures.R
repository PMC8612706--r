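# Shared fixtures: small deterministic worlds used across test files.

# noiseless single-subtype world: PBMC must equal the subtype exactly
noiseless_config <- function(seed = 11) {
  m <- matrix(c(6, 3, 2, 5, 300), nrow = 1,
              dimnames = list("monocytes", c("CS", "CI", "CII", "CIV", "mtDNAcn")))
  synthetic_config(
    n_participants = 6, celltype_means = m, celltype_cv = 0,
    sex_effects = 1, age_slopes = 0,
    composition_mean = c(monocytes = 1), composition_concentration = 10,
    platelet_cv = 0, platelet_share = c(CS = 0, CI = 0, CII = 0, CIV = 0, mtDNAcn = 0),
    seed = seed)
}

small_cohort <- function(seed = 3, n = 12) {
  generate_cohort(synthetic_config(n_participants = n, seed = seed))
}

# tiny tidy feature table with known structure
toy_features <- function() {
  data.frame(
    sample_id = paste0("s", 1:6),
    participant = rep(c("P1", "P2", "P3"), each = 2),
    subtype = rep(c("A", "B"), 3),
    CS = c(4, 8, 5, 10, 6, 12),
    CI = c(2, 4, 2.5, 5, 3, 6),
    CII = c(1, 2, 1.25, 2.5, 1.5, 3),
    CIV = c(3, 6, 3.75, 7.5, 4.5, 9),
    mtDNAcn = c(200, 400, 250, 500, 300, 600),
    stringsAsFactors = FALSE)
}
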