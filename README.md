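# immunomito

Mitochondrial phenotyping of purified human immune cell subtypes and mixed
PBMCs.

Blood-based assays of mitochondrial health usually profile peripheral blood
mononuclear cells (PBMCs). But PBMCs are a mixture: their apparent
mitochondrial content and respiratory-chain (RC) activity reflect (i) which
cell subtypes happen to be circulating, and (ii) contaminating platelets,
which carry mitochondria and mtDNA but no nuclear genome. `immunomito`
implements the full analysis chain for cell-subtype-resolved mitochondrial
phenotyping — from raw plate and qPCR tables to effect-size rankings — plus a
synthetic cohort generator with a known-truth channel so that every estimator
in the chain can be validated by parameter recovery.

## The quantities at its core

Five primary features per sample (cell-type aliquots of ~5×10⁶ cells):

* **CS** — citrate synthase activity, a marker of mitochondrial content;
* **CI, CII, CIV** — complex I, II, IV enzymatic activities (RC capacity);
* **mtDNAcn** — mtDNA copies per cell from two duplex qPCR assays
  (ND1/B2M and COX1/RNaseP):
  `mtDNAcn = 2 × 2^(Ct_nuc − Ct_mt)`, averaged across the two assays.

Derived quantities:

* **MHI** (mitochondrial health index), RC capacity per unit of content:
  `MHI = [(CI′+CII′+CIV′)/3] / [(CS′+mtDNAcn′)/2] × 100`,
  where primes are ratios to the reference mean (100 = reference point);
* **mitotypes** — 16 ratio indices over the five features (e.g. `CI/CS`,
  `mtDNAcn/CS` = mtDNA density per mitochondrion), in five categories,
  ranked by sex effect (Hedges' g) and age association (Spearman r) across
  the mitotype × cell-subtype grid, with chi-square category enrichment;
* co-regulation matrices (Spearman, Fisher-z-averaged to r_z′), weekly CV
  and rMSSD for repeated measures, and the platelet contribution share
  estimated from depletion experiments:
  `share = ((total − depleted)/total)/efficiency`.

## Worked example

```r
library(immunomito)

cfg    <- synthetic_config(n_participants = 21, seed = 42)
cohort <- generate_cohort(cfg)
#> Synthetic cohort: 21 participants, 189 samples (8 subtypes + PBMC)

# raw plate + Ct tables -> drift-corrected tidy features + MHI
raw      <- generate_raw_tables(cohort, well_cv = 0.03,
                                drift_per_position = 0.002, ct_sd = 0.05)
features <- ingest_features(raw$plate, raw$ct)
features <- merge(features, cohort$participants[, c("participant", "sex", "age")],
                  by = "participant")
features <- add_mhi(features)
head(features[, c("sample_id", "subtype", "CS", "CI", "mtDNAcn", "MHI")], 4)
#>        sample_id   subtype    CS    CI mtDNAcn    MHI
#> 1         P001_B         B 9.276 4.083   369.9 101.81
#> 2  P001_CD4_CMEM  CD4_CMEM 6.747 3.515   435.0  83.39
#> 3 P001_CD4_naive CD4_naive 2.523 2.757   218.4 149.07
#> 4  P001_CD8_CMEM  CD8_CMEM 7.347 3.958   343.0  83.06

# sex difference in CS activity in CD8+ CM-EM T cells (g > 0: higher in women)
hedges_g(features$CS[features$subtype == "CD8_CMEM" & features$sex == "F"],
         features$CS[features$subtype == "CD8_CMEM" & features$sex == "M"])
#> Hedges' g = 0.454 [-0.414, 1.323], fold change = 1.144, p = 0.5495 (n1=11, n2=10)

# mitotype grid and sex-effect ranking (16 indices x 8 purified subtypes)
mito <- compute_mitotypes(features)
rk   <- effect_ranking(mito[mito$subtype != "PBMC", ], "sex")
head(rk[order(-abs(rk$effect)), c("mitotype", "subtype", "effect", "p")], 3)
#>            mitotype     subtype effect      p
#> 1            CII/CS neutrophils  1.254 0.0102
#> 128          CIV/CS           B -0.948 0.0620
#> 127 CI/(mtDNAcn/CS) neutrophils -0.915 0.0528

# is CS activity a coherent person-level property across subtypes?
coregulation(features[features$subtype != "PBMC", ], "CS")
#> Co-regulation of CS across 28 subtype pairs: average r_z' = 0.107

# platelet contribution to the total PBMC signal, from depletion triplets
tr <- generate_depletion_triplets(cfg, n_subjects = 9)
platelet_share_estimate(tr)[1:3, ]
#>   feature share share_raw n efficiency
#> 1      CS  0.20      0.20 9          1
#> 2      CI  0.15      0.15 9          1
#> 3     CII  0.11      0.11 9          1
```

At n = 21 the individual sex contrast is not significant (wide CI around
g = 0.45) — the generator's configured +29% CS effect in CD8+ CM-EM cells is
recovered reliably only at larger n (see `tests/testthat/test-acceptance.R`,
which recovers it to within ±3 percentage points at n = 500). The platelet
share estimates recover the configured contamination world (20% of the CS
signal, 0 for CIV).

## Full pipeline and CLI

```r
res <- run_pipeline(pipeline_config(n_participants = 21, seed = 1,
                                    out_dir = "out"))
```

writes `features.csv`, `mitotypes.csv`, `celltype_summary.csv`,
`sex_ranking.csv` / `age_ranking.csv` + enrichment tables,
`coregulation.json`, `weekly_metrics.csv`, `depletion_analysis.csv`,
`platelet_share.csv`, and a `manifest.json` echoing the configuration and
seed (same config + seed ⇒ byte-identical outputs). The same pipeline is
scriptable via

```sh
Rscript inst/cli/immunomito.R run-all --seed 1 --out out
# subcommands: simulate ingest features mitotypes stats dynamics platelets run-all
```

## Scope notes

Wet-lab processing (FACS gating, absorbance traces) is out of scope: cell
compositions enter as tables and activities as measured rates. See
`vignettes/immunomito-methods.Rmd` for the model assumptions, parameter
defaults and their rationale, and known limitations.
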