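test_that("read_summary validates rows and computes missing p-values", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("rsid\tchr\tbp\tA1\tA2\tb\tstderr",
               "rs1\t1\t100\tA\tG\t0.1\t0.05",
               "rs2\t1\t200\tC\tT\t-0.2\t0.1",
               "rs3\t2\t300\tG\tA\t0.0\t0.1"), path)
  ds <- read_summary(path, default_column_map(snp = "rsid", chr = "chr",
                                              pos = "bp", ea = "A1", oa = "A2",
                                              beta = "b", se = "stderr",
                                              p = NA, n = NA, eaf = NA),
                     trait = "HDL-C")
  expect_equal(nrow(ds$records), 3)
  expect_equal(ds$records$pval, c(2 * pnorm(-2), 2 * pnorm(-2), 1.0))
})

test_that("rows with nonpositive se are dropped and logged", {
  ds <- summary_dataset(toy_records(c("rs1", "rs2"), beta = c(0.1, 0.2),
                                    se = c(0.05, 0)), trait = "TG")
  expect_equal(nrow(ds$records), 1)
  expect_equal(nrow(ds$dropped), 1)
  expect_equal(ds$dropped$reason, "se <= 0")
})

test_that("duplicate SNP ids are an error", {
  expect_error(summary_dataset(toy_records(c("rs1", "rs1"), beta = c(0.1, 0.2),
                                           se = c(0.1, 0.1)), trait = "TG"),
               "duplicate")
})

test_that("a synthetic dataset round-trips through write + read", {
  panel <- simulate_ld_panel(M = 1000, block_size = 20, rho = 0.5)
  pp <- simulate_polygenic_pair(panel, N = c(5000, 5000), seed = 31)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_summary(pp$a, path)
  back <- read_summary(path, trait = pp$a$trait)
  expect_equal(back$records$snp_id, pp$a$records$snp_id)
  expect_equal(back$records$beta, pp$a$records$beta, tolerance = 1e-12)
  expect_equal(back$records$se, pp$a$records$se, tolerance = 1e-12)
  expect_equal(back$records$pval, pp$a$records$pval, tolerance = 1e-12)
})

test_that("harmonization applies the allele-swap sign rule and strand flips", {
  d1 <- toy_dataset("rs1", beta = 0.1, se = 0.1, ea = "A", oa = "G", trait = "t1")
  swapped <- toy_dataset("rs1", beta = -0.1, se = 0.1, ea = "G", oa = "A", trait = "t2")
  h <- harmonize(list(d1, swapped))
  expect_equal(unname(h$beta[1, ]), c(0.1, 0.1))
  expect_equal(h$effect_allele, "A")

  flipped <- toy_dataset("rs1", beta = 0.1, se = 0.1, ea = "T", oa = "C", trait = "t2")
  h2 <- harmonize(list(d1, flipped))
  expect_equal(unname(h2$beta[1, ]), c(0.1, 0.1))

  flip_swap <- toy_dataset("rs1", beta = -0.1, se = 0.1, ea = "C", oa = "T", trait = "t2")
  h3 <- harmonize(list(d1, flip_swap))
  expect_equal(unname(h3$beta[1, ]), c(0.1, 0.1))
})

test_that("scrambled synthetic datasets harmonize back to the truth", {
  panel <- simulate_ld_panel(M = 500, block_size = 10, rho = 0.3)
  st <- simulate_three_sample_study(panel, beta = 0.3, seed = 77,
                                    N = c(5000, 5000, 5000))
  h <- harmonize(list(st$exposure, st$outcome))
  expect_equal(length(h$snp_ids), 500) # non-palindromic by construction
  ord <- match(h$snp_ids, panel$snp_ids)
  # the reference orientation is the (scrambled) exposure dataset, so
  # harmonized column 1 is the exposure as stored
  expect_equal(unname(h$beta[, 1]),
               st$exposure$records$beta[match(h$snp_ids, st$exposure$records$snp_id)])
  # undoing each dataset's recorded allele swap recovers the generator's
  # orientation; after harmonization the outcome column flipped back by the
  # *exposure's* swap must equal the outcome's truth-orientation beta
  exp_swap <- st$truth$scrambles$exposure$swap[ord]
  out_swap <- st$truth$scrambles$outcome$swap[ord]
  raw_beta_out <- st$outcome$records$beta[match(h$snp_ids, st$outcome$records$snp_id)]
  truth_beta_out <- ifelse(out_swap, -raw_beta_out, raw_beta_out)
  aligned_out <- ifelse(exp_swap, -h$beta[, 2], h$beta[, 2])
  expect_equal(unname(aligned_out), unname(truth_beta_out))
})

test_that("harmonization is involutive and sign-consistent", {
  panel <- simulate_ld_panel(M = 200, block_size = 10, rho = 0.3)
  st <- simulate_three_sample_study(panel, beta = 0.2, seed = 12,
                                    N = c(4000, 4000, 4000))
  h1 <- harmonize(list(st$exposure, st$outcome))
  d1 <- harmonized_column(h1, 1)
  d2 <- harmonized_column(h1, 2)
  h2 <- harmonize(list(d1, d2))
  expect_equal(h2$beta, h1$beta[match(h2$snp_ids, h1$snp_ids), ],
               ignore_attr = TRUE)
  expect_equal(length(h2$snp_ids), length(h1$snp_ids))

  # negate every beta and swap alleles in the second input: unchanged output
  rec <- st$outcome$records
  rec2 <- rec
  rec2$beta <- -rec$beta
  rec2$effect_allele <- rec$other_allele
  rec2$other_allele <- rec$effect_allele
  rec2$eaf <- 1 - rec$eaf
  flipped <- summary_dataset(rec2, trait = st$outcome$trait)
  h3 <- harmonize(list(st$exposure, flipped))
  expect_equal(h3$beta, h1$beta, ignore_attr = TRUE)
})

test_that("palindromic SNPs follow the configured policy", {
  d1 <- summary_dataset(toy_records(c("rs1", "rs2"), beta = c(0.1, 0.2),
                                    se = c(0.1, 0.1), ea = c("A", "A"),
                                    oa = c("T", "G"), eaf = c(0.2, 0.3)),
                        trait = "t1")
  d2 <- summary_dataset(toy_records(c("rs1", "rs2"), beta = c(0.1, 0.2),
                                    se = c(0.1, 0.1), ea = c("A", "A"),
                                    oa = c("T", "G"), eaf = c(0.25, 0.3)),
                        trait = "t2")
  h_drop <- harmonize(list(d1, d2), palindromic_policy = "drop")
  expect_equal(h_drop$snp_ids, "rs2")
  expect_equal(h_drop$dropped$reason, "palindromic")

  h_keep <- harmonize(list(d1, d2), palindromic_policy = "keep_if_eaf_informative")
  expect_setequal(h_keep$snp_ids, c("rs1", "rs2"))

  # ambiguous frequency near 0.5: dropped even under the keep policy
  d1a <- summary_dataset(toy_records("rs1", beta = 0.1, se = 0.1, ea = "A",
                                     oa = "T", eaf = 0.5), trait = "t1")
  d2a <- summary_dataset(toy_records("rs1", beta = 0.1, se = 0.1, ea = "A",
                                     oa = "T", eaf = 0.5), trait = "t2")
  expect_error(harmonize(list(d1a, d2a), palindromic_policy = "keep_if_eaf_informative"),
               NA)
  h_amb <- harmonize(list(d1a, d2a), palindromic_policy = "keep_if_eaf_informative")
  expect_equal(length(h_amb$snp_ids), 0)
})

test_that("IVW meta-analysis pools shared SNPs and passes singletons through", {
  a <- toy_dataset(c("rs1", "rs2"), beta = c(0.2, 0.2), se = c(0.1, 0.1),
                   trait = "S-HDL-P", name = "study_a")
  b <- toy_dataset("rs1", beta = 0.4, se = 0.1, trait = "S-HDL-P",
                   name = "study_b")
  m <- meta_analyze_ivw(a, b)
  r1 <- m$records[m$records$snp_id == "rs1", ]
  expect_equal(r1$beta, 0.3)
  expect_equal(r1$se, 0.1 / sqrt(2), tolerance = 1e-12)
  expect_equal(r1$n_studies, 2)
  r2 <- m$records[m$records$snp_id == "rs2", ]
  expect_equal(r2$beta, 0.2)
  expect_equal(r2$se, 0.1)
  expect_equal(r2$n_studies, 1)
  expect_error(meta_analyze_ivw(a, toy_dataset("rs1", 0.1, 0.1, trait = "TG")),
               "different traits")
})

test_that("meta-analysis reduces variance, is symmetric, and is idempotent on identical inputs", {
  set.seed(5)
  n <- 100
  ids <- sprintf("rs%03d", 1:n)
  a <- summary_dataset(toy_records(ids, beta = rnorm(n), se = runif(n, 0.05, 0.2)),
                       trait = "TG", name = "a")
  b <- summary_dataset(toy_records(ids, beta = rnorm(n), se = runif(n, 0.05, 0.2)),
                       trait = "TG", name = "b")
  m <- meta_analyze_ivw(a, b)
  ord <- match(ids, m$records$snp_id)
  expect_true(all(m$records$se[ord] <= pmin(a$records$se, b$records$se) + 1e-14))
  m2 <- meta_analyze_ivw(b, a)
  expect_equal(m$records$beta[ord], m2$records$beta[match(ids, m2$records$snp_id)],
               tolerance = 1e-12)
  m3 <- meta_analyze_ivw(a, summary_dataset(a$records, trait = "TG", name = "a2"))
  expect_equal(m3$records$beta[match(ids, m3$records$snp_id)], a$records$beta,
               tolerance = 1e-12)
})

test_that("three-sample design validation enforces selection disjointness", {
  mk <- function(name, tags = character()) {
    toy_dataset("rs1", 0.1, 0.1, trait = name, name = name, overlap_tags = tags)
  }
  davis <- mk("Davis")
  kettunen <- mk("Kettunen", c("GLGC", "CARDIoGRAMplusC4D"))
  ukbb <- mk("UKBB_MI")
  glgc <- mk("GLGC", c("Kettunen", "CARDIoGRAMplusC4D"))
  cardiogram <- mk("CARDIoGRAMplusC4D", c("GLGC", "Kettunen"))

  token <- validate_three_sample(davis, kettunen, ukbb)
  expect_s3_class(token, "three_sample_design")
  expect_false(token$exposure_outcome_overlap)

  expect_error(validate_three_sample(kettunen, glgc, ukbb), "GLGC")
  expect_error(validate_three_sample(kettunen, davis, cardiogram),
               "CARDIoGRAMplusC4D")

  # empty overlap tags: vacuous constraint
  expect_s3_class(validate_three_sample(mk("a"), mk("b"), mk("c")),
                  "three_sample_design")
  # same dataset in two roles is an overlap by identity
  expect_error(validate_three_sample(davis, davis, ukbb), "shares samples")
})

test_that("exposure-outcome overlap needs estimator support", {
  e <- toy_dataset("rs1", 0.1, 0.1, trait = "e", name = "exp_gwas",
                   overlap_tags = "out_gwas")
  o <- toy_dataset("rs1", 0.1, 0.1, trait = "o", name = "out_gwas")
  s <- toy_dataset("rs1", 0.1, 0.1, trait = "s", name = "sel_gwas")
  expect_error(validate_three_sample(s, e, o), "overlap")
  token <- validate_three_sample(s, e, o, estimator_allows_overlap = TRUE)
  expect_true(token$exposure_outcome_overlap)
})
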