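test_that("the same seed reproduces the cohort exactly", {
  cfg <- sim_config(n_patients = 6, seed = 42)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$embryos, b$embryos)
  expect_identical(a$divisions, b$divisions)
  expect_identical(a$counts[[1]]$counts, b$counts[[1]]$counts)
  expect_identical(lapply(a$samples, unclass), lapply(b$samples, unclass))
})

test_that("with every error channel off all cells stay euploid", {
  cfg <- sim_config(n_patients = 6, seed = 5,
                    meiotic_intercept = -50, sex_error_rate = 0,
                    per_division_missegregation_rate = 0,
                    per_division_segmental_rate = 0,
                    p_abnormal_first_division = 0,
                    p_abnormal_second_division = 0,
                    qc_fail_rate = 0)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$meiotic_truth), 0L)
  for (cells in coh$samples) {
    expect_true(all(cells[, 1:44] == 2L))
  }
  expect_true(all(coh$embryos$truth_n_aneuploid_final == 0))
})

test_that("meiotic error odds scale as exp(slope) per year of age", {
  cfg <- sim_config(meiotic_intercept = 0, meiotic_age_slope = 0.261)
  set.seed(31)
  n <- 20000
  hit <- function(age) {
    mean(vapply(seq_len(n), function(i) {
      nrow(sample_meiotic_errors(age, cfg, sex = "XX")) > 0
    }, logical(1)))
  }
  cfg$sex_error_rate <- 0
  p1 <- hit(cfg$maternal_age_mean)
  p2 <- hit(cfg$maternal_age_mean + 1)
  log_or <- log(p2 / (1 - p2)) - log(p1 / (1 - p1))
  expect_lt(abs(log_or - 0.261), 0.07)  # ~3 Monte-Carlo SE
})

test_that("chromosome weights direct meiotic errors to the weighted target", {
  w <- rep(0, 22); w[16] <- 1
  cfg <- sim_config(meiotic_intercept = 50, chromosome_weights = w,
                    meiotic_extra_mean = 0, sex_error_rate = 0)
  set.seed(8)
  chroms <- replicate(2000, sample_meiotic_errors(38.9, cfg)$chrom)
  expect_true(mean(unlist(chroms) == "chr16") >= 0.99)
})

test_that("tripolar division scatters the replicated complement", {
  cfg <- sim_config()
  set.seed(77)
  for (rep in 1:25) {
    d <- mosaicArrest:::tripolar_split(euploid_karyotype("XX"), 3L)
    expect_equal(nrow(d), 3L)
    auto <- d[, 1:44]
    # chromatid conservation: copies across daughters sum to 2 x parent
    expect_true(all(colSums(auto) == 4L))
    # hypodiploid daughters: somewhere a copy number of <= 1
    expect_true(any(auto <= 1))
  }
})

test_that("division rounds conserve total copy number (reciprocal errors)", {
  cfg <- sim_config(per_division_missegregation_rate = 0.2,
                    per_division_segmental_rate = 0.1,
                    monosomy_fitness = 1, nullisomy_fitness = 1,
                    trisomy_fitness = 1, polyploid_multipolar_prob = 0)
  set.seed(12)
  state <- mosaicArrest:::new_state(euploid_karyotype("XY"))
  for (round in 1:5) {
    before <- colSums(state$kar * state$n)
    state <- mosaicArrest:::divide_round(state, cfg, 38.9)
    after <- colSums(state$kar * state$n)
    expect_equal(unname(after), unname(2 * before))
  }
})

test_that("faithful mitosis leaves all descendants identical to the zygote", {
  cfg <- sim_config(per_division_missegregation_rate = 0,
                    per_division_segmental_rate = 0,
                    p_abnormal_first_division = 0,
                    p_abnormal_second_division = 0)
  set.seed(3)
  zyg <- euploid_karyotype("XY")
  cl <- simulate_cleavage(zyg, cfg)
  cells <- expand_cells(cl$state)
  expect_equal(nrow(cells), 8L)
  expect_true(all(apply(cells, 1, function(r) all(r == zyg))))
  expect_equal(as.character(cl$cells_after_first_division), "2")
})

test_that("abnormal-division rates match the configured probabilities", {
  coh <- simulate_cohort(sim_config(n_patients = 40, seed = 19),
                         include_reads = FALSE)
  d1 <- coh$divisions[coh$divisions$division_index == 1, ]
  d2 <- coh$divisions[coh$divisions$division_index == 2, ]
  n <- nrow(d1)
  se1 <- sqrt(0.26 * 0.74 / n)
  se2 <- sqrt(0.097 * 0.903 / n)
  expect_lt(abs(mean(d1$pattern != "normal") - 0.26), 3 * se1)
  expect_lt(abs(mean(d2$pattern != "normal") - 0.097), 3 * se2)
})

test_that("outcomes, stages, and samples respect their structural contracts", {
  coh <- simulate_cohort(sim_config(n_patients = 25, seed = 4))
  emb <- coh$embryos
  # roughly half the cohort blastulates under the default conditions
  expect_gt(mean(!emb$arrested), 0.40)
  expect_lt(mean(!emb$arrested), 0.65)
  # early arrest means at most 10 cells
  expect_true(all(emb$n_final_cells[emb$outcome == "early_arrest"] <= 10))
  # grades and day only for blastocysts
  expect_true(all(!is.na(emb$icm_grade[!emb$arrested])))
  expect_true(all(is.na(emb$biopsy_day[emb$arrested])))
  expect_true(all(emb$biopsy_day[!emb$arrested] %in% 5:7))
  for (i in seq_len(nrow(emb))) {
    cells <- coh$samples[[emb$sample_id[i]]]
    if (emb$arrested[i]) {
      expect_equal(nrow(cells), emb$n_final_cells[i])
      expect_equal(attr(cells, "sample_type"), "whole_arrested")
    } else {
      expect_true(nrow(cells) >= 5 && nrow(cells) <= 10)
      expect_equal(attr(cells, "sample_type"), "TE_biopsy")
    }
  }
})

test_that("null arrest model gives the baseline rate in every category", {
  cfg <- sim_config(n_patients = 50, seed = 9, arrest_per_chromosome = 0,
                    arrest_abnormal_division = 0, patient_sd = 0)
  coh <- simulate_cohort(cfg, include_reads = FALSE)
  p0 <- plogis(cfg$arrest_intercept)
  arr <- coh$embryos$arrested
  expect_lt(abs(mean(arr) - p0), 3 * sqrt(p0 * (1 - p0) / length(arr)))
  # independent of aneuploidy burden
  byaneu <- tapply(arr, coh$embryos$truth_n_meiotic > 0, mean)
  expect_true(all(abs(byaneu - p0) < 0.08))
})

test_that("expected read depth is linear in mean cell copy number", {
  gm <- test_genome()
  cfg <- sim_config()
  cells <- mosaic_cells(10, 4, "chr16")   # 40% mosaic trisomy 16
  nf <- simulate_reads(cells, gm, cfg, noise = FALSE)
  full <- gm$bins$width == gm$bin_size
  chr16 <- gm$bins$chrom == "chr16" & full
  base <- gm$bins$chrom == "chr1" & full
  expect_equal(mean(nf$counts[chr16]) / mean(nf$counts[base]), 1.2)
  # uniform disomy: every full-width autosomal bin at depth
  nf0 <- simulate_reads(mosaic_cells(10, 0), gm, cfg, noise = FALSE)
  auto_full <- full & !(gm$bins$chrom %in% c("chrX", "chrY"))
  expect_true(all(abs(nf0$counts[auto_full] - cfg$sequencing_depth) < 1e-9))
  # triploid-like uniform gain is scale-invisible after normalization
  cells3 <- mosaic_cells(10, 0); cells3[] <- 3L
  prof <- normalize_counts(simulate_reads(cells3, gm, cfg, noise = FALSE), gm)
  expect_true(all(abs(prof$displacement[1:22]) < 1e-9))
  # empty sample is an error
  expect_error(simulate_reads(cells[0, , drop = FALSE], gm, cfg), "no cells")
})

test_that("QC failures occur at the configured rate and corrupt the counts", {
  coh <- simulate_cohort(sim_config(n_patients = 40, seed = 13))
  qc <- vapply(coh$counts, function(x) x$qc_pass, logical(1))
  n <- length(qc)
  expect_lt(abs(mean(!qc) - 0.032), 3 * sqrt(0.032 * 0.968 / n))
})

test_that("configuration validation rejects malformed settings", {
  expect_error(sim_config(qc_fail_rate = 1.2), "probability")
  expect_error(sim_config(chromosome_weights = rep(1, 22)), "summing to 1")
  expect_error(sim_config(nonsense_field = 1), "unknown config fields")
  expect_error(sim_config(biopsy_cells_min = 8, biopsy_cells_max = 5),
               "biopsy")
  expect_error(sim_config(sequencing_depth = 0), "depth")
})

test_that("YAML configs round-trip; missing keys are listed", {
  cfg <- sim_config(n_patients = 9, seed = 77)
  path <- tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  back <- read_sim_config(path)
  expect_equal(unclass(back), unclass(cfg))
  partial <- tempfile(fileext = ".yaml")
  yaml::write_yaml(list(n_patients = 5), partial)
  expect_error(read_sim_config(partial), "missing required keys.*seed")
  expect_equal(read_sim_config(partial, partial = TRUE)$n_patients, 5)
})
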