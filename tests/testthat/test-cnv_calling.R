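gm <- test_genome()

test_that("noise-free disomic counts give zero displacement and no calls", {
  nf <- noise_free_counts(mosaic_cells(10, 0), gm)
  prof <- normalize_counts(nf, gm)
  expect_true(all(abs(prof$displacement[1:22]) < 1e-9))
  expect_lt(prof$noise_score, 1e-12)
  sc <- call_sample(nf, gm)
  expect_true(sc$qc_pass)
  expect_equal(nrow(sc$calls), 0L)
})

test_that("a full trisomy shows 1.5x depth, copy 3, displacement 100", {
  nf <- noise_free_counts(mosaic_cells(8, 8, "chr21"), gm)
  prof <- normalize_counts(nf, gm)
  expect_equal(unname(prof$copy["chr21"]), 3, tolerance = 1e-12)
  expect_equal(unname(prof$displacement["chr21"]), 100, tolerance = 1e-9)
  sc <- call_sample(nf, gm)
  expect_equal(nrow(sc$calls), 1L)
  expect_equal(sc$calls$chrom, "chr21")
  expect_equal(sc$calls$direction, "gain")
  expect_equal(sc$calls$origin, "meiotic")
})

test_that("a 40% mosaic trisomy lands at displacement 40, mitotic", {
  nf <- noise_free_counts(mosaic_cells(10, 4, "chr16"), gm)
  prof <- normalize_counts(nf, gm)
  expect_equal(unname(prof$displacement["chr16"]), 40, tolerance = 1e-9)
  sc <- call_sample(nf, gm)
  expect_equal(sc$calls$origin, "mitotic")
})

test_that("origin classification follows the 30-70 rule", {
  expect_equal(classify_origin(85, "chr16")$origin, "meiotic")
  expect_equal(classify_origin(50, "chr3")$origin, "mitotic")
  expect_false(classify_origin(0, "chr1")$is_call)
  expect_false(classify_origin(29.99, "chr1")$is_call)
  # both boundaries belong to the mitotic (mosaic) range
  expect_equal(classify_origin(30, "chr2")$origin, "mitotic")
  expect_equal(classify_origin(70, "chr2")$origin, "mitotic")
  expect_equal(classify_origin(70.01, "chr2")$origin, "meiotic")
  # sex chromosomes and segmental scope are never stratified
  expect_equal(classify_origin(45, "chrX")$origin, "not_classified")
  expect_equal(classify_origin(95, "chr5", "segmental_q")$origin,
               "not_classified")
})

test_that("arm-level events yield segmental calls with whole-chromosome precedence", {
  cfg <- sim_config()
  base <- euploid_karyotype("XX")
  # 5q loss in half the cells: 5q arm at 0.75x, 5p flat
  cells <- matrix(rep(base, 10), nrow = 10, byrow = TRUE,
                  dimnames = list(NULL, names(base)))
  cells[1:5, "chr5.q"] <- 1L
  nf <- simulate_reads(cells, gm, cfg, noise = FALSE)
  sc <- call_sample(nf, gm)
  expect_equal(nrow(sc$calls), 1L)
  expect_equal(sc$calls$scope, "segmental_q")
  expect_equal(sc$calls$direction, "loss")
  expect_equal(sc$calls$displacement, 50, tolerance = 1e-9)
  expect_equal(sc$calls$origin, "not_classified")
  # both arms displaced the same way -> whole-chromosome call only
  cells2 <- mosaic_cells(10, 5, "chr5", "loss")
  sc2 <- call_sample(noise_free_counts(cells2, gm), gm)
  expect_equal(sc2$calls$scope, "whole")
  expect_equal(nrow(sc2$calls), 1L)
  # flat profile -> no segmental calls
  prof <- normalize_counts(noise_free_counts(mosaic_cells(6, 0), gm), gm)
  expect_equal(nrow(detect_segmental(prof, gm)), 0L)
})

test_that("sex inference sets the X/Y expectations", {
  cfg <- sim_config()
  xy <- noise_free_counts(mosaic_cells(10, 0, sex = "XY"), gm)
  sc <- call_sample(xy, gm)
  expect_equal(sc$sex, "XY")
  expect_equal(nrow(sc$calls), 0L)
  xx <- noise_free_counts(mosaic_cells(10, 0, sex = "XX"), gm)
  expect_equal(call_sample(xx, gm)$sex, "XX")
  expect_equal(nrow(call_sample(xx, gm)$calls), 0L)
  # male with X at 0.75x baseline: X gain at 50% displacement, unclassified
  base <- euploid_karyotype("XY")
  cells <- matrix(rep(base, 10), nrow = 10, byrow = TRUE,
                  dimnames = list(NULL, names(base)))
  cells[1:5, c("chrX.p", "chrX.q")] <- 2L
  sc2 <- call_sample(simulate_reads(cells, gm, cfg, noise = FALSE), gm)
  expect_equal(sc2$sex, "XY")
  xcall <- sc2$calls[sc2$calls$chrom == "chrX", ]
  expect_equal(nrow(xcall), 1L)
  expect_equal(xcall$direction, "gain")
  expect_equal(xcall$displacement, 50, tolerance = 1e-9)
  expect_equal(xcall$origin, "not_classified")
  # ambiguous Y fraction: sex uncertain, sex calls suppressed
  cells3 <- matrix(rep(base, 10), nrow = 10, byrow = TRUE,
                   dimnames = list(NULL, names(base)))
  cells3[1:6, c("chrY.p", "chrY.q")] <- 0L  # Y ratio 0.2
  sc3 <- call_sample(simulate_reads(cells3, gm, cfg, noise = FALSE), gm)
  expect_equal(sc3$sex, "uncertain")
  expect_false(any(sc3$calls$chrom %in% c("chrX", "chrY")))
})

test_that("QC-flagged or hopeless samples are excluded, not called", {
  nf <- noise_free_counts(mosaic_cells(5, 0), gm)
  bad <- nf
  bad$qc_pass <- FALSE
  expect_error(normalize_counts(bad, gm), "quality control")
  sc <- call_sample(bad, gm)
  expect_s3_class(sc, "sample_calls")
  expect_false(sc$qc_pass)
  expect_equal(sc$qc_reason, "flagged")
  # wild noise trips the noise threshold
  set.seed(2)
  noisy <- nf
  noisy$counts <- rnbinom(length(nf$counts), mu = pmax(nf$counts, 1),
                          size = 0.3)
  sc2 <- call_sample(noisy, gm)
  expect_false(sc2$qc_pass)
  expect_equal(sc2$qc_reason, "noise")
  # all-zero counts: degenerate library
  zero <- nf
  zero$counts <- rep(0, length(nf$counts))
  sc3 <- call_sample(zero, gm)
  expect_false(sc3$qc_pass)
  expect_equal(sc3$qc_reason, "degenerate")
})

test_that("displacement is affine-exact in the mosaic cell fraction", {
  for (k in 0:10) {
    nf <- noise_free_counts(mosaic_cells(10, k, "chr7"), gm)
    prof <- normalize_counts(nf, gm)
    expect_equal(unname(prof$displacement["chr7"]), 100 * k / 10,
                 tolerance = 1e-9)
  }
})

test_that("classification is monotone in the mosaic fraction", {
  classes <- vapply(0:10, function(k) {
    sc <- call_sample(noise_free_counts(mosaic_cells(10, k, "chr7"), gm), gm)
    if (nrow(sc$calls) == 0) "disomy" else sc$calls$origin
  }, character(1))
  rank <- c(disomy = 1, mitotic = 2, meiotic = 3)
  expect_true(all(diff(rank[classes]) >= 0))
})

test_that("profiles with many displaced autosomes are flagged as unreliable", {
  base <- euploid_karyotype("XX")
  cells <- matrix(rep(base, 10), nrow = 10, byrow = TRUE,
                  dimnames = list(NULL, names(base)))
  # trisomy on 12 small autosomes (a minority of bins, so the median
  # baseline stays disomic and 12 > 11 autosomes appear displaced)
  for (c_i in 11:22) {
    cells[, c(2 * c_i - 1, 2 * c_i)] <- 3L
  }
  sc <- call_sample(noise_free_counts(cells, gm), gm)
  expect_true(sc$baseline_unreliable)
  sc0 <- call_sample(noise_free_counts(mosaic_cells(10, 10, "chr1"), gm), gm)
  expect_false(sc0$baseline_unreliable)
})

test_that("a uniform trisomy 21 is called meiotic end-to-end at default depth", {
  cfg <- sim_config()
  set.seed(21)
  cells <- mosaic_cells(7, 7, "chr21")
  bc <- simulate_reads(cells, gm, cfg, sample_id = "T21")
  sc <- call_sample(bc, gm)
  expect_true(sc$qc_pass)
  expect_equal(nrow(sc$calls), 1L)
  expect_equal(sc$calls$chrom, "chr21")
  expect_equal(sc$calls$origin, "meiotic")
  expect_equal(sc$calls$direction, "gain")
})

test_that("euploid samples stay call-free in >= 95% of noisy replicates", {
  cfg <- sim_config(qc_fail_rate = 0)  # measure specificity, not QC loss
  set.seed(6)
  clean <- vapply(1:20, function(i) {
    bc <- simulate_reads(mosaic_cells(8, 0, sex = "XY"), gm, cfg)
    sc <- call_sample(bc, gm)
    sc$qc_pass && nrow(sc$calls) == 0
  }, logical(1))
  expect_gte(mean(clean), 0.95)
})
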