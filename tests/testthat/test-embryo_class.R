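test_that("the five categories follow the call pattern", {
  expect_equal(as.character(categorize_calls(no_calls())), "Euploid")
  expect_equal(as.character(categorize_calls(
    call_row("chr16", origin = "meiotic"))), "Meiotic only")
  expect_equal(as.character(categorize_calls(rbind(
    call_row("chr16", origin = "meiotic"),
    call_row("chr3", direction = "loss", displacement = 45,
             origin = "mitotic")))),
    "Meiotic plus mitotic and/or seg")
  expect_equal(as.character(categorize_calls(
    call_row("chr3", displacement = 50, origin = "mitotic"))),
    "Mitotic only")
  expect_equal(as.character(categorize_calls(rbind(
    call_row("chr5", scope = "segmental_q", direction = "loss",
             displacement = 50, origin = "not_classified"),
    call_row("chr7", displacement = 40, origin = "mitotic")))),
    "Mitotic and/or seg")
  # segmental alone, no mitotic whole-chromosome
  expect_equal(as.character(categorize_calls(
    call_row("chr5", scope = "segmental_p", displacement = 35,
             origin = "not_classified"))),
    "Mitotic and/or seg")
  # meiotic + segmental (no mitotic whole)
  expect_equal(as.character(categorize_calls(rbind(
    call_row("chr16", origin = "meiotic"),
    call_row("chr5", scope = "segmental_q", displacement = 40,
             origin = "not_classified")))),
    "Meiotic plus mitotic and/or seg")
})

test_that("sex-chromosome calls never affect the category", {
  x_call <- call_row("chrX", displacement = 45, origin = "not_classified")
  expect_equal(as.character(categorize_calls(x_call)), "Euploid")
  mixed <- rbind(call_row("chr16", origin = "meiotic"), x_call)
  expect_equal(as.character(categorize_calls(mixed)), "Meiotic only")
})

test_that("categorization is invariant under call-list permutation", {
  calls <- rbind(
    call_row("chr16", origin = "meiotic"),
    call_row("chr3", displacement = 45, origin = "mitotic"),
    call_row("chr5", scope = "segmental_q", displacement = 40,
             origin = "not_classified"),
    call_row("chrX", displacement = 45, origin = "not_classified"))
  set.seed(1)
  ref <- categorize_calls(calls)
  for (i in 1:10) {
    perm <- calls[sample(nrow(calls)), ]
    expect_equal(categorize_calls(perm), ref)
  }
})

test_that("complexity counts distinct chromosomes and bins the total", {
  cx <- count_complexity(rbind(
    call_row("chr16", origin = "meiotic"),
    call_row("chr3", displacement = 45, origin = "mitotic"),
    call_row("chr5", scope = "segmental_q", displacement = 40,
             origin = "not_classified")))
  expect_equal(cx$n_meiotic_whole_autosome, 1L)
  expect_equal(cx$n_mitotic_whole_autosome, 1L)
  expect_equal(cx$n_segmental, 1L)
  expect_equal(cx$n_total_aneuploid_chromosomes, 3L)
  expect_equal(as.character(cx$binned_total), "3")

  expect_equal(count_complexity(no_calls())$n_total_aneuploid_chromosomes, 0L)
  expect_equal(as.character(count_complexity(no_calls())$binned_total), "0")

  many <- do.call(rbind, lapply(paste0("chr", 1:7), call_row,
                                displacement = 45, origin = "mitotic"))
  cx7 <- count_complexity(many)
  expect_equal(cx7$n_total_aneuploid_chromosomes, 7L)
  expect_equal(as.character(cx7$binned_total), ">=5")

  # one chromosome with both whole and segmental events counts once
  dup <- rbind(call_row("chr4", displacement = 45, origin = "mitotic"),
               call_row("chr4", scope = "segmental_p", displacement = 35,
                        origin = "not_classified"))
  expect_equal(count_complexity(dup)$n_total_aneuploid_chromosomes, 1L)
})

test_that("noise-free categories match an oracle applied to the sampled cells", {
  gm <- test_genome()
  cfg <- sim_config(n_patients = 4, seed = 30)
  coh <- simulate_cohort(cfg, include_reads = FALSE)
  # oracle: analytic thresholds on the sampled cells' mean copies,
  # written independently of the package's calling path
  karyo <- read.delim(system.file("extdata", "grch38_karyotype.tsv",
                                  package = "mosaicArrest"))
  arm_bins <- as.vector(rbind(ceiling(karyo$centromere / gm$bin_size),
                              ceiling((karyo$length - karyo$centromere) /
                                        gm$bin_size)))
  oracle_category <- function(cells) {
    has_mei <- FALSE; has_mit <- FALSE; has_seg <- FALSE
    arm_mean <- colMeans(cells)
    # per-bin median over autosomes: every bin of an arm shares the arm's
    # normalized rate in noise-free data, so weight arms by their bin counts
    med <- median(rep(arm_mean[1:44], arm_bins[1:44]))
    for (ci in 1:22) {
      p <- arm_mean[2 * ci - 1] / (med / 2)
      q <- arm_mean[2 * ci] / (med / 2)
      dp <- abs(p - 2) * 100; dq <- abs(q - 2) * 100
      whole <- dp >= 30 && dq >= 30 && sign(p - 2) == sign(q - 2)
      if (whole) {
        d <- abs((p + q) / 2 - 2) * 100
        if (d > 70) has_mei <- TRUE else has_mit <- TRUE
      } else if (xor(dp >= 30, dq >= 30)) {
        has_seg <- TRUE
      }
    }
    if (!has_mei && !has_mit && !has_seg) "Euploid"
    else if (has_mei && !has_mit && !has_seg) "Meiotic only"
    else if (has_mei) "Meiotic plus mitotic and/or seg"
    else if (has_mit && !has_seg) "Mitotic only"
    else "Mitotic and/or seg"
  }
  checked <- 0L
  for (sid in names(coh$samples)[1:30]) {
    cells <- coh$samples[[sid]]
    nf <- simulate_reads(cells, gm, cfg, sample_id = sid, noise = FALSE)
    sc <- call_sample(nf, gm)
    # skip near-threshold compositions where the oracle's unit-weight median
    # and the caller's trimmed mean legitimately differ
    prof <- normalize_counts(nf, gm)
    d <- prof$displacement[1:22]
    d_arm <- abs(prof$arm_copy[1:44] - 2) * 100
    if (any(abs(d - 30) < 2 | abs(d - 70) < 2) ||
        any(abs(d_arm - 30) < 2)) next
    expect_equal(as.character(categorize_calls(sc)), oracle_category(cells),
                 info = sid)
    checked <- checked + 1L
  }
  expect_gte(checked, 15L)
})
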