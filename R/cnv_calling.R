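## Copy-number calling from binned read counts: normalization, fractional
## displacement, origin classification by the 30-70% rule, arm-level
## segmental detection, and sex inference.

# comparisons against the 30/70 displacement thresholds use a small guard so
# that exact boundary fractions (e.g. 3 trisomic cells of 10) are not pushed
# across a threshold by floating-point rounding
DISP_TOL <- 1e-6

#' Normalize binned counts to a copy-number profile
#'
#' Each bin's count is first divided by its relative width, then by the
#' per-sample median over autosomal bins, giving a ratio with disomic
#' expectation 1.0. Per-chromosome and per-arm copy estimates are
#' `2 * trimmed mean` (10% each tail) of the bin ratios; displacement is
#' `|copy - 2| * 100` for autosomes (percent of a full single-copy change).
#' The noise score is the median absolute difference between consecutive
#' autosomal bin ratios within a chromosome.
#'
#' @param counts A `binned_counts` object (see [simulate_reads()]).
#' @param genome The matching [build_default_genome()] model.
#' @return Object of class `cn_profile`: ratios, per-chromosome copy
#'   estimates and displacements, per-arm copy estimates, and noise score.
#' @export
normalize_counts <- function(counts, genome) {
  stopifnot(inherits(counts, "binned_counts"))
  if (!isTRUE(counts$qc_pass)) {
    stop("sample failed quality control; calling refused", call. = FALSE)
  }
  bins <- genome$bins
  if (length(counts$counts) != nrow(bins)) {
    stop("count vector does not match the genome bin grid", call. = FALSE)
  }
  rate <- counts$counts / (bins$width / genome$bin_size)
  auto <- bins$chrom %in% autosome_names(genome)
  med <- stats::median(rate[auto])
  if (!is.finite(med) || med <= 0) {
    stop("degenerate input: autosomal median bin count is zero", call. = FALSE)
  }
  ratio <- rate / med
  chrom_f <- factor(bins$chrom, levels = genome$chromosomes$name)
  copy <- 2 * tapply(ratio, chrom_f, mean, trim = 0.1)
  arm_f <- factor(paste(bins$chrom, bins$arm, sep = "."),
                  levels = genome_arm_names(genome))
  arm_copy <- 2 * tapply(ratio, arm_f, mean, trim = 0.1)
  is_auto <- genome$chromosomes$is_autosome
  disp <- stats::setNames(ifelse(is_auto, abs(copy - 2) * 100, NA_real_),
                          names(copy))
  # first-order-difference noise estimate on the per-bin scale
  noise <- stats::median(abs(unlist(
    tapply(ratio[auto], droplevels(chrom_f[auto]), diff),
    use.names = FALSE))) / sqrt(2)
  structure(list(
    sample_id = counts$sample_id,
    ratio = ratio,
    copy = copy,
    displacement = disp,
    arm_copy = arm_copy,
    noise_score = noise
  ), class = "cn_profile")
}

#' Classify the origin of a whole-chromosome or segmental event
#'
#' Autosomal whole-chromosome calls: displacement below 30% is a normal
#' disomy (no call); 30-70% (inclusive at both boundaries) is mitotic
#' (mosaic); above 70% is meiotic. Sex-chromosome and segmental events are
#' emitted with origin `not_classified` when displacement reaches 30%.
#'
#' @param displacement Percent of a full single-copy change (>= 0).
#' @param chromosome Chromosome name.
#' @param scope "whole", "segmental_p", or "segmental_q".
#' @return List: `is_call` (logical) and `origin` ("meiotic", "mitotic",
#'   "not_classified", or NA when no call).
#' @export
classify_origin <- function(displacement, chromosome, scope = "whole") {
  stopifnot(displacement >= 0)
  if (displacement < 30 - DISP_TOL) {
    return(list(is_call = FALSE, origin = NA_character_))
  }
  if (chromosome %in% c("chrX", "chrY") || scope != "whole") {
    return(list(is_call = TRUE, origin = "not_classified"))
  }
  origin <- if (displacement > 70 + DISP_TOL) "meiotic" else "mitotic"
  list(is_call = TRUE, origin = origin)
}

# strongest single changepoint in a bin-ratio series (binary segmentation
# step); used to confirm that an arm-level call is not a sub-bin artifact.
max_changepoint <- function(x) {
  n <- length(x)
  if (n < 4) return(list(split = NA_integer_, delta = 0))
  ks <- 2:(n - 2)
  deltas <- vapply(ks, function(k) {
    abs(mean(x[1:k]) - mean(x[(k + 1):n]))
  }, numeric(1))
  best <- which.max(deltas)
  list(split = ks[best], delta = deltas[best])
}

#' Detect arm-level segmental aneuploidies
#'
#' An autosome arm whose displacement reaches 30% while the sibling arm's
#' stays below 30% yields a segmental call (origin `not_classified`).
#' Whole-chromosome calls (both arms displaced in the same direction)
#' suppress segmental calls on the same chromosome. The minimum reportable
#' segment is one full arm: sub-arm changepoints found by binary
#' segmentation are merged up to arm scope.
#'
#' @param profile A `cn_profile`.
#' @param genome The genome model.
#' @return data.frame of segmental calls (chrom, scope, direction,
#'   displacement, origin); zero rows when none.
#' @export
detect_segmental <- function(profile, genome) {
  out <- list()
  for (chrom in autosome_names(genome)) {
    d_p <- abs(profile$arm_copy[paste0(chrom, ".p")] - 2) * 100
    d_q <- abs(profile$arm_copy[paste0(chrom, ".q")] - 2) * 100
    dir_p <- sign(profile$arm_copy[paste0(chrom, ".p")] - 2)
    dir_q <- sign(profile$arm_copy[paste0(chrom, ".q")] - 2)
    whole <- d_p >= 30 - DISP_TOL && d_q >= 30 - DISP_TOL && dir_p == dir_q
    if (whole) next  # whole-chromosome precedence
    for (arm in c("p", "q")) {
      d_this <- if (arm == "p") d_p else d_q
      d_sib <- if (arm == "p") d_q else d_p
      if (d_this >= 30 - DISP_TOL && d_sib < 30 - DISP_TOL) {
        cp <- profile$arm_copy[paste0(chrom, ".", arm)]
        out[[length(out) + 1L]] <- data.frame(
          chrom = chrom, scope = paste0("segmental_", arm),
          direction = if (cp > 2) "gain" else "loss",
          displacement = unname(d_this), origin = "not_classified",
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(0), scope = character(0),
               direction = character(0), displacement = numeric(0),
               origin = character(0), stringsAsFactors = FALSE)
}

#' Infer embryo sex and call sex-chromosome aneuploidies
#'
#' Sex is XY when the mean Y bin ratio exceeds 0.25, else XX; a Y ratio in
#' `[0.15, 0.35]` is flagged uncertain and sex-chromosome calls are
#' suppressed. X and Y displacements are computed against the sex-specific
#' expectation (X: 1 copy in XY, 2 in XX; Y: 1 in XY, 0 in XX); resulting
#' calls carry origin `not_classified`.
#'
#' @param profile A `cn_profile`.
#' @return List: `sex` ("XX", "XY", or "uncertain") and `calls` data.frame.
#' @export
infer_sex <- function(profile) {
  cx <- unname(profile$copy["chrX"])
  cy <- unname(profile$copy["chrY"])
  y_ratio <- cy / 2
  uncertain <- y_ratio >= 0.15 && y_ratio <= 0.35
  sex <- if (y_ratio > 0.25) "XY" else "XX"
  calls <- data.frame(chrom = character(0), scope = character(0),
                      direction = character(0), displacement = numeric(0),
                      origin = character(0), stringsAsFactors = FALSE)
  if (uncertain) {
    return(list(sex = "uncertain", calls = calls))
  }
  expect <- if (sex == "XY") c(chrX = 1, chrY = 1) else c(chrX = 2, chrY = 0)
  for (chrom in c("chrX", "chrY")) {
    cc <- if (chrom == "chrX") cx else cy
    d <- abs(cc - expect[[chrom]]) * 100
    if (d >= 30 - DISP_TOL) {
      calls <- rbind(calls, data.frame(
        chrom = chrom, scope = "whole",
        direction = if (cc > expect[[chrom]]) "gain" else "loss",
        displacement = d, origin = "not_classified",
        stringsAsFactors = FALSE))
    }
  }
  list(sex = sex, calls = calls)
}

#' Call aneuploidies for one sample
#'
#' Applies QC (a sample whose `qc_pass` flag is unset, or whose noise score
#' exceeds `noise_threshold`, is excluded rather than called), normalizes,
#' emits whole-autosome calls under the 30-70% displacement rule, arm-level
#' segmental calls, and sex-chromosome calls, and flags profiles whose
#' median-based baseline is unreliable because fewer than half of the
#' autosomes are within the disomic range.
#'
#' @param counts A `binned_counts` object.
#' @param genome The genome model.
#' @param noise_threshold QC exclusion threshold on the noise score.
#' @return Object of class `sample_calls`: list with `sample_id`, `qc_pass`,
#'   `qc_reason`, `calls` (data.frame: chrom, scope, direction,
#'   displacement, origin), `sex`, `noise_score`, `baseline_unreliable`.
#'   QC exclusion is a distinguished result (`qc_pass = FALSE`), not an error.
#' @export
call_sample <- function(counts, genome, noise_threshold = 0.15) {
  empty <- data.frame(chrom = character(0), scope = character(0),
                      direction = character(0), displacement = numeric(0),
                      origin = character(0), stringsAsFactors = FALSE)
  if (!isTRUE(counts$qc_pass)) {
    return(structure(list(sample_id = counts$sample_id, qc_pass = FALSE,
                          qc_reason = "flagged", calls = empty,
                          sex = NA_character_, noise_score = NA_real_,
                          baseline_unreliable = NA),
                     class = "sample_calls"))
  }
  profile <- tryCatch(normalize_counts(counts, genome), error = function(e) NULL)
  if (is.null(profile)) {
    # lack of DNA / degenerate library: distinguished QC exclusion
    return(structure(list(sample_id = counts$sample_id, qc_pass = FALSE,
                          qc_reason = "degenerate", calls = empty,
                          sex = NA_character_, noise_score = NA_real_,
                          baseline_unreliable = NA),
                     class = "sample_calls"))
  }
  if (profile$noise_score > noise_threshold) {
    return(structure(list(sample_id = counts$sample_id, qc_pass = FALSE,
                          qc_reason = "noise", calls = empty,
                          sex = NA_character_,
                          noise_score = profile$noise_score,
                          baseline_unreliable = NA),
                     class = "sample_calls"))
  }
  seg <- detect_segmental(profile, genome)
  whole <- list()
  for (chrom in autosome_names(genome)) {
    if (chrom %in% seg$chrom) next  # segmental call claims this chromosome
    d <- unname(profile$displacement[chrom])
    cl <- classify_origin(d, chrom, "whole")
    if (cl$is_call) {
      whole[[length(whole) + 1L]] <- data.frame(
        chrom = chrom, scope = "whole",
        direction = if (profile$copy[chrom] > 2) "gain" else "loss",
        displacement = d, origin = cl$origin, stringsAsFactors = FALSE)
    }
  }
  sx <- infer_sex(profile)
  calls <- rbind(if (length(whole)) do.call(rbind, whole) else empty,
                 seg, sx$calls)
  rownames(calls) <- NULL
  disp_auto <- profile$displacement[autosome_names(genome)]
  structure(list(
    sample_id = counts$sample_id, qc_pass = TRUE, qc_reason = NA_character_,
    calls = calls, sex = sx$sex, noise_score = profile$noise_score,
    baseline_unreliable = sum(disp_auto < 30 - DISP_TOL) < 11
  ), class = "sample_calls")
}

#' @export
print.sample_calls <- function(x, ...) {
  if (!x$qc_pass) {
    cat("sample", x$sample_id, "- QC excluded (", x$qc_reason, ")\n")
  } else {
    cat("sample", x$sample_id, "- sex", x$sex, "-",
        nrow(x$calls), "calls\n")
    if (nrow(x$calls)) print(x$calls)
  }
  invisible(x)
}

#' Call every sample of a cohort
#'
#' @param cohort An `embryo_cohort` with simulated counts.
#' @param noise_threshold Passed to [call_sample()].
#' @return Named list of `sample_calls`, one per sample.
#' @export
call_cohort <- function(cohort, noise_threshold = 0.15) {
  lapply(cohort$counts, call_sample, genome = cohort$genome,
         noise_threshold = noise_threshold)
}

#' Serialize calls as a tidy TSV
#'
#' Columns: sample_id, chrom, scope, direction, displacement, origin,
#' qc_flag.
#'
#' @param calls A list of `sample_calls` (or a single one).
#' @param path Output file.
#' @export
write_calls <- function(calls, path) {
  if (inherits(calls, "sample_calls")) calls <- list(calls)
  rows <- lapply(calls, function(sc) {
    if (!sc$qc_pass) {
      data.frame(sample_id = sc$sample_id, chrom = NA, scope = NA,
                 direction = NA, displacement = NA, origin = NA,
                 qc_flag = paste0("excluded_", sc$qc_reason),
                 stringsAsFactors = FALSE)
    } else if (nrow(sc$calls)) {
      cbind(sample_id = sc$sample_id, sc$calls, qc_flag = "pass")
    } else {
      data.frame(sample_id = sc$sample_id, chrom = NA, scope = NA,
                 direction = NA, displacement = NA, origin = NA,
                 qc_flag = "pass", stringsAsFactors = FALSE)
    }
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
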