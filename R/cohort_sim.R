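## Cohort simulator: patients, cycles, meiotic errors, cleavage-driven
## mosaicism, arrest outcomes, morphology, biopsies and binned read counts.
##
## Cell karyotypes are integer vectors over 48 chromosome arms (chr1.p,
## chr1.q, ..., chrY.q). An embryo's cell population is kept clone-compressed:
## a matrix of distinct karyotypes plus a count per clone, in lineage order,
## so that a trophectoderm biopsy can sample a contiguous neighborhood.

CHROM_NAMES <- c(paste0("chr", 1:22), "chrX", "chrY")
ARM_NAMES <- as.vector(t(outer(CHROM_NAMES, c("p", "q"), paste, sep = ".")))
AUTOSOMES <- CHROM_NAMES[1:22]
DIVISION_PATTERNS <- c("normal", "multipolar", "precocious", "reverse", "failed")

#' Euploid cell karyotype
#'
#' @param sex "XX" or "XY".
#' @return Named integer vector of copy numbers over the 48 chromosome arms.
#' @export
euploid_karyotype <- function(sex = c("XX", "XY")) {
  sex <- match.arg(sex)
  kar <- rep(2L, 48L)
  names(kar) <- ARM_NAMES
  if (sex == "XY") {
    kar[c("chrX.p", "chrX.q")] <- 1L
    kar[c("chrY.p", "chrY.q")] <- 1L
  } else {
    kar[c("chrY.p", "chrY.q")] <- 0L
  }
  kar
}

arm_idx <- function(chrom) {
  i <- match(chrom, CHROM_NAMES)
  c(2L * i - 1L, 2L * i)
}

#' Draw meiotic errors for one zygote
#'
#' The probability that an embryo carries at least one autosomal meiotic
#' error is `plogis(meiotic_intercept + meiotic_age_slope * (age - age_mean))`;
#' the number of affected chromosomes is 1 + Poisson(`meiotic_extra_mean`),
#' chromosomes drawn without replacement by `chromosome_weights`, each a
#' whole-chromosome gain or loss with equal probability. Sex-chromosome
#' meiotic errors occur independently at rate `sex_error_rate`.
#'
#' @param age Maternal age in years.
#' @param config A [sim_config()].
#' @param sex "XX" or "XY" (determines which sex-chromosome events are possible).
#' @return data.frame with columns `chrom` and `direction` ("gain"/"loss");
#'   zero rows when no error is drawn.
#' @export
sample_meiotic_errors <- function(age, config, sex = "XX") {
  p <- stats::plogis(config$meiotic_intercept +
                     config$meiotic_age_slope * (age - config$maternal_age_mean))
  out <- data.frame(chrom = character(0), direction = character(0),
                    stringsAsFactors = FALSE)
  if (is.finite(p) && stats::runif(1) < p) {
    k <- min(1L + stats::rpois(1L, config$meiotic_extra_mean), 22L)
    chroms <- sample(AUTOSOMES, k, prob = config$chromosome_weights)
    out <- data.frame(chrom = chroms,
                      direction = sample(c("gain", "loss"), k, replace = TRUE),
                      stringsAsFactors = FALSE)
  }
  if (stats::runif(1) < config$sex_error_rate) {
    sc <- if (sex == "XX") "chrX" else sample(c("chrX", "chrY"), 1)
    dir <- sample(c("gain", "loss"), 1)
    out <- rbind(out, data.frame(chrom = sc, direction = dir,
                                 stringsAsFactors = FALSE))
  }
  out
}

apply_meiotic_errors <- function(kar, events) {
  if (nrow(events) == 0L) return(kar)
  for (i in seq_len(nrow(events))) {
    idx <- arm_idx(events$chrom[i])
    delta <- if (events$direction[i] == "gain") 1L else -1L
    kar[idx] <- pmax(kar[idx] + delta, 0L)
  }
  kar
}

## ---- lineage state -------------------------------------------------------

new_state <- function(kar) {
  list(kar = matrix(kar, nrow = 1, dimnames = list(NULL, ARM_NAMES)),
       n = 1L)
}

state_total <- function(state) sum(state$n)

#' Expand a clone-compressed cell population to one row per cell
#' @param state Lineage state as produced by [simulate_cleavage()].
#' @return Integer matrix, one row per cell, 48 arm columns, lineage order.
#' @export
expand_cells <- function(state) {
  state$kar[rep(seq_along(state$n), state$n), , drop = FALSE]
}

# mean copy number per chromosome across the population
state_mean_chrom_copy <- function(state) {
  w <- state$n / sum(state$n)
  arm_mean <- colSums(state$kar * w)
  (arm_mean[seq(1, 47, 2)] + arm_mean[seq(2, 48, 2)]) / 2
}

# whole autosomes whose population mean copy deviates by >= 0.3 copies from
# the disomic expectation, measured relative to the median autosomal ploidy
# (read depth is scale-free, so a uniform ploidy shift displaces nothing)
truth_n_aneuploid <- function(state) {
  cc <- state_mean_chrom_copy(state)[1:22]
  base <- stats::median(cc) / 2
  if (base <= 0) base <- 1
  sum(abs(cc / base - 2) >= 0.3)
}

clone_fitness <- function(kar, config) {
  cmin <- pmin(kar[seq(1, 43, 2)], kar[seq(2, 44, 2)])  # autosomes
  f <- prod(ifelse(cmin == 0, config$nullisomy_fitness,
            ifelse(cmin == 1, config$monosomy_fitness,
            ifelse(cmin >= 3, config$trisomy_fitness, 1))))
  max(f, 0.3)
}

is_polyploid <- function(kar) mean(kar[1:44]) >= 3.5

# Scatter the replicated chromatid complement of one cell over `poles`
# daughter cells (multipolar mitosis). For each chromosome, 2 x copy
# chromatids are assigned independently and uniformly to the poles, so
# daughter copies per chromosome sum to twice the parental copy and the
# daughters are hypodiploid, partially complementary clones.
tripolar_split <- function(kar, poles = 3L) {
  daughters <- matrix(0L, nrow = poles, ncol = 48L,
                      dimnames = list(NULL, ARM_NAMES))
  for (c_i in seq_len(24L)) {
    p_i <- 2L * c_i - 1L
    q_i <- 2L * c_i
    base <- min(kar[p_i], kar[q_i])
    if (base > 0) {
      alloc <- tabulate(sample.int(poles, 2L * base, replace = TRUE), poles)
      daughters[, p_i] <- daughters[, p_i] + alloc
      daughters[, q_i] <- daughters[, q_i] + alloc
    }
    # arms in excess of the whole-chromosome complement segregate alone
    for (a_i in c(p_i, q_i)) {
      extra <- kar[a_i] - base
      if (extra > 0) {
        alloc <- tabulate(sample.int(poles, 2L * extra, replace = TRUE), poles)
        daughters[, a_i] <- daughters[, a_i] + alloc
      }
    }
  }
  daughters
}

# One synchronous division round over all clones. Dividing cells copy each
# chromosome to both daughters; with probability `per_division_missegregation_rate`
# per chromosome one daughter gains and the other loses (reciprocal events);
# arm-level events likewise at `per_division_segmental_rate`. Polyploid
# (>= ~4N) cells divide multipolar with probability `polyploid_multipolar_prob`.
divide_round <- function(state, config, age, p_scale = 1) {
  q_w <- stats::plogis(stats::qlogis(config$per_division_missegregation_rate) +
                       config$mitotic_age_slope * (age - config$maternal_age_mean))
  p_any_w <- 1 - (1 - q_w)^22
  p_any_s <- 1 - (1 - config$per_division_segmental_rate)^44
  kar_out <- list()
  n_out <- integer(0)
  for (i in seq_along(state$n)) {
    kar <- state$kar[i, ]
    n_i <- state$n[i]
    f <- clone_fitness(kar, config) * p_scale
    m <- stats::rbinom(1L, n_i, f)
    stay <- n_i - m
    children_kar <- list()
    children_n <- integer(0)
    if (m > 0 && is_polyploid(kar) &&
        stats::runif(1) < config$polyploid_multipolar_prob) {
      n_scatter <- min(m, 4L)
      for (s in seq_len(n_scatter)) {
        d <- tripolar_split(kar, sample(3:4, 1L, prob = c(0.8, 0.2)))
        for (r in seq_len(nrow(d))) {
          children_kar <- c(children_kar, list(d[r, ]))
          children_n <- c(children_n, 1L)
        }
      }
      m <- m - n_scatter
    }
    nw <- stats::rbinom(1L, m, p_any_w)
    ns <- stats::rbinom(1L, m - nw, p_any_s)
    normal <- m - nw - ns
    if (nw > 0) {
      for (s in seq_len(nw)) {
        ci <- sample.int(22L, 1L)
        idx <- arm_idx(CHROM_NAMES[ci])
        if (all(kar[idx] > 0)) {
          up <- kar; up[idx] <- up[idx] + 1L
          dn <- kar; dn[idx] <- dn[idx] - 1L
          children_kar <- c(children_kar, list(up), list(dn))
          children_n <- c(children_n, 1L, 1L)
        } else normal <- normal + 1L
      }
    }
    if (ns > 0) {
      for (s in seq_len(ns)) {
        a_i <- sample.int(44L, 1L)
        if (kar[a_i] > 0) {
          up <- kar; up[a_i] <- up[a_i] + 1L
          dn <- kar; dn[a_i] <- dn[a_i] - 1L
          children_kar <- c(children_kar, list(up), list(dn))
          children_n <- c(children_n, 1L, 1L)
        } else normal <- normal + 1L
      }
    }
    kar_out <- c(kar_out, list(kar), children_kar)
    n_out <- c(n_out, stay + 2L * normal, children_n)
  }
  keep <- n_out > 0
  # always keep the first surviving representation of each position
  kar_mat <- do.call(rbind, kar_out)[keep, , drop = FALSE]
  colnames(kar_mat) <- ARM_NAMES
  list(kar = kar_mat, n = n_out[keep])
}

merge_clone_duplicates <- function(state) {
  key <- apply(state$kar, 1, paste, collapse = ",")
  if (!anyDuplicated(key)) return(state)
  first <- !duplicated(key)
  n_new <- as.vector(rowsum(state$n, factor(key, levels = unique(key))))
  list(kar = state$kar[first, , drop = FALSE], n = n_new)
}

## ---- cleavage ------------------------------------------------------------

sample_division_pattern <- function(p_abnormal, config) {
  if (stats::runif(1) < p_abnormal) {
    sample(names(config$abnormal_pattern_weights), 1L,
           prob = config$abnormal_pattern_weights)
  } else "normal"
}

#' Simulate the first cleavage divisions of one zygote
#'
#' Performs the first two (recorded) divisions plus a third normal round.
#' Normal divisions copy each chromosome to both daughters with a small
#' per-chromosome reciprocal missegregation probability. Multipolar
#' division scatters the replicated chromatid complement over 3-4 poles
#' (hypodiploid, partially complementary daughters). Precocious cleavage is
#' a normal split followed by a premature division of one daughter.
#' Reverse cleavage merges the two daughters back into one (tetraploid-like)
#' cell; failed cleavage doubles copy numbers without cytokinesis.
#'
#' @param zygote Named integer arm-copy vector (see [euploid_karyotype()]).
#' @param config A [sim_config()].
#' @param age Maternal age in years (modulates the missegregation rate).
#' @return List with `divisions` (data.frame: division_index, pattern,
#'   cells_after), `cells_after_first_division` (factor level among
#'   1/2/3/4/">4"), and `state` (clone-compressed cell population).
#' @export
simulate_cleavage <- function(zygote, config, age = config$maternal_age_mean) {
  stopifnot(length(zygote) == 48L, all(zygote >= 0))
  pat1 <- sample_division_pattern(config$p_abnormal_first_division, config)
  state <- switch(pat1,
    normal = divide_round(new_state(zygote), config, age),
    multipolar = {
      poles <- sample(c(3L, 4L, 5L), 1L, prob = c(0.8, 0.15, 0.05))
      d <- tripolar_split(zygote, poles)
      list(kar = d, n = rep(1L, nrow(d)))
    },
    precocious = {
      s <- divide_round(new_state(zygote), config, age)
      # one daughter cell divides again prematurely -> 3 cells
      extra <- divide_round(list(kar = s$kar[1, , drop = FALSE], n = 1L),
                            config, age)
      list(kar = rbind(extra$kar, s$kar), n = c(extra$n, s$n - c(1L, rep(0L, length(s$n) - 1L))))
    },
    reverse = new_state(2L * zygote),   # split then resorbed: one 4N cell
    failed = new_state(2L * zygote)     # karyokinesis without cytokinesis
  )
  state$n <- as.integer(state$n)
  keep <- state$n > 0
  state <- list(kar = state$kar[keep, , drop = FALSE], n = state$n[keep])
  cells1 <- state_total(state)
  div1 <- data.frame(division_index = 1L, pattern = pat1,
                     cells_after = cells1, stringsAsFactors = FALSE)

  pat2 <- sample_division_pattern(config$p_abnormal_second_division, config)
  if (pat2 == "normal") {
    state <- divide_round(state, config, age)
  } else {
    # apply the abnormal pattern to one cell, divide the rest normally
    pick <- sample.int(length(state$n), 1L, prob = state$n)
    kar_p <- state$kar[pick, ]
    state$n[pick] <- state$n[pick] - 1L
    rest <- list(kar = state$kar[state$n > 0, , drop = FALSE],
                 n = state$n[state$n > 0])
    if (length(rest$n)) rest <- divide_round(rest, config, age)
    add <- switch(pat2,
      multipolar = ,
      precocious = {
        d <- tripolar_split(kar_p, 3L)
        list(kar = d, n = rep(1L, nrow(d)))
      },
      reverse = ,
      failed = new_state(2L * kar_p)
    )
    state <- list(kar = rbind(rest$kar, add$kar), n = c(rest$n, add$n))
  }
  state <- merge_clone_duplicates(state)
  div2 <- data.frame(division_index = 2L, pattern = pat2,
                     cells_after = state_total(state), stringsAsFactors = FALSE)

  state <- merge_clone_duplicates(divide_round(state, config, age))
  caf <- if (cells1 > 4) ">4" else as.character(cells1)
  list(
    divisions = rbind(div1, div2),
    cells_after_first_division = factor(caf, levels = c("1", "2", "3", "4", ">4")),
    state = state
  )
}

grow_lineage <- function(state, config, age, target_cells, max_rounds = 12L) {
  r <- 0L
  while (state_total(state) < target_cells && r < max_rounds) {
    state <- merge_clone_duplicates(
      divide_round(state, config, age, p_scale = config$cell_division_prob))
    r <- r + 1L
  }
  state
}

# random cell loss down to `max_cells` (degeneration during arrest)
shrink_to <- function(state, max_cells) {
  total <- state_total(state)
  if (total <= max_cells) return(state)
  drop <- sample(rep(seq_along(state$n), state$n), total - max_cells)
  state$n <- state$n - tabulate(drop, length(state$n))
  keep <- state$n > 0
  list(kar = state$kar[keep, , drop = FALSE], n = state$n[keep])
}

## ---- outcome -------------------------------------------------------------

#' Assign developmental outcome, morphology grades, and biopsy day
#'
#' Arrest probability is `plogis(arrest_intercept +
#' arrest_per_chromosome * n_aneuploid + arrest_abnormal_division *
#' abnormal_division + patient_effect)`. Arrested embryos receive a stage
#' (early / mid / late; earlier for more abnormal lineages); blastocysts
#' receive ICM/TE grades from a latent-score ordinal cut model shifted
#' toward D with aneuploidy, and a biopsy day (5-7) whose distribution is
#' shifted 0.22 days later in expectation for aneuploid embryos.
#'
#' @param n_aneuploid Number of whole aneuploid autosomes (population truth).
#' @param abnormal_division 0/1: any abnormal first or second division.
#' @param patient_effect Patient random intercept on the logit scale.
#' @param config A [sim_config()].
#' @return List: outcome ("early_arrest"/"mid_arrest"/"late_arrest"/
#'   "blastocyst"), target_cells, icm_grade, te_grade, biopsy_day (grades
#'   and day are NA for arrested embryos).
#' @export
assign_outcome <- function(n_aneuploid, abnormal_division, patient_effect,
                           config) {
  p_arrest <- stats::plogis(config$arrest_intercept +
                            config$arrest_per_chromosome * n_aneuploid +
                            config$arrest_abnormal_division * abnormal_division +
                            patient_effect)
  if (stats::runif(1) < p_arrest) {
    sev <- n_aneuploid + 2 * abnormal_division
    p_early <- stats::plogis(-1.0 + 0.5 * sev)
    stage <- if (stats::runif(1) < p_early) "early_arrest"
             else sample(c("mid_arrest", "late_arrest"), 1L, prob = c(0.45, 0.55))
    target <- switch(stage,
      early_arrest = sample(4:10, 1L),
      mid_arrest   = sample(12:28, 1L),
      late_arrest  = sample(30:64, 1L))
    list(outcome = stage, target_cells = target,
         icm_grade = NA_character_, te_grade = NA_character_,
         biopsy_day = NA_integer_)
  } else {
    shared <- config$grade_aneuploid_shift * (n_aneuploid > 0) +
      config$grade_per_chromosome_shift * min(n_aneuploid, 6) +
      0.7 * stats::rnorm(1)
    cut_grade <- function(x) {
      c("A", "B", "C", "D")[findInterval(x, config$grade_cuts) + 1L]
    }
    day_probs <- if (n_aneuploid > 0) config$biopsy_day_probs_aneuploid
                 else config$biopsy_day_probs_euploid
    list(outcome = "blastocyst",
         target_cells = sample(90:140, 1L),
         icm_grade = cut_grade(shared + 0.7 * stats::rnorm(1)),
         te_grade = cut_grade(shared + 0.7 * stats::rnorm(1)),
         biopsy_day = sample(5:7, 1L, prob = day_probs))
  }
}

## ---- sampling and reads ----------------------------------------------------

# TE biopsy: contiguous window of k cells in lineage order (wrapping).
sample_biopsy <- function(state, config) {
  cells <- expand_cells(state)
  n <- nrow(cells)
  k <- sample(config$biopsy_cells_min:config$biopsy_cells_max, 1L)
  k <- min(k, n)
  start <- sample.int(n, 1L)
  idx <- ((start - 1L + seq_len(k) - 1L) %% n) + 1L
  cells[idx, , drop = FALSE]
}

#' Simulate binned low-coverage read counts for a sample
#'
#' The expected count in a bin equals `sequencing_depth * (width / bin_size)
#' * (mean copy number of the bin's arm across sampled cells) / 2`, i.e.
#' normalized read depth is linear in mean cell copy number. Counts are
#' negative binomial with overdispersion `read_noise` (Poisson when 0).
#' With probability `qc_fail_rate` the sample is marked as failing quality
#' control and its counts are heavily corrupted.
#'
#' @param cells Integer matrix of sampled cell karyotypes (rows = cells).
#' @param genome A [build_default_genome()] model.
#' @param config A [sim_config()].
#' @param sample_id Identifier stored on the result.
#' @param noise If `FALSE`, return exact (non-integer) expected counts and
#'   never fail QC; used for analytic, noise-free analyses.
#' @return Object of class `binned_counts`: list(sample_id, counts, qc_pass).
#' @export
simulate_reads <- function(cells, genome, config, sample_id = "S1",
                           noise = TRUE) {
  if (is.null(dim(cells)) || nrow(cells) == 0L) {
    stop("sample contains no cells", call. = FALSE)
  }
  arm_copy <- colMeans(cells)
  mu <- config$sequencing_depth * (genome$bins$width / genome$bin_size) *
    arm_copy[bin_arm_index(genome)] / 2
  if (!noise) {
    return(structure(list(sample_id = sample_id, counts = mu, qc_pass = TRUE),
                     class = "binned_counts"))
  }
  qc_pass <- stats::runif(1) >= config$qc_fail_rate
  counts <- if (!qc_pass) {
    # corrupted library: wild bin-to-bin noise swamps the copy-number signal
    stats::rnbinom(length(mu), mu = pmax(mu, 1) * stats::rlnorm(length(mu), 0, 1),
                   size = 0.3)
  } else if (config$read_noise > 0) {
    stats::rnbinom(length(mu), mu = mu, size = 1 / config$read_noise)
  } else {
    stats::rpois(length(mu), mu)
  }
  structure(list(sample_id = sample_id, counts = as.numeric(counts),
                 qc_pass = qc_pass),
            class = "binned_counts")
}

## ---- cohort ----------------------------------------------------------------

#' Simulate a full IVF embryo cohort
#'
#' Orchestrates patients, cycles, meiotic errors, cleavage lineages,
#' outcomes, biopsies, and binned read counts. Fully reproducible given
#' `config$seed`: all randomness flows from one seeded generator.
#'
#' @param config A [sim_config()].
#' @param genome A genome model; defaults to
#'   `build_default_genome(config$bin_size)`.
#' @param include_reads If `FALSE`, skip read-count simulation (the embryo
#'   and division tables and biopsy cell samples are still produced).
#' @return Object of class `embryo_cohort`: list with `embryos`,
#'   `divisions`, `meiotic_truth` data.frames, `samples` (list of cell
#'   matrices with attributes), `counts` (list of `binned_counts`),
#'   `config`, and `genome`.
#' @examples
#' \donttest{
#' coh <- simulate_cohort(sim_config(n_patients = 5, seed = 7))
#' table(coh$embryos$outcome)
#' }
#' @export
simulate_cohort <- function(config = sim_config(), genome = NULL,
                            include_reads = TRUE) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(genome)) genome <- build_default_genome(config$bin_size)
  set.seed(config$seed)

  n_pat <- config$n_patients
  ages <- numeric(n_pat)
  for (i in seq_len(n_pat)) {
    repeat {
      a <- stats::rnorm(1, config$maternal_age_mean, config$maternal_age_sd)
      if (a >= config$maternal_age_min && a <= config$maternal_age_max) break
    }
    ages[i] <- round(a, 1)
  }
  patient_effects <- stats::rnorm(n_pat, 0, config$patient_sd)
  cycles_per_patient <- 1L + stats::rpois(n_pat, config$extra_cycles_mean)

  embryos <- list(); divisions <- list(); meiotic <- list()
  samples <- list(); counts <- list()
  e_i <- 0L; cyc_i <- 0L
  for (p in seq_len(n_pat)) {
    pid <- sprintf("P%03d", p)
    for (cyc in seq_len(cycles_per_patient[p])) {
      cyc_i <- cyc_i + 1L
      cid <- sprintf("C%03d", cyc_i)
      n_zyg <- 1L + stats::rpois(1L, config$zygotes_per_cycle_mean - 1)
      for (z in seq_len(n_zyg)) {
        e_i <- e_i + 1L
        eid <- sprintf("E%04d", e_i)
        sex <- sample(c("XX", "XY"), 1L)
        mei <- sample_meiotic_errors(ages[p], config, sex)
        zygote <- apply_meiotic_errors(euploid_karyotype(sex), mei)
        cl <- simulate_cleavage(zygote, config, ages[p])
        abn <- as.integer(any(cl$divisions$pattern != "normal"))
        n_aneu <- truth_n_aneuploid(cl$state)
        out <- assign_outcome(n_aneu, abn, patient_effects[p], config)
        state <- grow_lineage(cl$state, config, ages[p], out$target_cells)
        if (out$outcome == "early_arrest") {
          state <- shrink_to(state, min(out$target_cells, 10L))
        }
        arrested <- out$outcome != "blastocyst"
        if (arrested && config$arrest_attrition > 0) {
          # degeneration: random cell loss unbalances clone proportions
          total <- state_total(state)
          keep_n <- max(2L, stats::rbinom(1L, total, 1 - config$arrest_attrition))
          state <- shrink_to(state, keep_n)
        }
        cells <- if (arrested) expand_cells(state) else sample_biopsy(state, config)
        sid <- sprintf("S%04d", e_i)
        attr(cells, "sample_id") <- sid
        attr(cells, "embryo_id") <- eid
        attr(cells, "sample_type") <- if (arrested) "whole_arrested" else "TE_biopsy"
        samples[[sid]] <- cells
        if (include_reads) {
          counts[[sid]] <- simulate_reads(cells, genome, config, sid)
        }
        n_aneu_final <- truth_n_aneuploid(state)
        w_cells <- state$n / sum(state$n)
        ploidy <- sum((state$kar[, 1:44, drop = FALSE] %*% rep(1 / 44, 44)) *
                        w_cells)
        embryos[[e_i]] <- data.frame(
          embryo_id = eid, patient_id = pid, cycle_id = cid,
          maternal_age = ages[p], sex = sex,
          outcome = out$outcome, arrested = arrested,
          n_final_cells = state_total(state),
          cells_after_first_division = as.character(cl$cells_after_first_division),
          abnormal_division = abn,
          truth_n_meiotic = sum(mei$chrom %in% AUTOSOMES),
          truth_n_aneuploid = n_aneu,
          truth_n_aneuploid_final = n_aneu_final,
          truth_mean_ploidy = ploidy,
          icm_grade = out$icm_grade, te_grade = out$te_grade,
          biopsy_day = out$biopsy_day,
          sample_id = sid, stringsAsFactors = FALSE)
        cl$divisions$embryo_id <- eid
        divisions[[e_i]] <- cl$divisions
        if (nrow(mei)) {
          mei$embryo_id <- eid
          meiotic[[e_i]] <- mei
        }
      }
    }
  }
  structure(list(
    embryos = do.call(rbind, embryos),
    divisions = do.call(rbind, divisions),
    meiotic_truth = if (length(meiotic)) do.call(rbind, meiotic) else
      data.frame(chrom = character(0), direction = character(0),
                 embryo_id = character(0)),
    samples = samples,
    counts = counts,
    config = config,
    genome = genome
  ), class = "embryo_cohort")
}

#' @export
print.embryo_cohort <- function(x, ...) {
  cat("embryo_cohort:", nrow(x$embryos), "embryos,",
      length(unique(x$embryos$patient_id)), "patients,",
      length(unique(x$embryos$cycle_id)), "cycles\n")
  print(table(x$embryos$outcome))
  invisible(x)
}

#' Write cohort tables (and optionally per-sample binned counts) to disk
#'
#' Emits `embryos.tsv`, `divisions.tsv`, and `meiotic_truth.tsv`, plus, when
#' `write_counts = TRUE`, one BED-like file per sample
#' (`counts/<sample_id>.bed`: chrom, start, end, count).
#'
#' @param cohort An `embryo_cohort`.
#' @param dir Output directory (created if absent).
#' @param write_counts Write per-sample BED-like count files.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir, write_counts = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(d, f) utils::write.table(
    d, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(cohort$embryos, "embryos.tsv")
  wt(cohort$divisions, "divisions.tsv")
  wt(cohort$meiotic_truth, "meiotic_truth.tsv")
  if (write_counts) {
    cdir <- file.path(dir, "counts")
    dir.create(cdir, showWarnings = FALSE)
    bins <- cohort$genome$bins
    for (sid in names(cohort$counts)) {
      bc <- cohort$counts[[sid]]
      utils::write.table(
        data.frame(chrom = bins$chrom, start = bins$start, end = bins$end,
                   count = bc$counts),
        file.path(cdir, paste0(sid, ".bed")),
        sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(dir)
}
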