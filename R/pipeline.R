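## End-to-end pipeline: simulate -> call -> classify -> analyze, plus the
## statistics block recomputed from the packaged reference category counts.

# round half-up at `digits` decimals (printed percentages follow this rule)
round_half_up <- function(x, digits = 0) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Statistics recomputed from the packaged reference category counts
#'
#' The package ships a reference tabulation of a 909-embryo PGT-A cohort:
#' five copy-number categories by outcome (297 whole arrested embryos, 612
#' trophectoderm biopsies), plus cohort totals (1232 normally fertilized
#' zygotes, 622 blastocysts, 610 arrested). This recomputes, from the
#' fixture alone, the category chi-squared, the per-outcome aneuploidy
#' percentages, the overall euploid/aneuploid split, the fraction of
#' arrested embryos tested, and the blastulation rate.
#'
#' @param counts Optional 5x2 data.frame (category, arrested, blastocyst);
#'   defaults to the packaged fixture.
#' @return List of statistics; an integrity error is raised when the
#'   fixture column totals are not 297 and 612.
#' @export
reference_cohort_stats <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- utils::read.delim(system.file(
      "extdata", "reference_category_counts.tsv",
      package = "mosaicArrest", mustWork = TRUE), stringsAsFactors = FALSE)
  }
  totals_df <- utils::read.delim(system.file(
    "extdata", "reference_cohort_totals.tsv",
    package = "mosaicArrest", mustWork = TRUE), stringsAsFactors = FALSE)
  totals <- stats::setNames(totals_df$value, totals_df$quantity)
  tab <- as.matrix(counts[, c("arrested", "blastocyst")])
  rownames(tab) <- counts$category
  if (sum(tab[, "arrested"]) != 297L || sum(tab[, "blastocyst"]) != 612L) {
    stop("fixture integrity error: column totals must be 297 and 612",
         call. = FALSE)
  }
  n_tested <- sum(tab)
  eu <- tab["Euploid", ]
  chi2 <- pearson_chi_squared(tab)
  list(
    table = tab,
    chi_squared = chi2$statistic,
    df = chi2$df,
    p = chi2$p,
    arrested_aneuploidy_pct = (1 - eu[["arrested"]] / 297) * 100,
    blastocyst_aneuploidy_pct = (1 - eu[["blastocyst"]] / 612) * 100,
    overall_euploid_pct = sum(eu) / n_tested * 100,
    overall_aneuploid_pct = (n_tested - sum(eu)) / n_tested * 100,
    arrested_tested_pct = totals[["tested_arrested"]] /
      totals[["arrested"]] * 100,
    blastulation_pct = totals[["blastocysts"]] /
      totals[["zygotes_2pn"]] * 100
  )
}

#' Analyze a called, classified cohort
#'
#' Computes the report blocks: the category-by-outcome table with
#' within-column percentages, chromosome-specific meiotic/mitotic
#' gain/loss counts, per-cycle quasi-binomial age trends for meiotic and
#' mitotic aneuploidy, enrichment tests (arrest x origin, division x
#' origin, division x arrest), a quasi-Poisson complexity model, binomial
#' GLMMs of arrest on category / complexity / first-division cell count
#' with AMEs, the morphology-grade chi-squared, and the biopsy-day LMM.
#'
#' @param cohort An `embryo_cohort`.
#' @param calls Output of [call_cohort()].
#' @param glmm_nodes Quadrature nodes for the GLMMs.
#' @return Object of class `analysis_report` (a list of result blocks).
#' @export
analyze_cohort <- function(cohort, calls, glmm_nodes = 15L) {
  # degenerate cohorts (e.g. an all-euploid null run) make single-level
  # predictors; affected model blocks are reported as NULL, not errors
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  cls <- classify_cohort(cohort, calls)
  emb <- merge(cohort$embryos, cls[, c("embryo_id", "qc_pass", "category",
                                       "n_meiotic", "n_mitotic",
                                       "n_segmental", "n_total")],
               by = "embryo_id", sort = FALSE)
  tested <- emb[emb$qc_pass, ]
  tested$category <- factor(tested$category, levels = embryo_categories())
  tested$has_meiotic <- tested$n_meiotic > 0
  tested$has_mitotic_or_seg <- tested$n_mitotic > 0 | tested$n_segmental > 0
  tested$has_mitotic <- tested$n_mitotic > 0
  tested$aneuploid <- tested$n_total > 0

  table1 <- table(tested$category,
                  factor(ifelse(tested$arrested, "arrested", "blastocyst"),
                         levels = c("arrested", "blastocyst")))
  table1_pct <- sweep(table1, 2, colSums(table1), "/") * 100

  # chromosome-specific whole-autosome counts by origin and direction
  call_rows <- do.call(rbind, lapply(calls[tested$sample_id], function(sc) {
    if (nrow(sc$calls) == 0) return(NULL)
    cbind(sample_id = sc$sample_id, sc$calls)
  }))
  chrom_counts <- if (!is.null(call_rows)) {
    w <- call_rows[call_rows$scope == "whole" &
                   call_rows$origin %in% c("meiotic", "mitotic"), ]
    as.data.frame(table(chrom = factor(w$chrom, levels = AUTOSOMES),
                        origin = w$origin, direction = w$direction))
  } else NULL

  # per-cycle age trends (quasi-binomial; each point is one IVF cycle)
  cyc <- do.call(rbind, lapply(split(tested, tested$cycle_id), function(d) {
    data.frame(age = d$maternal_age[1], n = nrow(d),
               mei = sum(d$has_meiotic), mit = sum(d$has_mitotic_or_seg))
  }))
  age_trend_meiotic <- safe(fit_quasi_glm(cyc$mei, cyc$age, "quasibinomial",
                                          trials = cyc$n))
  age_trend_mitotic <- safe(fit_quasi_glm(cyc$mit, cyc$age, "quasibinomial",
                                          trials = cyc$n))

  xtab <- function(a, b) table(factor(a, levels = c(TRUE, FALSE)),
                               factor(b, levels = c(TRUE, FALSE)))
  enrichment <- list(
    arrest_meiotic = fisher_exact(xtab(tested$arrested, tested$has_meiotic)),
    arrest_mitotic = fisher_exact(xtab(tested$arrested,
                                       tested$has_mitotic_or_seg)),
    division_mitotic = fisher_exact(xtab(tested$abnormal_division == 1,
                                         tested$has_mitotic_or_seg)),
    division_meiotic = fisher_exact(xtab(tested$abnormal_division == 1,
                                         tested$has_meiotic)),
    division_arrest = fisher_exact(xtab(tested$abnormal_division == 1,
                                        tested$arrested))
  )

  complexity_model <- safe(fit_quasi_glm(tested$n_total,
                                         factor(tested$has_mitotic_or_seg,
                                                levels = c(FALSE, TRUE)),
                                         "quasipoisson"))

  glmm_category <- safe(fit_binomial_glmm(as.integer(tested$arrested),
                                          tested$category, tested$patient_id,
                                          nodes = glmm_nodes))
  ame_category <- if (!is.null(glmm_category) && glmm_category$converged)
    safe(average_marginal_effect(glmm_category)) else NULL
  glmm_complexity <- safe(fit_binomial_glmm(as.integer(tested$arrested),
                                            pmin(tested$n_total, 10L),
                                            tested$patient_id,
                                            nodes = glmm_nodes))
  ame_complexity <- if (!is.null(glmm_complexity) && glmm_complexity$converged)
    safe(average_marginal_effect(glmm_complexity)) else NULL
  glmm_division <- safe(fit_binomial_glmm(
    as.integer(tested$arrested),
    factor(tested$cells_after_first_division,
           levels = c("2", "1", "3", "4", ">4")),
    tested$patient_id, nodes = glmm_nodes))

  bl <- tested[!tested$arrested & !is.na(tested$icm_grade), ]
  bl$grade_pair <- paste0(bl$icm_grade, bl$te_grade)
  grade_tab <- table(bl$grade_pair, factor(bl$aneuploid,
                                           levels = c(FALSE, TRUE)))
  grade_tab <- grade_tab[rowSums(grade_tab) >= 5, , drop = FALSE]
  morphology_test <- if (nrow(grade_tab) >= 2 && all(colSums(grade_tab) > 0))
    pearson_chi_squared(grade_tab) else NULL
  grade_aneuploidy_pct <- if (nrow(grade_tab))
    grade_tab[, "TRUE"] / rowSums(grade_tab) * 100 else NULL

  biopsy_day_model <- safe(fit_lmm(bl$biopsy_day, as.integer(bl$aneuploid),
                                   bl$patient_id))

  structure(list(
    n_embryos = nrow(emb),
    n_tested = nrow(tested),
    n_qc_excluded = sum(!emb$qc_pass),
    table1 = table1,
    table1_pct = round_half_up(table1_pct),
    chrom_counts = chrom_counts,
    age_trend_meiotic = age_trend_meiotic,
    age_trend_mitotic = age_trend_mitotic,
    enrichment = enrichment,
    complexity_model = complexity_model,
    glmm_category = glmm_category,
    ame_category = ame_category,
    glmm_complexity = glmm_complexity,
    ame_complexity = ame_complexity,
    glmm_division = glmm_division,
    morphology_test = morphology_test,
    grade_aneuploidy_pct = grade_aneuploidy_pct,
    biopsy_day_model = biopsy_day_model,
    embryo_table = tested
  ), class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("analysis_report:", x$n_embryos, "embryos,", x$n_tested,
      "tested (", x$n_qc_excluded, "QC-excluded )\n\n")
  cat("category x outcome (counts):\n"); print(x$table1)
  cat("\ncategory x outcome (column %):\n"); print(x$table1_pct)
  if (!is.null(x$age_trend_meiotic)) {
    cat("\nage trend, meiotic: "); print(x$age_trend_meiotic)
  }
  if (!is.null(x$age_trend_mitotic)) {
    cat("age trend, mitotic: "); print(x$age_trend_mitotic)
  }
  cat("\ndivision x mitotic aneuploidy: ")
  print(x$enrichment$division_mitotic)
  cat("division x arrest: "); print(x$enrichment$division_arrest)
  if (!is.null(x$biopsy_day_model)) {
    cat("\nbiopsy day: "); print(x$biopsy_day_model)
  }
  invisible(x)
}

#' Run the full pipeline
#'
#' simulate -> call -> classify -> analyze, deterministic given the config
#' seed. With `outdir`, every intermediate table is serialized (embryos,
#' divisions, calls, per-embryo categories, report blocks) so that each
#' report number is traceable to an intermediate TSV.
#'
#' @param config A [sim_config()], or the path to a YAML config file.
#' @param outdir Optional output directory.
#' @param glmm_nodes Quadrature nodes for the GLMMs.
#' @param write_counts Also write per-sample BED-like binned counts.
#' @return An `analysis_report` (invisibly contains the embryo table).
#' @export
run_pipeline <- function(config, outdir = NULL, glmm_nodes = 15L,
                         write_counts = FALSE) {
  if (is.character(config)) config <- read_sim_config(config)
  stopifnot(inherits(config, "sim_config"))
  cohort <- simulate_cohort(config)
  calls <- call_cohort(cohort)
  report <- analyze_cohort(cohort, calls, glmm_nodes = glmm_nodes)
  if (!is.null(outdir)) {
    write_cohort(cohort, outdir, write_counts = write_counts)
    write_calls(calls, file.path(outdir, "calls.tsv"))
    cls <- classify_cohort(cohort, calls)
    utils::write.table(cls, file.path(outdir, "categories.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_report(report, file.path(outdir, "report.md"))
    log <- c(paste("seed:", config$seed),
             paste("config_hash:",
                   sum(utils::head(utf8ToInt(paste(
                     names(unlist(config)), unlist(config), collapse = ";")),
                     1e5))),
             paste("qc_excluded:", report$n_qc_excluded))
    writeLines(log, file.path(outdir, "pipeline.log"))
  }
  report
}

#' Write a human-readable Markdown report
#'
#' @param report An `analysis_report`.
#' @param path Output file.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(paste0(...), con)
  w("# Cohort analysis report")
  w("")
  w("Embryos: ", report$n_embryos, "; tested: ", report$n_tested,
    "; QC-excluded: ", report$n_qc_excluded)
  w("")
  w("## Category by outcome")
  tab <- report$table1
  pct <- report$table1_pct
  w("| category | arrested | blastocyst |")
  w("|---|---|---|")
  for (r in rownames(tab)) {
    w("| ", r, " | ", tab[r, 1], " (", pct[r, 1], "%) | ",
      tab[r, 2], " (", pct[r, 2], "%) |")
  }
  w("")
  if (!is.null(report$age_trend_meiotic)) {
    w("## Age trends (quasi-binomial, per cycle)")
    w("- meiotic: beta = ", signif(report$age_trend_meiotic$coefficient, 3),
      ", SE = ", signif(report$age_trend_meiotic$se, 3))
    w("- mitotic: beta = ", signif(report$age_trend_mitotic$coefficient, 3),
      ", SE = ", signif(report$age_trend_mitotic$se, 3))
    w("")
  }
  w("## Enrichment (Fisher exact; unadjusted p-values, as reported)")
  for (nm in names(report$enrichment)) {
    e <- report$enrichment[[nm]]
    w("- ", nm, ": OR = ", signif(e$odds_ratio, 3), " [",
      signif(e$ci95[1], 3), ", ", signif(e$ci95[2], 3), "], p = ",
      format.pval(e$p, digits = 3))
  }
  w("")
  if (!is.null(report$ame_category)) {
    w("## Arrest GLMM (category; AME vs euploid)")
    a <- report$ame_category
    for (i in seq_len(nrow(a))) {
      w("- ", a$level[i], ": AME = ", signif(a$ame[i], 3),
        " [", signif(a$ci_low[i], 3), ", ", signif(a$ci_high[i], 3), "]")
    }
    w("")
  }
  if (!is.null(report$biopsy_day_model)) {
    w("## Biopsy day (LMM)")
    w("- AME = ", signif(report$biopsy_day_model$ame, 3), ", SE = ",
      signif(report$biopsy_day_model$ame_se, 3))
  }
  invisible(path)
}
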