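## Five mutually exclusive copy-number categories per embryo, and complexity
## counts (number of aneuploid chromosomes).

#' The five copy-number categories
#'
#' Factor levels, in display order: "Euploid", "Meiotic only", "Meiotic plus
#' mitotic and/or seg", "Mitotic only", "Mitotic and/or seg".
#' @return Character vector of the five category labels.
#' @export
embryo_categories <- function() {
  c("Euploid", "Meiotic only", "Meiotic plus mitotic and/or seg",
    "Mitotic only", "Mitotic and/or seg")
}

#' Assign an embryo to one of the five copy-number categories
#'
#' Sex-chromosome calls never affect the assignment (their origin cannot be
#' stratified). Over the autosomal calls: none -> Euploid; meiotic
#' whole-chromosome only -> "Meiotic only"; meiotic together with mitotic
#' whole-chromosome or segmental -> "Meiotic plus mitotic and/or seg";
#' mitotic whole-chromosome only -> "Mitotic only"; segmental present
#' without meiotic (with or without mitotic whole) -> "Mitotic and/or seg".
#' The categories are mutually exclusive and exhaustive.
#'
#' @param calls data.frame of calls (chrom, scope, direction, displacement,
#'   origin) for one sample, or a `sample_calls` object.
#' @return Factor of length 1 with levels [embryo_categories()].
#' @export
categorize_calls <- function(calls) {
  if (inherits(calls, "sample_calls")) {
    if (!calls$qc_pass) return(factor(NA, levels = embryo_categories()))
    calls <- calls$calls
  }
  calls <- calls[!(calls$chrom %in% c("chrX", "chrY")), , drop = FALSE]
  has_mei <- any(calls$scope == "whole" & calls$origin == "meiotic")
  has_mit <- any(calls$scope == "whole" & calls$origin == "mitotic")
  has_seg <- any(calls$scope != "whole")
  lab <- if (!has_mei && !has_mit && !has_seg) "Euploid"
    else if (has_mei && !has_mit && !has_seg) "Meiotic only"
    else if (has_mei) "Meiotic plus mitotic and/or seg"
    else if (has_mit && !has_seg) "Mitotic only"
    else "Mitotic and/or seg"
  factor(lab, levels = embryo_categories())
}

#' Count aneuploid chromosomes per origin class
#'
#' Counts distinct autosomes per class; a chromosome bearing both whole and
#' segmental events counts once toward the total. The binned total follows
#' the 0 / 1 / 2 / 3 / 4 / ">=5" convention.
#'
#' @inheritParams categorize_calls
#' @return List: n_meiotic_whole_autosome, n_mitotic_whole_autosome,
#'   n_segmental, n_total_aneuploid_chromosomes, binned_total (factor).
#' @export
count_complexity <- function(calls) {
  if (inherits(calls, "sample_calls")) calls <- calls$calls
  calls <- calls[!(calls$chrom %in% c("chrX", "chrY")), , drop = FALSE]
  n_mei <- length(unique(calls$chrom[calls$scope == "whole" &
                                     calls$origin == "meiotic"]))
  n_mit <- length(unique(calls$chrom[calls$scope == "whole" &
                                     calls$origin == "mitotic"]))
  n_seg <- length(unique(calls$chrom[calls$scope != "whole"]))
  n_total <- length(unique(calls$chrom))
  bins <- c("0", "1", "2", "3", "4", ">=5")
  list(
    n_meiotic_whole_autosome = n_mei,
    n_mitotic_whole_autosome = n_mit,
    n_segmental = n_seg,
    n_total_aneuploid_chromosomes = n_total,
    binned_total = factor(if (n_total >= 5) ">=5" else as.character(n_total),
                          levels = bins)
  )
}

#' Per-embryo category table for a called cohort
#'
#' @param cohort An `embryo_cohort`.
#' @param calls Output of [call_cohort()].
#' @return data.frame: embryo_id, sample_id, qc_pass, category, n_meiotic,
#'   n_mitotic, n_segmental, n_total, outcome (one row per embryo).
#' @export
classify_cohort <- function(cohort, calls) {
  emb <- cohort$embryos
  rows <- lapply(seq_len(nrow(emb)), function(i) {
    sc <- calls[[emb$sample_id[i]]]
    if (is.null(sc) || !sc$qc_pass) {
      data.frame(embryo_id = emb$embryo_id[i], sample_id = emb$sample_id[i],
                 qc_pass = FALSE, category = NA_character_,
                 n_meiotic = NA_integer_, n_mitotic = NA_integer_,
                 n_segmental = NA_integer_, n_total = NA_integer_,
                 outcome = emb$outcome[i], stringsAsFactors = FALSE)
    } else {
      cx <- count_complexity(sc)
      data.frame(embryo_id = emb$embryo_id[i], sample_id = emb$sample_id[i],
                 qc_pass = TRUE,
                 category = as.character(categorize_calls(sc)),
                 n_meiotic = cx$n_meiotic_whole_autosome,
                 n_mitotic = cx$n_mitotic_whole_autosome,
                 n_segmental = cx$n_segmental,
                 n_total = cx$n_total_aneuploid_chromosomes,
                 outcome = emb$outcome[i], stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, rows)
}
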