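#' Build the default genome model
#'
#' Constructs the shared chromosome/bin coordinate system used by the
#' simulator and the copy-number caller. Chromosome lengths and centromere
#' positions (approximate GRCh38) are packaged constants; no reference
#' sequence is read. Bins tile each chromosome arm in 0-based half-open
#' `[start, end)` intervals of `bin_size`; a bin never spans the centromere,
#' so the bin containing it is truncated and a fresh bin starts at the
#' centromere. The last bin of each arm may be short.
#'
#' @param bin_size Bin width in bp. Must be at least 100 kb.
#' @return An object of class `genome_model`: a list with `chromosomes`
#'   (data.frame: name, length, centromere, is_autosome), `bin_size`, and
#'   `bins` (data.frame: chrom, start, end, arm, width).
#' @examples
#' gm <- build_default_genome(1e6)
#' sum(gm$bins$chrom == "chr21")
#' @export
build_default_genome <- function(bin_size = 1e6) {
  if (!is.numeric(bin_size) || length(bin_size) != 1L || is.na(bin_size) ||
      bin_size < 1e5) {
    stop("`bin_size` must be a single number >= 100000 bp", call. = FALSE)
  }
  bin_size <- as.numeric(bin_size)
  path <- system.file("extdata", "grch38_karyotype.tsv",
                      package = "mosaicArrest", mustWork = TRUE)
  chroms <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(
    nrow(chroms) == 24L,
    sum(chroms$is_autosome) == 22L,
    all(chroms$length > 0), all(chroms$centromere > 0),
    all(chroms$centromere < chroms$length)
  )
  bins <- do.call(rbind, lapply(seq_len(nrow(chroms)), function(i) {
    len <- chroms$length[i]
    cen <- chroms$centromere[i]
    p_starts <- seq(0, cen - 1, by = bin_size)
    q_starts <- seq(cen, len - 1, by = bin_size)
    data.frame(
      chrom = chroms$name[i],
      start = c(p_starts, q_starts),
      end   = c(pmin(p_starts + bin_size, cen), pmin(q_starts + bin_size, len)),
      arm   = rep(c("p", "q"), c(length(p_starts), length(q_starts))),
      stringsAsFactors = FALSE
    )
  }))
  bins$width <- bins$end - bins$start
  rownames(bins) <- NULL
  structure(
    list(chromosomes = chroms, bin_size = bin_size, bins = bins),
    class = "genome_model"
  )
}

#' @export
print.genome_model <- function(x, ...) {
  cat("genome_model:", nrow(x$chromosomes), "chromosomes,",
      nrow(x$bins), "bins of", format(x$bin_size, big.mark = ","), "bp\n")
  invisible(x)
}

# arm labels in fixed order: chr1.p, chr1.q, ..., chrY.q
genome_arm_names <- function(genome) {
  as.vector(t(outer(genome$chromosomes$name, c("p", "q"), paste, sep = ".")))
}

# index of each bin into the arm vector above
bin_arm_index <- function(genome) {
  match(paste(genome$bins$chrom, genome$bins$arm, sep = "."),
        genome_arm_names(genome))
}

autosome_names <- function(genome) {
  genome$chromosomes$name[genome$chromosomes$is_autosome]
}
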