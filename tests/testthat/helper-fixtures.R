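# Shared fixtures: all built in code at test time.

# a genome at coarse resolution keeps unit tests fast where bin-level
# resolution does not matter
test_genome <- function(bin_size = 1e6) build_default_genome(bin_size)

# biopsy of n cells, k of which carry a whole-chromosome event
mosaic_cells <- function(n, k, chrom = "chr16", direction = "gain",
                         sex = "XX") {
  base <- euploid_karyotype(sex)
  cells <- matrix(rep(base, n), nrow = n, byrow = TRUE,
                  dimnames = list(NULL, names(base)))
  if (k > 0) {
    idx <- paste0(chrom, c(".p", ".q"))
    delta <- if (direction == "gain") 1L else -1L
    cells[seq_len(k), idx] <- cells[seq_len(k), idx] + delta
  }
  cells
}

# exact expected counts (no sampling noise, QC always passes)
noise_free_counts <- function(cells, genome, depth = 100,
                              sample_id = "NF1") {
  cfg <- sim_config(sequencing_depth = depth)
  simulate_reads(cells, genome, cfg, sample_id = sample_id, noise = FALSE)
}

# analytic threshold classifier: the independent oracle for displacement f
# (fraction of a full copy change, in percent)
oracle_class <- function(d) {
  if (d < 30) "disomy" else if (d <= 70) "mitotic" else "meiotic"
}

# a call data.frame row in the package's schema
call_row <- function(chrom, scope = "whole", direction = "gain",
                     displacement = 100, origin = "meiotic") {
  data.frame(chrom = chrom, scope = scope, direction = direction,
             displacement = displacement, origin = origin,
             stringsAsFactors = FALSE)
}

no_calls <- function() {
  data.frame(chrom = character(0), scope = character(0),
             direction = character(0), displacement = numeric(0),
             origin = character(0), stringsAsFactors = FALSE)
}
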