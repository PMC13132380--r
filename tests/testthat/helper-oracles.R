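# Shared fixtures and independent oracles for the test suite.

# Brute-force oracle for the exact conditional count test: direct log-space
# tail summation of P(y | x) = (x+y)! / (x! y! 2^(x+y+1)), conditioning on
# the larger count. Deliberately independent of the pnbinom-based
# implementation.
ac_pvalue_brute <- function(x1, x2) {
  hi <- max(x1, x2); lo <- min(x1, x2)
  logp <- function(y) lgamma(hi + y + 1) - lgamma(hi + 1) - lgamma(y + 1) -
    (hi + y + 1) * log(2)
  lower <- sum(exp(logp(0:lo)))
  upper <- 1 - if (lo > 0) sum(exp(logp(0:(lo - 1)))) else 0
  min(1, 2 * min(lower, upper))
}

# Planted simulator state -> CBS label.
state_to_label <- c(K4_HIGH = "CLUSTER_I_K4_HIGH",
                    K27_HIGH = "CLUSTER_II_K27_HIGH",
                    EQUAL = "CLUSTER_III_EQUAL",
                    NONBIVALENT_ACTIVE = "NONBIVALENT",
                    NONBIVALENT_SILENT = "NONBIVALENT")

# A tiny hand-built annotation used across core_io tests.
tiny_annotation <- function() {
  data.frame(
    gene_id = c("gA", "gB", "gC"),
    chrom = c("chr1", "chr1", "chr2"),
    strand = c("+", "-", "+"),
    tss = c(1000L, 8000L, 500L),
    biotype = c("protein_coding", "protein_coding", "lncRNA"),
    stringsAsFactors = FALSE)
}

write_tmp_bed <- function(lines) {
  f <- tempfile(fileext = ".bed")
  writeLines(lines, f)
  f
}

# Run bona fide calling on a simulation for one condition.
call_condition <- function(sim, cond = "A") {
  sep <- call_bivalent_separate(sim$peaks[[cond]]$k4, sim$peaks[[cond]]$k27,
                                sim$promoters)
  sq <- call_bivalent_sequential(sim$peaks[[cond]]$seq, sim$promoters)
  bona_fide_bivalent(sep, sq)
}

# Build program instances for cluster_programs tests without running NMF.
manual_instance <- function(sample_id, k, factor_index, genes) {
  new_program_instance(sample_id, k, factor_index, genes,
                       stats::setNames(rep(1, length(genes)), genes))
}
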