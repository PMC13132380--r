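# Bona fide bivalent promoters: genes positive in BOTH the separate H3K4me3 +
# H3K27me3 ChIP-seq intersection and the sequential (re-ChIP) assay. The
# intersection is at gene level — a promoter with several qualifying peaks
# still counts once.

#' Genes bivalent by separate ChIP-seq
#'
#' A gene qualifies when its promoter window is occupied by at least one
#' H3K4me3 peak and at least one H3K27me3 peak.
#'
#' @param k4,k27 `PeakSet`s for the two marks; their labels must differ (equal
#'   labels almost certainly mean the same file was passed twice).
#' @param prom A `PromoterSet`.
#' @return Character vector of gene ids.
#' @export
call_bivalent_separate <- function(k4, k27, prom) {
  stopifnot(inherits(k4, "PeakSet"), inherits(k27, "PeakSet"))
  if (identical(k4$label, k27$label))
    stop("the two peak sets carry the same label ('", k4$label,
         "'); expected distinct marks")
  occ4 <- overlap_promoters(k4, prom)
  occ27 <- overlap_promoters(k27, prom)
  occ4$gene_id[occ4$occupied & occ27$occupied]
}

#' Genes bivalent by sequential (re-ChIP) ChIP-seq
#'
#' @param seq_peaks `PeakSet` from the sequential H3K27me3->H3K4me3 ChIP.
#' @param prom A `PromoterSet`.
#' @return Character vector of gene ids.
#' @export
call_bivalent_sequential <- function(seq_peaks, prom) {
  occ <- overlap_promoters(seq_peaks, prom)
  occ$gene_id[occ$occupied]
}

#' Bona fide bivalent genes and Venn summary
#'
#' Bona fide = intersection of the separate-ChIP and sequential-ChIP gene
#' sets, both drawn from the same promoter universe.
#'
#' @param sep Character vector from [call_bivalent_separate()].
#' @param seq Character vector from [call_bivalent_sequential()].
#' @return A list with `calls` (data.frame `gene_id`, `by_separate`,
#'   `by_sequential`, `bona_fide` over the union of the two sets) and `venn`
#'   (`n_sequential`, `n_separate`, `n_overlap`).
#' @export
bona_fide_bivalent <- function(sep, seq) {
  sep <- unique(as.character(sep))
  seq <- unique(as.character(seq))
  universe <- union(sep, seq)
  calls <- data.frame(
    gene_id = universe,
    by_separate = universe %in% sep,
    by_sequential = universe %in% seq,
    stringsAsFactors = FALSE)
  calls$bona_fide <- calls$by_separate & calls$by_sequential
  venn <- list(n_sequential = length(seq),
               n_separate = length(sep),
               n_overlap = sum(calls$bona_fide))
  list(calls = calls, venn = venn)
}

#' Fraction of bivalent promoters occupied by a factor
#'
#' E.g. the fraction of bona fide bivalent promoters carrying a beta-catenin
#' or PRC2-subunit peak (any >= 1 bp overlap with the promoter window).
#'
#' @param factor_peaks `PeakSet` of the factor.
#' @param bivalent Non-empty character vector of bivalent gene ids.
#' @param prom A `PromoterSet` covering the bivalent genes.
#' @return A single number in \[0, 1\].
#' @export
cooccupancy_fraction <- function(factor_peaks, bivalent, prom) {
  bivalent <- unique(as.character(bivalent))
  if (length(bivalent) == 0L)
    stop("bivalent gene set is empty; co-occupancy fraction undefined")
  occ <- overlap_promoters(factor_peaks, prom)
  missing <- setdiff(bivalent, occ$gene_id)
  if (length(missing))
    stop("bivalent gene(s) absent from promoter set: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  mean(occ$occupied[match(bivalent, occ$gene_id)])
}
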