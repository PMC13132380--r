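# Coordinate convention: everything crossing the package boundary (BED files,
# annotation TSS columns) is 0-based half-open, BED-native. Internally ranges
# are held in GRanges (1-based closed); the conversion lives only in the
# readers/writers in this file, so overlap arithmetic downstream is unambiguous
# (a peak ending exactly at a promoter start never overlaps).

#' Construct a peak set
#'
#' A `PeakSet` bundles a label (mark or factor name, e.g. `"H3K4me3"` or
#' `"beta-catenin"`) with a [GenomicRanges::GRanges] of peak intervals and an
#' optional non-negative `score` metadata column (peak height/intensity).
#'
#' @param ranges A `GRanges`; may carry a numeric `score` metadata column
#'   (`NA` allowed, meaning "no score").
#' @param label Single character label for the mark/factor.
#' @return An object of class `PeakSet`.
#' @export
new_peak_set <- function(ranges, label) {
  if (!methods::is(ranges, "GRanges"))
    stop("'ranges' must be a GRanges")
  if (!is.character(label) || length(label) != 1L || is.na(label))
    stop("'label' must be a single character string")
  sc <- S4Vectors::mcols(ranges)$score
  if (!is.null(sc)) {
    bad <- !is.na(sc) & (!is.finite(sc) | sc < 0)
    if (any(bad))
      stop("peak scores must be non-negative and finite")
  } else {
    S4Vectors::mcols(ranges)$score <- rep(NA_real_, length(ranges))
  }
  structure(list(label = label, ranges = ranges), class = "PeakSet")
}

#' @export
length.PeakSet <- function(x) length(x$ranges)

#' @export
print.PeakSet <- function(x, ...) {
  cat(sprintf("PeakSet '%s': %d peaks on %d sequence(s)\n",
              x$label, length(x$ranges),
              length(unique(as.character(GenomicRanges::seqnames(x$ranges))))))
  invisible(x)
}

#' Read a BED3/BED5 peak file
#'
#' Coordinates are taken as BED-native 0-based half-open. Column 5, when
#' present and numeric, is used as the peak score; a non-numeric placeholder
#' (`"."`) yields a missing score. `track`/`browser`/`#` lines are skipped.
#'
#' @param path Path to a BED file (plain text).
#' @param label Label for the resulting [new_peak_set()]; defaults to the
#'   filename stem.
#' @return A `PeakSet`.
#' @export
read_bed <- function(path, label = NULL) {
  if (!file.exists(path))
    stop("BED file not found: ", path)
  if (is.null(label))
    label <- sub("\\.bed$", "", basename(path), ignore.case = TRUE)
  lines <- readLines(path)
  keep <- which(nzchar(trimws(lines)) &
                  !grepl("^(#|track\\b|browser\\b)", lines))
  if (!length(keep))
    return(new_peak_set(GenomicRanges::GRanges(), label))
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 3L))
    stop("BED parse error at line ", keep[which(nf < 3L)[1L]],
         ": fewer than 3 fields")
  chrom <- vapply(fields, `[[`, character(1L), 1L)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 2L)))
  end   <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1L), 3L)))
  bad <- which(!is.finite(start) | !is.finite(end) |
                 start != floor(start) | end != floor(end))
  if (length(bad))
    stop("BED parse error at line ", keep[bad[1L]],
         ": non-integer coordinates")
  bad <- which(start < 0)
  if (length(bad))
    stop("BED parse error at line ", keep[bad[1L]], ": negative start")
  bad <- which(start >= end)
  if (length(bad))
    stop("BED parse error at line ", keep[bad[1L]], ": start >= end")
  score <- rep(NA_real_, length(keep))
  has5 <- nf >= 5L
  if (any(has5)) {
    score[has5] <- suppressWarnings(
      as.numeric(vapply(fields[has5], `[[`, character(1L), 5L)))
  }
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end),
                               score = score)
  new_peak_set(gr, label)
}

#' Write a peak set to BED
#'
#' Writes BED3 when no peak carries a score, BED5 (with `"."` names) when any
#' does, converting back to 0-based half-open coordinates so that
#' `read_bed(write_bed(x))` round-trips intervals and scores exactly.
#'
#' @param peaks A `PeakSet`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(peaks, path) {
  stopifnot(inherits(peaks, "PeakSet"))
  gr <- peaks$ranges
  if (length(gr) == 0L) {
    writeLines(character(0L), path)
    return(invisible(path))
  }
  df <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end   = GenomicRanges::end(gr))
  sc <- S4Vectors::mcols(gr)$score
  if (any(!is.na(sc))) {
    df$name <- "."
    df$score <- ifelse(is.na(sc), ".",
                       format(sc, scientific = FALSE, trim = TRUE, digits = 15))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a gene annotation table
#'
#' Tab-separated with header columns `gene_id`, `chrom`, `strand`, `tss`,
#' `biotype`. The TSS is a single 0-based coordinate per gene; collapsing of
#' multi-TSS genes is the caller's responsibility upstream.
#'
#' @param path Path to the TSV.
#' @return A validated `data.frame`.
#' @export
read_annotation <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  validate_annotation(ann)
}

#' Validate a gene annotation table
#'
#' @param ann A data.frame with columns `gene_id`, `chrom`, `strand`, `tss`,
#'   `biotype`.
#' @return The annotation, with the Unicode minus normalized to `"-"`.
#' @export
validate_annotation <- function(ann) {
  need <- c("gene_id", "chrom", "strand", "tss", "biotype")
  miss <- setdiff(need, names(ann))
  if (length(miss))
    stop("annotation is missing column(s): ", paste(miss, collapse = ", "))
  if (anyDuplicated(ann$gene_id))
    stop("annotation gene_id values must be unique")
  ann$strand <- gsub("−", "-", ann$strand)
  if (!all(ann$strand %in% c("+", "-")))
    stop("annotation strand must be '+' or '-'")
  if (!is.numeric(ann$tss) || any(!is.finite(ann$tss)) || any(ann$tss < 0))
    stop("annotation tss must be non-negative finite numbers")
  ann
}

#' Build strand-aware promoter windows around each TSS
#'
#' For a `+` strand gene the window is `[tss - upstream_bp, tss + downstream_bp)`
#' and for a `-` strand gene `[tss - downstream_bp, tss + upstream_bp)`, in
#' 0-based half-open coordinates, clamped at position 0 (clamped rather than
#' dropped, so gene universes stay aligned across marks).
#'
#' @param ann Annotation data.frame (see [read_annotation()]).
#' @param upstream_bp,downstream_bp Positive window half-sizes in bp
#'   (default 1000 each, i.e. TSS +/- 1 kb).
#' @param biotype_filter Optional biotype to retain (e.g. `"protein_coding"`).
#' @return A `PromoterSet`: gene_id-named promoter intervals plus the window
#'   parameters and the annotation rows used.
#' @export
make_promoters <- function(ann, upstream_bp = 1000L, downstream_bp = 1000L,
                           biotype_filter = NULL) {
  ann <- validate_annotation(ann)
  if (upstream_bp <= 0 || downstream_bp <= 0)
    stop("window sizes must be positive")
  if (!is.null(biotype_filter))
    ann <- ann[ann$biotype %in% biotype_filter, , drop = FALSE]
  if (nrow(ann) == 0L)
    stop("no promoters: annotation empty after biotype filtering")
  plus <- ann$strand == "+"
  start0 <- ifelse(plus, ann$tss - upstream_bp, ann$tss - downstream_bp)
  end0   <- ifelse(plus, ann$tss + downstream_bp, ann$tss + upstream_bp)
  start0 <- pmax(0, start0)
  gr <- GenomicRanges::GRanges(ann$chrom,
                               IRanges::IRanges(start0 + 1L, end0),
                               strand = ann$strand,
                               gene_id = ann$gene_id)
  names(gr) <- ann$gene_id
  structure(list(ranges = gr,
                 upstream_bp = upstream_bp,
                 downstream_bp = downstream_bp,
                 annotation = ann),
            class = "PromoterSet")
}

#' @export
length.PromoterSet <- function(x) length(x$ranges)

#' @export
print.PromoterSet <- function(x, ...) {
  cat(sprintf("PromoterSet: %d promoters (TSS -%d/+%d bp)\n",
              length(x$ranges), x$upstream_bp, x$downstream_bp))
  invisible(x)
}

#' Promoter occupancy of a peak set
#'
#' A promoter is occupied when at least one peak overlaps its window by >= 1 bp
#' (half-open semantics: a peak ending exactly at the window start does not
#' count). The reported intensity is the maximum score among overlapping peaks,
#' 0 when there is none or scores are absent.
#'
#' @param peaks A `PeakSet`.
#' @param promoters A `PromoterSet` (must be non-empty).
#' @return A data.frame with columns `gene_id`, `occupied`, `intensity`, one
#'   row per promoter, in promoter order.
#' @export
overlap_promoters <- function(peaks, promoters) {
  stopifnot(inherits(peaks, "PeakSet"), inherits(promoters, "PromoterSet"))
  if (length(promoters$ranges) == 0L)
    stop("promoter set is empty")
  n <- length(promoters$ranges)
  occupied <- logical(n)
  intensity <- numeric(n)
  if (length(peaks$ranges) > 0L) {
    hits <- suppressWarnings(
      GenomicRanges::findOverlaps(promoters$ranges, peaks$ranges))
    qh <- S4Vectors::queryHits(hits)
    occupied[unique(qh)] <- TRUE
    sc <- S4Vectors::mcols(peaks$ranges)$score[S4Vectors::subjectHits(hits)]
    sc[is.na(sc)] <- 0
    if (length(qh)) {
      mx <- tapply(sc, qh, max)
      intensity[as.integer(names(mx))] <- as.numeric(mx)
    }
  }
  data.frame(gene_id = names(promoters$ranges),
             occupied = occupied,
             intensity = intensity,
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Read a gene-by-sample matrix from TSV
#'
#' First column `gene_id`, remaining columns one per sample. Used both for
#' promoter signal matrices and gene expression tables.
#'
#' @param path Path to the TSV.
#' @return A numeric matrix with gene rownames and sample colnames.
#' @export
read_matrix_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L)
    stop("matrix TSV needs a gene_id column plus at least one sample column")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- df[[1L]]
  if (anyDuplicated(rownames(m)))
    stop("duplicate gene ids in matrix")
  m
}

#' Write a gene-by-sample matrix to TSV
#'
#' @param m Numeric matrix with rownames (genes) and colnames (samples).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  df <- data.frame(gene_id = rownames(m), m,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Validate a promoter signal matrix
#'
#' Entries must be non-negative and finite; row (gene) and column (sample)
#' names unique. The notion of "signal" is deliberately agnostic: any
#' non-negative per-promoter peak-height summary qualifies.
#'
#' @param m Numeric matrix.
#' @return `m`, invisibly, after validation.
#' @export
validate_signal_matrix <- function(m) {
  if (!is.matrix(m) || !is.numeric(m))
    stop("signal matrix must be a numeric matrix")
  if (is.null(rownames(m)) || anyDuplicated(rownames(m)))
    stop("signal matrix needs unique gene rownames")
  if (is.null(colnames(m)) || anyDuplicated(colnames(m)))
    stop("signal matrix needs unique sample colnames")
  if (any(!is.finite(m)) || any(m < 0))
    stop("signal matrix entries must be non-negative and finite")
  invisible(m)
}
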