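# Quantitative between-condition comparison of promoter mark intensity:
# M-A rescaling fitted on commonly occupied promoters, an exact conditional
# count test on the normalized intensities, and the significance rule
# P < 0.05 together with |log2FC| >= 0.58 (both FC boundaries inclusive).

#' M-A transform of paired intensities
#'
#' `M = log2((x1 + c) / (x2 + c))`, `A = (log2(x1 + c) + log2(x2 + c)) / 2`.
#' The pseudocount may be 0 when all intensities are strictly positive.
#'
#' @param x1,x2 Non-negative finite intensity vectors.
#' @param pseudocount Non-negative pseudocount `c` (default 1).
#' @return data.frame with columns `M` and `A`.
#' @export
ma_transform <- function(x1, x2, pseudocount = 1) {
  if (length(x1) != length(x2)) stop("x1 and x2 must have equal length")
  if (any(!is.finite(x1)) || any(!is.finite(x2)) || any(x1 < 0) || any(x2 < 0))
    stop("intensities must be non-negative and finite")
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  l1 <- log2(x1 + pseudocount)
  l2 <- log2(x2 + pseudocount)
  if (any(!is.finite(l1)) || any(!is.finite(l2)))
    stop("zero intensity with zero pseudocount gives non-finite M/A")
  data.frame(M = l1 - l2, A = (l1 + l2) / 2)
}

#' Fit the M-A normalization model on common promoters
#'
#' Ordinary least squares of `M = a + b * A` on promoters occupied in both
#' conditions, followed by one robustness pass dropping points with
#' `|residual| > 3 * MAD` and refitting. The rescaling rule is
#' `log2(x2') = log2(x2 + c) + a + b * A`, which drives the median M of the
#' common subset to ~0.
#'
#' @param M,A Numeric vectors (common promoters only).
#' @param min_points Minimum number of common points (default 10).
#' @param mad_pass Run the single MAD-based outlier-removal pass (default
#'   TRUE).
#' @return A `NormalizationModel` list: `a`, `b`, `n_used`.
#' @export
fit_normalization <- function(M, A, min_points = 10L, mad_pass = TRUE) {
  if (length(M) != length(A)) stop("M and A must have equal length")
  if (length(M) < min_points)
    stop("need >= ", min_points, " common promoters to fit normalization (got ",
         length(M), ")")
  if (stats::sd(A) == 0)
    stop("all A values identical; check the intensity input")
  fit <- stats::lm.fit(cbind(1, A), M)
  if (mad_pass) {
    r <- fit$residuals
    s <- stats::mad(r)
    keep <- if (s > 0) abs(r) <= 3 * s else rep(TRUE, length(r))
    if (sum(keep) >= min_points && stats::sd(A[keep]) > 0)
      fit <- stats::lm.fit(cbind(1, A[keep]), M[keep])
  }
  structure(list(a = unname(fit$coefficients[1L]),
                 b = unname(fit$coefficients[2L]),
                 n_used = length(fit$residuals)),
            class = "NormalizationModel")
}

#' @export
print.NormalizationModel <- function(x, ...) {
  cat(sprintf("M-A normalization: M = %.4f + %.4f * A (fit on %d promoters)\n",
              x$a, x$b, x$n_used))
  invisible(x)
}

# pmf of the exact conditional count model: P(y | x) = (x+y)! / (x! y! 2^(x+y+1)),
# i.e. NegBinomial(size = x + 1, prob = 1/2) in y.
exact_count_pmf <- function(y, x) {
  stats::dnbinom(y, size = x + 1, prob = 0.5)
}

#' Exact conditional count test p-value
#'
#' Two-sided p-value for the difference of two (rounded, normalized) counts
#' under the null `P(y | x) = (x + y)! / (x! y! 2^(x + y + 1))`:
#' `p = min(1, 2 * min(P(Y <= lo | hi), P(Y >= lo | hi)))`, where the pair is
#' ordered so that the conditioning count is the larger of the two. The
#' ordering makes the test exchangeable in the two samples
#' (`p(x1, x2) == p(x2, x1)`); for `x1 >= x2` it coincides with conditioning
#' on the first sample. Tails are computed through the negative-binomial
#' identity, which is evaluated in log space internally and is exact for
#' large counts.
#'
#' @param x1,x2 Non-negative integer counts (vectors recycle).
#' @return p-values in (0, 1\].
#' @export
exact_count_pvalue <- function(x1, x2) {
  if (any(!is.finite(x1)) || any(!is.finite(x2)) ||
      any(x1 < 0) || any(x2 < 0))
    stop("counts must be non-negative and finite")
  if (any(x1 != round(x1)) || any(x2 != round(x2)))
    stop("counts must be integers (round normalized intensities first)")
  n <- max(length(x1), length(x2))
  x1 <- rep_len(x1, n); x2 <- rep_len(x2, n)
  hi <- pmax(x1, x2)
  lo <- pmin(x1, x2)
  lower <- stats::pnbinom(lo, size = hi + 1, prob = 0.5)
  upper <- stats::pnbinom(lo - 1, size = hi + 1, prob = 0.5,
                          lower.tail = FALSE)
  pmin(1, 2 * pmin(lower, upper))
}

#' Differential promoter marking between two conditions
#'
#' Fits the M-A normalization on common promoters (both raw intensities above
#' `floor`), rescales condition 2, recomputes the log2 fold-change, tests each
#' gene with [exact_count_pvalue()] on the rounded normalized intensities, and
#' applies the significance rule: `p < alpha` AND
#' (`log2FC >= lfc_threshold` OR `log2FC <= -lfc_threshold`) — the fold-change
#' boundary is inclusive, the p boundary strict.
#'
#' @param x1,x2 Named non-negative intensity vectors over the same gene
#'   universe (condition 1 and condition 2).
#' @param genes Genes to report (default: the full shared universe).
#' @param mark Optional mark label stored in the result.
#' @param alpha P-value cutoff (strict; default 0.05).
#' @param lfc_threshold Absolute log2 fold-change cutoff (inclusive; default
#'   0.58).
#' @param pseudocount Pseudocount for the M-A transform (default 1).
#' @param floor Occupancy floor: genes with both raw intensities > `floor`
#'   are "common" and used for the fit (default 0).
#' @param fdr Apply Benjamini-Hochberg correction and test the adjusted
#'   p-value against `alpha` instead (extension; default FALSE, matching a
#'   raw-p analysis).
#' @return data.frame of per-gene results: raw and normalized intensities,
#'   `log2FC`, `p_value` (and `p_adj` when `fdr`), `significant`, `direction`.
#' @export
call_differential <- function(x1, x2, genes = NULL, mark = NA_character_,
                              alpha = 0.05, lfc_threshold = 0.58,
                              pseudocount = 1, floor = 0, fdr = FALSE) {
  if (is.null(names(x1)) || is.null(names(x2)))
    stop("x1 and x2 must be named by gene id")
  if (!setequal(names(x1), names(x2)))
    stop("x1 and x2 cover different gene universes")
  x2 <- x2[names(x1)]
  if (is.null(genes)) genes <- names(x1)
  missing <- setdiff(genes, names(x1))
  if (length(missing))
    stop("requested gene(s) not in the universe: ",
         paste(utils::head(missing, 3L), collapse = ", "))

  ma <- ma_transform(x1, x2, pseudocount)
  common <- x1 > floor & x2 > floor
  model <- fit_normalization(ma$M[common], ma$A[common])
  m_norm <- ma$M - (model$a + model$b * ma$A)
  x2_norm <- pmax(0, 2^(log2(x2 + pseudocount) + model$a + model$b * ma$A) -
                    pseudocount)
  p <- exact_count_pvalue(round(x1), round(x2_norm))

  res <- data.frame(
    gene_id = names(x1),
    mark = mark,
    x1 = unname(x1),
    x2_normalized = unname(x2_norm),
    log2FC = unname(m_norm),
    p_value = unname(p),
    stringsAsFactors = FALSE)
  crit_p <- if (fdr) {
    res$p_adj <- stats::p.adjust(res$p_value, method = "BH")
    res$p_adj < alpha
  } else res$p_value < alpha
  pass_fc <- res$log2FC >= lfc_threshold | res$log2FC <= -lfc_threshold
  res$significant <- crit_p & pass_fc
  res$direction <- ifelse(!res$significant, "none",
                          ifelse(res$log2FC > 0, "up", "down"))
  attr(res, "normalization") <- model
  res[match(genes, res$gene_id), , drop = FALSE]
}
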