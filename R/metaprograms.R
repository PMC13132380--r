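# Recurrent-NMF meta-programs: per-sample NMF over a sweep of ranks, each
# factor summarized as its top-90 genes, instances filtered for recurrence
# across ranks within a sample, then greedily clustered across samples by
# Jaccard similarity of their gene sets.

#' Construct a program instance
#'
#' One NMF factor from one sample at one rank, summarized by its top-scoring
#' genes.
#'
#' @param sample_id Sample identifier.
#' @param k Factorization rank the factor came from.
#' @param factor_index Column index of the factor within that factorization.
#' @param genes Character vector of the top genes (highest loadings first).
#' @param scores Named non-negative loading vector over all genes (normalized
#'   to max 1 so scores are comparable across factorizations).
#' @return A `ProgramInstance` list.
#' @export
new_program_instance <- function(sample_id, k, factor_index, genes, scores) {
  if (any(scores < 0)) stop("program scores must be non-negative")
  structure(list(sample_id = sample_id, k = as.integer(k),
                 factor_index = as.integer(factor_index),
                 genes = as.character(genes), scores = scores),
            class = "ProgramInstance")
}

#' Preprocess an expression matrix for NMF
#'
#' `log1p` transform followed by per-gene clipping at a high quantile
#' (tempering rare extreme cells); no centering, keeping the matrix
#' non-negative as NMF requires.
#'
#' @param expr Non-negative matrix (genes x cells).
#' @param clip_quantile Per-gene upper clipping quantile (default 0.999).
#' @return Transformed matrix.
#' @export
preprocess_expression <- function(expr, clip_quantile = 0.999) {
  if (any(expr < 0)) stop("expression must be non-negative")
  m <- log1p(expr)
  caps <- apply(m, 1L, stats::quantile, probs = clip_quantile, names = FALSE)
  pmin(m, matrix(caps, nrow(m), ncol(m)))
}

#' Run a rank sweep of NMF on one sample
#'
#' Factorizes the (preprocessed) matrix at every rank in `ks` and emits one
#' [new_program_instance()] per factor, its gene set being the `n_top` genes
#' with the highest loadings in that factor. Ranks exceeding the matrix
#' dimensions are skipped with a warning.
#'
#' @param expr Non-negative matrix (genes x cells) with gene rownames.
#' @param ks Integer ranks (default 4:9).
#' @param n_top Genes per program (default 90; capped at the number of
#'   genes).
#' @param seed Seed forwarded to [nmf_factorize()].
#' @param sample_id Sample identifier attached to the instances.
#' @param preprocess Apply [preprocess_expression()] first (default TRUE).
#' @return List of `ProgramInstance`s (length `sum(ks)` when none skipped).
#' @export
run_nmf_sweep <- function(expr, ks = 4:9, n_top = 90L, seed = 1L,
                          sample_id = "sample", preprocess = TRUE) {
  if (is.null(rownames(expr))) stop("expr needs gene rownames")
  if (any(expr < 0)) stop("expression must be non-negative")
  if (nrow(expr) < n_top)
    n_top <- nrow(expr)
  V <- if (preprocess) preprocess_expression(expr) else expr
  out <- list()
  for (k in ks) {
    if (k > min(dim(V))) {
      warning("skipping k = ", k, ": exceeds matrix dimensions")
      next
    }
    fit <- nmf_factorize(V, k, seed = seed)
    for (j in seq_len(k)) {
      w <- fit$W[, j]
      mx <- max(w)
      scores <- stats::setNames(if (mx > 0) w / mx else w, rownames(V))
      top <- rownames(V)[order(-w, seq_along(w))][seq_len(n_top)]
      out[[length(out) + 1L]] <-
        new_program_instance(sample_id, k, j, top, scores)
    }
  }
  out
}

#' Jaccard similarity of two gene sets
#'
#' `|a intersect b| / |a union b|`; 0 when both sets are empty.
#'
#' @param a,b Character vectors (treated as sets).
#' @return A number in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0L) return(0)
  length(intersect(a, b)) / u
}

#' Cluster recurrent NMF programs into meta-programs
#'
#' Greedy agglomeration: (1) discard instances without a within-sample
#' partner at a different rank with Jaccard >= `j_min_within` (so each kept
#' program recurs across at least `min_k_recurrence` ranks; the within-sample
#' threshold is deliberately stricter than the cross-sample one — a factor is
#' only a robust program when nearly the same gene set reappears at another
#' rank, which also screens out rank-specific merged factors and background
#' factors); (2) seed a cluster from
#' the instance with the most cross-sample partners at Jaccard >= `j_min`;
#' (3) absorb all its partnered instances and take as consensus the `n_top`
#' genes most frequent across members (ties broken by summed normalized
#' score); (4) remove them and repeat; (5) keep only clusters spanning at
#' least `min_samples` distinct samples. Fully deterministic: instances are
#' ordered by (sample, k, factor) and all ties break on that order.
#'
#' @param instances List of `ProgramInstance`s.
#' @param j_min Cross-sample Jaccard threshold for partnership (default 0.2).
#' @param j_min_within Within-sample, cross-rank Jaccard threshold for the
#'   recurrence filter (default 0.7).
#' @param min_samples Minimum distinct samples per meta-program (default 2).
#' @param min_k_recurrence Minimum distinct ranks a program must recur at
#'   within its sample (default 2).
#' @param n_top Consensus gene-set size (default 90).
#' @return List of `MetaProgram`s: `mp_id`, `members` (data.frame),
#'   `consensus` genes, `support` = (n_samples, n_k).
#' @export
cluster_programs <- function(instances, j_min = 0.2, j_min_within = 0.7,
                             min_samples = 2L,
                             min_k_recurrence = 2L, n_top = 90L) {
  if (!length(instances)) stop("no program instances supplied")
  ord <- order(vapply(instances, `[[`, character(1L), "sample_id"),
               vapply(instances, `[[`, integer(1L), "k"),
               vapply(instances, `[[`, integer(1L), "factor_index"))
  instances <- instances[ord]
  n <- length(instances)
  samp <- vapply(instances, `[[`, character(1L), "sample_id")
  kk <- vapply(instances, `[[`, integer(1L), "k")
  sets <- lapply(instances, `[[`, "genes")

  J <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (j > i) J[i, j] <- jaccard(sets[[i]], sets[[j]])
    }
  }
  J <- J + t(J); diag(J) <- 1

  # (1) within-sample rank recurrence
  keep <- vapply(seq_len(n), function(i) {
    partners <- which(samp == samp[i] & kk != kk[i] & J[i, ] >= j_min_within)
    length(unique(c(kk[i], kk[partners]))) >= min_k_recurrence
  }, logical(1L))
  alive <- which(keep)

  mps <- list()
  while (length(alive)) {
    cross <- vapply(alive, function(i)
      sum(samp[alive] != samp[i] & J[i, alive] >= j_min), integer(1L))
    if (max(cross) == 0L) break
    seed_i <- alive[which.max(cross)]  # which.max: first max in sorted order
    members <- alive[J[seed_i, alive] >= j_min]
    member_inst <- instances[members]

    freq <- table(unlist(lapply(member_inst, `[[`, "genes")))
    score_sum <- Reduce(`+`, lapply(member_inst, function(p) {
      s <- p$scores[names(freq)]
      s[is.na(s)] <- 0
      unname(s)
    }))
    o <- order(-as.integer(freq), -score_sum, names(freq))
    consensus <- names(freq)[o][seq_len(min(n_top, length(freq)))]

    mps[[length(mps) + 1L]] <- structure(list(
      mp_id = sprintf("MP%02d", length(mps) + 1L),
      members = data.frame(
        sample_id = samp[members], k = kk[members],
        factor_index = vapply(member_inst, `[[`, integer(1L), "factor_index"),
        stringsAsFactors = FALSE),
      consensus = consensus,
      support = c(n_samples = length(unique(samp[members])),
                  n_k = length(unique(kk[members])))),
      class = "MetaProgram")
    alive <- setdiff(alive, members)
  }
  mps[vapply(mps, function(mp) mp$support[["n_samples"]] >= min_samples,
             logical(1L))]
}

#' @export
print.MetaProgram <- function(x, ...) {
  cat(sprintf("%s: %d member programs, %d samples, %d ranks; consensus %d genes\n",
              x$mp_id, nrow(x$members), x$support[["n_samples"]],
              x$support[["n_k"]], length(x$consensus)))
  invisible(x)
}
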