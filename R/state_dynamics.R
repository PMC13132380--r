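# Chromatin bivalency states (CBS): bivalent promoters are split by the ratio
# of their H3K4me3 to H3K27me3 intensity into cluster I (H3K4me3-high,
# ratio >= 1.5), cluster II (H3K27me3-high, inverse ratio >= 1.5) and
# cluster III (equal, |log ratio| < log 1.5); boundaries are inclusive toward
# the high clusters. Non-bivalent genes carry the NONBIVALENT label.

#' CBS label levels
#' @return Character vector of the four labels, cluster I/II/III plus
#'   NONBIVALENT.
#' @export
cbs_levels <- function() {
  c("CLUSTER_I_K4_HIGH", "CLUSTER_II_K27_HIGH", "CLUSTER_III_EQUAL",
    "NONBIVALENT")
}

#' Classify bivalent promoters into chromatin bivalency states
#'
#' `r = (k4 + c) / (k27 + c)`; `r >= fc_threshold` gives cluster I,
#' `1/r >= fc_threshold` cluster II, otherwise cluster III. The two high
#' conditions are mutually exclusive for any `fc_threshold > 1`.
#'
#' @param k4,k27 Non-negative intensity vectors (recycled to equal length).
#' @param fc_threshold Fold-change boundary, inclusive (default 1.5).
#' @param pseudocount Ratio pseudocount guarding zero intensities (default
#'   0.5).
#' @return Character vector of labels among the first three of
#'   [cbs_levels()].
#' @export
classify_cbs <- function(k4, k27, fc_threshold = 1.5, pseudocount = 0.5) {
  if (any(!is.finite(k4)) || any(!is.finite(k27)) ||
      any(k4 < 0) || any(k27 < 0))
    stop("intensities must be non-negative and finite")
  if (fc_threshold <= 1) stop("fc_threshold must be > 1")
  n <- max(length(k4), length(k27))
  k4 <- rep_len(k4, n); k27 <- rep_len(k27, n)
  r <- (k4 + pseudocount) / (k27 + pseudocount)
  ifelse(r >= fc_threshold, "CLUSTER_I_K4_HIGH",
         ifelse(1 / r >= fc_threshold, "CLUSTER_II_K27_HIGH",
                "CLUSTER_III_EQUAL"))
}

#' Assign CBS labels over a gene universe for one condition
#'
#' Bivalent genes are classified by [classify_cbs()] from their promoter
#' intensities; all other genes get `NONBIVALENT`.
#'
#' @param k4,k27 Named intensity vectors over the gene universe.
#' @param bivalent Character vector of (bona fide) bivalent gene ids.
#' @param condition Condition id stored with the assignment.
#' @param fc_threshold,pseudocount Passed to [classify_cbs()].
#' @return A `StateAssignment`: list with `condition`, named `labels`,
#'   `fc_threshold`, and the intensities used.
#' @export
assign_states <- function(k4, k27, bivalent, condition = "cond",
                          fc_threshold = 1.5, pseudocount = 0.5) {
  if (is.null(names(k4)) || !identical(names(k4), names(k27)))
    stop("k4 and k27 must be named identically by gene id")
  labels <- stats::setNames(rep("NONBIVALENT", length(k4)), names(k4))
  biv <- intersect(unique(as.character(bivalent)), names(k4))
  labels[biv] <- classify_cbs(k4[biv], k27[biv], fc_threshold, pseudocount)
  structure(list(condition = condition, labels = labels,
                 fc_threshold = fc_threshold,
                 k4 = k4, k27 = k27),
            class = "StateAssignment")
}

#' CBS transitions between two conditions
#'
#' One record per gene in the union of the two assignments; a gene present in
#' (or bivalent in) only one condition is recorded with `NONBIVALENT` on the
#' other side. Counts form the alluvial-ready contingency table over ordered
#' label pairs.
#'
#' @param a,b `StateAssignment`s (or named label vectors); must share at
#'   least one gene.
#' @return A `TransitionTable`: list with `records` (data.frame `gene_id`,
#'   `from`, `to`) and `counts` (4 x 4 table over [cbs_levels()]).
#' @export
transition_table <- function(a, b) {
  la <- if (inherits(a, "StateAssignment")) a$labels else a
  lb <- if (inherits(b, "StateAssignment")) b$labels else b
  if (is.null(names(la)) || is.null(names(lb)))
    stop("assignments must be named by gene id")
  if (!length(intersect(names(la), names(lb))))
    stop("assignments share no genes; check the inputs")
  genes <- union(names(la), names(lb))
  from <- ifelse(genes %in% names(la), la[genes], "NONBIVALENT")
  to <- ifelse(genes %in% names(lb), lb[genes], "NONBIVALENT")
  records <- data.frame(gene_id = genes, from = from, to = to,
                        row.names = NULL, stringsAsFactors = FALSE)
  counts <- table(factor(from, levels = cbs_levels()),
                  factor(to, levels = cbs_levels()),
                  dnn = c("from", "to"))
  structure(list(records = records, counts = counts),
            class = "TransitionTable")
}

#' @export
print.TransitionTable <- function(x, ...) {
  cat("CBS transition counts:\n")
  print(x$counts)
  invisible(x)
}

#' Fraction of bivalency-switch genes with increased expression
#'
#' A switch is, by default, resolution toward the active state: cluster II ->
#' cluster I or cluster III -> cluster I. The fraction is the share of switch
#' genes with expression log2 fold-change > 0.
#'
#' @param tt A `TransitionTable`.
#' @param expression_lfc Named numeric vector of per-gene expression log2
#'   fold-changes covering every switch gene.
#' @param switch_definition List of `c(from, to)` label pairs (default
#'   II->I and III->I).
#' @return List with `fraction` and `n_switch`.
#' @export
switch_expression_fraction <- function(tt, expression_lfc,
                                       switch_definition = list(
                                         c("CLUSTER_II_K27_HIGH",
                                           "CLUSTER_I_K4_HIGH"),
                                         c("CLUSTER_III_EQUAL",
                                           "CLUSTER_I_K4_HIGH"))) {
  stopifnot(inherits(tt, "TransitionTable"))
  key <- paste(tt$records$from, tt$records$to, sep = "->")
  want <- vapply(switch_definition, function(p) paste(p, collapse = "->"),
                 character(1L))
  sw <- tt$records$gene_id[key %in% want]
  if (!length(sw))
    stop("no switch genes under the given definition; fraction undefined")
  missing <- setdiff(sw, names(expression_lfc))
  if (length(missing))
    stop("switch gene(s) without an expression value: ",
         paste(utils::head(missing, 3L), collapse = ", "))
  list(fraction = mean(expression_lfc[sw] > 0), n_switch = length(sw))
}

#' Correlation of bivalency change with expression change
#'
#' Pearson correlation of per-gene mark log2 fold-change against expression
#' log2 fold-change, with a two-sided p-value from the t transform on n - 2
#' degrees of freedom (via [stats::cor.test]).
#'
#' @param delta_mark,delta_expr Numeric vectors; when both are named, genes
#'   are matched by name, otherwise by position. At least 3 finite pairs
#'   required.
#' @return List with `r`, `p_value`, `n`.
#' @export
bivalency_expression_correlation <- function(delta_mark, delta_expr) {
  if (!is.null(names(delta_mark)) && !is.null(names(delta_expr))) {
    shared <- intersect(names(delta_mark), names(delta_expr))
    delta_mark <- delta_mark[shared]
    delta_expr <- delta_expr[shared]
  }
  if (length(delta_mark) != length(delta_expr))
    stop("unnamed inputs must have equal length")
  ok <- is.finite(delta_mark) & is.finite(delta_expr)
  x <- delta_mark[ok]; y <- delta_expr[ok]
  if (length(x) < 3L) stop("need >= 3 paired finite values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' k-means cross-check of the CBS threshold labels
#'
#' Diagnostic only: runs k-means (k = 3, 50 restarts, fixed seed) on
#' `(log2 k4, log2 k27)` of the bivalent genes, maps each k-means cluster to
#' its majority CBS label, and reports the agreement fraction. The threshold
#' rule remains the primary classifier; this mirrors running a k-means pass
#' over the same intensities as an independent view.
#'
#' @param k4,k27 Intensities of bivalent genes.
#' @param labels Their CBS labels from [classify_cbs()].
#' @param pseudocount Log pseudocount (default 0.5).
#' @param seed RNG seed for the restarts.
#' @return Agreement fraction in \[0, 1\].
#' @export
cbs_kmeans_concordance <- function(k4, k27, labels, pseudocount = 0.5,
                                   seed = 1L) {
  if (length(unique(labels)) < 2L)
    return(1)
  with_seed(seed, {
    km <- stats::kmeans(cbind(log2(k4 + pseudocount),
                              log2(k27 + pseudocount)),
                        centers = 3L, nstart = 50L)
    mapped <- vapply(seq_len(3L), function(cl) {
      names(which.max(table(labels[km$cluster == cl])))
    }, character(1L))
    mean(mapped[km$cluster] == labels)
  })
}
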