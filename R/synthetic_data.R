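# Synthetic genomes, ChIP peak sets and expression with planted truth.
# The generators define the study conditions the test-suite runs under; every
# one is bit-reproducible given its seed and leaves the caller's RNG untouched.

#' Chromatin state labels used by the simulator
#'
#' Three bivalent states (H3K4me3-high, H3K27me3-high, equal) plus two
#' non-bivalent ones (active = H3K4me3 only, silent = neither mark).
#'
#' @return Character vector of the five state names.
#' @export
sim_states <- function() {
  c("K4_HIGH", "K27_HIGH", "EQUAL", "NONBIVALENT_ACTIVE", "NONBIVALENT_SILENT")
}

#' States counted as bivalent
#' @return Character vector of the three bivalent state names.
#' @export
bivalent_states <- function() c("K4_HIGH", "K27_HIGH", "EQUAL")

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("seed must be a single finite number")
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Simulation configuration
#'
#' Defaults encode the study conditions the package is validated under: a
#' 30% bivalent genome (10% H3K4me3-high, 12% H3K27me3-high, 8% equal), state
#' mean intensities separated enough that the 1.5-fold classification rule is
#' unambiguous, log-normal multiplicative locus noise, a 10% state-switch
#' fraction between conditions, and an 85% probability that a switch toward
#' the H3K4me3-high state comes with increased expression.
#'
#' @param n_genes Number of genes.
#' @param state_fractions Named fractions over [sim_states()], summing to 1.
#' @param mean_intensity Named list state -> c(k4, k27) positive mean
#'   intensities.
#' @param noise_sigma SD (natural-log scale) of the log-normal multiplicative
#'   locus noise shared by the two marks at a promoter within a condition.
#' @param switch_fraction Fraction of genes whose state changes from condition
#'   A to condition B (drawn from H3K27me3-high/equal genes, moved to
#'   H3K4me3-high).
#' @param coupling_prob Probability that a switch-to-K4-high gene receives a
#'   positive expression log2 fold-change.
#' @param seed Integer seed.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 1000L,
                       state_fractions = c(K4_HIGH = 0.10, K27_HIGH = 0.12,
                                           EQUAL = 0.08,
                                           NONBIVALENT_ACTIVE = 0.35,
                                           NONBIVALENT_SILENT = 0.35),
                       mean_intensity = list(
                         K4_HIGH = c(k4 = 8,   k27 = 2),
                         K27_HIGH = c(k4 = 2,  k27 = 8),
                         EQUAL = c(k4 = 5,     k27 = 5),
                         NONBIVALENT_ACTIVE = c(k4 = 8,   k27 = 0.5),
                         NONBIVALENT_SILENT = c(k4 = 0.5, k27 = 0.5)),
                       noise_sigma = 0.3,
                       switch_fraction = 0.1,
                       coupling_prob = 0.85,
                       seed = 1L) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  if (!setequal(names(state_fractions), sim_states()))
    stop("state_fractions must be named by sim_states()")
  state_fractions <- state_fractions[sim_states()]
  if (abs(sum(state_fractions) - 1) > 1e-9)
    stop("state_fractions must sum to 1")
  if (any(state_fractions < 0)) stop("state_fractions must be non-negative")
  if (!setequal(names(mean_intensity), sim_states()))
    stop("mean_intensity must be named by sim_states()")
  mus <- unlist(mean_intensity)
  if (any(!is.finite(mus)) || any(mus <= 0))
    stop("all mean intensities must be positive")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  if (switch_fraction < 0 || switch_fraction > 1)
    stop("switch_fraction must be in [0, 1]")
  if (coupling_prob < 0 || coupling_prob > 1)
    stop("coupling_prob must be in [0, 1]")
  structure(list(n_genes = as.integer(n_genes),
                 state_fractions = state_fractions,
                 mean_intensity = mean_intensity[sim_states()],
                 noise_sigma = noise_sigma,
                 switch_fraction = switch_fraction,
                 coupling_prob = coupling_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Largest-remainder apportionment of n among fractions; ties broken by
# enumeration order of the fractions vector.
largest_remainder <- function(fractions, n) {
  raw <- fractions * n
  counts <- floor(raw)
  short <- n - sum(counts)
  if (short > 0) {
    ord <- order(-(raw - counts), seq_along(fractions))
    counts[ord[seq_len(short)]] <- counts[ord[seq_len(short)]] + 1
  }
  stats::setNames(as.integer(counts), names(fractions))
}

#' Simulate a gene annotation
#'
#' TSS positions are spaced 10 kb apart along chromosomes of 500 genes each,
#' so default 1 kb promoter windows never overlap; strands are drawn from the
#' seed. Deterministic given `(n_genes, seed)`.
#'
#' @param n_genes Number of genes (>= 1).
#' @param seed Integer seed.
#' @param prop_noncoding Fraction of genes labelled `"lncRNA"` instead of
#'   `"protein_coding"` (default 0).
#' @return An annotation data.frame (see [read_annotation()]).
#' @export
simulate_genome <- function(n_genes, seed, prop_noncoding = 0) {
  if (n_genes < 1L) stop("n_genes must be >= 1")
  with_seed(seed, {
    per_chrom <- 500L
    idx <- seq_len(n_genes) - 1L
    chrom <- paste0("chr", idx %/% per_chrom + 1L)
    tss <- (idx %% per_chrom) * 10000L + 5000L
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    biotype <- rep("protein_coding", n_genes)
    if (prop_noncoding > 0) {
      n_nc <- round(prop_noncoding * n_genes)
      if (n_nc > 0)
        biotype[sample.int(n_genes, n_nc)] <- "lncRNA"
    }
    data.frame(gene_id = sprintf("G%05d", seq_len(n_genes)),
               chrom = chrom, strand = strand, tss = tss,
               biotype = biotype, stringsAsFactors = FALSE)
  })
}

# Draw per-gene mark intensities for one condition: a single log-normal locus
# factor exp(eps), eps ~ N(0, sigma^2), scales both marks at a promoter
# (locus-level efficiency/accessibility); state means carry the mark contrast.
draw_intensities <- function(states, cfg) {
  mu_k4 <- vapply(cfg$mean_intensity, `[[`, numeric(1L), "k4")[states]
  mu_k27 <- vapply(cfg$mean_intensity, `[[`, numeric(1L), "k27")[states]
  eps <- exp(stats::rnorm(length(states), 0, cfg$noise_sigma))
  cbind(H3K4me3 = mu_k4 * eps, H3K27me3 = mu_k27 * eps)
}

#' Simulate ChIP-seq peak sets and promoter signal for two conditions
#'
#' Each gene is assigned a planted chromatin state per condition (counts follow
#' largest-remainder rounding of the configured fractions). Mark intensities
#' are the state means under multiplicative log-normal locus noise; a separate
#' ChIP peak is emitted at the promoter when the mark's intensity exceeds twice
#' the silent-state mean, and a sequential (re-ChIP) peak is emitted exactly at
#' planted-bivalent promoters. Between conditions, a `switch_fraction` subset
#' of genes moves from the H3K27me3-high or equal state to H3K4me3-high,
#' mimicking bivalency resolution under treatment pressure.
#'
#' @param ann Annotation data.frame (typically from [simulate_genome()]).
#' @param cfg A [sim_config()].
#' @return A list with elements `peaks` (per condition: `PeakSet`s `k4`,
#'   `k27`, `seq`), `signal` (per condition: gene x mark matrix; 0 where no
#'   peak was emitted), `truth` (data.frame of planted states and flags),
#'   and `promoters` (the `PromoterSet` used).
#' @export
simulate_chip <- function(ann, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  ann <- validate_annotation(ann)
  n <- nrow(ann)
  promoters <- make_promoters(ann)
  with_seed(cfg$seed, {
    counts <- largest_remainder(cfg$state_fractions, n)
    state_a <- sample(rep(sim_states(), counts))
    candidates <- which(state_a %in% c("K27_HIGH", "EQUAL"))
    n_switch <- min(round(cfg$switch_fraction * n), length(candidates))
    switch_idx <- if (n_switch > 0) sample(candidates, n_switch) else integer(0)
    state_b <- state_a
    state_b[switch_idx] <- "K4_HIGH"

    silent_mu <- cfg$mean_intensity$NONBIVALENT_SILENT
    thr <- 2 * silent_mu  # per-mark emission threshold

    build_condition <- function(states) {
      x <- draw_intensities(states, cfg)
      emitted <- sweep(x, 2L, c(thr[["k4"]], thr[["k27"]]), `>`)
      signal <- x * emitted
      rownames(signal) <- ann$gene_id
      biv <- states %in% bivalent_states()
      mk_peaks <- function(sel, scores, label) {
        gr <- promoters$ranges[sel]
        S4Vectors::mcols(gr) <- NULL
        S4Vectors::mcols(gr)$score <- scores
        names(gr) <- NULL
        new_peak_set(gr, label)
      }
      list(
        k4 = mk_peaks(emitted[, 1L], x[emitted[, 1L], 1L], "H3K4me3"),
        k27 = mk_peaks(emitted[, 2L], x[emitted[, 2L], 2L], "H3K27me3"),
        seq = mk_peaks(biv, pmin(x[biv, 1L], x[biv, 2L]), "sequential_K27-K4"),
        signal = signal)
    }
    cond_a <- build_condition(state_a)
    cond_b <- build_condition(state_b)

    truth <- data.frame(
      gene_id = ann$gene_id,
      state_a = state_a,
      state_b = state_b,
      is_bivalent_a = state_a %in% bivalent_states(),
      is_bivalent_b = state_b %in% bivalent_states(),
      is_switch = seq_len(n) %in% switch_idx,
      stringsAsFactors = FALSE)

    list(peaks = list(A = cond_a[c("k4", "k27", "seq")],
                      B = cond_b[c("k4", "k27", "seq")]),
         signal = list(A = cond_a$signal, B = cond_b$signal),
         truth = truth,
         promoters = promoters)
  })
}

#' Simulate expression log2 fold-changes coupled to bivalency switches
#'
#' Genes that switch to the H3K4me3-high state receive a positive log2
#' fold-change with probability `coupling_prob` (negative otherwise), with
#' magnitudes drawn from Gamma(shape = 2, scale = 0.75) (mean 1.5 log2 units);
#' non-switch genes draw from Normal(0, 1).
#'
#' @param truth Planted-truth data.frame from [simulate_chip()].
#' @param cfg The [sim_config()] used (its `coupling_prob` and `seed` apply;
#'   the expression stream is seeded at `seed + 1` so it is independent of the
#'   ChIP draw but still fully determined by the config).
#' @return A data.frame `gene_id`, `lfc`, `is_switch`, `planted_sign`
#'   (+1/-1 for switch genes, `NA` otherwise).
#' @export
simulate_expression <- function(truth, cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  n <- nrow(truth)
  with_seed(cfg$seed + 1L, {
    lfc <- stats::rnorm(n, 0, 1)
    sgn <- rep(NA_real_, n)
    sw <- which(truth$is_switch)
    if (length(sw)) {
      sgn[sw] <- ifelse(stats::runif(length(sw)) < cfg$coupling_prob, 1, -1)
      lfc[sw] <- sgn[sw] * stats::rgamma(length(sw), shape = 2, scale = 0.75)
    }
    data.frame(gene_id = truth$gene_id, lfc = lfc,
               is_switch = truth$is_switch, planted_sign = sgn,
               stringsAsFactors = FALSE)
  })
}

#' Simulate program-structured multi-sample expression matrices
#'
#' Emulates scRNA-seq expression across tumors sharing additive gene programs:
#' each sample matrix is non-negative baseline noise plus, for every program
#' assigned to the sample, an additive block on (program genes x a random cell
#' subset). Used to validate recurrent-NMF meta-program recovery.
#'
#' @param n_samples Number of samples (>= 1).
#' @param n_cells_per_sample Cells per sample.
#' @param n_genes Total genes (shared universe across samples); the default
#'   leaves a 550-gene non-program background so that chance overlap between
#'   background-dominated factors stays well below the meta-program Jaccard
#'   threshold, as it does in a real transcriptome.
#' @param planted_programs List of pairwise-disjoint gene-id character vectors;
#'   default: five disjoint 90-gene programs drawn from the universe.
#' @param program_share Named list program -> sample indices carrying it;
#'   default: every program in every sample. Each program must appear in at
#'   least 2 samples.
#' @param baseline_mean Mean of the Gamma baseline noise (0 switches noise
#'   off).
#' @param signal_mean Mean of the additive Gamma program signal.
#' @param active_cell_frac Fraction of a sample's cells expressing each
#'   program.
#' @param seed Integer seed.
#' @return A list `matrices` (named list of gene x cell matrices) and `truth`
#'   (planted programs, share map, active cells).
#' @export
simulate_program_matrices <- function(n_samples = 8L,
                                      n_cells_per_sample = 150L,
                                      n_genes = 1000L,
                                      planted_programs = NULL,
                                      program_share = NULL,
                                      baseline_mean = 0.5,
                                      signal_mean = 4,
                                      active_cell_frac = 0.35,
                                      seed = 1L) {
  if (n_samples < 1L) stop("n_samples must be >= 1")
  if (n_cells_per_sample < 1L) stop("n_cells_per_sample must be >= 1")
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    if (is.null(planted_programs)) {
      if (n_genes < 5L * 90L)
        stop("default planted programs need >= 450 genes")
      pool <- sample(genes, 5L * 90L)
      planted_programs <- split(pool, rep(seq_len(5L), each = 90L))
      names(planted_programs) <- paste0("P", seq_len(5L))
    }
    all_pg <- unlist(planted_programs)
    if (anyDuplicated(all_pg))
      stop("planted programs must be pairwise disjoint")
    if (!all(all_pg %in% genes))
      stop("planted program genes must come from the gene universe")
    if (is.null(program_share))
      program_share <- lapply(planted_programs, function(p) seq_len(n_samples))
    if (any(lengths(program_share) < 2L))
      stop("each planted program must be present in >= 2 samples")
    samples <- paste0("S", seq_len(n_samples))
    active <- list()
    mats <- lapply(seq_len(n_samples), function(s) {
      m <- matrix(0, n_genes, n_cells_per_sample,
                  dimnames = list(genes,
                                  paste0(samples[s], "_C",
                                         seq_len(n_cells_per_sample))))
      if (baseline_mean > 0)
        m[] <- stats::rgamma(length(m), shape = 1, scale = baseline_mean)
      for (p in names(planted_programs)) {
        if (!(s %in% program_share[[p]])) next
        n_act <- max(2L, round(active_cell_frac * n_cells_per_sample))
        cells <- sample.int(n_cells_per_sample, n_act)
        gidx <- planted_programs[[p]]
        m[gidx, cells] <- m[gidx, cells] +
          stats::rgamma(length(gidx) * n_act, shape = 8,
                        scale = signal_mean / 8)
        active[[paste(samples[s], p, sep = ":")]] <<- cells
      }
      m
    })
    names(mats) <- samples
    list(matrices = mats,
         truth = list(programs = planted_programs,
                      share = program_share,
                      active_cells = active))
  })
}
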