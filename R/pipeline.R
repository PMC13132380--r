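# Pipeline orchestration: simulate -> call-bivalent -> diff -> classify ->
# transitions (-> metaprograms), driven by one nested config, writing every
# stage's output as plain text and a machine-readable JSON run summary.

#' Default run configuration
#'
#' Every module parameter at its documented default; user configs (YAML)
#' override by key. The schema is versioned so configs written today stay
#' interpretable.
#'
#' @return Nested named list.
#' @export
default_run_config <- function() {
  list(
    schema_version = 1L,
    seed = 1L,
    out_dir = "bivalstate_run",
    promoters = list(upstream_bp = 1000L, downstream_bp = 1000L,
                     biotype_filter = "protein_coding"),
    simulate = list(enabled = TRUE, n_genes = 1000L, noise_sigma = 0.3,
                    switch_fraction = 0.1, coupling_prob = 0.85),
    inputs = list(),  # annotation, k4_a/k27_a/seq_a, k4_b/k27_b/seq_b,
                      # signal_a, signal_b, expression_lfc when not simulating
    differential = list(alpha = 0.05, lfc_threshold = 0.58,
                        pseudocount = 1, fdr = FALSE),
    classify = list(fc_threshold = 1.5, pseudocount = 0.5),
    correlation = list(genes = "bivalent"),
    metaprograms = list(enabled = FALSE, k_min = 4L, k_max = 9L,
                        n_top = 90L, j_min = 0.2, min_samples = 2L,
                        min_k_recurrence = 2L)
  )
}

# Recursively overlay user values on the defaults.
merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]]))
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    else base[[nm]] <- override[[nm]]
  }
  base
}

#' Read a run configuration (YAML), overlaid on the defaults
#' @param path Path to a YAML config file.
#' @return Full config list.
#' @export
read_run_config <- function(path) {
  user <- yaml::read_yaml(path)
  merge_config(default_run_config(), user)
}

#' Write a run configuration to YAML
#' @param cfg Config list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_run_config <- function(cfg, path) {
  yaml::write_yaml(cfg, path)
  invisible(path)
}

pipeline_log <- function(...) message("[bivalstate] ", ...)

#' Run the full bivalency pipeline
#'
#' Stages: (optional) synthetic-data simulation, bona fide bivalent calling
#' per condition, differential marking per mark between conditions, CBS
#' classification per condition, transition tracking with the
#' switch-expression fraction and the mark/expression correlation, and
#' (optional) meta-program discovery. All stage outputs are written under
#' `cfg$out_dir`; the run summary is returned and serialized as JSON.
#'
#' @param cfg Config list (see [default_run_config()]) or path to a YAML
#'   file.
#' @return The run summary list, invisibly.
#' @export
run_pipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- read_run_config(cfg)
  cfg <- merge_config(default_run_config(), cfg)
  out <- cfg$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)

  if (!isTRUE(cfg$simulate$enabled)) {
    needed <- c("annotation", "k4_a", "k27_a", "seq_a", "k4_b", "k27_b",
                "seq_b", "signal_a", "signal_b", "expression_lfc")
    miss <- needed[vapply(cfg$inputs[needed], is.null, logical(1L))]
    if (length(miss))
      stop("config validation: simulate disabled but input path(s) missing: ",
           paste(miss, collapse = ", "))
    miss <- needed[!vapply(cfg$inputs[needed], file.exists, logical(1L))]
    if (length(miss))
      stop("config validation: input file(s) not found: ",
           paste(unlist(cfg$inputs[miss]), collapse = ", "))
  }

  # ---- stage: simulate or load ----
  if (isTRUE(cfg$simulate$enabled)) {
    pipeline_log("stage simulate: n_genes=", cfg$simulate$n_genes,
                 " seed=", cfg$seed)
    scfg <- sim_config(n_genes = cfg$simulate$n_genes,
                       noise_sigma = cfg$simulate$noise_sigma,
                       switch_fraction = cfg$simulate$switch_fraction,
                       coupling_prob = cfg$simulate$coupling_prob,
                       seed = cfg$seed)
    ann <- simulate_genome(scfg$n_genes, scfg$seed)
    sim <- simulate_chip(ann, scfg)
    expr <- simulate_expression(sim$truth, scfg)
    expr_lfc <- stats::setNames(expr$lfc, expr$gene_id)
    utils::write.table(ann, file.path(out, "annotation.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$truth, file.path(out, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(expr, file.path(out, "expression_lfc.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (cond in c("A", "B")) {
      write_bed(sim$peaks[[cond]]$k4,
                file.path(out, paste0("k4_", cond, ".bed")))
      write_bed(sim$peaks[[cond]]$k27,
                file.path(out, paste0("k27_", cond, ".bed")))
      write_bed(sim$peaks[[cond]]$seq,
                file.path(out, paste0("seq_", cond, ".bed")))
      write_matrix_tsv(sim$signal[[cond]],
                       file.path(out, paste0("signal_", cond, ".tsv")))
    }
    peaks <- sim$peaks
    signal <- sim$signal
  } else {
    pipeline_log("stage load: reading user inputs")
    ann <- read_annotation(cfg$inputs$annotation)
    peaks <- list(
      A = list(k4 = read_bed(cfg$inputs$k4_a, "H3K4me3"),
               k27 = read_bed(cfg$inputs$k27_a, "H3K27me3"),
               seq = read_bed(cfg$inputs$seq_a, "sequential_K27-K4")),
      B = list(k4 = read_bed(cfg$inputs$k4_b, "H3K4me3"),
               k27 = read_bed(cfg$inputs$k27_b, "H3K27me3"),
               seq = read_bed(cfg$inputs$seq_b, "sequential_K27-K4")))
    signal <- list(A = read_matrix_tsv(cfg$inputs$signal_a),
                   B = read_matrix_tsv(cfg$inputs$signal_b))
    lapply(signal, validate_signal_matrix)
    expr_tab <- utils::read.delim(cfg$inputs$expression_lfc,
                                  stringsAsFactors = FALSE)
    expr_lfc <- stats::setNames(expr_tab$lfc, expr_tab$gene_id)
  }

  promoters <- make_promoters(ann,
                              upstream_bp = cfg$promoters$upstream_bp,
                              downstream_bp = cfg$promoters$downstream_bp,
                              biotype_filter = cfg$promoters$biotype_filter)

  # ---- stage: bona fide bivalent calling per condition ----
  pipeline_log("stage call-bivalent")
  calls <- lapply(peaks, function(pk) {
    bona_fide_bivalent(
      call_bivalent_separate(pk$k4, pk$k27, promoters),
      call_bivalent_sequential(pk$seq, promoters))
  })
  for (cond in names(calls)) {
    utils::write.table(calls[[cond]]$calls,
                       file.path(out, paste0("bivalent_calls_", cond, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bivalent <- lapply(calls, function(cl)
    cl$calls$gene_id[cl$calls$bona_fide])

  # ---- stage: differential marking per mark (condition B vs A) ----
  pipeline_log("stage diff")
  genes_all <- names(promoters$ranges)
  diff_res <- lapply(c("H3K4me3", "H3K27me3"), function(mark) {
    xb <- stats::setNames(signal$B[genes_all, mark], genes_all)
    xa <- stats::setNames(signal$A[genes_all, mark], genes_all)
    call_differential(xb, xa, mark = mark,
                      alpha = cfg$differential$alpha,
                      lfc_threshold = cfg$differential$lfc_threshold,
                      pseudocount = cfg$differential$pseudocount,
                      fdr = cfg$differential$fdr)
  })
  names(diff_res) <- c("H3K4me3", "H3K27me3")
  for (mark in names(diff_res)) {
    utils::write.table(diff_res[[mark]],
                       file.path(out, paste0("differential_", mark, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  # ---- stage: CBS classification + transitions ----
  pipeline_log("stage classify/transitions")
  assignments <- lapply(c(A = "A", B = "B"), function(cond) {
    assign_states(
      stats::setNames(signal[[cond]][genes_all, "H3K4me3"], genes_all),
      stats::setNames(signal[[cond]][genes_all, "H3K27me3"], genes_all),
      bivalent[[cond]], condition = cond,
      fc_threshold = cfg$classify$fc_threshold,
      pseudocount = cfg$classify$pseudocount)
  })
  tt <- transition_table(assignments$A, assignments$B)
  long <- as.data.frame(tt$counts, stringsAsFactors = FALSE)
  names(long) <- c("from", "to", "n")
  utils::write.table(long, file.path(out, "transitions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(tt$records, file.path(out, "transition_records.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  swf <- tryCatch(switch_expression_fraction(tt, expr_lfc),
                  error = function(e) list(fraction = NA_real_, n_switch = 0L))

  corr_genes <- if (identical(cfg$correlation$genes, "bivalent"))
    union(bivalent$A, bivalent$B) else genes_all
  dk4 <- stats::setNames(diff_res$H3K4me3$log2FC, diff_res$H3K4me3$gene_id)
  corr <- tryCatch(
    bivalency_expression_correlation(dk4[corr_genes], expr_lfc[corr_genes]),
    error = function(e) list(r = NA_real_, p_value = NA_real_, n = 0L))

  # ---- stage: meta-programs (optional) ----
  mp_summary <- NULL
  if (isTRUE(cfg$metaprograms$enabled)) {
    pipeline_log("stage metaprograms")
    pm <- simulate_program_matrices(seed = cfg$seed)
    instances <- unlist(lapply(names(pm$matrices), function(s) {
      run_nmf_sweep(pm$matrices[[s]],
                    ks = cfg$metaprograms$k_min:cfg$metaprograms$k_max,
                    n_top = cfg$metaprograms$n_top, seed = cfg$seed,
                    sample_id = s)
    }), recursive = FALSE)
    mps <- cluster_programs(instances,
                            j_min = cfg$metaprograms$j_min,
                            min_samples = cfg$metaprograms$min_samples,
                            min_k_recurrence = cfg$metaprograms$min_k_recurrence,
                            n_top = cfg$metaprograms$n_top)
    mp_tab <- do.call(rbind, lapply(mps, function(mp)
      data.frame(mp_id = mp$mp_id, gene_id = mp$consensus,
                 stringsAsFactors = FALSE)))
    utils::write.table(mp_tab, file.path(out, "metaprograms.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    mp_summary <- list(n_instances = length(instances),
                       n_metaprograms = length(mps))
  }

  summary <- list(
    schema_version = cfg$schema_version,
    seed = cfg$seed,
    n_promoters = length(promoters$ranges),
    venn = lapply(calls, `[[`, "venn"),
    n_bivalent = lapply(bivalent, length),
    n_significant = lapply(diff_res, function(d) sum(d$significant)),
    cbs_counts = lapply(assignments, function(a)
      as.list(table(factor(a$labels, levels = cbs_levels())))),
    transitions = stats::setNames(as.list(as.integer(long$n)),
                                  paste(long$from, long$to, sep = "->")),
    switch_fraction = swf$fraction,
    n_switch = swf$n_switch,
    correlation = corr,
    metaprograms = mp_summary)
  json <- jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                           pretty = TRUE, null = "null")
  writeLines(json, file.path(out, "summary.json"))
  pipeline_log("done: summary written to ", file.path(out, "summary.json"))
  invisible(summary)
}
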