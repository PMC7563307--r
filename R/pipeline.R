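## End-to-end orchestration: simulate/read -> pool -> detect -> classify ->
## reannotate -> orphan triage -> statistics, with a manifest for
## reproducibility.

#' Pipeline configuration
#'
#' Either `simulate` (a [sim_params()] object; the pipeline generates its
#' own inputs) or `paths` (a list with `fasta`, `gff3`, and per-condition
#' track paths) must be given.
#'
#' @param out_dir output directory (created if absent).
#' @param simulate optional [sim_params()].
#' @param paths optional list: `fasta`, `gff3`, and `tracks` -- a named
#'   list (one element per condition) of lists of track inputs, each either
#'   a single BED path or a `c(plus=, minus=)` bedGraph pair; optionally
#'   `coverage` (bedGraph pair for the untagged library), `alt_starts`
#'   (TSV `locus_tag`, `alt_start`), and `library_sizes` per condition.
#' @param detection [detection_params()].
#' @param classification [classification_params()].
#' @param conditions two condition labels (default `CT`, `Cu`).
#' @param tolerance match tolerance (nt) for intersections and the
#'   differential table.
#' @param lfc_threshold |logFC| cutoff for the differential flag.
#' @param pseudocount pseudocount for the log fold change.
#' @param alpha adjusted-p cutoff for enrichment.
#' @param seed recorded in the manifest; overrides `simulate$seed` when
#'   simulating.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(out_dir, simulate = NULL, paths = NULL,
                            detection = detection_params(),
                            classification = classification_params(),
                            conditions = c("CT", "Cu"),
                            tolerance = 5, lfc_threshold = 1,
                            pseudocount = 0.5, alpha = 0.05,
                            seed = 1L) {
  if (is.null(simulate) && is.null(paths))
    stop("config error: either simulate or paths must be given")
  if (!is.null(simulate)) {
    stopifnot(inherits(simulate, "sim_params"))
    simulate$seed <- as.integer(seed)
  }
  structure(list(out_dir = out_dir, simulate = simulate, paths = paths,
                 detection = detection, classification = classification,
                 conditions = conditions, tolerance = tolerance,
                 lfc_threshold = lfc_threshold, pseudocount = pseudocount,
                 alpha = alpha, seed = as.integer(seed)),
            class = "pipeline_config")
}

stage_log <- function(stage, fmt, ...) {
  message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full TSS annotation pipeline
#'
#' Stages: input (simulate or load) -> pool replicates per condition ->
#' detect TSSs -> classify -> per-replicon summary -> CDS re-annotation
#' (when alternative starts are available) -> orphan triage -> differential
#' TSS expression, positional profiles, and functional-class enrichment.
#' All outputs are TSVs under `config$out_dir`, plus a `manifest.json`
#' echoing every parameter and output row count. Deterministic for a fixed
#' config and seed.
#'
#' @param config a [pipeline_config()].
#' @return Invisibly, a list with the in-memory results and the manifest.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  conds <- config$conditions
  coverage <- NULL
  alt_starts <- NULL
  truth <- NULL

  if (!is.null(config$simulate)) {
    stage_log("simulate", "seed %d, %d TSSs, %d CDSs",
              config$simulate$seed, config$simulate$n_tss,
              config$simulate$n_cds)
    sim <- simulate_tagrnaseq(config$simulate, out_dir = config$out_dir)
    genome <- sim$genome
    truth <- sim$truth
    tracks <- sim$tracks
    names(tracks) <- conds
  } else {
    p <- config$paths
    stage_log("input", "reading genome %s + %s", p$fasta, p$gff3)
    genome <- read_genome(p$fasta, p$gff3)
    lens <- stats::setNames(genome$replicons$length,
                            genome$replicons$name)
    tracks <- lapply(stats::setNames(nm = conds), function(cond) {
      inputs <- p$tracks[[cond]]
      if (is.null(inputs))
        stop("data error [input]: no tracks for condition ", cond)
      lapply(inputs, function(tp)
        read_end_counts(tp, replicon_lengths = lens,
                        library_size = p$library_sizes[[cond]],
                        condition = cond))
    })
    if (!is.null(p$coverage))
      coverage <- read_end_counts(p$coverage, replicon_lengths = lens)
    if (!is.null(p$alt_starts))
      alt_starts <- read_tss_table(p$alt_starts)
  }

  pooled <- lapply(stats::setNames(nm = conds), function(cond) {
    pl <- pool_tracks(tracks[[cond]])
    stage_log("pool", "%s: %d replicates, pooled library %g reads",
              cond, length(tracks[[cond]]), pl$library_size)
    pl
  })

  calls <- lapply(stats::setNames(nm = conds), function(cond) {
    cl <- detect_tss(pooled[[cond]], config$detection, condition = cond)
    stage_log("detect", "%s: %d TSS calls", cond, nrow(cl))
    cl
  })

  annotations <- lapply(stats::setNames(nm = conds), function(cond) {
    ann <- classify_tss(calls[[cond]], genome, config$classification)
    tab <- table(factor(ann$tss_class, TSS_CLASSES))
    stage_log("classify", "%s: %s", cond,
              paste(names(tab), tab, sep = "=", collapse = " "))
    ann
  })

  summary_tab <- summarize_tss_classes(annotations[[1]], annotations[[2]],
                                       tolerance = config$tolerance,
                                       labels = conds)

  reann <- NULL
  if (!is.null(alt_starts)) {
    reann <- propose_reannotations(genome, annotations[[1]], alt_starts,
                                   config$classification)
    stage_log("reannotate", "%d candidate(s)", nrow(reann))
  }

  orphans <- lapply(stats::setNames(nm = conds), function(cond) {
    orp <- withCallingHandlers(
      triage_orphans(genome, annotations[[cond]], coverage,
                     config$classification),
      warning = function(w) {
        stage_log("orphans", "warning: %s", conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    stage_log("orphans", "%s: %s", cond,
              paste(names(table(orp$orphan_category)),
                    table(orp$orphan_category),
                    sep = "=", collapse = " "))
    orp
  })

  diff <- diff_tss(annotations[[1]], annotations[[2]],
                   tolerance = config$tolerance,
                   lfc_threshold = config$lfc_threshold,
                   pseudocount = config$pseudocount)
  stage_log("stats", "%d TSSs in differential table, %d differential",
            nrow(diff), sum(diff$de_flag))

  profiles <- do.call(rbind, lapply(conds, function(cond) {
    do.call(rbind, lapply(c("iTSS", "aTSS"), function(cls) {
      pr <- positional_profile(annotations[[cond]], cls)
      if (nrow(pr) == 0) return(NULL)
      cbind(condition = cond, tss_class = cls, pr)
    }))
  }))

  universe <- genome$cds$locus_tag
  class_map <- stats::setNames(genome$cds$functional_class, universe)
  enrichment <- do.call(rbind, lapply(conds, function(cond) {
    ann <- annotations[[cond]]
    do.call(rbind, lapply(TSS_CLASSES[-5], function(cls) {
      target <- intersect(unique(
        ann$cognate_locus[ann$tss_class == cls]), universe)
      if (length(target) == 0 || length(universe) == 0) return(NULL)
      cbind(condition = cond, tss_class = cls,
            class_enrichment(target, universe, class_map,
                             alpha = config$alpha))
    }))
  }))

  ## ---- outputs -------------------------------------------------------
  outputs <- list()
  emit <- function(x, name) {
    if (is.null(x)) return()
    path <- file.path(config$out_dir, paste0(name, ".tsv"))
    write_tss_table(x, path)
    outputs[[paste0(name, ".tsv")]] <<- nrow(x)
  }
  for (cond in conds) {
    emit(calls[[cond]], paste0("calls_", cond))
    write_tss_bed(calls[[cond]],
                  file.path(config$out_dir,
                            paste0("calls_", cond, ".bed")))
    emit(annotations[[cond]], paste0("annotations_", cond))
    emit(orphans[[cond]], paste0("orphans_", cond))
  }
  emit(summary_tab, "summary")
  emit(reann, "reannotations")
  emit(diff, "differential")
  emit(profiles, "profiles")
  emit(enrichment, "enrichment")

  manifest <- list(
    seed = config$seed,
    conditions = as.list(conds),
    parameters = list(
      detection = unclass(config$detection),
      classification = unclass(config$classification),
      simulate = if (!is.null(config$simulate))
        lapply(unclass(config$simulate), function(v)
          if (is.numeric(v) && !is.null(names(v))) as.list(v) else v),
      tolerance = config$tolerance,
      lfc_threshold = config$lfc_threshold,
      pseudocount = config$pseudocount,
      alpha = config$alpha),
    outputs = outputs)
  jsonlite::write_json(manifest,
                       file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, null = "null", digits = NA,
                       pretty = TRUE)
  invisible(list(genome = genome, truth = truth, calls = calls,
                 annotations = annotations, summary = summary_tab,
                 reannotations = reann, orphans = orphans, diff = diff,
                 profiles = profiles, enrichment = enrichment,
                 manifest = manifest))
}
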