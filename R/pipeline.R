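#' Pipeline configuration
#'
#' Paths and thresholds for an end-to-end run. Referenced input files must
#' exist when [run_all()] executes the corresponding stage.
#'
#' @param ct_table Replicate-level CT TSV (see [read_ct_table()]).
#' @param clinical Clinical CSV (see [read_clinical_table()]).
#' @param mapping Name-mapping TSV, or `NULL` to skip renaming.
#' @param literature Literature-evidence TSV; defaults to the packaged
#'   table.
#' @param tissue Tissue-expression TSV, or `NULL` to skip the lookup.
#' @param targets miRNA-to-target TSV.
#' @param terms GMT term database.
#' @param pool_composition Data frame mapping pools to groups; default the
#'   five-pool layout of [default_pool_composition()].
#' @param outdir Output directory.
#' @param ct_cutoff,sd_cutoff Status-calling cutoffs.
#' @param fdr,min_mirnas,p_threshold ORA filters.
#' @param alpha Significance level of the clinical statistics.
#' @param drop_sex_covariate Drop sex from the wetting-length regression.
#' @param group_order Group order of the matrices.
#' @param seed Seed for any stochastic step (Monte Carlo fallbacks).
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ct_table = NULL, clinical = NULL,
                            mapping = NULL,
                            literature = system.file(
                              "extdata", "literature_evidence.tsv",
                              package = "tearmiR"),
                            tissue = NULL, targets = NULL, terms = NULL,
                            pool_composition = default_pool_composition(),
                            outdir = "tearmir_out",
                            ct_cutoff = 40, sd_cutoff = 5, fdr = 0.01,
                            min_mirnas = 5, p_threshold = 0.05,
                            alpha = 0.05, drop_sex_covariate = FALSE,
                            group_order = DEFAULT_GROUPS, seed = 1L) {
  if (ct_cutoff <= 0 || sd_cutoff <= 0 || fdr <= 0 || p_threshold <= 0 ||
      alpha <= 0)
    stop("thresholds must be positive", call. = FALSE)
  structure(
    list(ct_table = ct_table, clinical = clinical, mapping = mapping,
         literature = literature, tissue = tissue, targets = targets,
         terms = terms, pool_composition = pool_composition,
         outdir = outdir, ct_cutoff = ct_cutoff, sd_cutoff = sd_cutoff,
         fdr = fdr, min_mirnas = min_mirnas, p_threshold = p_threshold,
         alpha = alpha, drop_sex_covariate = drop_sex_covariate,
         group_order = group_order, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Write the synthetic input file set
#'
#' Wraps the synthetic-data generators: simulates a clinical cohort, a
#' ground-truth status matrix realised as a replicate-level CT table, and
#' the annotation fixtures (target map and GMT term database), and writes
#' them to `outdir` (`clinical.csv`, `ct_table.tsv`, `truth.tsv`,
#' `target_map.tsv`, `terms.gmt`).
#'
#' @param outdir Output directory (created if needed).
#' @param seed Master seed passed to every generator.
#' @param cohort A [cohort_config()].
#' @param noise A [ct_noise_config()].
#' @param truth_probs Status probabilities of the planted truth.
#' @param annotation_args Arguments passed to [generate_annotation_db()].
#' @return Named list of the files written, plus the in-memory objects
#'   (invisibly returned as attributes would be unwieldy): a list with
#'   `files`, `truth`, `query_mirnas`.
#' @export
simulate_inputs <- function(outdir, seed = 1L,
                            cohort = cohort_config(seed = seed),
                            noise = ct_noise_config(seed = seed),
                            truth_probs = c(none = 0.35, low = 0.2,
                                            high = 0.45),
                            annotation_args = list()) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  clin <- generate_cohort(cohort)
  truth <- generate_truth_matrix(n_mirnas = noise$n_mirnas,
                                 probs = truth_probs, seed = seed)
  ct <- generate_ct_experiment(truth, noise)
  ann <- do.call(generate_annotation_db,
                 c(list(seed = seed), annotation_args))

  files <- list(
    clinical = file.path(outdir, "clinical.csv"),
    ct_table = file.path(outdir, "ct_table.tsv"),
    truth = file.path(outdir, "truth.tsv"),
    targets = file.path(outdir, "target_map.tsv"),
    terms = file.path(outdir, "terms.gmt")
  )
  utils::write.csv(clin, files$clinical, row.names = FALSE, na = "")
  write_ct_table(ct, files$ct_table)
  truth_df <- data.frame(
    mirna_id = rep(rownames(truth), ncol(truth)),
    pool_id = rep(colnames(truth), each = nrow(truth)),
    status = as.vector(truth), stringsAsFactors = FALSE)
  utils::write.table(truth_df, files$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_target_map(ann$target_map, files$targets)
  write_gmt(ann$termdb, files$terms)
  invisible(list(files = files, truth = truth,
                 query_mirnas = ann$query_mirnas))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", stage, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full pipeline
#'
#' Executes status calling, intersection analysis, clinical statistics,
#' annotation and overrepresentation analysis, writing all stage outputs
#' and a run manifest to `config$outdir`. Rerunning with identical inputs
#' yields byte-identical non-timestamp outputs.
#'
#' @param config A [pipeline_config()].
#' @return The manifest, invisibly (also written to `manifest.json`).
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  counts <- list()
  scc <- status_calling_config(config$ct_cutoff, config$sd_cutoff)

  # stage 1: status calling
  sm <- run_stage("call-status", {
    if (is.null(config$ct_table) || !file.exists(config$ct_table))
      stop("CT table missing: ", config$ct_table %||% "<unset>")
    meas <- read_ct_table(config$ct_table)
    call_status_matrix(meas, config$pool_composition, scc,
                       group_order = config$group_order)
  })
  write_status_matrix(sm, file.path(config$outdir, "status_matrix.tsv"))
  utils::write.table(sm$internal_controls,
                     file.path(config$outdir, "internal_controls.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  counts$mirnas <- nrow(sm$status)
  counts$internal_controls <-
    length(unique(sm$internal_controls$mirna_id))

  # stage 2: intersections
  report <- run_stage("intersect", {
    upset_assignment(binarize_high(sm))
  })
  pm <- binarize_high(sm)
  diseases <- setdiff(config$group_order, "control")
  write_intersections(report, pm, config$outdir, diseases)
  counts$found_in_all <- report$found_in_all
  counts$found_in_none <- report$found_in_none

  # stage 3: clinical statistics
  clin_stage <- run_stage("clin-stats", {
    if (is.null(config$clinical) || !file.exists(config$clinical))
      stop("clinical table missing: ", config$clinical %||% "<unset>")
    clin <- read_clinical_table(config$clinical)
    list(n = nrow(clin),
         stats = clinical_stats_battery(
           clin, alpha = config$alpha,
           drop_sex_covariate = config$drop_sex_covariate))
  })
  counts$subjects <- clin_stage$n
  write_clinical_stats(clin_stage$stats,
                       file.path(config$outdir, "stats.json"))

  # stage 4: annotation
  annotated <- run_stage("annotate", {
    if (is.null(config$literature) || !file.exists(config$literature))
      stop("literature fixture missing: ",
           config$literature %||% "<unset>")
    lit <- read_literature(config$literature)
    mapping <- if (!is.null(config$mapping))
      read_name_mapping(config$mapping) else NULL
    tissue <- if (!is.null(config$tissue))
      read_tissue_table(config$tissue) else NULL
    lapply(stats::setNames(diseases, diseases), function(d) {
      cand <- disease_candidate_set(report, d)
      ann <- annotate_candidates(cand, d, mapping, lit_db = lit,
                                 tissue_table = tissue,
                                 known_diseases = diseases)
      utils::write.table(
        ann$table,
        file.path(config$outdir,
                  paste0("annotated_candidates_", d, ".tsv")),
        sep = "\t", quote = FALSE, row.names = FALSE)
      ann
    })
  })
  counts$candidates <- vapply(annotated, function(a) nrow(a$table),
                              integer(1))

  # stage 5: overrepresentation analysis
  if (!is.null(config$targets) && !is.null(config$terms)) {
    ora_res <- run_stage("ora", {
      if (!file.exists(config$targets))
        stop("target map missing: ", config$targets)
      if (!file.exists(config$terms))
        stop("term database missing: ", config$terms)
      tmap <- read_target_map(config$targets)
      termdb <- read_gmt(config$terms)
      lapply(stats::setNames(diseases, diseases), function(d) {
        cand <- disease_candidate_set(report, d)
        res <- run_ora(cand$mirna_id[cand$direction == "present"],
                       cand$mirna_id[cand$direction == "absent"],
                       tmap, termdb, p_threshold = config$p_threshold,
                       fdr_filter = config$fdr,
                       min_mirnas = config$min_mirnas)
        utils::write.table(res,
                           file.path(config$outdir,
                                     paste0("ora_", d, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        res
      })
    })
    counts$ora_terms <- vapply(ora_res, nrow, integer(1))
  }

  manifest <- list(
    tool = "tearmiR", version = as.character(utils::packageVersion("tearmiR")),
    config_hash = hash_config(config),
    seed = config$seed,
    counts = counts,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(config$outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# md5 of the serialised config (timestamp-free) for the run manifest
hash_config <- function(config) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(unclass(config), tmp)
  unname(tools::md5sum(tmp))
}
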