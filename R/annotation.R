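# Closed biofluid vocabulary of the literature-evidence table.
BIOFLUIDS <- c("blood", "csf", "brain")

#' Read a miRNA name-mapping table
#'
#' Two-column TSV (`panel_name`, `current_name`) mapping the profiling
#' panel's assay names to the current miRBase annotation. An empty
#' `current_name` marks a panel assay with no current annotation; such
#' miRNAs are excluded from downstream candidate analysis.
#'
#' @param path Path to the TSV.
#' @return Data frame with columns `panel_name`, `current_name`.
#' @export
read_name_mapping <- function(path) {
  if (!file.exists(path))
    stop("name mapping not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "",
                          na.strings = NULL)
  if (!all(c("panel_name", "current_name") %in% names(df)))
    stop("name mapping needs columns panel_name and current_name",
         call. = FALSE)
  if (anyDuplicated(tolower(df$panel_name)))
    stop("panel names must be unique (case-insensitively)", call. = FALSE)
  df
}

#' Normalize miRNA names against a mapping table
#'
#' Case-insensitive lookup of panel names in the mapping. Names mapping to
#' an empty target, or absent from the mapping altogether, are returned in
#' the `unannotated` list and should be excluded downstream.
#'
#' @param names Character vector of panel miRNA names.
#' @param mapping Data frame from [read_name_mapping()].
#' @return List with `renamed` (data frame: `panel_name`, `current_name`
#'   for annotated inputs) and `unannotated` (character vector).
#' @export
normalize_names <- function(names, mapping) {
  idx <- match(tolower(names), tolower(mapping$panel_name))
  target <- ifelse(is.na(idx), "", trimws(mapping$current_name[idx]))
  ok <- !is.na(idx) & target != ""
  list(
    renamed = data.frame(panel_name = names[ok], current_name = target[ok],
                         stringsAsFactors = FALSE),
    unannotated = names[!ok]
  )
}

#' Read a literature-evidence table
#'
#' TSV with columns `mirna_id`, `disease`, `biofluid`, `citation`; one row
#' per (miRNA, disease, biofluid, citation). The biofluid vocabulary is
#' closed (`blood`, `csf`, `brain`); evidence in several fluids is
#' represented as several rows.
#'
#' @param path Path to the TSV; defaults to the packaged evidence table of
#'   miRNAs reported as significantly changed in PD/MSA/PSP in other
#'   biofluid studies.
#' @return Data frame of literature evidence.
#' @export
read_literature <- function(path = system.file("extdata",
                                               "literature_evidence.tsv",
                                               package = "tearmiR")) {
  if (!file.exists(path))
    stop("literature table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  required <- c("mirna_id", "disease", "biofluid", "citation")
  if (!all(required %in% names(df)))
    stop("literature table needs columns ",
         paste(required, collapse = ", "), call. = FALSE)
  bad <- setdiff(unique(df$biofluid), BIOFLUIDS)
  if (length(bad) > 0)
    stop("unknown biofluid(s): ", paste(bad, collapse = ", "),
         " (allowed: ", paste(BIOFLUIDS, collapse = ", "), ")",
         call. = FALSE)
  if (anyDuplicated(df[, required]))
    stop("duplicate (mirna, disease, biofluid, citation) rows",
         call. = FALSE)
  df
}

#' Cross-reference candidate miRNAs against the literature
#'
#' For each candidate miRNA, collects the biofluids in which it has been
#' reported as significantly changed for the given disease, and tallies the
#' candidates into described / not described, per-biofluid counts, and the
#' single-fluid vs multi-fluid partition.
#'
#' @param candidates Character vector of miRNA ids (current annotation).
#' @param disease Disease label to look up (must appear in the table,
#'   e.g. `"PD"`, `"MSA"`, `"PSP"`).
#' @param lit_db Data frame from [read_literature()].
#' @param aliases Optional named character vector mapping alternative
#'   spellings in the evidence table to the candidate naming (applied to
#'   the table's `mirna_id` before matching).
#' @param known_diseases Labels accepted for `disease`; defaults to those
#'   present in the table.
#' @return List with `evidence` (data frame: `mirna_id`, `biofluids`
#'   comma-joined, `citations`), `described`, `not_described`, `by_fluid`
#'   (named counts of described miRNAs with evidence in each fluid),
#'   `single_fluid` (named counts of miRNAs whose evidence is confined to
#'   one fluid) and `multi_fluid` (count).
#' @export
literature_lookup <- function(candidates, disease, lit_db = read_literature(),
                              aliases = c("hsa-miR-516a-6p" =
                                            "hsa-miR-516a-5p"),
                              known_diseases = unique(lit_db$disease)) {
  if (!disease %in% known_diseases)
    stop("unknown disease label: ", disease, call. = FALSE)
  db <- lit_db[lit_db$disease == disease, , drop = FALSE]
  hit <- match(db$mirna_id, names(aliases))
  db$mirna_id[!is.na(hit)] <- aliases[hit[!is.na(hit)]]

  per_mirna <- lapply(candidates, function(m) {
    rows <- db[tolower(db$mirna_id) == tolower(m), , drop = FALSE]
    list(fluids = sort(unique(rows$biofluid)),
         citations = sort(unique(rows$citation)))
  })
  names(per_mirna) <- candidates
  fluids_per <- lapply(per_mirna, `[[`, "fluids")
  described_mask <- lengths(fluids_per) > 0

  evidence <- data.frame(
    mirna_id = candidates,
    biofluids = vapply(fluids_per, paste, character(1), collapse = ","),
    citations = vapply(per_mirna, function(x)
      paste(x$citations, collapse = "; "), character(1)),
    stringsAsFactors = FALSE
  )
  by_fluid <- vapply(BIOFLUIDS, function(f)
    sum(vapply(fluids_per, function(fl) f %in% fl, logical(1))), integer(1))
  single <- vapply(BIOFLUIDS, function(f)
    sum(vapply(fluids_per, function(fl) identical(fl, f), logical(1))),
    integer(1))
  list(
    evidence = evidence,
    described = sum(described_mask),
    not_described = sum(!described_mask),
    by_fluid = by_fluid,
    single_fluid = single,
    multi_fluid = sum(lengths(fluids_per) > 1)
  )
}

#' Read a tissue-expression table
#'
#' TSV with columns `mirna_id`, `tissue`, `read_count` giving
#' small-RNA-seq read counts per miRNA and tissue, as exported from a
#' tissue expression database.
#'
#' @param path Path to the TSV.
#' @return Data frame with `read_count` numeric.
#' @export
read_tissue_table <- function(path) {
  if (!file.exists(path))
    stop("tissue table not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  required <- c("mirna_id", "tissue", "read_count")
  if (!all(required %in% names(df)))
    stop("tissue table needs columns ", paste(required, collapse = ", "),
         call. = FALSE)
  df$read_count <- as.numeric(df$read_count)
  if (any(is.na(df$read_count)) || any(df$read_count < 0))
    stop("read_count must be non-negative numeric", call. = FALSE)
  df
}

#' Brain-tissue presence of miRNAs
#'
#' A miRNA counts as expressed when some row for it in a brain or
#' brain-stem tissue has a read count strictly above the threshold
#' (default: > 1 read counts). miRNAs absent from the table are not
#' expressed.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param expr_table Data frame from [read_tissue_table()].
#' @param threshold Read-count threshold (strict inequality).
#' @param tissue_pattern Regular expression selecting the tissues of
#'   interest (case-insensitive); defaults to anything containing "brain".
#' @return Named logical vector over `mirnas`.
#' @export
tissue_presence <- function(mirnas, expr_table, threshold = 1,
                            tissue_pattern = "brain") {
  rel <- expr_table[grepl(tissue_pattern, expr_table$tissue,
                          ignore.case = TRUE) &
                      expr_table$read_count > threshold, , drop = FALSE]
  expressed <- tolower(mirnas) %in% tolower(rel$mirna_id)
  stats::setNames(expressed, mirnas)
}

#' Annotate a disease candidate set
#'
#' Full annotation pass for one disease: candidate panel names are
#' normalized to current miRBase annotation (unannotated assays dropped),
#' literature evidence is attached, and brain-tissue presence is looked up
#' for the candidates without prior disease literature.
#'
#' @param candidates Data frame from [disease_candidate_set()] (`mirna_id`,
#'   `direction`).
#' @param disease Disease label.
#' @param mapping Data frame from [read_name_mapping()], or `NULL` to skip
#'   renaming.
#' @param lit_db Data frame from [read_literature()].
#' @param tissue_table Data frame from [read_tissue_table()], or `NULL` to
#'   skip the tissue lookup.
#' @param ... Passed to [literature_lookup()].
#' @return List with `table` (data frame: `mirna_id`, `direction`,
#'   `described_in`, `brain_expressed`), `unannotated` (dropped panel
#'   names) and `tallies` (the [literature_lookup()] tallies).
#' @export
annotate_candidates <- function(candidates, disease, mapping = NULL,
                                lit_db = read_literature(),
                                tissue_table = NULL, ...) {
  stopifnot(is.data.frame(candidates),
            all(c("mirna_id", "direction") %in% names(candidates)))
  if (!is.null(mapping)) {
    nm <- normalize_names(candidates$mirna_id, mapping)
    keep <- match(nm$renamed$panel_name, candidates$mirna_id)
    candidates <- data.frame(mirna_id = nm$renamed$current_name,
                             direction = candidates$direction[keep],
                             stringsAsFactors = FALSE)
    unannotated <- nm$unannotated
  } else {
    unannotated <- character(0)
  }
  lk <- literature_lookup(candidates$mirna_id, disease, lit_db, ...)
  brain <- if (!is.null(tissue_table))
    tissue_presence(candidates$mirna_id, tissue_table)
  else
    rep(NA, nrow(candidates))
  tbl <- data.frame(
    mirna_id = candidates$mirna_id,
    direction = candidates$direction,
    described_in = lk$evidence$biofluids,
    brain_expressed = unname(brain),
    stringsAsFactors = FALSE
  )
  list(table = tbl, unannotated = unannotated, tallies = lk)
}
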