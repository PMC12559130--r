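#' Binarize high-certainty calls
#'
#' Collapses the three-level status matrix to presence/absence for the
#' intersection analysis: a miRNA is *present* in a group iff it was
#' amplified with high certainty there; low-certainty and not-amplified
#' calls both count as absent.
#'
#' @param sm A `status_matrix` from [call_status_matrix()], or a character
#'   matrix of statuses with miRNA rownames and group colnames.
#' @return A logical matrix (miRNAs x groups) of class `presence_matrix`.
#' @export
binarize_high <- function(sm) {
  status <- if (inherits(sm, "status_matrix")) sm$status else sm
  if (!is.matrix(status))
    stop("`sm` must be a status_matrix or a status matrix", call. = FALSE)
  bad <- setdiff(unique(as.vector(status)), STATUS_LEVELS)
  if (length(bad) > 0)
    stop("invalid status value(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  pm <- status == "high"
  class(pm) <- c("presence_matrix", class(pm))
  pm
}

#' UpSet-style intersection assignment
#'
#' Assigns every miRNA to exactly one of the `2^k` presence patterns over
#' the `k` groups (for the 4-group design: 16 cells), the tabulation that an
#' UpSet plot displays. Patterns are encoded as bit strings in the fixed
#' group (column) order, e.g. `"0100"` = present only in the second group.
#'
#' For each group `D` the report also extracts the two disease-relevant
#' cells: `exclusive_present[[D]]`, the miRNAs present only in `D`, and
#' `exclusive_absent[[D]]`, those present in exactly all other groups but
#' not `D`.
#'
#' @param pm A logical presence matrix (miRNAs x groups) as returned by
#'   [binarize_high()].
#' @return An object of class `intersection_report`: list with
#'   `pattern_counts` (named integer vector over all patterns), `members`
#'   (pattern -> sorted miRNA vector), `exclusive_present` and
#'   `exclusive_absent` (group -> sorted miRNA vector), `found_in_all`,
#'   `found_in_none` and `groups`.
#' @export
upset_assignment <- function(pm) {
  if (!is.matrix(pm) || !is.logical(pm))
    stop("`pm` must be a logical presence matrix", call. = FALSE)
  groups <- colnames(pm)
  if (is.null(groups) || anyNA(pm))
    stop("`pm` needs group colnames and no missing values", call. = FALSE)
  k <- length(groups)
  all_patterns <- vapply(
    0:(2^k - 1),
    function(x) paste(as.integer(bitwAnd(x, 2^((k - 1):0)) > 0), collapse = ""),
    character(1)
  )
  pattern <- if (nrow(pm) == 0) character(0) else
    apply(pm, 1, function(row) paste(as.integer(row), collapse = ""))
  counts <- table(factor(pattern, levels = all_patterns))
  members <- lapply(all_patterns, function(p) {
    sort(rownames(pm)[pattern == p])
  })
  names(members) <- all_patterns

  only_d <- function(d) {
    p <- rep("0", k); p[d] <- "1"; paste(p, collapse = "")
  }
  all_but_d <- function(d) {
    p <- rep("1", k); p[d] <- "0"; paste(p, collapse = "")
  }
  exclusive_present <- lapply(seq_len(k), function(d) members[[only_d(d)]])
  exclusive_absent <- lapply(seq_len(k), function(d) members[[all_but_d(d)]])
  names(exclusive_present) <- names(exclusive_absent) <- groups

  structure(
    list(
      pattern_counts = stats::setNames(as.integer(counts), all_patterns),
      members = members,
      exclusive_present = exclusive_present,
      exclusive_absent = exclusive_absent,
      found_in_all = as.integer(counts[[paste(rep("1", k), collapse = "")]]),
      found_in_none = as.integer(counts[[paste(rep("0", k), collapse = "")]]),
      groups = groups
    ),
    class = "intersection_report"
  )
}

#' @export
print.intersection_report <- function(x, ...) {
  n <- sum(x$pattern_counts)
  cat("Intersection report over", n, "miRNAs,",
      length(x$groups), "groups (", paste(x$groups, collapse = ", "), ")\n")
  cat("  found in all groups:", x$found_in_all,
      " | found in none:", x$found_in_none, "\n")
  for (g in x$groups)
    cat(sprintf("  %s: %d exclusively present, %d exclusively absent\n", g,
                length(x$exclusive_present[[g]]),
                length(x$exclusive_absent[[g]])))
  invisible(x)
}

#' Disease candidate set
#'
#' The candidate miRNAs for a disease group: those exclusively amplified
#' with high certainty in that group (`direction = "present"`) together with
#' those amplified with high certainty in every other group but not this one
#' (`direction = "absent"`).
#'
#' @param report An `intersection_report` from [upset_assignment()].
#' @param disease A group label present in the report.
#' @return Data frame with columns `mirna_id` and `direction`
#'   (`"present"`/`"absent"`), sorted by direction then miRNA.
#' @export
disease_candidate_set <- function(report, disease) {
  stopifnot(inherits(report, "intersection_report"))
  if (!disease %in% report$groups)
    stop("unknown disease label: ", disease, call. = FALSE)
  pres <- report$exclusive_present[[disease]]
  abs_ <- report$exclusive_absent[[disease]]
  data.frame(
    mirna_id = c(pres, abs_),
    direction = rep(c("present", "absent"), c(length(pres), length(abs_))),
    stringsAsFactors = FALSE
  )
}

#' Write intersection outputs
#'
#' Writes `upset_counts.tsv` (pattern, count), `memberships.tsv`
#' (mirna_id, pattern), a binary `presence_matrix.tsv` consumable by UpSet
#' plotting tools, and one `candidates_<disease>.tsv` per requested disease.
#'
#' @param report An `intersection_report`.
#' @param pm The presence matrix the report was computed from.
#' @param outdir Output directory (created if needed).
#' @param diseases Groups to write candidate sets for; defaults to all
#'   groups except the first (the control column).
#' @return Invisibly, the vector of files written.
#' @export
write_intersections <- function(report, pm, outdir,
                                diseases = report$groups[-1]) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)

  f <- file.path(outdir, "upset_counts.tsv")
  utils::write.table(
    data.frame(pattern = names(report$pattern_counts),
               count = report$pattern_counts),
    f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  memb <- do.call(rbind, lapply(names(report$members), function(p) {
    m <- report$members[[p]]
    if (length(m) == 0) return(NULL)
    data.frame(mirna_id = m, pattern = p, stringsAsFactors = FALSE)
  }))
  if (is.null(memb))
    memb <- data.frame(mirna_id = character(0), pattern = character(0))
  memb <- memb[order(memb$mirna_id), , drop = FALSE]
  f <- file.path(outdir, "memberships.tsv")
  utils::write.table(memb, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  bm <- data.frame(mirna_id = rownames(pm), 1L * pm, check.names = FALSE)
  bm <- bm[order(bm$mirna_id), , drop = FALSE]
  f <- file.path(outdir, "presence_matrix.tsv")
  utils::write.table(bm, f, sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c(files, f)

  for (d in diseases) {
    f <- file.path(outdir, paste0("candidates_", d, ".tsv"))
    utils::write.table(disease_candidate_set(report, d), f, sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files <- c(files, f)
  }
  invisible(files)
}
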