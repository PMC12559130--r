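# Ordered levels of the three-level amplification status. The ordering
# none < low < high is what the biological-replicate merge maximises over.
STATUS_LEVELS <- c("none", "low", "high")

#' Status-calling configuration
#'
#' Thresholds for the three-level amplification-status classification of
#' replicate CT (cycle threshold) values: a miRNA is *amplified with high
#' certainty* when both technical replicates have a numeric CT strictly below
#' `ct_cutoff` and the replicate standard deviation is strictly below
#' `sd_cutoff`; *not amplified* when both replicates are undetermined; and
#' *amplified with low certainty* in every other case.
#'
#' @param ct_cutoff Maximum CT in cycles for a high-certainty call (exclusive).
#'   Default 40, the conventional end of the qPCR run.
#' @param sd_cutoff Maximum replicate SD in cycles for a high-certainty call
#'   (exclusive). Default 5.
#' @param sd_denominator `"n-1"` (sample SD, default) or `"n"` (population
#'   SD). For duplicates the sample SD is `|a - b| / sqrt(2)`; which
#'   denominator the original QC rule intended is ambiguous, so it is exposed
#'   here. The choice only matters for replicate differences in
#'   `[sd_cutoff, sd_cutoff * sqrt(2))`.
#' @return An object of class `status_calling_config`.
#' @export
status_calling_config <- function(ct_cutoff = 40, sd_cutoff = 5,
                                  sd_denominator = c("n-1", "n")) {
  sd_denominator <- match.arg(sd_denominator)
  if (!is.numeric(ct_cutoff) || length(ct_cutoff) != 1L || ct_cutoff <= 0)
    stop("`ct_cutoff` must be a single positive number", call. = FALSE)
  if (!is.numeric(sd_cutoff) || length(sd_cutoff) != 1L || sd_cutoff <= 0)
    stop("`sd_cutoff` must be a single positive number", call. = FALSE)
  structure(
    list(ct_cutoff = ct_cutoff, sd_cutoff = sd_cutoff,
         sd_denominator = sd_denominator),
    class = "status_calling_config"
  )
}

# Tokens (lower-cased) that mark a CT value as undetermined in input tables.
UNDETERMINED_TOKENS <- c("undetermined", "na", "")

#' Read a replicate-level CT table
#'
#' Parses a delimited table of replicate-level CT measurements. Required
#' columns: `mirna_id`, `pool_id`, `replicate` (1 or 2) and `ct`. The `ct`
#' column may contain the tokens `"Undetermined"` (any case), `"NA"` or an
#' empty cell, all of which map to the undetermined state (`NA` in the
#' returned data frame). An optional `is_internal_control` column (0/1)
#' flags the panel's internal control assays.
#'
#' @param path Path to a TSV or CSV file.
#' @param sep Field separator; guessed from the file extension when `NULL`
#'   (`.csv` means comma, anything else tab).
#' @return A data frame with columns `mirna_id`, `pool_id`, `replicate`,
#'   `ct` (numeric, `NA` = undetermined) and `is_internal_control` (logical).
#' @export
read_ct_table <- function(path, sep = NULL) {
  if (!file.exists(path))
    stop("CT table not found: ", path, call. = FALSE)
  if (is.null(sep))
    sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "",
                           blank.lines.skip = FALSE, na.strings = NULL)
  required <- c("mirna_id", "pool_id", "replicate", "ct")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0)
    stop("CT table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  ct <- parse_ct_values(raw$ct, line_offset = 1L)
  replicate <- suppressWarnings(as.integer(raw$replicate))
  bad_rep <- which(is.na(replicate) | !replicate %in% c(1L, 2L))
  if (length(bad_rep) > 0)
    stop("invalid replicate index at line ", bad_rep[1] + 1L,
         " (must be 1 or 2)", call. = FALSE)
  icc <- if ("is_internal_control" %in% names(raw)) {
    raw$is_internal_control %in% c("1", "TRUE", "true", "yes")
  } else {
    rep(FALSE, nrow(raw))
  }
  key <- paste(raw$mirna_id, raw$pool_id, replicate, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0)
    stop("duplicate (mirna_id, pool_id, replicate) at line ", dup[1] + 1L,
         ": ", raw$mirna_id[dup[1]], " / ", raw$pool_id[dup[1]],
         " / replicate ", replicate[dup[1]], call. = FALSE)
  data.frame(
    mirna_id = raw$mirna_id,
    pool_id = raw$pool_id,
    replicate = replicate,
    ct = ct,
    is_internal_control = icc,
    stringsAsFactors = FALSE
  )
}

# Parse a character vector of CT tokens; undetermined tokens -> NA,
# anything else must be a positive number. Errors carry the 1-based data
# line (line_offset accounts for the header).
parse_ct_values <- function(tokens, line_offset = 0L) {
  trimmed <- trimws(tokens)
  und <- tolower(trimmed) %in% UNDETERMINED_TOKENS
  out <- rep(NA_real_, length(tokens))
  num <- suppressWarnings(as.numeric(trimmed[!und]))
  bad <- which(!und)[is.na(num)]
  if (length(bad) > 0)
    stop("unparseable ct value ", dQuote(tokens[bad[1]]), " at line ",
         bad[1] + line_offset, call. = FALSE)
  nonpos <- which(!und)[!is.na(num) & num <= 0]
  if (length(nonpos) > 0)
    stop("non-positive ct value at line ", nonpos[1] + line_offset,
         call. = FALSE)
  out[!und] <- num
  out
}

#' Replicate standard deviation of a CT duplicate
#'
#' SD of two technical replicates. With the default `"n-1"` (sample)
#' denominator this is `|a - b| / sqrt(2)`; with `"n"` it is `|a - b| / 2`.
#'
#' @param ct_a,ct_b Numeric CT values in cycles. Undetermined (`NA`) inputs
#'   are a domain error: the SD of an undetermined pair is undefined.
#' @param denominator `"n-1"` or `"n"`.
#' @return SD in cycles.
#' @export
replicate_sd <- function(ct_a, ct_b, denominator = c("n-1", "n")) {
  denominator <- match.arg(denominator)
  if (anyNA(ct_a) || anyNA(ct_b))
    stop("replicate_sd is undefined for undetermined CT values",
         call. = FALSE)
  d <- abs(ct_a - ct_b)
  if (denominator == "n-1") d / sqrt(2) else d / 2
}

#' Call the amplification status of one CT duplicate
#'
#' Three-level classification of a technical duplicate:
#' * `"high"` — both replicates numeric, both strictly below the CT cutoff,
#'   and the replicate SD strictly below the SD cutoff;
#' * `"none"` — both replicates undetermined (no amplification detected);
#' * `"low"` — every other combination.
#'
#' A numeric CT at or above the cutoff still counts as *amplified* (the
#' instrument detected a product, just late), so such a pair can never be
#' `"none"`; only a missing/undetermined Cq counts as not amplified.
#'
#' @param ct_a,ct_b CT values in cycles, or `NA` for undetermined.
#' @param config A [status_calling_config()].
#' @return One of `"high"`, `"low"`, `"none"`. Vectorised over the inputs.
#' @export
call_status <- function(ct_a, ct_b, config = status_calling_config()) {
  stopifnot(inherits(config, "status_calling_config"))
  n <- max(length(ct_a), length(ct_b))
  ct_a <- rep_len(as.numeric(ct_a), n)
  ct_b <- rep_len(as.numeric(ct_b), n)
  both_na <- is.na(ct_a) & is.na(ct_b)
  both_num <- !is.na(ct_a) & !is.na(ct_b)
  sd_ok <- rep(FALSE, n)
  if (any(both_num)) {
    sd_val <- replicate_sd(ct_a[both_num], ct_b[both_num],
                           denominator = config$sd_denominator)
    sd_ok[both_num] <- sd_val < config$sd_cutoff
  }
  high <- both_num & ct_a < config$ct_cutoff & ct_b < config$ct_cutoff & sd_ok
  out <- rep("low", n)
  out[both_na] <- "none"
  out[high] <- "high"
  out
}

#' Merge statuses across biological replicates
#'
#' A miRNA called `"high"` in at least one biological replicate (PD sample
#' pool) is `"high"` for the group. Non-high combinations are merged by the
#' maximum under the order none < low < high, so `"low"` in either pool
#' yields `"low"` and only two `"none"` calls stay `"none"`.
#'
#' @param s1,s2 Status vectors with values in `"none"`, `"low"`, `"high"`.
#' @return Merged status vector.
#' @export
merge_biological_replicates <- function(s1, s2) {
  i1 <- match(s1, STATUS_LEVELS)
  i2 <- match(s2, STATUS_LEVELS)
  if (anyNA(i1) || anyNA(i2))
    stop("statuses must be one of ",
         paste(dQuote(STATUS_LEVELS), collapse = ", "), call. = FALSE)
  STATUS_LEVELS[pmax(i1, i2)]
}

#' Call the full status matrix from a replicate-level CT table
#'
#' Computes the per-pool three-level status for every miRNA, then merges
#' pools belonging to the same group (the PD group is screened as two
#' biological-replicate pools) with [merge_biological_replicates()].
#' Internal-control assays are excluded from the matrix and returned as a
#' separate QC report.
#'
#' @param measurements Data frame as returned by [read_ct_table()].
#' @param pool_composition Data frame with columns `pool_id`, `group` and
#'   optionally `n_subjects`. At most two pools may map to one group.
#' @param config A [status_calling_config()].
#' @param group_order Order of groups in the resulting matrix; defaults to
#'   the order of first appearance in `pool_composition`.
#' @return An object of class `status_matrix`: a list with `status`
#'   (character matrix, miRNAs x groups), `pool_status` (miRNAs x pools,
#'   before merging), `groups`, `pool_composition` and `internal_controls`
#'   (per-pool status data frame for the control assays).
#' @export
call_status_matrix <- function(measurements, pool_composition,
                               config = status_calling_config(),
                               group_order = NULL) {
  stopifnot(is.data.frame(measurements), is.data.frame(pool_composition))
  if (!all(c("pool_id", "group") %in% names(pool_composition)))
    stop("`pool_composition` needs columns pool_id and group", call. = FALSE)
  if (anyDuplicated(pool_composition$pool_id))
    stop("duplicate pool_id in `pool_composition`", call. = FALSE)
  pools_per_group <- table(pool_composition$group)
  if (any(pools_per_group > 2))
    stop("unsupported design: more than 2 pools for group(s) ",
         paste(names(pools_per_group)[pools_per_group > 2], collapse = ", "),
         call. = FALSE)
  unknown <- setdiff(unique(measurements$pool_id), pool_composition$pool_id)
  if (length(unknown) > 0)
    stop("measurements reference pool(s) missing from `pool_composition`: ",
         paste(unknown, collapse = ", "), call. = FALSE)

  if (!"is_internal_control" %in% names(measurements))
    measurements$is_internal_control <- FALSE
  pool_ids <- pool_composition$pool_id
  if (is.null(group_order)) group_order <- unique(pool_composition$group)

  pool_status_of <- function(df) {
    # df: measurements for one stratum (assays x pools x replicates)
    mirnas <- sort(unique(df$mirna_id))
    if (length(mirnas) == 0)
      return(matrix(character(0), nrow = 0, ncol = length(pool_ids),
                    dimnames = list(NULL, pool_ids)))
    cnt <- table(factor(df$mirna_id, mirnas), factor(df$pool_id, pool_ids))
    bad <- which(cnt != 2, arr.ind = TRUE)
    if (nrow(bad) > 0)
      stop("expected exactly 2 replicates for miRNA ", mirnas[bad[1, 1]],
           " in pool ", pool_ids[bad[1, 2]], call. = FALSE)
    a <- matrix(NA_real_, length(mirnas), length(pool_ids),
                dimnames = list(mirnas, pool_ids))
    b <- a
    i <- cbind(match(df$mirna_id, mirnas), match(df$pool_id, pool_ids))
    a[i[df$replicate == 1L, , drop = FALSE]] <- df$ct[df$replicate == 1L]
    b[i[df$replicate == 2L, , drop = FALSE]] <- df$ct[df$replicate == 2L]
    matrix(call_status(as.vector(a), as.vector(b), config),
           nrow = length(mirnas), dimnames = list(mirnas, pool_ids))
  }

  assay <- measurements[!measurements$is_internal_control, , drop = FALSE]
  ctrl <- measurements[measurements$is_internal_control, , drop = FALSE]
  pool_status <- pool_status_of(assay)

  status <- matrix(NA_character_, nrow(pool_status), length(group_order),
                   dimnames = list(rownames(pool_status), group_order))
  for (g in group_order) {
    gp <- pool_composition$pool_id[pool_composition$group == g]
    if (length(gp) == 0)
      stop("group ", g, " has no pool in `pool_composition`", call. = FALSE)
    s <- pool_status[, gp[1]]
    if (length(gp) == 2)
      s <- merge_biological_replicates(s, pool_status[, gp[2]])
    status[, g] <- s
  }

  internal_controls <- if (nrow(ctrl) > 0) {
    ps <- pool_status_of(ctrl)
    data.frame(
      mirna_id = rep(rownames(ps), ncol(ps)),
      pool_id = rep(colnames(ps), each = nrow(ps)),
      status = as.vector(ps),
      stringsAsFactors = FALSE
    )
  } else {
    data.frame(mirna_id = character(0), pool_id = character(0),
               status = character(0), stringsAsFactors = FALSE)
  }

  structure(
    list(status = status, pool_status = pool_status, groups = group_order,
         pool_composition = pool_composition,
         internal_controls = internal_controls, config = config),
    class = "status_matrix"
  )
}

#' @export
print.status_matrix <- function(x, ...) {
  cat("Amplification status matrix: ", nrow(x$status), " miRNAs x ",
      length(x$groups), " groups (", paste(x$groups, collapse = ", "),
      ")\n", sep = "")
  tab <- apply(x$status, 2, function(col) table(factor(col, STATUS_LEVELS)))
  print(tab)
  if (nrow(x$internal_controls) > 0)
    cat(length(unique(x$internal_controls$mirna_id)),
        "internal control assay(s) reported separately\n")
  invisible(x)
}

#' Write a status matrix to TSV
#'
#' One row per miRNA, one column per group, values `high`/`low`/`none`;
#' deterministic row order (lexicographic by miRNA).
#'
#' @param sm A `status_matrix`.
#' @param path Output file.
#' @export
write_status_matrix <- function(sm, path) {
  stopifnot(inherits(sm, "status_matrix"))
  df <- data.frame(mirna_id = rownames(sm$status), sm$status,
                   check.names = FALSE, stringsAsFactors = FALSE)
  df <- df[order(df$mirna_id), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
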