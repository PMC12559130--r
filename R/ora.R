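# Term categories of the annotation databases used in the screen.
ORA_CATEGORIES <- c("GO_MF", "GO_BP", "GO_CC", "KEGG")

#' Read a miRNA-to-target map
#'
#' Two-column TSV (`mirna_id`, `gene`); one row per predicted or validated
#' miRNA-target interaction.
#'
#' @param path Path to the TSV.
#' @return Named list mapping miRNA id to a character vector of unique
#'   gene ids.
#' @export
read_target_map <- function(path) {
  if (!file.exists(path))
    stop("target map not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          colClasses = "character", quote = "")
  if (!all(c("mirna_id", "gene") %in% names(df)))
    stop("target map needs columns mirna_id and gene", call. = FALSE)
  lapply(split(df$gene, df$mirna_id), function(g) sort(unique(g)))
}

#' Read a GMT term database
#'
#' Standard GMT format: one tab-separated line per term — term id,
#' description, then the member genes. The term category (`GO_MF`,
#' `GO_BP`, `GO_CC`, `KEGG`) is taken from the description field when it
#' matches a known category, otherwise from `default_category`.
#'
#' @param path Path to the GMT file.
#' @param default_category Category assigned when the description field is
#'   not a recognised category label.
#' @return Object of class `term_db`: list with `terms` (data frame:
#'   `term_id`, `category`), `genes` (term id -> gene vector) and
#'   `background` (union of all member genes).
#' @export
read_gmt <- function(path, default_category = "GO_BP") {
  if (!file.exists(path))
    stop("GMT file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(parts) < 3)
  if (length(short) > 0)
    stop("malformed GMT line ", short[1], ": need term, description, genes",
         call. = FALSE)
  ids <- vapply(parts, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate term ids in GMT", call. = FALSE)
  descr <- vapply(parts, `[[`, character(1), 2)
  category <- ifelse(descr %in% ORA_CATEGORIES, descr, default_category)
  genes <- lapply(parts, function(p) sort(unique(p[-(1:2)])))
  names(genes) <- ids
  structure(
    list(terms = data.frame(term_id = ids, category = category,
                            stringsAsFactors = FALSE),
         genes = genes,
         background = sort(unique(unlist(genes, use.names = FALSE)))),
    class = "term_db"
  )
}

#' Write a term database to GMT
#'
#' @param termdb A `term_db` object.
#' @param path Output file.
#' @export
write_gmt <- function(termdb, path) {
  stopifnot(inherits(termdb, "term_db"))
  lines <- vapply(seq_len(nrow(termdb$terms)), function(i) {
    id <- termdb$terms$term_id[i]
    paste(c(id, termdb$terms$category[i], termdb$genes[[id]]),
          collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Gene union of miRNA target sets
#'
#' Aggregates the predicted target genes of a miRNA list by set union (the
#' "gene union" strategy): every gene targeted by at least one input miRNA
#' enters the query set once. Input miRNAs without an entry in the target
#' map contribute nothing and are reported.
#'
#' @param mirnas Character vector of miRNA ids.
#' @param tmap Named list from [read_target_map()].
#' @return List with `genes` (sorted unique gene vector) and `unmapped`
#'   (miRNAs absent from the map).
#' @export
union_targets <- function(mirnas, tmap) {
  mirnas <- unique(mirnas)
  mapped <- mirnas[mirnas %in% names(tmap)]
  list(
    genes = sort(unique(c(character(0),
                          unlist(tmap[mapped], use.names = FALSE)))),
    unmapped = setdiff(mirnas, mapped)
  )
}

#' Hypergeometric overrepresentation test for one term
#'
#' Upper-tail hypergeometric probability `P[X >= k]` of observing at least
#' the actual overlap between the query gene set and the term's gene set,
#' drawing `|query|` genes without replacement from the background
#' (equivalently a one-sided Fisher test).
#'
#' @param query_genes Query gene set (subset of `background`).
#' @param term_genes Term gene set (subset of `background`).
#' @param background Background gene universe.
#' @return List with `p` and `n_overlap`.
#' @export
term_test <- function(query_genes, term_genes, background) {
  query_genes <- unique(query_genes)
  term_genes <- unique(term_genes)
  background <- unique(background)
  if (length(query_genes) > length(background))
    stop("query larger than background", call. = FALSE)
  if (!all(query_genes %in% background) || !all(term_genes %in% background))
    stop("query and term genes must be subsets of the background",
         call. = FALSE)
  k <- length(intersect(query_genes, term_genes))
  # P[X >= k] with population N, K successes, n draws
  p <- stats::phyper(k - 1, length(term_genes),
                     length(background) - length(term_genes),
                     length(query_genes), lower.tail = FALSE)
  list(p = p, n_overlap = k)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, returned in input order.
#'
#' @param ps Numeric vector of p-values in [0, 1].
#' @return Adjusted values (same length/order).
#' @export
bh_fdr <- function(ps) {
  if (length(ps) == 0) return(numeric(0))
  if (anyNA(ps) || any(ps < 0 | ps > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(ps, method = "BH")
}

#' Signed overrepresentation analysis of disease candidate miRNAs
#'
#' Runs the full ORA for one disease: the exclusively-present and
#' exclusively-absent miRNA sets are analysed separately. For each
#' direction the target genes are aggregated by [union_targets()], every
#' term is tested with the upper-tail hypergeometric test, and BH-FDR is
#' applied within each (category, direction) stratum. Retained terms
#' satisfy `p <= p_threshold`, `fdr < fdr_filter` and have targets from at
#' least `min_mirnas` input miRNAs inside the term. The enrichment ratio is
#' the overlap divided by the term size, negated for the absent direction.
#'
#' @param present_set,absent_set Disjoint miRNA id vectors (either may be
#'   empty).
#' @param tmap Target map from [read_target_map()].
#' @param termdb Term database from [read_gmt()].
#' @param p_threshold Raw p-value threshold (default 0.05).
#' @param fdr_filter FDR filter, strict (default 0.01).
#' @param min_mirnas Minimum number of input miRNAs with at least one
#'   target in the term (default 5).
#' @param background Gene universe; defaults to all genes in the term
#'   database and target map.
#' @return Data frame of enrichment results (columns `term_id`, `category`,
#'   `direction`, `p`, `fdr`, `n_overlap`, `term_size`,
#'   `enrichment_ratio`, `n_contributing_mirnas`), sorted by category then
#'   decreasing `|enrichment_ratio|` (ties: smaller fdr, then term id).
#' @export
run_ora <- function(present_set, absent_set, tmap, termdb,
                    p_threshold = 0.05, fdr_filter = 0.01, min_mirnas = 5,
                    background = NULL) {
  stopifnot(inherits(termdb, "term_db"))
  present_set <- sort(unique(present_set))
  absent_set <- sort(unique(absent_set))
  if (length(intersect(present_set, absent_set)) > 0)
    stop("present and absent sets must be disjoint", call. = FALSE)
  if (is.null(background))
    background <- sort(unique(c(termdb$background,
                                unlist(tmap, use.names = FALSE))))

  test_direction <- function(mirnas, direction) {
    if (length(mirnas) == 0) return(NULL)
    ut <- union_targets(mirnas, tmap)
    query <- intersect(ut$genes, background)
    res <- lapply(seq_len(nrow(termdb$terms)), function(i) {
      id <- termdb$terms$term_id[i]
      term_genes <- intersect(termdb$genes[[id]], background)
      tt <- term_test(query, term_genes, background)
      contributing <- sum(vapply(mirnas, function(m) {
        tg <- tmap[[m]]
        !is.null(tg) && length(intersect(tg, term_genes)) > 0
      }, logical(1)))
      data.frame(
        term_id = id, category = termdb$terms$category[i],
        direction = direction, p = tt$p,
        n_overlap = tt$n_overlap, term_size = length(term_genes),
        enrichment_ratio = (if (direction == "absent") -1 else 1) *
          tt$n_overlap / max(1L, length(term_genes)),
        n_contributing_mirnas = contributing,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, res)
  }

  res <- rbind(test_direction(present_set, "present"),
               test_direction(absent_set, "absent"))
  if (is.null(res) || nrow(res) == 0)
    return(empty_ora_result())
  # BH within each (category, direction) stratum
  res$fdr <- NA_real_
  for (s in split(seq_len(nrow(res)),
                  paste(res$category, res$direction))) {
    res$fdr[s] <- bh_fdr(res$p[s])
  }
  keep <- res$p <= p_threshold & res$fdr < fdr_filter &
    res$n_contributing_mirnas >= min_mirnas
  res <- res[keep, , drop = FALSE]
  res <- res[order(res$category, -abs(res$enrichment_ratio), res$fdr,
                   res$term_id), , drop = FALSE]
  rownames(res) <- NULL
  res[, c("term_id", "category", "direction", "p", "fdr", "n_overlap",
          "term_size", "enrichment_ratio", "n_contributing_mirnas")]
}

empty_ora_result <- function() {
  data.frame(term_id = character(0), category = character(0),
             direction = character(0), p = numeric(0), fdr = numeric(0),
             n_overlap = integer(0), term_size = integer(0),
             enrichment_ratio = numeric(0),
             n_contributing_mirnas = integer(0),
             stringsAsFactors = FALSE)
}

#' Top terms per category and direction
#'
#' Selects the `k` terms with the largest absolute enrichment ratio within
#' each (category, direction) stratum; ties are broken by smaller FDR,
#' then lexicographic term id.
#'
#' @param results Data frame from [run_ora()].
#' @param k Number of terms to keep per stratum (default 5).
#' @return Filtered and ordered data frame.
#' @export
top_terms <- function(results, k = 5) {
  if (k <= 0 || nrow(results) == 0) return(results[0, , drop = FALSE])
  picked <- lapply(split(seq_len(nrow(results)),
                         paste(results$category, results$direction)),
                   function(s) {
    o <- s[order(-abs(results$enrichment_ratio[s]), results$fdr[s],
                 results$term_id[s])]
    o[seq_len(min(k, length(o)))]
  })
  out <- results[sort(unlist(picked)), , drop = FALSE]
  out <- out[order(out$category, out$direction,
                   -abs(out$enrichment_ratio), out$fdr, out$term_id), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
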