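# Named substreams: each generator derives its own seed from the master
# seed and an operation name, so adding a generator never shifts the
# random numbers another one draws.
substream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.double(seed) * 7919 + h * 104729) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(substream_seed(seed, name))
  expr
}

# Default per-group parameters of the study population: sizes, age, sex,
# disease duration, cumulative wetting length, miRNA concentration and the
# per-group concentration~WL correlation, plus ophthalmic flag frequencies.
DEFAULT_GROUPS <- c("control", "PD", "MSA", "PSP")

default_group_params <- function() {
  list(
    group_sizes = c(control = 10, PD = 29, MSA = 7, PSP = 10),
    age_mean = c(control = 74, PD = 68, MSA = 67, PSP = 72),
    age_sd = c(control = 8.2, PD = 9.1, MSA = 13, PSP = 5.8),
    sex_fraction_female = c(control = 0.30, PD = 0.17, MSA = 0.29,
                            PSP = 0.60),
    duration_mean = c(PD = 8.3, MSA = 1.9, PSP = 2.7),
    duration_sd = c(PD = 0.7, MSA = 0.9, PSP = 1.6),
    wl_mean = c(control = 37, PD = 21, MSA = 20, PSP = 18),
    wl_sd = c(control = 22, PD = 17, MSA = 21, PSP = 9),
    conc_mean = c(control = 22, PD = 13, MSA = 12, PSP = 17),
    conc_sd = c(control = 15, PD = 10, MSA = 13, PSP = 11),
    target_corr_conc_wl = c(control = 0.68, PD = 0.58, MSA = 0.91,
                            PSP = 0.74),
    eye_disease_prob = c(control = 0.30, PD = 0.28, MSA = 0.14, PSP = 0.20),
    eye_medication_prob = c(control = 0.40, PD = 0.24, MSA = 0.14,
                            PSP = 0.10),
    anticholinergic_prob = c(control = 0.10, PD = 0.24, MSA = 0.14,
                             PSP = 0.20),
    anticholinergic_missing_prob = c(control = 0.20, PD = 0, MSA = 0,
                                     PSP = 0),
    hy_mean = c(PD = 2.2), hy_sd = c(PD = 1)
  )
}

#' Cohort simulation configuration
#'
#' Per-group parameters of the simulated study population. Defaults mirror
#' the published cohort: group sizes 10 (control), 29 (PD), 7 (MSA),
#' 10 (PSP); group means/SDs for age, disease duration, cumulative wetting
#' length (mm/5 min) and miRNA concentration (ng/ul); per-group target
#' Pearson correlation between concentration and wetting length; and
#' frequencies of the ophthalmic/medication flags.
#'
#' @param ... Named overrides of any default parameter (see
#'   `default_group_params()` internals); vectors are matched by group
#'   name and merged into the defaults.
#' @param seed Master seed of the generator.
#' @return Object of class `cohort_config`.
#' @export
cohort_config <- function(..., seed = 1L) {
  cfg <- default_group_params()
  overrides <- list(...)
  unknown <- setdiff(names(overrides), names(cfg))
  if (length(unknown) > 0)
    stop("unknown cohort parameter(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (nm in names(overrides)) {
    v <- overrides[[nm]]
    if (nm == "group_sizes" || is.null(names(v)) ||
        !all(names(v) %in% names(cfg[[nm]]))) {
      # group_sizes replaces wholesale: it defines which groups exist
      cfg[[nm]] <- v
    } else {
      cfg[[nm]][names(v)] <- v
    }
  }
  bad_group <- setdiff(names(cfg$group_sizes), DEFAULT_GROUPS)
  if (length(bad_group) > 0)
    stop("invalid group name(s): ", paste(bad_group, collapse = ", "),
         call. = FALSE)
  if (any(cfg$group_sizes <= 0) || any(cfg$group_sizes != round(cfg$group_sizes)))
    stop("group sizes must be positive integers", call. = FALSE)
  for (nm in grep("_sd$", names(cfg), value = TRUE))
    if (any(cfg[[nm]] < 0))
      stop("standard deviations must be >= 0 (", nm, ")", call. = FALSE)
  if (any(abs(cfg$target_corr_conc_wl) > 1))
    stop("target correlations must lie in [-1, 1]", call. = FALSE)
  cfg$seed <- as.integer(seed)
  class(cfg) <- "cohort_config"
  cfg
}

#' Simulate a clinical cohort
#'
#' Draws one clinical record per subject. Within each group, (miRNA
#' concentration, cumulative wetting length) are drawn from a bivariate
#' normal with the configured means, SDs and target correlation, then
#' truncated at 0 (and the cumulative WL capped at 70 mm, the physical
#' two-strip maximum). The cumulative WL is split between the eyes by a
#' Beta(5, 5) fraction constrained so that each eye stays within the 35 mm
#' strip while the two eyes still sum to the drawn cumulative value.
#' Disease duration is drawn for the disease groups only (truncated at
#' 0.1 years); Hoehn & Yahr stage for PD. Output is fully determined by
#' the config seed.
#'
#' @param config A [cohort_config()].
#' @return Data frame of clinical records (see [read_clinical_table()] for
#'   the column set).
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  with_substream(config$seed, "generate_cohort", {
    rows <- lapply(names(config$group_sizes), function(g) {
      n <- config$group_sizes[[g]]
      age <- round(stats::rnorm(n, config$age_mean[[g]],
                                config$age_sd[[g]]))
      age <- pmax(age, 18)
      sex <- ifelse(stats::runif(n) < config$sex_fraction_female[[g]],
                    "F", "M")
      rho <- config$target_corr_conc_wl[[g]]
      z1 <- stats::rnorm(n)
      z2 <- rho * z1 + sqrt(1 - rho^2) * stats::rnorm(n)
      conc <- pmax(0, config$conc_mean[[g]] + config$conc_sd[[g]] * z1)
      wl <- pmin(70, pmax(0, config$wl_mean[[g]] + config$wl_sd[[g]] * z2))
      b <- stats::rbeta(n, 5, 5)
      wl_left <- pmin(pmax(wl * b, wl - 35), 35)
      wl_right <- wl - wl_left
      duration <- if (g == "control") rep(NA_real_, n) else
        pmax(0.1, round(stats::rnorm(n, config$duration_mean[[g]],
                                     config$duration_sd[[g]]), 1))
      hy <- if (g == "PD")
        pmin(5, pmax(1, round(stats::rnorm(n, config$hy_mean[["PD"]],
                                           config$hy_sd[["PD"]]) * 2) / 2))
      else rep(NA_real_, n)
      tri_flag <- function(p_yes, p_missing) {
        u <- stats::runif(n)
        out <- ifelse(stats::runif(n) < p_yes, "yes", "no")
        out[u < p_missing] <- NA_character_
        out
      }
      data.frame(
        subject_id = sprintf("%s_%02d", g, seq_len(n)),
        group = g, age = age, sex = sex,
        disease_duration = duration, hy_stage = hy,
        wl_left = round(wl_left, 1), wl_right = round(wl_right, 1),
        mirna_conc = round(conc, 2),
        eye_disease = tri_flag(config$eye_disease_prob[[g]], 0),
        eye_medication = tri_flag(config$eye_medication_prob[[g]], 0),
        anticholinergic = tri_flag(
          config$anticholinergic_prob[[g]],
          config$anticholinergic_missing_prob[[g]]),
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  })
}

#' CT experiment noise configuration
#'
#' Noise model for the replicate-level CT simulation. The margin invariant
#' guarantees that planted high-status amplicons can never be pushed across
#' either cutoff by replicate noise: replicate noise is clamped at four SDs,
#' so the config requires `max(mean_ct_range) + 4 * replicate_sd <
#' ct_cutoff` and `4 * sqrt(2) * replicate_sd < sd_cutoff`.
#'
#' @param mean_ct_range Interval the planted high-status mean CTs are drawn
#'   from (default c(20, 34)).
#' @param replicate_sd Technical replicate SD in cycles (default 0.3).
#' @param dropout_prob_low Probability that a planted low-status duplicate
#'   is realised as one undetermined replicate (otherwise as two numeric
#'   replicates with SD above the cutoff). Default 0.5.
#' @param n_mirnas Panel size (default 1113).
#' @param n_internal_controls Internal control assays (default 3).
#' @param ct_cutoff,sd_cutoff Cutoffs the margins are enforced against
#'   (defaults 40 and 5, matching [status_calling_config()]).
#' @param seed Master seed.
#' @return Object of class `ct_noise_config`.
#' @export
ct_noise_config <- function(mean_ct_range = c(20, 34), replicate_sd = 0.3,
                            dropout_prob_low = 0.5, n_mirnas = 1113,
                            n_internal_controls = 3, ct_cutoff = 40,
                            sd_cutoff = 5, seed = 1L) {
  if (replicate_sd < 0)
    stop("`replicate_sd` must be >= 0", call. = FALSE)
  if (dropout_prob_low < 0 || dropout_prob_low > 1)
    stop("`dropout_prob_low` must be in [0, 1]", call. = FALSE)
  if (length(mean_ct_range) != 2 || mean_ct_range[1] <= 0 ||
      mean_ct_range[1] > mean_ct_range[2])
    stop("`mean_ct_range` must be an increasing interval above 0",
         call. = FALSE)
  if (mean_ct_range[2] + 4 * replicate_sd >= ct_cutoff)
    stop("margin violated: max(mean_ct_range) + 4 * replicate_sd must be ",
         "below ct_cutoff", call. = FALSE)
  if (4 * sqrt(2) * replicate_sd >= sd_cutoff)
    stop("margin violated: 4 * sqrt(2) * replicate_sd must be below ",
         "sd_cutoff", call. = FALSE)
  structure(
    list(mean_ct_range = mean_ct_range, replicate_sd = replicate_sd,
         dropout_prob_low = dropout_prob_low, n_mirnas = n_mirnas,
         n_internal_controls = n_internal_controls, ct_cutoff = ct_cutoff,
         sd_cutoff = sd_cutoff, seed = as.integer(seed)),
    class = "ct_noise_config"
  )
}

#' Default pool layout of the screen
#'
#' The five pooled samples: one control pool, two PD biological-replicate
#' pools (19 and 10 subjects), one MSA and one PSP pool.
#'
#' @return Data frame with `pool_id`, `group`, `n_subjects`.
#' @export
default_pool_composition <- function() {
  data.frame(
    pool_id = c("POOL_CTRL", "POOL_PD_A", "POOL_PD_B", "POOL_MSA",
                "POOL_PSP"),
    group = c("control", "PD", "PD", "MSA", "PSP"),
    n_subjects = c(10L, 19L, 10L, 7L, 10L),
    stringsAsFactors = FALSE
  )
}

#' Generate a random ground-truth status matrix
#'
#' Draws an amplification status for every (miRNA, pool) cell from the
#' given status probabilities — the planted truth that
#' [generate_ct_experiment()] realises as noisy CT replicates.
#'
#' @param n_mirnas Number of panel miRNAs.
#' @param pools Pool ids (default: the five-pool layout).
#' @param probs Named probabilities for `none`, `low`, `high` (summing
#'   to 1).
#' @param seed Master seed.
#' @return Character matrix (miRNAs x pools) of statuses.
#' @export
generate_truth_matrix <- function(n_mirnas = 1113,
                                  pools = default_pool_composition()$pool_id,
                                  probs = c(none = 0.35, low = 0.2,
                                            high = 0.45),
                                  seed = 1L) {
  stopifnot(all(sort(names(probs)) == sort(STATUS_LEVELS)),
            abs(sum(probs) - 1) < 1e-9)
  with_substream(seed, "generate_truth_matrix", {
    mirnas <- sprintf("hsa-sim-miR-%04d", seq_len(n_mirnas))
    matrix(sample(names(probs), n_mirnas * length(pools), replace = TRUE,
                  prob = probs),
           nrow = n_mirnas, dimnames = list(mirnas, pools))
  })
}

#' Simulate a replicate-level CT experiment from a truth matrix
#'
#' Realises each planted status as a technical duplicate:
#' * `high` — two numeric replicates around a mean drawn from
#'   `mean_ct_range`, noise clamped at four replicate SDs, so a
#'   high-certainty call is guaranteed under the configured cutoffs;
#' * `low` — with probability `dropout_prob_low` exactly one replicate is
#'   undetermined (the other numeric); otherwise two numeric replicates
#'   whose SD is guaranteed at or above the SD cutoff;
#' * `none` — both replicates undetermined.
#'
#' Internal-control assays are emitted for every pool as tight numeric
#' duplicates with `is_internal_control = TRUE`.
#'
#' @param truth Character matrix from [generate_truth_matrix()] (miRNAs x
#'   pools).
#' @param noise A [ct_noise_config()]; `n_mirnas` must match `nrow(truth)`.
#' @return Data frame in the layout of [read_ct_table()].
#' @export
generate_ct_experiment <- function(truth, noise = ct_noise_config()) {
  stopifnot(inherits(noise, "ct_noise_config"), is.matrix(truth))
  bad <- setdiff(unique(as.vector(truth)), STATUS_LEVELS)
  if (length(bad) > 0 || anyNA(truth))
    stop("truth matrix must be complete with statuses in none/low/high",
         call. = FALSE)
  with_substream(noise$seed, "generate_ct_experiment", {
    mirnas <- rownames(truth)
    pools <- colnames(truth)
    n_cells <- length(truth)
    status <- as.vector(truth)

    clamp <- function(x, s) pmin(pmax(x, -4 * s), 4 * s)
    mu <- stats::runif(n_cells, noise$mean_ct_range[1],
                       noise$mean_ct_range[2])
    a <- mu + clamp(stats::rnorm(n_cells, 0, noise$replicate_sd),
                    noise$replicate_sd)
    b <- mu + clamp(stats::rnorm(n_cells, 0, noise$replicate_sd),
                    noise$replicate_sd)

    # low status: either one dropout replicate, or a wide numeric pair
    is_low <- status == "low"
    dropout <- is_low & stats::runif(n_cells) < noise$dropout_prob_low
    drop_first <- stats::runif(n_cells) < 0.5
    wide <- is_low & !dropout
    # spread the pair so the sample SD clears the cutoff with margin
    delta <- noise$sd_cutoff * sqrt(2) *
      stats::runif(n_cells, 1.05, 1.5)
    b[wide] <- a[wide] + delta[wide]
    a[dropout & drop_first] <- NA_real_
    b[dropout & !drop_first] <- NA_real_

    is_none <- status == "none"
    a[is_none] <- NA_real_
    b[is_none] <- NA_real_

    assay <- rbind(
      data.frame(mirna_id = rep(mirnas, length(pools)),
                 pool_id = rep(pools, each = length(mirnas)),
                 replicate = 1L, ct = a, is_internal_control = FALSE,
                 stringsAsFactors = FALSE),
      data.frame(mirna_id = rep(mirnas, length(pools)),
                 pool_id = rep(pools, each = length(mirnas)),
                 replicate = 2L, ct = b, is_internal_control = FALSE,
                 stringsAsFactors = FALSE)
    )

    if (noise$n_internal_controls > 0) {
      ic_ids <- sprintf("internal-control-%d",
                        seq_len(noise$n_internal_controls))
      nic <- length(ic_ids) * length(pools)
      ic_mu <- stats::runif(nic, 18, 25)
      ic <- data.frame(
        mirna_id = rep(ic_ids, length(pools)),
        pool_id = rep(pools, each = length(ic_ids)),
        stringsAsFactors = FALSE
      )
      ic <- rbind(
        cbind(ic, replicate = 1L,
              ct = ic_mu + clamp(stats::rnorm(nic, 0, noise$replicate_sd),
                                 noise$replicate_sd),
              is_internal_control = TRUE),
        cbind(ic, replicate = 2L,
              ct = ic_mu + clamp(stats::rnorm(nic, 0, noise$replicate_sd),
                                 noise$replicate_sd),
              is_internal_control = TRUE)
      )
      assay <- rbind(assay, ic)
    }
    rownames(assay) <- NULL
    assay
  })
}

#' Generate a synthetic target map and term database
#'
#' Builds an annotation fixture for the ORA stage: a miRNA-to-gene target
#' map and a GMT-style term database. Planted terms draw the requested
#' fraction of their genes from the union target set of the designated
#' query miRNAs (making them strongly enriched for that set); all other
#' term genes are drawn uniformly from the rest of the gene universe.
#'
#' @param n_terms Number of terms (planted terms included).
#' @param n_genes Size of the gene universe.
#' @param planted_terms Named numeric vector: term id -> overlap fraction
#'   in [0, 1]. May be empty.
#' @param seed Master seed.
#' @param n_mirnas Number of simulated miRNAs in the target map.
#' @param targets_per_mirna Genes per miRNA target set.
#' @param term_size_range Size interval the term gene sets are drawn from.
#' @param query_mirnas miRNA ids the planted terms are enriched for;
#'   default: the first half of the simulated miRNAs.
#' @param categories Categories cycled over the terms.
#' @return List with `target_map` (as [read_target_map()]), `termdb` (a
#'   `term_db`) and `query_mirnas`.
#' @export
generate_annotation_db <- function(n_terms = 40, n_genes = 1000,
                                   planted_terms = numeric(0), seed = 1L,
                                   n_mirnas = 20, targets_per_mirna = 40,
                                   term_size_range = c(30, 80),
                                   query_mirnas = NULL,
                                   categories = ORA_CATEGORIES) {
  if (length(planted_terms) > 0 &&
      (any(planted_terms < 0) || any(planted_terms > 1)))
    stop("overlap fractions must lie in [0, 1]", call. = FALSE)
  if (length(planted_terms) > n_terms)
    stop("more planted terms than terms", call. = FALSE)
  if (length(planted_terms) > 0 && is.null(names(planted_terms)))
    names(planted_terms) <- sprintf("PLANTED%02d",
                                    seq_along(planted_terms))
  with_substream(seed, "generate_annotation_db", {
    genes <- sprintf("GENE%05d", seq_len(n_genes))
    mirnas <- sprintf("hsa-sim-miR-%04d", seq_len(n_mirnas))
    target_map <- lapply(mirnas, function(m)
      sort(sample(genes, min(targets_per_mirna, n_genes))))
    names(target_map) <- mirnas
    if (is.null(query_mirnas))
      query_mirnas <- mirnas[seq_len(ceiling(n_mirnas / 2))]
    query_union <- sort(unique(unlist(target_map[query_mirnas],
                                      use.names = FALSE)))

    term_ids <- character(n_terms)
    planted_ids <- names(planted_terms)
    if (length(planted_terms) > 0) term_ids[seq_along(planted_ids)] <- planted_ids
    auto <- sprintf("TERM%04d", seq_len(n_terms))
    term_ids[term_ids == ""] <- setdiff(auto, planted_ids)[
      seq_len(sum(term_ids == ""))]

    sizes <- sample(term_size_range[1]:term_size_range[2], n_terms,
                    replace = TRUE)
    term_genes <- vector("list", n_terms)
    for (i in seq_len(n_terms)) {
      if (i <= length(planted_terms)) {
        frac <- planted_terms[[i]]
        n_in <- round(frac * sizes[i])
        if (n_in > length(query_union) ||
            sizes[i] - n_in > n_genes - length(query_union))
          stop("n_genes too small to satisfy the requested overlap",
               call. = FALSE)
        term_genes[[i]] <- sort(c(
          sample(query_union, n_in),
          sample(setdiff(genes, query_union), sizes[i] - n_in)))
      } else {
        term_genes[[i]] <- sort(sample(genes, sizes[i]))
      }
    }
    names(term_genes) <- term_ids
    termdb <- structure(
      list(terms = data.frame(
             term_id = term_ids,
             category = rep_len(categories, n_terms),
             stringsAsFactors = FALSE),
           genes = term_genes,
           background = genes),
      class = "term_db"
    )
    list(target_map = target_map, termdb = termdb,
         query_mirnas = query_mirnas)
  })
}

#' Write a target map to TSV
#'
#' @param tmap Named list (miRNA -> gene vector).
#' @param path Output file.
#' @export
write_target_map <- function(tmap, path) {
  df <- data.frame(
    mirna_id = rep(names(tmap), lengths(tmap)),
    gene = unlist(tmap, use.names = FALSE),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a replicate-level CT table to TSV
#'
#' Undetermined measurements are written as the token `Undetermined`.
#'
#' @param ct_table Data frame from [generate_ct_experiment()].
#' @param path Output file.
#' @export
write_ct_table <- function(ct_table, path) {
  out <- ct_table
  out$ct <- ifelse(is.na(out$ct), "Undetermined",
                   format(out$ct, trim = TRUE, digits = 10))
  out$is_internal_control <- as.integer(out$is_internal_control)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
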