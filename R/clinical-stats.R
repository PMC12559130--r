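#' Cumulative Schirmer wetting length
#'
#' Sum of the per-eye wetting lengths (mm per 5 min). Each eye is measured
#' on a 35 mm Schirmer strip, so the cumulative value lies in [0, 70].
#'
#' @param left,right Per-eye wetting lengths in mm, each in [0, 35].
#' @return Cumulative wetting length in mm. Vectorised.
#' @export
cumulative_wetting <- function(left, right) {
  if (any(is.na(left)) || any(is.na(right)))
    stop("wetting lengths must not be missing", call. = FALSE)
  if (any(left < 0 | left > 35) || any(right < 0 | right > 35))
    stop("per-eye wetting length must be in [0, 35] mm", call. = FALSE)
  left + right
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation of two equal-length vectors. Thin wrapper
#' around [stats::cor()] with the degenerate cases turned into errors.
#'
#' @param xs,ys Numeric vectors, length >= 3, neither constant.
#' @return r in [-1, 1].
#' @export
pearson_r <- function(xs, ys) {
  if (length(xs) != length(ys))
    stop("`xs` and `ys` must have equal length", call. = FALSE)
  if (anyNA(xs) || anyNA(ys))
    stop("missing values not allowed; subset before correlating",
         call. = FALSE)
  if (length(xs) < 3)
    stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(xs) == 0 || stats::sd(ys) == 0)
    stop("constant vector: correlation undefined", call. = FALSE)
  stats::cor(xs, ys)
}

#' Fisher-z confidence interval from summary statistics
#'
#' 95% (or `1 - alpha`) confidence interval for a Pearson correlation given
#' only the coefficient and the sample size, via the Fisher z-transform:
#' `z = atanh(r)` is approximately normal with standard error
#' `1/sqrt(n - 3)`, so the bounds are
#' `tanh(z -/+ z_{1-alpha/2} / sqrt(n - 3))`.
#'
#' @param r Pearson coefficient, strictly inside (-1, 1).
#' @param n Sample size, at least 4.
#' @param alpha Significance level (default 0.05 for a 95% CI).
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @export
fisher_ci_from_summary <- function(r, n, alpha = 0.05) {
  if (!is.numeric(r) || length(r) != 1L || abs(r) >= 1)
    stop("`r` must be a single value strictly inside (-1, 1)", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 4)
    stop("`n` must be at least 4", call. = FALSE)
  if (alpha <= 0 || alpha >= 1)
    stop("`alpha` must be in (0, 1)", call. = FALSE)
  z <- atanh(r)
  hw <- stats::qnorm(1 - alpha / 2) / sqrt(n - 3)
  c(ci_low = tanh(z - hw), ci_high = tanh(z + hw))
}

#' Two-sided p-value for a Pearson correlation from summary statistics
#'
#' Standard t-test accompanying a Pearson correlation:
#' `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2` degrees of freedom.
#'
#' @param r Pearson coefficient, strictly inside (-1, 1).
#' @param n Sample size, at least 3.
#' @return Two-sided p-value.
#' @export
pearson_p <- function(r, n) {
  if (!is.numeric(r) || length(r) != 1L || abs(r) >= 1)
    stop("`r` must be a single value strictly inside (-1, 1)", call. = FALSE)
  if (!is.numeric(n) || length(n) != 1L || n < 3)
    stop("`n` must be at least 3", call. = FALSE)
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

#' Pearson correlation with CI and p-value
#'
#' Convenience wrapper producing the full correlation result: coefficient,
#' sample size, Fisher-z confidence interval and t-based p-value.
#'
#' @param xs,ys Numeric vectors (missing pairs removed pairwise).
#' @param alpha Significance level for the CI.
#' @return List of class `correlation_result` with `r`, `n`, `ci_low`,
#'   `ci_high`, `p`, `alpha`.
#' @export
correlate <- function(xs, ys, alpha = 0.05) {
  keep <- !is.na(xs) & !is.na(ys)
  xs <- xs[keep]; ys <- ys[keep]
  n <- length(xs)
  if (n < 4)
    stop("need at least 4 complete pairs", call. = FALSE)
  r <- pearson_r(xs, ys)
  ci <- if (abs(r) < 1) fisher_ci_from_summary(r, n, alpha) else c(r, r)
  p <- if (abs(r) < 1) pearson_p(r, n) else 0
  structure(
    list(r = r, n = n, ci_low = unname(ci[1]), ci_high = unname(ci[2]),
         p = p, alpha = alpha),
    class = "correlation_result"
  )
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("Pearson r = %.2f (n = %d), %d%% CI [%.2f, %.2f], p = %.3g\n",
              x$r, x$n, round(100 * (1 - x$alpha)), x$ci_low, x$ci_high,
              x$p))
  invisible(x)
}

#' Multiple linear regression with confidence intervals
#'
#' Ordinary least squares fit via [stats::lm()] with t-based confidence
#' intervals and p-values per coefficient. Character/factor covariates are
#' coded as treatment contrasts; `group` defaults to reference level
#' `"control"` and `sex` to `"F"` when those levels are present.
#'
#' @param formula Model formula.
#' @param data Data frame of the outcome and covariates.
#' @param alpha Significance level for the CIs.
#' @return Object of class `regression_result`: list with `coefficients`
#'   (data frame: term, estimate, ci_low, ci_high, p), `outcome`,
#'   `covariates`, `n`, `sigma` and the underlying `lm` fit.
#' @export
fit_linear_model <- function(formula, data, alpha = 0.05) {
  data <- as.data.frame(data)
  vars <- all.vars(formula)
  data <- data[stats::complete.cases(data[, vars, drop = FALSE]), ,
               drop = FALSE]
  for (v in vars) {
    if (is.character(data[[v]])) data[[v]] <- factor(data[[v]])
    if (is.factor(data[[v]])) {
      for (ref in c("control", "F"))
        if (ref %in% levels(data[[v]]))
          data[[v]] <- stats::relevel(data[[v]], ref = ref)
    }
  }
  fit <- stats::lm(formula, data = data)
  if (fit$rank < length(stats::coef(fit)))
    stop("singular design: model matrix is rank deficient", call. = FALSE)
  est <- summary(fit)$coefficients
  ci <- stats::confint(fit, level = 1 - alpha)
  coefs <- data.frame(
    term = rownames(est),
    estimate = est[, "Estimate"],
    ci_low = ci[, 1],
    ci_high = ci[, 2],
    p = est[, "Pr(>|t|)"],
    row.names = NULL,
    stringsAsFactors = FALSE
  )
  structure(
    list(coefficients = coefs,
         outcome = deparse(formula[[2]]),
         covariates = attr(stats::terms(fit), "term.labels"),
         n = nrow(data), sigma = summary(fit)$sigma, fit = fit,
         alpha = alpha),
    class = "regression_result"
  )
}

#' @export
print.regression_result <- function(x, ...) {
  cat("Linear model:", x$outcome, "~",
      paste(x$covariates, collapse = " + "), " (n =", x$n, ")\n")
  df <- x$coefficients
  df$estimate <- round(df$estimate, 3)
  df$ci_low <- round(df$ci_low, 3)
  df$ci_high <- round(df$ci_high, 3)
  df$p <- signif(df$p, 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' One-way ANOVA with Tukey post hoc testing
#'
#' Ordinary one-way analysis of variance across groups followed by
#' Tukey's honest significant differences (the Tukey-Kramer procedure for
#' unequal group sizes), via [stats::aov()] and [stats::TukeyHSD()].
#'
#' @param values Numeric outcome vector.
#' @param groups Group label for each value.
#' @return Object of class `group_test_result`: list with `statistic` (F),
#'   `df`, `p` (overall) and `pairwise` (data frame: group_i, group_j,
#'   diff, adjusted p).
#' @export
one_way_anova <- function(values, groups) {
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]
  groups <- factor(as.character(groups)[keep])
  if (nlevels(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  sizes <- table(groups)
  if (any(sizes < 2))
    stop("every group needs n >= 2 (violated by: ",
         paste(names(sizes)[sizes < 2], collapse = ", "), ")",
         call. = FALSE)
  if (stats::var(values) == 0) {
    # no variation anywhere: independence holds trivially
    lv <- levels(groups)
    ij <- utils::combn(lv, 2)
    return(structure(
      list(statistic = 0,
           df = c(nlevels(groups) - 1, length(values) - nlevels(groups)),
           p = 1,
           pairwise = data.frame(group_i = ij[2, ], group_j = ij[1, ],
                                 diff = 0, p_adj = 1,
                                 stringsAsFactors = FALSE),
           n = length(values)),
      class = "group_test_result"))
  }
  fit <- stats::aov(values ~ groups)
  tab <- summary(fit)[[1]]
  fstat <- tab[1, "F value"]
  p <- tab[1, "Pr(>F)"]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- do.call(rbind, strsplit(rownames(tk), "-", fixed = TRUE))
  pairwise <- data.frame(
    group_i = pairs[, 1], group_j = pairs[, 2],
    diff = tk[, "diff"], p_adj = tk[, "p adj"],
    row.names = NULL, stringsAsFactors = FALSE
  )
  structure(
    list(statistic = fstat, df = c(tab[1, "Df"], tab[2, "Df"]), p = p,
         pairwise = pairwise, n = length(values)),
    class = "group_test_result"
  )
}

#' @export
print.group_test_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.3f, p = %.4g\n",
              x$df[1], x$df[2], x$statistic, x$p))
  pw <- x$pairwise
  pw$diff <- round(pw$diff, 3); pw$p_adj <- signif(pw$p_adj, 3)
  print(pw, row.names = FALSE)
  invisible(x)
}

#' Freeman-Halton exact test for an r x c contingency table
#'
#' Exact conditional test of independence for an r x c table of counts with
#' fixed margins (the Freeman-Halton generalisation of Fisher's exact
#' test). All tables with the observed margins are enumerated recursively
#' and the two-sided p-value is the total null probability of tables no
#' more probable than the observed one (with a small relative tolerance for
#' ties). When the enumeration would exceed `max_tables`, the test falls
#' back to Monte Carlo sampling from the null distribution of tables with
#' the given margins (Patefield's algorithm via [stats::r2dtable()]) and
#' reports the simulation standard error.
#'
#' @param x Matrix of non-negative integer counts, no all-zero row/column.
#' @param max_tables Enumeration budget: beyond this many tables the Monte
#'   Carlo fallback is used.
#' @param mc_samples Number of Monte Carlo tables in the fallback.
#' @param tol Relative tolerance when comparing table probabilities.
#' @return List with `p`, `method` (`"enumeration"` or `"monte carlo"`),
#'   and for the fallback `se` (simulation standard error of `p`).
#' @export
fisher_exact_rxc <- function(x, max_tables = 2e5, mc_samples = 1e5,
                             tol = 1e-7) {
  x <- as.matrix(x)
  if (any(is.na(x)) || any(x < 0) || any(x != round(x)))
    stop("`x` must contain non-negative integer counts", call. = FALSE)
  x <- x[rowSums(x) > 0, colSums(x) > 0, drop = FALSE]
  if (nrow(x) == 0 || ncol(x) == 0)
    stop("table has no non-empty row/column", call. = FALSE)
  if (nrow(x) < 2 || ncol(x) < 2)
    return(list(p = 1, method = "enumeration"))
  rs <- rowSums(x); cs <- colSums(x); n <- sum(x)

  # log null probability of a table with these margins (hypergeometric)
  log_const <- sum(lgamma(rs + 1)) + sum(lgamma(cs + 1)) - lgamma(n + 1)
  logp_table <- function(tab) log_const - sum(lgamma(tab + 1))
  logp_obs <- logp_table(x)
  cutoff <- logp_obs + tol * abs(logp_obs) + 1e-12

  # enumerate all tables with the observed margins, row by row
  nr <- length(rs); nc <- length(cs)
  total_logp <- -Inf
  n_tables <- 0L
  overflow <- FALSE
  fill_row <- function(row_idx, col_rem, lg_acc) {
    if (overflow) return()
    if (row_idx == nr) {
      # last row forced by the column remainders
      n_tables <<- n_tables + 1L
      if (n_tables > max_tables) { overflow <<- TRUE; return() }
      lg <- lg_acc - sum(lgamma(col_rem + 1)) + log_const
      if (lg <= cutoff)
        total_logp <<- max(total_logp, lg) +
          log1p(exp(min(total_logp, lg) - max(total_logp, lg)))
      return()
    }
    target <- rs[row_idx]
    cell <- integer(nc)
    rec <- function(j, rem) {
      if (overflow) return()
      if (j == nc) {
        if (rem > col_rem[nc]) return()
        cell[nc] <<- rem
        fill_row(row_idx + 1L, col_rem - cell,
                 lg_acc - sum(lgamma(cell + 1)))
        return()
      }
      for (v in 0:min(rem, col_rem[j])) {
        cell[j] <<- v
        rec(j + 1L, rem - v)
      }
    }
    rec(1L, target)
  }
  fill_row(1L, cs, 0)

  if (!overflow)
    return(list(p = min(1, exp(total_logp)), method = "enumeration"))

  # Monte Carlo fallback under the same null
  sims <- stats::r2dtable(mc_samples, rs, cs)
  hits <- vapply(sims, function(tab) logp_table(tab) <= cutoff, logical(1))
  p <- mean(hits)
  list(p = p, method = "monte carlo",
       se = sqrt(p * (1 - p) / mc_samples))
}

#' Run the full clinical statistics battery
#'
#' Reproduces the subject-level analysis battery on a clinical table:
#' Pearson correlations (with Fisher-z CIs) of miRNA concentration against
#' cumulative wetting length, age and disease duration, overall and within
#' each group; the wetting-length multiple linear regression on group
#' adjusted for the confounders age and sex; one-way ANOVAs with Tukey post
#' hoc tests for age, disease duration and miRNA concentration; and exact
#' tests on the categorical variables (sex, eye disease, eye medication,
#' anticholinergic medication). Missing values are excluded pairwise per
#' analysis.
#'
#' @param clinical Data frame with the columns of a clinical record:
#'   `subject_id`, `group`, `age`, `sex`, `disease_duration`, `wl_left`,
#'   `wl_right`, `mirna_conc`, and tri-state flags `eye_disease`,
#'   `eye_medication`, `anticholinergic` (values yes/no/NA).
#' @param alpha Significance level.
#' @param drop_sex_covariate If `TRUE`, the wetting-length regression
#'   adjusts for age only.
#' @return Named list of `correlation_result` / `regression_result` /
#'   `group_test_result` / exact-test entries, suitable for
#'   [write_clinical_stats()].
#' @export
clinical_stats_battery <- function(clinical, alpha = 0.05,
                                   drop_sex_covariate = FALSE) {
  clinical <- as.data.frame(clinical)
  clinical$wl_cumulative <- cumulative_wetting(clinical$wl_left,
                                               clinical$wl_right)
  out <- list()
  corr_or_null <- function(x, y) {
    tryCatch(correlate(x, y, alpha), error = function(e) NULL)
  }
  groups <- unique(clinical$group)

  for (spec in list(c("wl", "wl_cumulative"), c("age", "age"),
                    c("duration", "disease_duration"))) {
    label <- spec[1]; col <- spec[2]
    if (!col %in% names(clinical)) next
    sub <- if (label == "duration")
      clinical[clinical$group != "control", , drop = FALSE] else clinical
    out[[paste0("conc_vs_", label, "_overall")]] <-
      corr_or_null(sub$mirna_conc, sub[[col]])
    for (g in intersect(groups, unique(sub$group)))
      out[[paste0("conc_vs_", label, "_", g)]] <-
        corr_or_null(sub$mirna_conc[sub$group == g], sub[[col]][sub$group == g])
  }

  wl_formula <- if (drop_sex_covariate)
    wl_cumulative ~ group + age else wl_cumulative ~ group + age + sex
  out$wl_regression <- fit_linear_model(wl_formula, clinical, alpha)

  for (spec in list(c("age", "age"), c("duration", "disease_duration"),
                    c("conc", "mirna_conc"))) {
    label <- spec[1]; col <- spec[2]
    sub <- if (label == "duration")
      clinical[clinical$group != "control", , drop = FALSE] else clinical
    out[[paste0("anova_", label)]] <-
      tryCatch(one_way_anova(sub[[col]], sub$group),
               error = function(e) NULL)
  }

  for (flag in c("sex", "eye_disease", "eye_medication", "anticholinergic")) {
    if (!flag %in% names(clinical)) next
    keep <- !is.na(clinical[[flag]])
    tab <- table(clinical$group[keep], clinical[[flag]][keep])
    out[[paste0("exact_", flag)]] <-
      tryCatch(c(fisher_exact_rxc(tab), list(n = sum(tab))),
               error = function(e) NULL)
  }

  out[!vapply(out, is.null, logical(1))]
}

#' Write clinical statistics to JSON
#'
#' Serialises the output of [clinical_stats_battery()] to a `stats.json`
#' file at full precision (model fit objects are dropped).
#'
#' @param stats Output of [clinical_stats_battery()].
#' @param path Output file.
#' @export
write_clinical_stats <- function(stats, path) {
  strip <- function(x) {
    if (inherits(x, "regression_result")) x$fit <- NULL
    unclass(x)
  }
  jsonlite::write_json(lapply(stats, strip), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, na = "null")
  invisible(path)
}

#' Read a clinical CSV table
#'
#' Reads a subject-level clinical table (one row per subject; empty cells
#' are missing). Tri-state flags are normalised to `"yes"`/`"no"`/`NA`.
#'
#' @param path Path to the CSV file.
#' @return Data frame of clinical records.
#' @export
read_clinical_table <- function(path) {
  if (!file.exists(path))
    stop("clinical table not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"))
  required <- c("subject_id", "group", "age", "sex", "wl_left", "wl_right",
                "mirna_conc")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0)
    stop("clinical table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  for (flag in c("eye_disease", "eye_medication", "anticholinergic"))
    if (flag %in% names(df))
      df[[flag]] <- ifelse(is.na(df[[flag]]), NA_character_,
                           tolower(as.character(df[[flag]])))
  df
}
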