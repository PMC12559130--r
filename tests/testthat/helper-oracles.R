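# Independent brute-force oracles, written directly from the published
# classification rules and textbook formulas; deliberately naive and kept
# separate from the package implementation paths they check.

# Literal three-rule status predicate: a replicate is "amplified" iff a Cq
# was reported at all; high certainty needs both CT < 40 and SD < 5.
oracle_status <- function(ct_a, ct_b, ct_cutoff = 40, sd_cutoff = 5) {
  amplified_a <- !is.na(ct_a)
  amplified_b <- !is.na(ct_b)
  if (!amplified_a && !amplified_b) return("none")
  if (amplified_a && amplified_b) {
    sdev <- sd(c(ct_a, ct_b))
    if (ct_a < ct_cutoff && ct_b < ct_cutoff && sdev < sd_cutoff)
      return("high")
  }
  "low"
}

# Exact upper-tail overrepresentation p by enumerating every possible draw
# of |query| genes from the background (only feasible for tiny universes).
oracle_hyper_p <- function(query_genes, term_genes, background) {
  n_draw <- length(query_genes)
  k_obs <- length(intersect(query_genes, term_genes))
  draws <- utils::combn(background, n_draw, simplify = FALSE)
  hits <- vapply(draws, function(d)
    length(intersect(d, term_genes)) >= k_obs, logical(1))
  mean(hits)
}

# OLS through the normal equations, no lm().
oracle_ols <- function(X, y) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Two-sided Fisher exact p for a 2x2 table from the point hypergeometric
# probabilities (classic formulation: sum of outcomes no more likely than
# the observed one).
oracle_fisher_2x2 <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); n <- sum(tab)
  k_range <- max(0, cs[1] - rs[2]):min(rs[1], cs[1])
  probs <- dhyper(k_range, rs[1], rs[2], cs[1])
  p_obs <- dhyper(tab[1, 1], rs[1], rs[2], cs[1])
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Tiny helpers for building fixtures in code ---------------------------

make_ct_df <- function(mirna, pool, ct1, ct2, internal = FALSE) {
  data.frame(
    mirna_id = rep(mirna, 2), pool_id = rep(pool, 2),
    replicate = c(1L, 2L), ct = c(ct1, ct2),
    is_internal_control = internal, stringsAsFactors = FALSE
  )
}

write_tsv_tmp <- function(df, ext = ".tsv") {
  path <- tempfile(fileext = ext)
  utils::write.table(df, path,
                     sep = if (ext == ".csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  path
}
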