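test_that("union_targets unions target sets and reports unmapped inputs", {
  tmap <- list(mA = c("g1", "g2"), mB = c("g2", "g3"))
  res <- union_targets(c("mA", "mB"), tmap)
  expect_identical(res$genes, c("g1", "g2", "g3"))
  expect_length(res$unmapped, 0)
  expect_identical(union_targets(character(0), tmap)$genes, character(0))
  res2 <- union_targets(c("mA", "mB", "mX"), tmap)
  expect_identical(res2$genes, c("g1", "g2", "g3"))
  expect_identical(res2$unmapped, "mX")
})

test_that("hypergeometric tail matches exhaustive draw enumeration", {
  bg <- paste0("g", 1:10)
  term <- bg[1:4]
  query <- bg[c(1:4, 9)] # overlap 4 of a 5-gene query
  tt <- term_test(query, term, bg)
  expect_equal(tt$n_overlap, 4)
  expect_equal(tt$p, 6 / 252, tolerance = 1e-12)
  expect_equal(tt$p, oracle_hyper_p(query, term, bg), tolerance = 1e-12)
  # degenerate tails
  expect_equal(term_test(bg[5:9], bg[1:3], bg)$p, 1) # overlap 0: P[X>=0]
  expect_equal(term_test(bg[1:5], bg, bg)$p, 1)      # term = background
  # random small cases against the enumeration oracle
  set.seed(13)
  for (i in 1:15) {
    n_bg <- sample(8:13, 1)
    bg <- paste0("g", seq_len(n_bg))
    term <- sample(bg, sample(2:5, 1))
    query <- sample(bg, sample(3:6, 1))
    expect_equal(term_test(query, term, bg)$p,
                 oracle_hyper_p(query, term, bg), tolerance = 1e-10)
  }
  expect_error(term_test("x1", "g1", c("g1", "g2")), "subset")
  expect_error(term_test(paste0("x", 1:3), "g1", c("g1", "g2")), "larger")
})

test_that("BH adjustment matches hand-computed step-up vectors", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  # hand-computed: sorted p (0.005, 0.04, 0.30), m = 3:
  # q3 = 0.30, q2 = min(0.30, 0.04*3/2) = 0.06, q1 = min(0.06, 0.015)
  expect_equal(bh_fdr(c(0.04, 0.005, 0.30)), c(0.06, 0.015, 0.30))
  ps <- runif(50)
  qs <- bh_fdr(ps)
  expect_true(all(qs >= ps) && all(qs <= 1))
  # monotone: p_i <= p_j implies q_i <= q_j
  o <- order(ps)
  expect_true(all(diff(qs[o]) >= -1e-12))
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted terms pass the filters and rank first", {
  db <- generate_annotation_db(
    n_terms = 24, n_genes = 1200, n_mirnas = 16, targets_per_mirna = 60,
    planted_terms = c(PLANTED_UP = 1.0), seed = 31)
  res <- run_ora(db$query_mirnas, character(0), db$target_map, db$termdb)
  expect_true("PLANTED_UP" %in% res$term_id)
  planted <- res[res$term_id == "PLANTED_UP", ]
  expect_lt(planted$fdr, 0.01)
  expect_gte(planted$n_contributing_mirnas, 5)
  expect_gt(planted$enrichment_ratio, 0)
  # ranks first in its category by |enrichment ratio|
  cat_res <- res[res$category == planted$category, ]
  expect_identical(cat_res$term_id[1], "PLANTED_UP")
  # the planted term attains the minimal p among all terms
  all_p <- vapply(db$termdb$terms$term_id, function(id)
    term_test(union_targets(db$query_mirnas, db$target_map)$genes,
              db$termdb$genes[[id]], db$termdb$background)$p, numeric(1))
  expect_equal(names(which.min(all_p)), "PLANTED_UP")
})

test_that("the absent direction flips the sign at equal magnitude", {
  db <- generate_annotation_db(
    n_terms = 24, n_genes = 1200, n_mirnas = 16, targets_per_mirna = 60,
    planted_terms = c(PLANTED_UP = 1.0), seed = 31)
  up <- run_ora(db$query_mirnas, character(0), db$target_map, db$termdb)
  down <- run_ora(character(0), db$query_mirnas, db$target_map, db$termdb)
  u <- up[up$term_id == "PLANTED_UP", ]
  d <- down[down$term_id == "PLANTED_UP", ]
  expect_equal(d$enrichment_ratio, -u$enrichment_ratio)
  expect_equal(d$p, u$p)
  expect_identical(d$direction, "absent")
  expect_error(run_ora("m1", "m1", db$target_map, db$termdb), "disjoint")
})

test_that("the minimum-miRNA filter removes sparse terms", {
  # one term fully covered by the targets of a single miRNA
  tmap <- list(m1 = paste0("g", 1:10))
  for (i in 2:6) tmap[[paste0("m", i)]] <- paste0("h", i)
  genes <- c(paste0("g", 1:10), paste0("h", 2:6), paste0("z", 1:85))
  termdb <- structure(
    list(terms = data.frame(term_id = "T1", category = "GO_BP",
                            stringsAsFactors = FALSE),
         genes = list(T1 = paste0("g", 1:10)),
         background = genes),
    class = "term_db")
  res <- run_ora(names(tmap), character(0), tmap, termdb,
                 min_mirnas = 5)
  expect_equal(nrow(res), 0) # only 1 contributing miRNA, fdr irrelevant
  res2 <- run_ora(names(tmap), character(0), tmap, termdb, min_mirnas = 1)
  expect_equal(nrow(res2), 1)
})

test_that("run_ora is invariant to miRNA input order", {
  db <- generate_annotation_db(
    n_terms = 16, n_genes = 800, n_mirnas = 12, targets_per_mirna = 50,
    planted_terms = c(P1 = 0.9), seed = 33)
  a <- run_ora(db$query_mirnas, character(0), db$target_map, db$termdb)
  b <- run_ora(rev(db$query_mirnas), character(0), db$target_map,
               db$termdb)
  expect_identical(a, b)
})

test_that("top_terms keeps k per stratum with the stated tie-breaks", {
  res <- data.frame(
    term_id = c("tB", "tA", "tC", "tD"),
    category = "GO_MF", direction = "present",
    p = c(1e-4, 1e-4, 1e-3, 1e-3),
    fdr = c(0.002, 0.001, 0.003, 0.003),
    n_overlap = 5L, term_size = 10L,
    enrichment_ratio = c(0.5, 0.5, 0.5, 0.3),
    n_contributing_mirnas = 6L, stringsAsFactors = FALSE
  )
  top2 <- top_terms(res, k = 2)
  # equal ratio: smaller fdr first; then lexicographic id
  expect_identical(top2$term_id, c("tA", "tB"))
  expect_equal(nrow(top_terms(res, k = 5)), 4) # fewer survivors than k
  expect_equal(nrow(top_terms(res, k = 0)), 0)
})

test_that("GMT and target-map files round-trip", {
  db <- generate_annotation_db(n_terms = 8, n_genes = 300, n_mirnas = 6,
                               seed = 35)
  gmt <- tempfile(fileext = ".gmt")
  write_gmt(db$termdb, gmt)
  back <- read_gmt(gmt)
  expect_identical(back$terms$term_id, db$termdb$terms$term_id)
  expect_identical(back$genes, db$termdb$genes)
  expect_identical(back$terms$category, db$termdb$terms$category)
  tm <- tempfile(fileext = ".tsv")
  write_target_map(db$target_map, tm)
  expect_identical(read_target_map(tm), db$target_map)
})

test_that("unplanted databases are independent of the target map", {
  db <- generate_annotation_db(n_terms = 10, n_genes = 500, n_mirnas = 8,
                               planted_terms = numeric(0), seed = 37)
  db2 <- generate_annotation_db(n_terms = 10, n_genes = 500, n_mirnas = 8,
                                planted_terms = numeric(0), seed = 37)
  # seeded determinism: identical on rerun
  expect_identical(db$termdb$genes, db2$termdb$genes)
  expect_identical(db$target_map, db2$target_map)
  # overlap-infeasible configs are config errors
  expect_error(
    generate_annotation_db(n_terms = 4, n_genes = 30, n_mirnas = 10,
                           targets_per_mirna = 30,
                           planted_terms = c(X = 0), seed = 1,
                           term_size_range = c(25, 28)),
    "too small")
  expect_error(generate_annotation_db(planted_terms = c(A = 1.5)),
               "\\[0, 1\\]")
})
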