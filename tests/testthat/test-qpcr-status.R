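test_that("replicate SD of a duplicate follows the sample formula", {
  expect_equal(replicate_sd(30, 30), 0)
  expect_equal(replicate_sd(30, 38), 8 / sqrt(2), tolerance = 1e-12)
  expect_equal(replicate_sd(35, 36), 1 / sqrt(2), tolerance = 1e-12)
  expect_equal(replicate_sd(30, 38, denominator = "n"), 4)
  expect_error(replicate_sd(NA, 30), "undefined")
})

test_that("call_status implements the three-level rule", {
  cfg <- status_calling_config()
  cases <- list(
    list(35, 36, "high"),            # both < 40, SD 0.707 < 5
    list(NA, NA, "none"),            # not amplified in both replicates
    list(NA, 35, "low"),             # one amplified: in between
    list(30, 38, "low"),             # SD 5.657 >= 5 fails high certainty
    list(40, 35, "low"),             # CT 40 is not < 40, partner amplified
    list(39.9, 39.9, "high"),        # just inside both cutoffs
    list(20, NA, "low")
  )
  for (cs in cases)
    expect_identical(call_status(cs[[1]], cs[[2]], cfg), cs[[3]])
})

test_that("call_status agrees with the literal-rule oracle on a full grid", {
  cfg <- status_calling_config()
  vals <- c(5:45, NA)
  grid <- expand.grid(a = vals, b = vals)
  got <- call_status(grid$a, grid$b, cfg)
  want <- mapply(oracle_status, grid$a, grid$b)
  expect_identical(got, unname(want))
})

test_that("call_status is symmetric and monotone in CT", {
  cfg <- status_calling_config()
  set.seed(42)
  for (i in 1:200) {
    a <- if (runif(1) < 0.2) NA else runif(1, 5, 45)
    b <- if (runif(1) < 0.2) NA else runif(1, 5, 45)
    expect_identical(call_status(a, b, cfg), call_status(b, a, cfg))
    # lowering a numeric CT never demotes a high call
    if (!is.na(a) && call_status(a, b, cfg) == "high") {
      a2 <- a - runif(1, 0, min(4.9, a - 1)) # keep SD inside the cutoff
      if (!is.na(b) && abs(a2 - b) / sqrt(2) < 5)
        expect_identical(call_status(a2, b, cfg), "high")
    }
  }
})

test_that("cutoffs are configurable and strict", {
  cfg <- status_calling_config(ct_cutoff = 35, sd_cutoff = 2)
  expect_identical(call_status(34, 34.5, cfg), "high")
  expect_identical(call_status(35, 34, cfg), "low")
  expect_identical(call_status(30, 30 + 2 * sqrt(2), cfg), "low") # SD == 2
  # the n denominator only matters for |diff| in [5*sqrt(2), 10)
  cfg_n <- status_calling_config(sd_denominator = "n")
  expect_identical(call_status(30, 38, cfg_n), "high") # SD = 8/2 = 4 < 5
  expect_identical(call_status(30, 38), "low")         # SD = 8/sqrt(2) >= 5
})

test_that("biological-replicate merge is the max under none < low < high", {
  expect_identical(merge_biological_replicates("high", "none"), "high")
  expect_identical(merge_biological_replicates("none", "none"), "none")
  expect_identical(merge_biological_replicates("low", "none"), "low")
  s <- c("none", "low", "high")
  for (x in s) for (y in s) {
    # commutative
    expect_identical(merge_biological_replicates(x, y),
                     merge_biological_replicates(y, x))
    # idempotent
    expect_identical(merge_biological_replicates(x, x), x)
    # none is the identity
    expect_identical(merge_biological_replicates(x, "none"), x)
    for (z in s) # associative
      expect_identical(
        merge_biological_replicates(merge_biological_replicates(x, y), z),
        merge_biological_replicates(x, merge_biological_replicates(y, z)))
  }
  expect_error(merge_biological_replicates("high", "maybe"), "statuses")
})

test_that("CT tables round-trip through the TSV reader", {
  df <- rbind(
    make_ct_df("hsa-miR-21-5p", "POOL_PD_A", 27.43, 27.51),
    make_ct_df("hsa-miR-1-3p", "POOL_PD_A", NA, 35.0),
    make_ct_df("ictrl", "POOL_PD_A", 20.1, 20.2, internal = TRUE)
  )
  path <- write_tsv_tmp(within(df, {
    ct <- ifelse(is.na(ct), "Undetermined", ct)
    is_internal_control <- as.integer(is_internal_control)
  }))
  got <- read_ct_table(path)
  expect_equal(got$ct[1], 27.43)
  expect_true(is.na(got$ct[3]))
  expect_identical(got$is_internal_control,
                   c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  # undetermined tokens are case-insensitive; "NA" and "" also count
  df2 <- data.frame(mirna_id = "m", pool_id = "p", replicate = 1:2,
                    ct = c("UNDETERMINED", "na"))
  expect_true(all(is.na(read_ct_table(write_tsv_tmp(df2))$ct)))
})

test_that("malformed CT tables are rejected with line context", {
  df <- data.frame(mirna_id = c("m1", "m1"), pool_id = "p",
                   replicate = c(1L, 1L), ct = c("30", "31"))
  expect_error(read_ct_table(write_tsv_tmp(df)), "duplicate")
  df2 <- data.frame(mirna_id = "m1", pool_id = "p", replicate = 1L,
                    ct = "not-a-number")
  expect_error(read_ct_table(write_tsv_tmp(df2)), "line 2")
  df3 <- data.frame(mirna_id = "m1", pool_id = "p", replicate = 3L,
                    ct = "30")
  expect_error(read_ct_table(write_tsv_tmp(df3)), "replicate")
})

test_that("status matrix merges the two PD pools and routes controls", {
  pools <- default_pool_composition()
  meas <- rbind(
    # m1: high in PD_A, none in PD_B -> PD high (merge rule)
    make_ct_df("m1", "POOL_PD_A", 25, 25.3),
    make_ct_df("m1", "POOL_PD_B", NA, NA),
    make_ct_df("m1", "POOL_CTRL", NA, NA),
    make_ct_df("m1", "POOL_MSA", NA, 33),
    make_ct_df("m1", "POOL_PSP", 41, 41.2),
    # m2: low in PD_A (one dropout), none elsewhere
    make_ct_df("m2", "POOL_PD_A", NA, 30),
    make_ct_df("m2", "POOL_PD_B", NA, NA),
    make_ct_df("m2", "POOL_CTRL", NA, NA),
    make_ct_df("m2", "POOL_MSA", NA, NA),
    make_ct_df("m2", "POOL_PSP", NA, NA),
    # spike-in control assay
    make_ct_df("ictrl-1", "POOL_PD_A", 20, 20.1, internal = TRUE),
    make_ct_df("ictrl-1", "POOL_PD_B", 20, 20.1, internal = TRUE),
    make_ct_df("ictrl-1", "POOL_CTRL", 20, 20.1, internal = TRUE),
    make_ct_df("ictrl-1", "POOL_MSA", 20, 20.1, internal = TRUE),
    make_ct_df("ictrl-1", "POOL_PSP", 20, 20.1, internal = TRUE)
  )
  sm <- call_status_matrix(meas, pools)
  expect_identical(colnames(sm$status), c("control", "PD", "MSA", "PSP"))
  expect_identical(unname(sm$status["m1", ]),
                   c("none", "high", "low", "low"))
  expect_identical(unname(sm$status["m2", ]),
                   c("none", "low", "none", "none"))
  # internal controls excluded from the matrix, present in the QC report
  expect_false("ictrl-1" %in% rownames(sm$status))
  expect_equal(nrow(sm$internal_controls), 5)
  expect_true(all(sm$internal_controls$status == "high"))
})

test_that("incomplete or oversized designs are integrity errors", {
  pools <- default_pool_composition()
  meas <- make_ct_df("m1", "POOL_PD_A", 25, 25.3)[1, ] # missing replicate 2
  expect_error(call_status_matrix(meas, pools), "2 replicates")
  bad_pools <- rbind(pools,
                     data.frame(pool_id = "POOL_PD_C", group = "PD",
                                n_subjects = 5L))
  meas2 <- rbind(make_ct_df("m1", "POOL_PD_A", 25, 25.3))
  expect_error(call_status_matrix(meas2, bad_pools), "more than 2 pools")
})
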