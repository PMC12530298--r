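test_that("group sizes follow the ceil-rank arithmetic on tie-free input", {
  atlas <- assign_groups(distinct_medians(100))
  expect_equal(group_sizes(atlas), c(1L, 4L, 95L))
  # floating-point q*N just above an integer must not inflate the rank
  atlas2 <- assign_groups(distinct_medians(1000))
  expect_equal(group_sizes(atlas2), c(10L, 40L, 950L))
  # generic tie-free property over random sizes
  withr::local_seed(14)
  for (rep in 1:20) {
    N <- sample(50:3000, 1)
    q1 <- stats::runif(1, 0.005, 0.05)
    q2 <- stats::runif(1, q1 + 0.01, 0.3)
    sizes <- group_sizes(assign_groups(distinct_medians(N), q1, q2))
    k1 <- ceiling(q1 * N - 1e-9)
    k2 <- ceiling(q2 * N - 1e-9)
    expect_equal(sizes, as.integer(c(k1, k2 - k1, N - k2)))
  }
})

test_that("full ties resolve by the stable ascending-id rule", {
  m <- tibble::tibble(orthogroup_id = sprintf("og%02d", 1:10),
                      median_aasd = rep(0.5, 10))
  atlas <- assign_groups(m)
  expect_equal(group_sizes(atlas), c(1L, 0L, 9L))
  expect_equal(tidy(atlas)$orthogroup_id[tidy(atlas)$group == 1], "og01")
})

test_that("group membership is invariant to input order", {
  withr::local_seed(33)
  m <- distinct_medians(500)
  m$median_aasd[40:60] <- m$median_aasd[40]   # a boundary tie block
  a1 <- tidy(assign_groups(m))
  a2 <- tidy(assign_groups(m[sample.int(500), ]))
  merged <- dplyr::inner_join(a1, a2, by = "orthogroup_id",
                              suffix = c("_a", "_b"))
  expect_equal(merged$group_a, merged$group_b)
  expect_equal(merged$rank_a, merged$rank_b)
})

test_that("excluded focal genes are scored against fixed thresholds", {
  m <- distinct_medians(200)
  focal <- c("og000001", "og000050", "og000150")  # high, mid, low medians
  atlas <- assign_groups(m, exclude_ids = focal)
  expect_equal(atlas$N, 197)
  ent <- tidy(atlas)
  expect_false(any(ent$in_reference[ent$orthogroup_id %in% focal]))
  # the top focal gene exceeds the Group-1 cutoff, the low one does not
  expect_equal(ent$group[ent$orthogroup_id == "og000001"], 1L)
  expect_equal(ent$group[ent$orthogroup_id == "og000150"], 3L)
  # reference group sizes still follow the arithmetic on N = 197
  expect_equal(group_sizes(atlas, reference_only = TRUE),
               c(2L, 8L, 187L))
})

test_that("focal-gene flagging reports groups, ranks and warnings", {
  m <- distinct_medians(100)
  atlas <- assign_groups(m)
  fl <- flag_candidates(atlas, c(og000001 = "SoxH", og000050 = "FoxA"))
  expect_true(fl$highly_divergent[fl$orthogroup_id == "og000001"])
  expect_equal(fl$group[fl$orthogroup_id == "og000050"], 3L)
  expect_false(fl$highly_divergent[fl$orthogroup_id == "og000050"])
  expect_warning(flag_candidates(atlas, c(missing_og = "Dmrt")),
                 "not present")
})

test_that("non-finite medians are rejected", {
  m <- distinct_medians(10)
  m$median_aasd[3] <- NaN
  expect_error(assign_groups(m), "non-finite")
})

test_that("the pipeline is deterministic end to end", {
  study <- generate_study(n_genes = 30, n_tips = 8, seed = 61)
  cfg <- aasd_config(candidates = "LG", validate_n = 10, seed = 2)
  r1 <- run_pipeline(study, cfg)
  r2 <- run_pipeline(study, cfg)
  expect_identical(tidy(r1$atlas), tidy(r2$atlas))
  expect_identical(r1$validation$r, r2$validation$r)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  run_pipeline(study, aasd_config(candidates = "LG", validate_n = 0,
                                  out_dir = d1))
  run_pipeline(study, aasd_config(candidates = "LG", validate_n = 0,
                                  out_dir = d2))
  expect_identical(readLines(file.path(d1, "atlas.tsv")),
                   readLines(file.path(d2, "atlas.tsv")))
})

test_that("the pipeline consumes FASTA directories and logs filter reasons", {
  dir <- withr::local_tempdir()
  study <- generate_study(n_genes = 15, n_tips = 6, seed = 77, dir = dir)
  run <- run_pipeline(dir, aasd_config(candidates = "LG", validate_n = 0))
  expect_equal(nrow(run$log), 15)
  expect_true(all(run$log$status %in% c("retained", "dropped")))
  expect_equal(sum(run$log$status == "retained"),
               nrow(tidy(run$atlas)))
})

test_that("degenerate inputs fail loudly with per-orthogroup reasons", {
  expect_error(run_pipeline(list()), "empty input")
  study <- generate_study(n_genes = 10, n_tips = 4, seed = 5,
                          dropout_p = 0, gap_block_rate = 0)
  cfg <- aasd_config(candidates = "LG", min_species = 30, validate_n = 0)
  expect_error(run_pipeline(study, cfg), "occupancy")
})

test_that("focal genes route through config into the run report", {
  study <- generate_study(n_genes = 40, n_tips = 8, seed = 91)
  fast <- study$truth$orthogroup_id[study$truth$class == "fast"]
  focal <- stats::setNames(rep("planted", length(fast)), fast)
  run <- run_pipeline(study, aasd_config(candidates = "LG", validate_n = 0,
                                         focal_ids = focal))
  expect_equal(nrow(run$flags), length(fast))
  expect_false(any(tidy(run$atlas)$in_reference[
    tidy(run$atlas)$orthogroup_id %in% fast]))
})

test_that("tidiers and autoplot produce well-formed outputs", {
  study <- generate_study(n_genes = 20, n_tips = 6, seed = 44)
  run <- run_pipeline(study, aasd_config(candidates = "LG", validate_n = 10))
  g <- glance(run)
  expect_equal(g$n_group1 + g$n_group2 + g$n_group3, g$n_reference)
  expect_s3_class(autoplot(run$atlas), "ggplot")
  expect_s3_class(autoplot(run$validation), "ggplot")
  aln <- study$alignments[[1]]
  dm <- distance_matrix(trim_columns(aln)$alignment, load_model("LG"))
  expect_s3_class(autoplot(dm), "ggplot")
  td <- tidy(dm)
  expect_equal(nrow(td), choose(length(dm$labels), 2))
})
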