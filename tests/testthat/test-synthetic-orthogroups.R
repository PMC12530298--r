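test_that("species-tree simulation hits the requested shape and depth", {
  tr <- simulate_species_tree(3, seed = 11, depth = 0.5)
  depths <- ape::node.depth.edgelength(tr)[1:3]
  expect_equal(mean(depths), 0.5, tolerance = 1e-9)

  tr34 <- simulate_species_tree(34, seed = 11, depth = 0.5)
  expect_equal(length(tr34$tip.label), 34)
  expect_equal(tr34$Nnode, 33)
  expect_equal(mean(ape::node.depth.edgelength(tr34)[1:34]), 0.5,
               tolerance = 1e-9)

  expect_identical(ape::write.tree(simulate_species_tree(10, seed = 7)),
                   ape::write.tree(simulate_species_tree(10, seed = 7)))
  expect_error(simulate_species_tree(2, seed = 1), "n_tips")
})

test_that("a zero rate multiplier freezes the root sequence", {
  tr <- simulate_species_tree(6, seed = 3)
  m <- load_model("LG")
  aln <- simulate_alignment(tr, m, gene_rate_profile(0, 50, seed = 5))
  expect_equal(n_species(aln), 6)
  expect_equal(n_sites(aln), 50)
  expect_true(all(apply(aln$seq, 2, function(col) length(unique(col)) == 1)))
})

test_that("pairwise mismatch proportion matches the equal-rates closed form", {
  # two tips at total path 0.3 under the uniform model
  tr <- ape::read.tree(text = "(a:0.15,b:0.15,c:0.05);")
  m <- uniform_aa_model()
  L <- 1e5
  aln <- simulate_alignment(tr, m, gene_rate_profile(1, L, seed = 2024))
  p_obs <- mean(aln$seq["a", ] != aln$seq["b", ])
  p_true <- (19 / 20) * (1 - exp(-20 / 19 * 0.3))
  se <- sqrt(p_true * (1 - p_true) / L)
  expect_lt(abs(p_obs - p_true), 3 * se)
})

test_that("simulated alignments have the contracted shape and no gaps", {
  tr <- simulate_species_tree(34, seed = 8)
  aln <- simulate_alignment(tr, load_model("LG"),
                            gene_rate_profile(1, 200, seed = 1))
  expect_equal(dim(aln$seq), c(34, 200))
  expect_false(any(aln$seq %in% aa_alphabet()$gap_chars))
  expect_setequal(rownames(aln$seq), tr$tip.label)
})

test_that("long-run residue frequencies converge to the stationary law", {
  m <- load_model("LG")
  tr <- simulate_species_tree(4, seed = 5, depth = 0.3)
  aln <- simulate_alignment(tr, m, gene_rate_profile(1, 1e5, seed = 2))
  freq <- table(factor(aln$seq, levels = aa_alphabet()$residues))
  tv <- sum(abs(freq / sum(freq) - m$pi)) / 2
  expect_lt(tv, 0.01)
})

test_that("missingness injection honors its contracts", {
  tr <- simulate_species_tree(34, seed = 9)
  aln <- simulate_alignment(tr, load_model("LG"),
                            gene_rate_profile(1, 40, seed = 3))
  # no-op parameters return the input unchanged
  expect_identical(apply_missingness(aln, 0, 0, seed = 1), aln)
  # determinism
  a1 <- apply_missingness(aln, 0.3, 1, seed = 77)
  a2 <- apply_missingness(aln, 0.3, 1, seed = 77)
  expect_identical(a1, a2)
  # at least three taxa always survive, even under extreme dropout
  a3 <- apply_missingness(aln, 0.95, 0, seed = 5)
  expect_gte(n_species(a3), 3)
})

test_that("taxon dropout matches the conditioned binomial mean", {
  tr <- simulate_species_tree(34, seed = 10)
  aln <- simulate_alignment(tr, load_model("LG"),
                            gene_rate_profile(1, 2, seed = 4))
  n_rep <- 1e4
  kept <- withr::with_seed(123, {
    vapply(seq_len(n_rep),
           function(i) n_species(apply_missingness(aln, 0.5, 0)),
           numeric(1))
  })
  se <- sqrt(34 * 0.25 / n_rep)
  expect_lt(abs(mean(kept) - 17), 3 * se)
})

test_that("study generation plants the right number of fast genes", {
  study <- generate_study(n_genes = 200, n_tips = 6, fast_fraction = 0.05,
                          seed = 5)
  expect_equal(sum(study$truth$class == "fast"), round(200 * 0.05))
  expect_equal(nrow(study$truth), 200)
  # fast genes carry the multiplier in their recorded rho on average
  expect_gt(mean(study$truth$rho[study$truth$class == "fast"]),
            mean(study$truth$rho[study$truth$class == "background"]))
})

test_that("study generation is deterministic and serializes byte-identically", {
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  s1 <- generate_study(n_genes = 50, n_tips = 6, seed = 31, dir = dir1)
  s2 <- generate_study(n_genes = 50, n_tips = 6, seed = 31, dir = dir2)
  expect_identical(s1$truth, s2$truth)
  expect_identical(ape::write.tree(s1$tree), ape::write.tree(s2$tree))
  expect_identical(readLines(file.path(dir1, "truth.tsv")),
                   readLines(file.path(dir2, "truth.tsv")))
  f1 <- file.path(dir1, "og0007.fasta")
  expect_true(file.exists(f1))
  expect_identical(readLines(f1), readLines(file.path(dir2, "og0007.fasta")))
  # FASTA round-trips through the reader
  back <- read_orthogroup(f1)
  expect_equal(back$seq, s1$alignments[["og0007"]]$seq)
})

test_that("a unit fast multiplier is statistically invisible downstream", {
  # planted "fast" genes with multiplier 1 are background draws, so their
  # highly-divergent flag count across replicates should be binomial at the
  # top-5% base rate
  n_rep <- 20
  flags <- withr::with_seed(52, {
    vapply(seq_len(n_rep), function(i) {
      study <- generate_study(n_genes = 120, n_tips = 8,
                              fast_fraction = 0.05, fast_multiplier = 1,
                              seed = sample.int(1e6, 1))
      run <- run_pipeline(study, aasd_config(candidates = "LG",
                                             validate_n = 0))
      fast <- study$truth$orthogroup_id[study$truth$class == "fast"]
      ent <- tidy(run$atlas)
      sum(ent$group[ent$orthogroup_id %in% fast] %in% c(1, 2))
    }, numeric(1))
  })
  n_planted <- round(120 * 0.05) * n_rep
  bt <- stats::binom.test(sum(flags), n_planted, p = 0.05)
  expect_gt(bt$p.value, 0.01)
})

test_that("recovered pairwise distances are consistent with the truth", {
  # pairs simulated at known path distance: ML estimates under the
  # generating model are nearly unbiased at long alignments
  m <- load_model("WAG")
  for (d in c(0.2, 1.0)) {
    tr <- ape::read.tree(text = sprintf("(a:%f,b:%f,c:0.01);", d / 2, d / 2))
    aln <- simulate_alignment(tr, m, gene_rate_profile(1, 1e5, seed = 17))
    est <- distance_matrix(aln, m)$D["a", "b"]
    expect_equal(est, d, tolerance = 0.02)
  }
})
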