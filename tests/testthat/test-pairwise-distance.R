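test_that("identical sequences give zero distance under any model", {
  for (nm in c("LG", "Blosum62")) {
    m <- load_model(nm)
    r <- pairwise_ml_distance("MKVLAASTW", "MKVLAASTW", m)
    expect_equal(r$distance, 0)
    expect_equal(r$n_shared, 9)
  }
})

test_that("the ML distance matches the equal-rates closed form to 1e-6", {
  m <- uniform_aa_model()
  n <- 1000
  for (p in seq(0.01, 0.90, by = 0.01)) {
    k <- round(p * n)
    pair <- mismatch_pair(n, k)
    d <- pairwise_ml_distance(pair$a, pair$b, m)$distance
    expect_equal(d, equal_rates_distance(k / n), tolerance = 1e-6)
  }
})

test_that("fully divergent pairs saturate at the cap", {
  m <- uniform_aa_model()
  r <- pairwise_ml_distance(strrep("A", 50), strrep("R", 50), m)
  expect_equal(r$distance, 10)
  r2 <- pairwise_ml_distance(strrep("A", 50), strrep("R", 50), m, t_max = 4)
  expect_equal(r2$distance, 4)
})

test_that("pairs with no shared residue columns are masked, not fatal", {
  m <- load_model("LG")
  r <- pairwise_ml_distance("AAAA----", "----KKKK", m)
  expect_true(is.na(r$distance))
  expect_equal(r$n_shared, 0)

  aln <- toy_alignment(c(a = "AAAA----", b = "----KKKK", c = "AAAAKKKK"))
  dm <- distance_matrix(aln, m)
  expect_false(dm$mask["a", "b"])
  expect_true(is.na(dm$D["a", "b"]))
  expect_true(dm$mask["a", "c"])
  expect_true(is.finite(dm$D["a", "c"]))
  expect_equal(median_aasd(dm), stats::median(c(dm$D["a", "c"],
                                                dm$D["b", "c"])))
})

test_that("the distance is symmetric and monotone in substitutions", {
  m <- uniform_aa_model()
  pair <- mismatch_pair(200, 30)
  expect_identical(pairwise_ml_distance(pair$a, pair$b, m)$distance,
                   pairwise_ml_distance(pair$b, pair$a, m)$distance)
  dists <- vapply(seq(0, 150, by = 10), function(k) {
    pq <- mismatch_pair(200, k)
    pairwise_ml_distance(pq$a, pq$b, m)$distance
  }, numeric(1))
  expect_true(all(diff(dists) >= 0))
})

test_that("distance matrices recover true path distances from long alignments", {
  m <- load_model("LG")
  tr <- ape::read.tree(
    text = "((a:0.10,b:0.15):0.05,(c:0.20,d:0.25):0.05);")
  truth <- ape::cophenetic.phylo(tr)
  aln <- simulate_alignment(tr, m, gene_rate_profile(1, 1e5, seed = 41))
  dm <- distance_matrix(aln, m)
  D <- dm$D[rownames(truth), colnames(truth)]
  off <- upper.tri(truth)
  expect_true(all(abs(D[off] - truth[off]) / truth[off] < 0.02))
})

test_that("our estimates agree with an independent ML distance implementation", {
  skip_if_not_installed("phangorn")
  m <- load_model("LG")
  tr <- simulate_species_tree(6, seed = 42, depth = 0.4)
  aln <- simulate_alignment(tr, m, gene_rate_profile(1, 500, seed = 7))
  dm <- distance_matrix(aln, m)
  ref <- as.matrix(phangorn::dist.ml(
    phangorn::as.phyDat(aln$seq, type = "AA"), model = "LG"))
  ref <- ref[rownames(dm$D), colnames(dm$D)]
  expect_lt(max(abs(dm$D - ref)), 1e-4)
})

test_that("distance matrices serialize as square TSV with masked NAs", {
  aln <- toy_alignment(c(a = "AAAA----", b = "----KKKK", c = "AAAAKKKK"))
  dm <- distance_matrix(aln, load_model("LG"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_distance_matrix(dm, path)
  back <- utils::read.delim(path)
  expect_equal(back$species, c("a", "b", "c"))
  expect_true(is.na(back$b[1]))
  expect_equal(back$c[1], dm$D["a", "c"], tolerance = 1e-12)
})

test_that("model selection recovers the generating matrix and breaks ties", {
  # single candidate: trivially chosen
  aln <- toy_alignment(c(a = "MKVL", b = "MKIL", c = "MRIL"))
  expect_identical(select_model(aln, "JTT")$model_name, "JTT")

  # equal scores (same matrix under two names): alphabetical winner
  lg_path <- system.file("extdata", "models", "LG.dat", package = "aasd")
  twins <- list(load_model(lg_path, name = "Zed"),
                load_model(lg_path, name = "Abel"))
  expect_identical(select_model(aln, twins)$model_name, "Abel")

  # self-consistency: data simulated under WAG picks WAG
  tr <- simulate_species_tree(34, seed = 12, depth = 0.5)
  wag <- load_model("WAG")
  aln2 <- simulate_alignment(tr, wag, gene_rate_profile(1, 2000, seed = 13))
  sel <- select_model(aln2, c("LG", "WAG", "JTT"))
  expect_identical(sel$model_name, "WAG")
  expect_equal(sel$n_pairs, 34 * 33 / 2)
  expect_identical(tidy(sel)$model[1], "WAG")
})

test_that("median AASD follows the midpoint convention", {
  mk <- function(vals) {
    D <- matrix(0, 3, 3)
    D[upper.tri(D)] <- vals
    D + t(D)
  }
  expect_equal(median_aasd(mk(c(0.1, 0.2, 0.4))), 0.2)
  D2 <- matrix(c(0, 0.1, NA, 0.1, 0, 0.3, NA, 0.3, 0), 3, 3)
  expect_equal(median_aasd(D2), 0.2)
  aln <- toy_alignment(c(a = "AAA", b = "AAA", c = "AAA"))
  expect_equal(median_aasd(distance_matrix(aln, uniform_aa_model())), 0)
  allmask <- toy_alignment(c(a = "A---", b = "-K--", c = "--L-"))
  expect_error(median_aasd(distance_matrix(allmask, uniform_aa_model())),
               "masked")
})
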