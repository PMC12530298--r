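# Shared fixtures: tiny alignments and model objects built in code.

toy_alignment <- function(strings, id = "og_toy") {
  aa_alignment(strings, id = id)
}

# n distinct, strictly decreasing medians with stable ids
distinct_medians <- function(n) {
  tibble::tibble(
    orthogroup_id = sprintf("og%06d", seq_len(n)),
    median_aasd = seq(2, 0.01, length.out = n)
  )
}

# a random tree-metric (additive) distance matrix plus its generating tree
random_additive_matrix <- function(n) {
  tr <- ape::rtree(n, br = function(k) stats::runif(k, 0.05, 1))
  list(tree = tr, D = ape::cophenetic.phylo(tr))
}

# closed-form ML distance of the equal-rates model at mismatch proportion p
equal_rates_distance <- function(p) -(19 / 20) * log(1 - (20 / 19) * p)

# two residue strings of length n differing in exactly k positions
mismatch_pair <- function(n, k) {
  a <- rep("A", n)
  b <- a
  if (k > 0) b[seq_len(k)] <- rep(c("R", "N", "D", "C", "Q"), length.out = k)
  list(a = paste(a, collapse = ""), b = paste(b, collapse = ""))
}
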