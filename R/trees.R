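#' Neighbor-joining tree from a distance matrix
#'
#' Saitou--Nei neighbor joining with two deterministic conventions: ties in
#' the Q-criterion are broken by the first pair in row-major scan order
#' (i.e., by label order of the current clusters), and negative branch
#' lengths are clamped to zero with the deficit transferred to the sister
#' branch so that the joined pair's path length is preserved. On an additive
#' (tree-like) matrix the input path metric is reproduced exactly.
#'
#' @param dm An [distance_matrix()] result or a symmetric numeric matrix
#'   with dimnames. All entries among retained taxa must be unmasked.
#' @return An unrooted `ape::phylo` tree.
#' @seealso [tip_to_tip()]
#' @export
nj_tree <- function(dm) {
  if (inherits(dm, "aasd_dist")) {
    if (!all(dm$mask)) stop("masked entries among retained taxa; ",
                            "drop unestimable taxa before tree building")
    D <- dm$D
  } else {
    D <- as.matrix(dm)
    if (anyNA(D)) stop("masked (NA) entries among retained taxa")
  }
  n <- nrow(D)
  if (n < 3) stop("need at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))

  # cluster bookkeeping: node ids 1..n are tips, provisional internal ids
  # count upward; the final join creates the (trifurcating) root
  node_of <- seq_len(n)
  next_internal <- n + 1L
  edges <- matrix(0L, 0, 2)
  lens <- numeric(0)

  while (nrow(D) > 3) {
    m <- nrow(D)
    r <- rowSums(D)
    best <- c(NA_integer_, NA_integer_)
    best_q <- Inf
    for (i in 1:(m - 1)) {
      for (j in (i + 1):m) {
        q <- (m - 2) * D[i, j] - r[i] - r[j]
        if (q < best_q - 1e-12) {
          best_q <- q
          best <- c(i, j)
        }
      }
    }
    i <- best[1]; j <- best[2]
    bi <- 0.5 * D[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    bj <- D[i, j] - bi
    if (bi < 0) { bj <- bj + bi; bi <- 0 }
    if (bj < 0) { bi <- bi + bj; bj <- 0 }
    u <- next_internal
    next_internal <- next_internal + 1L
    edges <- rbind(edges, c(u, node_of[i]), c(u, node_of[j]))
    lens <- c(lens, bi, bj)
    du <- 0.5 * (D[i, ] + D[j, ] - D[i, j])
    D <- rbind(cbind(D, du), c(du, 0))
    keep <- setdiff(seq_len(m + 1), c(i, j))
    D <- D[keep, keep, drop = FALSE]
    node_of <- c(node_of, u)[keep]
  }
  # final three-cluster star: closed-form branch lengths
  v <- next_internal
  b1 <- max(0, (D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  b2 <- max(0, (D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  b3 <- max(0, (D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  edges <- rbind(edges, c(v, node_of[1]), c(v, node_of[2]), c(v, node_of[3]))
  lens <- c(lens, b1, b2, b3)

  # renumber internals so the root is n+1, as ape expects
  internals <- sort(unique(edges[edges > n]), decreasing = TRUE)
  remap <- seq_len(max(edges))
  remap[internals] <- n + seq_along(internals)
  edges[] <- remap[edges]
  tree <- structure(
    list(edge = edges, edge.length = unname(lens), tip.label = labels,
         Nnode = length(internals)),
    class = "phylo"
  )
  ape::reorder.phylo(tree, "cladewise")
}

#' Tip-to-tip (patristic) distance matrix of a tree
#'
#' Sums branch lengths along the path between every pair of tips.
#'
#' @param tree An `ape::phylo` tree with branch lengths.
#' @return A symmetric numeric matrix with tip labels as dimnames.
#' @export
#' @examples
#' tr <- ape::read.tree(text = "(a:0.1,b:0.2);")
#' tip_to_tip(tr)
tip_to_tip <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  D <- ape::cophenetic.phylo(tree)
  D[tree$tip.label, tree$tip.label]
}

#' Correlation check of median AASD against tree and covariates
#'
#' Pearson correlations (with two-sided p-values from the t transform)
#' between per-orthogroup median pairwise ML distances and (i) median
#' tip-to-tip tree distances, (ii) alignment lengths, (iii) species counts.
#' A strong tip-to-tip correlation indicates that the cheap pairwise
#' statistic tracks the phylogenetic signal; weak covariate correlations
#' indicate the statistic is not driven by alignment size or occupancy.
#' Zero-variance vectors yield an `NA` correlation flagged as undefined
#' rather than an error.
#'
#' @param medians Numeric vector of per-orthogroup median AASD values.
#' @param tree_medians Numeric vector of per-orthogroup median tip-to-tip
#'   distances (same length and order).
#' @param lengths,n_species Optional covariate vectors.
#' @return A tibble of class `aasd_validation` with columns `term`, `r`,
#'   `p_value`, `n` and `defined`; the paired data are kept in the
#'   `"data"` attribute for plotting.
#' @export
validate_aasd <- function(medians, tree_medians, lengths = NULL,
                          n_species = NULL) {
  stopifnot(length(medians) == length(tree_medians))
  if (length(medians) < 3) stop("need at least 3 paired orthogroups")
  one <- function(term, y) {
    ok <- is.finite(medians) & is.finite(y)
    x <- medians[ok]; y <- y[ok]
    if (length(x) < 3 || stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(tibble::tibble(term = term, r = NA_real_, p_value = NA_real_,
                            n = length(x), defined = FALSE))
    }
    ct <- stats::cor.test(x, y, method = "pearson")
    tibble::tibble(term = term, r = unname(ct$estimate),
                   p_value = ct$p.value, n = length(x), defined = TRUE)
  }
  rows <- list(one("tip_to_tip", tree_medians))
  if (!is.null(lengths)) rows <- c(rows, list(one("aln_length", lengths)))
  if (!is.null(n_species)) rows <- c(rows, list(one("n_species", n_species)))
  out <- dplyr::bind_rows(rows)
  attr(out, "data") <- tibble::tibble(
    median_aasd = medians, tree_median = tree_medians,
    aln_length = if (is.null(lengths)) NA_real_ else lengths,
    n_species = if (is.null(n_species)) NA_real_ else n_species
  )
  class(out) <- c("aasd_validation", class(out))
  out
}
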