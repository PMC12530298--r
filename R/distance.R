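#' Maximum-likelihood pairwise amino acid distance
#'
#' Estimates the evolutionary distance between two aligned amino acid
#' sequences under an empirical substitution model by maximizing the
#' pairwise likelihood
#' \deqn{L(t) = \sum_{\mathrm{shared\ columns}} \log\left(\pi_a \, P_{ab}(t)\right)}
#' over branch length `t` in `[0, t_max]`. Columns where either sequence has
#' a gap or ambiguity code are skipped. Identical sequences give distance 0;
#' if every shared column differs, the likelihood is maximized at the
#' saturation cap `t_max`. If the two sequences share no residue-bearing
#' column the pair is unestimable and `NA` is returned (a masked pair, not
#' an error).
#'
#' @param seq_a,seq_b Aligned sequences: single strings or character vectors
#'   of residues, equal length.
#' @param model An [load_model()] object.
#' @param t_max Saturation cap in substitutions per site (default 10).
#' @param tol Convergence tolerance on `t` for the bounded Brent
#'   optimization (default 1e-9).
#' @return A list with `distance` (expected substitutions per site, `NA` if
#'   masked), `loglik` (maximized log-likelihood) and `n_shared` (number of
#'   columns where both sequences carry residues).
#' @export
#' @examples
#' m <- uniform_aa_model()
#' a <- strrep("A", 90)
#' b <- paste0(strrep("A", 80), strrep("R", 10))
#' pairwise_ml_distance(a, b, m)$distance
#' # closed form for the equal-rates model at p = 0.1:
#' -(19 / 20) * log(1 - (20 / 19) * 0.1)
pairwise_ml_distance <- function(seq_a, seq_b, model, t_max = 10,
                                 tol = 1e-9) {
  stopifnot(inherits(model, "aa_model"))
  a <- if (length(seq_a) == 1) strsplit(seq_a, "")[[1]] else seq_a
  b <- if (length(seq_b) == 1) strsplit(seq_b, "")[[1]] else seq_b
  if (length(a) != length(b)) stop("sequences must have equal aligned length")
  ca <- encode_residues(a)
  cb <- encode_residues(b)
  counts <- matrix(0, 20, 20)
  ok <- !is.na(ca) & !is.na(cb)
  if (any(ok)) {
    tab <- table(factor(ca[ok], levels = 1:20), factor(cb[ok], levels = 1:20))
    counts <- matrix(as.numeric(tab), 20, 20)
  }
  sp <- model$spectrum
  res <- cpp_ml_from_counts(counts, sp$E1, sp$E2, sp$lambda, model$pi,
                            t_max, tol)
  list(distance = res[1], loglik = res[2], n_shared = res[3])
}

#' Per-orthogroup matrix of ML pairwise distances
#'
#' Fills all unordered species pairs of an orthogroup alignment with
#' [pairwise_ml_distance()] estimates. Pairs with no shared residue columns
#' are masked (`NA` distance, `FALSE` in `mask`) and excluded from all
#' downstream summaries.
#'
#' @param aln An [aa_alignment()] with at least 3 sequences.
#' @inheritParams pairwise_ml_distance
#' @return An object of class `aasd_dist`: list with `id`, `labels`, `D`
#'   (symmetric distance matrix, zero diagonal), `loglik` (per-pair
#'   maximized log-likelihoods), `mask` (logical matrix, `TRUE` where the
#'   pair is estimable) and `model_name`.
#' @seealso [median_aasd()], [select_model()], [nj_tree()]
#' @export
distance_matrix <- function(aln, model, t_max = 10, tol = 1e-9) {
  stopifnot(inherits(aln, "aa_alignment"), inherits(model, "aa_model"))
  if (n_species(aln) < 3) stop("need at least 3 sequences, got ",
                               n_species(aln))
  codes <- encode_alignment(aln)
  sp <- model$spectrum
  res <- cpp_ml_distmat(codes, sp$E1, sp$E2, sp$lambda, model$pi, t_max, tol)
  D <- res$D
  labels <- rownames(aln$seq)
  dimnames(D) <- list(labels, labels)
  mask <- !is.na(D)
  diag(mask) <- TRUE
  dimnames(res$loglik) <- dimnames(D)
  structure(
    list(id = aln$id, labels = labels, D = D, loglik = res$loglik,
         mask = mask, model_name = model$name),
    class = "aasd_dist"
  )
}

#' @export
print.aasd_dist <- function(x, ...) {
  nm <- sum(!x$mask[upper.tri(x$mask)])
  cat("<aasd_dist> ", x$id, ": ", length(x$labels), " taxa, model ",
      x$model_name, if (nm > 0) paste0(", ", nm, " masked pair(s)"), "\n",
      sep = "")
  invisible(x)
}

#' Write a distance matrix as square TSV
#'
#' Serializes an [distance_matrix()] result as a square tab-separated table
#' with species labels in the first column and header; masked pairs are
#' written as `NA`.
#'
#' @param dm An `aasd_dist` object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(dm, path) {
  stopifnot(inherits(dm, "aasd_dist"))
  df <- tibble::as_tibble(dm$D, rownames = "species")
  readr::write_tsv(df, path)
  invisible(path)
}

#' Best-fit model among a candidate set
#'
#' Scores each candidate model by the sum over unordered pairs of the
#' per-pair maximized log-likelihood and picks the maximum. All empirical
#' matrices have the same number of free parameters, so the likelihood
#' ranking coincides with an information-criterion ranking. Ties are broken
#' alphabetically by model name.
#'
#' @param aln An [aa_alignment()] with at least 3 sequences.
#' @param candidates Character vector of model names / file paths, or a list
#'   of `aa_model` objects. Default: the five bundled models.
#' @inheritParams pairwise_ml_distance
#' @return An object of class `aasd_model_selection`: list with `scores`
#'   (tibble of model name and total log-likelihood, sorted), `model_name`
#'   (the winner) and `n_pairs`.
#' @export
select_model <- function(aln, candidates = aa_models(), t_max = 10,
                         tol = 1e-9) {
  if (length(candidates) == 0) stop("empty candidate list")
  models <- lapply(candidates, function(m) {
    if (inherits(m, "aa_model")) m else load_model(m)
  })
  nms <- vapply(models, function(m) m$name, character(1))
  scores <- vapply(models, function(m) {
    dm <- distance_matrix(aln, m, t_max = t_max, tol = tol)
    sum(dm$loglik[upper.tri(dm$loglik)][dm$mask[upper.tri(dm$mask)]],
        na.rm = TRUE)
  }, numeric(1))
  tbl <- tibble::tibble(model = nms, loglik = scores)
  tbl <- tbl[order(-tbl$loglik, tbl$model), ]
  n <- n_species(aln)
  structure(
    list(scores = tbl, model_name = tbl$model[1],
         n_pairs = n * (n - 1) / 2),
    class = "aasd_model_selection"
  )
}

#' @export
print.aasd_model_selection <- function(x, ...) {
  cat("<aasd_model_selection> best: ", x$model_name, " (", x$n_pairs,
      " pairs)\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' Median amino acid sequence divergence of an orthogroup
#'
#' The AASD summary statistic: the median over the unmasked upper-triangle
#' entries of a per-orthogroup distance matrix (diagonal excluded; even
#' counts use the midpoint convention).
#'
#' @param dm An [distance_matrix()] result, or a plain symmetric numeric
#'   matrix.
#' @return The median pairwise distance (a single number).
#' @export
median_aasd <- function(dm) {
  if (inherits(dm, "aasd_dist")) {
    up <- upper.tri(dm$D)
    vals <- dm$D[up & dm$mask]
  } else {
    vals <- dm[upper.tri(dm)]
    vals <- vals[!is.na(vals)]
  }
  if (length(vals) == 0) stop("all pairs are masked; median AASD undefined")
  stats::median(vals)
}
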