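UPPER_ONES <- upper.tri(matrix(0, 20, 20), diag = TRUE) * 1

# Run expr under a fixed RNG seed when one is given, otherwise use the
# caller's RNG stream (so composite generators stay reproducible from a
# single master seed).
with_opt_seed <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

#' Simulate a species tree
#'
#' Draws a pure-birth (Yule) tree and rescales its branch lengths so that
#' the mean root-to-tip path equals `depth` expected substitutions per site
#' (at per-gene rate multiplier 1). The tree is the shared scaffold along
#' which all synthetic orthogroups evolve.
#'
#' @param n_tips Number of species (>= 3).
#' @param seed Integer seed; `NULL` to use the current RNG state.
#' @param depth Target mean root-to-tip path length (> 0), substitutions
#'   per site.
#' @return An `ape::phylo` tree with tip labels `sp01`, `sp02`, ...
#' @export
#' @examples
#' tr <- simulate_species_tree(8, seed = 1)
#' max(ape::node.depth.edgelength(tr))
simulate_species_tree <- function(n_tips, seed = NULL, depth = 0.5) {
  stopifnot(n_tips >= 3, depth > 0)
  with_opt_seed(seed, {
    tree <- ape::rphylo(n_tips, birth = 1, death = 0)
    tree$tip.label <- sprintf("sp%02d", seq_len(n_tips))
    tip_depths <- ape::node.depth.edgelength(tree)[seq_len(n_tips)]
    tree$edge.length <- tree$edge.length * depth / mean(tip_depths)
    tree
  })
}

#' Per-gene rate profile
#'
#' Bundles the generating parameters of one synthetic orthogroup: the
#' per-gene rate multiplier `rho` (branch lengths of the shared species tree
#' are multiplied by `rho` for this gene), its class label, the alignment
#' length, and an optional seed.
#'
#' @param rho Rate multiplier (> 0; 0 is allowed and yields invariant
#'   sequences).
#' @param length Alignment length in sites (>= 1).
#' @param class_label `"background"` or `"fast"`.
#' @param seed Optional integer seed for [simulate_alignment()].
#' @return A list of class `gene_rate_profile`.
#' @export
gene_rate_profile <- function(rho, length, class_label = "background",
                              seed = NULL) {
  stopifnot(is.numeric(rho), rho >= 0, length >= 1,
            class_label %in% c("background", "fast"))
  structure(list(rho = rho, length = as.integer(length),
                 class_label = class_label, seed = seed),
            class = "gene_rate_profile")
}

#' Evolve one orthogroup alignment along a species tree
#'
#' The root sequence is drawn site-wise from the model's stationary
#' frequencies; characters then evolve down each branch `b` by sampling from
#' the transition matrix `P(rho * len(b))`. The result has one gap-free
#' aligned sequence per tip, all of length `profile$length`.
#'
#' @param tree An `ape::phylo` species tree with branch lengths.
#' @param model An [load_model()] object (the generating model).
#' @param profile A [gene_rate_profile()].
#' @param id Orthogroup identifier.
#' @return An [aa_alignment()].
#' @export
simulate_alignment <- function(tree, model, profile, id = "orthogroup") {
  stopifnot(inherits(model, "aa_model"),
            inherits(profile, "gene_rate_profile"))
  n_tip <- length(tree$tip.label)
  if (n_tip < 3) stop("tree must have at least 3 tips")
  L <- profile$length
  with_opt_seed(profile$seed, {
    tree <- stats::reorder(tree, "cladewise")  # parents before children
    n_node <- tree$Nnode
    states <- matrix(NA_integer_, n_tip + n_node, L)
    root <- n_tip + 1L
    states[root, ] <- sample.int(20L, L, replace = TRUE, prob = model$pi)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]
      child <- tree$edge[e, 2]
      bl <- profile$rho * tree$edge.length[e]
      if (bl == 0) {
        states[child, ] <- states[parent, ]
        next
      }
      sp <- model$spectrum
      P <- sp$E1 %*% (exp(sp$lambda * bl) * sp$E2)
      P[P < 0] <- 0
      cum <- P %*% UPPER_ONES      # row-wise cumulative probabilities
      cum[, 20] <- 1
      u <- stats::runif(L)
      # inverse-CDF draw, vectorized across sites
      states[child, ] <- rowSums(cum[states[parent, ], , drop = FALSE] < u) + 1L
    }
    mat <- matrix(AA_RESIDUES[states[seq_len(n_tip), , drop = FALSE]],
                  nrow = n_tip, dimnames = list(tree$tip.label, NULL))
    structure(list(id = id, seq = mat), class = "aa_alignment")
  })
}

#' Inject taxon dropout and gap blocks
#'
#' Emulates the missing-data structure of real orthogroups: each taxon is
#' independently removed with probability `dropout_p` (resampling until at
#' least 3 taxa survive), and each surviving sequence receives a
#' Poisson(`gap_block_rate`) number of gap blocks with geometric lengths
#' (mean `mean_block_len`) at uniform positions.
#'
#' @param aln An [aa_alignment()].
#' @param dropout_p Per-taxon removal probability in `[0, 1)`.
#' @param gap_block_rate Expected gap blocks per surviving sequence (>= 0).
#' @param seed Integer seed; `NULL` to use the current RNG state.
#' @param mean_block_len Mean gap block length in sites.
#' @return An [aa_alignment()] with possibly fewer taxa and injected gaps.
#' @export
apply_missingness <- function(aln, dropout_p, gap_block_rate, seed = NULL,
                              mean_block_len = 10) {
  stopifnot(inherits(aln, "aa_alignment"),
            dropout_p >= 0, dropout_p < 1, gap_block_rate >= 0)
  if (dropout_p == 0 && gap_block_rate == 0) return(aln)
  with_opt_seed(seed, {
    n <- n_species(aln)
    L <- n_sites(aln)
    keep <- rep(TRUE, n)
    if (dropout_p > 0) {
      repeat {
        keep <- stats::runif(n) >= dropout_p
        if (sum(keep) >= 3) break
      }
    }
    mat <- aln$seq[keep, , drop = FALSE]
    if (gap_block_rate > 0) {
      for (i in seq_len(nrow(mat))) {
        n_blocks <- stats::rpois(1, gap_block_rate)
        for (b in seq_len(n_blocks)) {
          len <- stats::rgeom(1, 1 / mean_block_len) + 1L
          start <- sample.int(L, 1)
          mat[i, start:min(L, start + len - 1L)] <- "-"
        }
      }
    }
    structure(list(id = aln$id, seq = mat), class = "aa_alignment")
  })
}

#' Generate a synthetic orthogroup study
#'
#' Produces a full synthetic dataset with the statistical structure the
#' divergence atlas assumes: single-copy orthogroups evolved along a shared
#' species tree, per-gene rate multipliers drawn from a right-skewed
#' log-normal background plus a rare planted "fast" class, variable
#' alignment lengths, per-gene taxon dropout and gap injection — together
#' with a truth table recording each gene's generating parameters for
#' recovery tests.
#'
#' The defaults are a desk-scale mirror of a 34-species genome study:
#' 1,000 genes, alignment lengths uniform on 120--600, a 1% fast class at
#' rate multiplier 4, and moderate missingness.
#'
#' @param n_genes Number of orthogroups (>= 10).
#' @param n_tips Number of species.
#' @param fast_fraction Fraction of genes in the fast class (in `[0, 0.5)`);
#'   the planted count is `round(n_genes * fast_fraction)`.
#' @param fast_multiplier Extra rate factor applied to fast genes.
#' @param rate_meanlog,rate_sdlog Parameters of the log-normal background
#'   rate multiplier distribution.
#' @param length_range Integer range alignment lengths are drawn from.
#' @param depth Mean root-to-tip depth of the species tree (substitutions
#'   per site at rate multiplier 1).
#' @param dropout_p,gap_block_rate,mean_block_len Missingness parameters,
#'   see [apply_missingness()].
#' @param model Generating model (registry name or `aa_model`).
#' @param seed Master seed; every random draw in the study derives from it.
#' @param dir Optional output directory; when given, one FASTA per
#'   orthogroup plus `truth.tsv` and `species_tree.nwk` are written.
#' @return A list of class `aasd_study`: `alignments` (named list of
#'   [aa_alignment()]), `truth` (tibble: `orthogroup_id`, `rho`, `class`,
#'   `length`, `n_species`, `model`), `tree` and `params`.
#' @export
#' @examples
#' study <- generate_study(n_genes = 12, n_tips = 6, seed = 7)
#' study$truth
generate_study <- function(n_genes = 1000, n_tips = 34, fast_fraction = 0.01,
                           fast_multiplier = 4, rate_meanlog = 0,
                           rate_sdlog = 0.4, length_range = c(120, 600),
                           depth = 0.5, dropout_p = 0.1, gap_block_rate = 1,
                           mean_block_len = 10, model = "LG", seed = 1,
                           dir = NULL) {
  stopifnot(n_genes >= 10, fast_fraction >= 0, fast_fraction < 0.5)
  mod <- if (inherits(model, "aa_model")) model else load_model(model)
  params <- list(n_genes = n_genes, n_tips = n_tips,
                 fast_fraction = fast_fraction,
                 fast_multiplier = fast_multiplier,
                 rate_meanlog = rate_meanlog, rate_sdlog = rate_sdlog,
                 length_range = length_range, depth = depth,
                 dropout_p = dropout_p, gap_block_rate = gap_block_rate,
                 mean_block_len = mean_block_len, model = mod$name,
                 seed = seed)
  out <- withr::with_seed(as.integer(seed), {
    tree <- simulate_species_tree(n_tips, seed = NULL, depth = depth)
    n_fast <- round(n_genes * fast_fraction)
    fast_idx <- sort(sample.int(n_genes, n_fast))
    rho <- stats::rlnorm(n_genes, rate_meanlog, rate_sdlog)
    rho[fast_idx] <- rho[fast_idx] * fast_multiplier
    lens <- sample(seq(length_range[1], length_range[2]), n_genes,
                   replace = TRUE)
    ids <- sprintf("og%04d", seq_len(n_genes))
    cls <- rep("background", n_genes)
    cls[fast_idx] <- "fast"
    alns <- vector("list", n_genes)
    n_sp <- integer(n_genes)
    for (g in seq_len(n_genes)) {
      prof <- gene_rate_profile(rho[g], lens[g], cls[g])
      aln <- simulate_alignment(tree, mod, prof, id = ids[g])
      aln <- apply_missingness(aln, dropout_p, gap_block_rate,
                               mean_block_len = mean_block_len)
      alns[[g]] <- aln
      n_sp[g] <- n_species(aln)
    }
    names(alns) <- ids
    truth <- tibble::tibble(orthogroup_id = ids, rho = rho, class = cls,
                            length = lens, n_species = n_sp,
                            model = mod$name)
    list(alignments = alns, truth = truth, tree = tree)
  })
  study <- structure(c(out, list(params = params)), class = "aasd_study")
  if (!is.null(dir)) write_study(study, dir)
  study
}

#' @export
print.aasd_study <- function(x, ...) {
  cat("<aasd_study> ", length(x$alignments), " orthogroups, ",
      x$params$n_tips, " species, ", sum(x$truth$class == "fast"),
      " planted fast gene(s), model ", x$params$model, "\n", sep = "")
  invisible(x)
}

#' @rdname generate_study
#' @param study An `aasd_study`.
#' @export
write_study <- function(study, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory '", dir, "'")
  }
  for (aln in study$alignments) {
    write_orthogroup(aln, file.path(dir, paste0(aln$id, ".fasta")))
  }
  readr::write_tsv(study$truth, file.path(dir, "truth.tsv"))
  ape::write.tree(study$tree, file.path(dir, "species_tree.nwk"))
  invisible(dir)
}
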