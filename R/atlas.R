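# ceiling(q * N) robust to binary floating point (0.01 * 100 is slightly
# above 1 in double arithmetic and must still give 1, not 2)
quantile_rank <- function(q, N) {
  as.integer(ceiling(q * N - 1e-9))
}

#' Assign divergence groups by upper quantiles
#'
#' Partitions the per-orthogroup median AASD distribution into three groups:
#' Group 1 is the upper `q1` quantile (default 1%), Group 2 the entries
#' between the `q1` and `q2` (default 5%) upper quantiles, Group 3 the
#' remainder. The quantile convention is rank-based: entries are sorted by
#' descending median (ties broken by ascending orthogroup id, stably); the
#' top `ceil(q1 * N)` form Group 1 and ranks up to `ceil(q2 * N)` complete
#' Group 2. Groups 1 and 2 together are the "highly divergent" genes.
#'
#' Optionally, a set of focal orthogroups can be excluded from threshold
#' estimation (`exclude_ids`): thresholds and group sizes are then computed
#' from the remaining entries only, and each excluded entry is afterwards
#' scored against the realized cutoffs (>= Group-1 cutoff -> Group 1,
#' >= Group-2 cutoff -> Group 2, else Group 3). This mirrors holding
#' candidate genes out of the reference distribution they are judged
#' against.
#'
#' @param medians A data frame with columns `orthogroup_id` and
#'   `median_aasd` (extra columns are carried through), or a named numeric
#'   vector.
#' @param q1,q2 Upper-quantile fractions, `0 < q1 < q2 < 1`.
#' @param exclude_ids Optional orthogroup ids excluded from threshold
#'   estimation.
#' @return An object of class `aasd_atlas`: list with `entries` (tibble
#'   with `rank`, `group`, `in_reference` columns added), `N` (reference
#'   count), `q1`, `q2` and `thresholds` (realized median-AASD cutoffs).
#' @export
#' @examples
#' set.seed(1)
#' m <- tibble::tibble(
#'   orthogroup_id = sprintf("og%03d", 1:100),
#'   median_aasd = rlnorm(100, -1, 0.5)
#' )
#' atlas <- assign_groups(m)
#' glance(atlas)
assign_groups <- function(medians, q1 = 0.01, q2 = 0.05,
                          exclude_ids = NULL) {
  if (is.numeric(medians) && !is.null(names(medians))) {
    medians <- tibble::tibble(orthogroup_id = names(medians),
                              median_aasd = unname(medians))
  }
  stopifnot(is.data.frame(medians),
            all(c("orthogroup_id", "median_aasd") %in% names(medians)),
            q1 > 0, q1 < q2, q2 < 1)
  entries <- tibble::as_tibble(medians)
  if (nrow(entries) < 1) stop("no orthogroups to group")
  if (any(!is.finite(entries$median_aasd))) {
    stop("non-finite median AASD for: ",
         paste(utils::head(
           entries$orthogroup_id[!is.finite(entries$median_aasd)], 3),
           collapse = ", "))
  }
  entries$in_reference <- !(entries$orthogroup_id %in% exclude_ids)
  ref <- entries[entries$in_reference, ]
  N <- nrow(ref)
  if (N < 1) stop("all orthogroups excluded from threshold estimation")
  ord <- order(-ref$median_aasd, ref$orthogroup_id)
  k1 <- quantile_rank(q1, N)
  k2 <- quantile_rank(q2, N)
  thr <- c(group1 = ref$median_aasd[ord[k1]],
           group2 = ref$median_aasd[ord[k2]])
  ref_group <- integer(N)
  ref_group[ord] <- ifelse(seq_len(N) <= k1, 1L,
                           ifelse(seq_len(N) <= k2, 2L, 3L))
  entries$group <- NA_integer_
  entries$group[entries$in_reference] <- ref_group
  out_ref <- !entries$in_reference
  if (any(out_ref)) {
    m <- entries$median_aasd[out_ref]
    entries$group[out_ref] <- ifelse(m >= thr["group1"], 1L,
                                     ifelse(m >= thr["group2"], 2L, 3L))
  }
  # rank over the full table, same descending / id-ascending convention
  full_ord <- order(-entries$median_aasd, entries$orthogroup_id)
  entries$rank <- integer(nrow(entries))
  entries$rank[full_ord] <- seq_len(nrow(entries))
  entries <- entries[order(entries$rank), ]
  structure(
    list(entries = entries, N = N, q1 = q1, q2 = q2, thresholds = thr),
    class = "aasd_atlas"
  )
}

#' @export
print.aasd_atlas <- function(x, ...) {
  sizes <- group_sizes(x)
  cat("<aasd_atlas> ", nrow(x$entries), " orthogroups (",
      x$N, " in reference distribution)\n", sep = "")
  cat("  groups (q1=", x$q1, ", q2=", x$q2, "): ",
      paste0(sizes, collapse = " / "), "\n", sep = "")
  cat("  median-AASD cutoffs: group1 >= ", signif(x$thresholds[1], 4),
      ", group2 >= ", signif(x$thresholds[2], 4), "\n", sep = "")
  invisible(x)
}

#' Group sizes of an atlas
#'
#' @param atlas An [assign_groups()] result.
#' @param reference_only Count only entries in the reference distribution.
#' @return Integer vector of length 3 (Groups 1, 2, 3).
#' @export
group_sizes <- function(atlas, reference_only = FALSE) {
  e <- atlas$entries
  if (reference_only) e <- e[e$in_reference, ]
  vapply(1:3, function(g) sum(e$group == g), integer(1))
}

#' Flag focal genes as highly divergent
#'
#' Looks up a set of focal orthogroups (e.g., candidate sex-determination
#' gene families) in a divergence atlas and reports each one's group,
#' median, rank and a "highly divergent" flag (group 1 or 2). Unknown ids
#' produce a warning and an `NA` row rather than an abort.
#'
#' @param atlas An [assign_groups()] result.
#' @param focal_ids A data frame with columns `orthogroup_id` and `family`,
#'   or a named character vector `orthogroup_id -> family`.
#' @return A tibble with one row per focal gene: `orthogroup_id`, `family`,
#'   `median_aasd`, `rank`, `group`, `highly_divergent`.
#' @export
flag_candidates <- function(atlas, focal_ids) {
  stopifnot(inherits(atlas, "aasd_atlas"))
  if (is.character(focal_ids) && !is.null(names(focal_ids))) {
    focal_ids <- tibble::tibble(orthogroup_id = names(focal_ids),
                                family = unname(focal_ids))
  }
  stopifnot(is.data.frame(focal_ids),
            all(c("orthogroup_id", "family") %in% names(focal_ids)))
  unknown <- setdiff(focal_ids$orthogroup_id, atlas$entries$orthogroup_id)
  if (length(unknown) > 0) {
    warning("focal id(s) not present in the atlas: ",
            paste(unknown, collapse = ", "))
  }
  out <- dplyr::left_join(
    tibble::as_tibble(focal_ids),
    atlas$entries[, c("orthogroup_id", "median_aasd", "rank", "group")],
    by = "orthogroup_id"
  )
  out$highly_divergent <- !is.na(out$group) & out$group %in% c(1L, 2L)
  out
}

#' Pipeline configuration
#'
#' Collects every tunable of [run_pipeline()] with the canonical defaults:
#' 40% gap-threshold trimming, 50/50 spurious-sequence overlap limits,
#' occupancy at half the study species set, the five bundled candidate
#' models, and 1%/5% upper-quantile grouping.
#'
#' @param gap_threshold,gap_rule See [trim_columns()].
#' @param res_overlap,seq_overlap See [remove_spurious_sequences()].
#' @param min_species Occupancy threshold; `NULL` means
#'   `ceiling(0.5 * n_study_species)` with the study species count inferred
#'   from the inputs.
#' @param candidates Candidate model names for [select_model()]; a single
#'   name skips model selection.
#' @param q1,q2 Upper-quantile fractions for [assign_groups()].
#' @param t_max,tol Optimizer settings for [pairwise_ml_distance()].
#' @param validate_n Number of orthogroups sampled (without replacement,
#'   seeded) for the NJ tip-to-tip validation; 0 disables it.
#' @param exclude_focal Hold focal genes out of threshold estimation
#'   (default `TRUE`).
#' @param focal_ids Optional focal gene map, see [flag_candidates()].
#' @param seed Seed for the validation subsample.
#' @param out_dir Optional directory for TSV outputs.
#' @return A list of class `aasd_config`.
#' @export
aasd_config <- function(gap_threshold = 0.40,
                        gap_rule = "min_residue_fraction",
                        res_overlap = 0.5, seq_overlap = 50,
                        min_species = NULL, candidates = aa_models(),
                        q1 = 0.01, q2 = 0.05, t_max = 10, tol = 1e-9,
                        validate_n = 200, exclude_focal = TRUE,
                        focal_ids = NULL, seed = 1, out_dir = NULL) {
  structure(
    list(gap_threshold = gap_threshold, gap_rule = gap_rule,
         res_overlap = res_overlap, seq_overlap = seq_overlap,
         min_species = min_species, candidates = candidates, q1 = q1,
         q2 = q2, t_max = t_max, tol = tol, validate_n = validate_n,
         exclude_focal = exclude_focal, focal_ids = focal_ids, seed = seed,
         out_dir = out_dir),
    class = "aasd_config"
  )
}

#' Run the full divergence-atlas pipeline
#'
#' Executes, per orthogroup: gap-threshold trimming, spurious-sequence
#' removal, occupancy filtering, best-fit model selection, ML pairwise
#' distances and the median-AASD summary; then groups the medians by upper
#' quantiles, flags focal genes, and (on a seeded subsample) validates the
#' pairwise statistic against median tip-to-tip distances of per-orthogroup
#' neighbor-joining trees. Orthogroups failing a filter are logged with the
#' reason, not silently dropped.
#'
#' @param input A directory of per-orthogroup FASTA files, a named list of
#'   [aa_alignment()] objects, or an `aasd_study`.
#' @param config An [aasd_config()].
#' @return An object of class `aasd_run`: list with `atlas`
#'   ([assign_groups()] result), `flags` (focal gene report or `NULL`),
#'   `validation` ([validate_aasd()] result or `NULL`), `log` (per-
#'   orthogroup status tibble) and `config`. If `config$out_dir` is set,
#'   `atlas.tsv`, `log.tsv` and (when present) `flags.tsv`,
#'   `validation.tsv` are written there.
#' @export
run_pipeline <- function(input, config = aasd_config()) {
  stopifnot(inherits(config, "aasd_config"))
  alns <- pipeline_inputs(input)
  if (length(alns) == 0) stop("empty input set: no orthogroup alignments")

  n_study <- max(vapply(alns, n_species, integer(1)))
  min_sp <- if (is.null(config$min_species)) occupancy_min(n_study) else
    as.integer(config$min_species)

  models <- lapply(config$candidates,
                   function(m) if (inherits(m, "aa_model")) m else
                     load_model(m))
  names(models) <- vapply(models, function(m) m$name, character(1))

  log_rows <- vector("list", length(alns))
  results <- vector("list", length(alns))
  dms <- vector("list", length(alns))
  for (k in seq_along(alns)) {
    aln <- alns[[k]]
    id <- aln$id
    tr <- trim_columns(aln, config$gap_threshold, config$gap_rule)
    sp <- remove_spurious_sequences(tr$alignment, config$res_overlap,
                                    config$seq_overlap)
    aln2 <- sp$alignment
    if (n_sites(aln2) == 0) {
      log_rows[[k]] <- log_row(id, "dropped", "no columns left after trimming")
      next
    }
    if (!occupancy_filter(aln2, max(2L, min_sp)) ||
        n_species(aln2) < max(3L, min_sp)) {
      log_rows[[k]] <- log_row(
        id, "dropped",
        sprintf("occupancy %d < %d", n_species(aln2), min_sp))
      next
    }
    if (length(models) > 1) {
      sel <- select_model(aln2, models, t_max = config$t_max,
                          tol = config$tol)
      best <- sel$model_name
    } else {
      best <- names(models)[1]
    }
    dm <- distance_matrix(aln2, models[[best]], t_max = config$t_max,
                          tol = config$tol)
    if (sum(dm$mask[upper.tri(dm$mask)]) == 0) {
      log_rows[[k]] <- log_row(id, "dropped", "all pairs masked")
      next
    }
    dms[[k]] <- dm
    results[[k]] <- tibble::tibble(
      orthogroup_id = id,
      median_aasd = median_aasd(dm),
      n_species = n_species(aln2),
      aln_length = n_sites(aln2),
      model = best
    )
    log_rows[[k]] <- log_row(
      id, "retained",
      sprintf("cols_removed=%d seqs_removed=%d",
              tr$report$columns_removed, sp$report$n_removed))
  }
  log_tbl <- dplyr::bind_rows(log_rows)
  medians <- dplyr::bind_rows(results)
  if (nrow(medians) == 0)

    stop("all orthogroups were filtered out; see the run log:\n",
         paste(utils::capture.output(print(log_tbl)), collapse = "\n"))

  exclude <- NULL
  if (config$exclude_focal && !is.null(config$focal_ids)) {
    fids <- config$focal_ids
    exclude <- if (is.data.frame(fids)) fids$orthogroup_id else names(fids)
  }
  atlas <- assign_groups(medians, q1 = config$q1, q2 = config$q2,
                         exclude_ids = exclude)
  flags <- if (!is.null(config$focal_ids)) {
    flag_candidates(atlas, config$focal_ids)
  }

  validation <- NULL
  if (config$validate_n > 0) {
    ok <- which(!vapply(dms, is.null, logical(1)))
    full <- ok[vapply(dms[ok], function(d) all(d$mask), logical(1))]
    if (length(full) >= 3) {
      take <- withr::with_seed(as.integer(config$seed), {
        sample(full, min(config$validate_n, length(full)))
      })
      tree_med <- vapply(dms[take], function(d) {
        tt <- tip_to_tip(nj_tree(d))
        stats::median(tt[upper.tri(tt)])
      }, numeric(1))
      pair_med <- vapply(dms[take], median_aasd, numeric(1))
      cov <- dplyr::bind_rows(results[take])
      validation <- validate_aasd(pair_med, tree_med,
                                  lengths = cov$aln_length,
                                  n_species = cov$n_species)
    }
  }

  run <- structure(
    list(atlas = atlas, flags = flags, validation = validation,
         log = log_tbl, config = config),
    class = "aasd_run"
  )
  if (!is.null(config$out_dir)) write_run(run, config$out_dir)
  run
}

pipeline_inputs <- function(input) {
  if (inherits(input, "aasd_study")) return(input$alignments)
  if (is.character(input) && length(input) == 1) {
    if (!dir.exists(input)) stop("input directory '", input, "' not found")
    files <- sort(list.files(input, pattern = "\\.(fa|fasta|faa)$",
                             full.names = TRUE))
    if (length(files) == 0) stop("no FASTA files in '", input, "'")
    return(lapply(files, read_orthogroup))
  }
  stopifnot(is.list(input), all(vapply(input, inherits, logical(1),
                                       "aa_alignment")))
  input
}

log_row <- function(id, status, reason) {
  tibble::tibble(orthogroup_id = id, status = status, reason = reason)
}

#' @export
print.aasd_run <- function(x, ...) {
  cat("<aasd_run> ", sum(x$log$status == "retained"), " retained / ",
      nrow(x$log), " orthogroups\n", sep = "")
  print(x$atlas)
  if (!is.null(x$validation)) {
    r <- x$validation$r[x$validation$term == "tip_to_tip"]
    cat("  tip-to-tip validation: r = ", signif(r, 3), " (n = ",
        x$validation$n[1], ")\n", sep = "")
  }
  invisible(x)
}

write_run <- function(run, dir) {
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE)) {
    stop("cannot create output directory '", dir, "'")
  }
  readr::write_tsv(run$atlas$entries, file.path(dir, "atlas.tsv"))
  readr::write_tsv(run$log, file.path(dir, "log.tsv"))
  if (!is.null(run$flags)) {
    readr::write_tsv(run$flags, file.path(dir, "flags.tsv"))
  }
  if (!is.null(run$validation)) {
    readr::write_tsv(tibble::as_tibble(run$validation),
                     file.path(dir, "validation.tsv"))
  }
  invisible(dir)
}
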