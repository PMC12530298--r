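#' Tidy a divergence atlas
#'
#' @param x An [assign_groups()] result.
#' @param ... Unused.
#' @return The per-orthogroup entries as a tibble (`orthogroup_id`,
#'   `median_aasd`, `rank`, `group`, `in_reference`, plus any covariates
#'   carried through).
#' @export
tidy.aasd_atlas <- function(x, ...) {
  tibble::as_tibble(x$entries)
}

#' One-row summary of a divergence atlas
#'
#' @param x An [assign_groups()] result.
#' @param ... Unused.
#' @return A one-row tibble: total and reference counts, quantile settings,
#'   realized cutoffs and group sizes.
#' @export
glance.aasd_atlas <- function(x, ...) {
  sizes <- group_sizes(x)
  tibble::tibble(
    n_total = nrow(x$entries), n_reference = x$N, q1 = x$q1, q2 = x$q2,
    cutoff_group1 = unname(x$thresholds["group1"]),
    cutoff_group2 = unname(x$thresholds["group2"]),
    n_group1 = sizes[1], n_group2 = sizes[2], n_group3 = sizes[3]
  )
}

#' Tidy a per-orthogroup distance matrix into pair rows
#'
#' @param x A [distance_matrix()] result.
#' @param ... Unused.
#' @return A tibble with one row per unordered species pair: `species_a`,
#'   `species_b`, `distance`, `loglik`, `masked`.
#' @export
tidy.aasd_dist <- function(x, ...) {
  up <- which(upper.tri(x$D), arr.ind = TRUE)
  tibble::tibble(
    orthogroup_id = x$id,
    species_a = x$labels[up[, 1]],
    species_b = x$labels[up[, 2]],
    distance = x$D[up],
    loglik = x$loglik[up],
    masked = !x$mask[up]
  )
}

#' Tidy model-selection scores
#'
#' @param x A [select_model()] result.
#' @param ... Unused.
#' @return The per-candidate score table, best first.
#' @export
tidy.aasd_model_selection <- function(x, ...) x$scores

#' One-row summary of a pipeline run
#'
#' @param x A [run_pipeline()] result.
#' @param ... Unused.
#' @return A one-row tibble combining retention counts, group sizes and the
#'   tip-to-tip validation correlation (if computed).
#' @export
glance.aasd_run <- function(x, ...) {
  out <- glance(x$atlas)
  out$n_input <- nrow(x$log)
  out$n_retained <- sum(x$log$status == "retained")
  if (!is.null(x$validation)) {
    out$validation_r <- x$validation$r[x$validation$term == "tip_to_tip"]
    out$validation_n <- x$validation$n[1]
  }
  out
}
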