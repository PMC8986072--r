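#' Select marker genes by within-subset pairwise correlation
#'
#' For each cell subset, Pearson correlations across samples are computed
#' between all pairs of candidate marker genes within the subset. Each
#' candidate's statistic is the mean of its pairwise correlations with its
#' co-subset candidates (`mean_r`); its significance comes from the Fisher
#' z transform of `mean_r` at the sample count
#' (`z = atanh(mean_r) * sqrt(n - 3)`, two-sided normal). A gene is kept iff
#' `mean_r > r_threshold` and `p < p_threshold` (both strict). In
#' `"pairwise_all"` mode a gene is instead required to exceed the threshold
#' in every one of its pairwise correlations.
#'
#' @param expr An `expr_mat`.
#' @param candidates A candidate `marker_panel` (>= 2 candidates per subset).
#' @param r_threshold Correlation threshold, default 0.50.
#' @param p_threshold Significance threshold, default 0.01.
#' @param mode `"per_gene"` (default) or `"pairwise_all"`.
#' @return A `marker_panel` at stage `"selected"` containing only kept
#'   genes; attribute `selection_record` is the full per-candidate record
#'   (`subset`, `gene_id`, `panel_group`, `mean_r`, `p_value`, `kept`).
#' @export
select_markers <- function(expr, candidates, r_threshold = 0.50,
                           p_threshold = 0.01, mode = c("per_gene", "pairwise_all")) {
  mode <- match.arg(mode)
  stopifnot(inherits(expr, "expr_mat"))
  n <- ncol(expr$values)
  if (n < 4) abort("Marker selection needs >= 4 samples.", class = "triomics_input_error")
  candidates <- as_tibble(candidates)
  present <- candidates$gene_id %in% gene_ids(expr)
  if (!all(present)) {
    warn(paste0("Candidate gene(s) absent from expression matrix dropped: ",
      paste(candidates$gene_id[!present], collapse = ", ")))
    candidates <- candidates[present, ]
  }
  small <- candidates |> count(.data$subset) |> filter(.data$n < 2)
  if (nrow(small) > 0) {
    abort(paste0("Subset(s) with < 2 candidates: ",
      paste(small$subset, collapse = ", ")), class = "triomics_input_error")
  }

  record <- candidates |>
    group_by(.data$subset) |>
    group_modify(function(df, key) {
      M <- t(expr$values[df$gene_id, , drop = FALSE])
      const <- apply(M, 2, \(v) sd(v) == 0)
      if (any(const)) {
        warn(paste0("Constant-expression candidate(s) dropped in subset '",
          key$subset, "': ", paste(df$gene_id[const], collapse = ", ")))
      }
      R <- suppressWarnings(cor(M))
      diag(R) <- NA
      mean_r <- rowMeans(R, na.rm = TRUE)
      mean_r[const] <- NA_real_
      z <- atanh(pmin(pmax(mean_r, -1 + 1e-12), 1 - 1e-12)) * sqrt(n - 3)
      p <- 2 * pnorm(-abs(z))
      kept <- if (mode == "per_gene") {
        !is.na(mean_r) & mean_r > r_threshold & p < p_threshold
      } else {
        apply(R, 1, \(row) all(row[!is.na(row)] > r_threshold)) &
          !const & p < p_threshold
      }
      tibble(gene_id = df$gene_id, panel_group = df$panel_group,
        mean_r = unname(mean_r), p_value = unname(p),
        kept = unname(kept) & !const)
    }) |>
    ungroup()

  sel <- record |> filter(.data$kept) |>
    select("subset", "gene_id", "panel_group")
  panel <- marker_panel(sel, stage = "selected")
  attr(panel, "selection_record") <- record
  attr(panel, "thresholds") <- c(r_threshold = r_threshold, p_threshold = p_threshold)
  panel
}

#' Per-sample cell composition scores
#'
#' The raw composition score of subset `k` in sample `s` is the sum over the
#' subset's panel groups of the simple mean of the group's selected markers'
#' log2 expression; for a single panel group this is the plain marker mean.
#' Scores are reported raw, in log2-expression units (no simplex
#' normalisation), as relative abundance proxies comparable across groups.
#'
#' @param expr An `expr_mat`.
#' @param panel A selected `marker_panel`.
#' @return A `composition_scores` tibble, long format: `sample_id`,
#'   `subset`, `score`. Subsets with no selected markers yield an `NA`
#'   score column and a warning.
#' @export
composition_scores <- function(expr, panel) {
  stopifnot(inherits(expr, "expr_mat"))
  if (!identical(attr(panel, "stage"), "selected")) {
    abort("`panel` must be a selected marker panel (run select_markers()).",
      class = "triomics_input_error")
  }
  panel_tbl <- as_tibble(panel)
  subsets <- unique(panel_tbl$subset)
  rec <- attr(panel, "selection_record")
  if (!is.null(rec)) {
    missing_sub <- setdiff(unique(rec$subset), subsets)
    if (length(missing_sub) > 0) {
      warn(paste0("Subset(s) with no selected markers scored as NA: ",
        paste(missing_sub, collapse = ", ")))
      subsets <- c(subsets, missing_sub)
    }
  }
  scores <- purrr::map_dfr(subsets, function(k) {
    genes_k <- panel_tbl |> filter(.data$subset == k)
    if (nrow(genes_k) == 0) {
      return(tibble(sample_id = sample_ids(expr), subset = k, score = NA_real_))
    }
    per_group <- genes_k |>
      group_by(.data$panel_group) |>
      group_map(\(df, key) colMeans(expr$values[df$gene_id, , drop = FALSE]))
    tibble(sample_id = sample_ids(expr), subset = k,
      score = Reduce(`+`, per_group))
  })
  structure(scores,
    thresholds = attr(panel, "thresholds"),
    class = c("composition_scores", class(scores)))
}

#' Compare composition scores against simulated ground truth
#'
#' For each subset, the Pearson correlation between the composition score
#' and the true per-sample signal component of that subset's markers (the
#' weight log-ratio plus any planted group effect -- the deterministic part
#' of the generative model that the score estimates).
#'
#' @param scores A `composition_scores` tibble.
#' @param study The `simulated_study` the scores were computed from.
#' @return A tibble with `subset`, `n`, `recovery_r`, and
#'   `recovery_r_weight` (correlation against the raw log2 weight alone).
#' @export
score_recovery_report <- function(scores, study) {
  stopifnot(inherits(study, "simulated_study"))
  truth <- study$truth$weights
  inner_join(as_tibble(scores), truth, by = c("sample_id", "subset")) |>
    group_by(.data$subset) |>
    summarise(
      n = sum(!is.na(.data$score)),
      recovery_r = if (sum(!is.na(.data$score)) >= 3)
        suppressWarnings(cor(.data$score, .data$signal,
          use = "complete.obs")) else NA_real_,
      recovery_r_weight = if (sum(!is.na(.data$score)) >= 3)
        suppressWarnings(cor(.data$score, log2(.data$weight),
          use = "complete.obs")) else NA_real_,
      .groups = "drop"
    )
}
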