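#' Holm-Sidak step-down family-wise adjustment
#'
#' Sort p values ascending; the i-th adjusted value is
#' `max_{j <= i} [1 - (1 - p_(j))^(m - j + 1)]`, clipped to 1; the result is
#' returned in input order. Controls the family-wise error rate and is
#' uniformly more powerful than Bonferroni-Holm.
#'
#' @param p Numeric vector of p values in `[0, 1]`; `NA` is an error.
#' @return Adjusted p values, same order as `p`.
#' @export
holm_sidak <- function(p) {
  if (anyNA(p)) abort("NA/NaN p values are not allowed.", class = "triomics_input_error")
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1].", class = "triomics_input_error")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  ps <- p[o]
  adj <- pmin(1 - (1 - ps)^(m - seq_len(m) + 1), 1)
  adj <- cummax(adj)
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Compare composition scores between participant groups
#'
#' For each score (cell subset), runs the requested two-group comparisons:
#' unpaired pooled-variance two-sided t tests for trio-vs-HC comparisons
#' (normality and equal variances assumed) and paired two-sided t tests for
#' within-trio comparisons (paired on `family_id`, incomplete pairs
#' dropped). Raw p values are Holm-Sidak-adjusted within each score's
#' family of comparisons; the number of scores is deliberately not adjusted
#' for.
#'
#' @param scores A `composition_scores` tibble (long: `sample_id`, `subset`,
#'   `score`) or any tibble with those columns.
#' @param meta Sample metadata.
#' @param comparisons Character vector like `c("proband:HC", "mother:HC",
#'   "proband:mother")`. The special group `"parent"` pools fathers and
#'   mothers. Comparisons listed in `paired` are paired on family.
#' @param paired Character vector naming which comparisons are paired.
#' @return A `comparison_result` tibble: `score`, `comparison`, `test`,
#'   `estimate` (case minus reference mean), `n_case`, `n_ref`, `p_raw`,
#'   `p_adjusted`, `family`.
#' @export
compare_scores <- function(scores, meta,
                           comparisons = c("proband:HC", "parent:HC", "proband:parent"),
                           paired = "proband:parent") {
  scores <- as_tibble(scores)
  stopifnot(all(c("sample_id", "subset", "score") %in% names(scores)))
  bad <- setdiff(paired, comparisons)
  if (length(bad) > 0) {
    abort(paste0("`paired` entries not in `comparisons`: ", paste(bad, collapse = ", ")),
      class = "triomics_input_error")
  }
  df <- scores |>
    left_join(select(meta, "sample_id", "group", "family_id"), by = "sample_id") |>
    filter(!is.na(.data$score))

  group_values <- function(d, g) {
    if (g == "parent") {
      # one value per family: the mean over available parents
      d |> filter(.data$group %in% c("father", "mother")) |>
        group_by(.data$family_id) |>
        summarise(score = mean(.data$score), .groups = "drop")
    } else {
      d |> filter(.data$group == g) |>
        select("family_id", "score")
    }
  }

  out <- purrr::map_dfr(unique(df$subset), function(k) {
    dk <- df |> filter(.data$subset == k)
    rows <- purrr::map_dfr(comparisons, function(cmp) {
      gg <- strsplit(cmp, ":", fixed = TRUE)[[1]]
      is_paired <- cmp %in% paired
      a <- group_values(dk, gg[1])
      b <- group_values(dk, gg[2])
      if (is_paired) {
        fams <- intersect(a$family_id, b$family_id)
        x <- a$score[match(fams, a$family_id)]
        y <- b$score[match(fams, b$family_id)]
        if (length(fams) < 2) {
          warn(sprintf("Comparison '%s' for score '%s' skipped: < 2 complete pairs.", cmp, k))
          return(tibble())
        }
        d0 <- x - y
        if (sd(d0) == 0) {
          est <- mean(d0); p <- 1
        } else {
          tt <- t.test(x, y, paired = TRUE)
          est <- mean(d0); p <- tt$p.value
        }
        tibble(score = k, comparison = cmp, test = "t_paired", estimate = est,
          n_case = length(x), n_ref = length(y), p_raw = p)
      } else {
        if (nrow(a) < 2 || nrow(b) < 2) {
          warn(sprintf("Comparison '%s' for score '%s' skipped: a group has < 2 observations.", cmp, k))
          return(tibble())
        }
        if (sd(a$score) == 0 && sd(b$score) == 0) {
          # degenerate zero-variance comparison: conservatively p = 1
          est <- mean(a$score) - mean(b$score)
          p <- 1
        } else {
          tt <- t.test(a$score, b$score, var.equal = TRUE)
          est <- mean(a$score) - mean(b$score); p <- tt$p.value
        }
        tibble(score = k, comparison = cmp, test = "t_independent", estimate = est,
          n_case = nrow(a), n_ref = nrow(b), p_raw = p)
      }
    })
    if (nrow(rows) == 0) return(rows)
    rows$p_adjusted <- holm_sidak(rows$p_raw)
    rows$family <- paste0("score:", k)
    rows
  })
  structure(out, class = c("comparison_result", class(out)))
}

#' Kruskal-Wallis test with Dunn's control comparisons
#'
#' Kruskal-Wallis H (tie-corrected) across >= 3 groups; if `p < alpha`,
#' Dunn's z statistics compare each group against the control using mean
#' ranks and the tie-corrected variance, with p values
#' Bonferroni-multiplied by the number of control comparisons; otherwise
#' the post hoc table is suppressed.
#'
#' @param values Numeric vector of per-sample measurements.
#' @param groups Group labels, same length as `values`.
#' @param control The control group label.
#' @param alpha Gate on the Kruskal-Wallis p value, default 0.05.
#' @return A list with `kw_h`, `kw_df`, `kw_p`, and `posthoc` (a tibble of
#'   Dunn comparisons vs control, or `NULL` when suppressed).
#' @export
kruskal_dunn <- function(values, groups, control, alpha = 0.05) {
  groups <- as.character(groups)
  stopifnot(length(values) == length(groups))
  if (length(unique(groups)) < 3) {
    abort("Need >= 3 groups.", class = "triomics_input_error")
  }
  if (!control %in% groups) {
    abort(sprintf("Control group '%s' not found.", control),
      class = "triomics_input_error")
  }
  if (length(unique(values)) == 1) {
    abort("All values tied; H is undefined.", class = "triomics_input_error")
  }
  kw <- kruskal.test(values, factor(groups))
  posthoc <- NULL
  if (kw$p.value < alpha) {
    N <- length(values)
    r <- rank(values)
    ties <- table(values)
    tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
    v0 <- N * (N + 1) / 12 - tie_term
    mean_ranks <- tapply(r, groups, mean)
    ns <- table(groups)
    others <- setdiff(names(mean_ranks), control)
    k_cmp <- length(others)
    posthoc <- purrr::map_dfr(others, function(g) {
      z <- (mean_ranks[[g]] - mean_ranks[[control]]) /
        sqrt(v0 * (1 / ns[[g]] + 1 / ns[[control]]))
      p_raw <- 2 * pnorm(-abs(z))
      tibble(score = NA_character_,
        comparison = paste0(g, ":", control), test = "dunn",
        estimate = unname(mean_ranks[[g]] - mean_ranks[[control]]),
        n_case = unname(ns[[g]]), n_ref = unname(ns[[control]]),
        p_raw = p_raw, p_adjusted = min(p_raw * k_cmp, 1),
        family = "dunn_vs_control")
    })
  }
  list(kw_h = unname(kw$statistic), kw_df = unname(kw$parameter),
    kw_p = kw$p.value, posthoc = posthoc)
}
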