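#' Compare composition scores between clinical subgroups
#'
#' Stratifies proband samples by a clinical variable (`cftr_class`,
#' `pancreatic`, or `pa_infection`) and, per score, runs unpaired
#' pooled-variance t tests between strata and of each stratum against HC,
#' with Holm-Sidak adjustment within each score.
#'
#' @param scores A `composition_scores` tibble.
#' @param meta Sample metadata.
#' @param stratifier One of `"cftr_class"`, `"pancreatic"`, `"pa_infection"`.
#' @param include_hc Also compare each stratum against the HC group.
#' @param min_n Minimum samples per stratum (smaller strata are skipped with
#'   a warning).
#' @return A `comparison_result` tibble as in [compare_scores()].
#' @export
subgroup_compare <- function(scores, meta,
                             stratifier = c("cftr_class", "pancreatic", "pa_infection"),
                             include_hc = TRUE, min_n = 2) {
  stratifier <- match.arg(stratifier)
  scores <- as_tibble(scores)
  df <- scores |>
    left_join(select(meta, "sample_id", "group", strat = all_of(stratifier)),
      by = "sample_id") |>
    filter(!is.na(.data$score))
  # canonical stratum order: more severe phenotype first, so comparison
  # estimates read as severe minus mild
  canonical <- list(cftr_class = c("I_II_III", "IV"),
    pancreatic = c("PI", "PS"), pa_infection = c("pos", "neg"))[[stratifier]]
  strata <- df |>
    filter(!is.na(.data$strat)) |>
    distinct(.data$strat) |>
    pull()
  strata <- c(intersect(canonical, strata), sort(setdiff(strata, canonical)))
  if (length(strata) < 2 && !include_hc) {
    abort("Need >= 2 strata.", class = "triomics_input_error")
  }
  pairs <- if (length(strata) >= 2) utils::combn(strata, 2, simplify = FALSE) else list()
  out <- purrr::map_dfr(unique(df$subset), function(k) {
    dk <- df |> filter(.data$subset == k)
    vals <- function(lbl) {
      if (lbl == "HC") dk$score[dk$group == "HC"] else
        dk$score[!is.na(dk$strat) & dk$strat == lbl]
    }
    cmp_list <- c(
      purrr::map(pairs, \(p) c(p[1], p[2])),
      if (include_hc) purrr::map(strata, \(s) c(s, "HC")) else list()
    )
    rows <- purrr::map_dfr(cmp_list, function(p) {
      x <- vals(p[1]); y <- vals(p[2])
      if (length(x) < min_n || length(y) < min_n) {
        warn(sprintf("Stratum comparison '%s:%s' for score '%s' skipped (too few samples).",
          p[1], p[2], k))
        return(tibble())
      }
      p_raw <- if (sd(c(x, y)) == 0) 1 else t.test(x, y, var.equal = TRUE)$p.value
      tibble(score = k, comparison = paste0(p[1], ":", p[2]),
        test = "t_independent", estimate = mean(x) - mean(y),
        n_case = length(x), n_ref = length(y), p_raw = p_raw)
    })
    if (nrow(rows) == 0) return(rows)
    rows$p_adjusted <- holm_sidak(rows$p_raw)
    rows$family <- paste0("score:", k, "|strat:", stratifier)
    rows
  })
  structure(out, class = c("comparison_result", class(out)))
}

#' Correlate composition scores with clinical covariates
#'
#' Pearson correlation (with the t transform of r at n-2 degrees of freedom
#' for the two-sided p value) and simple least-squares regression of the
#' covariate on the score, per (score, covariate) pair. Missing covariate
#' values are dropped pairwise; HC samples are excluded by default since
#' the clinical covariates describe disease severity. P values are not
#' multiplicity-adjusted by default; `adjust = TRUE` applies Holm-Sidak
#' across the covariates within each score.
#'
#' @param scores A `composition_scores` tibble.
#' @param meta Sample metadata.
#' @param covariates Covariate column names in `meta`.
#' @param groups Which participant groups to use (default probands only).
#' @param adjust Apply Holm-Sidak within each score's covariate family.
#' @return An `association_result` tibble: `score`, `covariate`, `n`, `r`,
#'   `r_squared`, `p_value`, `slope`, `intercept`. Pairs with fewer than 4
#'   complete observations get an `NA` row.
#' @export
correlate_clinical <- function(scores, meta,
                               covariates = c("sweat_chloride", "fev1_pct"),
                               groups = "proband", adjust = FALSE) {
  scores <- as_tibble(scores)
  df <- scores |>
    inner_join(meta, by = "sample_id") |>
    filter(.data$group %in% groups, !is.na(.data$score))
  out <- purrr::map_dfr(unique(df$subset), function(k) {
    dk <- df |> filter(.data$subset == k)
    rows <- purrr::map_dfr(covariates, function(cv) {
      ok <- !is.na(dk[[cv]])
      x <- dk$score[ok]; y <- dk[[cv]][ok]
      if (sum(ok) < 4 || sd(x) == 0 || sd(y) == 0) {
        return(tibble(score = k, covariate = cv, n = sum(ok), r = NA_real_,
          r_squared = NA_real_, p_value = NA_real_, slope = NA_real_,
          intercept = NA_real_))
      }
      ct <- cor.test(x, y)
      fit <- lm(y ~ x)
      tibble(score = k, covariate = cv, n = sum(ok),
        r = unname(ct$estimate), r_squared = unname(ct$estimate)^2,
        p_value = ct$p.value, slope = unname(coef(fit)[2]),
        intercept = unname(coef(fit)[1]))
    })
    if (adjust && any(!is.na(rows$p_value))) {
      ok <- !is.na(rows$p_value)
      rows$p_value[ok] <- holm_sidak(rows$p_value[ok])
    }
    rows
  })
  structure(out, class = c("association_result", class(out)))
}

#' Fold-change concordance between two contrasts
#'
#' Splits a gene set by fold-change direction in the first contrast and,
#' within each half, reports the Pearson correlation, R squared, p value and
#' simple linear regression of the second contrast's log2 fold changes on
#' the first's. This quantifies how consistently two comparisons (e.g.
#' proband-vs-HC and parent-vs-HC) regulate a shared gene set.
#'
#' @param deA,deB `de_result` objects; `deA` defines the direction split.
#' @param genes Gene IDs to use (must be present in both universes).
#' @return A tibble with one row per direction (`up`, `down`): `n`, `r`,
#'   `r_squared`, `p_value`, `slope`, `intercept`. Halves with fewer than 3
#'   genes are `NA`.
#' @export
fold_change_concordance <- function(deA, deB, genes) {
  missing_g <- setdiff(genes, intersect(deA$gene_id, deB$gene_id))
  if (length(missing_g) > 0) {
    abort(paste0("Gene(s) absent from a DE universe: ",
      paste(head(missing_g, 10), collapse = ", ")),
      class = "triomics_universe_error")
  }
  fa <- deA$log2fc[match(genes, deA$gene_id)]
  fb <- deB$log2fc[match(genes, deB$gene_id)]
  dir_a <- ifelse(fa >= 0, "up", "down")
  purrr::map_dfr(c("up", "down"), function(d) {
    sel <- dir_a == d
    x <- fa[sel]; y <- fb[sel]
    if (sum(sel) < 3 || sd(x) == 0) {
      return(tibble(direction = d, n = sum(sel), r = NA_real_,
        r_squared = NA_real_, p_value = NA_real_, slope = NA_real_,
        intercept = NA_real_))
    }
    ct <- cor.test(x, y)
    fit <- lm(y ~ x)
    tibble(direction = d, n = sum(sel), r = unname(ct$estimate),
      r_squared = unname(ct$estimate)^2, p_value = ct$p.value,
      slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]))
  })
}
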