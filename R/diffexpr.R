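#' Define a two-group contrast
#'
#' @param case_group,reference_group Group labels; the log2 fold change is
#'   case minus reference.
#' @param paired If `TRUE`, samples are paired on `family_id` (both groups
#'   must then be trio members) and incomplete pairs are dropped.
#' @param name Contrast label; defaults to `"case_vs_reference"`.
#' @return A `contrast` list.
#' @export
contrast <- function(case_group, reference_group, paired = FALSE, name = NULL) {
  if (identical(case_group, reference_group)) {
    abort("case and reference group must differ.", class = "triomics_contrast_error")
  }
  trio_groups <- c("proband", "father", "mother")
  if (paired && !(case_group %in% trio_groups && reference_group %in% trio_groups)) {
    abort("Paired contrasts require both groups to be trio members.",
      class = "triomics_contrast_error")
  }
  structure(list(
    name = name %||% paste0(case_group, "_vs_", reference_group),
    case_group = case_group, reference_group = reference_group,
    paired = paired
  ), class = "contrast")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Invert the trigamma function by Newton iteration (monotone decreasing),
# used for moment-matching the variance prior.
trigamma_inverse <- function(y) {
  if (y > 1e7) return(1 / sqrt(y))
  if (y < 1e-6) return(1 / y)
  x <- 0.5 + 1 / y
  for (i in 1:75) {
    tri <- trigamma(x)
    dif <- tri * (1 - tri / y) / psigamma(x, 2)
    x <- x + dif
    if (abs(dif / x) < 1e-10) break
  }
  x
}

#' Fit the empirical-Bayes variance prior
#'
#' Moment-matches the scaled F prior for gene-wise variances: with
#' `e_g = log(s2_g) - digamma(d_g/2) + log(d_g/2)`, the prior degrees of
#' freedom `d0` solve `trigamma(d0/2) = var(e) - trigamma(d_g/2)` (Newton
#' inversion of the trigamma function) and the prior variance is
#' `s0_sq = exp(mean(e) + digamma(d0/2) - log(d0/2))`. When the trigamma
#' equation has no positive root the prior is flagged infinite and
#' `s0_sq = exp(mean(e))`.
#'
#' @param s2 Gene-wise residual variances.
#' @param df Residual degrees of freedom (scalar or per-gene).
#' @return A list with `d0` (possibly `Inf`) and `s0_sq`.
#' @export
fit_variance_prior <- function(s2, df) {
  ok <- is.finite(s2) & s2 > 0
  if (!any(ok)) {
    abort("All gene variances are zero; cannot fit a moderation prior.",
      class = "triomics_prior_error")
  }
  df <- rep_len(df, length(s2))
  z <- log(s2[ok])
  e <- z - digamma(df[ok] / 2) + log(df[ok] / 2)
  emean <- mean(e)
  evar <- var(e) - mean(trigamma(df[ok] / 2))
  if (!is.finite(evar) || evar <= 0) {
    # no excess spread beyond sampling noise: infinite prior df, scale =
    # mean variance (the standard convention for the limiting case)
    return(list(d0 = Inf, s0_sq = mean(s2[ok])))
  }
  d0 <- 2 * trigamma_inverse(evar)
  s0_sq <- exp(emean + digamma(d0 / 2) - log(d0 / 2))
  list(d0 = d0, s0_sq = s0_sq)
}

#' Moderated two-group differential expression
#'
#' Per gene: the log2 fold change is the difference of group means (or the
#' mean of paired within-family differences), the residual variance is the
#' pooled within-group variance (paired: variance of the differences), and
#' the variance is shrunk toward an empirical-Bayes prior fitted across
#' genes ([fit_variance_prior()]). The moderated t statistic uses the
#' posterior variance `(d0*s0_sq + d_g*s2_g)/(d0 + d_g)` and a t reference
#' with `d_g + d0` degrees of freedom. P values are FDR-adjusted by
#' Benjamini-Hochberg, and a gene is flagged a DEG when it passes both the
#' fold gate (`|log2fc| >= log2(fold_threshold)`) and the FDR gate
#' (`fdr_q < q_threshold`).
#'
#' @param expr An `expr_mat`.
#' @param meta Sample metadata tibble (must match `expr`'s samples).
#' @param contrast A [contrast()].
#' @param fold_threshold Fold-change gate, default 2 (i.e. `|log2fc| >= 1`).
#' @param q_threshold FDR gate, default 0.05 (strict `<`).
#' @param prior Optional list `(d0, s0_sq)` overriding the fitted prior
#'   (`d0 = 0` recovers the ordinary pooled-variance t test).
#' @return A `de_result` tibble with one row per gene: `gene_id`,
#'   `locus_type`, `log2fc`, `s2_g`, `t_mod`, `df_total`, `p_value`,
#'   `fdr_q`, `direction`, `is_deg`. The fitted prior, contrast and
#'   thresholds are carried as attributes.
#' @export
fit_moderated <- function(expr, meta, contrast, fold_threshold = 2,
                          q_threshold = 0.05, prior = NULL) {
  stopifnot(inherits(expr, "expr_mat"), inherits(contrast, "contrast"))
  check_sample_alignment(expr, meta)
  X <- expr$values
  meta <- meta[match(colnames(X), meta$sample_id), ]
  case_s <- meta$sample_id[meta$group == contrast$case_group]
  ref_s <- meta$sample_id[meta$group == contrast$reference_group]
  if (length(case_s) == 0 || length(ref_s) == 0) {
    abort(sprintf("Contrast group absent from metadata: %s.",
      paste(c(contrast$case_group, contrast$reference_group)[
        c(length(case_s) == 0, length(ref_s) == 0)], collapse = ", ")),
      class = "triomics_contrast_error")
  }

  if (contrast$paired) {
    fam_case <- meta$family_id[match(case_s, meta$sample_id)]
    fam_ref <- meta$family_id[match(ref_s, meta$sample_id)]
    common <- intersect(fam_case, fam_ref)
    if (length(common) < 2) {
      abort("Paired contrast needs >= 2 complete pairs.",
        class = "triomics_contrast_error")
    }
    D <- X[, case_s[match(common, fam_case)], drop = FALSE] -
      X[, ref_s[match(common, fam_ref)], drop = FALSE]
    log2fc <- rowMeans(D)
    n_pairs <- ncol(D)
    s2 <- rowSums((D - log2fc)^2) / (n_pairs - 1)
    d_g <- n_pairs - 1
    se_factor <- sqrt(1 / n_pairs)
    n1 <- n2 <- n_pairs
  } else {
    if (length(case_s) < 2 || length(ref_s) < 2) {
      abort("Both contrast groups need >= 2 samples.",
        class = "triomics_contrast_error")
    }
    Xc <- X[, case_s, drop = FALSE]
    Xr <- X[, ref_s, drop = FALSE]
    mc <- rowMeans(Xc)
    mr <- rowMeans(Xr)
    log2fc <- mc - mr
    n1 <- ncol(Xc); n2 <- ncol(Xr)
    ss <- rowSums((Xc - mc)^2) + rowSums((Xr - mr)^2)
    d_g <- n1 + n2 - 2
    s2 <- ss / d_g
    se_factor <- sqrt(1 / n1 + 1 / n2)
  }

  if (is.null(prior)) prior <- fit_variance_prior(s2, d_g)
  if (is.infinite(prior$d0)) {
    s2_post <- rep(prior$s0_sq, length(s2))
    df_total <- Inf
  } else {
    s2_post <- (prior$d0 * prior$s0_sq + d_g * s2) / (prior$d0 + d_g)
    df_total <- d_g + prior$d0
  }
  t_mod <- log2fc / (sqrt(s2_post) * se_factor)
  # zero posterior variance with zero fold change is a perfect null
  t_mod[is.nan(t_mod)] <- 0
  p <- 2 * pt(-abs(t_mod), df = df_total)
  q <- benjamini_hochberg(p)

  res <- tibble(
    gene_id = rownames(X),
    locus_type = expr$genes$locus_type[match(rownames(X), expr$genes$gene_id)],
    log2fc = unname(log2fc),
    s2_g = unname(s2),
    t_mod = unname(t_mod),
    df_total = df_total,
    p_value = unname(p),
    fdr_q = unname(q),
    direction = ifelse(log2fc >= 0, "up", "down"),
    is_deg = abs(log2fc) >= log2(fold_threshold) & q < q_threshold
  )
  structure(res,
    contrast = contrast, prior = prior,
    fold_threshold = fold_threshold, q_threshold = q_threshold,
    n_case = n1, n_ref = n2, paired = contrast$paired,
    class = c("de_result", class(res)))
}

#' Benjamini-Hochberg step-up FDR adjustment
#'
#' `q_i = min over j with p_(j) >= p_(i) of m * p_(j) / j`, clipped to 1;
#' input order is preserved.
#'
#' @param p Numeric vector of p values in `[0, 1]`; `NA`/`NaN` is an error.
#' @return Vector of q values, same order as `p`.
#' @export
benjamini_hochberg <- function(p) {
  if (anyNA(p)) abort("NA/NaN p values are not allowed.", class = "triomics_input_error")
  if (any(p < 0 | p > 1)) abort("p values must lie in [0, 1].", class = "triomics_input_error")
  p.adjust(p, method = "BH")
}

#' DEG counts by locus type
#'
#' Tabulates up- and downregulated DEGs per locus-type category, with the
#' up:down ratio, mirroring the breakdown of differentially expressed
#' transcripts by array locus type.
#'
#' @param de A `de_result`.
#' @param locus_type Optional per-gene category vector overriding the one
#'   stored in `de`.
#' @return A tibble with one row per locus type plus a `total` row.
#' @export
deg_summary <- function(de, locus_type = NULL) {
  lt <- locus_type %||% de$locus_type
  tab <- tibble(locus_type = factor(lt, levels = LOCUS_TYPES),
    direction = de$direction, is_deg = de$is_deg) |>
    filter(.data$is_deg) |>
    count(.data$locus_type, .data$direction, .drop = FALSE) |>
    tidyr::pivot_wider(names_from = "direction", values_from = "n",
      values_fill = 0L)
  for (col in c("up", "down")) if (!col %in% names(tab)) tab[[col]] <- 0L
  tab <- tab |>
    mutate(locus_type = as.character(.data$locus_type),
      n_deg = .data$up + .data$down,
      up_down_ratio = ifelse(.data$down > 0, .data$up / .data$down, NA_real_)) |>
    select("locus_type", "up", "down", "n_deg", "up_down_ratio")
  bind_rows(tab, tibble(locus_type = "total",
    up = sum(tab$up), down = sum(tab$down), n_deg = sum(tab$n_deg),
    up_down_ratio = ifelse(sum(tab$down) > 0, sum(tab$up) / sum(tab$down), NA_real_)))
}

#' Volcano-plot table
#'
#' Pure projection of a DE result onto `(gene, log2fc, -log10 p, flag)`.
#'
#' @param de A `de_result`.
#' @return A tibble with `gene_id`, `log2fc`, `neg_log10_p`, `is_deg`.
#' @export
volcano_table <- function(de) {
  tibble(gene_id = de$gene_id, log2fc = de$log2fc,
    neg_log10_p = -log10(de$p_value), is_deg = de$is_deg)
}
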