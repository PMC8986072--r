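#' Partition two DEG lists into shared and unique sets
#'
#' Given DE results for two contrasts on the same gene universe (typically
#' proband-vs-HC and parent-vs-HC), derives the trio-shared set (DEG in
#' both), the A-unique set (proband-unique) and the B-unique set
#' (parent-unique), with per-gene directions.
#'
#' @param deA,deB `de_result` objects on the same gene universe.
#' @param labels Length-2 character vector naming the two inputs.
#' @return A `deg_set_family` list with character vectors `shared`,
#'   `a_unique`, `b_unique`, a `counts` tibble, and a `detail` tibble with
#'   per-gene membership and directions.
#' @export
venn_partition <- function(deA, deB, labels = c("A", "B")) {
  if (!setequal(deA$gene_id, deB$gene_id)) {
    miss <- c(setdiff(deA$gene_id, deB$gene_id), setdiff(deB$gene_id, deA$gene_id))
    abort(paste0("Gene universes differ; unmatched genes: ",
      paste(head(miss, 10), collapse = ", "),
      if (length(miss) > 10) sprintf(" (+%d more)", length(miss) - 10) else ""),
      class = "triomics_universe_error")
  }
  a <- deA$gene_id[deA$is_deg]
  b <- deB$gene_id[deB$is_deg]
  shared <- intersect(a, b)
  fam <- list(
    shared = shared,
    a_unique = setdiff(a, b),
    b_unique = setdiff(b, a)
  )
  detail <- tibble(gene_id = union(a, b)) |>
    mutate(
      in_a = .data$gene_id %in% a,
      in_b = .data$gene_id %in% b,
      direction_a = deA$direction[match(.data$gene_id, deA$gene_id)],
      direction_b = deB$direction[match(.data$gene_id, deB$gene_id)],
      membership = case_when(
        .data$in_a & .data$in_b ~ "shared",
        .data$in_a ~ "a_unique",
        TRUE ~ "b_unique"
      )
    )
  counts <- tibble(
    set = c(labels[1], labels[2], "shared", paste0(labels[1], "_unique"),
      paste0(labels[2], "_unique")),
    n = c(length(a), length(b), length(fam$shared), length(fam$a_unique),
      length(fam$b_unique))
  )
  structure(c(fam, list(counts = counts, detail = detail, labels = labels)),
    class = "deg_set_family")
}

#' @export
print.deg_set_family <- function(x, ...) {
  cat("<deg_set_family>\n")
  print(x$counts)
  invisible(x)
}

#' Build a direction-consistent cross-model input gene set
#'
#' Three-step construction of an enrichment query set from two proband
#' contrasts (different cellular models) and one parent contrast:
#' (1) intersect the coding DEGs of the two proband-vs-HC results;
#' (2) intersect with the parent-vs-HC DEGs; (3) keep genes whose fold
#' change direction agrees between the two proband models. "Coding" means
#' locus type `coding` or `multiple_complex` (array annotations reported in
#' multiple locus types are treated as protein coding).
#'
#' @param de_model1_proband,de_model2_proband `de_result`s for proband vs HC
#'   in two models.
#' @param de_parent `de_result` for parent vs HC.
#' @param coding_only Restrict step 1 to coding/multiple_complex genes.
#' @return A tibble with `gene_id`, `direction`, and the two models' fold
#'   changes; attribute `step_counts` holds the three intermediate sizes.
#' @export
build_input_gene_set <- function(de_model1_proband, de_model2_proband,
                                 de_parent, coding_only = TRUE) {
  deg_genes <- function(de) {
    g <- de$gene_id[de$is_deg]
    if (coding_only) {
      lt <- de$locus_type[match(g, de$gene_id)]
      g <- g[lt %in% c("coding", "multiple_complex")]
    }
    g
  }
  s1 <- intersect(deg_genes(de_model1_proband), deg_genes(de_model2_proband))
  s2 <- intersect(s1, de_parent$gene_id[de_parent$is_deg])
  d1 <- de_model1_proband$direction[match(s2, de_model1_proband$gene_id)]
  d2 <- de_model2_proband$direction[match(s2, de_model2_proband$gene_id)]
  s3 <- s2[d1 == d2]
  counts <- c(step1_cross_model = length(s1), step2_with_parent = length(s2),
    step3_same_direction = length(s3))
  if (length(s3) == 0) {
    warn("Input gene set is empty after the direction-consistency step.")
  }
  out <- tibble(
    gene_id = s3,
    direction = de_model1_proband$direction[match(s3, de_model1_proband$gene_id)],
    log2fc_model1 = de_model1_proband$log2fc[match(s3, de_model1_proband$gene_id)],
    log2fc_model2 = de_model2_proband$log2fc[match(s3, de_model2_proband$gene_id)]
  )
  attr(out, "step_counts") <- counts
  out
}

#' Overlap a gene set with an annotated set and correlate fold changes
#'
#' Intersects two fold-change-annotated gene sets (matching gene symbols
#' case-insensitively) and reports the Pearson correlation of the paired
#' fold changes. `flip_sign` negates set A's fold changes first, the
#' convention used when comparing a suppression signature against an
#' induction signature.
#'
#' @param setA,setB Tibbles with columns `gene_id` and `log2fc`.
#' @param flip_sign Negate `setA`'s fold changes before correlating.
#' @return A list with `overlap` (tibble of genes with both fold changes),
#'   `n`, `r`, `r_squared`, `p_value`. With fewer than 3 overlapping genes
#'   the correlation is `NA`.
#' @export
overlap_with_annotated <- function(setA, setB, flip_sign = FALSE) {
  if (nrow(setA) == 0 || nrow(setB) == 0) {
    abort("Both gene sets must be nonempty.", class = "triomics_input_error")
  }
  a <- mutate(as_tibble(setA), key = normalize_gene_ids(.data$gene_id))
  b <- mutate(as_tibble(setB), key = normalize_gene_ids(.data$gene_id))
  ov <- inner_join(
    select(a, "key", gene_id_a = "gene_id", log2fc_a = "log2fc"),
    select(b, "key", gene_id_b = "gene_id", log2fc_b = "log2fc"),
    by = "key"
  ) |> select(-"key")
  if (flip_sign) ov$log2fc_a <- -ov$log2fc_a
  if (nrow(ov) >= 3) {
    ct <- cor.test(ov$log2fc_a, ov$log2fc_b)
    r <- unname(ct$estimate); p <- ct$p.value
  } else {
    r <- NA_real_; p <- NA_real_
  }
  list(overlap = ov, n = nrow(ov), r = r, r_squared = r^2, p_value = p)
}
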