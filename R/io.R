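#' Construct an expression matrix object
#'
#' The central container of the package: a genes x samples matrix of
#' log2-scale, pre-normalized expression values together with a per-gene
#' locus-type annotation (`coding`, `multiple_complex`, `noncoding`, `other`
#' -- the categories used on whole-transcriptome arrays).
#'
#' @param values Numeric matrix, genes in rows (rownames = gene IDs), samples
#'   in columns (colnames = sample IDs). All values must be finite.
#' @param locus_type Character vector, one entry per gene. Unknown categories
#'   are mapped to `"other"` with a warning.
#' @return An object of class `expr_mat`: a list with elements `genes`
#'   (tibble with `gene_id`, `locus_type`) and `values` (the matrix).
#' @export
expression_matrix <- function(values, locus_type) {
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("`values` must be a numeric matrix.", class = "triomics_format_error")
  }
  gene_ids <- rownames(values)
  sample_ids <- colnames(values)
  if (is.null(gene_ids) || is.null(sample_ids)) {
    abort("`values` must have gene IDs as rownames and sample IDs as colnames.",
      class = "triomics_format_error")
  }
  dup_g <- unique(gene_ids[duplicated(gene_ids)])
  if (length(dup_g) > 0) {
    abort(paste0("Duplicate gene IDs: ", paste(dup_g, collapse = ", ")),
      class = "triomics_format_error")
  }
  dup_s <- unique(sample_ids[duplicated(sample_ids)])
  if (length(dup_s) > 0) {
    abort(paste0("Duplicate sample IDs: ", paste(dup_s, collapse = ", ")),
      class = "triomics_format_error")
  }
  if (!all(is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite expression value at gene '%s', sample '%s'.",
      gene_ids[bad[1]], sample_ids[bad[2]]), class = "triomics_format_error")
  }
  locus_type <- as.character(locus_type)
  if (length(locus_type) != nrow(values)) {
    abort("`locus_type` must have one entry per gene.", class = "triomics_format_error")
  }
  unknown <- setdiff(unique(locus_type), LOCUS_TYPES)
  if (length(unknown) > 0) {
    warn(paste0("Unknown locus type(s) mapped to 'other': ",
      paste(unknown, collapse = ", ")))
    locus_type[locus_type %in% unknown] <- "other"
  }
  structure(
    list(
      genes = tibble(gene_id = gene_ids, locus_type = locus_type),
      values = values
    ),
    class = "expr_mat"
  )
}

#' @export
print.expr_mat <- function(x, ...) {
  cat(sprintf("<expr_mat> %d genes x %d samples (log2 scale)\n",
    nrow(x$values), ncol(x$values)))
  print(dplyr::count(x$genes, .data$locus_type))
  invisible(x)
}

#' @export
dim.expr_mat <- function(x) dim(x$values)

#' Gene and sample identifiers of an expression matrix
#' @param x An `expr_mat`.
#' @return Character vector of IDs.
#' @export
gene_ids <- function(x) x$genes$gene_id

#' @rdname gene_ids
#' @export
sample_ids <- function(x) colnames(x$values)

#' @export
as_tibble.expr_mat <- function(x, ...) {
  as_tibble(x$values, rownames = "gene_id") |>
    left_join(x$genes, by = "gene_id") |>
    relocate("gene_id", "locus_type") |>
    tidyr::pivot_longer(-c("gene_id", "locus_type"),
      names_to = "sample_id", values_to = "log2_expr")
}

#' Subset an expression matrix to a set of genes
#' @param x An `expr_mat`.
#' @param genes Character vector of gene IDs (order preserved as in `x`).
#' @return An `expr_mat` restricted to the matching genes.
#' @export
subset_genes <- function(x, genes) {
  keep <- gene_ids(x) %in% genes
  expression_matrix(x$values[keep, , drop = FALSE], x$genes$locus_type[keep])
}

#' Read a gene x sample expression table
#'
#' Expects tab-delimited text: first column gene ID, second column locus
#' type, remaining columns one per sample, with a header row. Ordering is
#' preserved.
#'
#' @param path File path.
#' @return An [expression_matrix()] object.
#' @export
read_expression <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  if (ncol(df) < 3) {
    abort("Expression file needs gene_id, locus_type and >= 1 sample column.",
      class = "triomics_format_error")
  }
  samp_cols <- names(df)[-(1:2)]
  vals <- as.matrix(df[samp_cols])
  num <- suppressWarnings(apply(vals, 2, as.numeric))
  if (anyNA(num)) {
    bad <- which(is.na(num) & !is.na(vals), arr.ind = TRUE)
    if (nrow(bad) == 0) bad <- which(is.na(num), arr.ind = TRUE)
    abort(sprintf("Non-numeric expression value at row %d, column '%s'.",
      bad[1, 1], samp_cols[bad[1, 2]]), class = "triomics_format_error")
  }
  num <- matrix(num, nrow = nrow(df),
    dimnames = list(df[[1]], samp_cols))
  expression_matrix(num, df[[2]])
}

#' Write an expression matrix as tab-delimited text
#'
#' Floats are written with 6 significant digits; `read_expression()` on the
#' result reproduces the object up to that precision.
#'
#' @param x An `expr_mat`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(x, path) {
  df <- bind_cols(
    x$genes,
    as_tibble(apply(x$values, 2, fmt_num), .name_repair = "minimal")
  )
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

# 6-significant-digit float formatting shared by all writers
fmt_num <- function(x) {
  out <- formatC(signif(x, 6), format = "g", digits = 6)
  trimws(out)
}

#' Read a sample metadata table
#'
#' Tab-delimited with columns `sample_id`, `group`, `family_id`, `model`,
#' `cftr_class`, `pancreatic`, `pa_infection`, `sweat_chloride`, `fev1_pct`.
#' Missing clinical values are the literal `NA`.
#'
#' @param path File path.
#' @return A validated tibble.
#' @export
read_metadata <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    sample_id = readr::col_character(),
    group = readr::col_character(),
    family_id = readr::col_character(),
    model = readr::col_character(),
    cftr_class = readr::col_character(),
    pancreatic = readr::col_character(),
    pa_infection = readr::col_character(),
    sweat_chloride = readr::col_double(),
    fev1_pct = readr::col_double()
  ), progress = FALSE)
  validate_metadata(df)
}

#' Validate a sample metadata tibble
#'
#' Enforces the metadata invariants: required columns present, known factor
#' levels, every non-HC sample carries a family ID, at most one sample per
#' (family, group, model), clinical covariates non-negative when present.
#'
#' @param meta A data frame of sample metadata.
#' @return The validated tibble (with `family_id` NA normalised to `""` for HC).
#' @export
validate_metadata <- function(meta) {
  required <- c("sample_id", "group", "family_id", "model", "cftr_class",
    "pancreatic", "pa_infection", "sweat_chloride", "fev1_pct")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols) > 0) {
    abort(paste0("Metadata is missing column(s): ", paste(missing_cols, collapse = ", ")),
      class = "triomics_format_error")
  }
  meta <- as_tibble(meta)
  dup <- unique(meta$sample_id[duplicated(meta$sample_id)])
  if (length(dup) > 0) {
    abort(paste0("Duplicate sample IDs: ", paste(dup, collapse = ", ")),
      class = "triomics_format_error")
  }
  bad_grp <- setdiff(unique(meta$group), SAMPLE_GROUPS)
  if (length(bad_grp) > 0) {
    abort(paste0("Unknown group(s): ", paste(bad_grp, collapse = ", ")),
      class = "triomics_format_error")
  }
  meta$family_id[is.na(meta$family_id)] <- ""
  no_fam <- meta$sample_id[meta$group != "HC" & meta$family_id == ""]
  if (length(no_fam) > 0) {
    abort(paste0("Non-HC sample(s) without family_id: ", paste(no_fam, collapse = ", ")),
      class = "triomics_format_error")
  }
  dup_slot <- meta |>
    filter(.data$family_id != "") |>
    count(.data$family_id, .data$group, .data$model) |>
    filter(.data$n > 1)
  if (nrow(dup_slot) > 0) {
    abort(sprintf("Family '%s' has %d samples for group '%s' / model '%s'.",
      dup_slot$family_id[1], dup_slot$n[1], dup_slot$group[1], dup_slot$model[1]),
      class = "triomics_format_error")
  }
  for (cv in c("sweat_chloride", "fev1_pct")) {
    bad <- which(!is.na(meta[[cv]]) & meta[[cv]] < 0)
    if (length(bad) > 0) {
      abort(sprintf("Negative %s for sample '%s'.", cv, meta$sample_id[bad[1]]),
        class = "triomics_format_error")
    }
  }
  meta
}

#' Write a tibble as tab-delimited text
#'
#' Numeric columns are formatted with 6 significant digits so that writes
#' are deterministic and round-trips are lossless at that precision.
#'
#' @param obj A data frame.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_table <- function(obj, path) {
  out <- mutate(as_tibble(obj), across(where(is.numeric), \(v) {
    res <- rep(NA_character_, length(v))
    res[!is.na(v)] <- fmt_num(v[!is.na(v)])
    res
  }))
  readr::write_tsv(out, path, na = "NA", progress = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' One set per line: `name TAB description TAB gene TAB gene ...`. Duplicate
#' genes within a line are removed. Gene symbols are matched
#' case-insensitively downstream (MSigDB symbols are uppercase), so IDs are
#' stored as read but comparisons go through [normalize_gene_ids()].
#'
#' @param path File path.
#' @param name Collection name (defaults to the file name).
#' @return A `gene_set_collection`: named list of character vectors with a
#'   `descriptions` attribute.
#' @export
read_gmt <- function(path, name = basename(path)) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  descs <- character()
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      abort(sprintf("GMT line %d has %d field(s); need set name, description and >= 1 gene.",
        i, length(fields)), class = "triomics_format_error")
    }
    genes <- unique(fields[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) == 0) {
      abort(sprintf("GMT line %d ('%s') has no genes.", i, fields[1]),
        class = "triomics_format_error")
    }
    sets[[fields[1]]] <- genes
    descs[fields[1]] <- fields[2]
  }
  gene_set_collection(sets, descriptions = descs, name = name)
}

#' Construct a gene-set collection
#' @param sets Named list of character vectors (no empty sets).
#' @param descriptions Optional named character vector of per-set descriptions.
#' @param name Collection name.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL, name = "collection") {
  if (length(sets) > 0 && (is.null(names(sets)) || any(!nzchar(names(sets))))) {
    abort("All gene sets must be named.", class = "triomics_format_error")
  }
  empty <- names(sets)[lengths(sets) == 0]
  if (length(empty) > 0) {
    abort(paste0("Empty gene set(s): ", paste(empty, collapse = ", ")),
      class = "triomics_format_error")
  }
  structure(lapply(sets, \(g) unique(as.character(g))),
    descriptions = descriptions, collection_name = name,
    class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> '%s': %d sets (sizes %s)\n",
    attr(x, "collection_name"), length(x),
    if (length(x)) paste(range(lengths(x)), collapse = "-") else "-"))
  invisible(x)
}

#' Write a gene-set collection in GMT format
#' @param x A `gene_set_collection`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  descs <- attr(x, "descriptions")
  lines <- vapply(names(x), function(nm) {
    d <- if (!is.null(descs) && nm %in% names(descs)) descs[[nm]] else "na"
    paste(c(nm, d, x[[nm]]), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}

#' Case-normalise gene identifiers for cross-namespace matching
#' @param ids Character vector.
#' @return Uppercased IDs.
#' @export
normalize_gene_ids <- function(ids) toupper(as.character(ids))

#' Read a candidate marker panel
#'
#' Tab-delimited with columns `subset`, `gene_id`, `panel_group`.
#'
#' @param path File path.
#' @return A `marker_panel` tibble at stage `"candidate"`.
#' @export
read_marker_panel <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE)
  missing_cols <- setdiff(c("subset", "gene_id"), names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Marker panel is missing column(s): ",
      paste(missing_cols, collapse = ", ")), class = "triomics_format_error")
  }
  if (!"panel_group" %in% names(df)) df$panel_group <- "main"
  marker_panel(df[c("subset", "gene_id", "panel_group")], stage = "candidate")
}

#' Construct a marker panel
#' @param df Tibble with `subset`, `gene_id` and optional `panel_group`.
#' @param stage `"candidate"` or `"selected"`.
#' @return A `marker_panel` tibble.
#' @export
marker_panel <- function(df, stage = c("candidate", "selected")) {
  stage <- match.arg(stage)
  df <- as_tibble(df)
  if (!"panel_group" %in% names(df)) df$panel_group <- "main"
  dup <- df |> count(.data$subset, .data$gene_id) |> filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("Gene '%s' listed twice for subset '%s'.",
      dup$gene_id[1], dup$subset[1]), class = "triomics_format_error")
  }
  structure(df, stage = stage, class = c("marker_panel", class(df)))
}

#' Check that an expression matrix and metadata describe the same samples
#'
#' Every downstream stage calls this; a mismatch in either direction is an
#' error listing the offending IDs.
#'
#' @param expr An `expr_mat`.
#' @param meta A metadata tibble.
#' @return Invisibly `TRUE`.
#' @export
check_sample_alignment <- function(expr, meta) {
  es <- sample_ids(expr)
  ms <- meta$sample_id
  only_e <- setdiff(es, ms)
  only_m <- setdiff(ms, es)
  if (length(only_e) > 0 || length(only_m) > 0) {
    abort(paste0(
      "Expression/metadata sample mismatch.",
      if (length(only_e)) paste0(" Only in expression: ", paste(only_e, collapse = ", "), ".") else "",
      if (length(only_m)) paste0(" Only in metadata: ", paste(only_m, collapse = ", "), ".") else ""
    ), class = "triomics_sample_mismatch")
  }
  invisible(TRUE)
}
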