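#' Hypergeometric overlap enrichment against a gene-set collection
#'
#' For each set in the collection (intersected with the universe), the
#' overlap with the input set is tested with the one-sided hypergeometric
#' tail `p = P[X >= k]` for `X ~ Hypergeometric(N, K, n)` (universe size N,
#' set size K, input size n, overlap k), the standard offline counterpart
#' of an MSigDB overlap query. Q values are Benjamini-Hochberg across the
#' collection, and results are ranked by q, then p, then set name. Gene
#' symbols are matched case-insensitively.
#'
#' @param input_set Character vector of gene IDs (must lie in `universe`).
#' @param collection A `gene_set_collection`.
#' @param universe Character vector of gene IDs (e.g. all genes on the
#'   expression matrix).
#' @return An `enrichment_result` tibble: `set_name`, `overlap` (k),
#'   `set_size` (K), `input_size` (n), `universe_size` (N), `p_value`,
#'   `fdr_q`, `rank`, `genes` (comma-separated overlapping IDs).
#' @export
enrich <- function(input_set, collection, universe) {
  if (length(universe) == 0) abort("Empty universe.", class = "triomics_input_error")
  if (length(input_set) == 0) abort("Empty input set.", class = "triomics_input_error")
  uni <- unique(normalize_gene_ids(universe))
  inp <- unique(normalize_gene_ids(input_set))
  outside <- setdiff(inp, uni)
  if (length(outside) > 0) {
    abort(paste0("Input gene(s) outside the universe: ",
      paste(head(outside, 10), collapse = ", ")), class = "triomics_input_error")
  }
  N <- length(uni)
  n <- length(inp)
  res <- purrr::map_dfr(names(collection), function(nm) {
    set_g <- intersect(unique(normalize_gene_ids(collection[[nm]])), uni)
    K <- length(set_g)
    ov <- intersect(inp, set_g)
    k <- length(ov)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    tibble(set_name = nm, overlap = k, set_size = K, input_size = n,
      universe_size = N, p_value = p, genes = paste(sort(ov), collapse = ","))
  })
  res$fdr_q <- benjamini_hochberg(res$p_value)
  res <- res |>
    arrange(.data$fdr_q, .data$p_value, .data$set_name) |>
    mutate(rank = row_number()) |>
    select("set_name", "overlap", "set_size", "input_size", "universe_size",
      "p_value", "fdr_q", "rank", "genes")
  structure(res, class = c("enrichment_result", class(res)))
}

#' Top-k enrichment results
#'
#' Stable head of the ranked enrichment table (ranking: q, then p, then set
#' name), mirroring the "top 10 matched gene sets ranked by q value"
#' reporting convention.
#'
#' @param results An `enrichment_result`.
#' @param k Number of sets to keep, default 10.
#' @return The first `k` rows (the whole table if `k` exceeds it).
#' @export
top_k <- function(results, k = 10) {
  stopifnot(k >= 0)
  results |>
    arrange(.data$rank) |>
    head(k)
}
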