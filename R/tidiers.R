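#' Tidy methods for package result objects
#'
#' `tidy()` returns the per-unit table of a result as a plain tibble;
#' `glance()` returns a one-row summary of the fit.
#'
#' @param x A result object.
#' @param ... Unused.
#' @return A tibble.
#' @name triomics-tidiers
NULL

#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @rdname triomics-tidiers
#' @export
tidy.de_result <- function(x, ...) {
  as_tibble(unclass_result(x))
}

#' @rdname triomics-tidiers
#' @export
glance.de_result <- function(x, ...) {
  pr <- attr(x, "prior")
  ct <- attr(x, "contrast")
  tibble(
    contrast = ct$name, paired = attr(x, "paired"),
    n_case = attr(x, "n_case"), n_ref = attr(x, "n_ref"),
    n_genes = nrow(x), n_deg = sum(x$is_deg),
    n_up = sum(x$is_deg & x$direction == "up"),
    n_down = sum(x$is_deg & x$direction == "down"),
    d0 = pr$d0, s0_sq = pr$s0_sq,
    fold_threshold = attr(x, "fold_threshold"),
    q_threshold = attr(x, "q_threshold")
  )
}

#' @rdname triomics-tidiers
#' @export
tidy.comparison_result <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname triomics-tidiers
#' @export
tidy.association_result <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname triomics-tidiers
#' @export
tidy.enrichment_result <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname triomics-tidiers
#' @export
tidy.composition_scores <- function(x, ...) as_tibble(unclass_result(x))

#' @rdname triomics-tidiers
#' @export
tidy.clustering_result <- function(x, ...) {
  hc <- x$hclust
  tibble(
    step = seq_len(nrow(hc$merge)),
    left = hc$merge[, 1], right = hc$merge[, 2],
    height = hc$height
  )
}

#' @rdname triomics-tidiers
#' @export
glance.clustering_result <- function(x, ...) {
  tibble(n_samples = length(x$sample_ids), linkage = x$linkage,
    distance = x$distance, max_height = max(x$hclust$height))
}

# strip package classes so as_tibble() yields a plain tibble copy
unclass_result <- function(x) {
  class(x) <- setdiff(class(x),
    c("de_result", "comparison_result", "association_result",
      "enrichment_result", "composition_scores", "marker_panel"))
  x
}
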