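# Small fixture builders shared across test files.

make_expr <- function(X, locus = rep("coding", nrow(X))) {
  expression_matrix(X, locus)
}

# Two independent groups (case + HC), singleton pseudo-families.
two_group_meta <- function(n_case, n_ref, case_group = "proband") {
  tibble::tibble(
    sample_id = c(sprintf("C%02d", seq_len(n_case)), sprintf("H%02d", seq_len(n_ref))),
    group = c(rep(case_group, n_case), rep("HC", n_ref)),
    family_id = c(sprintf("F%02d", seq_len(n_case)), sprintf("H%02d", seq_len(n_ref))),
    model = "PBMC",
    cftr_class = NA_character_, pancreatic = NA_character_,
    pa_infection = NA_character_,
    sweat_chloride = NA_real_, fev1_pct = NA_real_
  )
}

# n_fam trio families (proband + mother) plus HCs, for paired designs.
paired_meta <- function(n_fam, n_hc = 0) {
  fams <- sprintf("F%02d", seq_len(n_fam))
  tibble::tibble(
    sample_id = c(paste0(fams, "_P"), paste0(fams, "_M"),
      if (n_hc > 0) sprintf("H%02d", seq_len(n_hc))),
    group = c(rep("proband", n_fam), rep("mother", n_fam), rep("HC", n_hc)),
    family_id = c(fams, fams, if (n_hc > 0) sprintf("H%02d", seq_len(n_hc))),
    model = "PBMC",
    cftr_class = NA_character_, pancreatic = NA_character_,
    pa_infection = NA_character_,
    sweat_chloride = NA_real_, fev1_pct = NA_real_
  )
}

# Random two-group expression fixture with labelled samples.
random_two_group <- function(n_genes, n_case, n_ref, shift_genes = 0,
                             shift = 0, sd = 1, seed = 1) {
  set.seed(seed)
  meta <- two_group_meta(n_case, n_ref)
  X <- matrix(rnorm(n_genes * (n_case + n_ref), 8, sd), n_genes,
    dimnames = list(sprintf("G%04d", seq_len(n_genes)), meta$sample_id))
  if (shift_genes > 0) {
    X[seq_len(shift_genes), seq_len(n_case)] <-
      X[seq_len(shift_genes), seq_len(n_case)] + shift
  }
  list(expr = make_expr(X), meta = meta)
}

# Minimal stand-in DE result (plain tibble with the de_result columns) for
# the set-logic operations, which are defined on the columns only.
fake_de <- function(universe, degs, log2fc = NULL,
                    locus = rep("coding", length(universe))) {
  if (is.null(log2fc)) {
    log2fc <- stats::setNames(rep(0, length(universe)), universe)
    log2fc[degs] <- 2
  }
  fc <- unname(log2fc[universe])
  tibble::tibble(
    gene_id = universe,
    locus_type = locus,
    log2fc = fc,
    direction = ifelse(fc >= 0, "up", "down"),
    is_deg = universe %in% degs
  )
}

# Long-format composition score tibble from a sample x subset matrix.
scores_from_matrix <- function(M) {
  tibble::as_tibble(M, rownames = "sample_id") |>
    tidyr::pivot_longer(-sample_id, names_to = "subset", values_to = "score")
}

# Fast small simulation config for tests that only need structure.
small_config <- function(seed = 1, ...) {
  sim_config(n_families = 6, n_hc = 6, n_genes = 400,
    markers_per_subset = 5, decoys_per_subset = 2, n_family_genes = 60,
    seed = seed, ...)
}
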