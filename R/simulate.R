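#' Configuration for a simulated trio study
#'
#' Defines the generative model for a proband-parent-control expression
#' study: per-sample cell-subset mixing weights on the simplex, marker genes
#' whose log2 expression tracks the log-ratio of their subset's weight to
#' its expected value, a myeloid suppression shared by all trio members
#' (probands and carrier parents), a familial random effect shared within
#' each family on a declared background gene subset, and clinical covariates
#' linked to the per-family severity of the myeloid suppression.
#'
#' For sample `s` with weights `w_s ~ Dirichlet(mixture_concentration)`, a
#' marker gene `g` of subset `k` takes the value
#' `x_gs = b_g + a*log2(w_ks / wbar_k) - delta_f * 1[k myeloid & s in a trio]
#' + eps`, with `eps ~ N(0, sigma^2)` and `wbar_k` the expected weight of
#' subset `k`. Background genes are `b_g + gamma_f + eps`, where the familial
#' effect `gamma_f ~ N(0, tau^2)` is shared by all members of family `f` on
#' the declared family-effect gene subset (healthy controls form singleton
#' pseudo-families). `delta_f = delta * s_f` with a per-family severity draw
#' `s_f` (mean 1), so that `E[delta_f] = delta`.
#'
#' @param n_families Number of complete proband-father-mother trios.
#' @param n_hc Number of unrelated healthy controls.
#' @param n_genes Total number of genes.
#' @param subsets Cell subset names; defaults to the ten-subset PBMC panel.
#' @param myeloid_subsets Which subsets carry the suppression.
#' @param markers_per_subset True marker genes per subset (>= 2).
#' @param decoys_per_subset Uncorrelated background genes added to each
#'   subset's candidate panel.
#' @param mixture_concentration Dirichlet concentration, one value per subset.
#' @param mixture_amplitude `a`, log2 units of expression per log2 unit of
#'   relative weight.
#' @param myeloid_suppression_delta `delta`, log2 units subtracted from
#'   myeloid marker signal in trio samples.
#' @param family_effect_sd `tau`, log2 SD of the shared familial effect.
#' @param noise_sd `sigma`, log2 SD of the i.i.d. measurement noise.
#' @param frac_coding,frac_multiple_complex,frac_noncoding Locus-type
#'   proportions; the remainder is `"other"`.
#' @param n_family_genes Number of background genes carrying the familial
#'   effect.
#' @param clinical_link_slope Sweat chloride mmol/L per unit of myeloid
#'   suppression (`delta_f`).
#' @param fev1_slope Percent-predicted FEV1 lost per unit of `delta_f`.
#' @param clinical_noise_sd SD of the clinical covariate noise.
#' @param model Cellular model label stamped on the metadata.
#' @param seed Integer seed; fully determines the study.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_families = 14,
                       n_hc = 18,
                       n_genes = 2000,
                       subsets = PBMC_SUBSETS,
                       myeloid_subsets = MYELOID_SUBSETS,
                       markers_per_subset = 20,
                       decoys_per_subset = 4,
                       mixture_concentration = rep(6.8, length(subsets)),
                       mixture_amplitude = 1,
                       myeloid_suppression_delta = 0.8,
                       family_effect_sd = 0.6,
                       noise_sd = 0.3,
                       frac_coding = 0.45,
                       frac_multiple_complex = 0.25,
                       frac_noncoding = 0.20,
                       n_family_genes = 300,
                       clinical_link_slope = 20,
                       fev1_slope = 35,
                       clinical_noise_sd = 4,
                       model = "PBMC",
                       seed = 1L) {
  cfg <- list(
    n_families = n_families, n_hc = n_hc, n_genes = n_genes,
    subsets = subsets, myeloid_subsets = myeloid_subsets,
    markers_per_subset = markers_per_subset,
    decoys_per_subset = decoys_per_subset,
    mixture_concentration = mixture_concentration,
    mixture_amplitude = mixture_amplitude,
    myeloid_suppression_delta = myeloid_suppression_delta,
    family_effect_sd = family_effect_sd, noise_sd = noise_sd,
    frac_coding = frac_coding, frac_multiple_complex = frac_multiple_complex,
    frac_noncoding = frac_noncoding, n_family_genes = n_family_genes,
    clinical_link_slope = clinical_link_slope, fev1_slope = fev1_slope,
    clinical_noise_sd = clinical_noise_sd, model = model,
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
}

validate_sim_config <- function(cfg) {
  K <- length(cfg$subsets)
  if (length(cfg$mixture_concentration) != K || any(cfg$mixture_concentration <= 0)) {
    abort("`mixture_concentration` needs one positive value per subset.",
      class = "triomics_config_error")
  }
  if (cfg$markers_per_subset < 2) {
    abort("`markers_per_subset` must be >= 2 (pairwise correlation needs pairs).",
      class = "triomics_config_error")
  }
  fracs <- c(cfg$frac_coding, cfg$frac_multiple_complex, cfg$frac_noncoding)
  if (any(fracs < 0) || sum(fracs) > 1) {
    abort("Locus-type fractions must be non-negative and sum to <= 1.",
      class = "triomics_config_error")
  }
  if (any(c(cfg$family_effect_sd, cfg$noise_sd, cfg$clinical_noise_sd) < 0)) {
    abort("Standard deviations must be >= 0.", class = "triomics_config_error")
  }
  n_markers <- K * cfg$markers_per_subset
  if (cfg$n_genes < n_markers) {
    abort(sprintf("n_genes (%d) < subsets x markers_per_subset (%d).",
      cfg$n_genes, n_markers), class = "triomics_config_error")
  }
  n_bg <- cfg$n_genes - n_markers
  if (n_bg < cfg$n_family_genes + K * cfg$decoys_per_subset) {
    abort("Not enough background genes for family-effect genes plus decoys.",
      class = "triomics_config_error")
  }
  if (!all(cfg$myeloid_subsets %in% cfg$subsets)) {
    abort("`myeloid_subsets` must be a subset of `subsets`.",
      class = "triomics_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' Simulate a trio-structured expression study with known ground truth
#'
#' @param config A [sim_config()].
#' @return A `simulated_study`: list with `expression` (an `expr_mat`),
#'   `metadata` (sample tibble), `candidates` (candidate `marker_panel`:
#'   true markers plus decoys), and `truth` (list of tibbles: `genes`,
#'   `samples`, `weights`, `families`).
#' @export
simulate_study <- function(config) {
  cfg <- validate_sim_config(config)
  set.seed(cfg$seed)
  K <- length(cfg$subsets)
  m <- cfg$markers_per_subset

  # ---- samples ----
  fam_ids <- sprintf("F%02d", seq_len(cfg$n_families))
  trio <- tidyr::expand_grid(family_id = fam_ids,
    group = c("proband", "father", "mother")) |>
    mutate(sample_id = paste0(.data$family_id, "_",
      c(proband = "P", father = "F", mother = "M")[.data$group]))
  hc <- tibble(
    family_id = sprintf("HC%02d", seq_len(cfg$n_hc)),
    group = "HC",
    sample_id = sprintf("HC%02d", seq_len(cfg$n_hc))
  )
  samples <- bind_rows(trio, hc)
  n_samp <- nrow(samples)
  all_fams <- c(fam_ids, hc$family_id)

  # ---- genes ----
  marker_genes <- as.vector(t(outer(cfg$subsets, seq_len(m),
    \(s, i) sprintf("MK_%s_%02d", toupper(s), i))))
  marker_subset <- rep(cfg$subsets, each = m)
  n_bg <- cfg$n_genes - length(marker_genes)
  bg_genes <- sprintf("BG%05d", seq_len(n_bg))
  gene_id <- c(marker_genes, bg_genes)

  n_cod <- max(round(cfg$frac_coding * cfg$n_genes), length(marker_genes))
  n_mc <- round(cfg$frac_multiple_complex * cfg$n_genes)
  n_nc <- round(cfg$frac_noncoding * cfg$n_genes)
  n_other <- cfg$n_genes - n_cod - n_mc - n_nc
  locus_type <- c(rep("coding", n_cod), rep("multiple_complex", n_mc),
    rep("noncoding", n_nc), rep("other", max(n_other, 0)))[seq_len(cfg$n_genes)]

  family_genes <- sample(bg_genes, cfg$n_family_genes)
  plain_bg <- setdiff(bg_genes, family_genes)

  # ---- mixture weights ----
  alpha <- setNames(cfg$mixture_concentration, cfg$subsets)
  wbar <- alpha / sum(alpha)
  raw <- matrix(rgamma(n_samp * K, shape = rep(alpha, each = n_samp)),
    nrow = n_samp, ncol = K, dimnames = list(samples$sample_id, cfg$subsets))
  w <- raw / rowSums(raw)

  # ---- family severity and suppression ----
  sev <- setNames(sample(c(0.6, 1.4), cfg$n_families, replace = TRUE) +
    runif(cfg$n_families, -0.1, 0.1), fam_ids)
  delta_f <- cfg$myeloid_suppression_delta * sev
  samples$severity <- unname(sev[samples$family_id])
  samples$delta_f <- ifelse(samples$group == "HC", 0,
    unname(delta_f[samples$family_id]))

  # ---- expression ----
  b <- setNames(runif(cfg$n_genes, 4, 12), gene_id)
  X <- matrix(b, nrow = cfg$n_genes, ncol = n_samp,
    dimnames = list(gene_id, samples$sample_id))

  is_myeloid <- marker_subset %in% cfg$myeloid_subsets
  log_ratio <- log2(sweep(w, 2, wbar, "/"))        # samples x subsets
  k_idx <- match(marker_subset, cfg$subsets)
  sig <- cfg$mixture_amplitude * t(log_ratio)[k_idx, , drop = FALSE]
  supp <- outer(as.numeric(is_myeloid), samples$delta_f)
  X[marker_genes, ] <- X[marker_genes, ] + sig - supp

  if (cfg$n_family_genes > 0 && cfg$family_effect_sd > 0) {
    gam <- matrix(rnorm(cfg$n_family_genes * length(all_fams),
      sd = cfg$family_effect_sd),
      nrow = cfg$n_family_genes, dimnames = list(family_genes, all_fams))
    X[family_genes, ] <- X[family_genes, ] + gam[, samples$family_id, drop = FALSE]
  }
  if (cfg$noise_sd > 0) {
    X <- X + matrix(rnorm(length(X), sd = cfg$noise_sd), nrow = nrow(X))
  }

  # ---- clinical covariates ----
  is_prob <- samples$group == "proband"
  sweat <- runif(n_samp, 10, 40)
  sweat[is_prob] <- 100 + cfg$clinical_link_slope * samples$delta_f[is_prob] +
    rnorm(sum(is_prob), sd = cfg$clinical_noise_sd)
  fev1 <- rep(NA_real_, n_samp)
  fev1[is_prob] <- pmin(pmax(95 - cfg$fev1_slope * samples$delta_f[is_prob] +
    rnorm(sum(is_prob), sd = cfg$clinical_noise_sd), 20), 120)
  cftr_class <- ifelse(is_prob, ifelse(samples$severity >= 1, "I_II_III", "IV"), NA)
  pancreatic <- ifelse(is_prob,
    ifelse(samples$severity + runif(n_samp, -0.25, 0.25) >= 1, "PI", "PS"), NA)
  pa_prob <- pmin(0.9, pmax(0.1, 0.5 + 0.5 * (samples$severity - 1)))
  pa_infection <- ifelse(is_prob,
    ifelse(rbinom(n_samp, 1, ifelse(is.na(pa_prob), 0.5, pa_prob)) == 1, "pos", "neg"),
    NA)

  metadata <- tibble(
    sample_id = samples$sample_id,
    group = samples$group,
    family_id = samples$family_id,
    model = cfg$model,
    cftr_class = cftr_class,
    pancreatic = pancreatic,
    pa_infection = pa_infection,
    sweat_chloride = round(sweat, 1),
    fev1_pct = round(fev1, 1)
  )

  # ---- candidate panel: true markers plus decoys ----
  decoys <- if (cfg$decoys_per_subset > 0) {
    dec <- sample(plain_bg, K * cfg$decoys_per_subset)
    tibble(subset = rep(cfg$subsets, each = cfg$decoys_per_subset),
      gene_id = dec, panel_group = "main")
  } else {
    tibble(subset = character(), gene_id = character(), panel_group = character())
  }
  candidates <- marker_panel(bind_rows(
    tibble(subset = marker_subset, gene_id = marker_genes, panel_group = "main"),
    decoys
  ), stage = "candidate")

  # ---- ground truth ----
  truth_genes <- tibble(
    gene_id = gene_id,
    locus_type = locus_type,
    baseline = unname(b),
    role = c(rep("marker", length(marker_genes)),
      ifelse(bg_genes %in% family_genes, "family_background", "background")),
    subset = c(marker_subset, rep(NA_character_, n_bg)),
    is_decoy = gene_id %in% decoys$gene_id,
    true_group_effect = c(ifelse(is_myeloid, -cfg$myeloid_suppression_delta, 0),
      rep(0, n_bg))
  )
  truth_weights <- as_tibble(w, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "subset", values_to = "weight") |>
    mutate(
      signal = cfg$mixture_amplitude * log2(.data$weight / wbar[.data$subset]) -
        ifelse(.data$subset %in% cfg$myeloid_subsets,
          samples$delta_f[match(.data$sample_id, samples$sample_id)], 0)
    )
  truth_samples <- tibble(
    sample_id = samples$sample_id,
    group = samples$group,
    family_id = samples$family_id,
    severity = samples$severity,
    delta_f = samples$delta_f
  )
  truth_families <- tibble(family_id = fam_ids, severity = unname(sev),
    delta_f = unname(delta_f))

  structure(list(
    expression = expression_matrix(X, locus_type),
    metadata = validate_metadata(metadata),
    candidates = candidates,
    truth = list(genes = truth_genes, samples = truth_samples,
      weights = truth_weights, families = truth_families),
    config = cfg
  ), class = "simulated_study")
}

#' @export
print.simulated_study <- function(x, ...) {
  cat(sprintf("<simulated_study> %d genes x %d samples; %d trio families + %d HC (seed %d)\n",
    nrow(x$expression$values), ncol(x$expression$values),
    x$config$n_families, x$config$n_hc, x$config$seed))
  invisible(x)
}

#' Ground-truth report of a simulated study
#'
#' Collects the per-gene and per-sample ground truth as plain tibbles and
#' optionally writes them as TSV, for use in recovery tests.
#'
#' @param study A `simulated_study`.
#' @param dir Optional directory; if given, writes `truth_genes.tsv`,
#'   `truth_samples.tsv` and `truth_weights.tsv` there.
#' @return A list of tibbles `genes`, `samples`, `weights`.
#' @export
truth_report <- function(study, dir = NULL) {
  stopifnot(inherits(study, "simulated_study"))
  out <- study$truth[c("genes", "samples", "weights")]
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_table(out$genes, file.path(dir, "truth_genes.tsv"))
    write_table(out$samples, file.path(dir, "truth_samples.tsv"))
    write_table(out$weights, file.path(dir, "truth_weights.tsv"))
  }
  out
}
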