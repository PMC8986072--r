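make_clinical_fixture <- function(n = 12, seed = 71) {
  set.seed(seed)
  meta <- two_group_meta(n, 4)
  meta$sweat_chloride[meta$group == "proband"] <- rnorm(n, 100, 10)
  meta$fev1_pct[meta$group == "proband"] <- rnorm(n, 70, 15)
  score <- rnorm(n + 4, 5, 1)
  list(meta = meta, scores = tibble::tibble(sample_id = meta$sample_id,
    subset = "monocyte", score = score))
}

test_that("an affine covariate gives |r| = 1 and a vanishing p", {
  fx <- make_clinical_fixture()
  fx$meta$sweat_chloride[fx$meta$group == "proband"] <-
    3 * fx$scores$score[fx$meta$group == "proband"] + 40
  fx$meta$fev1_pct[fx$meta$group == "proband"] <-
    -2 * fx$scores$score[fx$meta$group == "proband"] + 90
  a <- correlate_clinical(fx$scores, fx$meta)
  expect_equal(a$r[a$covariate == "sweat_chloride"], 1, tolerance = 1e-10)
  expect_equal(a$r[a$covariate == "fev1_pct"], -1, tolerance = 1e-10)
  expect_lt(max(a$p_value), 1e-12)
  expect_equal(a$slope[a$covariate == "sweat_chloride"], 3, tolerance = 1e-10)
  expect_equal(a$intercept[a$covariate == "sweat_chloride"], 40, tolerance = 1e-8)
})

test_that("Pearson r matches the textbook sum formula on a 5-pair dataset", {
  x <- c(4.1, 5.3, 3.8, 6.2, 5.0)
  y <- c(102, 95, 110, 88, 99)
  meta <- two_group_meta(5, 2)
  meta$sweat_chloride[meta$group == "proband"] <- y
  sc <- tibble::tibble(sample_id = meta$sample_id, subset = "macrophage",
    score = c(x, 0, 0))
  a <- correlate_clinical(sc, meta, covariates = "sweat_chloride")
  expect_equal(a$r, brute_pearson(x, y), tolerance = 1e-10)
  expect_equal(a$r_squared, a$r^2, tolerance = 1e-12)
  expect_identical(a$n, 5L)
})

test_that("correlations drop NA pairs, exclude HC, and guard small n", {
  fx <- make_clinical_fixture()
  fx$meta$sweat_chloride[fx$meta$group == "proband"][1:3] <- NA
  a <- correlate_clinical(fx$scores, fx$meta, covariates = "sweat_chloride")
  expect_identical(a$n, 9L)  # 12 probands - 3 NA; HC never enters
  few <- fx
  few$meta$sweat_chloride[few$meta$group == "proband"][1:9] <- NA
  a2 <- correlate_clinical(few$scores, few$meta, covariates = "sweat_chloride")
  expect_true(is.na(a2$r))
  expect_identical(a2$n, 3L)
})

test_that("r is invariant to affine rescaling of the covariate", {
  fx <- make_clinical_fixture(seed = 72)
  a1 <- correlate_clinical(fx$scores, fx$meta, covariates = "sweat_chloride")
  fx$meta$sweat_chloride <- 0.1 * fx$meta$sweat_chloride + 7
  a2 <- correlate_clinical(fx$scores, fx$meta, covariates = "sweat_chloride")
  expect_equal(a1$r, a2$r, tolerance = 1e-10)
  expect_equal(a1$p_value, a2$p_value, tolerance = 1e-10)
})

test_that("subgroup comparisons stratify probands and adjust within score", {
  set.seed(73)
  meta <- two_group_meta(12, 8)
  meta$cftr_class[meta$group == "proband"] <- rep(c("I_II_III", "IV"), each = 6)
  sc <- tibble::tibble(sample_id = rep(meta$sample_id, 2),
    subset = rep(c("monocyte", "B"), each = nrow(meta)),
    score = rnorm(2 * nrow(meta), 5, 0.4))
  sc$score[sc$subset == "monocyte"][meta$cftr_class %in% "I_II_III"] <- 2
  sg <- subgroup_compare(sc, meta, "cftr_class")
  expect_setequal(unique(sg$comparison),
    c("I_II_III:IV", "I_II_III:HC", "IV:HC"))
  for (k in unique(sg$score)) {
    rows <- sg[sg$score == k, ]
    expect_equal(rows$p_adjusted, holm_sidak(rows$p_raw))
  }
  sev <- sg[sg$score == "monocyte" & sg$comparison == "I_II_III:IV", ]
  expect_lt(sev$estimate, 0)
  expect_lt(sev$p_adjusted, 0.01)
  # identical strata show nothing
  null_sg <- sg[sg$score == "B", ]
  expect_true(all(null_sg$p_adjusted > 0.05))
})

test_that("fold-change concordance is exact on identity and degrades with noise", {
  set.seed(74)
  uni <- sprintf("G%03d", 1:200)
  fc <- stats::setNames(c(runif(100, 0.5, 3), runif(100, -3, -0.5)), uni)
  deA <- fake_de(uni, uni, log2fc = fc)
  cc <- fold_change_concordance(deA, deA, uni)
  expect_equal(cc$r_squared, c(1, 1), tolerance = 1e-12)
  expect_identical(cc$direction, c("up", "down"))
  expect_identical(cc$n, c(100L, 100L))

  r2_at_noise <- purrr::map_dbl(c(0.1, 0.6, 2.0), function(tau) {
    mean(purrr::map_dbl(1:20, function(s) {
      set.seed(1000 * tau + s)
      fcB <- fc + rnorm(length(fc), 0, tau)
      deB <- fake_de(uni, uni, log2fc = stats::setNames(fcB, uni))
      mean(fold_change_concordance(deA, deB, uni)$r_squared)
    }))
  })
  expect_true(all(diff(r2_at_noise) < 0))

  # halves with < 3 genes are NA
  small <- fold_change_concordance(deA, deA, names(fc)[1:2])
  expect_true(is.na(small$r_squared[small$direction == "down"]))
  expect_error(fold_change_concordance(deA, deA, "NOPE"),
    class = "triomics_universe_error")
})

test_that("trio-shared genes are more concordant than proband-unique genes", {
  # familial effects make proband and mother fold changes co-vary on the
  # family gene set; plain background genes have no shared component
  res <- purrr::map_dfr(1:5, function(s) {
    st <- simulate_study(sim_config(n_families = 10, n_hc = 10, n_genes = 800,
      n_family_genes = 300, family_effect_sd = 1.2, seed = 800 + s))
    deP <- fit_moderated(st$expression, st$metadata, contrast("proband", "HC"))
    deM <- fit_moderated(st$expression, st$metadata, contrast("mother", "HC"))
    tg <- st$truth$genes
    shared_like <- tg$gene_id[tg$role == "family_background"]
    unique_like <- tg$gene_id[tg$role == "background"]
    tibble::tibble(
      shared = mean(fold_change_concordance(deP, deM, shared_like)$r_squared,
        na.rm = TRUE),
      unique = mean(fold_change_concordance(deP, deM, unique_like)$r_squared,
        na.rm = TRUE))
  })
  expect_true(all(res$shared > res$unique))
})
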