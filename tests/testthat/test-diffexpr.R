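test_that("identical groups give zero fold changes and no DEGs", {
  set.seed(21)
  X0 <- matrix(rnorm(50 * 4, 8), 50, 4)
  X <- cbind(X0, X0)
  dimnames(X) <- list(sprintf("G%03d", 1:50),
    c(sprintf("C%02d", 1:4), sprintf("H%02d", 1:4)))
  fx <- make_expr(X)
  meta <- two_group_meta(4, 4)
  de <- fit_moderated(fx, meta, contrast("proband", "HC"))
  expect_true(all(de$log2fc == 0))
  expect_true(all(!de$is_deg))
  expect_true(all(de$p_value == 1))
})

test_that("with a null prior (d0 = 0) the moderated t is the ordinary pooled t", {
  fx <- random_two_group(80, 5, 7, shift_genes = 10, shift = 2, seed = 22)
  de <- fit_moderated(fx$expr, fx$meta, contrast("proband", "HC"),
    prior = list(d0 = 0, s0_sq = 1))
  case <- fx$meta$sample_id[fx$meta$group == "proband"]
  ref <- fx$meta$sample_id[fx$meta$group == "HC"]
  for (g in sample(gene_ids(fx$expr), 25)) {
    tt <- t.test(fx$expr$values[g, case], fx$expr$values[g, ref],
      var.equal = TRUE)
    i <- which(de$gene_id == g)
    expect_lt(abs(de$t_mod[i] - unname(tt$statistic)), 1e-10)
    expect_lt(abs(de$p_value[i] - tt$p.value), 1e-10)
  }
})

test_that("paired fit with d0 = 0 matches the paired t test", {
  set.seed(23)
  meta <- paired_meta(6)
  X <- matrix(rnorm(40 * 12, 8), 40, 12, dimnames = list(sprintf("G%03d", 1:40),
    meta$sample_id))
  fx <- make_expr(X)
  de <- fit_moderated(fx, meta, contrast("proband", "mother", paired = TRUE),
    prior = list(d0 = 0, s0_sq = 1))
  for (g in c("G001", "G017", "G040")) {
    tt <- t.test(X[g, 1:6], X[g, 7:12], paired = TRUE)
    i <- which(de$gene_id == g)
    expect_lt(abs(de$t_mod[i] - unname(tt$statistic)), 1e-10)
    expect_lt(abs(de$log2fc[i] - unname(tt$estimate)), 1e-12)
  }
})

test_that("moderated statistics agree with an independent empirical-Bayes fit", {
  skip_if_not_installed("limma")
  set.seed(24)
  n <- 400
  sds <- sqrt(0.25 * 4 / stats::rchisq(n, 4))
  meta <- two_group_meta(6, 6)
  X <- matrix(rnorm(n * 12, 8, rep(sds, 12)), n,
    dimnames = list(sprintf("G%04d", 1:n), meta$sample_id))
  X[1:30, 1:6] <- X[1:30, 1:6] + 1.5
  de <- fit_moderated(make_expr(X), meta, contrast("proband", "HC"))
  design <- cbind(HC = 1, proband = rep(c(1, 0), each = 6))
  fit <- limma::eBayes(limma::lmFit(X, design))
  expect_equal(attr(de, "prior")$d0, fit$df.prior, tolerance = 1e-8)
  expect_equal(attr(de, "prior")$s0_sq, fit$s2.prior, tolerance = 1e-8)
  expect_equal(de$t_mod, unname(fit$t[, "proband"]), tolerance = 1e-10)
  expect_equal(de$p_value, unname(fit$p.value[, "proband"]), tolerance = 1e-10)
})

test_that("BH adjustment matches hand computation and the step-up oracle", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(benjamini_hochberg(rep(0.2, 5)), rep(0.2, 5))
  expect_error(benjamini_hochberg(c(0.1, NA)), class = "triomics_input_error")
  expect_error(benjamini_hochberg(c(0.1, 1.2)), class = "triomics_input_error")
  set.seed(25)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    expect_equal(benjamini_hochberg(p), brute_bh(p), tolerance = 1e-14)
  }
})

test_that("DEG summaries count by locus type and conserve totals", {
  universe <- sprintf("G%03d", 1:100)
  lt <- rep(c("coding", "noncoding"), c(60, 40))
  fc <- stats::setNames(rep(0, 100), universe)
  fc[1:10] <- 2       # up coding
  fc[11:40] <- -2     # down coding
  fc[61:65] <- 2      # up noncoding
  de <- fake_de(universe, universe[c(1:40, 61:65)], log2fc = fc, locus = lt)
  s <- deg_summary(de)
  expect_identical(s$up[s$locus_type == "coding"], 10L)
  expect_identical(s$down[s$locus_type == "coding"], 30L)
  expect_equal(s$up_down_ratio[s$locus_type == "coding"], 1 / 3)
  expect_identical(s$n_deg[s$locus_type == "total"], 45L)
  expect_identical(sum(s$n_deg[s$locus_type != "total"]),
    s$n_deg[s$locus_type == "total"])
  # no DEGs -> all-zero table
  s0 <- deg_summary(fake_de(universe, character(0), locus = lt))
  expect_true(all(s0$n_deg == 0))
})

test_that("volcano table is a faithful projection", {
  fx <- random_two_group(30, 4, 4, shift_genes = 5, shift = 3, seed = 26)
  de <- fit_moderated(fx$expr, fx$meta, contrast("proband", "HC"))
  vt <- volcano_table(de)
  expect_identical(vt$gene_id, de$gene_id)
  expect_equal(vt$log2fc, de$log2fc)
  expect_equal(vt$neg_log10_p, -log10(de$p_value))
  expect_identical(vt$is_deg, de$is_deg)
})

test_that("DEG counts are monotone in the gates", {
  st <- simulate_study(small_config(seed = 27, myeloid_suppression_delta = 1.5))
  counts <- purrr::map_int(c(0.01, 0.05, 0.2), function(q) {
    sum(fit_moderated(st$expression, st$metadata, contrast("proband", "HC"),
      q_threshold = q)$is_deg)
  })
  expect_true(all(diff(counts) >= 0))
  counts_f <- purrr::map_int(c(4, 2, 1.2), function(fold) {
    sum(fit_moderated(st$expression, st$metadata, contrast("proband", "HC"),
      fold_threshold = fold)$is_deg)
  })
  expect_true(all(diff(counts_f) >= 0))
})

test_that("a huge prior df pins every posterior variance to the prior variance", {
  fx <- random_two_group(100, 8, 8, sd = 0.1, seed = 28)
  meta <- fx$meta
  de <- fit_moderated(fx$expr, meta, contrast("proband", "HC"),
    prior = list(d0 = 1e6, s0_sq = 0.01))
  sef <- sqrt(1 / 8 + 1 / 8)
  s2_post <- (de$log2fc / (de$t_mod * sef))^2
  expect_true(all(abs(s2_post - 0.01) <= 1e-6))
})

test_that("degenerate inputs raise the documented errors", {
  X <- matrix(5, 3, 6, dimnames = list(c("A", "B", "C"),
    two_group_meta(3, 3)$sample_id))
  expect_error(fit_moderated(make_expr(X), two_group_meta(3, 3),
    contrast("proband", "HC")), class = "triomics_prior_error")
  fx <- random_two_group(10, 3, 3)
  expect_error(fit_moderated(fx$expr, fx$meta, contrast("mother", "HC")),
    class = "triomics_contrast_error")
  expect_error(contrast("HC", "HC"), class = "triomics_contrast_error")
  expect_error(contrast("proband", "HC", paired = TRUE),
    class = "triomics_contrast_error")
})

test_that("empirical FDR among flagged genes is controlled with planted effects", {
  res <- purrr::map_dbl(1:8, function(s) {
    set.seed(300 + s)
    n <- 2000; n_true <- 200
    meta <- two_group_meta(8, 8)
    X <- matrix(rnorm(n * 16, 8, 0.3), n,
      dimnames = list(sprintf("G%04d", 1:n), meta$sample_id))
    X[1:n_true, 1:8] <- X[1:n_true, 1:8] + 2
    de <- fit_moderated(make_expr(X), meta, contrast("proband", "HC"))
    flagged <- which(de$is_deg)
    if (length(flagged) == 0) return(0)
    mean(flagged > n_true)  # false discoveries
  })
  se <- sd(res) / sqrt(length(res))
  expect_lte(mean(res), 0.05 + 3 * max(se, 1e-3))
})
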