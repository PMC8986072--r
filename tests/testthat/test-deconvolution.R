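test_that("near-duplicate candidates are all kept with mean_r near 1", {
  set.seed(51)
  n_s <- 30
  latent <- rnorm(n_s, 8, 1)
  X <- t(sapply(1:6, function(i) latent + rnorm(n_s, 0, 1e-4)))
  dimnames(X) <- list(sprintf("M%02d", 1:6), sprintf("S%02d", 1:n_s))
  panel <- marker_panel(tibble::tibble(subset = "monocyte",
    gene_id = rownames(X)))
  sel <- select_markers(make_expr(X), panel)
  rec <- attr(sel, "selection_record")
  expect_true(all(rec$kept))
  expect_true(all(rec$mean_r > 0.999))
})

test_that("a correlated marker block is kept and independent decoys dropped", {
  res <- purrr::map_dfr(1:20, function(s) {
    set.seed(500 + s)
    n_s <- 60
    f <- rnorm(n_s)
    true_m <- t(sapply(1:12, \(i) 8 + sqrt(0.8) * f + sqrt(0.2) * rnorm(n_s)))
    decoys <- matrix(rnorm(3 * n_s, 8), 3)
    X <- rbind(true_m, decoys)
    dimnames(X) <- list(c(sprintf("T%02d", 1:12), sprintf("D%02d", 1:3)),
      sprintf("S%02d", 1:n_s))
    panel <- marker_panel(tibble::tibble(subset = "monocyte",
      gene_id = rownames(X)))
    rec <- attr(select_markers(make_expr(X), panel), "selection_record")
    tibble::tibble(
      true_kept = mean(rec$kept[grepl("^T", rec$gene_id)]),
      decoy_kept = mean(rec$kept[grepl("^D", rec$gene_id)]))
  })
  expect_gte(mean(res$true_kept), 0.95)
  expect_lte(mean(res$decoy_kept), 0.05)
})

test_that("selection thresholds behave strictly and monotonically", {
  set.seed(52)
  n_s <- 20
  f <- rnorm(n_s)
  X <- t(sapply(1:5, \(i) 8 + f + rnorm(n_s, 0, 0.3)))
  dimnames(X) <- list(sprintf("M%02d", 1:5), sprintf("S%02d", 1:n_s))
  panel <- marker_panel(tibble::tibble(subset = "NK", gene_id = rownames(X)))
  em <- make_expr(X)
  # r_threshold = 1 keeps nothing (strict inequality)
  expect_identical(nrow(select_markers(em, panel, r_threshold = 1)), 0L)
  # raising the threshold never adds a gene
  kept <- purrr::map(c(0.2, 0.5, 0.8, 0.95), function(thr) {
    select_markers(em, panel, r_threshold = thr)$gene_id
  })
  for (i in seq_len(length(kept) - 1)) {
    expect_true(all(kept[[i + 1]] %in% kept[[i]]))
  }
})

test_that("constant candidates are dropped with a warning", {
  set.seed(53)
  X <- rbind(matrix(rnorm(3 * 10, 8), 3), rep(5, 10))
  dimnames(X) <- list(c("A", "B", "C", "CONST"), sprintf("S%02d", 1:10))
  panel <- marker_panel(tibble::tibble(subset = "B", gene_id = rownames(X)))
  expect_warning(sel <- select_markers(make_expr(X), panel), "CONST")
  rec <- attr(sel, "selection_record")
  expect_false(rec$kept[rec$gene_id == "CONST"])
})

test_that("composition scores are per-group means summed over panel groups", {
  n_s <- 6
  ids <- sprintf("S%02d", 1:n_s)
  X <- rbind(
    matrix(3, 2, n_s), # group g1: constant 3
    matrix(4, 2, n_s)  # group g2: constant 4
  )
  dimnames(X) <- list(c("A1", "A2", "B1", "B2"), ids)
  panel <- marker_panel(tibble::tibble(
    subset = "monocyte", gene_id = c("A1", "A2", "B1", "B2"),
    panel_group = c("g1", "g1", "g2", "g2")), stage = "selected")
  sc <- composition_scores(make_expr(X), panel)
  expect_true(all(sc$score == 7))  # 3 + 4

  # single panel group: plain mean
  panel1 <- marker_panel(tibble::tibble(subset = "monocyte",
    gene_id = c("A1", "A2")), stage = "selected")
  sc1 <- composition_scores(make_expr(X), panel1)
  expect_true(all(sc1$score == 3))
})

test_that("scores are translation-equivariant and order-invariant", {
  set.seed(54)
  X <- matrix(rnorm(8 * 10, 8), 8, dimnames = list(sprintf("M%d", 1:8),
    sprintf("S%02d", 1:10)))
  panel <- marker_panel(tibble::tibble(subset = rep(c("B", "NK"), each = 4),
    gene_id = rownames(X)), stage = "selected")
  sc <- composition_scores(make_expr(X), panel)
  # + c shifts every single-group score by c
  sc_shift <- composition_scores(make_expr(X + 1.5), panel)
  expect_equal(sc_shift$score, sc$score + 1.5)
  # permuting markers and samples changes nothing
  perm_g <- sample(nrow(X)); perm_s <- sample(ncol(X))
  panel_perm <- marker_panel(dplyr::slice(tibble::as_tibble(panel),
    sample(dplyr::n())), stage = "selected")
  sc_perm <- composition_scores(make_expr(X[perm_g, perm_s]), panel_perm)
  j <- dplyr::inner_join(tidy(sc), tidy(sc_perm), by = c("sample_id", "subset"))
  expect_equal(j$score.x, j$score.y)
})

test_that("subsets with no surviving markers give NA scores with a warning", {
  set.seed(55)
  f <- rnorm(20)
  good <- t(sapply(1:4, \(i) 8 + f + rnorm(20, 0, 0.2)))
  noise <- matrix(rnorm(4 * 20, 8), 4)
  X <- rbind(good, noise)
  dimnames(X) <- list(c(sprintf("G%d", 1:4), sprintf("N%d", 1:4)),
    sprintf("S%02d", 1:20))
  panel <- marker_panel(tibble::tibble(subset = rep(c("B", "DC"), each = 4),
    gene_id = rownames(X)))
  sel <- select_markers(make_expr(X), panel)
  expect_false("DC" %in% sel$subset)
  expect_warning(sc <- composition_scores(make_expr(X), sel), "DC")
  expect_true(all(is.na(sc$score[sc$subset == "DC"])))
  expect_true(all(!is.na(sc$score[sc$subset == "B"])))
})

test_that("scores recover the planted mixture signal on a simulated study", {
  st <- simulate_study(sim_config(seed = 56))
  sel <- select_markers(st$expression, st$candidates)
  sc <- composition_scores(st$expression, sel)
  rep <- score_recovery_report(sc, st)
  expect_identical(nrow(rep), 10L)
  expect_true(all(rep$recovery_r >= 0.9))
  # lymphoid subsets carry no suppression, so raw-weight recovery holds too
  lym <- rep$recovery_r_weight[rep$subset %in%
    c("T_total", "T_CD4", "B", "NK", "other_lymphoid")]
  expect_true(all(lym >= 0.9))
})

test_that("a noise-free study gives perfect score recovery", {
  st <- simulate_study(small_config(seed = 57, noise_sd = 0,
    family_effect_sd = 0))
  tg <- st$truth$genes
  true_panel <- marker_panel(
    tibble::tibble(subset = tg$subset[tg$role == "marker"],
      gene_id = tg$gene_id[tg$role == "marker"]), stage = "selected")
  sc <- composition_scores(st$expression, true_panel)
  rep <- score_recovery_report(sc, st)
  expect_true(all(rep$recovery_r > 1 - 1e-9))
})
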