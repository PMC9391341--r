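toy_expr <- function(signal, dose) {
  colnames(signal) <- paste0("s", seq_len(ncol(signal)))
  expression_matrix(
    signal,
    data.frame(
      sample_id = colnames(signal), dose_gy = dose,
      time_days = 1, study = "toy"
    )
  )
}

test_that("Spearman ranking matches the closed-form rank oracle", {
  # hand-ranked: signal (1,5,2,9,4) vs dose (0,1,2,3,4)
  x <- c(1, 5, 2, 9, 4)
  dose <- 0:4
  d <- rank(x) - rank(dose)
  rho_oracle <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
  em <- toy_expr(
    rbind(g_hand = x, g_mono = c(1, 2, 3, 4, 5) * 2 + 3),
    dose
  )
  res <- rank_genes_by_dose_correlation(em)
  expect_equal(res$rho[res$gene_id == "g_hand"], rho_oracle) # = 0.5
  expect_equal(res$rho[res$gene_id == "g_hand"], 0.5)
  # strictly monotone signal has rho exactly 1
  expect_equal(res$rho[res$gene_id == "g_mono"], 1)
  # small-n untied p agrees with the exact permutation null
  ref <- cor.test(x, dose, method = "spearman", exact = TRUE)
  expect_equal(res$p_value[res$gene_id == "g_hand"], ref$p.value)
})

test_that("Spearman rho is invariant under strictly increasing transforms", {
  withr::with_seed(11, {
    for (i in 1:5) {
      x <- rnorm(20)
      dose <- sample(rep(c(0, 1, 2, 4, 8), 4))
      em1 <- toy_expr(rbind(g = x), dose)
      em2 <- toy_expr(rbind(g = exp(2 * x + 1)), dose)
      r1 <- rank_genes_by_dose_correlation(em1)$rho
      r2 <- rank_genes_by_dose_correlation(em2)$rho
      expect_equal(r1, r2)
    }
  })
})

test_that("signature genes outrank background under strong dose response", {
  em <- generate_array_study(array_sim_config(
    noise_sd = 0.3, n_background_genes = 100,
    samples_per_condition = 2, seed = 7
  ))
  res <- rank_genes_by_dose_correlation(em)
  up_rho <- res$rho[grepl("^UP", res$gene_id)]
  bg_rho <- res$rho[grepl("^BG", res$gene_id)]
  expect_gt(min(up_rho), max(bg_rho))
})

test_that("constant genes are flagged and excluded from the Bonferroni family", {
  sig <- rbind(flat = rep(3, 6), g1 = c(1, 2, 3, 4, 5, 6))
  em <- toy_expr(sig, c(0, 0, 1, 1, 2, 2))
  expect_warning(res <- rank_genes_by_dose_correlation(em), "constant")
  expect_true(res$excluded[res$gene_id == "flat"])
  expect_true(is.na(res$rho[res$gene_id == "flat"]))
  # multiplier is the number of genes actually tested (1, not 2)
  expect_equal(
    res$p_bonferroni[res$gene_id == "g1"],
    min(1, res$p_value[res$gene_id == "g1"] * 1)
  )
})

test_that("Bonferroni filter keeps p*m < alpha and tolerates empty survivors", {
  cors <- tibble::tibble(
    gene_id = c("a", "b", "c"),
    rho = c(0.9, 0.5, -0.4),
    p_value = c(0.0004, 0.001, 0.2),
    p_bonferroni = pmin(1, p_value * 100),
    direction = c("up", "up", "down"),
    excluded = FALSE
  )
  kept <- bonferroni_filter(cors, alpha = 0.05)
  expect_equal(kept$gene_id, "a") # 0.04 kept, 0.1 and 1 dropped
  empty <- bonferroni_filter(dplyr::mutate(cors, p_bonferroni = 1))
  expect_equal(nrow(empty), 0)
})

test_that("false positives after Bonferroni are as rare as the level implies", {
  fp <- 0
  n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    em <- generate_array_study(array_sim_config(
      n_background_genes = 200, samples_per_condition = 1, seed = 1000 + s
    ))
    surv <- bonferroni_filter(rank_genes_by_dose_correlation(em))
    fp <- fp + sum(grepl("^BG", surv$gene_id))
  }
  # expected count <= alpha per family; 40 families => lambda <= 2
  expect_lte(fp, 9)
})

test_that("signature selection orders by rho with p then gene-ID tie-breaks", {
  cors <- tibble::tibble(
    gene_id = c("g1", "g2", "g3"),
    rho = c(0.9, -0.9, 0.1),
    p_value = c(1e-6, 1e-6, 0.2),
    p_bonferroni = pmin(1, p_value * 3),
    direction = c("up", "down", "up"),
    excluded = FALSE
  )
  sig <- select_signature(cors, n_up = 1, n_down = 1)
  expect_equal(sig$up_genes, "g1")
  expect_equal(sig$down_genes, "g2")
  expect_error(
    select_signature(cors, n_up = 3, n_down = 1),
    "insufficient.*3 up \\(have 2\\)"
  )

  # exhaustive oracle ordering under ties
  withr::with_seed(3, {
    tied <- tibble::tibble(
      gene_id = sprintf("t%02d", 1:8),
      rho = rep(c(0.8, 0.6), each = 4),
      p_value = rep(c(0.01, 0.02), 4),
      p_bonferroni = p_value,
      direction = "up",
      excluded = FALSE
    )
    tied <- tied[sample.int(8), ]
  })
  oracle <- tied$gene_id[order(-tied$rho, tied$p_value, tied$gene_id)]
  expect_error(select_signature(tied, n_up = 5, n_down = 1), "insufficient")
  neg <- dplyr::mutate(tied, rho = -rho)
  sig3 <- select_signature(
    dplyr::bind_rows(tied, neg |>
      dplyr::mutate(gene_id = paste0("n", gene_id))),
    n_up = 5, n_down = 5
  )
  expect_equal(sig3$up_genes, oracle[1:5])
  expect_equal(sig3$down_genes, paste0("n", oracle[1:5]))
})

test_that("pairwise correlation matrix is symmetric with unit diagonal", {
  withr::with_seed(8, {
    base <- rnorm(12)
    sig <- rbind(
      a = base, b = base, c = -base, d = rnorm(12)
    )
  })
  em <- toy_expr(sig, rep(c(0, 1, 2, 4), 3))
  m <- pairwise_correlation_matrix(em, c("a", "b", "c", "d"))
  expect_equal(m, t(m))
  expect_equal(unname(diag(m)), rep(1, 4))
  expect_true(all(m >= -1 & m <= 1))
  expect_equal(m["a", "b"], 1) # identical profiles
  expect_equal(m["a", "c"], -1) # negated profile
  # per-pair brute force (Pearson option)
  mp <- pairwise_correlation_matrix(em, rownames(sig), method = "pearson")
  for (i in rownames(sig)) {
    for (j in rownames(sig)) {
      expect_equal(mp[i, j], cor(sig[i, ], sig[j, ]))
    }
  }
  # constant gene flagged
  em2 <- toy_expr(rbind(a = base, flat = rep(1, 12)), rep(c(0, 1, 2, 4), 3))
  expect_warning(m2 <- pairwise_correlation_matrix(em2, c("a", "flat")),
    "constant"
  )
  expect_identical(attr(m2, "constant_genes"), "flat")
  expect_true(is.na(m2["a", "flat"]))
})
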