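test_that("log2 transform applies the pseudocount elementwise", {
  m <- matrix(c(0, 7, 1023, 3), 2, 2)
  lt <- log2_transform(m)
  expect_equal(lt[1, 1], 0)
  expect_equal(lt[2, 1], 3)
  expect_equal(lt[1, 2], 10)
  expect_equal(attr(lt, "pseudocount"), 1)
  expect_error(log2_transform(matrix(-1)), "negative")
})

test_that("water content follows the FW/DW formula and is scale invariant", {
  expect_equal(water_content(2.0, 0.5), 75.0)
  expect_equal(water_content(1.3, 1.3), 0.0)
  expect_equal(water_content(2.5, 0), 100.0)
  expect_error(water_content(1.0, 1.5), "DW")
  expect_error(water_content(0, 0), "positive")
  set.seed(71)
  fw <- runif(20, 1, 3); dw <- fw * runif(20)
  expect_equal(water_content(fw, dw), water_content(5.7 * fw, 5.7 * dw))
})

test_that("2^-ddCt fold changes recover planted values", {
  mk_ct <- function(shift_1h) {
    rows <- expand.grid(condition = c("0h", "1h"), replicate = 1:3)
    rbind(
      data.frame(gene = "ref", rows, ct = 20),
      data.frame(gene = "tgt", rows,
                 ct = 25 + ifelse(rows$condition == "1h", shift_1h, 0))
    )
  }
  flat <- ddct_fold_change(mk_ct(0), "ref", "0h")
  expect_equal(flat$fold[flat$condition == "1h"], 1)
  up <- ddct_fold_change(mk_ct(-1), "ref", "0h")
  expect_equal(up$fold[up$condition == "1h"], 2)

  # invariance: adding a constant to every Ct of a sample cancels out
  ct <- mk_ct(-1)
  shifted <- ct
  bump <- ifelse(paste(shifted$condition, shifted$replicate) == "1h 2", 3, 0)
  shifted$ct <- shifted$ct + bump
  expect_equal(ddct_fold_change(shifted, "ref", "0h")$fold,
               ddct_fold_change(ct, "ref", "0h")$fold)

  expect_error(ddct_fold_change(mk_ct(0), "nope", "0h"), "not found")

  # generator-planted fold of 0.25 at 24 h
  folds <- list(G1 = c("0" = 1, "1" = 1, "6" = 1, "12" = 1, "24" = 0.25))
  sim <- simulate_expression(expr_sim_spec(seed = 72, qpcr_genes = "G1",
                                           qpcr_folds = folds))
  fc <- ddct_fold_change(sim$ct, "actin", 0)
  expect_equal(fc$fold[fc$condition == 24], 0.25, tolerance = 0.15)
})

test_that("regression reports r, slope and a sound t-test", {
  x <- 1:10
  perfect <- expression_water_regression(x, 3 + 2 * x)
  expect_equal(perfect$pearson_r, 1)
  expect_equal(perfect$slope, 2)
  expect_lt(perfect$p_value, 1e-12)
  expect_true(perfect$significant)

  flat <- expression_water_regression(1:10, rep(80, 10))
  expect_false(flat$defined)
  expect_false(flat$significant)
  expect_error(expression_water_regression(1:2, 1:2), "at least 3")

  # planted r is recovered on average across seeds
  rs <- sapply(1:100, function(i) {
    set.seed(i)
    w <- rnorm(12, 80, 5)
    e <- 10 + 1.2 * w + rnorm(12, 0, 1.2 * 5 * sqrt(1 / 0.9^2 - 1))
    expression_water_regression(e, w)$pearson_r
  })
  expect_equal(mean(rs), 0.9, tolerance = 0.05)
})

test_that("one-way ANOVA with Tukey letters matches hand-computed F", {
  res <- anova_tukey(list(a = c(1, 2, 3), b = c(2, 3, 4), c = c(3, 4, 5)))
  expect_equal(res$F, 3.0)
  expect_equal(res$p, pf(3, 2, 6, lower.tail = FALSE))
  # no pair clears Tukey at this weak separation: one shared letter
  expect_true(all(res$letters == res$letters[1]))

  same <- anova_tukey(list(a = c(5, 6, 7), b = c(5, 6, 7)))
  expect_lt(same$F, 1e-10)
  expect_true(all(same$tukey$p_adj > 0.05))

  far <- anova_tukey(list(lo = c(1, 1.1, 0.9), hi = c(9, 9.1, 8.9),
                          mid = c(5, 5.1, 4.9)))
  expect_true(all(far$tukey$p_adj < 0.05))
  expect_equal(length(unique(far$letters)), 3L)

  expect_error(anova_tukey(list(a = c(1, 1), b = c(2, 2))), "variance")
})

test_that("candidate selection returns exactly the planted genes", {
  sim <- simulate_expression(expr_sim_spec(seed = 73, n_genes = 40,
                                           n_correlated = 3))
  outer <- sim$samples$sample_id[sim$samples$tissue == "O"]
  outer_late <- sim$samples$sample_id[
    sim$samples$tissue == "O" & sim$samples$stage >= 95]
  wc <- setNames(sim$water$percent, sim$water$sample_id)
  cors <- lapply(rownames(sim$fpkm), function(g) {
    expression_water_regression(sim$fpkm[g, outer], wc[outer])
  })
  names(cors) <- rownames(sim$fpkm)
  sel <- candidate_selection(cors, sim$fpkm, outer_late, fpkm_min = 5)
  expect_setequal(sel$gene_id, sim$truth$correlated_genes)
  expect_equal(sel$gene_id, sel$gene_id[order(-sel$pearson_r)])

  # an impossible expression threshold empties the list
  none <- candidate_selection(cors, sim$fpkm, outer_late, fpkm_min = 1e6)
  expect_equal(nrow(none), 0L)

  # with no significant genes the list is empty
  null_cors <- lapply(cors, function(x) {
    x$significant <- FALSE
    x
  })
  expect_equal(nrow(candidate_selection(null_cors, sim$fpkm, outer_late)),
               0L)
})
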