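test_that("linear schedules step symmetrically and truncate at overlap", {
  s1 <- linear_threshold_schedule(1, 0, 0.0225, 20)
  expect_equal(nrow(s1), 20L)
  expect_equal(unname(s1[20, ]), c(1 - 19 * 0.0225, 19 * 0.0225))
  s2 <- linear_threshold_schedule(0.9, 0.1, 0.0175, 20)
  expect_equal(unname(s2[20, ]), c(0.5675, 0.4325))
  s3 <- linear_threshold_schedule(0.6, 0.4, 0.2, 5)
  expect_equal(nrow(s3), 1L)
  expect_true(attr(s3, "truncated"))
  expect_error(linear_threshold_schedule(0.3, 0.5, 0.1, 3), "beta0 < alpha0")
})

test_that("the twelve-patient sequential run reproduces its level grid", {
  fit <- seq_dtrs(covid$levels, universe = covid$universe,
                  concept = covid$concept)
  expect_equal(fit$levels[[1]]$membership[["c1"]], 5 / 12)
  expect_equal(level_counts(fit), covid$expected$counts)
  for (i in 1:3) {
    expect_setequal(fit$levels[[i]]$pos, covid$expected$pos_by_level[[i]])
    expect_setequal(fit$levels[[i]]$neg, covid$expected$neg_by_level[[i]])
  }
  acc <- accumulate_regions(fit)
  expect_equal(acc$accumulated_pos, covid$expected$accumulated_pos)
  expect_equal(acc$accumulated_neg, covid$expected$accumulated_neg)
  expect_equal(acc$terminal_bnd, character(0))
  expect_equal(fit$stop_reason, "bnd_empty")
})

test_that("singleton granulation classifies everything in one level", {
  set.seed(21)
  tab <- random_table(8, 3)   # continuous: rows distinct, all blocks singleton
  fit <- seq_dtrs(list(list(attrs = tab$condition_attrs,
                            alpha = 0.7, beta = 0.3)), x = tab)
  expect_true(all(fit$levels[[1]]$membership %in% c(0, 1)))
  expect_length(fit$terminal_bnd, 0L)
})

test_that("sequential traces match a straight-line per-level oracle", {
  set.seed(23)
  for (rep in 1:10) {
    tab <- random_table(10, 2, discrete = TRUE)
    levels <- list(list(attrs = c("a1", "a2"), alpha = 0.8, beta = 0.2),
                   list(attrs = c("a1", "a2"), alpha = 0.6, beta = 0.4))
    fit <- seq_dtrs(levels, x = tab)
    Ui <- tab$object_ids
    Xi <- tab$concept
    for (i in seq_along(fit$levels)) {
      blocks <- equivalence_partition(tab, levels[[i]]$attrs)$blocks
      ref <- oracle_seq_level(blocks, Ui, Xi, levels[[i]]$alpha,
                              levels[[i]]$beta)
      expect_setequal(fit$levels[[i]]$pos, ref$pos)
      expect_setequal(fit$levels[[i]]$bnd, ref$bnd)
      expect_setequal(fit$levels[[i]]$neg, ref$neg)
      Ui <- ref$bnd
      Xi <- intersect(Xi, Ui)
    }
  }
})

test_that("the five-object generalized run reproduces every printed step", {
  fit <- gseq_dtrs(fiveobj$table, xi = fiveobj$xi,
                   thresholds = fiveobj$thresholds)
  expect_length(fit$levels, 3L)
  expect_equal(fit$levels[[1]]$membership,
               fiveobj$expected$level1_membership)
  for (i in 1:3) {
    expect_setequal(fit$levels[[i]]$pos, fiveobj$expected$pos_by_level[[i]])
    expect_setequal(fit$levels[[i]]$bnd, fiveobj$expected$bnd_by_level[[i]])
    expect_setequal(fit$levels[[i]]$neg, fiveobj$expected$neg_by_level[[i]])
  }
  # the level-2 concept is X1 restricted to the level-1 boundary
  expect_setequal(fit$levels[[2]]$concept, c("c1", "c3"))
  expect_equal(level_counts(fit), fiveobj$expected$counts)
  expect_equal(fit$stop_reason, "bnd_empty")
})

test_that("a full-universe concept empties in one all-POS level", {
  tab <- fiveobj$table
  fit <- gseq_dtrs(tab, xi = 0.6, thresholds = rbind(c(0.8, 0.2)),
                   concept = tab$object_ids)
  expect_length(fit$levels, 1L)
  expect_setequal(fit$levels[[1]]$pos, tab$object_ids)
})

test_that("generalized traces satisfy the sequential invariants", {
  set.seed(31)
  for (rep in 1:8) {
    tab <- random_table(12, 3)
    fit <- gseq_dtrs(tab, xi = runif(1, 0.4, 0.9),
                     alpha0 = 0.9, beta0 = 0.1, step = 0.05, max_levels = 8)
    sizes <- vapply(fit$levels, function(l) length(l$universe), integer(1))
    expect_true(all(diff(sizes) <= 0))
    prev_U <- tab$object_ids
    prev_X <- tab$concept
    for (l in fit$levels) {
      expect_length(c(l$pos, l$bnd, l$neg), length(l$universe))
      expect_true(all(l$universe %in% prev_U))
      expect_true(all(l$concept %in% prev_X))
      expect_true(all(l$concept %in% l$universe))
      prev_U <- l$bnd
      prev_X <- intersect(l$concept, l$bnd)
    }
    acc <- accumulate_regions(fit)
    expect_setequal(unlist(acc), tab$object_ids)
    expect_length(intersect(acc$accumulated_pos, acc$accumulated_neg), 0L)
  }
})

test_that("xi = 1 on discrete tables reduces to the classical engine", {
  set.seed(37)
  thrs <- rbind(c(alpha = 0.7, beta = 0.3), c(alpha = 0.55, beta = 0.45))
  for (rep in 1:5) {
    tab <- random_table(12, 2, discrete = TRUE)
    g <- suppressWarnings(gseq_dtrs(tab, xi = 1, thresholds = thrs))
    s <- seq_dtrs(list(list(attrs = tab$condition_attrs, alpha = 0.7,
                            beta = 0.3),
                       list(attrs = tab$condition_attrs, alpha = 0.55,
                            beta = 0.45)), x = tab)
    expect_equal(length(g$levels), length(s$levels))
    for (i in seq_along(g$levels)) {
      expect_equal(g$levels[[i]]$membership, s$levels[[i]]$membership)
      expect_setequal(g$levels[[i]]$pos, s$levels[[i]]$pos)
      expect_setequal(g$levels[[i]]$bnd, s$levels[[i]]$bnd)
      expect_setequal(g$levels[[i]]$neg, s$levels[[i]]$neg)
    }
  }
})

test_that("force-assign resolves a terminal boundary by majority membership", {
  tab <- fiveobj$table
  # one tight level leaves a boundary; force-assign must empty it
  fit <- gseq_dtrs(tab, xi = 0.59, thresholds = rbind(c(0.95, 0.05)),
                   force_assign = TRUE)
  expect_length(fit$terminal_bnd, 0L)
  expect_setequal(c(fit$accumulated_pos, fit$accumulated_neg),
                  tab$object_ids)
  # memberships at level 1: >= 0.5 everywhere, so all forced to POS
  expect_setequal(fit$accumulated_pos, tab$object_ids)
})

test_that("trace export carries one row per object and level", {
  fit <- gseq_dtrs(fiveobj$table, xi = fiveobj$xi,
                   thresholds = fiveobj$thresholds)
  df <- as.data.frame(fit)
  expect_equal(nrow(df), 5 + 4 + 2)
  expect_true(all(df$region %in% c("POS", "BND", "NEG")))
  s <- summary(fit)
  expect_equal(s$table$cum_pos, c(1, 2, 3))
})
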