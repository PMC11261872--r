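test_that("equivalence partition groups identical rows deterministically", {
  expect_length(equivalence_partition(fiveobj$table, c("a", "b", "c"))$blocks,
                5L)
  tab <- information_table(matrix(c(1, 1, 2, 5, 9, 5), 3,
                                  dimnames = list(NULL, c("a", "b"))),
                           decision = c(TRUE, FALSE, TRUE))
  part <- equivalence_partition(tab, "a")
  expect_equal(part$blocks, list(c("o1", "o2"), "o3"))
  expect_error(equivalence_partition(tab, character(0)), "nonempty")

  # refinement: adding attributes only splits blocks
  set.seed(41)
  for (i in 1:20) {
    t2 <- random_table(8, 3, discrete = TRUE)
    coarse <- equivalence_partition(t2, "a1")$block_of
    fine <- equivalence_partition(t2, c("a1", "a2"))$block_of
    same_fine <- outer(fine, fine, "==")
    same_coarse <- outer(coarse, coarse, "==")
    expect_true(all(same_coarse[same_fine]))
  }
})

test_that("pairwise similarity is a ratio of sums with the worked values", {
  norm <- max_normalize(fiveobj$table)$values
  expect_equal(pairwise_similarity(norm["c1", ], norm["c2", ]), 0.59922179,
               tolerance = 1e-8)
  expect_equal(pairwise_similarity(norm["c3", ], norm["c5", ]), 0.90909091,
               tolerance = 1e-8)
  expect_equal(pairwise_similarity(c(0.3, 0.7), c(0.3, 0.7)), 1)
  expect_equal(pairwise_similarity(numeric(2), numeric(2)), 1)
  expect_error(pairwise_similarity(1, c(1, 2)), "length")
  expect_error(pairwise_similarity(-1, 1), "nonnegative")
})

test_that("similarity matrix is symmetric with unit diagonal", {
  sim <- similarity_matrix(max_normalize(fiveobj$table))
  expect_equal(unclass(sim), t(unclass(sim)))
  expect_equal(unname(diag(sim)), rep(1, 5))

  one <- similarity_matrix(information_table(matrix(2, 1, 1), TRUE))
  expect_equal(dim(one), c(1L, 1L))
  expect_equal(one[1, 1], 1)

  set.seed(7)
  t2 <- random_table(6, 4)
  s2 <- similarity_matrix(max_normalize(t2))
  for (i in 1:5) for (j in (i + 1):6)
    expect_equal(s2[i, j], pairwise_similarity(max_normalize(t2)$values[j, ],
                                               max_normalize(t2)$values[i, ]))
})

test_that("xi-thresholded classes match the worked granulations", {
  sim <- similarity_matrix(max_normalize(fiveobj$table))
  cov59 <- similarity_classes(sim, 0.59)
  expect_equal(cov59$class_of, fiveobj$expected$level1_classes)
  cov70 <- similarity_classes(sim, 0.7)
  expect_equal(cov70$class_of, fiveobj$expected$level3_classes)
  tiny <- similarity_classes(sim, 1e-9)
  expect_true(all(vapply(tiny$class_of, setequal, logical(1),
                         paste0("c", 1:5))))
  expect_error(similarity_classes(sim, 0), "0, 1")
  expect_error(similarity_classes(sim, 1.2), "0, 1")
})

test_that("coverings cover, shrink monotonically in xi, and are symmetric", {
  set.seed(11)
  for (i in 1:10) {
    tab <- random_table(8, 3)
    sim <- similarity_matrix(max_normalize(tab))
    xs <- sort(runif(2, 0.1, 0.9))
    lo <- similarity_classes(sim, xs[1])
    hi <- similarity_classes(sim, xs[2])
    expect_setequal(unique(unlist(lo$class_of)), tab$object_ids)
    for (c in tab$object_ids) {
      expect_true(all(hi$class_of[[c]] %in% lo$class_of[[c]]))
      expect_true(c %in% lo$class_of[[c]])
      # membership symmetry: owners of classes containing c = c's class
      expect_setequal(lo$member_index[[c]], lo$class_of[[c]])
    }
  }
})

test_that("xi = 1 recovers the equivalence partition on all attributes", {
  set.seed(13)
  for (i in 1:10) {
    tab <- random_table(10, 2, discrete = TRUE)
    sim <- suppressWarnings(similarity_matrix(max_normalize(tab)))
    cov <- similarity_classes(sim, 1)
    part <- equivalence_partition(tab, tab$condition_attrs)
    for (c in tab$object_ids)
      expect_setequal(cov$class_of[[c]], part$blocks[[part$block_of[[c]]]])
  }
})
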