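test_that("attribution scores sum to one over aspects", {
  Y <- rand_bm(30, 10, p = 0.4, seed = 1)
  fit <- fit_ab(Y, K = 3, n_iter = 100, n_restarts = 2, seed = 6)
  r <- attribution_scores(fit)
  expect_equal(dim(r), c(10L, 3L))
  expect_true(all(abs(rowSums(r) - 1) < 1e-8))
  expect_true(all(r >= 0 & r <= 1))
})

test_that("attribution closed forms: K = 1 and the symmetric two-genome toy", {
  f1 <- toy_fit(matrix(1, 4, 1), matrix(c(0.2, 0.6, 0.9), 1, 3))
  expect_true(all(attribution_scores(f1) == 1))

  # gamma rows (1,0) and (0,1), beta identical 0.5: each aspect explains
  # exactly one genome fully, so r = 0.5 for both
  f2 <- toy_fit(rbind(c(1, 0), c(0, 1)), matrix(0.5, 2, 2))
  r <- attribution_scores(f2)
  expect_equal(unname(r), matrix(0.5, 2, 2), tolerance = 1e-9)
})

test_that("attribution is invariant to genome order", {
  Y <- rand_bm(20, 8, seed = 3)
  fit <- fit_ab(Y, K = 2, n_iter = 100, n_restarts = 1, seed = 2)
  perm <- sample(nrow(Y))
  fitp <- fit
  fitp$gamma <- fit$gamma[perm, ]
  fitp$Y <- suppressWarnings(binary_matrix(unclass(Y)[perm, ]))
  expect_equal(attribution_scores(fitp), attribution_scores(fit),
               tolerance = 1e-12)
})

test_that("probabilistic representatives apply the argmax + 2/K rule", {
  # K = 2: threshold is 1, so even gamma = 0.9 is excluded
  f <- toy_fit(rbind(c(0.9, 0.1)), matrix(0.5, 2, 3))
  reps <- probabilistic_representatives(f)
  expect_length(unlist(reps), 0L)

  # K = 10 with max weight 0.25 at aspect 3: 0.25 > 0.2, so included there
  g <- rep(0.75 / 9, 10); g[3] <- 0.25
  f10 <- toy_fit(matrix(g, 1, 10), matrix(0.5, 10, 12))
  reps10 <- probabilistic_representatives(f10)
  expect_identical(reps10[[3]], "g1")
  expect_length(unlist(reps10[-3]), 0L)

  # uniform weights qualify nowhere
  fu <- toy_fit(matrix(1 / 4, 2, 4), matrix(0.5, 4, 5))
  expect_length(unlist(probabilistic_representatives(fu)), 0L)

  # sets are disjoint on a real fit
  Y <- rand_bm(50, 12, seed = 8)
  fit <- fit_ab(Y, K = 4, n_iter = 150, n_restarts = 2, seed = 4)
  reps <- probabilistic_representatives(fit)
  all_g <- unlist(reps)
  expect_identical(anyDuplicated(all_g), 0L)
})

test_that("abundance adjustment matches hand counts and handles degeneracy", {
  # two genomes both carry function A, neither carries B
  Y <- suppressWarnings(binary_matrix(
    rbind(c(1, 0), c(1, 0)), c("g1", "g2"), c("A", "B")))
  q <- abundance_adjustment(list(aspect1 = c("g1", "g2")), Y)
  expect_equal(unname(q[, 1]), c(2, 0))

  # uniform carriage: q = 1 everywhere, column mean 1
  Yu <- binary_matrix(matrix(1L, 3, 4))
  qu <- abundance_adjustment(list(a = rownames(Yu)), Yu)
  expect_true(all(qu == 1))

  # empty and all-zero representative sets give zero columns with warnings
  expect_warning(q0 <- abundance_adjustment(list(a = character(0)), Yu),
                 "no probabilistic representatives")
  expect_true(all(q0 == 0))
  Yz <- suppressWarnings(binary_matrix(rbind(c(0, 0), c(1, 1))))
  expect_warning(qz <- abundance_adjustment(list(a = "g1"), Yz),
                 "carry no functions")
  expect_true(all(qz == 0))
})

test_that("guild scores multiply r and q and rank deterministically", {
  r <- matrix(c(0.5, 0.2, 0.2), 3, 1,
              dimnames = list(c("fB", "fA", "fC"), "aspect1"))
  q <- matrix(c(2, 1, 1), 3, 1, dimnames = dimnames(r))
  gs <- guild_scores(r, q)
  expect_equal(gs$s["fB", 1], 1.0)
  # tie between fA and fC broken by ascending function ID
  expect_identical(gs$ranked_functions[[1]], c("fB", "fA", "fC"))
  # q = 1 leaves the r-ranking unchanged
  gs2 <- guild_scores(r, matrix(1, 3, 1, dimnames = dimnames(r)))
  expect_identical(gs2$ranked_functions[[1]],
                   rownames(r)[order(-r[, 1], rownames(r))])
  expect_error(guild_scores(r, q[1:2, , drop = FALSE]), "dimensions")
})

test_that("planted block structure tops each aspect's ranking", {
  # 4 blocks of 20 genomes x 5 functions at K = 4 (the 2/K = 0.5 threshold
  # keeps each block's genomes as representatives of their aspect)
  Y <- block_bm(80, 20, n_blocks = 4)
  fit <- fit_ab(Y, K = 4, n_iter = 300, n_restarts = 8, seed = 15)
  sc <- ab_scores(fit)
  blocks <- lapply(1:4, function(b) colnames(Y)[(b - 1) * 5 + 1:5])
  tops <- lapply(sc$ranked_functions, head, 5)
  # every aspect's top-5 is exactly one block, and all blocks are covered
  matched <- vapply(tops, function(tp)
    which(vapply(blocks, setequal, TRUE, y = tp))[1], 1L)
  expect_false(anyNA(matched))
  expect_setequal(matched, 1:4)
  # all guild functions outrank all non-guild functions in their aspect
  for (k in 1:4) {
    s_k <- sc$s[, k]
    guild_fns <- blocks[[matched[k]]]
    expect_gt(min(s_k[guild_fns]), max(s_k[setdiff(colnames(Y), guild_fns)]))
  }
})

test_that("score ranking is invariant to genome order", {
  Y <- rand_bm(40, 10, seed = 22)
  fit <- fit_ab(Y, K = 3, n_iter = 200, n_restarts = 2, seed = 5)
  sc <- suppressWarnings(ab_scores(fit))
  perm <- sample(nrow(Y))
  fitp <- fit
  fitp$gamma <- fit$gamma[perm, ]
  fitp$Y <- suppressWarnings(binary_matrix(unclass(Y)[perm, ]))
  scp <- suppressWarnings(ab_scores(fitp))
  expect_identical(scp$ranked_functions, sc$ranked_functions)
})

test_that("score tables serialize with documented columns", {
  Y <- rand_bm(30, 8, seed = 9)
  fit <- fit_ab(Y, K = 2, n_iter = 100, n_restarts = 1, seed = 3)
  sc <- suppressWarnings(ab_scores(fit))
  dir <- withr::local_tempdir()
  write_ab_scores(sc, dir)
  tab <- read.table(file.path(dir, "scores.tsv"), header = TRUE, sep = "\t")
  expect_identical(colnames(tab),
                   c("aspect", "rank", "function_id", "r", "q", "s"))
  expect_equal(nrow(tab), 8L * 2L)
  expect_equal(tab$s, tab$r * tab$q, tolerance = 1e-12)
})
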