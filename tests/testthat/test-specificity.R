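test_that("confidence matches hand counts and is directional", {
  # A in genomes 1-3, B in genomes 1-2 (4 genomes total)
  Y <- suppressWarnings(binary_matrix(
    rbind(c(1, 1), c(1, 1), c(1, 0), c(0, 0)),
    function_ids = c("A", "B")))
  expect_equal(confidence(Y, "A", "B"), 2 / 3)
  expect_equal(confidence(Y, "B", "A"), 1)
  # identity: A -> A is 1 whenever A has support
  expect_equal(confidence(Y, "A", "A"), 1)
  # zero-support antecedent is missing, never 0 or 1
  Yz <- suppressWarnings(binary_matrix(rbind(c(0, 1), c(0, 1)),
                                       function_ids = c("A", "B")))
  expect_true(is.na(confidence(Yz, "A", "B")))
  expect_error(confidence(Y, "A", "nope"), "nope")
  # genome-subset restriction
  expect_equal(confidence(Y, "A", "B", genomes = c("g1", "g2")), 1)
  expect_error(confidence(Y, "A", "B", genomes = "gX"), "gX")
})

test_that("confidence within mapback genomes is exactly 1 (property)", {
  for (i in 1:30) {
    Y <- rand_bm(sample(15:40, 1), sample(5, 1) + 5, p = 0.6,
                 seed = 500 + i)
    # guild built from a genome's own functions: nonempty mapback
    g <- which(rowSums(Y) >= 2)[1]
    if (is.na(g)) next
    fns <- sample(colnames(Y)[unclass(Y)[g, ] == 1], 2)
    mb <- mapback_genomes(Y, fns)
    expect_gte(length(mb), 1L)
    for (a in fns) for (b in fns)
      expect_identical(confidence(Y, a, b, genomes = mb), 1)
  }
})

test_that("guild reports: mapback all 1, summaries ordered and bounded", {
  Y <- rand_bm(60, 10, p = 0.5, seed = 77)
  g1 <- which(rowSums(Y) >= 3)[1]
  fns <- head(colnames(Y)[unclass(Y)[g1, ] == 1], 3)
  guild <- guildAB:::new_ab_guild(1L, fns, mapback_genomes(Y, fns),
                                  "fixed_size")
  rep <- guild_confidence_report(Y, guild)
  off <- rep$mapback[row(rep$mapback) != col(rep$mapback)]
  expect_true(all(off == 1))
  expect_true(all(diag(rep$mapback) == 1))
  expect_gte(rep$avg_outgroup, rep$min_outgroup)
  expect_true(rep$min_outgroup >= 0 && rep$avg_outgroup <= 1)
})

test_that("outgroup confidence recovers a planted co-occurrence rate", {
  # 40 mapback genomes carry A and B; in the 500 outgroup genomes with A,
  # B co-occurs with probability 0.10
  set.seed(99)
  n_out <- 500
  outA <- rep(1L, n_out)
  outB <- rbinom(n_out, 1L, 0.10)
  vals <- rbind(cbind(A = rep(1L, 40), B = rep(1L, 40)),
                cbind(A = outA, B = outB))
  Y <- suppressWarnings(binary_matrix(vals))
  guild <- guildAB:::new_ab_guild(1L, c("A", "B"), rownames(Y)[1:40],
                                  "fixed_size")
  rep <- guild_confidence_report(Y, guild)
  expect_equal(rep$outgroup["A", "B"], 0.10, tolerance = 0.03 / 0.10)
  expect_true(all(rep$mapback == 1))
})

test_that("guild functions absent from the outgroup give missing summaries", {
  # planted perfect guild: functions occur ONLY in mapback genomes
  base <- generate_base_matrix(100, 10, density = 0.3, seed = 3)
  sim <- insert_artificial_guilds(base, guild_spec(3, 0.1), seed = 4)
  fns <- sim$truth[[1]]$functions
  guild <- guildAB:::new_ab_guild(1L, fns,
                                  mapback_genomes(sim$matrix, fns),
                                  "fixed_size")
  rep <- guild_confidence_report(sim$matrix, guild)
  expect_true(all(is.na(rep$outgroup)))
  expect_true(is.na(rep$min_outgroup))
  expect_equal(rep$n_skipped, length(fns) * (length(fns) - 1L))
})

test_that("empty mapback sets warn and report missing mapback confidences", {
  Y <- suppressWarnings(binary_matrix(rbind(c(1, 0), c(0, 1)),
                                      function_ids = c("A", "B")))
  guild <- guildAB:::new_ab_guild(1L, c("A", "B"),
                                  mapback_genomes(Y, c("A", "B")),
                                  "fixed_size")
  expect_warning(rep <- guild_confidence_report(Y, guild), "no mapback")
  expect_true(all(is.na(rep$mapback)))
})

test_that("confidence tables serialize with support counts", {
  Y <- rand_bm(30, 6, p = 0.6, seed = 8)
  fns <- colnames(Y)[1:2]
  guild <- guildAB:::new_ab_guild(1L, fns, mapback_genomes(Y, fns),
                                  "fixed_size")
  rep <- guild_confidence_report(Y, guild)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ab_confidence(list(rep), Y, path)
  tab <- read.table(path, header = TRUE, sep = "\t")
  expect_identical(colnames(tab),
                   c("aspect", "approach", "antecedent", "consequent",
                     "scope", "confidence", "n_antecedent", "n_both"))
  expect_setequal(unique(tab$scope), c("mapback", "outgroup", "all"))
  mb <- tab[tab$scope == "mapback", ]
  expect_true(all(mb$confidence == 1))
})
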