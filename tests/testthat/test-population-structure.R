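rand_gm <- function(n, m, seed) {
  set.seed(seed)
  cells <- lapply(seq_len(m), function(j) {
    sample(c("A", "C", "G", "ref"), n, replace = TRUE)
  })
  names(cells) <- sprintf("G_%d", seq_len(m))
  tibble::as_tibble(c(list(sample_id = sprintf("s%02d", 1:n),
                           class = rep(c("drug", "fiber"), length.out = n)),
                      cells))
}

test_that("Gower distance is the mismatch fraction over compared loci", {
  gm <- tibble::tibble(sample_id = c("a", "b", "c"),
                       class = c("drug", "drug", "fiber"),
                       G_1 = c("A", "A", "C"), G_2 = c("C", "C", "G"),
                       G_3 = c("G", "T", "T"), G_4 = c("T", "A", "A"))
  d <- gower_distance(gm)
  expect_equal(d["a", "a"], 0)
  expect_equal(d["a", "c"], 1)           # differ everywhere
  expect_equal(d["a", "b"], 0.5)         # 2 of 4 loci differ
  expect_equal(d, t(d))
})

test_that("missing loci leave the pair denominator and empty overlap errors", {
  gm <- tibble::tibble(sample_id = c("a", "b"), class = c("drug", "fiber"),
                       G_1 = c("A", NA), G_2 = c("C", "G"))
  d <- gower_distance(gm)
  expect_equal(d["a", "b"], 1)  # only G_2 compared, and it differs

  gm2 <- tibble::tibble(sample_id = c("a", "b"), class = c("drug", "fiber"),
                        G_1 = c("A", NA), G_2 = c(NA, "G"))
  expect_error(gower_distance(gm2), "no comparable loci")
})

test_that("Gower distances satisfy the metric axioms", {
  for (seed in 1:5) {
    gm <- rand_gm(n = 8, m = 6, seed = seed)
    d <- gower_distance(gm)
    expect_true(all(diag(d) == 0))
    expect_equal(d, t(d))
    expect_true(all(d >= 0 & d <= 1))
    n <- nrow(d)
    for (i in 1:n) for (j in 1:n) for (k in 1:n) {
      expect_lte(d[i, j], d[i, k] + d[k, j] + 1e-12)
    }
  }
})

test_that("identical samples share MDS coordinates", {
  gm <- tibble::tibble(sample_id = c("a", "b", "c"),
                       class = c("drug", "drug", "fiber"),
                       G_1 = c("A", "A", "C"), G_2 = c("T", "T", "G"))
  coords <- classical_mds(gower_distance(gm))
  expect_lt(max(abs(unlist(coords[1, -1]) - unlist(coords[2, -1]))), 1e-6)
})

test_that("three equidistant samples embed as an equilateral triangle", {
  d <- matrix(0.6, 3, 3) - diag(0.6, 3)
  dimnames(d) <- list(letters[1:3], letters[1:3])
  coords <- classical_mds(d)
  pts <- as.matrix(coords[, c("MDS1", "MDS2")])
  emb <- as.matrix(dist(pts))
  expect_equal(emb[lower.tri(emb)], rep(0.6, 3), tolerance = 1e-10)
})

test_that("MDS reconstructs Euclidean-embeddable distances", {
  set.seed(12)
  pts <- matrix(rnorm(20), ncol = 2)
  d <- as.matrix(dist(pts))
  dimnames(d) <- list(sprintf("s%d", 1:10), sprintf("s%d", 1:10))
  coords <- classical_mds(d, dims = 2)
  emb <- as.matrix(dist(as.matrix(coords[, c("MDS1", "MDS2")])))
  expect_equal(unname(emb), unname(d), tolerance = 1e-8)
  # deterministic sign convention: largest-magnitude loading positive
  for (j in c("MDS1", "MDS2")) {
    v <- coords[[j]]
    expect_gte(v[which.max(abs(v))], 0)
  }
})

test_that("entropy summaries match direct Shannon arithmetic", {
  mono <- tibble::tibble(sample_id = c("a", "b"), class = c("drug", "fiber"),
                         G_1 = c("A", "A"), G_2 = c("C", "C"))
  e <- entropy_summary(mono, groups = c("g1", "g2"))
  expect_equal(e$overall, 0)
  expect_equal(unname(e$within), c(0, 0))
  expect_equal(e$between, 0)

  half <- tibble::tibble(sample_id = sprintf("s%d", 1:4),
                         class = rep(c("drug", "fiber"), 2),
                         G_1 = c("A", "A", "T", "T"))
  e2 <- entropy_summary(half, groups = rep("g", 4))
  expect_equal(e2$overall, log(2))
  # base-2 option
  e2b <- entropy_summary(half, groups = rep("g", 4), base = 2)
  expect_equal(e2b$overall, 1)

  # two groups with identical consensus alleles -> between-group 0
  e3 <- entropy_summary(half, groups = c("g1", "g1", "g2", "g2"))
  expect_equal(unname(e3$within), c(0, 0))
  expect_equal(e3$between, log(2))  # consensus A vs T differ

  expect_error(entropy_summary(half, groups = c("g1", "g1")), "one entry")
})

test_that("entropy is bounded by log of the allele count", {
  gm <- rand_gm(10, 5, seed = 3)
  e <- entropy_summary(gm, groups = gm$class)
  max_alleles <- max(vapply(sprintf("G_%d", 1:5),
                            function(l) length(unique(gm[[l]])), 1L))
  expect_lte(e$overall, log(max_alleles))
})

test_that("chemotype ratios and groups reproduce the reference table", {
  chem <- chem_ratio_and_group(chemotype_reference())
  row <- function(v) chem[chem$variety == v, ]
  expect_equal(round(row("Flash Babylon")$ratio, 2), 51.43)
  expect_equal(round(row("Chocolope")$ratio, 2), 12.84)
  expect_equal(row("Chocolope")$group, 4L)
  expect_equal(round(row("BC God Bud")$ratio, 2), 32.00)
  expect_equal(round(row("Golden Berry")$ratio, 2), 28.10)
  expect_equal(round(row("Skunk #11")$ratio, 2), 0.97)
  expect_equal(row("Skunk #11")$group, 3L)
  # zero CBD and zero THC -> ratio 0, group 1
  expect_equal(row("Santhica 27")$ratio, 0)
  expect_equal(row("Santhica 27")$group, 1L)

  # grouping from the printed ratios splits classes into 1-2 vs 3-4
  printed <- chem_ratio_and_group(
    dplyr::mutate(chemotype_reference(), thc = ratio_printed, cbd = 1))
  expect_true(all(printed$group[printed$class == "fiber"] %in% 1:2))
  expect_true(all(printed$group[printed$class == "drug"] %in% 3:4))

  expect_error(chem_ratio_and_group(tibble::tibble(thc = -1, cbd = 1)),
               "non-negative")
})

test_that("boundary ratios fall in the lower group and zero CBD with THC is group 4", {
  chem <- chem_ratio_and_group(tibble::tibble(
    thc = c(0.05, 0.2, 10, 10.01, 5), cbd = c(1, 1, 1, 1, 0)))
  expect_equal(chem$group, c(1L, 2L, 3L, 4L, 4L))
  expect_equal(chem$ratio[5], Inf)
})

test_that("plot helpers return ggplot objects", {
  panel <- small_clean_panel()
  sc <- score_samples(panel$genotypes, indel_score_spec())
  expect_s3_class(plot_scores(sc), "ggplot")
  coords <- classical_mds(gower_distance(panel$genotypes))
  expect_s3_class(plot_mds(coords, panel$metadata[, c("sample_id", "class")]),
                  "ggplot")
  expect_s3_class(plot_chemotypes(chemotype_reference()), "ggplot")
})
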