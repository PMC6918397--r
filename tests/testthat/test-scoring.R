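make_gm <- function(cells, classes) {
  # cells: named list locus -> character vector
  tibble::as_tibble(c(list(
    sample_id = sprintf("s%02d", seq_along(classes)), class = classes),
    cells))
}

test_that("consensus profile takes the modal allele with ordered tie-breaks", {
  gm <- make_gm(list(THCAS_10 = c("T", "T", "R", "C", "C", "C")),
                c("drug", "drug", "drug", "fiber", "fiber", "fiber"))
  prof <- consensus_profile(gm, "THCAS_10")
  expect_equal(prof$drug_allele, "T")  # mode of {T, T, R}
  expect_equal(prof$fiber_allele, "C")

  gm2 <- make_gm(list(THCAS_10 = c("T", "T", "C", "C", "A", "A")),
                 c(rep("drug", 4), "fiber", "fiber"))
  expect_warning(prof2 <- consensus_profile(gm2, "THCAS_10"), "tie")
  expect_equal(prof2$drug_allele, "C")  # {T,T,C,C}: C before T in ordering

  expect_error(consensus_profile(gm, "THCAS_99"), "absent")
})

test_that("locus points follow the three-way consensus rule", {
  expect_identical(locus_points(c("T", "C", "R", "del"), "T", "C"),
                   c(1L, -1L, 0L, 0L))
})

test_that("the published indel weights generate exactly four score values", {
  gm <- make_gm(list(CBDAS_153_del = c("del", "del", "ref", "ref"),
                     CBDAS_755_ins = c("ins", "ref", "ins", "ref")),
                c("drug", "drug", "fiber", "fiber"))
  sc <- score_samples(gm, indel_score_spec())
  expect_equal(sc$score, c(0.1, 1.1, -1, 0))
})

test_that("a sample missing a spec locus scores zero there with a warning", {
  gm <- make_gm(list(CBDAS_153_del = c("del", "ref")), c("drug", "fiber"))
  expect_warning(sc <- score_samples(gm, indel_score_spec()), "missing")
  expect_equal(sc$score, c(1.1, 0))
})

test_that("AUC matches exhaustive pair enumeration", {
  expect_equal(auc_mw(c(2, 1, 1, 0), c("drug", "drug", "fiber", "fiber")),
               0.875)
  expect_equal(auc_mw(c(5, 4, 1, 0), rep(c("drug", "fiber"), each = 2)), 1)
  expect_equal(auc_mw(rep(3, 6), rep(c("drug", "fiber"), 3)), 0.5)

  set.seed(77)
  for (i in 1:20) {
    n <- sample(4:20, 1)
    labels <- sample(c("drug", "fiber"), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    scores <- sample(0:5, n, replace = TRUE)  # many ties
    expect_equal(auc_mw(scores, labels), pair_enum_auc(scores, labels))
  }
  expect_error(auc_mw(1:3, rep("drug", 3)), "both classes")
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(5)
  labels <- rep(c("drug", "fiber"), each = 25)
  scores <- rnorm(50, mean = ifelse(labels == "drug", 1, 0))
  ours <- auc_mw(scores, labels)
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = labels, predictor = scores, levels = c("fiber", "drug"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-12)
})

test_that("weight optimisation finds perfect single loci and obeys the sign cap", {
  classes <- rep(c("drug", "fiber"), each = 6)
  gm <- make_gm(list(
    THCAS_136 = rep(c("ref", "G"), each = 6),     # perfect separator
    THCAS_300 = rep(c("A", "C", "A"), 4)),        # uninformative
    classes)
  prof <- consensus_profile(gm, c("THCAS_136", "THCAS_300"))
  sp <- optimize_weights(gm, prof, k = 1)
  expect_equal(sp$loci, "THCAS_136")
  expect_equal(sp$auc, 1)

  noise_only <- optimize_weights(gm, prof, k = 1,
                                 candidates = "THCAS_300")
  expect_lt(noise_only$auc, 0.7)

  expect_error(optimize_weights(gm, prof, k = 5), "exceeds")
})

test_that("two-locus indel optimisation is not beaten by any grid pair", {
  panel <- small_clean_panel()
  gm <- panel$genotypes
  prof <- consensus_profile(gm, c("CBDAS_153_del", "CBDAS_755_ins"))
  sp <- optimize_weights(gm, prof, k = 2,
                         candidates = c("CBDAS_153_del", "CBDAS_755_ins"))
  expect_lte(sum(sp$weights < 0), 1)

  k1 <- optimize_weights(gm, prof, k = 1,
                         candidates = c("CBDAS_153_del", "CBDAS_755_ins"))
  expect_gte(sp$auc, k1$auc)

  # exhaustive grid check with at most one negative weight
  del <- as.integer(gm$CBDAS_153_del != "ref")
  ins <- as.integer(gm$CBDAS_755_ins != "ref")
  grid <- seq(-2, 2, by = 0.1)
  best <- 0
  for (w1 in grid) for (w2 in grid) {
    if ((w1 < 0) + (w2 < 0) > 1) next
    best <- max(best, auc_mw(w1 * del + w2 * ins, gm$class))
  }
  expect_equal(sp$auc, best)
})

test_that("optimised AUC is non-decreasing as k grows", {
  panel <- small_clean_panel()
  gm <- panel$genotypes
  scan <- memo("small_scan", scan_loci(gm))
  sig <- scan$locus[scan$significant]
  prof <- consensus_profile(gm, sig)
  aucs <- vapply(1:3, function(k) {
    optimize_weights(gm, prof, k = k, candidates = sig[1:4])$auc
  }, numeric(1))
  expect_true(all(diff(aucs) >= -1e-12))
})

test_that("evaluation returns calibrated metrics and sane intervals", {
  panel <- small_clean_panel()
  sc <- score_samples(panel$genotypes, indel_score_spec())
  ev <- evaluate_score(sc, threshold = 0, B = 300, seed = 4)
  td <- tidy(ev)
  expect_equal(td$estimate[td$metric == "sensitivity"], 1)
  expect_equal(td$estimate[td$metric == "specificity"], 1)
  expect_true(all(td$ci_low <= td$estimate & td$estimate <= td$ci_high))
  # constant metric -> degenerate interval equal to the point
  expect_equal(td$ci_low[td$metric == "sensitivity"], 1)
  expect_equal(td$ci_high[td$metric == "sensitivity"], 1)

  expect_error(evaluate_score(sc, B = 0, seed = 1), "at least 1")
  expect_error(evaluate_score(sc, B = 10), "seed")

  # fixed seed reproduces the intervals
  ev2 <- evaluate_score(sc, threshold = 0, B = 300, seed = 4)
  expect_identical(tidy(ev), tidy(ev2))
})

test_that("an all-reference fiber panel has specificity one", {
  gm <- make_gm(list(CBDAS_153_del = c("del", "ref", "ref", "ref"),
                     CBDAS_755_ins = c("ins", "ref", "ref", "ref")),
                c("drug", "fiber", "fiber", "fiber"))
  sc <- score_samples(gm, indel_score_spec())
  ev <- evaluate_score(sc, B = 50, seed = 2)
  expect_equal(glance(ev)$specificity, 1)
})
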