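test_that("identical sequences align gap-free at the maximal score", {
  al <- align_global("ACGTACGT", "ACGTACGT")
  expect_false(grepl("-", al$pattern))
  expect_false(grepl("-", al$subject))
  expect_equal(al$score, 2 * 8)
})

test_that("a single missing base yields exactly one gap column", {
  al <- align_global("ACT", "ACGT")
  gaps <- strsplit(al$pattern, "")[[1]] == "-"
  expect_equal(sum(gaps), 1)
  expect_false(grepl("-", al$subject))
})

test_that("alignment scores match exhaustive enumeration on short sequences", {
  set.seed(101)
  for (i in 1:12) {
    a <- paste(sample(c("A", "C", "G", "T"), sample(3:7, 1), replace = TRUE),
               collapse = "")
    b <- paste(sample(c("A", "C", "G", "T"), sample(3:8, 1), replace = TRUE),
               collapse = "")
    expect_equal(align_global(a, b)$score, brute_force_align_score(a, b),
                 info = paste(a, b))
  }
})

test_that("calls recover a planted deletion, insertion and het SNP", {
  panel <- small_clean_panel()
  ref_b <- panel$references[panel$references$gene == "CBDAS", ]
  drug_seq <- panel$sequences$sequence[
    panel$sequences$gene == "CBDAS" &
      grepl("^drug", panel$sequences$sample_id)][1]
  calls <- call_variants(align_global(drug_seq, ref_b$cds), ref_b)

  del <- calls[calls$kind == "deletion", ]
  expect_equal(nrow(del), 1)
  expect_equal(del$pos, 153L)
  expect_equal(del$ref, "CGTA")
  ins <- calls[calls$kind == "insertion", ]
  expect_equal(nrow(ins), 1)
  expect_equal(ins$pos, 755L)
  expect_equal(ins$alt, "AAC")
  expect_equal(sort(calls$pos[calls$kind == "snp"]),
               c(407L, 545L, 583L, 588L, 613L, 637L, 688L, 704L))

  # heterozygous IUPAC base at a reference site -> het SNP call
  het_seq <- ref_b$cds
  stopifnot(substr(het_seq, 583, 583) == "A")
  substr(het_seq, 583, 583) <- "W"  # A/T het
  hcalls <- call_variants(align_global(het_seq, ref_b$cds), ref_b)
  expect_equal(hcalls$kind, "snp")
  expect_equal(hcalls$pos, 583L)
  expect_equal(hcalls$alt, "W")
  expect_equal(hcalls$zygosity, "het")
})

test_that("calling on a clean panel recovers the truth table exactly", {
  panel <- small_clean_panel()
  calls <- call_panel_variants(panel$sequences, panel$references)
  truth <- panel$truth$sample_variants
  key <- function(d) {
    d <- d[order(d$sample_id, d$gene, d$pos, d$kind), ]
    paste(d$sample_id, d$gene, d$pos, d$kind, d$ref, d$alt, d$zygosity)
  }
  expect_setequal(key(calls), key(truth))
})

test_that("applying emitted calls to the reference rebuilds each sample", {
  panel <- small_clean_panel()
  calls <- call_panel_variants(panel$sequences, panel$references)
  for (sid in panel$metadata$sample_id[c(1, 7)]) {
    for (g in panel$references$gene) {
      ref <- panel$references[panel$references$gene == g, ]
      v <- calls[calls$sample_id == sid & calls$gene == g, ]
      rebuilt <- apply_variants(ref, v)
      expect_identical(
        rebuilt,
        panel$sequences$sequence[panel$sequences$sample_id == sid &
                                   panel$sequences$gene == g])
    }
  }
})

test_that("variant positions ignore flanking reference-identical context", {
  ref <- tibble::tibble(gene = "G", cds = paste(rep("ACGT", 30), collapse = ""))
  mut <- ref$cds
  substr(mut, 50, 50) <- "T"
  calls <- call_variants(align_global(mut, ref$cds), ref)
  expect_equal(calls$pos, 50L)
  expect_equal(calls$kind, "snp")
})

test_that("indels are left-normalised inside repeats", {
  # reference ...A AAA C...: deleting any single A is reported at the
  # leftmost equivalent position
  ref <- tibble::tibble(gene = "G", cds = "ATGCAAAACGGTTAG")
  mut <- "ATGCAAACGGTTAG"  # one A of the run removed
  calls <- call_variants(align_global(mut, ref$cds), ref)
  del <- calls[calls$kind == "deletion", ]
  expect_equal(del$pos, 5L)
  expect_equal(del$ref, "A")
})

test_that("genotype matrix defaults, restriction and errors behave", {
  labels <- tibble::tibble(sample_id = c("s1", "s2"),
                           class = c("drug", "fiber"))
  calls <- tibble::tibble(sample_id = "s2", gene = "THCAS", pos = 10L,
                          kind = "snp", ref = "C", alt = "T",
                          zygosity = "hom")
  gm <- build_matrix(calls, labels)
  expect_equal(gm$THCAS_10, c("ref", "T"))
  expect_equal(locus_info(gm)$ref_allele, "C")

  # restriction drops loci outside the list
  calls2 <- dplyr::bind_rows(calls, tibble::tibble(
    sample_id = "s1", gene = "THCAS", pos = 99L, kind = "snp",
    ref = "A", alt = "G", zygosity = "hom"))
  gm2 <- build_matrix(calls2, labels,
                      loci = tibble::tibble(gene = "THCAS", pos = 10L))
  expect_identical(setdiff(names(gm2), c("sample_id", "class")), "THCAS_10")

  # no calls -> all-reference matrix with no locus columns
  empty <- build_matrix(calls[0, ], labels)
  expect_equal(nrow(empty), 2)
  expect_length(setdiff(names(empty), c("sample_id", "class")), 0)

  expect_error(build_matrix(calls, labels[c(1, 1), ]), "duplicate")
})
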