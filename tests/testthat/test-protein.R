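test_that("translation stops at the first in-frame stop codon", {
  p <- translate_cds("ATGAAATAA")
  expect_equal(p$aa_sequence, "MK")
  expect_equal(p$stop_codon_index, 3L)
  expect_true(p$has_stop)

  nostop <- translate_cds("ATGAAACCC")
  expect_false(nostop$has_stop)
  expect_equal(nostop$aa_sequence, "MKP")

  expect_error(translate_cds("ATGR"), "non-ACGT")
  expect_error(translate_cds("AT"), "at least one codon")
})

test_that("codon arithmetic reproduces the printed position-residue pairs", {
  expect_equal(codon_of(583), 195L)
  expect_equal(codon_of(153), 51L)
  expect_equal(codon_of(c(269, 494, 749, 763)), c(90L, 165L, 250L, 255L))
  expect_error(codon_of(0), "1-based")
})

test_that("variants apply right-to-left with overlap and zygosity guards", {
  ref <- "ATGGCTAAATAA"
  expect_identical(apply_variants(ref, tibble::tibble(
    pos = integer(), kind = character(), ref = character(),
    alt = character())), ref)

  snp <- tibble::tibble(pos = 5L, kind = "snp", ref = "C", alt = "A")
  expect_identical(apply_variants(ref, snp), "ATGGATAAATAA")

  del <- tibble::tibble(pos = 4L, kind = "deletion", ref = "GCTA", alt = "")
  expect_identical(apply_variants(ref, del), "ATGAATAA")
  expect_equal(nchar(apply_variants(ref, del)), nchar(ref) - 4)

  both <- tibble::tibble(pos = c(4L, 10L), kind = c("deletion", "insertion"),
                         ref = c("GCTA", ""), alt = c("", "CCC"))
  expect_identical(apply_variants(ref, both), "ATGAATCCCAA")

  overlap <- tibble::tibble(pos = c(4L, 5L), kind = c("deletion", "snp"),
                            ref = c("GCTA", "C"), alt = c("", "A"))
  expect_error(apply_variants(ref, overlap), "overlapping")

  het <- tibble::tibble(pos = 5L, kind = "snp", ref = "C", alt = "M",
                        zygosity = "het")
  expect_error(apply_variants(ref, het), "heterozygous")
})

test_that("synonymy classification agrees with full-translation comparison", {
  set.seed(21)
  ref <- make_references(panel_config(seed = 3))$cds[1]
  for (i in 1:25) {
    pos <- sample(4:(nchar(ref) - 3), 1)
    rb <- substr(ref, pos, pos)
    ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
    v <- tibble::tibble(pos = pos, kind = "snp", ref = rb, alt = ab)
    ann <- annotate_consequences(ref, v)
    mutant_prot <- translate_cds(apply_variants(ref, v))$aa_sequence
    ref_prot <- translate_cds(ref)$aa_sequence
    expect_identical(ann$annotations$synonymous[1],
                     identical(mutant_prot, ref_prot),
                     info = paste("pos", pos, rb, ">", ab))
  }
})

test_that("substitution impact follows the side-chain classes", {
  # V (GTT, hydrophobic) -> D (GAT, charged): high impact
  ref <- "ATGGTTAAATAA"
  high <- annotate_consequences(ref, tibble::tibble(
    pos = 5L, kind = "snp", ref = "T", alt = "A"))
  expect_equal(high$annotations$impact, "high")
  expect_equal(high$annotations$ref_aa, "V")
  expect_equal(high$annotations$alt_aa, "D")

  # A (GCT, hydrophobic) -> T (ACT, polar): moderate
  mod <- annotate_consequences("ATGGCTAAATAA", tibble::tibble(
    pos = 4L, kind = "snp", ref = "G", alt = "A"))
  expect_equal(mod$annotations$impact, "moderate")

  # synonymous third-position change: low
  syn <- annotate_consequences("ATGGTTAAATAA", tibble::tibble(
    pos = 6L, kind = "snp", ref = "T", alt = "C"))
  expect_true(syn$annotations$synonymous)
  expect_equal(syn$annotations$impact, "low")
  expect_equal(syn$summary$n_syn, 1L)
})

test_that("frameshift flags follow indel length modulo three", {
  ref <- make_references(panel_config(seed = 3))$cds[2]
  del4 <- tibble::tibble(pos = 153L, kind = "deletion",
                         ref = substr(ref, 153, 156), alt = "")
  expect_true(annotate_consequences(ref, del4)$summary$frameshift)
  del3 <- tibble::tibble(pos = 153L, kind = "deletion",
                         ref = substr(ref, 153, 155), alt = "")
  expect_false(annotate_consequences(ref, del3)$summary$frameshift)
  ins3 <- tibble::tibble(pos = 755L, kind = "insertion", ref = "", alt = "AAC")
  expect_false(annotate_consequences(ref, ins3)$summary$frameshift)
})

test_that("the planted marker sets reproduce the documented summaries", {
  panel <- small_clean_panel()
  refs <- panel$references
  loci <- panel$truth$loci

  thcas_vars <- dplyr::transmute(
    loci[loci$gene == "THCAS" & loci$kind == "snp", ],
    pos = pos, kind = kind, ref = ref_allele, alt = fiber_allele)
  ann_a <- annotate_consequences(refs[refs$gene == "THCAS", ], thcas_vars)
  expect_equal(ann_a$summary$n_snps, 25L)
  expect_equal(ann_a$summary$n_nonsyn, 19L)
  expect_equal(ann_a$summary$n_syn, 6L)
  expect_equal(ann_a$summary$n_aa_changes, 18L)
  expect_equal(round(ann_a$summary$nonsyn_syn_ratio, 1), 3.2)
  # four high-impact residues at the documented positions
  high <- ann_a$annotations[ann_a$annotations$impact == "high", ]
  expect_setequal(high$codon_index, c(90L, 165L, 250L, 255L))
  # ten changes of moderate-or-high impact among the 18
  expect_equal(sum(ann_a$annotations$impact %in% c("moderate", "high")), 10L)

  cbdas_vars <- dplyr::transmute(
    loci[loci$gene == "CBDAS" & loci$kind == "snp", ],
    pos = pos, kind = kind, ref = ref_allele, alt = drug_allele)
  ann_b <- annotate_consequences(refs[refs$gene == "CBDAS", ], cbdas_vars)
  expect_true(ann_b$summary$truncated)
  expect_equal(ann_b$summary$stop_codon_index, 195L)
  expect_equal(ann_b$summary$ref_stop_codon_index, 545L)
  # the two PROVEAN-flagged substitutions are present as annotated
  ann136 <- ann_b$annotations[ann_b$annotations$codon_index == 136, ]
  expect_equal(paste0(ann136$ref_aa, ann136$alt_aa), "RH")
  ann182 <- ann_b$annotations[ann_b$annotations$codon_index == 182, ]
  expect_equal(paste0(ann182$ref_aa, ann182$alt_aa), "GA")
})

test_that("literature deleteriousness annotations are exposed", {
  pa <- provean_annotations()
  expect_setequal(pa$residue[pa$gene == "CBDAS"], c(136L, 182L))
  expect_equal(pa$residue[pa$gene == "THCAS"], 165L)
  expect_true(all(pa$call == "deleterious"))
})
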