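# Panel configuration and the fixed marker design planted by the generator.
#
# The design places 25 discriminating SNPs in the THCAS-like gene (reference
# = drug-type consensus) and 8 SNPs plus a 4-bp deletion (CGTA, positions
# 153-156) and a 3-bp insertion (AAC after 755) in the CBDAS-like gene
# (reference = fiber-type consensus). Allele identities are invented but
# engineered so the downstream consequence summaries take the documented
# values: 19 non-synonymous + 6 synonymous THCAS SNPs producing 18 amino
# acid changes (two SNPs share codon 46, two synonymous SNPs share codon
# 288), four high-impact substitutions at residues 90/165/250/255, the
# CBDAS A>T change at position 583 creating a premature stop in codon 195,
# and the deletion removing Leu51/Val52.

.NONSTOP_CODONS <- {
  b <- c("A", "C", "G", "T")
  all <- as.vector(outer(outer(b, b, paste0), b, paste0))
  setdiff(all, c("TAA", "TAG", "TGA"))
}

# ref codons pinned in the THCAS-like reference (1-based codon index)
.design_codons_a <- function() {
  tibble(
    codon = c(46L, 52L, 74L, 90L, 96L, 100L, 119L, 128L, 129L, 137L, 138L,
              140L, 142L, 165L, 169L, 204L, 226L, 233L, 248L, 250L, 255L,
              288L, 290L),
    triplet = c("CTG", "GCT", "TTT", "ATA", "GGT", "GGT", "CCA", "GCA",
                "TCA", "AAA", "CAT", "ATT", "TTG", "ATG", "TTC", "ACA",
                "CCT", "TCT", "ATA", "GTT", "TGT", "CTA", "TGG"))
}

# the 25 discriminating SNPs: position on the drug-type reference, allele
# fixed in fiber-type samples (drug allele = reference base)
.design_snps_a <- function() {
  tibble(
    pos = c(136L, 137L, 154L, 221L, 269L, 287L, 300L, 355L, 383L, 385L,
            409L, 412L, 418L, 424L, 494L, 505L, 612L, 678L, 699L, 744L,
            749L, 763L, 862L, 864L, 869L),
    alt = c("G", "C", "A", "C", "A", "A", "C", "A", "T", "G",
            "G", "T", "G", "A", "A", "A", "G", "G", "C", "G",
            "A", "C", "T", "G", "C"))
}

.design_codons_b <- function() {
  tibble(
    codon = c(51L, 52L, 136L, 182L, 195L, 196L, 205L, 213L, 230L, 235L, 252L),
    triplet = c("CTC", "GTA", "CGT", "GGT", "AAA", "GGA", "GAT", "CTT",
                "TCA", "ACT", "GAT"))
}

# the 8 CBDAS SNPs: position on the fiber-type reference, allele fixed in
# drug-type samples (fiber allele = reference base)
.design_snps_b <- function() {
  tibble(
    pos = c(407L, 545L, 583L, 588L, 613L, 637L, 688L, 704L),
    alt = c("A", "C", "T", "G", "A", "A", "G", "T"))
}

#' Configure a synthetic marker panel
#'
#' Builds the configuration object consumed by [make_references()],
#' [simulate_panel()] and [simulate_chemotable()]. The defaults reproduce
#' the study conditions the package's analyses assume: 47 drug-type plants
#' across 11 varieties and 50 fiber-type plants across 10 varieties, plus
#' 20 drug-type and 50 fiber-type seeds (167 samples in total); a ~1.6 kb
#' THCAS-like CDS carrying 25 fiber-fixed SNPs and a ~1.6 kb CBDAS-like CDS
#' carrying 8 drug-fixed SNPs, a 4-bp deletion (positions 153-156) and a
#' 3-bp AAC insertion (after position 755) in drug-type samples.
#'
#' @param seed Integer seed; mandatory, drives every random draw.
#' @param n_drug_plants,n_fiber_plants,n_drug_seeds,n_fiber_seeds Sample
#'   counts per class and tissue.
#' @param gene_lengths Named or unnamed length-2 integer vector of CDS
#'   lengths (THCAS-like, CBDAS-like); each must be divisible by 3.
#' @param n_disc_snps_gene_a,n_disc_snps_gene_b Number of planted
#'   discriminating SNPs used from the fixed design (at most 25 and 8).
#' @param het_rate Probability that a drug-type sample's background variant
#'   is emitted as a heterozygous IUPAC call rather than a homozygous base.
#' @param background_mutation_rate Per-site probability of private
#'   (sample-specific) variation at non-marker positions.
#' @param indel_discordance_rate Probability a drug-type sample carries only
#'   one of the two CBDAS indels instead of both.
#' @param het_at_markers If `TRUE`, planted marker alleles may themselves be
#'   emitted heterozygous (at `het_rate`); off by default, matching the
#'   focus on homozygous discriminating loci.
#' @param n_drug_varieties,n_fiber_varieties Number of named varieties the
#'   plants/seeds are spread over.
#' @return A `panel_config` list.
#' @examples
#' cfg <- panel_config(seed = 1)
#' cfg$n_drug_plants + cfg$n_fiber_plants
#' @export
panel_config <- function(seed,
                         n_drug_plants = 47, n_fiber_plants = 50,
                         n_drug_seeds = 20, n_fiber_seeds = 50,
                         gene_lengths = c(THCAS = 1638L, CBDAS = 1635L),
                         n_disc_snps_gene_a = 25,
                         n_disc_snps_gene_b = 8,
                         het_rate = 0.3,
                         background_mutation_rate = 0.001,
                         indel_discordance_rate = 0,
                         het_at_markers = FALSE,
                         n_drug_varieties = 11,
                         n_fiber_varieties = 10) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort("panel_config() requires a single integer seed")
  }
  counts <- c(n_drug_plants, n_fiber_plants, n_drug_seeds, n_fiber_seeds,
              n_drug_varieties, n_fiber_varieties)
  if (any(counts < 0) || any(counts != floor(counts))) {
    abort("sample and variety counts must be non-negative integers")
  }
  if (n_drug_plants + n_drug_seeds > 0 && n_drug_varieties < 1) {
    abort("need at least one drug variety when drug samples are requested")
  }
  if (n_fiber_plants + n_fiber_seeds > 0 && n_fiber_varieties < 1) {
    abort("need at least one fiber variety when fiber samples are requested")
  }
  gene_lengths <- as.integer(gene_lengths)
  if (length(gene_lengths) != 2 || any(gene_lengths %% 3 != 0)) {
    abort("gene_lengths must be two CDS lengths, each divisible by 3")
  }
  rates <- c(het_rate, background_mutation_rate, indel_discordance_rate)
  if (any(rates < 0) || any(rates > 1)) {
    abort("het_rate, background_mutation_rate and indel_discordance_rate must lie in [0, 1]")
  }
  if (n_disc_snps_gene_a < 0 || n_disc_snps_gene_a > 25 ||
      n_disc_snps_gene_b < 0 || n_disc_snps_gene_b > 8) {
    abort("the fixed design provides up to 25 gene-A and 8 gene-B discriminating SNPs")
  }
  snps_a <- head(.design_snps_a(), n_disc_snps_gene_a)
  snps_b <- head(.design_snps_b(), n_disc_snps_gene_b)
  if (anyDuplicated(snps_a$pos) || anyDuplicated(snps_b$pos)) {
    abort("discriminating positions must be distinct")
  }
  needed_a <- max(.design_codons_a()$codon) * 3 + 3
  needed_b <- max(.design_codons_b()$codon) * 3 + 3
  if (gene_lengths[1] < needed_a || gene_lengths[2] < needed_b) {
    abort(paste0("gene lengths must be at least ", needed_a, " and ",
                 needed_b, " nt to hold the marker design"))
  }
  structure(list(
    seed = as.integer(seed),
    n_drug_plants = n_drug_plants, n_fiber_plants = n_fiber_plants,
    n_drug_seeds = n_drug_seeds, n_fiber_seeds = n_fiber_seeds,
    gene_names = c("THCAS", "CBDAS"),
    gene_lengths = gene_lengths,
    snps_a = snps_a, snps_b = snps_b,
    deletion_start = 153L, deletion_len = 4L,
    insertion_pos = 755L, insertion_seq = "AAC",
    het_rate = het_rate,
    background_mutation_rate = background_mutation_rate,
    indel_discordance_rate = indel_discordance_rate,
    het_at_markers = het_at_markers,
    n_drug_varieties = n_drug_varieties,
    n_fiber_varieties = n_fiber_varieties
  ), class = "panel_config")
}

# evaluate expr with a temporary RNG seed, restoring global RNG state after
.with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}
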