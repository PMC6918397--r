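# Synthetic panel generation: reference CDS pair, per-sample sequences with
# planted discriminating markers, metadata, genotype matrix, truth tables,
# and a chemotype table mirroring the drug/fiber THC and CBD ranges.

.make_refs_unseeded <- function(config) {
  lens <- config$gene_lengths
  build <- function(len, pinned) {
    n_codons <- len / 3
    codons <- c("ATG",
                sample(.NONSTOP_CODONS, n_codons - 2, replace = TRUE),
                "TAA")
    codons[pinned$codon] <- pinned$triplet
    paste(codons, collapse = "")
  }
  tibble(
    gene = config$gene_names,
    cds = c(build(lens[1], .design_codons_a()),
            build(lens[2], .design_codons_b())),
    ref_class = c("drug", "fiber"),
    source_label = c("synthetic drug-type THCAS-like CDS",
                     "synthetic fiber-type CBDAS-like CDS"))
}

#' Generate the synthetic reference CDS pair
#'
#' Builds one drug-type THCAS-like and one fiber-type CBDAS-like coding
#' sequence: ATG start, a single terminal stop codon, no internal in-frame
#' stops, with the fixed marker-design codons pinned and all other codons
#' drawn uniformly from the 61 non-stop codons. Deterministic for a given
#' `config$seed`. Real reference sequences (e.g. GenBank CDS FASTA) can be
#' used instead anywhere a reference tibble is accepted.
#'
#' @param config A [panel_config()].
#' @return A tibble with columns `gene`, `cds`, `ref_class` (which class the
#'   reference represents) and `source_label`.
#' @examples
#' refs <- make_references(panel_config(seed = 1))
#' nchar(refs$cds)
#' @export
make_references <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  .with_seed(config$seed, .make_refs_unseeded(config))
}

# substitute a single base (possibly an IUPAC code) at pos
.sub_base <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

.variety_names <- function(class, n) {
  sprintf("%s%02d", ifelse(class == "drug", "DrugVar", "FiberVar"), seq_len(n))
}

# spread k samples over varieties as evenly as possible
.assign_varieties <- function(k, varieties) {
  if (k == 0) return(character(0))
  rep(varieties, length.out = max(k, 0))[seq_len(k)] |> sort()
}

#' Simulate a genotyped cannabis panel
#'
#' Emits per-sample gene sequences (FASTA-ready), sample metadata, the
#' samples-by-loci genotype matrix, and ground-truth tables for every
#' planted and background variant. Drug-type samples carry the drug allele
#' at every planted locus and (unless discordant) both CBDAS indels;
#' fiber-type samples carry the fiber alleles and neither indel. Private
#' background variation is added per sample at `background_mutation_rate`,
#' heterozygous calls are encoded as IUPAC codes, and every emitted
#' sequence is consistent with the truth tables.
#'
#' @param config A [panel_config()].
#' @return A list of class `cm_panel` with elements `references`,
#'   `sequences` (tibble: `id` = `sample|gene`, `sample_id`, `gene`,
#'   `sequence`), `metadata` (`sample_id`, `variety`, `class`, `tissue`),
#'   `genotypes` (genotype matrix tibble, see [build_matrix()]), and
#'   `truth` (list: `loci`, `sample_variants`, `indel_carriage`).
#' @examples
#' panel <- simulate_panel(panel_config(seed = 1, n_drug_plants = 3,
#'   n_fiber_plants = 3, n_drug_seeds = 0, n_fiber_seeds = 0,
#'   background_mutation_rate = 0))
#' panel$metadata
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  .with_seed(config$seed, {
    refs <- .make_refs_unseeded(config)
    ref_a <- refs$cds[1]; ref_b <- refs$cds[2]
    gene_a <- refs$gene[1]; gene_b <- refs$gene[2]
    len_a <- nchar(ref_a); len_b <- nchar(ref_b)

    drug_vars <- .variety_names("drug", config$n_drug_varieties)
    fiber_vars <- .variety_names("fiber", config$n_fiber_varieties)
    meta <- bind_rows(
      tibble(class = "drug", tissue = "leaf",
             variety = .assign_varieties(config$n_drug_plants, drug_vars)),
      tibble(class = "fiber", tissue = "leaf",
             variety = .assign_varieties(config$n_fiber_plants, fiber_vars)),
      tibble(class = "drug", tissue = "seed",
             variety = .assign_varieties(config$n_drug_seeds, drug_vars)),
      tibble(class = "fiber", tissue = "seed",
             variety = .assign_varieties(config$n_fiber_seeds, fiber_vars)))
    meta$sample_id <- sprintf("%s_%s_%03d", meta$class, meta$tissue,
                              stats::ave(seq_len(nrow(meta)),
                                         paste(meta$class, meta$tissue),
                                         FUN = seq_along))
    meta <- meta[, c("sample_id", "variety", "class", "tissue")]
    if (nrow(meta) == 0) abort("config requests zero samples")

    # planted truth loci; 'ref' cells carry the reference-class allele
    snps_a <- config$snps_a
    snps_b <- config$snps_b
    truth_loci <- bind_rows(
      tibble(gene = gene_a, pos = snps_a$pos, kind = "snp",
             ref_allele = substring(ref_a, snps_a$pos, snps_a$pos),
             drug_allele = substring(ref_a, snps_a$pos, snps_a$pos),
             fiber_allele = snps_a$alt),
      tibble(gene = gene_b, pos = snps_b$pos, kind = "snp",
             ref_allele = substring(ref_b, snps_b$pos, snps_b$pos),
             drug_allele = snps_b$alt,
             fiber_allele = substring(ref_b, snps_b$pos, snps_b$pos)),
      tibble(gene = gene_b, pos = config$deletion_start, kind = "deletion",
             ref_allele = substring(ref_b, config$deletion_start,
                                    config$deletion_start + config$deletion_len - 1),
             drug_allele = "del", fiber_allele = "ref"),
      tibble(gene = gene_b, pos = config$insertion_pos, kind = "insertion",
             ref_allele = "", drug_allele = "ins", fiber_allele = "ref"))
    truth_loci$planted_significant <- TRUE

    # positions background mutations must avoid (markers, indel flanks, ends)
    excl_a <- c(1:3, (len_a - 2):len_a, snps_a$pos)
    excl_b <- c(1:3, (len_b - 2):len_b, snps_b$pos,
                (config$deletion_start - 1):(config$deletion_start + config$deletion_len),
                (config$insertion_pos - 1):(config$insertion_pos + 2))

    n <- nrow(meta)
    indel_carriage <- tibble(sample_id = meta$sample_id,
                             has_deletion = FALSE, has_insertion = FALSE)
    sample_variants <- vector("list", n)
    seq_a <- character(n); seq_b <- character(n)

    for (i in seq_len(n)) {
      cls <- meta$class[i]
      sid <- meta$sample_id[i]
      rows <- list()
      sa <- ref_a; sb <- ref_b

      # planted SNPs: non-reference class carries the alternative allele
      emit_snp <- function(gene, pos, ref_base, allele) {
        zyg <- "hom"; cell <- allele
        if (config$het_at_markers && allele != ref_base &&
            runif(1) < config$het_rate) {
          cell <- iupac_code(c(ref_base, allele)); zyg <- "het"
        }
        list(cell = cell, zyg = zyg)
      }
      if (cls == "fiber") {
        for (j in seq_len(nrow(snps_a))) {
          e <- emit_snp(gene_a, snps_a$pos[j],
                        substring(ref_a, snps_a$pos[j], snps_a$pos[j]),
                        snps_a$alt[j])
          sa <- .sub_base(sa, snps_a$pos[j], e$cell)
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sid, gene = gene_a, pos = snps_a$pos[j],
            kind = "snp", ref = substring(ref_a, snps_a$pos[j], snps_a$pos[j]),
            alt = e$cell, zygosity = e$zyg)
        }
      } else {
        for (j in seq_len(nrow(snps_b))) {
          e <- emit_snp(gene_b, snps_b$pos[j],
                        substring(ref_b, snps_b$pos[j], snps_b$pos[j]),
                        snps_b$alt[j])
          sb <- .sub_base(sb, snps_b$pos[j], e$cell)
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sid, gene = gene_b, pos = snps_b$pos[j],
            kind = "snp", ref = substring(ref_b, snps_b$pos[j], snps_b$pos[j]),
            alt = e$cell, zygosity = e$zyg)
        }
      }

      # background private variation (hom, or het IUPAC for drug samples)
      for (g in 1:2) {
        ref_seq <- if (g == 1) ref_a else ref_b
        excl <- if (g == 1) excl_a else excl_b
        gname <- if (g == 1) gene_a else gene_b
        len <- nchar(ref_seq)
        hits <- which(runif(len) < config$background_mutation_rate)
        hits <- setdiff(hits, excl)
        for (p in hits) {
          rb <- substring(ref_seq, p, p)
          ab <- sample(setdiff(c("A", "C", "G", "T"), rb), 1)
          zyg <- "hom"; cell <- ab
          if (cls == "drug" && runif(1) < config$het_rate) {
            cell <- iupac_code(c(rb, ab)); zyg <- "het"
          }
          if (g == 1) sa <- .sub_base(sa, p, cell) else sb <- .sub_base(sb, p, cell)
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sid, gene = gname, pos = p, kind = "snp",
            ref = rb, alt = cell, zygosity = zyg)
        }
      }

      # CBDAS indels in drug samples (both, unless discordant)
      if (cls == "drug") {
        has_del <- TRUE; has_ins <- TRUE
        if (runif(1) < config$indel_discordance_rate) {
          if (runif(1) < 0.5) has_del <- FALSE else has_ins <- FALSE
        }
        indel_carriage$has_deletion[i] <- has_del
        indel_carriage$has_insertion[i] <- has_ins
        # apply right-to-left so coordinates stay valid
        if (has_ins) {
          sb <- paste0(substring(sb, 1, config$insertion_pos),
                       config$insertion_seq,
                       substring(sb, config$insertion_pos + 1, nchar(sb)))
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sid, gene = gene_b, pos = config$insertion_pos,
            kind = "insertion", ref = "", alt = config$insertion_seq,
            zygosity = "hom")
        }
        if (has_del) {
          del_ref <- substring(ref_b, config$deletion_start,
                               config$deletion_start + config$deletion_len - 1)
          sb <- paste0(substring(sb, 1, config$deletion_start - 1),
                       substring(sb, config$deletion_start + config$deletion_len,
                                 nchar(sb)))
          rows[[length(rows) + 1]] <- tibble(
            sample_id = sid, gene = gene_b, pos = config$deletion_start,
            kind = "deletion", ref = del_ref, alt = "", zygosity = "hom")
        }
      }

      sample_variants[[i]] <- bind_rows(rows)
      seq_a[i] <- sa; seq_b[i] <- sb
    }

    sample_variants <- bind_rows(sample_variants)
    if (nrow(sample_variants) > 0) {
      sample_variants <- arrange(sample_variants, .data$sample_id,
                                 .data$gene, .data$pos)
    } else {
      sample_variants <- tibble(sample_id = character(), gene = character(),
                                pos = integer(), kind = character(),
                                ref = character(), alt = character(),
                                zygosity = character())
    }

    sequences <- bind_rows(
      tibble(sample_id = meta$sample_id, gene = gene_a, sequence = seq_a),
      tibble(sample_id = meta$sample_id, gene = gene_b, sequence = seq_b))
    sequences <- mutate(sequences, id = paste0(.data$sample_id, "|", .data$gene),
                        .before = 1)
    sequences <- arrange(sequences, .data$sample_id, .data$gene)

    genotypes <- build_matrix(sample_variants, labels = meta[, c("sample_id", "class")])

    truth <- list(loci = truth_loci,
                  sample_variants = sample_variants,
                  indel_carriage = indel_carriage)
    structure(list(references = refs, sequences = sequences,
                   metadata = meta, genotypes = genotypes, truth = truth),
              class = "cm_panel")
  })
}

#' @export
print.cm_panel <- function(x, ...) {
  cat("Synthetic cannabis marker panel\n")
  cat(sprintf("  samples: %d (%d drug / %d fiber; %d leaf / %d seed)\n",
              nrow(x$metadata),
              sum(x$metadata$class == "drug"), sum(x$metadata$class == "fiber"),
              sum(x$metadata$tissue == "leaf"), sum(x$metadata$tissue == "seed")))
  cat(sprintf("  genes: %s\n",
              paste(sprintf("%s (%d nt)", x$references$gene,
                            nchar(x$references$cds)), collapse = ", ")))
  cat(sprintf("  planted loci: %d (+%d indel)\n",
              sum(x$truth$loci$kind == "snp"),
              sum(x$truth$loci$kind != "snp")))
  invisible(x)
}

#' Bundled reference chemotype table
#'
#' Mean cannabinoid content (% of inflorescence dry weight) for the 21
#' varieties of the reference panel: 10 fiber-type and 11 drug-type
#' varieties, with per-variety plant counts, mean and SD of CBD and THC,
#' the printed THC/CBD ratio, and the class label. Used as the in-package
#' input for chemotype arithmetic checks; `-` (no SD, n < 2 or zero mean)
#' is encoded as `NA`.
#'
#' @return A tibble with columns `variety`, `n_plants`, `cbd`, `sd_cbd`,
#'   `thc`, `sd_thc`, `ratio_printed`, `class`.
#' @examples
#' chemotype_reference()
#' @export
chemotype_reference <- function() {
  tibble::tribble(
    ~variety, ~n_plants, ~cbd, ~sd_cbd, ~thc, ~sd_thc, ~ratio_printed, ~class,
    "Santhica 27",     5, 0.00,   NA, 0.00,   NA,  0.00, "fiber",
    "Carmagnola",      5, 3.89, 0.49, 0.24, 0.04,  0.06, "fiber",
    "Uso 31",          5, 0.24, 0.13, 0.03, 0.02,  0.12, "fiber",
    "Ermes",           5, 2.53, 0.37, 0.15, 0.03,  0.06, "fiber",
    "Finola",          5, 1.66, 0.34, 0.31, 0.10,  0.18, "fiber",
    "Ermo",            5, 0.01, 0.01, 0.00,   NA,  0.00, "fiber",
    "Futura 75",       5, 3.18, 0.21, 0.18, 0.02,  0.05, "fiber",
    "C.S.",            5, 3.91, 0.36, 0.24, 0.02,  0.08, "fiber",
    "Tygra",           5, 1.97, 0.38, 0.31, 0.12,  0.18, "fiber",
    "Carmaleonte",     5, 2.68, 0.47, 0.15, 0.03,  0.05, "fiber",
    "60 Days Wonder",  3, 0.22, 0.19, 6.97, 3.64, 32.17, "drug",
    "BC God Bud",     11, 0.20, 0.08, 6.40, 3.89, 32.00, "drug",
    "Chocolate Kush",  4, 0.96, 0.77, 5.42, 2.75,  5.67, "drug",
    "Chocolope",       3, 0.44, 0.02, 5.65, 1.06, 12.84, "drug",
    "Flash Babylon",   2, 0.14, 0.18, 7.20, 0.30, 51.43, "drug",
    "Golden Berry",    2, 0.42, 0.35, 11.80, 4.30, 28.10, "drug",
    "Northern Light",  4, 1.81, 1.84, 6.40, 4.90,  3.53, "drug",
    "Shiatsu Kush",    8, 0.40, 0.19, 6.10, 3.39, 15.44, "drug",
    "Skunk #11",       4, 2.15, 1.34, 2.08, 0.77,  0.97, "drug",
    "Star Ryder",      4, 0.84, 1.04, 11.33, 3.28, 13.53, "drug",
    "UK Werkle",       2, 1.54, 1.79, 6.70, 4.70,  4.36, "drug")
}

#' Simulate a per-variety chemotype table
#'
#' Draws mean THC and CBD percentages per variety inside the class-specific
#' ranges the panel assumes: drug-type mean THC uniform on [2.08, 11.80] %
#' of dry weight, fiber-type mean THC uniform on [0, 0.31] %; CBD uniform
#' on [0.10, 2.20] (drug) and [0, 4.00] (fiber); SDs drawn as U(0.05, 0.4)
#' fractions of the mean. Reproducible under `config$seed`.
#'
#' @param config A [panel_config()].
#' @return A tibble with columns `variety`, `n_plants`, `cbd`, `sd_cbd`,
#'   `thc`, `sd_thc`, `class`.
#' @examples
#' simulate_chemotable(panel_config(seed = 1))
#' @export
simulate_chemotable <- function(config) {
  stopifnot(inherits(config, "panel_config"))
  .with_seed(config$seed + 1L, {
    drug_vars <- .variety_names("drug", config$n_drug_varieties)
    fiber_vars <- .variety_names("fiber", config$n_fiber_varieties)
    counts <- function(total, vars) {
      if (length(vars) == 0) return(integer(0))
      tabulate(rep(seq_along(vars), length.out = max(total, 0)),
               nbins = length(vars))
    }
    tab <- bind_rows(
      tibble(variety = drug_vars, class = "drug",
             n_plants = counts(config$n_drug_plants, drug_vars),
             thc = runif(length(drug_vars), 2.08, 11.80),
             cbd = runif(length(drug_vars), 0.10, 2.20)),
      tibble(variety = fiber_vars, class = "fiber",
             n_plants = counts(config$n_fiber_plants, fiber_vars),
             thc = runif(length(fiber_vars), 0, 0.31),
             cbd = runif(length(fiber_vars), 0, 4.00)))
    tab <- mutate(tab,
                  thc = round(.data$thc, 2), cbd = round(.data$cbd, 2),
                  sd_thc = round(.data$thc * runif(dplyr::n(), 0.05, 0.4), 2),
                  sd_cbd = round(.data$cbd * runif(dplyr::n(), 0.05, 0.4), 2))
    tab[, c("variety", "n_plants", "cbd", "sd_cbd", "thc", "sd_thc", "class")]
  })
}
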