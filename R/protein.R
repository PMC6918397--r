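# Protein-consequence prediction: translation with premature-stop
# detection, codon arithmetic, application of variants to a reference CDS,
# synonymous/non-synonymous classification and side-chain impact grading.

# amino-acid side-chain classes used for impact grading; standard
# hydropathy-style groupings, overridable via the `classes` argument
.aa_classes <- function() {
  list(hydrophobic = c("A", "V", "L", "I", "M", "F", "W", "C"),
       polar = c("S", "T", "N", "Q", "Y", "G"),
       charged = c("D", "E", "K", "R", "H"),
       ring = c("F", "W", "Y", "H", "P"))
}

#' Map a CDS nucleotide position to its codon index
#'
#' `ceiling(position / 3)`: nucleotides 1-3 are codon 1, 4-6 codon 2, and
#' so on.
#'
#' @param position 1-based CDS nucleotide position(s).
#' @return Integer codon index / amino-acid residue number.
#' @examples
#' codon_of(c(269, 494, 749, 763))
#' @export
codon_of <- function(position) {
  if (any(position < 1)) abort("positions are 1-based; must be >= 1")
  as.integer(ceiling(position / 3))
}

#' Translate a coding sequence
#'
#' Standard-genetic-code translation halting at the first in-frame stop
#' codon. The 1-based index of the terminating stop codon is recorded; by
#' the reporting convention used throughout the package, a premature stop
#' at codon index s is described as an "s amino-acid" truncated protein
#' (the strict residues-before-stop count would be s - 1). If no stop is
#' found the sequence is translated to its end and flagged.
#'
#' @param cds Coding sequence (character scalar over A/C/G/T, length >= 3;
#'   ambiguity codes must be resolved upstream).
#' @param gene Optional gene name carried through to the result.
#' @return A list of class `protein_record`: `gene`, `aa_sequence`,
#'   `stop_codon_index` (NA when no stop), `has_stop`, `n_codons`.
#' @examples
#' translate_cds("ATGAAATAA")$aa_sequence
#' @export
translate_cds <- function(cds, gene = NA_character_) {
  cds <- toupper(cds)
  if (nchar(cds) < 3) abort("CDS must be at least one codon long")
  chars <- strsplit(cds, "")[[1]]
  bad <- which(!chars %in% c("A", "C", "G", "T"))
  if (length(bad) > 0) {
    abort(paste0("non-ACGT character '", chars[bad[1]], "' at position ",
                 bad[1], "; resolve ambiguity codes before translating"))
  }
  n_codons <- floor(nchar(cds) / 3)
  starts <- 3 * seq_len(n_codons) - 2
  codons <- substring(cds, starts, starts + 2)
  aas <- unname(Biostrings::GENETIC_CODE[codons])
  stop_idx <- which(aas == "*")[1]
  if (is.na(stop_idx)) {
    aa_seq <- paste(aas, collapse = "")
    has_stop <- FALSE
  } else {
    aa_seq <- paste(aas[seq_len(stop_idx - 1)], collapse = "")
    has_stop <- TRUE
  }
  structure(list(gene = gene, aa_sequence = aa_seq,
                 stop_codon_index = if (has_stop) as.integer(stop_idx) else NA_integer_,
                 has_stop = has_stop, n_codons = n_codons),
            class = "protein_record")
}

#' @export
print.protein_record <- function(x, ...) {
  cat(sprintf("Protein%s: %d aa%s\n",
              if (is.na(x$gene)) "" else paste0(" (", x$gene, ")"),
              nchar(x$aa_sequence),
              if (x$has_stop) sprintf(", stop at codon %d", x$stop_codon_index)
              else ", no stop codon found"))
  invisible(x)
}

#' Apply homozygous variants to a reference CDS
#'
#' Applies SNPs, deletions and insertions (as produced by
#' [call_variants()] or listed in a panel's truth table) to a reference
#' coding sequence, working right-to-left so earlier coordinates stay
#' valid. Variants must be homozygous (single-base A/C/G/T alternates for
#' SNPs) and non-overlapping.
#'
#' @param ref A one-row data frame with columns `gene` and `cds`, or a
#'   character scalar CDS.
#' @param variants A data frame with columns `pos`, `kind`, `ref`, `alt`
#'   (and optionally `zygosity`); may have zero rows.
#' @return The mutant CDS (character scalar).
#' @export
apply_variants <- function(ref, variants) {
  cds <- if (is.data.frame(ref)) ref$cds[1] else as.character(ref)
  if (is.null(variants) || nrow(variants) == 0) return(cds)
  if ("zygosity" %in% names(variants) && any(variants$zygosity == "het")) {
    abort("heterozygous variants must be resolved before applying")
  }
  if (any(variants$kind == "snp" & !variants$alt %in% c("A", "C", "G", "T"))) {
    abort("SNP alternates must be single unambiguous bases")
  }
  len <- nchar(cds)
  if (any(variants$pos < 1 | variants$pos > len)) {
    abort("variant position beyond the CDS")
  }
  span <- function(v) {
    w <- nchar(v$ref)
    c(v$pos, v$pos + max(w, 1) - 1)
  }
  vs <- arrange(variants, .data$pos)
  if (nrow(vs) > 1) {
    for (i in seq_len(nrow(vs) - 1)) {
      # an insertion sits between pos and pos+1, so it may share `pos`
      # with a SNP; true overlaps are ref-consuming spans that intersect
      if (vs$kind[i] == "insertion" || vs$kind[i + 1] == "insertion") next
      if (span(vs[i, ])[2] >= span(vs[i + 1, ])[1]) {
        abort(paste0("overlapping variants at positions ", vs$pos[i],
                     " and ", vs$pos[i + 1]))
      }
    }
  }
  vs <- arrange(vs, dplyr::desc(.data$pos))
  for (i in seq_len(nrow(vs))) {
    p <- vs$pos[i]
    if (vs$kind[i] == "snp") {
      substr(cds, p, p) <- vs$alt[i]
    } else if (vs$kind[i] == "deletion") {
      w <- nchar(vs$ref[i])
      cds <- paste0(substring(cds, 1, p - 1), substring(cds, p + w))
    } else if (vs$kind[i] == "insertion") {
      cds <- paste0(substring(cds, 1, p), vs$alt[i], substring(cds, p + 1))
    } else {
      abort(paste0("unknown variant kind: ", vs$kind[i]))
    }
  }
  cds
}

# grade one substitution by the side-chain rules
.impact_of <- function(ref_aa, alt_aa, classes) {
  if (ref_aa == alt_aa) return("low")
  if (alt_aa == "*" || ref_aa == "*") return("high")
  in_set <- function(aa, set) aa %in% classes[[set]]
  hydro_charged <- (in_set(ref_aa, "hydrophobic") && in_set(alt_aa, "charged")) ||
    (in_set(ref_aa, "charged") && in_set(alt_aa, "hydrophobic"))
  if (hydro_charged) return("high")
  hydro_polar <- (in_set(ref_aa, "hydrophobic") && in_set(alt_aa, "polar")) ||
    (in_set(ref_aa, "polar") && in_set(alt_aa, "hydrophobic"))
  ring_fluid <- xor(in_set(ref_aa, "ring"), in_set(alt_aa, "ring"))
  if (hydro_polar || ring_fluid) return("moderate")
  "low"
}

#' Annotate the protein consequences of a variant set
#'
#' Classifies each SNP as synonymous or non-synonymous by evaluating every
#' affected codon with all co-located alternate alleles applied jointly:
#' if the codon's amino acid changes, each SNP in it counts as
#' non-synonymous (two SNPs in one changed codon are 2 non-synonymous
#' mutations but 1 amino-acid change). Substitution impact is graded by
#' side-chain class: hydrophobic vs charged is high impact; hydrophobic vs
#' polar, or ring/rigid vs fluid, is moderate; anything else (including
#' every synonymous change) is low. Indels are reported as
#' frameshift/in-frame events, and the full mutant CDS is translated to
#' detect premature stops and truncation.
#'
#' @param ref A one-row data frame with columns `gene` and `cds`, or a
#'   character scalar CDS.
#' @param variants A data frame of homozygous variants (`pos`, `kind`,
#'   `ref`, `alt`).
#' @param classes Side-chain class sets (see Details); override to change
#'   the grading.
#' @return A list of class `consequence_set`: `annotations` (tibble:
#'   `gene`, `codon_index`, `ref_aa`, `alt_aa`, `synonymous`, `impact`,
#'   `positions`), `summary` (one-row tibble: `n_snps`, `n_nonsyn`,
#'   `n_syn`, `nonsyn_syn_ratio`, `n_aa_changes`, `frameshift`,
#'   `truncated`, `stop_codon_index`, `ref_stop_codon_index`).
#' @export
annotate_consequences <- function(ref, variants, classes = .aa_classes()) {
  cds <- if (is.data.frame(ref)) ref$cds[1] else as.character(ref)
  gene <- if (is.data.frame(ref)) ref$gene[1] else NA_character_
  len <- nchar(cds)
  if (nrow(variants) > 0 && any(variants$pos < 1 | variants$pos > len)) {
    abort("variant position beyond the CDS")
  }
  snps <- variants[variants$kind == "snp", , drop = FALSE]
  indels <- variants[variants$kind != "snp", , drop = FALSE]

  ann <- tibble(gene = character(), codon_index = integer(),
                ref_aa = character(), alt_aa = character(),
                synonymous = logical(), impact = character(),
                positions = list())
  n_nonsyn <- 0L; n_syn <- 0L; n_aa_changes <- 0L
  if (nrow(snps) > 0) {
    snps$codon_index <- codon_of(snps$pos)
    rows <- lapply(split(snps, snps$codon_index), function(grp) {
      ci <- grp$codon_index[1]
      start <- 3 * ci - 2
      ref_codon <- substring(cds, start, start + 2)
      alt_codon <- ref_codon
      for (i in seq_len(nrow(grp))) {
        off <- grp$pos[i] - start + 1
        substr(alt_codon, off, off) <- grp$alt[i]
      }
      ref_aa <- unname(Biostrings::GENETIC_CODE[ref_codon])
      alt_aa <- unname(Biostrings::GENETIC_CODE[alt_codon])
      syn <- ref_aa == alt_aa
      tibble(gene = gene, codon_index = ci, ref_aa = ref_aa,
             alt_aa = alt_aa, synonymous = syn,
             impact = if (syn) "low" else .impact_of(ref_aa, alt_aa, classes),
             positions = list(grp$pos), n_snps_in_codon = nrow(grp))
    })
    ann <- bind_rows(rows) |> arrange(.data$codon_index)
    n_nonsyn <- sum(ann$n_snps_in_codon[!ann$synonymous])
    n_syn <- sum(ann$n_snps_in_codon[ann$synonymous])
    n_aa_changes <- sum(!ann$synonymous)
    ann$n_snps_in_codon <- NULL
  }

  frameshift <- nrow(indels) > 0 && any(
    (nchar(indels$ref) + nchar(indels$alt)) %% 3 != 0)

  mutant <- apply_variants(cds, variants)
  prot_ref <- translate_cds(cds, gene)
  prot_mut <- translate_cds(mutant, gene)
  truncated <- prot_mut$has_stop && prot_ref$has_stop &&
    prot_mut$stop_codon_index < prot_ref$stop_codon_index

  summary <- tibble(
    n_snps = nrow(snps), n_nonsyn = n_nonsyn, n_syn = n_syn,
    nonsyn_syn_ratio = if (n_syn > 0) n_nonsyn / n_syn else NA_real_,
    n_aa_changes = n_aa_changes, frameshift = frameshift,
    truncated = truncated,
    stop_codon_index = prot_mut$stop_codon_index,
    ref_stop_codon_index = prot_ref$stop_codon_index)
  structure(list(annotations = ann, summary = summary,
                 mutant_cds = mutant), class = "consequence_set")
}

#' @export
print.consequence_set <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    "Consequences: %d SNPs (%d non-syn / %d syn, %d aa changes%s)%s%s\n",
    s$n_snps, s$n_nonsyn, s$n_syn, s$n_aa_changes,
    if (is.na(s$nonsyn_syn_ratio)) ""
    else sprintf(", ratio %.1f", s$nonsyn_syn_ratio),
    if (s$frameshift) "; frameshift" else "",
    if (s$truncated) sprintf("; truncated at codon %d", s$stop_codon_index)
    else ""))
  invisible(x)
}

#' Literature deleteriousness annotations
#'
#' PROVEAN-reported deleterious substitutions for the two synthase
#' proteins, stored as annotations (this package does not recompute
#' structure-based deleteriousness): THCAS residue 165, and CBDAS residues
#' 136 (Arg/His) and 182 (Gly/Ala).
#'
#' @return A tibble with columns `gene`, `residue`, `ref_aa`, `alt_aa`,
#'   `call`, `source`.
#' @export
provean_annotations <- function() {
  tibble::tribble(
    ~gene, ~residue, ~ref_aa, ~alt_aa, ~call, ~source,
    "THCAS", 165L, NA_character_, NA_character_, "deleterious", "PROVEAN (literature)",
    "CBDAS", 136L, "R", "H", "deleterious", "PROVEAN (literature)",
    "CBDAS", 182L, "G", "A", "deleterious", "PROVEAN (literature)")
}
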