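# Variant discovery: global alignment of each sample gene sequence to its
# reference CDS, SNP/indel calls in 1-based reference CDS coordinates, and
# assembly of the samples-by-loci categorical genotype matrix.

#' Globally align a sample sequence to a reference CDS
#'
#' Needleman-Wunsch global alignment with affine gap scoring (a gap of
#' length L costs `gap_open + L * gap_extend`), computed with
#' `Biostrings::pairwiseAlignment()`. IUPAC ambiguity codes in the sample
#' are scored by base-set overlap. The default scores favour one contiguous
#' indel over scattered mismatches, which keeps multi-base events such as a
#' 4-bp deletion in a single gap.
#'
#' @param sample_seq Sample sequence (character scalar, A/C/G/T/N/IUPAC).
#' @param ref_seq Reference CDS (character scalar, A/C/G/T).
#' @param match,mismatch,gap_open,gap_extend Alignment scores; penalties are
#'   negative.
#' @return A list of class `cm_alignment` with `pattern` and `subject`
#'   (gapped aligned strings, sample and reference respectively) and
#'   `score`.
#' @examples
#' align_global("ACGTT", "ACGT")$score
#' @export
align_global <- function(sample_seq, ref_seq,
                         match = 2, mismatch = -3,
                         gap_open = -5, gap_extend = -2) {
  if (!nzchar(sample_seq) || !nzchar(ref_seq)) {
    abort("align_global() requires non-empty sequences")
  }
  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE, type = "DNA")
  pa <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::DNAString(sample_seq),
    subject = Biostrings::DNAString(ref_seq),
    type = "global", substitutionMatrix = mat,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  structure(list(
    pattern = as.character(Biostrings::alignedPattern(pa)[[1]]),
    subject = as.character(Biostrings::alignedSubject(pa)[[1]]),
    score = Biostrings::score(pa)), class = "cm_alignment")
}

# left-normalize an indel: shift left while the flanking reference base
# equals the last base of the event allele (standard VCF-style rotation)
.left_normalize <- function(pos, allele, ref_chars, is_deletion) {
  len <- length(allele)
  if (len == 0) return(list(pos = pos, allele = allele))
  repeat {
    flank <- if (is_deletion) pos - 1L else pos
    if (flank < 1L || ref_chars[flank] != allele[len]) break
    allele <- c(ref_chars[flank], allele[-len])
    pos <- pos - 1L
  }
  list(pos = pos, allele = allele)
}

#' Call SNPs and indels from a global alignment
#'
#' Walks the aligned columns and emits one call per difference: mismatched
#' bases become SNPs (an IUPAC ambiguity code in the sample is reported as
#' a heterozygous call), runs of adjacent gap columns are merged into
#' single deletion/insertion events, and indels are left-normalised so
#' coordinates are deterministic inside repeats. Positions are 1-based on
#' the reference CDS; a deletion is reported at its first deleted base and
#' an insertion at the reference base after which the bases are inserted.
#' `N` in the sample is treated as missing data, not a variant.
#'
#' @param alignment A `cm_alignment` from [align_global()].
#' @param ref A one-row data frame with columns `gene` and `cds` (as in
#'   [make_references()]), or a character scalar (gene name then `""`).
#' @return A tibble with columns `gene`, `pos`, `kind`
#'   (`"snp"`/`"deletion"`/`"insertion"`), `ref`, `alt`, `zygosity`.
#' @export
call_variants <- function(alignment, ref) {
  stopifnot(inherits(alignment, "cm_alignment"))
  if (is.data.frame(ref)) {
    gene <- ref$gene[1]; ref_cds <- ref$cds[1]
  } else {
    gene <- NA_character_; ref_cds <- as.character(ref)
  }
  pat <- strsplit(alignment$pattern, "")[[1]]
  sub <- strsplit(alignment$subject, "")[[1]]
  if (length(pat) != length(sub)) abort("malformed alignment")
  if (paste(sub[sub != "-"], collapse = "") != ref_cds) {
    abort("alignment does not cover the full reference CDS")
  }
  ref_chars <- sub[sub != "-"]

  # reference position of each column (position after which an insertion sits)
  ref_pos <- cumsum(sub != "-")

  calls <- list()
  # SNPs: both non-gap, different, sample not N
  snp_cols <- which(pat != "-" & sub != "-" & pat != sub & pat != "N")
  for (j in snp_cols) {
    alt <- pat[j]
    calls[[length(calls) + 1]] <- tibble(
      gene = gene, pos = ref_pos[j], kind = "snp",
      ref = sub[j], alt = alt,
      zygosity = if (alt %in% c("A", "C", "G", "T")) "hom" else "het")
  }
  # deletions: runs of gaps in the sample
  r <- rle(pat == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    cols <- starts[k]:ends[k]
    del_seq <- sub[cols]
    norm <- .left_normalize(ref_pos[cols[1]], del_seq, ref_chars, TRUE)
    calls[[length(calls) + 1]] <- tibble(
      gene = gene, pos = norm$pos, kind = "deletion",
      ref = paste(norm$allele, collapse = ""), alt = "", zygosity = "hom")
  }
  # insertions: runs of gaps in the reference
  r <- rle(sub == "-")
  ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
  for (k in which(r$values)) {
    cols <- starts[k]:ends[k]
    ins_seq <- pat[cols]
    after <- ref_pos[cols[1]]  # position preceding the gap run
    norm <- .left_normalize(after, ins_seq, ref_chars, FALSE)
    calls[[length(calls) + 1]] <- tibble(
      gene = gene, pos = norm$pos, kind = "insertion",
      ref = "", alt = paste(norm$allele, collapse = ""), zygosity = "hom")
  }
  if (length(calls) == 0) {
    return(tibble(gene = character(), pos = integer(), kind = character(),
                  ref = character(), alt = character(), zygosity = character()))
  }
  arrange(bind_rows(calls), .data$pos, .data$kind)
}

#' Call variants for every sample of a panel
#'
#' Convenience wrapper: aligns each `sample|gene` sequence to its gene's
#' reference CDS with [align_global()] and calls variants with
#' [call_variants()].
#'
#' @param sequences A data frame with columns `sample_id`, `gene`,
#'   `sequence` (as produced by [simulate_panel()] or [read_fasta()]).
#' @param references A data frame with columns `gene` and `cds`.
#' @param ... Passed to [align_global()].
#' @return A tibble of calls with a leading `sample_id` column.
#' @export
call_panel_variants <- function(sequences, references, ...) {
  stopifnot(all(c("sample_id", "gene", "sequence") %in% names(sequences)),
            all(c("gene", "cds") %in% names(references)))
  missing_ref <- setdiff(unique(sequences$gene), references$gene)
  if (length(missing_ref) > 0) {
    abort(paste0("no reference for gene(s): ",
                 paste(missing_ref, collapse = ", ")))
  }
  purrr::pmap(sequences[, c("sample_id", "gene", "sequence")],
              function(sample_id, gene, sequence) {
                ref <- references[references$gene == gene, , drop = FALSE]
                if (sequence == ref$cds[1]) {  # identical: nothing to align
                  return(tibble(sample_id = character(), gene = character(),
                                pos = integer(), kind = character(),
                                ref = character(), alt = character(),
                                zygosity = character()))
                }
                al <- align_global(sequence, ref$cds[1], ...)
                calls <- call_variants(al, ref)
                calls$sample_id <- rep(sample_id, nrow(calls))
                calls[, c("sample_id", setdiff(names(calls), "sample_id"))]
              }) |> bind_rows()
}

.locus_name <- function(gene, pos, kind) {
  suffix <- c(snp = "", deletion = "_del", insertion = "_ins")[kind]
  paste0(gene, "_", pos, suffix)
}

#' Assemble the samples-by-loci genotype matrix
#'
#' Builds a wide tibble with one row per sample (`sample_id`, `class`) and
#' one categorical column per locus. SNP cells hold the sample's allele
#' symbol (base or IUPAC code) or `"ref"`; indel loci are encoded
#' presence/absence as `"del"`/`"ins"` vs `"ref"`. Cells default to `"ref"`
#' wherever a sample has no call. Locus metadata (gene, position, kind,
#' reference allele) is attached as the `"loci"` attribute and retrievable
#' with [locus_info()].
#'
#' @param calls A calls tibble (`sample_id`, `gene`, `pos`, `kind`, `ref`,
#'   `alt`, `zygosity`), e.g. from [call_panel_variants()].
#' @param labels A data frame with columns `sample_id` and `class`
#'   (`"drug"`/`"fiber"`); defines the full sample set, including samples
#'   with no calls.
#' @param loci Optional restriction: a data frame with columns `gene`,
#'   `pos` (and optionally `kind`) keeping only those loci.
#' @return A `cm_genotypes` tibble.
#' @export
build_matrix <- function(calls, labels, loci = NULL) {
  stopifnot(all(c("sample_id", "class") %in% names(labels)))
  if (anyDuplicated(labels$sample_id)) {
    abort(paste0("duplicate sample id: ",
                 labels$sample_id[duplicated(labels$sample_id)][1]))
  }
  if (nrow(calls) > 0 && !all(calls$sample_id %in% labels$sample_id)) {
    abort("calls contain sample ids absent from labels")
  }
  locus_tab <- if (nrow(calls) > 0) {
    dplyr::distinct(calls, .data$gene, .data$pos, .data$kind, .data$ref) |>
      group_by(.data$gene, .data$pos, .data$kind) |>
      summarise(ref_allele = .data$ref[1], .groups = "drop")
  } else {
    tibble(gene = character(), pos = integer(), kind = character(),
           ref_allele = character())
  }
  if (!is.null(loci)) {
    keep_kind <- if ("kind" %in% names(loci)) loci$kind else NULL
    key <- paste(loci$gene, loci$pos,
                 if (is.null(keep_kind)) "" else keep_kind)
    have <- paste(locus_tab$gene, locus_tab$pos,
                  if (is.null(keep_kind)) "" else locus_tab$kind)
    locus_tab <- locus_tab[have %in% key, , drop = FALSE]
  }
  locus_tab <- arrange(locus_tab, .data$gene, .data$pos, .data$kind)
  locus_tab <- mutate(locus_tab,
                      locus = .locus_name(.data$gene, .data$pos, .data$kind),
                      .before = 1)

  out <- tibble(sample_id = labels$sample_id, class = labels$class)
  cells <- matrix("ref", nrow = nrow(out), ncol = nrow(locus_tab),
                  dimnames = list(NULL, locus_tab$locus))
  if (nrow(calls) > 0 && nrow(locus_tab) > 0) {
    calls2 <- mutate(calls, locus = .locus_name(.data$gene, .data$pos, .data$kind))
    calls2 <- calls2[calls2$locus %in% locus_tab$locus, , drop = FALSE]
    ri <- match(calls2$sample_id, out$sample_id)
    ci <- match(calls2$locus, locus_tab$locus)
    sym <- ifelse(calls2$kind == "snp", calls2$alt,
                  ifelse(calls2$kind == "deletion", "del", "ins"))
    cells[cbind(ri, ci)] <- sym
  }
  out <- bind_cols(out, as_tibble(cells))
  attr(out, "loci") <- locus_tab
  class(out) <- c("cm_genotypes", class(out))
  out
}

#' Locus metadata of a genotype matrix
#'
#' Returns the per-locus table (locus name, gene, position, kind, reference
#' allele) attached by [build_matrix()]. If the attribute was stripped by
#' data manipulation, gene/position/kind are re-parsed from the column
#' names.
#'
#' @param genotypes A genotype matrix tibble.
#' @return A tibble with columns `locus`, `gene`, `pos`, `kind`,
#'   `ref_allele`.
#' @export
locus_info <- function(genotypes) {
  tab <- attr(genotypes, "loci")
  cols <- setdiff(names(genotypes), c("sample_id", "class"))
  if (!is.null(tab) && all(cols %in% tab$locus)) {
    return(tab[match(cols, tab$locus), , drop = FALSE])
  }
  m <- stringr::str_match(cols, "^(.*)_(\\d+)(_del|_ins)?$")
  if (anyNA(m[, 1])) abort("cannot parse locus columns; rebuild with build_matrix()")
  tibble(locus = cols, gene = m[, 2], pos = as.integer(m[, 3]),
         kind = dplyr::case_match(m[, 4], "_del" ~ "deletion",
                                  "_ins" ~ "insertion", .default = "snp"),
         ref_allele = NA_character_)
}

# locus columns of a genotype matrix, in order
.locus_cols <- function(genotypes) {
  setdiff(names(genotypes), c("sample_id", "class"))
}
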