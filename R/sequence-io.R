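# FASTA reading/writing and Sanger-style consensus merging.
#
# Sequences are plain uppercase DNA over {A,C,G,T,N,-} plus the 15 IUPAC
# ambiguity codes; heterozygous Sanger calls are carried as IUPAC codes
# (e.g. R = A/G) all the way through variant calling and scoring.

.fasta_alphabet <- c("A", "C", "G", "T", "N", "-",
                     "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

#' IUPAC ambiguity code utilities
#'
#' `iupac_bases()` expands a single-character nucleotide symbol to the set of
#' bases it denotes (e.g. `"R"` to `c("A","G")`); `iupac_code()` is the
#' inverse, mapping a non-empty base set to its IUPAC code. The 15 standard
#' codes are a bijection with the non-empty subsets of {A,C,G,T}.
#'
#' @param code Single character: a base or IUPAC ambiguity code.
#' @param bases Character vector of bases from {A,C,G,T}.
#' @return `iupac_bases()`: character vector of bases. `iupac_code()`: a
#'   single character.
#' @examples
#' iupac_bases("R")
#' iupac_code(c("A", "G"))
#' @export
iupac_bases <- function(code) {
  code <- toupper(code)
  map <- Biostrings::IUPAC_CODE_MAP
  if (!code %in% names(map)) {
    abort(paste0("not an IUPAC nucleotide code: '", code, "'"))
  }
  strsplit(map[[code]], "")[[1]]
}

#' @rdname iupac_bases
#' @export
iupac_code <- function(bases) {
  bases <- sort(unique(toupper(bases)))
  if (length(bases) == 0 || !all(bases %in% c("A", "C", "G", "T"))) {
    abort("bases must be a non-empty subset of {A, C, G, T}")
  }
  map <- Biostrings::IUPAC_CODE_MAP
  key <- paste(bases, collapse = "")
  rev_map <- setNames(names(map), vapply(
    map, function(x) paste(sort(strsplit(x, "")[[1]]), collapse = ""), ""))
  unname(rev_map[[key]])
}

.validate_bases <- function(seqs, ids) {
  for (i in seq_along(seqs)) {
    chars <- strsplit(seqs[[i]], "")[[1]]
    bad <- which(!chars %in% .fasta_alphabet)
    if (length(bad) > 0) {
      abort(paste0("illegal character '", chars[bad[1]], "' at position ",
                   bad[1], " in record '", ids[[i]], "'"))
    }
  }
  invisible(TRUE)
}

#' Read and write FASTA files of gene sequences
#'
#' `read_fasta()` parses a (wrapped or unwrapped) FASTA file into a tibble,
#' uppercasing bases and converting U to T; `write_fasta()` writes such a
#' tibble back out, wrapped at 70 columns. The two round-trip exactly.
#' Record ids of the form `sample|gene` (the convention used by
#' [simulate_panel()]) are split into `sample_id` and `gene` columns on read.
#'
#' @param path File path.
#' @param records A data frame with columns `id` and `sequence`.
#' @return `read_fasta()`: a tibble with columns `id`, `sequence`, and (when
#'   every id contains a single `|`) `sample_id` and `gene`. `write_fasta()`:
#'   the path, invisibly.
#' @export
read_fasta <- function(path) {
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0) abort(paste0("no FASTA records in ", path))
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    abort(paste0("duplicate record id '", ids[duplicated(ids)][1], "' in ", path))
  }
  seqs <- chartr("Uu", "Tt", as.character(set))
  seqs <- toupper(seqs)
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for record '", ids[which(nchar(seqs) == 0)[1]], "'"))
  }
  .validate_bases(seqs, ids)
  out <- tibble(id = ids, sequence = unname(seqs))
  if (all(vapply(strsplit(ids, "\\|"), length, 1L) == 2)) {
    parts <- strsplit(ids, "\\|")
    out$sample_id <- vapply(parts, `[[`, "", 1)
    out$gene <- vapply(parts, `[[`, "", 2)
  }
  out
}

#' @rdname read_fasta
#' @export
write_fasta <- function(records, path) {
  stopifnot(is.data.frame(records), all(c("id", "sequence") %in% names(records)))
  .validate_bases(records$sequence, records$id)
  lines <- unlist(purrr::map2(records$id, records$sequence, function(id, s) {
    body <- substring(s, seq(1, nchar(s), 70), pmin(seq(1, nchar(s), 70) + 69, nchar(s)))
    c(paste0(">", id), body)
  }))
  writeLines(lines, path)
  invisible(path)
}

#' Merge co-aligned reads into a consensus sequence
#'
#' Builds a per-sample consensus from forward/reverse Sanger reads that have
#' already been aligned to a common coordinate system (equal lengths, `-` for
#' gaps). In each column the fraction of non-gap reads supporting each base
#' is computed (an ambiguity code supports none of A/C/G/T exactly); if one
#' base reaches `min_agreement` it is emitted, otherwise the IUPAC code of
#' the union of all observed base sets is emitted. Columns that are gap in
#' every read are dropped, so a single read merges to itself with gaps
#' stripped.
#'
#' @param reads Character vector of equal-length aligned sequences (or a data
#'   frame with a `sequence` column).
#' @param min_agreement Fraction of non-gap reads a base must reach to be
#'   called outright; default 1 (any conflict becomes an ambiguity code),
#'   conservative for Sanger consensus work.
#' @return A single consensus sequence (character scalar).
#' @examples
#' merge_reads(c("ACGT", "ACGT"))
#' merge_reads(c("AA", "AG"))  # second column becomes "R"
#' @export
merge_reads <- function(reads, min_agreement = 1) {
  if (is.data.frame(reads)) reads <- reads$sequence
  if (length(reads) == 0) abort("merge_reads() needs at least one read")
  reads <- toupper(reads)
  lens <- nchar(reads)
  if (length(unique(lens)) != 1) {
    abort("reads must be pre-aligned to equal length")
  }
  .validate_bases(reads, paste0("read", seq_along(reads)))
  mat <- do.call(rbind, strsplit(reads, ""))
  cols <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(NA_character_)
    base_frac <- vapply(c("A", "C", "G", "T"),
                        function(b) mean(col == b), 0)
    if (max(base_frac) >= min_agreement) {
      return(names(base_frac)[which.max(base_frac)])
    }
    iupac_code(unique(unlist(lapply(col, iupac_bases))))
  })
  paste(cols[!is.na(cols)], collapse = "")
}
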