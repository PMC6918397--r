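# End-to-end orchestration: simulate -> align/call -> scan -> consensus
# score -> evaluate -> structure/chemotype -> protein consequences, as one
# seeded, reproducible run with a machine-readable report.

#' Run the full marker-discovery pipeline on a synthetic panel
#'
#' Generates (or accepts) a panel, calls variants for every sample against
#' the references, scans loci with Firth regression + BH correction,
#' builds consensus scores with AUC-optimized weights for each requested
#' `k`, evaluates the published-style indel score and the optimized scores
#' at threshold 0 with bootstrap CIs, computes Gower/MDS coordinates and
#' entropy summaries over chemotype groups, annotates the protein
#' consequences of the planted marker sets, and assembles a report. All
#' randomness derives from `config$seed`, so reruns are identical.
#'
#' @param config A [panel_config()].
#' @param q FDR level for the locus scan (default 0.05).
#' @param k_values Values of k for [optimize_weights()] (default 1).
#' @param B Bootstrap resamples for [evaluate_score()] (default 2000).
#' @param out_dir Optional directory; when given, tables are written as
#'   CSV/TSV and the report as JSON.
#' @return A list of class `cm_run` with elements `panel`, `calls`,
#'   `genotypes`, `scan`, `profile`, `specs`, `evaluations`,
#'   `indel_evaluation`, `chem`, `mds`, `entropy`, `protein`, `report`.
#' @export
run_pipeline <- function(config, q = 0.05, k_values = 1, B = 2000,
                         out_dir = NULL) {
  stopifnot(inherits(config, "panel_config"))
  notices <- character(0)

  panel <- simulate_panel(config)
  calls <- call_panel_variants(panel$sequences, panel$references)
  genotypes <- build_matrix(calls,
                            labels = panel$metadata[, c("sample_id", "class")])
  scan <- scan_loci(genotypes, q = q)
  sig <- scan$locus[scan$significant]

  specs <- list(); evaluations <- list(); profile <- NULL
  if (length(sig) == 0) {
    notices <- c(notices, "no significant loci; scoring stage skipped")
  } else {
    profile <- consensus_profile(genotypes, sig)
    for (k in k_values) {
      if (k > length(sig)) {
        notices <- c(notices, paste0("k = ", k, " exceeds ", length(sig),
                                     " significant loci; skipped"))
        next
      }
      sp <- optimize_weights(genotypes, profile, k = k)
      sc <- score_samples(genotypes, sp, profile)
      ev <- evaluate_score(sc, threshold = sp$threshold, B = B,
                           seed = config$seed + 2L)
      specs[[paste0("k", k)]] <- sp
      evaluations[[paste0("k", k)]] <- ev
    }
  }

  indel_eval <- NULL
  ispec <- indel_score_spec(
    del_locus = .locus_name(config$gene_names[2], config$deletion_start,
                            "deletion"),
    ins_locus = .locus_name(config$gene_names[2], config$insertion_pos,
                            "insertion"))
  if (all(ispec$loci %in% names(genotypes))) {
    isc <- score_samples(genotypes, ispec)
    indel_eval <- evaluate_score(isc, threshold = 0, B = B,
                                 seed = config$seed + 3L)
  } else {
    notices <- c(notices, "indel loci not called; indel score skipped")
  }

  chem <- chem_ratio_and_group(simulate_chemotable(config))
  sample_group <- chem$group[match(panel$metadata$variety, chem$variety)]
  d <- gower_distance(genotypes)
  mds <- classical_mds(d, dims = 2)
  entropy <- entropy_summary(genotypes, groups = sample_group)

  truth <- panel$truth$loci
  refs <- panel$references
  var_a <- truth[truth$gene == refs$gene[1] & truth$kind == "snp", ] |>
    mutate(alt = .data$fiber_allele) |> select("pos", "kind", "ref_allele", "alt") |>
    rename(ref = "ref_allele")
  var_b_snp <- truth[truth$gene == refs$gene[2] & truth$kind == "snp", ] |>
    mutate(alt = .data$drug_allele) |> select("pos", "kind", "ref_allele", "alt") |>
    rename(ref = "ref_allele")
  var_b_indel <- tibble(
    pos = c(config$deletion_start, config$insertion_pos),
    kind = c("deletion", "insertion"),
    ref = c(truth$ref_allele[truth$kind == "deletion"], ""),
    alt = c("", config$insertion_seq))
  protein <- list(
    thcas = annotate_consequences(refs[1, ], var_a),
    cbdas_snps_only = annotate_consequences(refs[2, ], var_b_snp),
    cbdas_full = annotate_consequences(refs[2, ],
                                       bind_rows(var_b_snp, var_b_indel)))

  report <- list(
    seed = config$seed,
    n_samples = nrow(panel$metadata),
    n_loci_called = length(.locus_cols(genotypes)),
    n_tested = nrow(scan),
    n_significant = length(sig),
    q = q,
    auc_by_k = purrr::map_dbl(specs, "auc"),
    indel_metrics = if (!is.null(indel_eval)) {
      setNames(indel_eval$metrics$estimate, indel_eval$metrics$metric)
    },
    thcas_consequences = as.list(protein$thcas$summary),
    cbdas_stop_codon = protein$cbdas_snps_only$summary$stop_codon_index,
    notices = notices)

  run <- structure(list(panel = panel, calls = calls, genotypes = genotypes,
                        scan = scan, profile = profile, specs = specs,
                        evaluations = evaluations,
                        indel_evaluation = indel_eval, chem = chem,
                        mds = mds, entropy = entropy, protein = protein,
                        report = report), class = "cm_run")
  if (!is.null(out_dir)) .write_run(run, out_dir)
  run
}

.write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(run$calls, file.path(out_dir, "calls.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(run$genotypes, file.path(out_dir, "genotypes.csv"),
                   row.names = FALSE)
  utils::write.table(run$scan, file.path(out_dir, "scan.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  utils::write.csv(run$mds, file.path(out_dir, "mds_coordinates.csv"),
                   row.names = FALSE)
  utils::write.csv(run$chem, file.path(out_dir, "chemotypes.csv"),
                   row.names = FALSE)
  write_fasta(dplyr::transmute(run$panel$sequences, id = .data$id,
                               sequence = .data$sequence),
              file.path(out_dir, "sequences.fasta"))
  specs_json <- purrr::map(run$specs, function(sp) {
    list(loci = sp$loci, weights = sp$weights, threshold = sp$threshold,
         auc = sp$auc)
  })
  jsonlite::write_json(specs_json, file.path(out_dir, "score_specs.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(run$report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}

#' @export
print.cm_run <- function(x, ...) {
  r <- x$report
  cat("Marker-discovery pipeline run\n")
  cat(sprintf("  %d samples, %d loci called, %d tested, %d significant (q = %g)\n",
              r$n_samples, r$n_loci_called, r$n_tested, r$n_significant, r$q))
  if (length(r$auc_by_k)) {
    cat("  optimized score AUC:",
        paste(sprintf("%s = %.4f", names(r$auc_by_k), r$auc_by_k),
              collapse = ", "), "\n")
  }
  if (!is.null(r$indel_metrics)) {
    cat(sprintf("  indel score: AUC %.4f, sens %.4f, spec %.4f\n",
                r$indel_metrics[["auc"]], r$indel_metrics[["sensitivity"]],
                r$indel_metrics[["specificity"]]))
  }
  for (n in r$notices) cat("  note:", n, "\n")
  invisible(x)
}
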