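# End-to-end orchestration: simulate -> assign -> QC -> repeats -> factors
# -> hits (-> enrichment), with a machine-readable report.

#' Run the full synthetic screen pipeline
#'
#' Executes every stage in dependency order on a seeded synthetic screen:
#' guide library, cells and ground truth, amplicon read generation and
#' sgRNA-to-cell assignment, cell/gene QC and normalization, repeat read
#' mapping and UMI collapsing, the multi-view factor fit, ZGA-factor
#' identification, the activation filter and per-sgRNA hit calling.
#' Rerunning with the same configuration reproduces every output.
#'
#' @param config A [simulation_config()].
#' @param profile QC profile; `NULL` (the default) uses
#'   [qc_profile_for_config()], the desk-style profile matched to the
#'   generator's scale.
#' @param K Number of factors.
#' @param fdr Hit-calling FDR threshold.
#' @param use_amplicon_reads Assign sgRNAs from simulated amplicon reads;
#'   if `FALSE`, the ground-truth assignment of singlet cells is used.
#' @param use_repeat_reads Quantify repeat families from simulated repeat
#'   reads; if `FALSE`, the simulated molecule table is used directly.
#' @param min_repeat_reads Family filter threshold; `NULL` scales the
#'   full-scale default of 1,000 reads (at ~200,000 cells) to the actual
#'   cell count.
#' @param do_enrichment Also run per-hit DGE and the cumulative
#'   signature-rank enrichment against the non-targeting background
#'   (costly; off by default).
#' @param keep_data Keep the filtered count matrix, the normalized matrix
#'   and the repeat counts inside the report (hundreds of MB at full
#'   scale; off by default).
#' @param outdir If given, all intermediates and results are written there
#'   in plain-text formats (TSV/MTX/FASTQ/JSON/YAML).
#' @param verbose Print stage progress.
#' @return A `screen_report` list: stage counts, assignment summary, QC
#'   report, factor fit, ZGA-factor table, hit table, ground truth, and
#'   (optionally) enrichment results.
#' @export
run_screen_pipeline <- function(config,
                                profile = NULL,
                                K = 5, fdr = 0.10,
                                use_amplicon_reads = TRUE,
                                use_repeat_reads = TRUE,
                                min_repeat_reads = NULL,
                                do_enrichment = FALSE,
                                keep_data = FALSE,
                                outdir = NULL,
                                verbose = FALSE) {
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- Sys.time()
  if (is.null(profile)) profile <- qc_profile_for_config(config)

  say("stage 1/7: guide library")
  lib <- generate_library(config)

  say("stage 2/7: cells and ground truth")
  sim <- generate_cells(config, lib)
  mat <- sim$matrix
  truth <- sim$truth

  say("stage 3/7: sgRNA assignment")
  if (use_amplicon_reads) {
    reads <- generate_amplicon_reads(config, truth, lib)
    matched <- match_reads(reads, lib)
    assignments <- assign_cells(matched)
  } else {
    singlet <- is.na(truth$cells$guide2)
    assignments <- data.frame(
      cell_barcode = truth$cells$barcode[singlet],
      category = "unique",
      assigned_guide = truth$cells$guide1[singlet],
      support_reads = NA_integer_, total_reads = NA_integer_,
      support_fraction = NA_real_, stringsAsFactors = FALSE
    )
    class(assignments) <- c("cell_assignment", "data.frame")
    matched <- NULL
  }
  assignment_summary <- summarize_assignments(assignments)

  say("stage 4/7: quality control")
  qc1 <- filter_cells(mat, profile)
  qc_report <- attr(qc1, "qc_report")
  qc2 <- filter_genes(qc1, profile$min_cells_per_gene)
  kept_assign <- match_barcodes(assignments, qc2$cell_meta$barcode)
  uniq <- kept_assign[kept_assign$category == "unique", , drop = FALSE]
  keep_cells <- match(uniq$cell_barcode, qc2$cell_meta$barcode)
  mat2 <- qc2
  mat2$counts <- qc2$counts[keep_cells, , drop = FALSE]
  if (!is.null(qc2$repeat_counts)) {
    mat2$repeat_counts <- qc2$repeat_counts[keep_cells, , drop = FALSE]
  }
  mat2$cell_meta <- qc2$cell_meta[keep_cells, , drop = FALSE]
  mat2$cell_meta$assigned_guide <- uniq$assigned_guide
  rownames(mat2$cell_meta) <- NULL
  stop_if_not(nrow(mat2$counts) > 0, "no uniquely assigned QC-passed cells")

  say("stage 5/7: repeat quantification")
  thr <- min_repeat_reads %||% max(50, round(1000 * nrow(mat2$counts) / 2e5))
  if (use_repeat_reads) {
    ref <- synthetic_repeat_reference(seed = config$seed + 4L)
    rreads <- generate_repeat_reads(config, truth, ref)
    rreads$family <- map_read_to_family(rreads, ref)
    rc <- collapse_umis(rreads, barcodes = mat2$cell_meta$barcode)
  } else {
    counts <- mat2$repeat_counts
    rc <- structure(list(counts = counts, family_reads = colSums(counts),
                         n_reads = c(total = sum(counts),
                                     mapped = sum(counts),
                                     unmapped = 0L, ambiguous = 0L)),
                    class = "repeat_counts")
  }
  rc <- filter_families(rc, thr)

  say("stage 6/7: normalization, HVGs, factor fit")
  norm <- normalize_log(mat2)
  # HVG mean bounds relative to the dataset's average back-scaled
  # expression (scale_factor / n_genes), so the published absolute bounds
  # (0.01, 5) at ~20k genes transfer to the synthetic gene count
  avg <- norm$scale_factor / ncol(norm$values)
  norm <- select_hvg(norm, min_mean = avg / 50, max_mean = 10 * avg)
  total <- mat2$cell_meta$total_umis
  rep_view <- log1p(rc$counts * (norm$scale_factor / total))
  gene_view <- norm$values[, norm$hvg_mask, drop = FALSE]
  colnames(gene_view) <- norm$gene_meta$gene_id[norm$hvg_mask]
  guides <- mat2$cell_meta$assigned_guide
  fit <- fit_factors(list(genes = gene_view, repeats = rep_view),
                     groups = guides, K = K)
  zga <- identify_zga_factor(fit, truth$signature_genes)
  zga_confident <- !is.na(zga$factor_index)
  factor_index <- zga$factor_index
  if (!zga_confident) {
    # fall back to the best-enriched factor so a hit table is always
    # produced; the report flags the identification as not confident
    pe <- zga$table$p_enrichment
    factor_index <- if (all(is.na(pe))) 1L else which.min(pe)
  }
  z <- fit$Z[, factor_index]
  # orient the factor so that higher values mean more ZGA-like: the summed
  # loading of the signature genes is made positive
  sig_load <- sum(fit$W$genes[rownames(fit$W$genes) %in%
                                truth$signature_genes, factor_index])
  if (is.finite(sig_load) && sig_load < 0) z <- -z

  say("stage 7/7: activation filter and hit calling")
  activation <- suppressWarnings(activation_filter(norm, lib))
  hits <- call_hits(z, guides, lib, activation, fdr = fdr)

  enrichment <- NULL
  if (do_enrichment) {
    say("optional stage: DGE enrichment for hit sgRNAs")
    nt_guides <- lib$guide_id[!lib$is_targeting]
    is_nt <- guides %in% nt_guides
    band <- nt_background(mat2$counts[is_nt, , drop = FALSE],
                          guides[is_nt], truth$signature_genes,
                          libsize = total[is_nt])
    hit_ids <- hits$sgrna_id[hits$is_hit]
    curves <- lapply(hit_ids, function(g) {
      sel <- is_nt | guides == g
      dge <- nb_glm_lrt(mat2$counts[sel, , drop = FALSE],
                        guides[sel] == g, libsize = total[sel])
      cumulative_zga_curve(rank_upregulated(dge), truth$signature_genes)
    })
    names(curves) <- hit_ids
    enrichment <- list(
      band = band,
      curves = curves,
      overlaps_background = vapply(curves, enrichment_call, TRUE,
                                   band = band)
    )
  }

  report <- structure(list(
    config = config,
    library = lib,
    truth = truth,
    counts = list(
      n_guides = nrow(lib),
      n_cells_simulated = nrow(mat$counts),
      n_amplicon_reads = if (is.null(matched)) NA_integer_ else nrow(matched),
      n_cells_qc = nrow(qc2$counts),
      n_genes_qc = ncol(qc2$counts),
      n_cells_unique_qc = nrow(mat2$counts),
      n_hvg = sum(norm$hvg_mask),
      n_repeat_families = ncol(rc$counts),
      n_activation_pass = sum(activation$passes_activation),
      n_tested = nrow(hits),
      n_hits = sum(hits$is_hit)
    ),
    assignment_summary = assignment_summary,
    qc_report = qc_report,
    factor_fit = fit,
    zga = c(zga, list(confident = zga_confident,
                      factor_used = factor_index)),
    activation = activation,
    hits = hits,
    enrichment = enrichment,
    matrix = if (keep_data) mat2,
    normalized = if (keep_data) norm,
    repeat_counts = if (keep_data) rc,
    runtime_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  ), class = "screen_report")

  if (!is.null(outdir)) {
    write_screen_outputs(report, outdir, assignments = assignments,
                         matrix = mat2, matched_reads = matched,
                         repeat_counts = rc)
  }
  report
}

#' @export
print.screen_report <- function(x, ...) {
  cat("screen_report\n")
  cat(sprintf("  guides: %d | cells simulated: %d | QC cells: %d | unique+QC: %d\n",
              x$counts$n_guides, x$counts$n_cells_simulated,
              x$counts$n_cells_qc, x$counts$n_cells_unique_qc))
  cat(sprintf("  HVGs: %d | repeat families: %d | ZGA factor: %s (confident: %s)\n",
              x$counts$n_hvg, x$counts$n_repeat_families,
              x$zga$factor_used, x$zga$confident))
  cat(sprintf("  sgRNAs tested: %d | hits at FDR: %d\n",
              x$counts$n_tested, x$counts$n_hits))
  cat(sprintf("  runtime: %.1f s\n", x$runtime_s))
  invisible(x)
}

# Serialize all pipeline outputs as plain text.
write_screen_outputs <- function(report, outdir, assignments = NULL,
                                 matrix = report$matrix,
                                 matched_reads = NULL,
                                 repeat_counts = report$repeat_counts) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_guide_library(report$library, file.path(outdir, "library.tsv"))
  write_sim_config(report$config, file.path(outdir, "config.yaml"))
  if (!is.null(matrix)) write_counts_mtx(matrix, file.path(outdir, "counts"))
  write_ground_truth(report$truth, outdir)
  if (!is.null(assignments)) {
    utils::write.table(assignments, file.path(outdir, "cell_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(matched_reads)) {
    utils::write.table(matched_reads,
                       file.path(outdir, "read_assignments.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(repeat_counts)) {
    rc <- data.frame(barcode = rownames(repeat_counts$counts),
                     repeat_counts$counts, check.names = FALSE)
    utils::write.table(rc, file.path(outdir, "repeat_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  if (!is.null(report$enrichment)) {
    cv <- report$enrichment$curves
    curves <- data.frame(rank = seq_along(report$enrichment$band$mean),
                         band_mean = report$enrichment$band$mean,
                         band_sd = report$enrichment$band$sd)
    for (g in names(cv)) curves[[g]] <- cv[[g]]
    utils::write.table(curves, file.path(outdir, "enrichment_curves.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(as.data.frame(report$hits),
                     file.path(outdir, "hits.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  z <- data.frame(barcode = rownames(report$factor_fit$Z),
                  report$factor_fit$Z, check.names = FALSE)
  utils::write.table(z, file.path(outdir, "factors_Z.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  for (v in names(report$factor_fit$W)) {
    w <- data.frame(feature_id = rownames(report$factor_fit$W[[v]]),
                    report$factor_fit$W[[v]], check.names = FALSE)
    utils::write.table(w, file.path(outdir, paste0("loadings_", v, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  ve <- data.frame(factor = rownames(report$factor_fit$var_explained),
                   report$factor_fit$var_explained, check.names = FALSE)
  utils::write.table(ve, file.path(outdir, "variance_explained.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  summary_json <- list(
    counts = report$counts,
    assignment = report$assignment_summary,
    qc = report$qc_report,
    zga = list(factor_used = report$zga$factor_used,
               confident = report$zga$confident),
    runtime_s = report$runtime_s
  )
  jsonlite::write_json(summary_json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}
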