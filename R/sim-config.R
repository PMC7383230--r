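#' Configuration for a synthetic CRISPRa screen
#'
#' Bundles every tunable of the synthetic-screen generator. Defaults follow
#' the design of a 475-guide maternal-regulator activation screen: 230 target
#' genes with two sgRNAs each plus fifteen non-targeting controls, a rare
#' ZGA-like transcriptional state active in ~2% of baseline cells and in
#' 8.56% of cells carrying a positive-regulator ("hit") sgRNA, and CRISPRa
#' activation of each sgRNA's own target gene.
#'
#' @param n_target_genes Number of genes targeted by the library.
#' @param sgrnas_per_target sgRNAs designed per target gene.
#' @param n_nontargeting Non-targeting control sgRNAs.
#' @param cells_per_sgrna Cells simulated per sgRNA.
#' @param n_genes Genes in the expression matrix (including mitochondrial
#'   and signature genes).
#' @param n_signature_genes Size of the planted ZGA-like gene signature.
#' @param n_mito_genes Mitochondrial genes (named with prefix `mt-`).
#' @param n_variable_genes Non-signature genes given cell-level
#'   log-normal overdispersion, emulating the other variable
#'   transcriptional programs of real single-cell data (without them,
#'   highly-variable-gene selection would return almost exclusively the
#'   signature, which real screens do not show).
#' @param variable_gene_sigma Upper end of the per-gene log-normal sigma
#'   of that overdispersion (sigmas are drawn uniformly from 0.3 up to
#'   this value, giving a dispersion continuum).
#' @param baseline_state_prob Probability that a cell with a non-hit sgRNA is
#'   in the ZGA-like state.
#' @param hit_state_prob Probability that a cell carrying a hit sgRNA is in
#'   the ZGA-like state.
#' @param n_true_hits Number of planted hit sgRNAs.
#' @param activation_log2fc log2 fold-change applied to a targeting sgRNA's
#'   own target gene (CRISPRa effect).
#' @param signature_log2fc log2 fold-change applied to signature genes in a
#'   ZGA-state cell, scaled by the cell's continuous factor intensity.
#' @param mervl_log2fc log2 fold-change of MERVL repeat expression in a
#'   ZGA-state cell, scaled by factor intensity.
#' @param nb_dispersion Negative-binomial dispersion `phi`
#'   (variance = mu + phi * mu^2).
#' @param mean_libsize Mean UMIs per cell.
#' @param libsize_lognormal_sigma Log-normal sigma of per-cell library size.
#' @param mito_beta_shape1,mito_beta_shape2 Beta parameters of the per-cell
#'   mitochondrial fraction for healthy cells (mean 2% by default).
#' @param low_quality_frac Fraction of cells planted as low quality (half
#'   with collapsed library size, half with high mitochondrial content) so
#'   the QC filter has labelled cells to remove.
#' @param amplicon_reads_per_cell Mean amplicon reads per cell (Poisson).
#' @param contamination_rate Probability an amplicon read carries a wrong
#'   sgRNA.
#' @param base_error_rate Per-base substitution probability in amplicon reads.
#' @param doublet_rate Probability a cell carries two sgRNAs.
#' @param repeat_reads_per_molecule Mean extra duplicate reads per repeat
#'   molecule (exercises UMI collapsing).
#' @param seed Integer seed; identical configurations give bit-identical
#'   datasets.
#' @return An object of class `sim_config` (a validated list).
#' @export
simulation_config <- function(n_target_genes = 230,
                              sgrnas_per_target = 2,
                              n_nontargeting = 15,
                              cells_per_sgrna = 100,
                              n_genes = 2000,
                              n_signature_genes = 150,
                              n_mito_genes = 13,
                              n_variable_genes = max(0, min(
                                300, n_genes - n_target_genes -
                                  n_signature_genes - n_mito_genes)),
                              variable_gene_sigma = 0.9,
                              baseline_state_prob = 0.02,
                              hit_state_prob = 0.0856,
                              n_true_hits = 10,
                              activation_log2fc = 2.0,
                              signature_log2fc = 3.0,
                              mervl_log2fc = 4.0,
                              nb_dispersion = 0.1,
                              mean_libsize = 8000,
                              libsize_lognormal_sigma = 0.15,
                              mito_beta_shape1 = 16,
                              mito_beta_shape2 = 784,
                              low_quality_frac = 0.02,
                              amplicon_reads_per_cell = 25,
                              contamination_rate = 0.05,
                              base_error_rate = 0.005,
                              doublet_rate = 0.03,
                              repeat_reads_per_molecule = 0.3,
                              seed = 1L) {
  cfg <- as.list(environment())
  probs <- c("baseline_state_prob", "hit_state_prob", "contamination_rate",
             "base_error_rate", "doublet_rate", "low_quality_frac")
  for (p in probs) {
    v <- cfg[[p]]
    stop_if_not(is.numeric(v) && length(v) == 1 && v >= 0 && v <= 1,
                sprintf("'%s' must be a probability in [0, 1]", p))
  }
  counts <- c("n_target_genes", "sgrnas_per_target", "n_nontargeting",
              "cells_per_sgrna", "n_genes", "n_signature_genes",
              "n_mito_genes", "n_true_hits")
  for (p in counts) {
    v <- cfg[[p]]
    stop_if_not(is.numeric(v) && length(v) == 1 && v >= 0 && v == round(v),
                sprintf("'%s' must be a non-negative integer", p))
  }
  stop_if_not(n_target_genes * sgrnas_per_target + n_nontargeting >= 1,
              "library must contain at least one sgRNA")
  stop_if_not(n_genes >= n_target_genes + n_signature_genes + n_mito_genes +
                n_variable_genes,
              "n_genes must accommodate targets, signature, mito and variable genes")
  stop_if_not(n_true_hits <= n_target_genes * sgrnas_per_target,
              "n_true_hits cannot exceed the number of targeting sgRNAs")
  stop_if_not(nb_dispersion > 0, "nb_dispersion must be positive")
  stop_if_not(mean_libsize > 0, "mean_libsize must be positive")
  cfg$n_sgrnas <- n_target_genes * sgrnas_per_target + n_nontargeting
  class(cfg) <- "sim_config"
  cfg
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic screen configuration\n")
  cat(sprintf("  library : %d targets x %d sgRNAs + %d non-targeting = %d guides\n",
              x$n_target_genes, x$sgrnas_per_target, x$n_nontargeting, x$n_sgrnas))
  cat(sprintf("  cells   : %d per sgRNA (%d total), %d genes\n",
              x$cells_per_sgrna, x$cells_per_sgrna * x$n_sgrnas, x$n_genes))
  cat(sprintf("  state   : baseline %.4f, hit %.4f, %d planted hit sgRNAs\n",
              x$baseline_state_prob, x$hit_state_prob, x$n_true_hits))
  cat(sprintf("  noise   : contamination %.3f, base error %.4f, doublets %.3f\n",
              x$contamination_rate, x$base_error_rate, x$doublet_rate))
  invisible(x)
}

#' Noise-free screen configuration with an overwhelming planted effect
#'
#' Convenience wrapper used for round-trip checks: no read errors, no
#' contamination, no doublets, no low-quality cells, no spontaneous
#' ZGA-like state, and a minimal planted effect (a single hit gene, two
#' sgRNAs) so penetrant (60% of hit-sgRNA cells) that hit calling is
#' expected to recover the planted hit set exactly. Keeping the planted
#' hit count minimal matters: under Benjamini-Hochberg control the chance
#' of at least one false discovery grows with the number of true
#' discoveries (roughly `1 - exp(-fdr * k)` for `k` strong hits), so a
#' large planted set would make "exact recovery" fail by design even with
#' perfectly calibrated null p-values.
#'
#' @param ... Overrides passed to [simulation_config()].
#' @return A `sim_config`.
#' @export
noiseless_config <- function(...) {
  defaults <- list(base_error_rate = 0, contamination_rate = 0,
                   doublet_rate = 0, low_quality_frac = 0,
                   baseline_state_prob = 0, hit_state_prob = 0.6,
                   n_true_hits = 2, n_variable_genes = 0)
  args <- utils::modifyList(defaults, list(...))
  do.call(simulation_config, args)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A `sim_config`.
#' @param path File path.
#' @return `read_sim_config` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$n_sgrnas <- NULL
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}
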