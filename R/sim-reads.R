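# Synthetic amplicon and repeat-derived reads.

#' Simulate sgRNA amplicon reads
#'
#' Each read is the 23-nt upstream vector context, the cell's 20-nt
#' protospacer, and the 23-nt downstream vector context (66 nt total), with
#' independent per-base substitution errors at `base_error_rate`. With
#' probability `contamination_rate` a read carries a uniformly drawn wrong
#' guide; doublet cells emit reads from both their guides. Read counts per
#' cell are Poisson with mean `amplicon_reads_per_cell`.
#'
#' @param config A [simulation_config()].
#' @param truth `ground_truth` from [generate_cells()].
#' @param library The matching `guide_library`.
#' @return A data.frame with columns `cell_barcode`, `umi`, `sequence` and
#'   the bookkeeping column `true_guide`.
#' @export
generate_amplicon_reads <- function(config, truth, library) {
  stop_if_not(inherits(truth, "ground_truth"), "truth must be a ground_truth")
  set.seed(config$seed + 2L)
  cells <- truth$cells
  n_reads_per_cell <- rpois(nrow(cells), config$amplicon_reads_per_cell)
  cell_idx <- rep.int(seq_len(nrow(cells)), n_reads_per_cell)
  n <- length(cell_idx)
  if (n == 0) {
    return(data.frame(cell_barcode = character(), umi = character(),
                      sequence = character(), true_guide = character(),
                      stringsAsFactors = FALSE))
  }
  guide <- cells$guide1[cell_idx]
  g2 <- cells$guide2[cell_idx]
  from2 <- !is.na(g2) & runif(n) < 0.5
  guide[from2] <- g2[from2]
  contam <- runif(n) < config$contamination_rate
  if (any(contam)) {
    idx <- which(contam)
    pick <- sample.int(nrow(library) - 1L, length(idx), replace = TRUE)
    gpos <- match(guide[idx], library$guide_id)
    pick <- ifelse(pick >= gpos, pick + 1L, pick)
    guide[idx] <- library$guide_id[pick]
  }
  proto <- library$protospacer[match(guide, library$guide_id)]
  seqs <- paste0(attr(library, "upstream_context"), proto,
                 attr(library, "downstream_context"))
  seqs <- inject_substitutions(seqs, config$base_error_rate)
  data.frame(
    cell_barcode = cells$barcode[cell_idx],
    umi = random_dna(n, 10),
    sequence = seqs,
    true_guide = guide,
    stringsAsFactors = FALSE
  )
}

#' Simulate repeat-derived reads
#'
#' Emits one or more reads for every planted repeat molecule recorded in the
#' ground truth (the same cells-by-families table placed in the screen
#' matrix). Each molecule gets a UMI unique within its (cell, family) group
#' and a read drawn as a random substring of a random instance sequence of
#' the family; `repeat_reads_per_molecule` controls extra duplicate reads so
#' UMI collapsing has work to do.
#'
#' @param config A [simulation_config()].
#' @param truth `ground_truth` from [generate_cells()].
#' @param reference A `repeat_reference` from [build_repeat_reference()] /
#'   [synthetic_repeat_reference()].
#' @param read_length Read width in nucleotides.
#' @return A data.frame with columns `cell_barcode`, `umi`, `sequence` and
#'   the bookkeeping column `true_family`.
#' @export
generate_repeat_reads <- function(config, truth, reference,
                                  read_length = 50) {
  stop_if_not(inherits(truth, "ground_truth"), "truth must be a ground_truth")
  stop_if_not(inherits(reference, "repeat_reference"),
              "reference must be a repeat_reference")
  set.seed(config$seed + 3L)
  mol <- truth$repeat_molecules
  fams <- colnames(mol)
  missing <- setdiff(fams[colSums(mol) > 0], names(reference))
  stop_if_not(length(missing) == 0,
              paste("reference lacks families:", paste(missing, collapse = ", ")))
  for (f in names(reference)) {
    lens <- nchar(reference[[f]]$instances)
    stop_if_not(all(lens >= read_length),
                sprintf("family '%s' has an instance shorter than the read length", f))
  }
  total <- sum(mol)
  if (total == 0) {
    return(data.frame(cell_barcode = character(), umi = character(),
                      sequence = character(), true_family = character(),
                      stringsAsFactors = FALSE))
  }
  nz <- which(mol > 0, arr.ind = TRUE)
  k <- mol[nz]
  cell_idx <- rep.int(nz[, 1], k)
  fam_idx <- rep.int(nz[, 2], k)
  n <- length(cell_idx)
  umi <- random_dna(n, 10)
  # UMIs must be distinct within a (cell, family) group so that collapsing
  # recovers the planted molecule table exactly
  key <- paste0(cell_idx, "_", fam_idx, "_", umi)
  while (anyDuplicated(key)) {
    dup <- which(duplicated(key))
    umi[dup] <- random_dna(length(dup), 10)
    key[dup] <- paste0(cell_idx[dup], "_", fam_idx[dup], "_", umi[dup])
  }
  dups <- rpois(n, config$repeat_reads_per_molecule)
  rd <- rep.int(seq_len(n), 1L + dups)
  m <- length(rd)
  fam_names <- fams[fam_idx[rd]]
  seqs <- character(m)
  for (f in unique(fam_names)) {
    sel <- which(fam_names == f)
    inst <- reference[[f]]$instances
    which_inst <- sample.int(length(inst), length(sel), replace = TRUE)
    max_off <- nchar(inst)[which_inst] - read_length
    off <- floor(runif(length(sel)) * (max_off + 1))
    seqs[sel] <- substr(inst[which_inst], off + 1, off + read_length)
  }
  data.frame(
    cell_barcode = rownames(mol)[cell_idx[rd]],
    umi = umi[rd],
    sequence = seqs,
    true_family = fam_names,
    stringsAsFactors = FALSE
  )
}

#' Write / read reads as FASTQ
#'
#' Read names encode the cell barcode and UMI as `CB:<16nt>_UMI:<10nt>`.
#' `read_reads_fastq` also accepts a separate barcode FASTQ (`barcode_path`)
#' whose records are the 16-nt cell barcode followed by the 10-nt UMI, the
#' layout produced by droplet platforms.
#'
#' @param reads Data.frame with `cell_barcode`, `umi`, `sequence`.
#' @param path FASTQ path for the sequence reads.
#' @param barcode_path Optional FASTQ path carrying barcode+UMI records.
#' @return `read_reads_fastq` returns a data.frame with columns
#'   `cell_barcode`, `umi`, `sequence`.
#' @export
write_reads_fastq <- function(reads, path, barcode_path = NULL) {
  ids <- sprintf("read%07d_CB:%s_UMI:%s", seq_len(nrow(reads)),
                 reads$cell_barcode, reads$umi)
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq")
  if (!is.null(barcode_path)) {
    b <- Biostrings::DNAStringSet(paste0(reads$cell_barcode, reads$umi))
    names(b) <- ids
    Biostrings::writeXStringSet(b, barcode_path, format = "fastq")
  }
  invisible(path)
}

#' @rdname write_reads_fastq
#' @export
read_reads_fastq <- function(path, barcode_path = NULL) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq")
  seqs <- as.character(x)
  ids <- names(x)
  if (is.null(barcode_path)) {
    cb <- sub(".*CB:([ACGTN]+)_UMI:.*", "\\1", ids)
    umi <- sub(".*_UMI:([ACGTN]+).*", "\\1", ids)
  } else {
    b <- as.character(Biostrings::readDNAStringSet(barcode_path, format = "fastq"))
    stop_if_not(length(b) == length(seqs),
                "barcode FASTQ and read FASTQ differ in length")
    cb <- substr(b, 1, 16)
    umi <- substr(b, 17, 26)
  }
  data.frame(cell_barcode = unname(cb), umi = unname(umi),
             sequence = unname(seqs), stringsAsFactors = FALSE)
}
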