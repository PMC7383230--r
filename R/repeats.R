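# Repeat-family quantification from multimapping-derived reads.

#' Build a stitched repeat-family reference
#'
#' Instances of each family are concatenated with `NNNNN` separators into a
#' single family genome; reads are only ever matched against windows that do
#' not cross a separator.
#'
#' @param families Named list: family name -> character vector of instance
#'   sequences.
#' @return A `repeat_reference`: named list with `instances` and `stitched`
#'   per family.
#' @export
build_repeat_reference <- function(families) {
  stop_if_not(is.list(families) && length(families) > 0 &&
                !is.null(names(families)), "families must be a named list")
  out <- lapply(names(families), function(f) {
    inst <- families[[f]]
    stop_if_not(length(inst) >= 1 && all(nchar(inst) > 0),
                sprintf("family '%s' has no instances", f))
    list(name = f, instances = as.character(inst),
         stitched = paste(inst, collapse = "NNNNN"))
  })
  names(out) <- names(families)
  class(out) <- "repeat_reference"
  out
}

#' Synthetic repeat reference
#'
#' Random instance sequences for the twelve repeat families tracked by the
#' simulator (or any subset), used when no real repeat annotation is
#' supplied.
#'
#' @param families Family names.
#' @param n_instances Instances per family.
#' @param instance_length Instance length in nucleotides.
#' @param seed Seed for the instance draw.
#' @return A `repeat_reference`.
#' @export
synthetic_repeat_reference <- function(families = names(REPEAT_FAMILY_MEANS),
                                       n_instances = 4,
                                       instance_length = 300,
                                       seed = 99L) {
  set.seed(seed)
  build_repeat_reference(setNames(
    lapply(families, function(f) random_dna(n_instances, instance_length)),
    families
  ))
}

#' Write / read a repeat reference as FASTA
#'
#' The family name is carried in the description line as
#' `<family>|instance_<i>`.
#'
#' @param reference A `repeat_reference`.
#' @param path FASTA path.
#' @return `read_repeat_reference` returns a `repeat_reference`.
#' @export
write_repeat_reference <- function(reference, path) {
  seqs <- do.call(c, unname(lapply(reference, function(f) {
    setNames(f$instances,
             paste0(f$name, "|instance_", seq_along(f$instances)))
  })))
  x <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_repeat_reference
#' @export
read_repeat_reference <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  fam <- sub("\\|.*$", "", names(x))
  build_repeat_reference(split(as.character(x), fam)[unique(fam)])
}

# 12-mer presence index used to prefilter candidate families: a read within
# `max_edits` (<= 2) of a window shares at least one of the 12-mers starting
# at read positions 1, 18 and 35 with the family genome (pigeonhole over
# three read segments).
family_kmer_sets <- function(reference, k = 12L) {
  lapply(reference, function(f) {
    kms <- unlist(lapply(f$instances, function(s) {
      n <- nchar(s)
      if (n < k) return(character(0))
      substring(s, 1:(n - k + 1), k:n)
    }))
    unique(kms)
  })
}

#' Map reads to repeat families
#'
#' Exact containment in an N-free window is resolved through a window hash;
#' remaining reads are verified by edit distance (up to `max_edits`) against
#' each instance, with a 12-mer seed prefilter selecting candidate families.
#' Reads matching two or more families are `AMBIGUOUS`; reads matching none
#' (including reads overlapping the `NNNNN` junctions) are `UNMAPPED`.
#'
#' @param reads Character vector of read sequences, or a data.frame with a
#'   `sequence` column.
#' @param reference A `repeat_reference`.
#' @param max_edits Maximum edit distance to a window.
#' @return Character vector: family name, `"UNMAPPED"` or `"AMBIGUOUS"`.
#' @export
map_read_to_family <- function(reads, reference, max_edits = 2) {
  seqs <- if (is.data.frame(reads)) reads$sequence else as.character(reads)
  out <- rep("UNMAPPED", length(seqs))
  if (!length(seqs)) return(out)
  fam_names <- names(reference)
  kmer_sets <- if (max_edits <= 2) family_kmer_sets(reference) else NULL
  for (L in unique(nchar(seqs))) {
    idx <- which(nchar(seqs) == L)
    # exact-containment table of all N-free windows of width L, per family
    win <- lapply(fam_names, function(f) {
      w <- unlist(lapply(reference[[f]]$instances, function(s) {
        n <- nchar(s)
        if (n < L) return(character(0))
        substring(s, 1:(n - L + 1), L:n)
      }))
      unique(w)
    })
    names(win) <- fam_names
    exact <- matrix(FALSE, length(idx), length(fam_names),
                    dimnames = list(NULL, fam_names))
    for (f in fam_names) exact[, f] <- seqs[idx] %in% win[[f]]
    # candidate families by the 12-mer seed prefilter (sound for <= 2 edits
    # on reads split into three segments)
    if (!is.null(kmer_sets) && L >= 14L) {
      seed_starts <- unique(pmin(c(1L, 18L, 35L), max(L - 11L, 1L)))
      cand <- matrix(FALSE, length(idx), length(fam_names),
                     dimnames = list(NULL, fam_names))
      for (s0 in seed_starts) {
        sd <- substr(seqs[idx], s0, s0 + 11L)
        for (f in fam_names) cand[, f] <- cand[, f] | (sd %in% kmer_sets[[f]])
      }
    } else {
      cand <- matrix(TRUE, length(idx), length(fam_names),
                     dimnames = list(NULL, fam_names))
    }
    cand <- cand | exact
    need_check <- cand & !exact
    n_exact <- rowSums(exact)
    to_verify <- which(rowSums(need_check) > 0 &
                         (n_exact + rowSums(need_check) > 1 | n_exact == 0))
    matched_n <- n_exact
    matched_fam <- ifelse(n_exact > 0,
                          fam_names[max.col(exact, ties.method = "first")],
                          NA_character_)
    for (i in to_verify) {
      s <- seqs[idx[i]]
      for (f in fam_names[need_check[i, ]]) {
        if (matched_n[i] > 1) break
        d <- suppressWarnings(
          adist(s, reference[[f]]$instances, partial = TRUE)
        )
        if (min(d) <= max_edits) {
          matched_n[i] <- matched_n[i] + 1L
          if (is.na(matched_fam[i])) matched_fam[i] <- f
        }
      }
    }
    res <- ifelse(matched_n == 0, "UNMAPPED",
                  ifelse(matched_n > 1, "AMBIGUOUS", matched_fam))
    out[idx] <- res
  }
  out
}

#' Collapse mapped repeat reads to molecules
#'
#' Reads sharing a cell barcode, a UMI and a family count as one molecule.
#' `UNMAPPED` and `AMBIGUOUS` reads are excluded.
#'
#' @param reads Data.frame with `cell_barcode`, `umi` and a `family` column
#'   (as produced by joining [map_read_to_family()] output onto the reads).
#' @param barcodes Optional barcode universe fixing row order of the output
#'   matrix (barcodes without mapped reads get zero rows).
#' @return A `repeat_counts`: list with `counts` (cells x families integer
#'   matrix), `family_reads` (mapped reads per family) and `n_reads`
#'   (mapped + excluded totals).
#' @export
collapse_umis <- function(reads, barcodes = NULL) {
  stop_if_not(all(c("cell_barcode", "umi", "family") %in% names(reads)),
              "reads must have cell_barcode, umi and family columns")
  keep <- !(reads$family %in% c("UNMAPPED", "AMBIGUOUS"))
  mapped <- reads[keep, , drop = FALSE]
  fams <- sort(unique(mapped$family))
  bcs <- barcodes %||% sort(unique(mapped$cell_barcode))
  counts <- matrix(0L, length(bcs), length(fams),
                   dimnames = list(bcs, fams))
  if (nrow(mapped)) {
    key <- !duplicated(paste0(mapped$cell_barcode, "\r", mapped$family,
                              "\r", mapped$umi))
    mol <- mapped[key, , drop = FALSE]
    bi <- match(mol$cell_barcode, bcs)
    fi <- match(mol$family, fams)
    ok <- !is.na(bi)
    tab <- table(factor(bi[ok], levels = seq_along(bcs)),
                 factor(fi[ok], levels = seq_along(fams)))
    counts[] <- as.integer(tab)
  }
  family_reads <- vapply(fams, function(f) sum(mapped$family == f), 0L)
  structure(list(counts = counts, family_reads = family_reads,
                 n_reads = c(total = nrow(reads), mapped = nrow(mapped),
                             unmapped = sum(reads$family == "UNMAPPED"),
                             ambiguous = sum(reads$family == "AMBIGUOUS"))),
            class = "repeat_counts")
}

#' Drop repeat families with too few mapped reads
#'
#' Mirrors the removal of inefficiently mapping families (for example
#' LINE-2 and Minor satellites) before downstream analysis.
#'
#' @param counts A `repeat_counts`.
#' @param min_total_reads Families with fewer total mapped reads are dropped.
#' @return A filtered `repeat_counts`.
#' @export
filter_families <- function(counts, min_total_reads = 1000) {
  stop_if_not(inherits(counts, "repeat_counts"),
              "counts must be a repeat_counts")
  keep <- counts$family_reads >= min_total_reads
  counts$counts <- counts$counts[, keep, drop = FALSE]
  counts$family_reads <- counts$family_reads[keep]
  counts
}

#' @export
print.repeat_counts <- function(x, ...) {
  cat(sprintf("repeat_counts: %d cells x %d families (%d mapped / %d reads)\n",
              nrow(x$counts), ncol(x$counts), x$n_reads["mapped"],
              x$n_reads["total"]))
  invisible(x)
}
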