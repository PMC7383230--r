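#' Generate a synthetic sgRNA library
#'
#' Draws distinct random protospacers whose minimum pairwise Levenshtein
#' distance is at least `min_distance`, the separation that makes the
#' two-edit correction tier of read matching unambiguous. Targeting guides
#' are assigned to target genes `g0001 ...`; non-targeting controls carry no
#' target.
#'
#' @param config A [simulation_config()].
#' @param protospacer_length Protospacer width in nucleotides.
#' @param min_distance Required minimum pairwise Levenshtein distance.
#' @return A `guide_library`: a data.frame with columns `guide_id`,
#'   `protospacer`, `target_gene`, `is_targeting`, and attributes
#'   `upstream_context` / `downstream_context` (23-nt vector flanks).
#' @export
generate_library <- function(config, protospacer_length = 20,
                             min_distance = 4) {
  stop_if_not(inherits(config, "sim_config"), "config must be a sim_config")
  n <- config$n_sgrnas
  # counting bound: codes of length L at distance >= d cannot exceed 4^(L-d+1)
  if (n > 4^(protospacer_length - min_distance + 1)) {
    stop("library size ", n, " cannot satisfy minimum distance ",
         min_distance, " at protospacer length ", protospacer_length,
         call. = FALSE)
  }
  set.seed(config$seed)
  protos <- random_dna_unique(n, protospacer_length)
  for (attempt in seq_len(25L)) {
    if (n == 1L) break
    d <- levenshtein(protos, protos)
    diag(d) <- Inf
    bad <- which(apply(d, 1, min) < min_distance)
    if (!length(bad)) break
    if (attempt == 25L) {
      stop("could not satisfy the pairwise distance constraint for ",
           "library size ", n, " at protospacer length ",
           protospacer_length, call. = FALSE)
    }
    protos[bad] <- random_dna(length(bad), protospacer_length)
    while (anyDuplicated(protos)) {
      dup <- which(duplicated(protos))
      protos[dup] <- random_dna(length(dup), protospacer_length)
    }
  }
  nt <- config$n_nontargeting
  ntarg <- config$n_target_genes * config$sgrnas_per_target
  target_gene <- c(
    rep(sprintf("g%04d", seq_len(config$n_target_genes)),
        each = config$sgrnas_per_target),
    rep(NA_character_, nt)
  )
  guide_id <- c(
    paste0("sg_", rep(sprintf("g%04d", seq_len(config$n_target_genes)),
                      each = config$sgrnas_per_target),
           "_", rep(seq_len(config$sgrnas_per_target),
                    config$n_target_genes)),
    sprintf("NT_%02d", seq_len(nt))
  )
  lib <- data.frame(
    guide_id = guide_id,
    protospacer = protos,
    target_gene = target_gene,
    is_targeting = c(rep(TRUE, ntarg), rep(FALSE, nt)),
    stringsAsFactors = FALSE
  )
  attr(lib, "upstream_context") <- VECTOR_UPSTREAM
  attr(lib, "downstream_context") <- VECTOR_DOWNSTREAM
  class(lib) <- c("guide_library", "data.frame")
  lib
}

#' Write / read a guide library as TSV
#'
#' The two 23-nt vector context sequences are stored as comment header lines
#' so the file round-trips the full library definition.
#'
#' @param library A `guide_library`.
#' @param path File path.
#' @return `read_guide_library` returns a `guide_library`.
#' @export
write_guide_library <- function(library, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    paste0("# upstream_context=", attr(library, "upstream_context")),
    paste0("# downstream_context=", attr(library, "downstream_context"))
  ), con)
  utils::write.table(as.data.frame(library), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_guide_library
#' @export
read_guide_library <- function(path) {
  hdr <- readLines(path, n = 2)
  up <- sub("^# upstream_context=", "", hdr[1])
  down <- sub("^# downstream_context=", "", hdr[2])
  lib <- utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                           stringsAsFactors = FALSE)
  lib$is_targeting <- as.logical(lib$is_targeting)
  attr(lib, "upstream_context") <- up
  attr(lib, "downstream_context") <- down
  class(lib) <- c("guide_library", "data.frame")
  lib
}
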