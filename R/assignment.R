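# sgRNA-to-cell assignment from amplicon reads.
#
# Matching is two-tiered: exact protospacer matches against the whitelist,
# then error correction for reads whose protospacer is within Levenshtein
# distance 1-2 of exactly one guide and whose flanking 23-nt vector contexts
# each match with at most 4 edits. Cells are called by a binomial-proportion
# confidence rule on their assigned reads.

#' Validate a guide library for error-corrected matching
#'
#' Reports every pair of protospacers closer than `min_distance` Levenshtein
#' edits. Correction is only safe when no such pair exists, because the
#' correction radius (2 edits) could otherwise reach two guides.
#'
#' @param library A `guide_library`.
#' @param min_distance Required minimum pairwise distance.
#' @return A list with `valid` (logical), `invalid_pairs` (data.frame of
#'   offending pairs with their distance) and `min_distance` observed.
#' @export
validate_library <- function(library, min_distance = 4) {
  stop_if_not(nrow(library) >= 1, "library is empty")
  ctx_ok <- nchar(attr(library, "upstream_context") %||% "") == 23 &&
    nchar(attr(library, "downstream_context") %||% "") == 23
  if (nrow(library) == 1) {
    return(list(valid = ctx_ok, invalid_pairs = data.frame(),
                min_distance = Inf))
  }
  d <- levenshtein(library$protospacer, library$protospacer)
  diag(d) <- NA
  bad <- which(d < min_distance & upper.tri(d), arr.ind = TRUE)
  invalid_pairs <- data.frame(
    guide_1 = library$guide_id[bad[, 1]],
    guide_2 = library$guide_id[bad[, 2]],
    distance = d[bad],
    stringsAsFactors = FALSE
  )
  list(valid = nrow(invalid_pairs) == 0 && ctx_ok,
       invalid_pairs = invalid_pairs,
       min_distance = min(d, na.rm = TRUE))
}

#' Extract the protospacer from an amplicon read
#'
#' Returns nucleotides 24-43 (1-based, inclusive) of each read sequence,
#' the 20-nt window between the vector contexts.
#'
#' @param sequence Character vector of read sequences.
#' @return Character vector of 20-nt protospacers.
#' @export
extract_protospacer <- function(sequence) {
  if (is.data.frame(sequence)) sequence <- sequence$sequence
  stop_if_not(all(nchar(sequence) >= 43),
              "reads must be at least 43 nt to contain positions 24-43")
  substr(sequence, 24, 43)
}

# Segment dictionary over protospacers: any query within 2 edits of a guide
# shares one of the guide's three segments exactly, shifted by at most 2.
protospacer_segments <- function(protos) {
  L <- nchar(protos[1])
  b <- c(1L, floor(L / 3) + 1L, floor(2 * L / 3) + 1L)
  e <- c(b[2] - 1L, b[3] - 1L, L)
  segs <- lapply(1:3, function(k) substr(protos, b[k], e[k]))
  list(begin = b, end = e, segments = segs)
}

# For unique query protospacers, return candidate guide pairs
# (query index, guide index) from the segment dictionary.
candidate_pairs <- function(queries, protos, radius = 2L) {
  dict <- protospacer_segments(protos)
  qi <- integer(0); gi <- integer(0)
  for (k in 1:3) {
    seg_dict <- split(seq_along(protos), dict$segments[[k]])
    len <- dict$end[k] - dict$begin[k] + 1L
    for (d in -radius:radius) {
      s0 <- dict$begin[k] + d
      if (s0 < 1L) next
      q <- substr(queries, s0, s0 + len - 1L)
      ok <- nchar(q) == len
      hit <- seg_dict[q[ok]]
      n <- lengths(hit)
      qi <- c(qi, rep.int(which(ok), n))
      gi <- c(gi, unlist(hit, use.names = FALSE))
    }
  }
  keep <- !duplicated(paste0(qi, "_", gi))
  list(query = qi[keep], guide = gi[keep])
}

#' Match amplicon reads against the guide whitelist
#'
#' Tier 1 assigns reads whose extracted protospacer matches a whitelist
#' protospacer exactly. Tier 2 (error correction) assigns a read if exactly
#' one guide lies within Levenshtein distance `max_correction` of its
#' protospacer AND the read's bases 1-23 / 44-66 match the upstream /
#' downstream vector context with at most `max_context_edits` edits each.
#' Ties at tier 2 and malformed reads are left unassigned. Correction is
#' refused (with a warning) on libraries that fail [validate_library()].
#'
#' @param reads Data.frame with `cell_barcode`, `umi`, `sequence`.
#' @param library A `guide_library`.
#' @param max_correction Correction radius on the protospacer (edits).
#' @param max_context_edits Allowed edits per 23-nt vector context.
#' @return The input data.frame plus `guide_id` (NA when unassigned),
#'   `match_tier` (`"exact"`, `"corrected"` or NA) and `reason` for
#'   unassigned reads.
#' @export
match_reads <- function(reads, library, max_correction = 2,
                        max_context_edits = 4) {
  stop_if_not(is.data.frame(reads) && "sequence" %in% names(reads),
              "reads must be a data.frame with a sequence column")
  n <- nrow(reads)
  guide_id <- rep(NA_character_, n)
  tier <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  len <- nchar(reads$sequence)
  short <- len < 43
  reason[short] <- "read shorter than 43 nt"
  okr <- which(!short)
  proto <- substr(reads$sequence[okr], 24, 43)
  m <- match(proto, library$protospacer)
  hit <- !is.na(m)
  guide_id[okr[hit]] <- library$guide_id[m[hit]]
  tier[okr[hit]] <- "exact"

  rest <- okr[!hit]
  if (length(rest) && max_correction > 0) {
    check <- validate_library(library)
    if (!check$valid) {
      warning("library fails the minimum-distance validation; ",
              "correction tier disabled", call. = FALSE)
      reason[rest] <- "no exact match (correction disabled)"
    } else {
      full <- nchar(reads$sequence[rest]) >= 66
      reason[rest[!full]] <- "read shorter than 66 nt (no context)"
      rest <- rest[full]
      if (length(rest)) {
        qp <- substr(reads$sequence[rest], 24, 43)
        uq <- unique(qp)
        cp <- candidate_pairs(uq, library$protospacer, radius = max_correction)
        # verify candidates by true Levenshtein distance, grouped by guide
        best <- rep(NA_integer_, length(uq))
        nmatch <- integer(length(uq))
        for (g in unique(cp$guide)) {
          qs <- cp$query[cp$guide == g]
          d <- as.vector(levenshtein(uq[qs], library$protospacer[g]))
          ok <- qs[d <= max_correction]
          nmatch[ok] <- nmatch[ok] + 1L
          best[ok[is.na(best[ok])]] <- g
        }
        qidx <- match(qp, uq)
        unique_cand <- nmatch[qidx] == 1L
        reason[rest[nmatch[qidx] == 0L]] <- "no guide within correction radius"
        reason[rest[nmatch[qidx] > 1L]] <- "ambiguous correction"
        cand_rows <- rest[unique_cand]
        if (length(cand_rows)) {
          up <- attr(library, "upstream_context")
          down <- attr(library, "downstream_context")
          d_up <- as.vector(levenshtein(
            substr(reads$sequence[cand_rows], 1, 23), up))
          d_down <- as.vector(levenshtein(
            substr(reads$sequence[cand_rows], 44, 66), down))
          ctx_ok <- d_up <= max_context_edits & d_down <= max_context_edits
          gsel <- best[qidx[unique_cand]]
          guide_id[cand_rows[ctx_ok]] <- library$guide_id[gsel[ctx_ok]]
          tier[cand_rows[ctx_ok]] <- "corrected"
          reason[cand_rows[!ctx_ok]] <- "vector context mismatch"
        }
      }
    }
  } else if (length(rest)) {
    reason[rest] <- "no exact match"
  }
  out <- reads
  out$guide_id <- guide_id
  out$match_tier <- tier
  out$reason <- reason
  out
}

#' @rdname match_reads
#' @param read A single read: a list or one-row data.frame with `sequence`
#'   (and optionally `cell_barcode`, `umi`).
#' @export
match_read <- function(read, library, max_correction = 2,
                       max_context_edits = 4) {
  df <- data.frame(cell_barcode = read$cell_barcode %||% NA_character_,
                   umi = read$umi %||% NA_character_,
                   sequence = read$sequence, stringsAsFactors = FALSE)
  res <- match_reads(df, library, max_correction, max_context_edits)
  list(guide_id = res$guide_id[1], match_tier = res$match_tier[1],
       reason = res$reason[1])
}

#' Call the sgRNA of each cell barcode
#'
#' For a barcode with `n` assigned reads of which `k` support the modal
#' guide, the guide is called unique iff the support fraction exceeds 0.9
#' and the binomial-proportion standard error at the threshold,
#' `sqrt(0.9 * 0.1 / n)`, is at most 0.1 (equivalently `n >= 9`). Otherwise
#' the barcode is categorised by how many guides have at least two
#' supporting reads: `two` (exactly two), `multiple` (three or more) or
#' `none`. Unassigned reads never enter the denominator.
#'
#' @param matched Output of [match_reads()].
#' @param support_threshold Required modal support fraction (strict).
#' @param max_se Maximum binomial-proportion standard error, evaluated at
#'   `support_threshold`.
#' @return A `cell_assignment` data.frame: `cell_barcode`, `category`,
#'   `assigned_guide`, `support_reads`, `total_reads`, `support_fraction`.
#' @export
assign_cells <- function(matched, support_threshold = 0.9, max_se = 0.1) {
  ok <- !is.na(matched$guide_id)
  bcs <- sort(unique(matched$cell_barcode))
  guides <- sort(unique(matched$guide_id[ok]))
  if (length(guides) == 0) {
    out <- data.frame(cell_barcode = bcs, category = "none",
                      assigned_guide = NA_character_, support_reads = 0L,
                      total_reads = 0L, support_fraction = NA_real_,
                      stringsAsFactors = FALSE)
    class(out) <- c("cell_assignment", "data.frame")
    return(out)
  }
  bi <- match(matched$cell_barcode[ok], bcs)
  gi <- match(matched$guide_id[ok], guides)
  ng <- length(guides)
  tab <- matrix(tabulate((bi - 1L) * ng + gi, nbins = length(bcs) * ng),
                nrow = ng)
  n_reads <- colSums(tab)
  modal_idx <- max.col(t(tab), ties.method = "first")
  k <- tab[cbind(modal_idx, seq_along(bcs))]
  phat <- ifelse(n_reads > 0, k / n_reads, NA_real_)
  se_ok <- sqrt(support_threshold * (1 - support_threshold) /
                  pmax(n_reads, 1)) <= max_se
  uniq <- n_reads > 0 & phat > support_threshold & se_ok
  n_supported <- colSums(tab >= 2L)
  category <- ifelse(uniq, "unique",
                     ifelse(n_supported == 2L, "two",
                            ifelse(n_supported >= 3L, "multiple", "none")))
  out <- data.frame(
    cell_barcode = bcs,
    category = category,
    assigned_guide = ifelse(uniq, guides[modal_idx], NA_character_),
    support_reads = k,
    total_reads = n_reads,
    support_fraction = phat,
    stringsAsFactors = FALSE
  )
  class(out) <- c("cell_assignment", "data.frame")
  out
}

#' @rdname assign_cells
#' @param guide_ids Character vector of per-read guide calls for ONE
#'   barcode (`NA` for unassigned reads).
#' @return `assign_cell` returns a one-row list with `category`,
#'   `assigned_guide`, `support_reads`, `total_reads`, `support_fraction`.
#' @export
assign_cell <- function(guide_ids, support_threshold = 0.9, max_se = 0.1) {
  if (length(guide_ids) == 0) {
    return(list(category = "none", assigned_guide = NA_character_,
                support_reads = 0L, total_reads = 0L,
                support_fraction = NA_real_))
  }
  df <- data.frame(cell_barcode = "cell", umi = NA_character_,
                   guide_id = guide_ids, stringsAsFactors = FALSE)
  res <- assign_cells(df, support_threshold, max_se)
  as.list(res[1, c("category", "assigned_guide", "support_reads",
                   "total_reads", "support_fraction")])
}

#' Restrict cell assignments to expression-matrix barcodes
#'
#' Keeps only assignments whose barcode was detected in the (QC-passed)
#' expression matrix; downstream analysis then uses the `unique` category.
#'
#' @param assignments A `cell_assignment`.
#' @param expression_barcodes Character vector of barcodes present in the
#'   expression data.
#' @return The filtered `cell_assignment`.
#' @export
match_barcodes <- function(assignments, expression_barcodes) {
  out <- assignments[assignments$cell_barcode %in% expression_barcodes, ,
                     drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarise assignment categories
#'
#' @param assignments A `cell_assignment`.
#' @return A data.frame with per-category cell counts and percentages,
#'   mirroring the standard assignment summary table.
#' @export
summarize_assignments <- function(assignments) {
  lev <- c("none", "unique", "two", "multiple")
  n <- vapply(lev, function(l) sum(assignments$category == l), 0L)
  data.frame(category = lev, n_cells = n,
             percentage = round(100 * n / max(sum(n), 1L), 2),
             stringsAsFactors = FALSE)
}
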