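# sgRNA read matching and cell assignment.

make_lib <- function(protos, up = strrep("A", 23), down = strrep("C", 23)) {
  lib <- data.frame(
    guide_id = paste0("sg", seq_along(protos)),
    protospacer = protos,
    target_gene = paste0("g", seq_along(protos)),
    is_targeting = TRUE, stringsAsFactors = FALSE
  )
  attr(lib, "upstream_context") <- up
  attr(lib, "downstream_context") <- down
  class(lib) <- c("guide_library", "data.frame")
  lib
}

ref_lib <- function() {
  cfg <- simulation_config(n_target_genes = 25, sgrnas_per_target = 2,
                           n_nontargeting = 10, n_genes = 300,
                           n_signature_genes = 30, n_variable_genes = 0,
                           seed = 12)
  generate_library(cfg)
}

read_for <- function(lib, guide_idx, proto = NULL) {
  p <- proto %||% lib$protospacer[guide_idx]
  paste0(attr(lib, "upstream_context"), p, attr(lib, "downstream_context"))
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("validate_library reports close and duplicate protospacers", {
  p <- "ACGTACGTACGTACGTACGT"
  p1 <- sub("^A", "T", p)
  bad <- make_lib(c(p, p1, "GGGGCCCCAAAATTTTGGGG"))
  rep <- validate_library(bad)
  expect_false(rep$valid)
  expect_equal(nrow(rep$invalid_pairs), 1)
  expect_equal(rep$invalid_pairs$distance, 1)
  dup <- make_lib(c(p, p, "GGGGCCCCAAAATTTTGGGG"))
  rep2 <- validate_library(dup)
  expect_false(rep2$valid)
  expect_true(0 %in% rep2$invalid_pairs$distance)
  expect_true(validate_library(ref_lib())$valid)
})

test_that("extract_protospacer returns 1-based positions 24-43", {
  x <- paste0(strrep("A", 23), "ACGTACGTACGTACGTACGT", strrep("T", 23))
  expect_equal(extract_protospacer(x), "ACGTACGTACGTACGTACGT")
  expect_error(extract_protospacer(strrep("A", 42)), "43")
})

test_that("tier 1 assigns exact matches regardless of context", {
  lib <- ref_lib()
  seq <- paste0(strrep("G", 23), lib$protospacer[4], strrep("G", 23))
  r <- match_read(list(sequence = seq), lib)
  expect_equal(r$guide_id, lib$guide_id[4])
  expect_equal(r$match_tier, "exact")
})

test_that("tier 2 corrects 1-2 edits when both contexts are close", {
  lib <- ref_lib()
  p <- lib$protospacer[7]
  p1 <- paste0("T", substr(p, 2, 20))
  if (substr(p, 1, 1) == "T") p1 <- paste0("A", substr(p, 2, 20))
  r <- match_read(list(sequence = read_for(lib, 7, p1)), lib)
  expect_equal(r$guide_id, lib$guide_id[7])
  expect_equal(r$match_tier, "corrected")
  # garble one context beyond 4 edits: correction refused
  bad_ctx <- paste0(strrep("G", 23), p1, attr(lib, "downstream_context"))
  r2 <- match_read(list(sequence = bad_ctx), lib)
  expect_true(is.na(r2$guide_id))
  # three edits: outside the correction radius
  p3 <- mutate_seq_subs(p, 3)
  r3 <- match_read(list(sequence = read_for(lib, 7, p3)), lib)
  expect_true(is.na(r3$guide_id))
})

test_that("a correction tie between two guides stays unassigned", {
  # two protospacers at distance exactly 4; a read protospacer 2 edits from
  # each is ambiguous and must not be corrected
  a <- "AAAAAAAAAACCCCCCCCCC"
  b <- "AAAAAAAAAACCCCCCTTTT"  # distance 4 from a
  q <- "AAAAAAAAAACCCCCCCCTT"  # distance 2 from both
  expect_equal(brute_levenshtein(a, b), 4)
  expect_equal(brute_levenshtein(q, a), 2)
  expect_equal(brute_levenshtein(q, b), 2)
  lib <- make_lib(c(a, b, "GGGGTTTTGGGGTTTTGGGG"))
  r <- match_read(list(sequence = read_for(lib, 1, q)), lib)
  expect_true(is.na(r$guide_id))
})

test_that("match_reads agrees with the exhaustive brute-force matcher", {
  set.seed(77)
  lib <- ref_lib()
  n <- 1000
  seqs <- character(n)
  for (i in seq_len(n)) {
    g <- sample(nrow(lib), 1)
    p <- lib$protospacer[g]
    kind <- sample(c("exact", "sub", "indel", "garbage"), 1,
                   prob = c(0.4, 0.3, 0.2, 0.1))
    p <- switch(kind,
      exact = p,
      sub = mutate_seq_subs(p, sample(1:3, 1)),
      indel = mutate_seq(p, sample(1:3, 1)),
      garbage = paste(sample(c("A", "C", "G", "T"), 20, TRUE), collapse = ""))
    ctx_up <- attr(lib, "upstream_context")
    ctx_down <- attr(lib, "downstream_context")
    if (runif(1) < 0.15) ctx_up <- mutate_seq(ctx_up, sample(1:6, 1))
    if (runif(1) < 0.15) ctx_down <- mutate_seq(ctx_down, sample(1:6, 1))
    seqs[i] <- paste0(ctx_up, p, ctx_down)
  }
  reads <- data.frame(cell_barcode = "b", umi = "u", sequence = seqs,
                      stringsAsFactors = FALSE)
  got <- match_reads(reads, lib)$guide_id
  want <- vapply(seqs, brute_match_read, "", library = lib,
                 USE.NAMES = FALSE)
  expect_identical(got, want)
})

test_that("the binomial confidence rule reproduces the worked examples", {
  # 9 reads, one guide: SE bound sqrt(.09/9) = 0.1 passes, p-hat = 1 > 0.9
  a9 <- assign_cell(rep("sgA", 9))
  expect_equal(a9$category, "unique")
  expect_equal(a9$assigned_guide, "sgA")
  # 8 reads: sqrt(.09/8) = 0.106 > 0.1 fails
  expect_false(assign_cell(rep("sgA", 8))$category == "unique")
  # 18/2 split: p-hat = 0.9 exactly, fails the strict inequality;
  # both guides have >= 2 reads -> category two
  a18 <- assign_cell(c(rep("sgA", 18), rep("sgB", 2)))
  expect_equal(a18$category, "two")
  # three supported guides -> multiple
  am <- assign_cell(c(rep("sgA", 5), rep("sgB", 3), rep("sgC", 2)))
  expect_equal(am$category, "multiple")
  # unassigned reads never enter the denominator
  au <- assign_cell(c(rep("sgA", 9), rep(NA_character_, 20)))
  expect_equal(au$category, "unique")
  expect_equal(au$total_reads, 9L)
  expect_equal(assign_cell(rep(NA_character_, 4))$category, "none")
})

test_that("assignment categories conserve the barcode count", {
  cfg <- simulation_config(n_target_genes = 10, sgrnas_per_target = 2,
                           n_nontargeting = 5, cells_per_sgrna = 40,
                           n_genes = 200, n_signature_genes = 30,
                           n_variable_genes = 0, seed = 21)
  lib <- generate_library(cfg)
  sim <- generate_cells(cfg, lib)
  reads <- generate_amplicon_reads(cfg, sim$truth, lib)
  asg <- assign_cells(match_reads(reads, lib))
  s <- summarize_assignments(asg)
  expect_equal(sum(s$n_cells), length(unique(reads$cell_barcode)))
  expect_setequal(s$category, c("none", "unique", "two", "multiple"))
})

test_that("match_barcodes keeps exactly the expression-set intersection", {
  asg <- data.frame(cell_barcode = c("b1", "b2", "b3"),
                    category = "unique", assigned_guide = "sgA",
                    support_reads = 9L, total_reads = 9L,
                    support_fraction = 1, stringsAsFactors = FALSE)
  expect_equal(match_barcodes(asg, c("b2", "b3", "b9"))$cell_barcode,
               c("b2", "b3"))
  expect_equal(nrow(match_barcodes(asg, character(0))), 0)
})

test_that("a library failing validation disables the correction tier", {
  p <- "ACGTACGTACGTACGTACGT"
  lib <- make_lib(c(p, sub("^A", "T", p), "GGGGCCCCAAAATTTTGGGG"))
  q <- mutate_seq_subs("GGGGCCCCAAAATTTTGGGG", 1)
  expect_warning(
    r <- match_read(list(sequence = read_for(lib, 3, q)), lib),
    "correction tier disabled")
  expect_true(is.na(r$guide_id))
})
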