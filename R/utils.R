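# Internal helpers shared across modules.

#' Levenshtein distance between character vectors
#'
#' Thin wrapper around [utils::adist()] restricted to unit-cost
#' insertions, deletions and substitutions.
#'
#' @param x,y Character vectors; the full `length(x)` x `length(y)` distance
#'   matrix is returned.
#' @return Integer matrix of edit distances.
#' @export
levenshtein <- function(x, y) {
  adist(x, y, costs = list(ins = 1, del = 1, sub = 1))
}

# Random DNA strings of a common width.
random_dna <- function(n, width) {
  m <- matrix(sample(DNA_BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE))
}

# Distinct random DNA strings (resamples collisions).
random_dna_unique <- function(n, width) {
  out <- unique(random_dna(n, width))
  while (length(out) < n) {
    out <- unique(c(out, random_dna(n - length(out), width)))
  }
  out[seq_len(n)]
}

# Substitute bases independently at `rate` per position, always to one of
# the three other bases. Drawn as a per-read Binomial error count plus
# distinct uniform positions — the same process as per-position Bernoulli
# trials, but linear in the number of errors rather than read length.
inject_substitutions <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0) return(seqs)
  width <- nchar(seqs[1])
  n <- length(seqs)
  k <- rbinom(n, width, rate)
  hit <- which(k > 0L)
  if (!length(hit)) return(seqs)
  read_idx <- rep.int(hit, k[hit])
  pos <- sample.int(width, length(read_idx), replace = TRUE)
  key <- (read_idx - 1) * width + pos
  while (anyDuplicated(key)) {  # positions must be distinct within a read
    dup <- which(duplicated(key))
    pos[dup] <- sample.int(width, length(dup), replace = TRUE)
    key[dup] <- (read_idx[dup] - 1) * width + pos[dup]
  }
  for (p in unique(pos)) {
    sel <- read_idx[pos == p]
    cur <- substr(seqs[sel], p, p)
    shift <- sample.int(3L, length(sel), replace = TRUE)
    new <- DNA_BASES[((match(cur, DNA_BASES) - 1L + shift) %% 4L) + 1L]
    substr(seqs[sel], p, p) <- new
  }
  seqs
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)
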