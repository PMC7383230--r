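# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths they check.

# Textbook dynamic-programming Levenshtein distance.
brute_levenshtein <- function(a, b) {
  x <- strsplit(a, "")[[1]]
  y <- strsplit(b, "")[[1]]
  n <- length(x); m <- length(y)
  prev <- 0:m
  for (i in seq_len(n)) {
    cur <- numeric(m + 1)
    cur[1] <- i
    for (j in seq_len(m)) {
      cur[j + 1] <- min(prev[j + 1] + 1, cur[j] + 1,
                        prev[j] + (x[i] != y[j]))
    }
    prev <- cur
  }
  prev[m + 1]
}

# Step-up Benjamini-Hochberg written from the definition.
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- p[o] * m / seq_len(m)
  q <- rev(cummin(rev(q)))
  pmin(1, q)[order(o)]
}

# Exact Fisher power by full outcome enumeration with fisher.test.
brute_fisher_power <- function(p0, p1, n, alpha) {
  pow <- 0
  for (k0 in 0:n) {
    for (k1 in 0:n) {
      pv <- stats::fisher.test(matrix(c(k1, n - k1, k0, n - k0), 2))$p.value
      if (pv <= alpha) pow <- pow + stats::dbinom(k0, n, p0) *
          stats::dbinom(k1, n, p1)
    }
  }
  pow
}

# Hypergeometric upper-tail probability by explicit summation.
brute_hyper_tail <- function(q, m, n, k) {
  x <- q:min(m, k)
  sum(exp(lchoose(m, x) + lchoose(n, k - x) - lchoose(m + n, k)))
}

# Exhaustive-search read matcher: distance of the extracted protospacer to
# EVERY guide, then the two-tier rule applied directly.
brute_match_read <- function(sequence, library, max_correction = 2,
                             max_context_edits = 4) {
  if (nchar(sequence) < 43) return(NA_character_)
  proto <- substr(sequence, 24, 43)
  exact <- which(library$protospacer == proto)
  if (length(exact) == 1) return(library$guide_id[exact])
  if (nchar(sequence) < 66) return(NA_character_)
  d <- vapply(library$protospacer, brute_levenshtein, 0, a = proto)
  near <- which(d <= max_correction)
  if (length(near) != 1) return(NA_character_)
  du <- brute_levenshtein(substr(sequence, 1, 23),
                          attr(library, "upstream_context"))
  dd <- brute_levenshtein(substr(sequence, 44, 66),
                          attr(library, "downstream_context"))
  if (du <= max_context_edits && dd <= max_context_edits) {
    library$guide_id[near]
  } else NA_character_
}

# Substitution-only mutations: keep length, exactly k edited positions.
mutate_seq_subs <- function(s, k) {
  pos <- sample(nchar(s), k)
  for (p in pos) {
    cur <- substr(s, p, p)
    substr(s, p, p) <- sample(setdiff(c("A", "C", "G", "T"), cur), 1)
  }
  s
}

# Apply random substitutions / insertions / deletions to a sequence.
mutate_seq <- function(s, n_edits) {
  bases <- c("A", "C", "G", "T")
  for (i in seq_len(n_edits)) {
    v <- strsplit(s, "")[[1]]
    op <- sample(c("sub", "ins", "del"), 1)
    pos <- sample(length(v), 1)
    v <- switch(op,
      sub = {v[pos] <- sample(setdiff(bases, v[pos]), 1); v},
      ins = append(v, sample(bases, 1), after = pos),
      del = v[-pos]
    )
    s <- paste(v, collapse = "")
  }
  s
}
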