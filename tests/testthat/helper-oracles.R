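# Independent oracles used across the suite. These deliberately share no
# code with the package implementation.

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")

# Gotoh affine-gap global alignment score, pure-R dynamic program.
# A gap of length k costs |open| + k * |ext| (opening charged once,
# extension per gapped base), matching scoring_scheme() semantics.
gotoh_score <- function(ref, query, match = 2, mismatch = -3,
                        open = -5, ext = -1) {
  a <- strsplit(ref, "")[[1]]
  b <- strsplit(query, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e9
  M <- matrix(NEG, n + 1, m + 1)   # last column aligned
  X <- matrix(NEG, n + 1, m + 1)   # gap in query (deletion), consumes ref
  Y <- matrix(NEG, n + 1, m + 1)   # gap in ref (insertion), consumes query
  M[1, 1] <- 0
  for (i in seq_len(n) + 1)
    X[i, 1] <- open + (i - 1) * ext
  for (j in seq_len(m) + 1)
    Y[1, j] <- open + (j - 1) * ext
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (a[i - 1] == b[j - 1] && a[i - 1] != "N") match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + open + ext, X[i - 1, j] + ext,
                     Y[i - 1, j] + open + ext)
      Y[i, j] <- max(M[i, j - 1] + open + ext, Y[i, j - 1] + ext,
                     X[i, j - 1] + open + ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# All placements of a single contiguous k-base deletion in ref that yield
# `clone` exactly: the repeat-ambiguity equivalence class. Returns a matrix
# with columns start, end (0-based half-open), possibly zero rows.
enum_del_placements <- function(ref, clone) {
  k <- nchar(ref) - nchar(clone)
  out <- NULL
  if (k > 0) {
    for (s in 0:(nchar(ref) - k)) {
      cand <- paste0(substr(ref, 1, s), substring(ref, s + k + 1))
      if (cand == clone) out <- rbind(out, c(start = s, end = s + k))
    }
  }
  if (is.null(out)) matrix(integer(0), 0, 2,
                           dimnames = list(NULL, c("start", "end")))
  else out
}

# Construct an edited clone directly from truth components.
edit_ref <- function(ref, del = NULL, ins_point = NULL, ins_seq = "") {
  s <- ref
  if (!is.null(del))
    s <- paste0(substr(s, 1, del[1]), substring(s, del[2] + 1))
  if (!is.null(ins_point)) {
    p <- ins_point
    if (!is.null(del) && ins_point >= del[2]) p <- ins_point - (del[2] - del[1])
    else if (!is.null(del) && ins_point > del[1]) p <- del[1]
    s <- paste0(substr(s, 1, p), ins_seq, substring(s, p + 1))
  }
  s
}

# Two-sided permutation test for a difference in group means.
perm_test_pair <- function(x, y, n_perm = 2000) {
  obs <- abs(mean(x) - mean(y))
  pool <- c(x, y)
  n <- length(x)
  hits <- 0
  for (i in seq_len(n_perm)) {
    idx <- sample(length(pool), n)
    if (abs(mean(pool[idx]) - mean(pool[-idx])) >= obs - 1e-12)
      hits <- hits + 1
  }
  hits / n_perm
}

# Default-scoring shorthand for tests
sc <- function() scoring_scheme()

# Assemble a clone_edit record directly from literal calls, bypassing the
# aligner: the right input for unit tests of footprint/profile arithmetic,
# where placement is given, not inferred.
make_record <- function(id, dels = NULL, ins = NULL) {
  calls <- data.frame(kind = character(0), start = integer(0),
                      end = integer(0), inserted_seq = character(0),
                      length = integer(0), stringsAsFactors = FALSE)
  if (!is.null(dels))
    calls <- rbind(calls, data.frame(
      kind = "deletion", start = as.integer(dels[, 1]),
      end = as.integer(dels[, 2]), inserted_seq = "",
      length = as.integer(dels[, 2] - dels[, 1])))
  if (!is.null(ins))
    calls <- rbind(calls, data.frame(
      kind = "insertion", start = as.integer(ins$point),
      end = as.integer(ins$point), inserted_seq = ins$seq,
      length = nchar(ins$seq)))
  calls <- calls[order(calls$start), ]
  net <- sum(calls$length[calls$kind == "insertion"]) -
    sum(calls$length[calls$kind == "deletion"])
  cls <- if (nrow(calls) == 0) "unmodified"
         else if (all(calls$kind == "deletion")) "deletion"
         else if (all(calls$kind == "insertion")) "insertion" else "both"
  structure(list(clone_id = id, calls = calls, net_change = as.integer(net),
                 edit_class = cls, substitutions = 0L, flagged = FALSE),
            class = "clone_edit")
}

# DNA with no adenine: used to build references whose cut-adjacent deletions
# have a unique (shift-free) placement when the base 5' of the cut is an A
dna_noA <- function(n) paste(sample(c("C", "G", "T"), n, TRUE), collapse = "")
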