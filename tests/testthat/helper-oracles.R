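# Independent brute-force oracles used across the suite. These deliberately
# avoid the package's own algorithms: folding is checked against exhaustive
# enumeration of all non-crossing pairings, alignment counting against a
# direct all-window Hamming scan, and the elimination bitset against a
# per-candidate scan of the whole 4^k space.

rand_rna <- function(n, pgc = 0.5) {
  paste(sample(c("A", "C", "G", "U"), n, replace = TRUE,
               prob = c((1 - pgc) / 2, pgc / 2, pgc / 2, (1 - pgc) / 2)),
        collapse = "")
}

.oracle_can_pair <- function(a, b) {
  paste0(a, b) %in% c("AU", "UA", "CG", "GC", "GU", "UG")
}

# maximum number of non-crossing pairs over WC+GU with hairpin loops >=
# min_loop, by exhaustive recursion over "position i unpaired or paired
# with some admissible j" (exponential; fine for n <= 12)
oracle_max_pairs <- function(seq, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  rec <- function(i, j) {
    if (j - i < min_loop + 1) return(0L)
    best <- rec(i + 1L, j)  # i unpaired
    for (l in (i + min_loop + 1L):j) {
      if (.oracle_can_pair(s[i], s[l])) {
        inner <- if (l - 1L >= i + 1L) rec(i + 1L, l - 1L) else 0L
        rest <- if (j >= l + 1L) rec(l + 1L, j) else 0L
        best <- max(best, 1L + inner + rest)
      }
    }
    best
  }
  if (length(s) < min_loop + 2) return(0L)
  rec(1L, length(s))
}

# dot-bracket structural validity: balanced, non-crossing by construction of
# the stack parser, pairs admissible, loops >= min_loop
oracle_valid_structure <- function(seq, db, min_loop = 3) {
  s <- strsplit(seq, "")[[1]]
  ch <- strsplit(db, "")[[1]]
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") stack <- c(stack, i)
    else if (ch[i] == ")") {
      if (length(stack) == 0) return(FALSE)
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      if (!.oracle_can_pair(s[j], s[i])) return(FALSE)
      if (i - j - 1L < min_loop) return(FALSE)
    }
  }
  length(stack) == 0
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# all-window Hamming hit count over a set of sequences, optionally both
# orientations
oracle_hits <- function(site, seqs, v, both = TRUE) {
  k <- nchar(site)
  strands <- if (both) c(seqs, rna_revcomp(seqs)) else seqs
  total <- 0L
  for (s in strands) {
    if (nchar(s) < k) next
    for (off in 0:(nchar(s) - k)) {
      if (oracle_hamming(site, substr(s, off + 1, off + k)) <= v) {
        total <- total + 1L
      }
    }
  }
  total
}

# per-candidate brute force: minimum Hamming distance of every site in the
# 4^k space to any reference window (vectorised over the candidate matrix,
# one reference window at a time)
oracle_min_dists <- function(k, seqs, both = TRUE) {
  all_sites <- seloligo:::decode_kmers(0:(4^k - 1), k)
  M <- matrix(unlist(strsplit(all_sites, "")), ncol = k, byrow = TRUE)
  strands <- if (both) c(seqs, rna_revcomp(seqs)) else seqs
  dmin <- rep(k + 1L, length(all_sites))
  for (s in strands) {
    if (nchar(s) < k) next
    for (off in 0:(nchar(s) - k)) {
      w <- strsplit(substr(s, off + 1, off + k), "")[[1]]
      d <- rowSums(M != matrix(w, nrow(M), k, byrow = TRUE))
      dmin <- pmin(dmin, d)
    }
  }
  names(dmin) <- all_sites
  dmin
}

oracle_survivors <- function(k, seqs, v, both = TRUE) {
  dmin <- oracle_min_dists(k, seqs, both = both)
  names(dmin)[dmin > v]
}

# longest antiparallel self-complementary run by direct scan over all
# alignment registers of s against its reverse
oracle_selfcomp_run <- function(s) {
  ch <- strsplit(s, "")[[1]]
  n <- length(ch)
  comp <- c(A = "U", C = "G", G = "C", U = "A")
  best <- 0L
  for (const in 2:(2 * n)) {
    run <- 0L
    for (i in max(1, const - n):min(n, const - 1)) {
      j <- const - i
      if (comp[[ch[i]]] == ch[j]) {
        run <- run + 1L
        best <- max(best, run)
      } else run <- 0L
    }
  }
  best
}

make_toy_index <- function(n_tx = 5, len = 60, k = 7, seed = 1,
                           both = TRUE) {
  set.seed(seed)
  seqs <- vapply(seq_len(n_tx), function(i) rand_rna(len), character(1))
  names(seqs) <- paste0("tx", seq_len(n_tx))
  list(seqs = seqs, index = build_index(seqs, k = k, both_orientations = both))
}
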