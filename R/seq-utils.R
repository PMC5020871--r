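# Low-level sequence helpers shared by the simulator and the assembly stages.
# Sequences are plain upper-case character scalars over {A,C,G,T,N}; Biostrings
# objects are built only at I/O and alignment boundaries.

DNA_BASES <- c("A", "C", "G", "T")

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores `.Random.seed` so simulator operations are pure
#' functions of their inputs and seed.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  expr
}

#' Random DNA sequence
#' @param n length in bases.
#' @return character scalar of length-`n` uniform i.i.d. bases.
#' @keywords internal
random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Reverse complement
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
#' @examples
#' revcomp("AAGCTT")  # palindromic site
revcomp <- function(x) {
  out <- vapply(x, function(s) {
    if (!nzchar(s)) return("")
    r <- rev(charToRaw(s))
    rawToChar(r)
  }, character(1), USE.NAMES = FALSE)
  chartr("ACGTacgt", "TGCAtgca", out)
}

# Substitution noise at a fixed per-base rate; indels are never introduced
# (the downstream identity thresholds are exercised by substitutions alone).
mutate_seq <- function(seq, rate) {
  n <- nchar(seq)
  if (rate <= 0 || n == 0L) return(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  r <- charToRaw(seq)
  bases <- charToRaw("ACGT")
  for (p in pos) {
    alt <- bases[bases != r[p]]
    r[p] <- alt[sample.int(3L, 1L)]
  }
  rawToChar(r)
}

# 1-based start positions of exact occurrences of `motif` in `seq`.
find_sites <- function(seq, motif) {
  m <- gregexpr(motif, seq, fixed = TRUE)[[1L]]
  if (m[1L] == -1L) integer(0) else as.integer(m)
}

# Rotate a circular sequence so it starts at 1-based position i.
rotate_seq <- function(seq, i) {
  n <- nchar(seq)
  i <- ((i - 1L) %% n) + 1L
  if (i == 1L) return(seq)
  paste0(substr(seq, i, n), substr(seq, 1L, i - 1L))
}

# 1-based start of the lexicographically minimal rotation. Vectorised
# candidate refinement: geometric shrink on random DNA; worst case on highly
# periodic strings is quadratic, which desk-scale inputs never hit.
min_rotation_start <- function(seq) {
  n <- nchar(seq)
  if (n <= 1L) return(1L)
  r <- as.integer(charToRaw(paste0(seq, seq)))
  head_r <- r[seq_len(n)]
  cand <- which(head_r == min(head_r))
  k <- 1L
  while (length(cand) > 1L && k < n) {
    ch <- r[cand + k]
    cand <- cand[ch == min(ch)]
    k <- k + 1L
  }
  cand[1L]
}

# Identity of two equal-length strings as matches / length ('N' never matches).
hamming_identity <- function(a, b) {
  n <- nchar(a)
  stopifnot(n == nchar(b))
  if (n == 0L) return(0)
  ra <- charToRaw(a)
  rb <- charToRaw(b)
  nn <- charToRaw("N")
  sum(ra == rb & ra != nn) / n
}

# Global-alignment identity (matches / alignment columns, gaps included).
# Used only on short windows when positional comparison is not applicable.
align_identity <- function(a, b) {
  if (nchar(a) == nchar(b)) return(hamming_identity(a, b))
  aln <- pairwiseAlignment(DNAString(a), DNAString(b), type = "global")
  cols <- nchar(as.character(Biostrings::alignedPattern(aln)))
  nmatch(aln) / cols
}

# Exact k-mer seed voting: where does `query` start inside `subject`?
# Samples k-mers at `qpos` (or evenly spaced) positions of `query`, finds all
# exact occurrences in `subject`, and tallies implied offsets
# (subject position of query base 1, 1-based; may be < 1). Substitution-only
# error models leave true offsets exact, so the modal offset is the alignment.
vote_offsets <- function(query, subject, k = 24L, n_seeds = 24L, qpos = NULL) {
  nq <- nchar(query)
  if (nq < k) return(data.frame(offset = integer(0), votes = integer(0)))
  if (is.null(qpos)) {
    qpos <- unique(as.integer(round(seq(1L, nq - k + 1L, length.out = min(n_seeds, nq - k + 1L)))))
  }
  qpos <- qpos[qpos >= 1L & qpos <= nq - k + 1L]
  offs <- integer(0)
  for (p in qpos) {
    pat <- substr(query, p, p + k - 1L)
    hits <- find_sites(subject, pat)
    if (length(hits)) offs <- c(offs, hits - p + 1L)
  }
  if (!length(offs)) return(data.frame(offset = integer(0), votes = integer(0)))
  tab <- table(offs)
  out <- data.frame(offset = as.integer(names(tab)), votes = as.integer(tab))
  out[order(-out$votes, out$offset), , drop = FALSE]
}

# Round half away from zero (the tables' rounding convention).
round_half_up <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
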