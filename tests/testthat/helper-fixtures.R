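# Shared fixtures, built in code and cached for the session.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small 10x library on one 400 kb chromosome, with truth profiles and map.
tiny_sim <- function() {
  cached("tiny_sim", function() {
    genome <- make_genome(1, 400000, 0, seed = 11)
    vec <- make_vector(seed = 2)
    clones <- simulate_bac_library(genome, vec, clone_coverage = 10,
                                   insert_mean = 40000, insert_sd = 5000,
                                   seed = 3)
    genome <- attr(clones, "genome")
    profiles <- clone_tag_profiles(clones, genome)
    list(genome = genome, vector = vec, clones = clones, profiles = profiles)
  })
}

tiny_pm <- function() {
  cached("tiny_pm", function() {
    physical_map(tiny_sim()$profiles)
  })
}

# Non-overlapping ("collision-free") clone set: disjoint inserts, so every
# tag belongs to exactly one clone and 3D deconvolution must be exact.
disjoint_library <- function() {
  cached("disjoint_library", function() {
    genome <- make_genome(1, 300000, 0, seed = 21)
    n <- 10L
    bounds <- as.integer(seq(0, 300000, length.out = n + 1L))
    idx <- seq_len(n) - 1L
    clones <- data.frame(
      clone_id = sprintf("d%02d", seq_len(n)),
      plate = idx %/% 4L + 1L, row = (idx %% 4L), col = (idx %% 2L) * 3L,
      chrom = "chr01", start = bounds[-(n + 1L)] + 100L, end = bounds[-1L] - 100L,
      strand = "+", stringsAsFactors = FALSE
    )
    class(clones) <- c("clone_library", "data.frame")
    attr(clones, "genome") <- genome
    clones
  })
}

# Synthetic tag profiles laid out as a linear tiling: clone i carries tags
# [start_i, start_i + width). Universe tags are "t0001"... Useful for exact
# clustering/ordering expectations.
tiling_profiles <- function(starts, width = 20L) {
  tags <- sprintf("t%04d", seq_len(max(starts) + width + 10L))
  profs <- lapply(starts, function(s) tags[(s + 1L):(s + width)])
  names(profs) <- sprintf("cl%02d", seq_along(starts))
  profs
}

random_seq <- function(n, seed) {
  with_seed_test(seed, paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = ""))
}

with_seed_test <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

# Brute-force N50-family oracle: sort descending, scan the cumulative sum.
brute_stats <- function(lengths, min_len = 500) {
  lens <- sort(lengths[lengths > min_len], decreasing = TRUE)
  if (!length(lens)) {
    return(list(total = 0, number = 0L, n50 = 0, c50 = 0L, n90 = 0, c90 = 0L,
                max = 0))
  }
  total <- sum(lens)
  pick <- function(frac) {
    acc <- 0
    for (x in lens) {
      acc <- acc + x
      if (acc >= frac * total) return(x)
    }
  }
  n50 <- pick(0.5)
  n90 <- pick(0.9)
  list(total = total, number = length(lens), n50 = n50,
       c50 = sum(lens >= n50), n90 = n90, c90 = sum(lens >= n90),
       max = max(lens))
}

# Plant substitutions at fixed positions (1-based), flipping each base to a
# different one deterministically.
plant_subs <- function(seq, positions) {
  r <- charToRaw(seq)
  flip <- c(A = "C", C = "G", G = "T", T = "A")
  for (p in positions) {
    r[p] <- charToRaw(flip[[rawToChar(r[p])]])
  }
  rawToChar(r)
}
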