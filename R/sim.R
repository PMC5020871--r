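# Synthetic-data generator: genomes, HindIII BAC libraries, MTP sequencing
# pools, pool-assembly unitigs (circular plasmids with a duplicated terminus),
# BES reads and WGS contigs, plus the truth tables needed to score every
# downstream stage. All operations are pure functions of (inputs, seed).

HINDIII <- "AAGCTT"
ECORI <- "GAATTC"
MSEI <- "TTAA"

#' Generate a synthetic truth genome
#'
#' Chromosomes are i.i.d. uniform DNA with optional planted dispersed
#' duplications totalling approximately `repeat_fraction` of the genome.
#' Planted copies are recorded so repeat-induced artifacts can be scored
#' downstream.
#'
#' @param n_chroms number of chromosomes.
#' @param chrom_len length of each chromosome in bp.
#' @param repeat_fraction target fraction of each chromosome covered by
#'   planted duplicate blocks (0 disables planting).
#' @param seed integer seed; fixes all randomness.
#' @return an object of class `genome_truth`: list with `chromosomes` (named
#'   character vector) and `repeats` (data.frame `chrom`, `start`, `end`,
#'   0-based half-open intervals of the planted copies).
#' @export
#' @examples
#' g <- make_genome(1, 5000, 0, seed = 1)
#' nchar(g$chromosomes)
make_genome <- function(n_chroms, chrom_len, repeat_fraction = 0, seed = 1L) {
  if (n_chroms < 1L || chrom_len < 1L) stop("n_chroms and chrom_len must be positive")
  if (repeat_fraction < 0 || repeat_fraction >= 1) stop("repeat_fraction must be in [0, 1)")
  with_seed(seed, {
    chroms <- character(n_chroms)
    names(chroms) <- sprintf("chr%02d", seq_len(n_chroms))
    reps <- list()
    for (i in seq_len(n_chroms)) {
      s <- random_dna(chrom_len)
      target <- repeat_fraction * chrom_len
      planted <- 0
      while (planted < target) {
        blk <- as.integer(round(runif(1, 2000, 8000)))
        blk <- min(blk, chrom_len %/% 4L)
        src <- sample.int(chrom_len - blk, 1L)
        dst <- sample.int(chrom_len - blk, 1L)
        block <- substr(s, src, src + blk - 1L)
        s <- paste0(substr(s, 1L, dst - 1L), block, substr(s, dst + blk, chrom_len))
        reps[[length(reps) + 1L]] <- data.frame(
          chrom = names(chroms)[i], start = dst - 1L, end = dst - 1L + blk
        )
        planted <- planted + blk
      }
      chroms[i] <- s
    }
    repeats <- if (length(reps)) do.call(rbind, reps) else
      data.frame(chrom = character(0), start = integer(0), end = integer(0))
    structure(list(chromosomes = chroms, repeats = repeats), class = "genome_truth")
  })
}

#' Construct a cloning-vector specification
#'
#' Emulates a pAGIBAC1-style vector: a circular sequence with exactly one
#' HindIII site (AAGCTT) at which inserts are cloned. The default is a random
#' 7.5 kb sequence with every spurious AAGCTT occurrence broken.
#'
#' @param length vector length in bp (>= 1000).
#' @param cloning_site_offset 0-based position of the single AAGCTT site;
#'   default places it at 100.
#' @param seed integer seed.
#' @param sequence optional explicit circular sequence; must contain exactly
#'   one AAGCTT at `cloning_site_offset`.
#' @return list of class `vector_spec` with `sequence` and
#'   `cloning_site_offset`.
#' @export
make_vector <- function(length = 7500L, cloning_site_offset = 100L, seed = 1L,
                        sequence = NULL) {
  if (is.null(sequence)) {
    if (length < 1000L) stop("vector length must be >= 1 kb")
    sequence <- with_seed(seed, {
      s <- random_dna(length)
      # break all chance AAGCTT occurrences, then plant the single site
      repeat {
        hits <- find_sites(s, HINDIII)
        if (!length(hits)) break
        for (h in hits) substr(s, h + 2L, h + 2L) <- "A"  # AAGCTT -> AAACTT
      }
      substr(s, cloning_site_offset + 1L, cloning_site_offset + 6L) <- HINDIII
      s
    })
  }
  hits <- find_sites(sequence, HINDIII)
  if (length(hits) != 1L || hits != cloning_site_offset + 1L) {
    stop("vector must contain exactly one AAGCTT at cloning_site_offset")
  }
  structure(list(sequence = sequence, cloning_site_offset = as.integer(cloning_site_offset)),
            class = "vector_spec")
}

# Genomic sequence of a clone insert (forward-strand truth coordinates).
clone_insert_seq <- function(clone, genome) {
  substr(genome$chromosomes[[clone$chrom]], clone$start + 1L, clone$end)
}

# Insert as present in the plasmid (reverse-complemented for '-' clones).
clone_cloned_seq <- function(clone, genome) {
  s <- clone_insert_seq(clone, genome)
  if (clone$strand == "-") revcomp(s) else s
}

#' Simulate a HindIII BAC library
#'
#' Samples `round(clone_coverage * genome_len / insert_mean)` clones with
#' N(insert_mean, insert_sd) target lengths and snaps both endpoints to the
#' nearest genomic AAGCTT occurrence, emulating a partial HindIII digest.
#' Chromosome ends (positions 0 and length) also count as valid fragment
#' boundaries, so clone coverage extends to the chromosome tails. When no
#' site lies within `2 * insert_sd` of a sampled interior endpoint, an AAGCTT
#' site is planted there (and the returned truth genome updated accordingly).
#' Clones are assigned 384-well addresses (16 rows x 24 columns) in fill
#' order.
#'
#' @param genome a `genome_truth`.
#' @param vector a `vector_spec` (recorded for provenance; inserts are vector
#'   free).
#' @param clone_coverage target clone coverage of the genome (e.g. 10).
#' @param insert_mean,insert_sd insert length distribution in bp.
#' @param seed integer seed.
#' @return data.frame of class `clone_library` with columns `clone_id`,
#'   `plate`, `row` (0-15), `col` (0-23), `chrom`, `start`, `end` (0-based
#'   half-open), `strand`; the possibly site-planted truth genome is attached
#'   as `attr(, "genome")`.
#' @export
simulate_bac_library <- function(genome, vector, clone_coverage = 10,
                                 insert_mean = 40000L, insert_sd = 5000L,
                                 seed = 1L) {
  if (clone_coverage <= 0) stop("clone_coverage must be positive")
  lens <- nchar(genome$chromosomes)
  if (insert_mean > max(lens)) stop("insert_mean larger than every chromosome")
  glen <- sum(lens)
  n_clones <- as.integer(round(clone_coverage * glen / insert_mean))
  with_seed(seed, {
    sites <- lapply(genome$chromosomes, find_sites, motif = HINDIII)
    chrom_pick <- sample(names(lens), n_clones, replace = TRUE, prob = lens / glen)
    out <- vector("list", n_clones)
    for (i in seq_len(n_clones)) {
      cn <- chrom_pick[i]
      clen <- lens[[cn]]
      L <- max(2000L, as.integer(round(rnorm(1, insert_mean, insert_sd))))
      s_raw <- as.integer(round(runif(1, -L / 2, clen - L / 2)))
      e_raw <- s_raw + L
      # snap an interior endpoint to the nearest AAGCTT start (1-based);
      # plant a site when none is near; clamp to the chromosome ends
      snap <- function(pos_raw) {
        if (pos_raw <= 0L) return(0L)
        if (pos_raw >= clen) return(clen)
        st <- sites[[cn]]
        if (length(st)) {
          d <- abs(st - 1L - pos_raw)  # site starts, 0-based
          j <- which.min(d)
          if (d[j] <= 2L * insert_sd) return(st[j] - 1L)
        }
        p0 <- min(max(pos_raw, 0L), clen - 6L)
        seqs <- genome$chromosomes
        substr(seqs[[cn]], p0 + 1L, p0 + 6L) <- HINDIII
        genome$chromosomes <<- seqs
        sites[[cn]] <<- sort(c(sites[[cn]], p0 + 1L))
        p0
      }
      s0 <- snap(s_raw)
      e0 <- snap(e_raw)
      if (e0 > clen - 6L && e0 < clen) e0 <- clen
      if (e0 > 0L && e0 < clen) e0 <- e0 + 6L  # include the closing AAGCTT
      if (e0 - s0 < 2000L) next
      out[[i]] <- data.frame(chrom = cn, start = s0, end = e0,
                             strand = sample(c("+", "-"), 1L))
    }
    out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
    n <- nrow(out)
    idx <- seq_len(n) - 1L
    plate <- idx %/% 384L + 1L
    within <- idx %% 384L
    row <- within %/% 24L
    col <- within %% 24L
    clones <- data.frame(
      clone_id = sprintf("b%03d%s%02d", plate, LETTERS[row + 1L], col + 1L),
      plate = plate, row = row, col = col,
      chrom = out$chrom, start = out$start, end = out$end, strand = out$strand,
      stringsAsFactors = FALSE
    )
    class(clones) <- c("clone_library", "data.frame")
    attr(clones, "genome") <- genome
    clones
  })
}

#' Simulate bi-directional BAC end sequences (BES)
#'
#' Forward read from the 5' end of the cloned insert, reverse read as the
#' reverse complement of its 3' end, with substitution errors.
#'
#' @param clone one row of a `clone_library` (as a list or 1-row data.frame).
#' @param genome the truth genome (use `attr(clones, "genome")`).
#' @param read_len read length in bp.
#' @param error_rate per-base substitution rate.
#' @param seed integer seed.
#' @return list with `forward` and `reverse` character reads.
#' @export
simulate_bes <- function(clone, genome, read_len = 700L, error_rate = 0.001,
                         seed = 1L) {
  if (read_len <= 0L) stop("read_len must be positive")
  ins <- clone_cloned_seq(clone, genome)
  L <- nchar(ins)
  if (read_len > L) stop("read_len exceeds insert length")
  with_seed(seed, {
    fwd <- mutate_seq(substr(ins, 1L, read_len), error_rate)
    rev <- mutate_seq(revcomp(substr(ins, L - read_len + 1L, L)), error_rate)
    list(forward = fwd, reverse = rev)
  })
}

# BES for a set of clones, keyed by clone_id.
simulate_bes_index <- function(clones, genome, read_len = 700L,
                               error_rate = 0.001, seed = 1L) {
  out <- vector("list", nrow(clones))
  names(out) <- clones$clone_id
  for (i in seq_len(nrow(clones))) {
    out[[i]] <- simulate_bes(clones[i, ], genome, read_len, error_rate,
                             seed = (seed + i) %% .Machine$integer.max)
  }
  out
}

POOL_CONFIGS <- c(row12 = 12L, tworow24 = 24L, fourcol32 = 32L,
                  sixcol48 = 48L, eightcol64 = 64L, plate96 = 96L)

#' Re-array MTP clones into 96-well plates and partition them into pools
#'
#' Clones are laid into 96-well plates (8 rows x 12 columns) in MTP order;
#' each plate is partitioned into sequencing pools according to its scheduled
#' configuration (recycled across plates). Row-based configurations chunk
#' wells row-major (so `row12` pools are plate rows), column-based ones
#' column-major. The final pool of a plate (and of the library) may be
#' smaller than the nominal size and keeps its label.
#'
#' @param mtp_clones character vector of clone ids in MTP order.
#' @param plate_size wells per plate (96).
#' @param config_schedule configurations from
#'   `c("row12","tworow24","fourcol32","sixcol48","eightcol64","plate96")`,
#'   one per plate, recycled.
#' @return data.frame `pool_id`, `config`, `plate`, `clone_id`.
#' @export
#' @examples
#' design_pools(sprintf("c%03d", 1:96), config_schedule = "row12")
design_pools <- function(mtp_clones, plate_size = 96L, config_schedule = "row12") {
  bad <- setdiff(config_schedule, names(POOL_CONFIGS))
  if (length(bad)) stop("unknown pool config: ", paste(bad, collapse = ", "))
  n <- length(mtp_clones)
  n_plates <- ceiling(n / plate_size)
  sched <- rep_len(config_schedule, n_plates)
  out <- list()
  for (p in seq_len(n_plates)) {
    wells <- mtp_clones[((p - 1L) * plate_size + 1L):min(p * plate_size, n)]
    cfg <- sched[p]
    size <- POOL_CONFIGS[[cfg]]
    if (grepl("col", cfg)) {
      # column-major traversal of the 8x12 plate
      nr <- 8L
      ord <- order(((seq_along(wells) - 1L) %% 12L), ((seq_along(wells) - 1L) %/% 12L))
      wells <- wells[ord]
    }
    k <- ceiling(length(wells) / size)
    for (j in seq_len(k)) {
      members <- wells[((j - 1L) * size + 1L):min(j * size, length(wells))]
      out[[length(out) + 1L]] <- data.frame(
        pool_id = sprintf("pool_p%02d_%s_%d", p, cfg, j),
        config = cfg, plate = p, clone_id = members, stringsAsFactors = FALSE
      )
    }
  }
  do.call(rbind, out)
}

# Circular plasmid sequence for a clone: vector opened at its HindIII site
# with the insert ligated in. The vector's own site is consumed; the insert
# carries the restored AAGCTT at both junctions.
clone_plasmid <- function(clone, genome, vector) {
  ins <- clone_cloned_seq(clone, genome)
  v <- vector$sequence
  cs0 <- vector$cloning_site_offset
  paste0(substr(v, 1L, cs0), ins, substr(v, cs0 + 7L, nchar(v)))
}

#' Simulate HGAP-style pool unitigs
#'
#' For each member clone of a pool, with probability `1 - fail_rate` emits a
#' unitig: the circular plasmid (vector + insert) linearized at a random
#' rotation with its first `dup_overlap_len` bases appended at the 3' end
#' (the duplicated terminus that marks a circular molecule), plus
#' substitution errors. With probability `fail_rate` a truncated linear
#' fragment is emitted instead.
#'
#' @param pool data.frame rows of one pool from [design_pools()].
#' @param clones the `clone_library`.
#' @param genome truth genome (use `attr(clones, "genome")`).
#' @param vector the `vector_spec`.
#' @param dup_overlap_len planted terminal duplication length (>= 500 so
#'   circularization is detectable at the default thresholds).
#' @param error_rate per-base substitution rate.
#' @param fail_rate probability a clone yields a truncated, non-circular
#'   fragment.
#' @param seed integer seed.
#' @return data.frame `unitig_id`, `source_pool_id`, `truth_clone_id`,
#'   `truth_is_circular`, `planted_terminal_dup_len`, `sequence`.
#' @export
simulate_pool_unitigs <- function(pool, clones, genome, vector,
                                  dup_overlap_len = 600L, error_rate = 5e-4,
                                  fail_rate = 0, seed = 1L) {
  if (dup_overlap_len < 500L) stop("dup_overlap_len must be >= 500")
  with_seed(seed, {
    out <- vector("list", nrow(pool))
    for (i in seq_len(nrow(pool))) {
      cid <- pool$clone_id[i]
      cl <- clones[clones$clone_id == cid, ]
      plasmid <- clone_plasmid(cl, genome, vector)
      plen <- nchar(plasmid)
      if (dup_overlap_len >= plen) stop("dup_overlap_len >= plasmid length")
      ok <- runif(1) >= fail_rate
      if (ok) {
        u <- rotate_seq(plasmid, sample.int(plen, 1L))
        u <- paste0(u, substr(u, 1L, dup_overlap_len))
        u <- mutate_seq(u, error_rate)
        circ <- TRUE
        dup <- dup_overlap_len
      } else {
        frag_len <- as.integer(round(runif(1, 0.3, 0.7) * plen))
        u <- rotate_seq(plasmid, sample.int(plen, 1L))
        u <- mutate_seq(substr(u, 1L, frag_len), error_rate)
        circ <- FALSE
        dup <- 0L
      }
      out[[i]] <- data.frame(
        unitig_id = sprintf("%s_utg%02d", pool$pool_id[i], i),
        source_pool_id = pool$pool_id[i], truth_clone_id = cid,
        truth_is_circular = circ, planted_terminal_dup_len = dup,
        sequence = u, stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate fragmented WGS contigs
#'
#' Cuts the truth genome at `n_breaks` random positions, drops pieces shorter
#' than `min_len`, and returns the remainder in random order and random
#' orientation. Emulates an independent short-read assembly of the same
#' genome (error-free; its role downstream is gap bridging).
#'
#' @param genome truth genome.
#' @param n_breaks number of random breakpoints across the genome.
#' @param min_len minimum retained piece length in bp.
#' @param seed integer seed.
#' @return named character vector of contig sequences; truth origins in
#'   `attr(, "truth")` (`contig_id`, `chrom`, `start`, `end`, `strand`).
#' @export
simulate_wgs_contigs <- function(genome, n_breaks, min_len = 500L, seed = 1L) {
  if (n_breaks < 0L) stop("n_breaks must be >= 0")
  lens <- nchar(genome$chromosomes)
  with_seed(seed, {
    pieces <- list()
    chrom_pick <- if (n_breaks > 0L) {
      sample(names(lens), n_breaks, replace = TRUE, prob = lens / sum(lens))
    } else character(0)
    for (cn in names(lens)) {
      cuts <- sort(unique(c(0L, vapply(which(chrom_pick == cn), function(i)
        sample.int(lens[[cn]] - 1L, 1L), integer(1)), lens[[cn]])))
      for (j in seq_len(length(cuts) - 1L)) {
        s <- cuts[j]; e <- cuts[j + 1L]
        if (e - s >= min_len) {
          pieces[[length(pieces) + 1L]] <- list(
            chrom = cn, start = s, end = e,
            seq = substr(genome$chromosomes[[cn]], s + 1L, e)
          )
        }
      }
    }
    if (!length(pieces)) {
      out <- character(0)
      attr(out, "truth") <- data.frame(contig_id = character(0), chrom = character(0),
                                       start = integer(0), end = integer(0),
                                       strand = character(0))
      return(out)
    }
    ord <- sample.int(length(pieces))
    pieces <- pieces[ord]
    strand <- sample(c("+", "-"), length(pieces), replace = TRUE)
    out <- vapply(seq_along(pieces), function(i) {
      if (strand[i] == "-") revcomp(pieces[[i]]$seq) else pieces[[i]]$seq
    }, character(1))
    names(out) <- sprintf("wgs%04d", seq_along(pieces))
    attr(out, "truth") <- data.frame(
      contig_id = names(out),
      chrom = vapply(pieces, `[[`, character(1), "chrom"),
      start = vapply(pieces, `[[`, integer(1), "start"),
      end = vapply(pieces, `[[`, integer(1), "end"),
      strand = strand, stringsAsFactors = FALSE
    )
    out
  })
}

#' Extract bridge contigs spanning coverage gaps
#'
#' Returns truth-genome segments covering each gap interval plus `flank`
#' bases on both sides, so a gap between two assembled flanks can be bridged
#' by terminal overlaps. Mirrors the role of the short-read contigs that
#' happen to span physical-map gaps.
#'
#' @param genome truth genome.
#' @param gaps data.frame with `chrom`, `start`, `end` (0-based half-open
#'   truth intervals of the gaps).
#' @param flank flanking length in bp added on each side.
#' @return named character vector of bridge sequences.
#' @export
simulate_bridge_contigs <- function(genome, gaps, flank = 5000L) {
  if (!nrow(gaps)) return(character(0))
  out <- character(nrow(gaps))
  for (i in seq_len(nrow(gaps))) {
    cn <- gaps$chrom[i]
    clen <- nchar(genome$chromosomes[[cn]])
    s <- max(0L, gaps$start[i] - flank)
    e <- min(clen, gaps$end[i] + flank)
    out[i] <- substr(genome$chromosomes[[cn]], s + 1L, e)
  }
  names(out) <- sprintf("bridge%03d", seq_len(nrow(gaps)))
  out
}

#' Write a simulation to disk
#'
#' Emits the simulator outputs as plain-text files: genome and vector FASTA,
#' clones TSV (0-based half-open coordinates), pools TSV, unitigs FASTA
#' (pool id in the header), BES FASTA, WGS contigs FASTA and the truth
#' tag-to-clone map TSV.
#'
#' @param sim a list as returned by [run_pipeline()] (or a subset of its
#'   fields: `genome`, `vector`, `clones`, `pools`, `unitigs`, `bes`,
#'   `wgs_contigs`, `profiles`).
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(sim$genome)) write_fasta(sim$genome$chromosomes, file.path(dir, "genome.fa"))
  if (!is.null(sim$vector)) {
    v <- sim$vector$sequence
    names(v) <- sprintf("vector cloning_site_offset=%d", sim$vector$cloning_site_offset)
    write_fasta(v, file.path(dir, "vector.fa"))
  }
  if (!is.null(sim$clones)) write_tsv(as.data.frame(sim$clones), file.path(dir, "clones.tsv"))
  if (!is.null(sim$pools)) write_tsv(sim$pools, file.path(dir, "pools.tsv"))
  if (!is.null(sim$unitigs)) {
    u <- sim$unitigs$sequence
    names(u) <- sprintf("%s pool=%s", sim$unitigs$unitig_id, sim$unitigs$source_pool_id)
    write_fasta(u, file.path(dir, "unitigs.fa"))
  }
  if (!is.null(sim$bes)) {
    reads <- unlist(lapply(names(sim$bes), function(cid) {
      r <- sim$bes[[cid]]
      stats::setNames(c(r$forward, r$reverse), paste0(cid, c(".f", ".r")))
    }))
    write_fasta(reads, file.path(dir, "bes.fa"))
  }
  if (!is.null(sim$wgs_contigs)) write_fasta(sim$wgs_contigs, file.path(dir, "wgs_contigs.fa"))
  if (!is.null(sim$profiles)) {
    tags <- data.frame(
      clone_id = rep(names(sim$profiles), lengths(sim$profiles)),
      tag = unlist(sim$profiles, use.names = FALSE)
    )
    write_tsv(tags, file.path(dir, "truth_tags.tsv"))
  }
  invisible(dir)
}
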