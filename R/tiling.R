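# Pseudomolecule construction: clone sequences are anchored to a guide
# reference (order/orientation only -- no guide bases ever enter the output),
# end-overlapping neighbors are merged keeping exactly one copy of the
# redundant overlap, and remaining gaps are bridged by WGS contigs that fully
# connect both flanks.

#' Pseudomolecule construction parameters
#'
#' Defaults follow the published merge rules: two sequences merge when they
#' share a terminal overlap of at least 1000 bp at 99% identity, with the
#' overlap required to be at the ends of both sequences (within
#' `terminal_slack`).
#'
#' @param min_overlap_seq minimum sequence-to-sequence overlap span (bp).
#' @param identity_seq minimum overlap identity.
#' @param terminal_slack tolerated distance (bp) from a sequence end.
#' @param require_end_overlap require overlaps to be terminal on both pieces.
#' @param gap_run length of the N run written for an open gap.
#' @param max_window cap (bp) on the terminal window searched for overlaps.
#' @return list of class `gpm_params`.
#' @export
gpm_params <- function(min_overlap_seq = 1000L, identity_seq = 0.99,
                       terminal_slack = 25L, require_end_overlap = TRUE,
                       gap_run = 100L, max_window = 200000L) {
  if (identity_seq <= 0 || identity_seq > 1) stop("identity_seq must lie in (0, 1]")
  structure(list(min_overlap_seq = as.integer(min_overlap_seq),
                 identity_seq = identity_seq,
                 terminal_slack = as.integer(terminal_slack),
                 require_end_overlap = require_end_overlap,
                 gap_run = as.integer(gap_run),
                 max_window = as.integer(max_window)),
            class = "gpm_params")
}

#' Anchor sequence pieces to a guide reference
#'
#' Each piece is placed on the guide by exact k-mer voting (31-mers sampled
#' along the piece, matched on both strands against every guide chromosome;
#' the locus with the most consistent votes wins, i.e. best total matching
#' bases). Pieces whose second-best locus attracts at least half the winning
#' votes are flagged as multi-mapping; when a physical-map order is supplied,
#' flagged or order-discordant pieces are re-placed by interpolating between
#' their map neighbors (the physical map wins over the guide). The guide
#' determines order and orientation only.
#'
#' @param pieces named character vector of sequences (BAC inserts or WGS
#'   pieces).
#' @param guide a `genome_truth` or named character vector of guide
#'   chromosomes.
#' @param pm_order optional data.frame `seq_id`, `contig_id`, `rank` giving
#'   the physical-map (MTP) order of the pieces.
#' @param source label recorded for the pieces ("BAC" or "WGS").
#' @param k seed k-mer length.
#' @param n_seeds seeds sampled per piece.
#' @return list `anchored` (data.frame `seq_id`, `source`, `chrom`,
#'   `anchor_start` 0-based, `orientation`, `votes`, `flagged`) and
#'   `unanchored` (character vector of piece ids).
#' @export
anchor_pieces <- function(pieces, guide, pm_order = NULL, source = "BAC",
                          k = 31L, n_seeds = 16L) {
  chroms <- if (inherits(guide, "genome_truth")) guide$chromosomes else guide
  seed_tab <- list()
  for (sid in names(pieces)) {
    s <- pieces[[sid]]
    ns <- nchar(s)
    if (ns < k) next
    ps <- unique(as.integer(round(seq(1L, ns - k + 1L,
                                      length.out = min(n_seeds, ns - k + 1L)))))
    for (orient in c("+", "-")) {
      q <- if (orient == "+") s else revcomp(s)
      seed_tab[[length(seed_tab) + 1L]] <- data.frame(
        seq_id = sid, orient = orient, qpos = ps,
        kmer = substr(rep(q, length(ps)), ps, ps + k - 1L)
      )
    }
  }
  seeds <- do.call(rbind, seed_tab)
  anchored <- list()
  unanchored <- setdiff(names(pieces), unique(seeds$seq_id))
  votes_all <- list()
  pd <- PDict(DNAStringSet(seeds$kmer))
  for (cn in names(chroms)) {
    mi <- matchPDict(pd, DNAString(chroms[[cn]]))
    starts <- startIndex(mi)
    hit <- which(lengths(starts) > 0L)
    if (!length(hit)) next
    votes_all[[cn]] <- data.frame(
      seq_id = rep(seeds$seq_id[hit], lengths(starts[hit])),
      orient = rep(seeds$orient[hit], lengths(starts[hit])),
      chrom = cn,
      anchor = unlist(starts[hit]) - rep(seeds$qpos[hit], lengths(starts[hit]))
    )  # 0-based implied anchor of the (oriented) piece start
  }
  votes <- do.call(rbind, votes_all)
  if (is.null(votes) || !nrow(votes)) {
    return(list(anchored = data.frame(seq_id = character(0), source = character(0),
                                      chrom = character(0), anchor_start = integer(0),
                                      orientation = character(0), votes = integer(0),
                                      flagged = logical(0)),
                unanchored = names(pieces)))
  }
  for (sid in unique(votes$seq_id)) {
    v <- votes[votes$seq_id == sid, , drop = FALSE]
    key <- paste(v$chrom, v$orient, v$anchor)
    tab <- sort(table(key), decreasing = TRUE)
    best <- strsplit(names(tab)[1L], " ")[[1L]]
    flagged <- length(tab) > 1L && tab[2L] >= tab[1L] / 2
    anchored[[sid]] <- data.frame(
      seq_id = sid, source = source, chrom = best[1L],
      anchor_start = as.integer(best[3L]), orientation = best[2L],
      votes = as.integer(tab[1L]), flagged = flagged
    )
  }
  anc <- do.call(rbind, anchored)
  unanchored <- c(unanchored, setdiff(names(pieces), anc$seq_id))
  if (!is.null(pm_order)) {
    anc <- reconcile_pm_order(anc, pm_order)
  }
  anc <- anc[order(anc$chrom, anc$anchor_start), , drop = FALSE]
  rownames(anc) <- NULL
  list(anchored = anc, unanchored = unanchored)
}

# Enforce physical-map order: within each map contig (walk order only), a
# piece that is both order-discordant and multi-mapping is re-anchored by
# interpolating its neighbors' anchors — the map order wins over an
# ambiguous guide placement. Discordant pieces with an unambiguous anchor
# are flagged but left where the guide put them.
reconcile_pm_order <- function(anc, pm_order) {
  for (ctg in unique(pm_order$contig_id)) {
    po <- pm_order[pm_order$contig_id == ctg, , drop = FALSE]
    po <- po[order(po$rank), , drop = FALSE]
    idx <- match(po$seq_id, anc$seq_id)
    idx <- idx[!is.na(idx)]
    if (length(idx) < 3L) next
    a <- anc$anchor_start[idx]
    if (sum(diff(a) > 0) < sum(diff(a) < 0)) {  # map runs right-to-left
      idx <- rev(idx)
      a <- rev(a)
    }
    multi <- anc$flagged[idx]  # multi-mapping flags from the vote stage
    for (j in seq_along(idx)) {
      lo <- if (j > 1L) a[j - 1L] else -Inf
      hi <- if (j < length(idx)) a[j + 1L] else Inf
      disc <- a[j] < min(lo, hi) || a[j] > max(lo, hi)
      if (!disc) next
      anc$flagged[idx[j]] <- TRUE
      neigh <- c(if (j > 1L) a[j - 1L], if (j < length(idx)) a[j + 1L])
      if (multi[j] && length(neigh) == 2L) {
        anc$anchor_start[idx[j]] <- as.integer(round(mean(neigh)))
        a[j] <- anc$anchor_start[idx[j]]
      }
    }
  }
  anc
}

# Find a terminal overlap: suffix of `a` against prefix of `b`. Returns
# list(d, span, identity) where `d` is the 1-based position in `a` at which
# b's first base aligns, or NULL. Seeds come from b's prefix; identity is
# positional at the modal offset (substitution error model).
find_end_overlap <- function(a, b, params, est = NULL) {
  na <- nchar(a)
  nb <- nchar(b)
  wa <- min(na, params$max_window)
  aw <- substr(a, na - wa + 1L, na)
  search_len <- if (!is.null(est) && est > 0) min(nb, est + 3000L) else min(nb, wa)
  qpos <- unique(c(seq(1L, min(800L, search_len), by = 53L),
                   as.integer(round(seq(1L, max(1L, search_len - 24L), length.out = 24L)))))
  votes <- vote_offsets(b, aw, k = 24L, qpos = qpos)
  if (!nrow(votes)) return(NULL)
  for (r in seq_len(nrow(votes))) {
    d <- votes$offset[r] + (na - wa)  # position in full `a`
    if (d < 1L) next
    span <- na - d + 1L
    if (span < params$min_overlap_seq) next
    cmp_len <- min(span, nb)
    ident <- hamming_identity(substr(a, d, d + cmp_len - 1L),
                              substr(b, 1L, cmp_len))
    if (ident >= params$identity_seq) {
      return(list(d = d, span = span, identity = ident))
    }
  }
  NULL
}

#' Choose which copy of a redundant overlap to keep
#'
#' When exactly one copy contains ambiguity characters (N), the clean copy is
#' kept; otherwise the upstream copy is kept (a deterministic tie-break; a
#' warning is logged when both copies carry Ns).
#'
#' @param a_overlap,b_overlap the two copies of the overlapping sequence
#'   (upstream piece's copy first).
#' @return the chosen copy.
#' @export
keep_one_copy <- function(a_overlap, b_overlap) {
  a_has <- grepl("N", a_overlap, fixed = TRUE)
  b_has <- grepl("N", b_overlap, fixed = TRUE)
  if (a_has && !b_has) return(b_overlap)
  if (a_has && b_has) warning("both overlap copies contain Ns; keeping upstream")
  a_overlap
}

#' Merge two anchored neighbors or record a gap
#'
#' Searches for a terminal overlap between a suffix window of `a` and a
#' prefix window of `b` spanning at least `min_overlap_seq` bp at
#' `identity_seq` identity. On success the pieces are joined with exactly one
#' copy of the overlap retained ([keep_one_copy()]); a piece fully contained
#' in its neighbor is dropped as redundant. Otherwise an open gap is
#' recorded.
#'
#' @param a,b lists with `seq_id`, `sequence` (oriented forward) and
#'   optionally `anchor_start`; `a` precedes `b`.
#' @param params a [gpm_params()].
#' @return list `type` ("merged"/"gap"/"contained") plus the merged piece
#'   (`seq_id`, `sequence`, `anchor_start`) or gap metadata.
#' @export
merge_neighbors <- function(a, b, params = gpm_params()) {
  est <- if (!is.null(a$anchor_start) && !is.null(b$anchor_start)) {
    (a$anchor_start + nchar(a$sequence)) - b$anchor_start
  } else {
    NULL
  }
  ov <- find_end_overlap(a$sequence, b$sequence, params, est = est)
  if (is.null(ov)) {
    return(list(type = "gap", left = a$seq_id, right = b$seq_id))
  }
  nb <- nchar(b$sequence)
  if (ov$span >= nb) {
    return(list(type = "contained", dropped = b$seq_id, piece = a))
  }
  na <- nchar(a$sequence)
  a_copy <- substr(a$sequence, ov$d, na)
  b_copy <- substr(b$sequence, 1L, ov$span)
  chosen <- keep_one_copy(a_copy, b_copy)
  merged <- paste0(substr(a$sequence, 1L, ov$d - 1L), chosen,
                   substr(b$sequence, ov$span + 1L, nb))
  list(type = "merged",
       piece = list(seq_id = paste(a$seq_id, b$seq_id, sep = "+"),
                    sequence = merged, anchor_start = a$anchor_start),
       span = ov$span, identity = ov$identity)
}

#' Build pseudomolecules from anchored pieces
#'
#' Per chromosome, pieces are sorted by anchor and folded left-to-right
#' through [merge_neighbors()]; runs of merged pieces separated by open gaps
#' become the pseudomolecule's contigs. Open gaps are written as runs of
#' `gap_run` Ns in the exported sequence.
#'
#' @param anchoring output of [anchor_pieces()] (its `anchored` element is
#'   used).
#' @param pieces named character vector of the piece sequences (unoriented).
#' @param params a [gpm_params()].
#' @return list of `pseudomolecule` objects: `chrom`, `runs` (list of
#'   `seq_id`/`sequence`/`anchor_start`), `gaps` (data.frame), `components`,
#'   `contig_count`.
#' @export
build_pseudomolecules <- function(anchoring, pieces, params = gpm_params()) {
  anc <- anchoring$anchored
  out <- list()
  for (cn in unique(anc$chrom)) {
    ac <- anc[anc$chrom == cn, , drop = FALSE]
    ac <- ac[order(ac$anchor_start), , drop = FALSE]
    runs <- list()
    gaps <- list()
    cur <- NULL
    for (i in seq_len(nrow(ac))) {
      seqi <- pieces[[ac$seq_id[i]]]
      if (ac$orientation[i] == "-") seqi <- revcomp(seqi)
      nxt <- list(seq_id = ac$seq_id[i], sequence = seqi,
                  anchor_start = ac$anchor_start[i])
      if (is.null(cur)) {
        cur <- nxt
        next
      }
      res <- merge_neighbors(cur, nxt, params)
      if (res$type == "merged" || res$type == "contained") {
        cur <- res$piece
      } else {
        runs[[length(runs) + 1L]] <- cur
        gaps[[length(gaps) + 1L]] <- data.frame(
          left_piece = cur$seq_id, right_piece = nxt$seq_id,
          left_anchor_end = cur$anchor_start + nchar(cur$sequence),
          right_anchor_start = nxt$anchor_start,
          status = "open", filler_seq_id = NA_character_, filled_length = NA_integer_
        )
        cur <- nxt
      }
    }
    if (!is.null(cur)) runs[[length(runs) + 1L]] <- cur
    ps <- structure(list(chrom = cn, runs = runs,
                         gaps = if (length(gaps)) do.call(rbind, gaps) else
                           data.frame(left_piece = character(0), right_piece = character(0),
                                      left_anchor_end = integer(0), right_anchor_start = integer(0),
                                      status = character(0), filler_seq_id = character(0),
                                      filled_length = integer(0)),
                         gap_run = params$gap_run),
                    class = "pseudomolecule")
    out[[cn]] <- refresh_components(ps)
  }
  out
}

# Rebuild the component table and contig count from runs + gaps.
refresh_components <- function(ps) {
  comps <- list()
  for (i in seq_along(ps$runs)) {
    r <- ps$runs[[i]]
    comps[[length(comps) + 1L]] <- list(type = "piece", id = r$seq_id,
                                        length = nchar(r$sequence),
                                        orientation = "+")
    if (i < length(ps$runs)) {
      comps[[length(comps) + 1L]] <- list(type = "gap", length = ps$gap_run)
    }
  }
  ps$components <- comps
  ps$contig_count <- length(ps$runs)
  ps
}

#' Export a pseudomolecule's sequence
#'
#' Contig runs joined by `gap_run`-length N runs at open gaps.
#' @param ps a `pseudomolecule`.
#' @return character scalar.
#' @export
pseudo_sequence <- function(ps) {
  paste(vapply(ps$runs, `[[`, character(1), "sequence"),
        collapse = strrep("N", ps$gap_run))
}

#' Fill pseudomolecule gaps with bridging WGS contigs
#'
#' For each open gap a WGS contig (either orientation) qualifies only when it
#' has a terminal overlap (>= `min_overlap_seq` bp, >= `identity_seq`,
#' terminal on both sequences) with the end of the left flank AND the start
#' of the right flank: it must fully connect the two neighbors. The contig is
#' inserted minus both overlap copies (the BAC copies are always retained);
#' when the trimmed filler has no length the flanks are joined directly.
#' Among multiple candidates the greatest summed identity wins, ties going to
#' the longer contig; a contig is consumed by the gap it fills. Every filled
#' gap reduces the contig count by exactly one.
#'
#' A physical map is blind beyond its terminal tags, so pseudomolecule ends
#' can stop short of the chromosome ends; with `extend_ends` a WGS contig
#' overlapping a pseudomolecule end terminally (same span/identity rules,
#' single-sided) extends it outward, again retaining the BAC copy of the
#' overlap.
#'
#' @param pseudos list of `pseudomolecule` objects.
#' @param wgs_contigs named character vector of WGS contig sequences.
#' @param params a [gpm_params()].
#' @param extend_ends also extend pseudomolecule ends with terminally
#'   overlapping contigs.
#' @return list `pseudos` (updated), `gap_report` (data.frame of all gaps
#'   with fill status; end extensions appear with status "end_extended").
#' @export
fill_gaps <- function(pseudos, wgs_contigs, params = gpm_params(),
                      extend_ends = TRUE) {
  available <- wgs_contigs
  report <- list()
  for (cn in names(pseudos)) {
    ps <- pseudos[[cn]]
    i <- 1L
    while (i < length(ps$runs)) {
      gp <- ps$gaps[i, , drop = FALSE]
      if (gp$status != "open") {
        i <- i + 1L
        next
      }
      L <- ps$runs[[i]]
      R <- ps$runs[[i + 1L]]
      best <- NULL
      for (cid in names(available)) {
        for (orient in c("+", "-")) {
          cseq <- if (orient == "+") available[[cid]] else revcomp(available[[cid]])
          ov1 <- find_end_overlap(L$sequence, cseq, params)
          if (is.null(ov1)) next
          ov2 <- find_end_overlap(cseq, R$sequence, params)
          if (is.null(ov2)) next
          sc <- ov1$identity + ov2$identity
          if (is.null(best) || sc > best$score ||
              (sc == best$score && nchar(cseq) > nchar(best$cseq))) {
            best <- list(cid = cid, cseq = cseq, ov1 = ov1, ov2 = ov2, score = sc)
          }
        }
      }
      if (is.null(best)) {
        i <- i + 1L
        next
      }
      fill_start <- best$ov1$span + 1L          # drop C's copy of the left overlap
      fill_end <- best$ov2$d - 1L               # drop C's copy of the right overlap
      filler <- if (fill_start > fill_end) "" else
        substr(best$cseq, fill_start, fill_end)
      # when the bridge shows the flanks themselves overlap (fill_start past
      # fill_end), drop the duplicated prefix of the right flank, keeping
      # the upstream copy
      r_trim <- max(0L, fill_start - 1L - fill_end)
      merged <- list(seq_id = paste(L$seq_id, best$cid, R$seq_id, sep = "+"),
                     sequence = paste0(L$sequence, filler,
                                       substr(R$sequence, r_trim + 1L,
                                              nchar(R$sequence))),
                     anchor_start = L$anchor_start)
      ps$runs[[i]] <- merged
      ps$runs[[i + 1L]] <- NULL
      ps$gaps$status[i] <- "filled"
      ps$gaps$filler_seq_id[i] <- best$cid
      ps$gaps$filled_length[i] <- nchar(filler)
      gp_row <- ps$gaps[i, , drop = FALSE]
      ps$gaps <- ps$gaps[-i, , drop = FALSE]
      report[[length(report) + 1L]] <- cbind(chrom = cn, gp_row)
      available <- available[names(available) != best$cid]
    }
    open <- ps$gaps
    if (nrow(open)) report[[length(report) + 1L]] <- cbind(chrom = cn, open)
    if (extend_ends) {
      for (side in c("left", "right")) {
        idx <- if (side == "left") 1L else length(ps$runs)
        run <- ps$runs[[idx]]
        best <- NULL
        for (cid in names(available)) {
          for (orient in c("+", "-")) {
            cseq <- if (orient == "+") available[[cid]] else revcomp(available[[cid]])
            ov <- if (side == "left") find_end_overlap(cseq, run$sequence, params)
                  else find_end_overlap(run$sequence, cseq, params)
            if (is.null(ov)) next
            ext_len <- if (side == "left") ov$d - 1L else nchar(cseq) - ov$span
            if (ext_len <= 0L) next
            if (is.null(best) || ov$identity > best$identity ||
                (ov$identity == best$identity && ext_len > best$ext_len)) {
              best <- list(cid = cid, cseq = cseq, ov = ov, ext_len = ext_len,
                           identity = ov$identity)
            }
          }
        }
        if (!is.null(best)) {
          if (side == "left") {
            run$sequence <- paste0(substr(best$cseq, 1L, best$ov$d - 1L),
                                   run$sequence)
            run$anchor_start <- run$anchor_start - best$ext_len
            run$seq_id <- paste(best$cid, run$seq_id, sep = "+")
          } else {
            run$sequence <- paste0(run$sequence,
                                   substr(best$cseq, best$ov$span + 1L,
                                          nchar(best$cseq)))
            run$seq_id <- paste(run$seq_id, best$cid, sep = "+")
          }
          ps$runs[[idx]] <- run
          available <- available[names(available) != best$cid]
          report[[length(report) + 1L]] <- data.frame(
            chrom = cn, left_piece = if (side == "left") best$cid else run$seq_id,
            right_piece = if (side == "left") run$seq_id else best$cid,
            left_anchor_end = NA_integer_, right_anchor_start = NA_integer_,
            status = "end_extended", filler_seq_id = best$cid,
            filled_length = best$ext_len
          )
        }
      }
    }
    pseudos[[cn]] <- refresh_components(ps)
  }
  gap_report <- if (length(report)) do.call(rbind, report) else
    data.frame(chrom = character(0), left_piece = character(0),
               right_piece = character(0), left_anchor_end = integer(0),
               right_anchor_start = integer(0), status = character(0),
               filler_seq_id = character(0), filled_length = integer(0))
  rownames(gap_report) <- NULL
  list(pseudos = pseudos, gap_report = gap_report)
}
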