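# Post-assembly processing of pool unitigs ("postHGAP"): a circular plasmid
# assembled from a pool carries a duplicated terminus; detecting and trimming
# that terminal self-overlap circularizes the unitig, the vector is then
# located and excised to linearize the insert, and the insert is assigned to
# a BAC clone by exact WGP-tag matching with a BES alignment fallback.

#' postHGAP parameters
#'
#' Defaults are the published fixed parameters: circularization requires a
#' terminal self-overlap of at least 500 bp at 95% identity; clone
#' identification requires at least 5 exactly-matching profile tags covering
#' at least 80% of the clone's profile; the BES fallback requires 98%
#' identity over the full read when no WGP tag evidence is available.
#'
#' @param min_overlap minimum terminal overlap span (bp).
#' @param overlap_identity minimum terminal overlap identity.
#' @param min_clone_tag_number minimum matched profile tags.
#' @param tag_match_identity tag comparison identity; fixed at 1 (exact).
#' @param tag_match_percent minimum fraction of a clone's profile matched.
#' @param bes_match_identity minimum BES alignment identity.
#' @param terminal_slack how close (bp) a self-overlap must reach to both
#'   sequence ends to count as terminal.
#' @param require_bes_orientation require the BES pair to face inward on the
#'   insert (suppresses spurious hits; switchable).
#' @return list of class `posthgap_params`.
#' @export
posthgap_params <- function(min_overlap = 500L, overlap_identity = 0.95,
                            min_clone_tag_number = 5L, tag_match_identity = 1,
                            tag_match_percent = 0.80, bes_match_identity = 0.98,
                            terminal_slack = 25L,
                            require_bes_orientation = TRUE) {
  if (tag_match_identity != 1) stop("tags are matched exactly (identity fixed at 100%)")
  ids <- c(overlap_identity, tag_match_percent, bes_match_identity)
  if (any(ids <= 0 | ids > 1)) stop("identities must lie in (0, 1]")
  if (min_overlap < 1L) stop("min_overlap must be >= 1")
  structure(list(min_overlap = as.integer(min_overlap),
                 overlap_identity = overlap_identity,
                 min_clone_tag_number = as.integer(min_clone_tag_number),
                 tag_match_identity = 1, tag_match_percent = tag_match_percent,
                 bes_match_identity = bes_match_identity,
                 terminal_slack = as.integer(terminal_slack),
                 require_bes_orientation = require_bes_orientation),
            class = "posthgap_params")
}

#' Detect a terminal self-overlap in a unitig
#'
#' Searches for the longest alignment between a prefix and a suffix of the
#' unitig that spans at least `min_overlap` bp at identity at least
#' `overlap_identity` and reaches both sequence ends (within
#' `terminal_slack`). Candidate overlap lengths come from exact k-mer seeds
#' sampled near the 5' end and located near the 3' end; identity is then
#' computed positionally over the full candidate span (the error model is
#' substitution-dominated, so true offsets are exact).
#'
#' @param unitig character sequence.
#' @param params a [posthgap_params()].
#' @return list `overlap_len`, `identity`, or `NULL` when no terminal
#'   overlap qualifies (including sequences shorter than `2 * min_overlap`).
#' @export
detect_terminal_overlap <- function(unitig, params = posthgap_params()) {
  n <- nchar(unitig)
  if (n <= 2L * params$min_overlap) return(NULL)
  k <- 24L
  # seeds throughout the first min_overlap window (several, to ride over
  # substitution errors), plus a few deeper ones for long duplications
  qpos <- unique(c(seq(1L, max(1L, params$min_overlap - k), by = 23L),
                   seq(params$min_overlap, min(4L * params$min_overlap, n %/% 3L), by = 101L)))
  cand <- integer(0)
  for (p in qpos) {
    pat <- substr(unitig, p, p + k - 1L)
    hits <- find_sites(unitig, pat)
    hits <- hits[hits > n %/% 2L & hits > p]
    cand <- c(cand, hits - p + 1L)  # implied offset d: u[1] aligns u[d]
  }
  if (!length(cand)) return(NULL)
  tab <- sort(table(cand), decreasing = TRUE)
  offsets <- as.integer(names(tab))
  # prefer longer overlaps (smaller offsets) among the voted candidates
  offsets <- offsets[order(offsets)]
  for (d in offsets) {
    L <- n - d + 1L
    if (L < params$min_overlap || d <= n %/% 2L) next
    ident <- hamming_identity(substr(unitig, 1L, L), substr(unitig, d, n))
    if (ident >= params$overlap_identity) {
      return(list(overlap_len = L, identity = ident))
    }
  }
  NULL
}

#' Circularize a unitig
#'
#' On detection of a terminal self-overlap the 3' copy is trimmed and the
#' sequence is rotation-canonicalized to start at its lexicographically
#' minimal rotation; otherwise the unitig is reported linear and kept as is.
#'
#' @param unitig character sequence.
#' @param params a [posthgap_params()].
#' @param unitig_id identifier carried through to the result.
#' @return list of class `circ_result`: `unitig_id`, `status`
#'   ("circularized"/"linear"), `overlap_len`, `overlap_identity_observed`,
#'   `sequence` (canonical circular sequence, or the original when linear).
#' @export
circularize <- function(unitig, params = posthgap_params(), unitig_id = "utg") {
  det <- detect_terminal_overlap(unitig, params)
  if (is.null(det)) {
    return(structure(list(unitig_id = unitig_id, status = "linear",
                          overlap_len = 0L, overlap_identity_observed = NA_real_,
                          sequence = unitig), class = "circ_result"))
  }
  circ <- substr(unitig, 1L, nchar(unitig) - det$overlap_len)
  circ <- rotate_seq(circ, min_rotation_start(circ))
  structure(list(unitig_id = unitig_id, status = "circularized",
                 overlap_len = det$overlap_len,
                 overlap_identity_observed = det$identity, sequence = circ),
            class = "circ_result")
}

# Locate the vector body (vector minus its cloning site) in a circular
# sequence; returns list(offset, identity) in coordinates of `circ`, or NULL.
locate_vector <- function(circ, body, min_identity = 0.95, min_coverage = 0.9) {
  nc <- nchar(circ)
  nb <- nchar(body)
  if (nb > nc) return(NULL)
  doubled <- paste0(circ, circ)
  votes <- vote_offsets(body, doubled, k = 24L, n_seeds = 30L)
  votes <- votes[votes$offset >= 1L & votes$offset <= nc, , drop = FALSE]
  if (!nrow(votes)) return(NULL)
  hits <- list()
  for (o in votes$offset) {
    ident <- hamming_identity(substr(doubled, o, o + nb - 1L), body)
    if (ident >= min_identity) hits[[as.character(o)]] <- ident
  }
  if (!length(hits)) return(NULL)
  offs <- as.integer(names(hits))
  # distinct (non-overlapping) passing placements = vector copies
  copies <- offs[c(TRUE, diff(sort(offs)) > nb %/% 2L)]
  list(offset = offs[which.max(unlist(hits))],
       identity = max(unlist(hits)), n_copies = length(copies))
}

#' Excise the vector from a circularized sequence
#'
#' Locates the vector (at >= 95% identity over >= 90% of its length, either
#' strand), removes it, and returns the insert linearized at the vector
#' junctions, oriented so the junction-adjacent AAGCTT reads forward (the
#' orientation in which the vector itself reads forward). Returns the
#' canonical circular sequence flagged `vectorless` when no vector is found,
#' and flags `chimeric` (unexcised) when two vector copies are present.
#'
#' @param circular_sequence canonical circular sequence from [circularize()].
#' @param vector a `vector_spec`.
#' @param params a [posthgap_params()].
#' @return list `insert`, `status` ("excised"/"vectorless"/"chimeric"/
#'   "empty"), `vector_identity`, `flipped` (TRUE when the insert was taken
#'   from the reverse strand).
#' @export
excise_vector <- function(circular_sequence, vector, params = posthgap_params()) {
  v <- vector$sequence
  cs0 <- vector$cloning_site_offset
  body <- paste0(substr(v, cs0 + 7L, nchar(v)), substr(v, 1L, cs0))
  circ <- circular_sequence
  flipped <- FALSE
  loc <- locate_vector(circ, body)
  if (is.null(loc)) {
    circ <- revcomp(circ)
    flipped <- TRUE
    loc <- locate_vector(circ, body)
  }
  if (is.null(loc)) {
    return(list(insert = circular_sequence, status = "vectorless",
                vector_identity = NA_real_, flipped = FALSE))
  }
  if (loc$n_copies > 1L) {
    return(list(insert = circular_sequence, status = "chimeric",
                vector_identity = loc$identity, flipped = flipped))
  }
  nc <- nchar(circ)
  nb <- nchar(body)
  if (nc - nb < 12L) {
    return(list(insert = "", status = "empty", vector_identity = loc$identity,
                flipped = flipped))
  }
  doubled <- paste0(circ, circ)
  insert <- substr(doubled, loc$offset + nb, loc$offset + nc - 1L)
  list(insert = insert, status = "excised", vector_identity = loc$identity,
       flipped = flipped)
}

# Best approximate placement of a BES read on the insert (either strand).
# Substitution-only matching; returns list(identity, strand, start) or NULL.
match_bes_read <- function(read, insert, min_identity) {
  n <- nchar(read)
  if (n > nchar(insert)) return(NULL)
  max_mm <- floor((1 - min_identity) * n)
  subj <- DNAString(insert)
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read else revcomp(read)
    m <- matchPattern(DNAString(pat), subj, max.mismatch = max_mm)
    if (length(m)) {
      idents <- vapply(seq_along(m), function(i)
        hamming_identity(as.character(m[[i]]), pat), numeric(1))
      best <- which.max(idents)
      return(list(identity = idents[best], strand = strand,
                  start = BiocGenerics::start(m)[best]))
    }
  }
  NULL
}

# Does the BES pair of `clone_id` support this insert? Inner-facing check:
# in one orientation of the insert the forward read maps '+' upstream of the
# reverse read mapping '-' (reads point toward each other).
bes_supports <- function(insert, bes_pair, params) {
  f <- match_bes_read(bes_pair$forward, insert, params$bes_match_identity)
  r <- match_bes_read(bes_pair$reverse, insert, params$bes_match_identity)
  if (is.null(f) || is.null(r)) return(NULL)
  if (params$require_bes_orientation) {
    inward <- (f$strand == "+" && r$strand == "-" && f$start <= r$start) ||
      (f$strand == "-" && r$strand == "+" && r$start <= f$start)
    if (!inward) return(NULL)
  }
  min(f$identity, r$identity)
}

#' Assign clone identities to excised inserts
#'
#' For each insert, its WGP tags (in-silico digestion of the insert; tag
#' extraction is strand-invariant) are matched exactly against every clone's
#' profile. A clone qualifies when at least `min_clone_tag_number` of its
#' tags match and they cover at least `tag_match_percent` of its profile;
#' among qualifying clones the one explaining the most insert tags (highest
#' matched count, ties broken by matched percentage) is assigned, with
#' qualifying members of the insert's own sequencing pool taking precedence
#' over out-of-pool candidates. When no clone qualifies
#' on tags, the BES pair is aligned and the clone is assigned at
#' `bes_match_identity` or better with an inner-facing pair. Two clones tied
#' at identical best evidence leave the insert unassigned with both
#' candidates reported. Assigned clones outside the insert's expected pool
#' members are labelled `non_mtp_clone`.
#'
#' @param inserts named character vector of insert sequences.
#' @param profiles named list clone_id -> tags.
#' @param bes named list clone_id -> list(forward, reverse), or NULL.
#' @param params a [posthgap_params()].
#' @param pool_members named list insert_id -> expected clone ids (the
#'   sequencing pool's members), or NULL to skip the MTP/non-MTP label.
#' @return data.frame `sequence_id`, `status` ("mtp_clone"/"non_mtp_clone"/
#'   "unassigned"), `clone_id`, `evidence` ("tags"/"bes"/""), `matched`,
#'   `total`, `percent`, `bes_identity`, `candidates`.
#' @export
assign_clone_ids <- function(inserts, profiles, bes = NULL,
                             params = posthgap_params(), pool_members = NULL) {
  tag_owner <- data.frame(
    clone_id = rep(names(profiles), lengths(profiles)),
    tag = unlist(profiles, use.names = FALSE)
  )
  sizes <- lengths(profiles)
  out <- vector("list", length(inserts))
  for (i in seq_along(inserts)) {
    sid <- names(inserts)[i]
    itags <- wgp_tag_set(inserts[[i]])
    hit <- tag_owner$clone_id[tag_owner$tag %in% itags]
    row <- data.frame(sequence_id = sid, status = "unassigned",
                      clone_id = NA_character_, evidence = "",
                      matched = 0L, total = NA_integer_, percent = NA_real_,
                      bes_identity = NA_real_, candidates = "")
    assigned <- FALSE
    if (length(hit)) {
      counts <- table(hit)
      cand <- names(counts)
      matched <- as.integer(counts)
      pct <- matched / sizes[cand]
      ok <- matched >= params$min_clone_tag_number & pct >= params$tag_match_percent
      if (any(ok)) {
        cand <- cand[ok]; matched <- matched[ok]; pct <- pct[ok]
        # an insert typically also contains every tag of clones nested inside
        # its interval; qualifying members of the expected pool outrank
        # out-of-pool candidates, which are considered only when no pool
        # member qualifies (re-array errors / contamination)
        if (!is.null(pool_members)) {
          inp <- cand %in% (pool_members[[sid]] %||% character(0))
          if (any(inp)) {
            cand <- cand[inp]; matched <- matched[inp]; pct <- pct[inp]
          }
        }
        # rank by matched count (percent is the qualifying filter): a clone
        # nested inside the insert matches 100% of its own profile, but the
        # true clone explains more of the insert's tags
        best <- which(matched == max(matched))
        if (length(best) > 1L) best <- best[pct[best] == max(pct[best])]
        if (length(best) > 1L && !is.null(pool_members)) {
          # clones with identical inserts tie on every content-based
          # measure; the sequencing pool's member list disambiguates
          in_pool <- which(cand[best] %in% (pool_members[[sid]] %||% character(0)))
          if (length(in_pool) == 1L) best <- best[in_pool]
        }
        if (length(best) > 1L) {
          row$candidates <- paste(cand[best], collapse = ",")
        } else {
          b <- best
          row$status <- "assigned"; row$clone_id <- cand[b]
          row$evidence <- "tags"; row$matched <- matched[b]
          row$total <- sizes[[cand[b]]]; row$percent <- pct[b]
          assigned <- TRUE
        }
      }
    }
    if (!assigned && !nzchar(row$candidates) && !is.null(bes)) {
      cand_ids <- if (!is.null(pool_members) && !is.null(pool_members[[sid]])) {
        intersect(pool_members[[sid]], names(bes))
      } else {
        names(bes)
      }
      idents <- vapply(cand_ids, function(cid)
        bes_supports(inserts[[i]], bes[[cid]], params) %||% NA_real_, numeric(1))
      if (!all(is.na(idents)) && length(cand_ids)) {
        passing <- which(!is.na(idents))
        if (length(passing) == 1L) {
          row$status <- "assigned"; row$clone_id <- cand_ids[passing]
          row$evidence <- "bes"; row$bes_identity <- idents[passing]
          assigned <- TRUE
        } else {
          top <- idents[passing]
          if (sum(top == max(top)) == 1L) {
            b <- passing[which.max(top)]
            row$status <- "assigned"; row$clone_id <- cand_ids[b]
            row$evidence <- "bes"; row$bes_identity <- idents[b]
            assigned <- TRUE
          } else {
            row$candidates <- paste(cand_ids[passing[top == max(top)]],
                                    collapse = ",")
          }
        }
      }
    }
    if (assigned && !is.null(pool_members)) {
      expected <- pool_members[[sid]] %||% character(0)
      row$status <- if (row$clone_id %in% expected) "mtp_clone" else "non_mtp_clone"
    } else if (assigned) {
      row$status <- "mtp_clone"
    }
    out[[i]] <- row
  }
  do.call(rbind, out)
}

#' Summarize a pooled-sequencing run
#'
#' Per-library bookkeeping: identified BAC sequences, fully circularized
#' count, full-circularization rate = round(100 x circularized / MTP clones
#' picked), mean insert length and non-MTP identifications.
#'
#' @param circ_results list of `circ_result` objects (or a data.frame with a
#'   `status` column).
#' @param assignments output of [assign_clone_ids()].
#' @param mtp_clones character vector of MTP clone ids picked.
#' @param insert_lengths optional numeric vector of insert lengths.
#' @return one-row data.frame `n_unitigs`, `identified`, `circularized`,
#'   `circularization_rate_pct`, `mean_insert_len`, `non_mtp`.
#' @export
#' @examples
#' # round(100 * 4415 / 4714) = 94
pool_report <- function(circ_results, assignments, mtp_clones,
                        insert_lengths = NULL) {
  statuses <- if (is.data.frame(circ_results)) circ_results$status else
    vapply(circ_results, `[[`, character(1), "status")
  n_circ <- sum(statuses == "circularized")
  data.frame(
    n_unitigs = length(statuses),
    identified = sum(assignments$status != "unassigned"),
    circularized = n_circ,
    circularization_rate_pct = round_half_up(100 * n_circ / length(mtp_clones)),
    mean_insert_len = if (is.null(insert_lengths)) NA_real_ else mean(insert_lengths),
    non_mtp = sum(assignments$status == "non_mtp_clone")
  )
}
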