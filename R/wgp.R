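# Whole Genome Profiling (WGP): in-silico EcoRI/MseI digestion yields 50-bp
# sequence tags anchored at EcoRI sites; 3D (plate/row/column) pool
# observations are deconvolved back to clone addresses. Tags are compared by
# exact string equality everywhere (tagMatchIdentity = 100%).

WGP_TAG_LEN <- 50L

#' Extract WGP sequence tags from a sequence
#'
#' For every EcoRI site (GAATTC) the 50 bases immediately 3' of the site are
#' read on each strand: the right flank on the forward strand, and the left
#' flank as its reverse complement (the read off the minus strand). A flank
#' is emitted only if it reaches the full 50 bp within the sequence and is
#' not interrupted by a nearer MseI site (TTAA). Tags are de-duplicated per
#' sequence. Under this read convention the tag set is strand-invariant:
#' `extract_wgp_tags(revcomp(s))` yields the same set as
#' `extract_wgp_tags(s)`.
#'
#' @param sequence DNA sequence (character scalar), length >= 50.
#' @param tag_len tag length (50).
#' @return data.frame `tag`, `enzyme`, `site_pos` (0-based start of the
#'   GAATTC occurrence), `side` ("right"/"left"), de-duplicated on `tag`.
#' @export
#' @examples
#' s <- paste0(strrep("A", 60), "GAATTC", strrep("C", 60))
#' extract_wgp_tags(s)$side
extract_wgp_tags <- function(sequence, tag_len = WGP_TAG_LEN) {
  if (!nzchar(sequence)) stop("empty sequence")
  n <- nchar(sequence)
  empty <- data.frame(tag = character(0), enzyme = character(0),
                      site_pos = integer(0), side = character(0))
  if (n < tag_len) return(empty)
  sites <- find_sites(sequence, ECORI)
  if (!length(sites)) return(empty)
  msei <- find_sites(sequence, MSEI)
  has_msei <- function(from, to) {
    # any TTAA occurrence fully inside [from, to]?
    length(msei) > 0L && any(msei >= from & msei <= to - 3L)
  }
  rows <- list()
  for (s in sites) {
    rs <- s + 6L
    if (rs + tag_len - 1L <= n && !has_msei(rs, rs + tag_len - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tag = substr(sequence, rs, rs + tag_len - 1L), enzyme = "EcoRI",
        site_pos = s - 1L, side = "right"
      )
    }
    ls <- s - tag_len
    if (ls >= 1L && !has_msei(ls, s - 1L)) {
      rows[[length(rows) + 1L]] <- data.frame(
        tag = revcomp(substr(sequence, ls, s - 1L)), enzyme = "EcoRI",
        site_pos = s - 1L, side = "left"
      )
    }
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out[!duplicated(out$tag), , drop = FALSE]
}

#' Unique WGP tag set of a sequence
#' @inheritParams extract_wgp_tags
#' @return character vector of unique tags.
#' @export
wgp_tag_set <- function(sequence, tag_len = WGP_TAG_LEN) {
  extract_wgp_tags(sequence, tag_len)$tag
}

#' Truth tag profiles of a clone library
#'
#' In-silico digestion of every clone insert; this is the simulator's truth
#' tag map (what aggregate WGP tagging and deconvolution delivers).
#'
#' @param clones a `clone_library`.
#' @param genome truth genome (defaults to `attr(clones, "genome")`).
#' @return named list clone_id -> character vector of tags.
#' @export
clone_tag_profiles <- function(clones, genome = attr(clones, "genome")) {
  out <- vector("list", nrow(clones))
  names(out) <- clones$clone_id
  for (i in seq_len(nrow(clones))) {
    out[[i]] <- wgp_tag_set(clone_insert_seq(clones[i, ], genome))
  }
  out
}

#' Build the 3D pooling design of a clone library
#'
#' Plate pools (one per 384-well plate), row pools (one per row letter across
#' plates) and column pools (one per column across plates). The three
#' dimensions intersect in exactly one well.
#'
#' @param clones a `clone_library`.
#' @return list with `design` (data.frame `pool_id`, `dim`, `value`) and
#'   `membership` (data.frame `pool_id`, `clone_id`).
#' @export
make_3d_design <- function(clones) {
  mk <- function(dim, value) sprintf("%s_%02d", dim, value)
  design <- rbind(
    data.frame(pool_id = mk("plate", sort(unique(clones$plate))), dim = "plate",
               value = sort(unique(clones$plate))),
    data.frame(pool_id = mk("row", sort(unique(clones$row))), dim = "row",
               value = sort(unique(clones$row))),
    data.frame(pool_id = mk("col", sort(unique(clones$col))), dim = "col",
               value = sort(unique(clones$col)))
  )
  membership <- rbind(
    data.frame(pool_id = mk("plate", clones$plate), clone_id = clones$clone_id),
    data.frame(pool_id = mk("row", clones$row), clone_id = clones$clone_id),
    data.frame(pool_id = mk("col", clones$col), clone_id = clones$clone_id)
  )
  list(design = design, membership = membership)
}

#' Simulate 3D pool tag observations
#'
#' Each tag is observed in every pool containing a clone whose profile holds
#' the tag (presence/absence only; no depth model).
#'
#' @param profiles named list clone_id -> tags (truth profiles).
#' @param design3d output of [make_3d_design()].
#' @return data.frame `tag`, `pool_id` (long format).
#' @export
make_tag_observations <- function(profiles, design3d) {
  tag_clone <- data.frame(
    clone_id = rep(names(profiles), lengths(profiles)),
    tag = unlist(profiles, use.names = FALSE)
  )
  m <- merge(tag_clone, design3d$membership, by = "clone_id")
  unique(m[, c("tag", "pool_id")])
}

#' Deconvolve 3D tag observations to clone addresses
#'
#' A tag is `unique` iff it is observed in exactly one pool of each of the
#' three dimensions; the (plate, row, col) intersection is its address. Tags
#' seen in two or more pools of any dimension are `ambiguous`; tags missing a
#' dimension entirely are `unassigned`.
#'
#' @param observations data.frame `tag`, `pool_id`.
#' @param design data.frame `pool_id`, `dim`, `value` (the `design` element
#'   of [make_3d_design()]).
#' @return data.frame `tag`, `status`, `plate`, `row`, `col` (address columns
#'   NA unless unique).
#' @export
deconvolve_tags <- function(observations, design) {
  unknown <- setdiff(observations$pool_id, design$pool_id)
  if (length(unknown)) stop("unknown pool id: ", paste(head(unknown), collapse = ", "))
  dims <- design$dim[match(observations$pool_id, design$pool_id)]
  vals <- design$value[match(observations$pool_id, design$pool_id)]
  sp <- split(data.frame(dim = dims, value = vals), observations$tag)
  res <- lapply(names(sp), function(tg) {
    d <- sp[[tg]]
    per_dim <- table(unique(d)$dim)
    if (any(per_dim > 1L)) {
      data.frame(tag = tg, status = "ambiguous", plate = NA_integer_,
                 row = NA_integer_, col = NA_integer_)
    } else if (length(per_dim) < 3L) {
      data.frame(tag = tg, status = "unassigned", plate = NA_integer_,
                 row = NA_integer_, col = NA_integer_)
    } else {
      u <- unique(d)
      data.frame(tag = tg, status = "unique",
                 plate = u$value[u$dim == "plate"],
                 row = u$value[u$dim == "row"],
                 col = u$value[u$dim == "col"])
    }
  })
  do.call(rbind, res)
}

#' Tag profiles from deconvolved assignments
#'
#' Only `unique`-status tags contribute; their address is mapped back to a
#' clone id. Clones without any tag are reported as the `untagged` attribute.
#'
#' @param assignments output of [deconvolve_tags()].
#' @param clones a `clone_library`.
#' @return named list clone_id -> tags, with attributes `untagged` (clone ids
#'   without tags) and `tagged_percent` (percentage of library clones tagged,
#'   one decimal).
#' @export
tag_profiles <- function(assignments, clones) {
  u <- assignments[assignments$status == "unique", , drop = FALSE]
  key <- paste(u$plate, u$row, u$col)
  clone_key <- paste(clones$plate, clones$row, clones$col)
  cid <- clones$clone_id[match(key, clone_key)]
  keep <- !is.na(cid)
  profs <- split(u$tag[keep], cid[keep])
  out <- stats::setNames(vector("list", nrow(clones)), clones$clone_id)
  for (nm in names(profs)) out[[nm]] <- unique(profs[[nm]])
  empty <- vapply(out, function(x) length(x) == 0L, logical(1))
  for (nm in names(out)[empty]) out[[nm]] <- character(0)
  attr(out, "untagged") <- clones$clone_id[empty]
  attr(out, "tagged_percent") <- round_half_up(100 * sum(!empty) / nrow(clones), 1L)
  out
}

#' Tagged-clone percentage
#'
#' Percentage of library clones with at least one tag, against the total
#' library size, reported to one decimal.
#'
#' @param n_tagged number of tagged clones.
#' @param n_library total clones in the library.
#' @return numeric percentage.
#' @export
#' @examples
#' tagged_percent(32829, 36864)
tagged_percent <- function(n_tagged, n_library) {
  round_half_up(100 * n_tagged / n_library, 1L)
}
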