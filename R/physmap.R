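# FPC-style physical map construction from clone tag profiles. Because tags
# are exact 50-mers compared at tolerance 0, the classical Sulston band
# overlap probability degenerates to an exact hypergeometric tail on shared
# tags: score = P(X >= m), X ~ Hypergeometric(N, |a|, |b|). Lower scores mean
# stronger overlap; clustering keeps edges with score <= cutoff, followed by
# the cutoff cascade (high-stringency build, DQ splitting, ends-to-ends
# merging, singleton incorporation) and minimum-tiling-path selection.

#' FPC-style clustering parameters
#'
#' Defaults follow the published cutoff cascade: high-stringency build at
#' 1e-15 with tolerance 0 (fixed; tags are matched exactly), DQ splitting at
#' 1e-18/1e-21/1e-24, ends-to-ends merging at 1e-9, singleton incorporation
#' at 1e-12. `min_mtp_shared` is the minimum shared-tag count between
#' consecutive MTP picks (echoing the clone-identification minimum of 5
#' tags).
#'
#' @param tolerance band tolerance; fixed at 0 (exact tag matching).
#' @param hs_cutoff high-stringency build cutoff.
#' @param dq_cutoffs three strictly decreasing DQ-split cutoffs.
#' @param end_merge_cutoff ends-to-ends merge cutoff.
#' @param singleton_cutoff singleton incorporation cutoff.
#' @param min_mtp_shared minimum shared tags between consecutive MTP clones.
#' @return list of class `fpc_params`.
#' @export
fpc_params <- function(tolerance = 0L, hs_cutoff = 1e-15,
                       dq_cutoffs = c(1e-18, 1e-21, 1e-24),
                       end_merge_cutoff = 1e-9, singleton_cutoff = 1e-12,
                       min_mtp_shared = 5L) {
  if (tolerance != 0L) stop("tolerance is fixed at 0 (exact tag matching)")
  cuts <- c(hs_cutoff, dq_cutoffs, end_merge_cutoff, singleton_cutoff)
  if (any(cuts <= 0 | cuts >= 1)) stop("cutoffs must lie in (0, 1)")
  if (any(diff(dq_cutoffs) >= 0)) stop("dq_cutoffs must be strictly decreasing")
  structure(list(tolerance = 0L, hs_cutoff = hs_cutoff, dq_cutoffs = dq_cutoffs,
                 end_merge_cutoff = end_merge_cutoff,
                 singleton_cutoff = singleton_cutoff,
                 min_mtp_shared = as.integer(min_mtp_shared)),
            class = "fpc_params")
}

#' Probability that two unrelated clones share at least the observed tags
#'
#' The chance that two random tag sets of the given sizes drawn from a
#' universe of `universe_size` tags share `>= m` tags, where `m` is the
#' observed intersection: the upper hypergeometric tail. Score 1 when m = 0.
#'
#' @param tags_a,tags_b character vectors of tags.
#' @param universe_size number of distinct tags in the universe (>= union).
#' @return list `shared_tags`, `score`.
#' @export
#' @examples
#' overlap_score(letters[1:4], letters[3:7], 26)
overlap_score <- function(tags_a, tags_b, universe_size) {
  a <- unique(tags_a)
  b <- unique(tags_b)
  if (universe_size < length(union(a, b))) stop("universe smaller than tag union")
  m <- length(intersect(a, b))
  score <- if (m == 0L) 1 else
    phyper(m - 1L, length(a), universe_size - length(a), length(b),
           lower.tail = FALSE)
  list(shared_tags = m, score = score)
}

# Shared-tag workspace: sparse pairwise shared counts and the full edge table
# with hypergeometric scores, computed once and reused across the cascade.
tag_space <- function(profiles, universe_size = NULL) {
  profiles <- lapply(profiles, unique)
  ids <- names(profiles)
  all_tags <- unique(unlist(profiles, use.names = FALSE))
  if (is.null(universe_size)) universe_size <- length(all_tags)
  sizes <- lengths(profiles)
  i <- rep(seq_along(profiles), sizes)
  j <- match(unlist(profiles, use.names = FALSE), all_tags)
  M <- sparseMatrix(i = i, j = j, x = 1,
                    dims = c(length(profiles), length(all_tags)))
  S <- tcrossprod(M)
  Sg <- methods::as(methods::as(S, "generalMatrix"), "TsparseMatrix")
  keep <- Sg@i < Sg@j
  ai <- Sg@i[keep] + 1L
  bj <- Sg@j[keep] + 1L
  m <- Sg@x[keep]
  score <- ifelse(m == 0, 1,
                  phyper(m - 1, sizes[ai], universe_size - sizes[ai], sizes[bj],
                         lower.tail = FALSE))
  edges <- data.frame(a = ids[ai], b = ids[bj], shared = as.integer(m),
                      score = score, stringsAsFactors = FALSE)
  list(profiles = profiles, ids = ids, sizes = stats::setNames(sizes, ids),
       N = universe_size, edges = edges)
}

# Connected components of `members` under edges with score <= cutoff.
# Returns a list of character vectors (clones without passing edges become
# singleton components).
cluster_at <- function(members, space, cutoff) {
  e <- space$edges
  e <- e[e$a %in% members & e$b %in% members & e$score <= cutoff, , drop = FALSE]
  g <- igraph::graph_from_data_frame(e[, c("a", "b")], directed = FALSE,
                                     vertices = data.frame(name = members))
  comp <- igraph::components(g)
  unname(split(names(comp$membership), comp$membership))
}

#' Build high-stringency map contigs
#'
#' Clones joined by edges whose hypergeometric score is at or below the
#' high-stringency cutoff form contigs (connected components with >= 2
#' clones); the rest are singletons.
#'
#' @param profiles named list clone_id -> tags.
#' @param params an [fpc_params()].
#' @param space optional precomputed workspace (internal reuse).
#' @return list `contigs` (list of clone-id vectors), `singletons`
#'   (character), `space` (reusable workspace).
#' @export
build_contigs <- function(profiles, params = fpc_params(), space = NULL) {
  if (!length(profiles)) stop("profiles must be non-empty")
  if (is.null(space)) space <- tag_space(profiles)
  comps <- cluster_at(space$ids, space, params$hs_cutoff)
  sizes <- lengths(comps)
  list(contigs = comps[sizes >= 2L],
       singletons = unlist(comps[sizes < 2L], use.names = FALSE) %||% character(0),
       space = space)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Split problematic contigs (DQ step)
#'
#' Each contig is re-clustered at successively stricter cutoffs; a split is
#' kept only when it yields at least two components, each with at least two
#' clones (splits shedding single clones are rejected). Recursion stops after
#' the last cutoff.
#'
#' @param contigs list of clone-id vectors.
#' @param profiles named list clone_id -> tags (ignored when `space` given).
#' @param params an [fpc_params()].
#' @param space precomputed workspace from [build_contigs()].
#' @return list of clone-id vectors.
#' @export
dq_split <- function(contigs, profiles = NULL, params = fpc_params(),
                     space = NULL) {
  if (is.null(space)) space <- tag_space(profiles)
  split_rec <- function(members, cutoffs) {
    if (!length(cutoffs)) return(list(members))
    comps <- cluster_at(members, space, cutoffs[1L])
    if (length(comps) >= 2L && all(lengths(comps) >= 2L)) {
      unlist(lapply(comps, split_rec, cutoffs = cutoffs[-1L]), recursive = FALSE)
    } else {
      split_rec(members, cutoffs[-1L])
    }
  }
  unlist(lapply(contigs, split_rec, cutoffs = params$dq_cutoffs),
         recursive = FALSE)
}

#' Order clones within a contig by spectral seriation
#'
#' The shared-tag counts between contig members form a similarity matrix
#' whose graph-Laplacian Fiedler vector (eigenvector of the second-smallest
#' eigenvalue) recovers the linear layout of an interval graph; clones are
#' ordered along it. The vector's sign is fixed so the lexicographically
#' smaller end clone comes first, making the ordering deterministic.
#' Positions are in tag units: a clone's position is the number of tags
#' placed before it that it does not carry, forced non-decreasing.
#'
#' @param contig_clones character vector of clone ids (connected under
#'   shared-tag edges; disconnected input is an error).
#' @param profiles named list clone_id -> tags (ignored when `space` given).
#' @param space precomputed workspace.
#' @param contig_id label for the contig.
#' @return list of class `pm_contig`: `contig_id`, `clones` (data.frame
#'   `clone_id`, `position`).
#' @export
order_clones <- function(contig_clones, profiles = NULL, space = NULL,
                         contig_id = "ctg") {
  if (is.null(space)) space <- tag_space(profiles)
  profs <- space$profiles[contig_clones]
  n <- length(contig_clones)
  if (n == 1L) {
    return(structure(list(contig_id = contig_id,
                          clones = data.frame(clone_id = contig_clones,
                                              position = 0L)),
                     class = "pm_contig"))
  }
  ordered <- if (n == 2L) {
    sort(contig_clones)
  } else {
    e <- space$edges
    e <- e[e$a %in% contig_clones & e$b %in% contig_clones, , drop = FALSE]
    W <- matrix(0, n, n, dimnames = list(contig_clones, contig_clones))
    if (nrow(e)) {
      W[cbind(e$a, e$b)] <- e$shared
      W[cbind(e$b, e$a)] <- e$shared
    }
    if (any(rowSums(W) == 0)) stop("contig is not connected under shared-tag edges")
    L <- diag(rowSums(W)) - W
    ev <- eigen(L, symmetric = TRUE)
    f <- ev$vectors[, n - 1L]
    o <- order(f, contig_clones)
    if (contig_clones[o[1L]] > contig_clones[o[n]]) o <- rev(o)
    contig_clones[o]
  }
  union_tags <- character(0)
  positions <- integer(n)
  for (i in seq_along(ordered)) {
    positions[i] <- length(setdiff(union_tags, profs[[ordered[i]]]))
    union_tags <- union(union_tags, profs[[ordered[i]]])
  }
  positions <- cummax(positions)
  structure(list(contig_id = contig_id,
                 clones = data.frame(clone_id = ordered,
                                     position = as.integer(positions))),
            class = "pm_contig")
}

# Fast pairwise score lookup over the precomputed edge table.
score_lookup <- function(space) {
  key <- ifelse(space$edges$a < space$edges$b,
                paste(space$edges$a, space$edges$b),
                paste(space$edges$b, space$edges$a))
  env <- new.env(parent = emptyenv(), size = length(key))
  for (i in seq_along(key)) assign(key[i], space$edges$score[i], envir = env)
  function(a, b) {
    k <- if (a < b) paste(a, b) else paste(b, a)
    get0(k, envir = env, ifnotfound = 1)
  }
}

shared_lookup <- function(space) {
  profs <- space$profiles
  function(a, b) length(intersect(profs[[a]], profs[[b]]))
}

#' Merge contigs end-to-end
#'
#' Two contigs merge when a clone among the three terminal clones of one end
#' of the first scores at or below the merge cutoff against a terminal clone
#' of an end of the second. Merges are applied greedily, best-scoring pair
#' first, re-ordering the merged contig each time.
#'
#' @param contigs list of `pm_contig` objects (ordered).
#' @param params an [fpc_params()].
#' @param space precomputed workspace.
#' @param end_zone number of terminal clones forming an end (3).
#' @return list of `pm_contig` objects.
#' @export
end_merge <- function(contigs, params = fpc_params(), space, end_zone = 3L) {
  sc <- score_lookup(space)
  ends_of <- function(ct) {
    cl <- ct$clones$clone_id
    unique(c(head(cl, end_zone), tail(cl, end_zone)))
  }
  repeat {
    if (length(contigs) < 2L) break
    best <- NULL
    for (i in seq_along(contigs)) {
      for (j in seq_along(contigs)) {
        if (j <= i) next
        ei <- ends_of(contigs[[i]])
        ej <- ends_of(contigs[[j]])
        s <- outer(ei, ej, Vectorize(sc))
        mn <- min(s)
        if (mn <= params$end_merge_cutoff &&
            (is.null(best) || mn < best$score)) {
          best <- list(i = i, j = j, score = mn)
        }
      }
    }
    if (is.null(best)) break
    members <- c(contigs[[best$i]]$clones$clone_id,
                 contigs[[best$j]]$clones$clone_id)
    merged <- order_clones(members, space = space,
                           contig_id = contigs[[best$i]]$contig_id)
    contigs <- c(contigs[-c(best$i, best$j)], list(merged))
  }
  contigs
}

#' Incorporate singletons into contigs
#'
#' Each singleton joins the contig of its best-scoring member clone when that
#' score is at or below the singleton cutoff; otherwise it remains a
#' singleton. Receiving contigs are re-ordered.
#'
#' @param contigs list of `pm_contig` objects.
#' @param singletons character vector of clone ids.
#' @param params an [fpc_params()].
#' @param space precomputed workspace.
#' @return list `contigs`, `singletons`, `report` (contig/clone/singleton
#'   counts).
#' @export
add_singletons <- function(contigs, singletons, params = fpc_params(), space) {
  sc <- score_lookup(space)
  remaining <- character(0)
  for (s in singletons) {
    best_i <- 0L
    best_s <- Inf
    for (i in seq_along(contigs)) {
      ss <- vapply(contigs[[i]]$clones$clone_id, function(m) sc(s, m), numeric(1))
      if (min(ss) < best_s) {
        best_s <- min(ss)
        best_i <- i
      }
    }
    if (best_i > 0L && best_s <= params$singleton_cutoff) {
      members <- c(contigs[[best_i]]$clones$clone_id, s)
      contigs[[best_i]] <- order_clones(members, space = space,
                                        contig_id = contigs[[best_i]]$contig_id)
    } else {
      remaining <- c(remaining, s)
    }
  }
  report <- data.frame(
    n_contigs = length(contigs),
    clones_in_contigs = sum(vapply(contigs, function(ct) nrow(ct$clones), integer(1))),
    n_singletons = length(remaining)
  )
  list(contigs = contigs, singletons = remaining, report = report)
}

#' Select the minimum tiling path of a contig
#'
#' Greedy farthest-reach: starting at the first-position clone, repeatedly
#' pick among clones sharing at least `min_mtp_shared` tags with the current
#' clone the one with the greatest position. Clones contributing no new reach
#' (e.g. contained clones) are never selected. If the overlap chain breaks,
#' the path jumps to the next clone by position and the break is flagged.
#'
#' @param contig a `pm_contig` (ordered).
#' @param profiles named list clone_id -> tags (ignored when `space` given).
#' @param min_mtp_shared minimum shared tags between consecutive picks.
#' @param space precomputed workspace.
#' @return list of class `mtp_path`: `contig_id`, `clone_ids`, `shared`
#'   (tag counts between consecutive picks; NA at flagged breaks), `breaks`
#'   (indices after which the chain broke).
#' @export
select_mtp <- function(contig, profiles = NULL, min_mtp_shared = 5L,
                       space = NULL) {
  if (is.null(space)) space <- tag_space(profiles)
  shl <- shared_lookup(space)
  cl <- contig$clones
  profs <- space$profiles
  path <- cl$clone_id[1L]
  path_union <- profs[[path]]
  shared <- integer(0)
  breaks <- integer(0)
  cur_i <- 1L
  repeat {
    cur <- cl$clone_id[cur_i]
    # only clones strictly beyond the current position that contribute tags
    # the path does not already carry advance it; contained and duplicate
    # clones (no new reach) are never selected
    ahead <- which(cl$position > cl$position[cur_i])
    ahead <- ahead[vapply(cl$clone_id[ahead], function(x)
      length(setdiff(profs[[x]], path_union)) > 0L, logical(1))]
    if (!length(ahead)) break
    m <- vapply(cl$clone_id[ahead], function(x) shl(cur, x), integer(1))
    ok <- ahead[m >= min_mtp_shared]
    if (length(ok)) {
      nxt <- ok[which.max(cl$position[ok])]
      shared <- c(shared, shl(cur, cl$clone_id[nxt]))
    } else {
      nxt <- ahead[which.min(cl$position[ahead])]  # chain broken: jump, flag
      breaks <- c(breaks, length(path))
      shared <- c(shared, NA_integer_)
    }
    path <- c(path, cl$clone_id[nxt])
    path_union <- union(path_union, profs[[cl$clone_id[nxt]]])
    cur_i <- nxt
  }
  # sweep-up: position ties at layout ends can hide clones that still carry
  # uncovered tags; append them so the MTP covers every contig tag. These
  # picks fall outside the walk order and are reported separately.
  swept <- character(0)
  repeat {
    rest <- setdiff(cl$clone_id, path)
    if (!length(rest)) break
    new_tags <- vapply(rest, function(x)
      length(setdiff(profs[[x]], path_union)), integer(1))
    if (all(new_tags == 0L)) break
    pick <- rest[order(-new_tags, rest)][1L]
    shared <- c(shared, shl(path[length(path)], pick))
    path <- c(path, pick)
    swept <- c(swept, pick)
    path_union <- union(path_union, profs[[pick]])
  }
  structure(list(contig_id = contig$contig_id, clone_ids = path,
                 shared = shared, breaks = breaks, swept = swept),
            class = "mtp_path")
}

#' Build a physical map end-to-end
#'
#' Runs the full cascade: high-stringency contig build, DQ splitting,
#' within-contig ordering, ends-to-ends merging and singleton incorporation,
#' then re-orders the final contigs.
#'
#' @param profiles named list clone_id -> tags.
#' @param params an [fpc_params()].
#' @param universe_size tag universe size (default: number of distinct tags
#'   observed).
#' @return list `contigs` (list of `pm_contig`), `singletons`, `report`,
#'   `space`.
#' @export
physical_map <- function(profiles, params = fpc_params(), universe_size = NULL) {
  space <- tag_space(profiles, universe_size)
  hs <- build_contigs(profiles, params, space = space)
  parts <- dq_split(hs$contigs, params = params, space = space)
  ordered <- lapply(seq_along(parts), function(i)
    order_clones(parts[[i]], space = space, contig_id = sprintf("ctg%03d", i)))
  merged <- end_merge(ordered, params = params, space = space)
  fin <- add_singletons(merged, hs$singletons, params = params, space = space)
  names(fin$contigs) <- vapply(fin$contigs, `[[`, character(1), "contig_id")
  c(fin, list(space = space))
}

#' Minimum tiling paths for every contig of a physical map
#'
#' @param pm output of [physical_map()].
#' @param min_mtp_shared minimum shared tags between consecutive picks.
#' @return list of `mtp_path` objects (one per contig) with attribute
#'   `clone_ids`: all MTP clones in map order.
#' @export
select_mtp_all <- function(pm, min_mtp_shared = 5L) {
  paths <- lapply(pm$contigs, select_mtp, min_mtp_shared = min_mtp_shared,
                  space = pm$space)
  attr(paths, "clone_ids") <- unlist(lapply(paths, `[[`, "clone_ids"),
                                     use.names = FALSE)
  paths
}
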