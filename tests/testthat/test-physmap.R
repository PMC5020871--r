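# Exhaustive overlap-probability oracle: with the first set fixed by
# symmetry, enumerate every draw of the second set and count how often the
# intersection reaches m. Independent of stats::phyper.
enumerate_tail <- function(N, ka, kb, m) {
  if (m == 0) return(1)
  sets <- utils::combn(N, kb)
  hits <- sum(apply(sets, 2, function(b) sum(b <= ka) >= m))
  hits / ncol(sets)
}

test_that("overlap_score matches exhaustive enumeration and the cutoff examples", {
  # small case: N=10, |a|=4, |b|=5, m=3 against brute force
  a <- paste0("t", 1:4)
  b <- paste0("t", c(2, 3, 4, 9, 10))
  sc <- overlap_score(a, b, 10)
  expect_equal(sc$shared_tags, 3L)
  expect_equal(sc$score, enumerate_tail(10, 4, 5, 3), tolerance = 1e-12)

  # disjoint sets: P(X >= 0) = 1
  expect_equal(overlap_score(paste0("x", 1:5), paste0("y", 1:5), 100)$score, 1)

  # identical 20-tag sets in a 10,000-tag universe pass the HS cutoff
  t20 <- paste0("t", 1:20)
  expect_lt(overlap_score(t20, t20, 10000)$score, 1e-15)

  expect_error(overlap_score(paste0("t", 1:5), paste0("u", 1:5), 8), "universe")
})

test_that("high-stringency contigs separate overlapping clones from singletons", {
  t20 <- paste0("t", 1:20)
  profs <- list(a = t20, b = t20, c = paste0("u", 1:20), d = character(0))
  res <- build_contigs(profs, fpc_params(),
                       space = clonetiler:::tag_space(profs, universe_size = 10000))
  expect_equal(lengths(res$contigs), 2L)
  expect_setequal(res$contigs[[1]], c("a", "b"))
  expect_setequal(res$singletons, c("c", "d"))
  expect_error(build_contigs(list()), "non-empty")
})

test_that("DQ splitting severs repeat-induced joins but never sheds single clones", {
  # two linear tilings far apart, joined only by a planted 10-tag repeat
  # shared between one clone of each group: that edge scores ~1.4e-16
  # (passes the 1e-15 build cutoff, fails the first DQ cutoff 1e-18)
  left <- tiling_profiles(c(0, 5, 10), width = 20)
  names(left) <- c("a1", "a2", "a3")
  right <- lapply(tiling_profiles(c(100, 105, 110), width = 20), identity)
  names(right) <- c("b1", "b2", "b3")
  rep_tags <- sprintf("rep%02d", 1:10)
  left$a3 <- c(left$a3, rep_tags)
  right$b1 <- c(right$b1, rep_tags)
  profs <- c(left, right)
  space <- clonetiler:::tag_space(profs, universe_size = 5000)
  hs <- build_contigs(profs, space = space)
  expect_equal(length(hs$contigs), 1L)  # joined at 1e-15 via the repeat edge
  split <- dq_split(hs$contigs, params = fpc_params(), space = space)
  expect_equal(length(split), 2L)
  expect_true(all(lengths(split) == 3L))
  expect_setequal(split[[1]], c("a1", "a2", "a3"))

  # a contig whose every edge is far below the deepest cutoff stays intact
  t30 <- paste0("s", 1:30)
  strong <- list(x = t30, y = t30, z = t30)
  sp2 <- clonetiler:::tag_space(strong, universe_size = 5000)
  hs2 <- build_contigs(strong, space = sp2)
  expect_equal(dq_split(hs2$contigs, params = fpc_params(), space = sp2),
               hs2$contigs)

  # a split that would shed a singleton (1 + n) is rejected
  t1 <- paste0("p", 1:20)
  t2 <- c(t1[6:20], paste0("p", 21:25))
  lone <- c(t1[1:9], paste0("q", 1:11))  # weakly attached third clone
  profs3 <- list(a = t1, b = t2, c = lone)
  sp3 <- clonetiler:::tag_space(profs3, universe_size = 5000)
  hs3 <- build_contigs(profs3, space = sp3)
  if (length(hs3$contigs) == 1L && length(hs3$contigs[[1]]) == 3L) {
    split3 <- dq_split(hs3$contigs, params = fpc_params(), space = sp3)
    expect_equal(lengths(split3), 3L)  # unchanged: no valid >=2x>=2 split
  }
})

test_that("clone ordering recovers a linear tiling with tag-unit positions", {
  # A overlaps B overlaps C along a line
  profs <- tiling_profiles(c(0, 10, 20), width = 20)
  oc <- order_clones(names(profs), profs, contig_id = "t")
  ids <- oc$clones$clone_id
  expect_true(identical(ids, c("cl01", "cl02", "cl03")) ||
                identical(ids, c("cl03", "cl02", "cl01")))
  expect_true(all(diff(oc$clones$position) >= 0))

  # two clones: positions 0 and |a \ b|
  p2 <- tiling_profiles(c(0, 12), width = 20)
  oc2 <- order_clones(names(p2), p2)
  expect_equal(oc2$clones$position, c(0L, 12L))

  # deterministic given the tie-break
  oc3 <- order_clones(names(profs), profs, contig_id = "t")
  expect_identical(oc$clones, oc3$clones)
})

test_that("ordering matches truth layout on a simulated contig", {
  sim <- tiny_sim()
  pm <- tiny_pm()
  big <- which.max(vapply(pm$contigs, function(ct) nrow(ct$clones), integer(1)))
  d <- pm$contigs[[big]]$clones
  d$start <- sim$clones$start[match(d$clone_id, sim$clones$clone_id)]
  rho <- abs(cor(seq_len(nrow(d)), d$start, method = "spearman"))
  expect_gte(rho, 0.95)
})

test_that("ends-to-ends merging rejoins artificially split contigs, best pair first", {
  # one linear tiling split into two halves sharing a strong terminal edge
  profs <- tiling_profiles(c(0, 8, 16, 24, 32, 40), width = 20)
  space <- clonetiler:::tag_space(profs, universe_size = 5000)
  left <- order_clones(c("cl01", "cl02", "cl03"), space = space, contig_id = "L")
  right <- order_clones(c("cl04", "cl05", "cl06"), space = space, contig_id = "R")
  merged <- end_merge(list(left, right), fpc_params(), space)
  expect_length(merged, 1L)
  expect_setequal(merged[[1]]$clones$clone_id, names(profs))
  rho <- cor(match(merged[[1]]$clones$clone_id, names(profs)),
             seq_len(6), method = "spearman")
  expect_equal(abs(rho), 1)

  # disjoint tag spaces never merge
  far <- lapply(1:2, function(i) {
    tiling_profiles(c(0, 8), width = 20)
  })
  profs2 <- c(stats::setNames(far[[1]], c("x1", "x2")),
              stats::setNames(lapply(far[[2]], function(t) chartr("t", "u", t)),
                              c("y1", "y2")))
  sp2 <- clonetiler:::tag_space(profs2, universe_size = 5000)
  c1 <- order_clones(c("x1", "x2"), space = sp2, contig_id = "A")
  c2 <- order_clones(c("y1", "y2"), space = sp2, contig_id = "B")
  expect_length(end_merge(list(c1, c2), fpc_params(), sp2), 2L)

  # three-way chain A-B-C resolves into a single contig deterministically
  chain <- tiling_profiles(c(0, 8, 26, 34, 52, 60), width = 25)
  sp3 <- clonetiler:::tag_space(chain, universe_size = 5000)
  ca <- order_clones(c("cl01", "cl02"), space = sp3, contig_id = "A")
  cb <- order_clones(c("cl03", "cl04"), space = sp3, contig_id = "B")
  cc <- order_clones(c("cl05", "cl06"), space = sp3, contig_id = "C")
  m1 <- end_merge(list(ca, cb, cc), fpc_params(), sp3)
  m2 <- end_merge(list(cc, ca, cb), fpc_params(), sp3)
  expect_length(m1, 1L)
  expect_setequal(m1[[1]]$clones$clone_id, names(chain))
  expect_identical(m1[[1]]$clones$clone_id, m2[[1]]$clones$clone_id)
})

test_that("singletons join their best contig only below the cutoff", {
  profs <- tiling_profiles(c(0, 10, 20), width = 20)
  profs$lone <- c(profs$cl02[1:18], paste0("z", 1:2))  # 90% shared with cl02
  profs$orphan <- paste0("w", 1:15)                    # unrelated
  profs$empty <- character(0)
  space <- clonetiler:::tag_space(profs, universe_size = 5000)
  ct <- order_clones(c("cl01", "cl02", "cl03"), space = space, contig_id = "c")
  res <- add_singletons(list(ct), c("lone", "orphan", "empty"),
                        fpc_params(), space)
  expect_true("lone" %in% res$contigs[[1]]$clones$clone_id)
  expect_setequal(res$singletons, c("orphan", "empty"))
  expect_equal(res$report$n_contigs, 1L)
  expect_equal(res$report$clones_in_contigs, 4L)
  expect_equal(res$report$n_singletons, 2L)
})

test_that("MTP selection walks forced chains and skips contained clones", {
  # neighbors-only overlaps force the full chain
  profs <- tiling_profiles(c(0, 10, 20, 30), width = 15)
  space <- clonetiler:::tag_space(profs, universe_size = 5000)
  ct <- order_clones(names(profs), space = space, contig_id = "c")
  path <- select_mtp(ct, min_mtp_shared = 5, space = space)
  expect_length(path$clone_ids, 4L)
  expect_true(all(path$shared >= 5))

  # a clone contained in another (shares all its tags) is never selected
  profs2 <- tiling_profiles(c(0, 14), width = 20)
  profs2$inner <- profs2$cl01[5:16]  # fully inside cl01
  sp2 <- clonetiler:::tag_space(profs2, universe_size = 5000)
  ct2 <- order_clones(names(profs2), space = sp2, contig_id = "c")
  path2 <- select_mtp(ct2, min_mtp_shared = 5, space = sp2)
  expect_false("inner" %in% path2$clone_ids)
})

test_that("a 10x simulated map yields an MTP covering what its contigs cover", {
  sim <- tiny_sim()
  pm <- tiny_pm()
  mtp <- select_mtp_all(pm)
  cl <- sim$clones
  coverage <- function(ids) {
    cov <- rep(FALSE, nchar(sim$genome$chromosomes[[1]]))
    for (cid in ids) {
      i <- match(cid, cl$clone_id)
      cov[(cl$start[i] + 1):cl$end[i]] <- TRUE
    }
    cov
  }
  contig_cov_all <- rep(FALSE, nchar(sim$genome$chromosomes[[1]]))
  mtp_cov_all <- contig_cov_all
  for (nm in names(pm$contigs)) {
    # in tag space the coverage is exact: every tag carried by a contig
    # clone is carried by an MTP clone
    contig_tags <- unique(unlist(sim$profiles[pm$contigs[[nm]]$clones$clone_id]))
    mtp_tags <- unique(unlist(sim$profiles[mtp[[nm]]$clone_ids]))
    expect_length(setdiff(contig_tags, mtp_tags), 0L)
    contig_cov_all <- contig_cov_all | coverage(pm$contigs[[nm]]$clones$clone_id)
    mtp_cov_all <- mtp_cov_all | coverage(mtp[[nm]]$clone_ids)
  }
  # at sequence level only tag-blind clone fringes can escape the walk
  expect_gte(sum(mtp_cov_all & contig_cov_all) / sum(contig_cov_all), 0.97)
  # expected MTP size: genome_len / (insert_mean - mean_overlap); the walk
  # steps by roughly the insert length minus the shared-tag overlap
  n_mtp <- length(attr(mtp, "clone_ids"))
  expect_gte(n_mtp, 10)
  expect_lte(n_mtp, 40)
})

test_that("clone membership stays a partition through the cascade", {
  sim <- tiny_sim()
  pm <- tiny_pm()
  members <- unlist(lapply(pm$contigs, function(ct) ct$clones$clone_id))
  all_ids <- c(members, pm$singletons)
  expect_false(any(duplicated(all_ids)))
  expect_setequal(all_ids, sim$clones$clone_id)
})
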