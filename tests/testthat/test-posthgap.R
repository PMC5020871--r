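test_that("terminal self-overlaps are detected at the span/identity thresholds", {
  s <- random_seq(4000, seed = 51)
  u_exact <- paste0(s, substr(s, 1, 600))
  det <- detect_terminal_overlap(u_exact)
  expect_equal(det$overlap_len, 600L)
  expect_equal(det$identity, 1)

  # 3% substitutions in the duplicated copy: detected, identity ~0.97
  dup <- plant_subs(substr(s, 1, 600), seq(10, 600, by = 34))
  u_noisy <- paste0(s, dup)
  det2 <- detect_terminal_overlap(u_noisy)
  expect_equal(det2$overlap_len, 600L)
  expect_gte(det2$identity, 0.95)
  expect_lt(det2$identity, 0.99)

  # 400 bp terminal copy: below minOverlap, not circularizable
  expect_null(detect_terminal_overlap(paste0(s, substr(s, 1, 400))))
  # sequence shorter than 2 x minOverlap: none, not an error
  expect_null(detect_terminal_overlap(substr(s, 1, 900)))
})

test_that("circularization trims one overlap copy and canonicalizes the rotation", {
  s <- random_seq(5000, seed = 52)
  u <- paste0(s, substr(s, 1, 600))
  res <- circularize(u, unitig_id = "u1")
  expect_equal(res$status, "circularized")
  expect_equal(res$overlap_len, 600L)
  expect_equal(nchar(res$sequence), nchar(u) - 600L)  # conservation
  # any rotation of the same plasmid canonicalizes identically
  for (r in c(123, 2500, 4999)) {
    rot <- clonetiler:::rotate_seq(s, r)
    res_r <- circularize(paste0(rot, substr(rot, 1, 600)), unitig_id = "u2")
    expect_identical(res_r$sequence, res$sequence)
  }
  lin <- circularize(substr(s, 1, 3000), unitig_id = "u3")
  expect_equal(lin$status, "linear")
  expect_identical(lin$sequence, substr(s, 1, 3000))
})

test_that("vector excision round-trips the cloned insert", {
  sim <- tiny_sim()
  pool <- design_pools(sim$clones$clone_id[1:12], config_schedule = "row12")
  u <- simulate_pool_unitigs(pool, sim$clones, sim$genome, sim$vector,
                             dup_overlap_len = 600, error_rate = 0,
                             fail_rate = 0, seed = 8)
  for (i in 1:4) {
    cc <- circularize(u$sequence[i], unitig_id = u$unitig_id[i])
    expect_equal(cc$status, "circularized")
    ex <- excise_vector(cc$sequence, sim$vector)
    expect_equal(ex$status, "excised")
    cl <- sim$clones[sim$clones$clone_id == u$truth_clone_id[i], ]
    truth <- substr(sim$genome$chromosomes[[cl$chrom]], cl$start + 1, cl$end)
    expect_true(ex$insert == truth || ex$insert == revcomp(truth))
  }

  # substitution noise: insert identity to truth >= 99.9%
  un <- simulate_pool_unitigs(pool, sim$clones, sim$genome, sim$vector,
                              dup_overlap_len = 600, error_rate = 5e-4,
                              fail_rate = 0, seed = 9)
  cc <- circularize(un$sequence[1], unitig_id = "n1")
  ex <- excise_vector(cc$sequence, sim$vector)
  cl <- sim$clones[sim$clones$clone_id == un$truth_clone_id[1], ]
  truth <- substr(sim$genome$chromosomes[[cl$chrom]], cl$start + 1, cl$end)
  expect_equal(nchar(ex$insert), nchar(truth))
  ident <- max(clonetiler:::hamming_identity(ex$insert, truth),
               clonetiler:::hamming_identity(ex$insert, revcomp(truth)))
  expect_gte(ident, 0.999)

  # vector-free circular sequence is flagged, not excised
  ex2 <- excise_vector(random_seq(9000, seed = 53), sim$vector)
  expect_equal(ex2$status, "vectorless")
})

test_that("clone identity comes from tags, falls back to BES, and flags swaps", {
  sim <- tiny_sim()
  profiles <- sim$profiles
  cl <- sim$clones[5, ]
  insert <- substr(sim$genome$chromosomes[[cl$chrom]], cl$start + 1, cl$end)

  asg <- assign_clone_ids(stats::setNames(insert, "s1"), profiles,
                          pool_members = list(s1 = cl$clone_id))
  expect_equal(asg$status, "mtp_clone")
  expect_equal(asg$clone_id, cl$clone_id)
  expect_equal(asg$evidence, "tags")
  expect_gte(asg$percent, 0.8)
  expect_gte(asg$matched, 5)

  # starve the tag evidence (keep only 4 profile tags < minCloneTagNumber)
  # and let the BES pair rescue the assignment
  weak <- profiles
  weak[[cl$clone_id]] <- weak[[cl$clone_id]][1:4]
  bes <- list(simulate_bes(cl, sim$genome, read_len = 700, error_rate = 0,
                           seed = 1))
  names(bes) <- cl$clone_id
  # restrict to this clone's profile universe so no other clone qualifies
  asg2 <- assign_clone_ids(stats::setNames(insert, "s1"),
                           weak[cl$clone_id], bes,
                           pool_members = list(s1 = cl$clone_id))
  expect_equal(asg2$evidence, "bes")
  expect_equal(asg2$clone_id, cl$clone_id)
  expect_gte(asg2$bes_identity, 0.98)

  # a well swap: the unitig's content belongs to a clone outside its pool
  other <- sim$clones[40, ]
  swap_insert <- substr(sim$genome$chromosomes[[other$chrom]],
                        other$start + 1, other$end)
  asg3 <- assign_clone_ids(stats::setNames(swap_insert, "s2"), profiles,
                           pool_members = list(s2 = cl$clone_id))
  expect_equal(asg3$status, "non_mtp_clone")
  expect_equal(asg3$clone_id, other$clone_id)
})

test_that("pool reports reproduce the published circularization rates", {
  mk_circ <- function(n_circ, n_lin) {
    data.frame(status = c(rep("circularized", n_circ), rep("linear", n_lin)))
  }
  asg <- data.frame(status = character(0))
  expect_equal(pool_report(mk_circ(4415, 156), asg,
                           sprintf("c%d", 1:4714))$circularization_rate_pct, 94)
  expect_equal(pool_report(mk_circ(4320, 168), asg,
                           sprintf("c%d", 1:4751))$circularization_rate_pct, 91)
  expect_equal(pool_report(mk_circ(0, 10), asg,
                           sprintf("c%d", 1:10))$circularization_rate_pct, 0)
})

test_that("end-to-end recovery holds on a collision-free low-error pool run", {
  sim <- tiny_sim()
  pm <- tiny_pm()
  mtp <- select_mtp_all(pm)
  ids <- attr(mtp, "clone_ids")
  pools <- design_pools(ids, config_schedule = "row12")
  params <- posthgap_params()
  n_circ <- 0L
  n_correct <- 0L
  total <- 0L
  for (pid in unique(pools$pool_id)) {
    p <- pools[pools$pool_id == pid, ]
    u <- simulate_pool_unitigs(p, sim$clones, sim$genome, sim$vector,
                               dup_overlap_len = 600, error_rate = 5e-4,
                               fail_rate = 0, seed = 60 + match(pid, unique(pools$pool_id)))
    for (i in seq_len(nrow(u))) {
      total <- total + 1L
      cc <- circularize(u$sequence[i], params, u$unitig_id[i])
      if (cc$status != "circularized") next
      n_circ <- n_circ + 1L
      ex <- excise_vector(cc$sequence, sim$vector, params)
      asg <- assign_clone_ids(stats::setNames(ex$insert, u$unitig_id[i]),
                              sim$profiles, params = params,
                              pool_members = stats::setNames(list(p$clone_id),
                                                             u$unitig_id[i]))
      if (!is.na(asg$clone_id) && asg$clone_id == u$truth_clone_id[i]) {
        n_correct <- n_correct + 1L
      }
    }
  }
  expect_gte(n_circ / total, 0.99)
  expect_equal(n_correct, n_circ)
})
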