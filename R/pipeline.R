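# End-to-end driver: simulate a genome and BAC library, build the WGP
# physical map, pick the MTP, pool and "sequence" the MTP clones, run the
# postHGAP stage, tile pseudomolecules and bridge gaps, and score everything
# against the simulator truth.

#' Default pipeline configuration
#'
#' Desk-scale defaults: a 2 Mb, 2-chromosome genome, 40 +/- 5 kb HindIII
#' inserts at 10x clone coverage, a 7.5 kb vector, 600 bp planted terminal
#' duplication, 0.05% substitution error and no pool failures. Each block can
#' be overridden via `modifyList()` or a YAML file ([read_config()]).
#'
#' @return nested list of parameter blocks.
#' @export
default_config <- function() {
  list(
    genome = list(n_chroms = 2L, chrom_len = 1000000L, repeat_fraction = 0),
    vector = list(length = 7500L, cloning_site_offset = 100L),
    library = list(clone_coverage = 10, insert_mean = 40000L, insert_sd = 5000L),
    bes = list(read_len = 700L, error_rate = 0.001),
    pools = list(config_schedule = "row12"),
    unitigs = list(dup_overlap_len = 600L, error_rate = 5e-4, fail_rate = 0),
    wgs = list(n_breaks = 40L, min_len = 500L, bridge_flank = 5000L),
    fpc = fpc_params(),
    posthgap = posthgap_params(),
    gpm = gpm_params()
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override [default_config()]; parameter blocks
#' (`fpc`, `posthgap`, `gpm`) are re-validated through their constructors.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
read_config <- function(path) {
  user <- yaml::read_yaml(path)
  cfg <- utils::modifyList(default_config(), user)
  cfg$fpc <- do.call(fpc_params, cfg$fpc[names(cfg$fpc) != "tolerance"])
  cfg$posthgap <- do.call(posthgap_params,
                          cfg$posthgap[names(cfg$posthgap) != "tag_match_identity"])
  cfg$gpm <- do.call(gpm_params, unclass(cfg$gpm))
  cfg
}

#' Run the full clone-by-clone assembly pipeline on a simulated genome
#'
#' Simulation, WGP tagging, physical map + MTP, pooling, unitig simulation,
#' postHGAP (circularization, vector excision, clone identification),
#' pseudomolecule tiling and WGS gap bridging, followed by truth-based
#' scoring.
#'
#' @param config configuration list ([default_config()]).
#' @param seed master integer seed; every stage derives its own sub-seed.
#' @param outdir optional directory: simulator inputs, FASTA/AGP outputs and
#'   reports are written there.
#' @return list with the intermediate objects (`genome`, `clones`,
#'   `profiles`, `pm`, `mtp`, `pools`, `unitigs`, `circ`, `assignments`,
#'   `anchoring`, `pseudos`, `gap_report`, `report`, `stats`) and `metrics`
#'   (scored against truth).
#' @export
run_pipeline <- function(config = default_config(), seed = 1L, outdir = NULL) {
  seed <- as.integer(seed) %% 100000000L
  genome <- make_genome(config$genome$n_chroms, config$genome$chrom_len,
                        config$genome$repeat_fraction, seed = seed + 1L)
  vec <- make_vector(config$vector$length, config$vector$cloning_site_offset,
                     seed = seed + 2L)
  clones <- simulate_bac_library(genome, vec, config$library$clone_coverage,
                                 config$library$insert_mean,
                                 config$library$insert_sd, seed = seed + 3L)
  genome <- attr(clones, "genome")  # may carry planted HindIII sites

  profiles <- clone_tag_profiles(clones, genome)
  pm <- physical_map(profiles, config$fpc)
  mtp <- select_mtp_all(pm, config$fpc$min_mtp_shared)
  mtp_clones <- attr(mtp, "clone_ids")

  pools <- design_pools(mtp_clones, config_schedule = config$pools$config_schedule)
  bes <- simulate_bes_index(clones[clones$clone_id %in% mtp_clones, ], genome,
                            config$bes$read_len, config$bes$error_rate,
                            seed = seed + 4L)
  unitig_list <- lapply(split(pools, pools$pool_id), function(p)
    simulate_pool_unitigs(p, clones, genome, vec,
                          config$unitigs$dup_overlap_len,
                          config$unitigs$error_rate, config$unitigs$fail_rate,
                          seed = (seed + 5L + match(p$pool_id[1L],
                                                    unique(pools$pool_id)))))
  unitigs <- do.call(rbind, unname(unitig_list))

  circ <- lapply(seq_len(nrow(unitigs)), function(i)
    circularize(unitigs$sequence[i], config$posthgap, unitigs$unitig_id[i]))
  circ_df <- data.frame(
    unitig_id = unitigs$unitig_id, pool_id = unitigs$source_pool_id,
    truth_clone_id = unitigs$truth_clone_id,
    truth_is_circular = unitigs$truth_is_circular,
    status = vapply(circ, `[[`, character(1), "status"),
    overlap_len = vapply(circ, `[[`, integer(1), "overlap_len")
  )
  is_circ <- circ_df$status == "circularized"
  inserts <- character(0)
  insert_meta <- list()
  for (i in which(is_circ)) {
    ex <- excise_vector(circ[[i]]$sequence, vec, config$posthgap)
    if (ex$status == "excised") {
      inserts[[unitigs$unitig_id[i]]] <- ex$insert
      insert_meta[[unitigs$unitig_id[i]]] <- ex
    }
  }
  pool_members <- lapply(stats::setNames(unitigs$source_pool_id, unitigs$unitig_id),
                         function(pid) pools$clone_id[pools$pool_id == pid])
  assignments <- assign_clone_ids(inserts, profiles, bes, config$posthgap,
                                  pool_members = pool_members[names(inserts)])
  report <- pool_report(circ_df, assignments, mtp_clones,
                        insert_lengths = nchar(inserts))

  # tiling: one piece per assigned clone (first occurrence wins on redos)
  assigned <- assignments[assignments$status != "unassigned", , drop = FALSE]
  assigned <- assigned[!duplicated(assigned$clone_id), , drop = FALSE]
  pieces <- stats::setNames(inserts[assigned$sequence_id], assigned$clone_id)
  pm_order <- do.call(rbind, lapply(mtp, function(p) {
    walk <- setdiff(p$clone_ids, p$swept)  # sweep-up picks have no walk rank
    data.frame(seq_id = walk, contig_id = p$contig_id,
               rank = seq_along(walk))
  }))
  pm_order <- pm_order[pm_order$seq_id %in% names(pieces), , drop = FALSE]
  anchoring <- anchor_pieces(pieces, genome, pm_order = pm_order, source = "BAC")
  pseudos <- build_pseudomolecules(anchoring, pieces, config$gpm)
  contigs_before <- sum(vapply(pseudos, `[[`, integer(1), "contig_count"))

  wgs <- simulate_wgs_contigs(genome, config$wgs$n_breaks, config$wgs$min_len,
                              seed = seed + 6L)
  open_gaps <- do.call(rbind, lapply(names(pseudos), function(cn) {
    g <- pseudos[[cn]]$gaps
    anc <- anchoring$anchored[anchoring$anchored$chrom == cn, , drop = FALSE]
    clen <- nchar(genome$chromosomes[[cn]])
    covered_to <- max(anc$anchor_start + nchar(pieces[anc$seq_id]))
    rows <- if (nrow(g)) {
      data.frame(chrom = cn, start = pmin(g$left_anchor_end, g$right_anchor_start),
                 end = pmax(g$left_anchor_end, g$right_anchor_start))
    } else {
      NULL
    }
    # tag-blind chromosome ends the map cannot reach
    if (min(anc$anchor_start) > 0L) {
      rows <- rbind(rows, data.frame(chrom = cn, start = 0L,
                                     end = min(anc$anchor_start)))
    }
    if (covered_to < clen) {
      rows <- rbind(rows, data.frame(chrom = cn, start = covered_to, end = clen))
    }
    rows
  }))
  bridges <- if (!is.null(open_gaps) && nrow(open_gaps)) {
    simulate_bridge_contigs(genome, open_gaps, config$wgs$bridge_flank)
  } else {
    character(0)
  }
  filled <- fill_gaps(pseudos, c(wgs, bridges), config$gpm)
  pseudos <- filled$pseudos
  contigs_after <- sum(vapply(pseudos, `[[`, integer(1), "contig_count"))

  contig_lengths <- lapply(pseudos, function(ps)
    vapply(ps$runs, function(r) nchar(r$sequence), numeric(1)))
  stats <- stats_table(contig_lengths, min_len = 500L)
  metrics <- score_pipeline(genome, circ_df, assignments, pseudos,
                            contigs_before, contigs_after)

  out <- list(genome = genome, vector = vec, clones = clones,
              profiles = profiles, pm = pm, mtp = mtp, pools = pools,
              bes = bes, unitigs = unitigs, circ = circ_df,
              assignments = assignments, report = report,
              anchoring = anchoring, pseudos = pseudos,
              gap_report = filled$gap_report, wgs_contigs = wgs,
              stats = stats, metrics = metrics)
  if (!is.null(outdir)) {
    write_simulation(out, outdir)
    seqs <- vapply(pseudos, pseudo_sequence, character(1))
    write_fasta(seqs, file.path(outdir, "pseudomolecules.fa"))
    write_agp(pseudos, file.path(outdir, "pseudomolecules.agp"))
    write_tsv(out$circ, file.path(outdir, "circularization.tsv"))
    write_tsv(out$assignments, file.path(outdir, "assignments.tsv"))
    write_tsv(out$gap_report, file.path(outdir, "gap_report.tsv"))
    write_tsv(out$stats, file.path(outdir, "assembly_stats.tsv"))
  }
  out
}

# Score the run against simulator truth.
score_pipeline <- function(genome, circ_df, assignments, pseudos,
                           contigs_before, contigs_after) {
  non_trunc <- circ_df[circ_df$truth_is_circular, , drop = FALSE]
  circ_rate <- 100 * mean(non_trunc$status == "circularized")
  m <- merge(assignments, circ_df[, c("unitig_id", "truth_clone_id")],
             by.x = "sequence_id", by.y = "unitig_id")
  assigned <- m[m$status != "unassigned", , drop = FALSE]
  id_acc <- if (nrow(m)) 100 * sum(assigned$clone_id == assigned$truth_clone_id) /
    nrow(m) else NA_real_
  per_chrom <- lapply(names(genome$chromosomes), function(cn) {
    truth <- genome$chromosomes[[cn]]
    if (is.null(pseudos[[cn]])) {
      return(data.frame(chrom = cn, identity_pct = 0, length_err_pct = 100))
    }
    ped <- pseudo_sequence(pseudos[[cn]])
    cmp <- compare_sequences(ped, truth)
    data.frame(chrom = cn, identity_pct = cmp$identity_pct,
               length_err_pct = cmp$length_err_pct)
  })
  per_chrom <- do.call(rbind, per_chrom)
  list(circularization_rate_pct = circ_rate,
       clone_id_accuracy_pct = id_acc,
       per_chrom = per_chrom,
       identity_pct = min(per_chrom$identity_pct),
       length_err_pct = max(abs(per_chrom$length_err_pct)),
       contigs_before_fill = contigs_before,
       contigs_after_fill = contigs_after)
}

#' Compare an assembled sequence to its truth counterpart
#'
#' Anchors the assembly on the truth by exact k-mer voting, then counts
#' positional matches over the aligned span; identity is matches over the
#' longer of the two lengths (missing or extra sequence counts against it;
#' Ns never match).
#'
#' @param assembly,truth character sequences.
#' @return list `identity_pct`, `length_err_pct` (signed percentage length
#'   difference), `offset`.
#' @export
compare_sequences <- function(assembly, truth) {
  na <- nchar(assembly)
  nt <- nchar(truth)
  votes <- vote_offsets(assembly, truth, k = 31L, n_seeds = 40L)
  if (!nrow(votes)) {
    return(list(identity_pct = 0, length_err_pct = 100 * (na - nt) / nt,
                offset = NA_integer_))
  }
  o <- votes$offset[1L]
  a_from <- max(1L, 2L - o)
  t_from <- o + a_from - 1L
  span <- min(na - a_from + 1L, nt - t_from + 1L)
  matches <- span * hamming_identity(substr(assembly, a_from, a_from + span - 1L),
                                     substr(truth, t_from, t_from + span - 1L))
  list(identity_pct = 100 * matches / max(na, nt),
       length_err_pct = 100 * (na - nt) / nt,
       offset = o)
}
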