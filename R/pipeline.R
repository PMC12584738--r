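#' Default run configuration
#'
#' One flat registry of every tunable the pipeline uses, so no stage
#' carries hidden constants.  Thresholds default to the screening,
#' copy-retrieval, solo-LTR, dating and orthology values the method is
#' defined with.
#'
#' @param seed Master RNG seed.
#' @param out_dir Output directory.
#' @return Named list.
#' @export
default_config <- function(seed = 1L, out_dir = tempfile("ervatlas_run_")) {
  list(
    seed = seed, out_dir = out_dir,
    host = "Msyn", species_a = "Msyn", species_b = "MsynB",
    # simulator
    background_gc = 0.42, min_spacing = 20000L,
    rate = 2.2e-9, kappa = 2,
    speciation_myr = 8,
    # POL-probe screen
    screen_min_identity = 0.30, screen_min_coverage = 0.40,
    screen_evalue_max = 1e-5, merge_gap = 1000L,
    # LTR structure
    ltr_min_len = 100L, ltr_max_len = 7000L,
    ltr_min_dist = 1000L, ltr_max_dist = 15000L, ltr_min_sim = 0.85,
    tsd_min = 4L, tsd_max = 6L,
    pbs_offset_max = 20L, pbs_mismatch_max = 2L,
    ppt_offset_max = 20L, ppt_min_len = 10L, ppt_min_purine = 0.9,
    min_internal = 500L,
    # lineages / consensus / solo LTRs
    copy_min_len = 4000L, copy_min_identity = 0.80,
    cluster_min_identity = 0.90,
    solo_evalue_max = 1e-5, solo_min_coverage = 0.10,
    solo_min_identity = 0.80, solo_window = 15000L,
    solo_group_identity = 0.90,
    # ORFs / motifs
    orf_min_nt = 180L, require_atg = TRUE,
    # cross-species / orthology
    rt_min_identity = 0.80, rt_min_coverage = 0.80, rt_evalue_max = 1e-5,
    ortho_min_identity = 0.85, ortho_min_coverage = 0.50,
    ortho_min_aln = 500L, ortho_flank = 30000L
  )
}

#' Demo plan: the bundled structural-genome study conditions
#'
#' 23 planted elements across three lineages, ages 0-10 Myr, mixing
#' intact, degraded, solo and nested states, including two minus-strand
#' insertions; elements are spaced far enough apart that solo/remnant
#' classification has unambiguous truth.
#'
#' @return Data frame with columns lineage/age_myr/state/strand.
#' @export
demo_plan <- function() {
  plan <- rbind(
    data.frame(lineage = "GammaA", age_myr = c(0, 1, 3, 5, 7, 9),
               state = "intact", strand = c("+", "+", "-", "+", "+", "+")),
    data.frame(lineage = "GammaA", age_myr = 6, state = "degraded", strand = "+"),
    data.frame(lineage = "GammaA", age_myr = c(2, 8), state = "solo", strand = "+"),
    data.frame(lineage = "GammaB", age_myr = c(2, 4, 6, 8),
               state = "intact", strand = c("+", "-", "+", "+")),
    data.frame(lineage = "GammaB", age_myr = 5, state = "degraded", strand = "+"),
    data.frame(lineage = "GammaB", age_myr = 4, state = "nested", strand = "+"),
    data.frame(lineage = "GammaB", age_myr = 3, state = "solo", strand = "+"),
    data.frame(lineage = "BetaA", age_myr = c(0, 5, 10),
               state = "intact", strand = "+"),
    data.frame(lineage = "BetaA", age_myr = 7, state = "degraded", strand = "+"),
    data.frame(lineage = "BetaA", age_myr = 2, state = "nested", strand = "+"),
    data.frame(lineage = "BetaA", age_myr = 6, state = "solo", strand = "+"))
  plan$state <- as.character(plan$state)
  plan$lineage <- as.character(plan$lineage)
  plan$strand <- as.character(plan$strand)
  plan
}

#' Demo plan for the orthology species pair
#' @return List with `ancestral` (5 shared elements, ages at the split)
#'   and `private_a` / `private_b` plans (post-split insertions).
#' @export
demo_pair_plan <- function() {
  list(
    ancestral = data.frame(
      lineage = c("GammaA", "GammaA", "GammaB", "GammaB", "BetaA"),
      age_myr = c(0.5, 1, 1.5, 2, 1), state = "intact", strand = "+",
      stringsAsFactors = FALSE),
    private_a = data.frame(
      lineage = c("GammaA", "GammaB", "BetaA"),
      age_myr = c(2, 4, 3), state = "intact", strand = "+",
      stringsAsFactors = FALSE),
    private_b = data.frame(
      lineage = c("GammaA", "BetaA"),
      age_myr = c(3, 5), state = "intact", strand = "+",
      stringsAsFactors = FALSE))
}

probe_panel <- function(templates) {
  probes <- vapply(templates, function(t) t$proteins$POL, character(1))
  names(probes) <- names(templates)
  probes
}

template_genus <- function(templates) {
  vapply(templates, function(t) t$genus, character(1))
}

screen_cfg <- function(config) {
  p <- screen_params()
  p$min_identity <- config$screen_min_identity
  p$min_coverage <- config$screen_min_coverage
  p$evalue_max <- config$screen_evalue_max
  p$merge_gap <- config$merge_gap
  p$rt_min_identity <- config$rt_min_identity
  p$rt_min_coverage <- config$rt_min_coverage
  p$rt_evalue_max <- config$rt_evalue_max
  p
}

ltr_cfg <- function(config) {
  p <- ltr_params()
  p$min_ltr <- config$ltr_min_len; p$max_ltr <- config$ltr_max_len
  p$min_dist <- config$ltr_min_dist; p$max_dist <- config$ltr_max_dist
  p$min_sim <- config$ltr_min_sim
  p$tsd_min <- config$tsd_min; p$tsd_max <- config$tsd_max
  p$pbs_offset_max <- config$pbs_offset_max
  p$pbs_mismatch_max <- config$pbs_mismatch_max
  p$ppt_offset_max <- config$ppt_offset_max
  p$ppt_min_len <- config$ppt_min_len
  p$ppt_min_purine <- config$ppt_min_purine
  p$min_internal <- config$min_internal
  p
}

ortho_cfg <- function(config) {
  p <- ortho_params()
  p$min_insertion_identity <- config$ortho_min_identity
  p$min_flank_coverage <- config$ortho_min_coverage
  p$min_aln_len <- config$ortho_min_aln
  p$flank <- config$ortho_flank
  p
}

# Analyze one genome: screen -> annotate -> cluster -> consensus ->
# copies -> solos -> motifs -> dating.  Returns the per-genome bundle.
analyze_genome <- function(genome, probes, genera, config, stage_log) {
  scfg <- screen_cfg(config)
  lcfg <- ltr_cfg(config)
  nt_index <- genome_index(genome, "nucleotide")
  cands <- screen_genome(probes, genome, params = scfg)
  stage_log("screen", sprintf("%d candidate loci", nrow(cands)))
  catalog <- annotate_candidates(genome, cands, params = lcfg)
  full <- Filter(function(p) isTRUE(p$full_length), catalog)
  stage_log("annotate", sprintf("%d paired-LTR elements (%d full length)",
                                length(catalog), length(full)))
  if (length(full) == 0) {
    return(list(candidates = cands, catalog = catalog, lineages = NULL))
  }
  elem_seqs <- vapply(full, function(p) extract_locus(genome, p$span)$seq,
                      character(1))
  clusters <- cluster_lineages(elem_seqs, config$cluster_min_identity)
  cand_genus <- stats::setNames(genera[cands$best_query], cands$id)
  elem_genus <- vapply(full, function(p) unname(cand_genus[p$id]), character(1))
  lineages <- list()
  for (cl in sort(unique(clusters))) {
    members <- which(clusters == cl)
    cons <- build_consensus(elem_seqs[members])
    genus <- elem_genus[members[1]]
    # consensus LTR from the members' 5' and 3' repeats
    ltrs <- unlist(lapply(members, function(i) {
      p <- full[[i]]
      c(extract_locus(genome, p$ltr5)$seq, extract_locus(genome, p$ltr3)$seq)
    }))
    ltr_cons <- build_consensus(ltrs)
    copies <- find_copies(cons, genome, min_len = config$copy_min_len,
                          min_identity = config$copy_min_identity,
                          index = nt_index)
    lineages[[length(lineages) + 1L]] <- list(
      cluster = cl, genus = genus, consensus = cons, ltr_consensus = ltr_cons,
      members = vapply(full[members], function(p) p$id, character(1)),
      copies = copies)
  }
  # nomenclature over full-length copies
  copy_tab <- do.call(rbind, lapply(seq_along(lineages), function(i) {
    cp <- lineages[[i]]$copies
    if (nrow(cp) == 0) return(NULL)
    cp$cluster <- lineages[[i]]$cluster
    cp$genus <- lineages[[i]]$genus
    cp
  }))
  copy_tab <- assign_names(copy_tab, host = config$host)
  for (i in seq_along(lineages)) {
    nm <- unique(copy_tab$lineage_name[copy_tab$cluster == lineages[[i]]$cluster])
    lineages[[i]]$name <- nm[1]
  }
  # lineage label on catalog elements (by cluster membership); `full`
  # holds copies, so refresh it afterwards
  for (i in seq_along(lineages)) {
    for (id in lineages[[i]]$members) {
      for (k in seq_along(catalog)) {
        if (catalog[[k]]$id == id) catalog[[k]]$lineage <- lineages[[i]]$name
      }
    }
  }
  full <- Filter(function(p) isTRUE(p$full_length), catalog)
  stage_log("lineages", sprintf("%d lineages, %d copies",
                                length(lineages), nrow(copy_tab)))

  # solo LTRs: remnant loci are provirus internal regions + raw screen hits
  remnants <- rbind(
    do.call(rbind, lapply(catalog, function(p) {
      data.frame(contig = p$contig, start = min(p$ltr5$start, p$ltr3$start),
                 end = max(p$ltr5$end, p$ltr3$end), stringsAsFactors = FALSE)
    })),
    cands[, c("contig", "start", "end")])
  ltr_queries <- stats::setNames(
    vapply(lineages, function(l) l$ltr_consensus, character(1)),
    vapply(lineages, function(l) l$name, character(1)))
  solos <- classify_solo_ltrs(ltr_queries, genome, remnants,
                              evalue_max = config$solo_evalue_max,
                              min_coverage = config$solo_min_coverage,
                              min_identity = config$solo_min_identity,
                              window = config$solo_window,
                              group_identity = config$solo_group_identity,
                              index = nt_index)
  solo_only <- solos[solos$is_solo, , drop = FALSE]
  if (nrow(solo_only) > 0) {
    solo_only$genus <- vapply(solo_only$lineage, function(nm)
      parse_erv_name(nm)$genus, character(1))
    solo_only <- assign_names(solo_only, host = config$host, solo = TRUE)
    solos$solo_name <- NA_character_
    solos$solo_name[solos$is_solo] <- solo_only$copy_name
  } else {
    solos$solo_name <- NA_character_
  }
  stage_log("solos", sprintf("%d solo LTRs among %d LTR hits",
                             sum(solos$is_solo), nrow(solos)))

  # motifs on lineage consensus ORFs
  motif_rows <- list()
  for (l in lineages) {
    orfs <- find_orfs(l$consensus, min_nt = config$orf_min_nt,
                      require_atg = config$require_atg)
    orfs <- assign_gene_guess(orfs)
    l_motifs <- list()
    for (g in c("GAG", "POL", "ENV")) {
      sel <- which(orfs$gene_guess == g)
      if (length(sel) == 0) next
      prot <- orfs$protein[sel[1]]
      mh <- scan_motifs(prot)
      if (nrow(mh) > 0) {
        mh$lineage <- l$name; mh$gene <- g
        l_motifs[[g]] <- mh
      }
    }
    l_motifs <- if (length(l_motifs)) do.call(rbind, l_motifs) else NULL
    env_sel <- which(orfs$gene_guess == "ENV")
    env_type <- if (length(env_sel) && !is.null(l_motifs)) {
      classify_env_type(l_motifs[l_motifs$gene == "ENV", , drop = FALSE])
    } else "indeterminate"
    motif_rows[[length(motif_rows) + 1L]] <-
      list(lineage = l$name, orfs = orfs, motifs = l_motifs,
           env_type = env_type)
  }
  stage_log("motifs", sprintf("%d lineages characterized", length(motif_rows)))

  # dating of full-length elements
  datings <- date_catalog(full, genome, R = config$rate)
  datings$lineage <- vapply(full, function(p) p$lineage %||% NA_character_,
                            character(1))
  stage_log("date", sprintf("%d elements dated (%d ok)",
                            nrow(datings), sum(datings$flag == "ok")))

  list(candidates = cands, catalog = catalog, full = full,
       lineages = lineages, copy_tab = copy_tab, solos = solos,
       motif_rows = motif_rows, datings = datings)
}

# RT consensus per lineage: the central ~900 bp of the longest
# forward-strand ORF (POL) of the lineage consensus.
rt_consensus_of <- function(lineage) {
  orfs <- find_orfs(lineage$consensus)
  orfs <- orfs[orfs$strand == "+", , drop = FALSE]
  if (nrow(orfs) == 0) return(NULL)
  pol <- orfs[which.max(orfs$aa_len), ]
  mid <- (pol$start + pol$end) %/% 2
  a <- max(pol$start, mid - 450L)
  b <- min(pol$end, mid + 450L)
  substr(lineage$consensus, a + 1L, b)
}

#' Run the full desk-scale pipeline
#'
#' Simulates the bundled demo genome and a descendant species pair, then
#' runs every analysis stage (screen, LTR annotation, lineage clustering
#' and consensus, solo-LTR classification, motif characterization,
#' paired-LTR dating, orthologous-insertion survey) and writes a report
#' bundle to `config$out_dir`.  Reruns with the same config and seed are
#' byte-identical.
#'
#' @param config Configuration list from [default_config()]; unknown keys
#'   are rejected.
#' @param plan Element plan for the structural demo genome (default
#'   [demo_plan()]).
#' @param pair_plan Plans for the orthology species pair (default
#'   [demo_pair_plan()]).
#' @return Invisibly, the in-memory bundle (simulation truth, per-stage
#'   tables, summary).
#' @export
run_pipeline <- function(config = default_config(), plan = demo_plan(),
                         pair_plan = demo_pair_plan()) {
  known <- names(default_config())
  unknown <- setdiff(names(config), known)
  if (length(unknown) > 0)
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  for (k in setdiff(known, names(config)))
    config[[k]] <- default_config()[[k]]
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(config$out_dir, "run.log")
  log_lines <- character()
  t_prev <- Sys.time()
  stage_log <- function(stage, msg) {
    dt <- round(as.numeric(Sys.time() - t_prev, units = "secs"), 1)
    t_prev <<- Sys.time()
    line <- sprintf("[%s] %s", stage, msg)
    message(sprintf("%s (%.1fs)", line, dt))
    # timings go to the console only: the run log must be byte-stable
    # across reruns with one seed
    log_lines <<- c(log_lines, line)
  }

  set.seed(config$seed)
  templates <- default_templates()
  probes <- probe_panel(templates)
  genera <- template_genus(templates)

  # stage 1: simulate
  sim <- simulate_genome(plan, templates,
                         gc = config$background_gc,
                         min_spacing = config$min_spacing,
                         species = config$species_a,
                         rate = config$rate, kappa = config$kappa)
  pp <- pair_plan
  # wider spacing than the structural demo: post-split private insertions
  # need clear stretches and the 30 kb flank windows should stay clean
  anc <- simulate_genome(pp$ancestral, templates, gc = config$background_gc,
                         min_spacing = 5L * config$min_spacing,
                         species = "anc",
                         rate = config$rate, kappa = config$kappa)
  pair <- simulate_species_pair(anc, speciation_myr = config$speciation_myr,
                                private_a = pp$private_a,
                                private_b = pp$private_b,
                                templates = templates,
                                species_a = config$species_a,
                                species_b = config$species_b,
                                rate = config$rate, kappa = config$kappa)
  stage_log("simulate", sprintf(
    "demo genome %d bp with %d elements; species pair with %d shared insertions",
    sum(nchar(sim$genome$contigs)), nrow(sim$truth),
    length(pair$ortholog_groups)))
  write_fasta(sim$genome, file.path(config$out_dir, "genome_demo.fasta"))
  write_tsv(sim$truth, file.path(config$out_dir, "truth_demo.tsv"))
  write_truth_bed(sim$truth, file.path(config$out_dir, "truth_demo.bed"))
  write_fasta(pair$genome_a, file.path(config$out_dir, "genome_pair_a.fasta"))
  write_fasta(pair$genome_b, file.path(config$out_dir, "genome_pair_b.fasta"))
  write_tsv(pair$truth, file.path(config$out_dir, "truth_pair.tsv"))

  # stages 2-7 on the demo genome
  main <- analyze_genome(sim$genome, probes, genera, config, stage_log)
  write_tsv(main$candidates, file.path(config$out_dir, "candidates.tsv"))
  write_gff3(catalog_features(main$catalog),
             file.path(config$out_dir, "catalog.gff3"))
  hits <- attr(main$candidates, "hits")
  if (!is.null(hits)) write_hits_tsv(hits, file.path(config$out_dir, "screen_hits.tsv"))
  if (!is.null(main$copy_tab))
    write_tsv(main$copy_tab, file.path(config$out_dir, "lineage_copies.tsv"))
  write_tsv(main$solos, file.path(config$out_dir, "solo_ltrs.tsv"))
  if (length(main$lineages) > 0) {
    cons <- stats::setNames(
      vapply(main$lineages, function(l) l$consensus, character(1)),
      vapply(main$lineages, function(l) l$name, character(1)))
    write_fasta(cons, file.path(config$out_dir, "lineage_consensus.fasta"))
  }
  motif_tab <- do.call(rbind, lapply(main$motif_rows, function(m) m$motifs))
  if (!is.null(motif_tab))
    write_tsv(motif_tab, file.path(config$out_dir, "motifs.tsv"))
  write_tsv(main$datings, file.path(config$out_dir, "dating.tsv"))

  # stage 8: orthology on the species pair
  pair_a <- analyze_genome(pair$genome_a, probes, genera, config, stage_log)
  spans_a <- do.call(rbind, lapply(pair_a$full, function(p) {
    data.frame(id = p$id, contig = p$contig, start = p$span$start,
               end = p$span$end, strand = p$strand, stringsAsFactors = FALSE)
  }))
  partner_list <- list()
  for (l in pair_a$lineages) {
    rt <- rt_consensus_of(l)
    if (is.null(rt) || nchar(rt) < 200) next
    rtc <- rt_cross_species_search(rt, pair$genome_b, params = screen_cfg(config))
    if (nrow(rtc) > 0) partner_list[[length(partner_list) + 1L]] <- rtc
  }
  partners_raw <- if (length(partner_list)) do.call(rbind, partner_list) else NULL
  orthologs <- NULL
  if (!is.null(partners_raw) && nrow(partners_raw) > 0 && !is.null(spans_a)) {
    partners_raw$id <- sprintf("bcand%03d", seq_len(nrow(partners_raw)))
    cat_b <- annotate_candidates(pair$genome_b, partners_raw,
                                 params = ltr_cfg(config))
    spans_b <- do.call(rbind, lapply(cat_b, function(p) {
      data.frame(contig = p$contig, start = p$span$start, end = p$span$end,
                 strand = p$strand, stringsAsFactors = FALSE)
    }))
    if (!is.null(spans_b) && nrow(spans_b) > 0) {
      orthologs <- survey_orthologs(spans_a, pair$genome_a, pair$genome_b,
                                    spans_b, params = ortho_cfg(config))
      write_tsv(orthologs, file.path(config$out_dir, "orthologs.tsv"))
    }
  }
  n_ortho <- if (is.null(orthologs)) 0L else sum(orthologs$verdict == "ortholog")
  stage_log("orthologs", sprintf("%d orthologous insertion(s)", n_ortho))

  # stage 9: summary
  summary <- report_summary(main, orthologs)
  write_tsv(summary, file.path(config$out_dir, "summary.tsv"))
  echo <- config[order(names(config))]
  writeLines(sprintf("%s=%s", names(echo),
                     vapply(echo, function(v) paste(format(v), collapse = ","),
                            character(1))),
             file.path(config$out_dir, "config_echo.txt"))
  writeLines(log_lines, log_path)

  invisible(list(config = config, sim = sim, pair = pair, main = main,
                 pair_a = pair_a, orthologs = orthologs, summary = summary))
}

#' Per-lineage summary table
#'
#' One row per lineage: copy and solo counts, full-length count, the
#' min-max insertion-age range in Mya (2 decimals; NA when all elements
#' are saturated or undatable), motif presence flags and the envelope
#' type call.
#'
#' @param main Per-genome bundle from the analysis stages.
#' @param orthologs Ortholog call table (or NULL).
#' @return Data frame.
#' @export
report_summary <- function(main, orthologs = NULL) {
  if (is.null(main$lineages) || length(main$lineages) == 0) {
    return(data.frame(lineage = character(), genus = character(),
                      n_copies = integer(), n_solo = integer(),
                      n_full_length = integer(), age_min_mya = numeric(),
                      age_max_mya = numeric(), env_type = character(),
                      n_orthologs = integer(), stringsAsFactors = FALSE))
  }
  motif_ids <- names(motif_patterns())
  rows <- lapply(main$lineages, function(l) {
    dat <- main$datings[main$datings$lineage %in% l$name &
                          main$datings$flag == "ok", , drop = FALSE]
    mt <- NULL
    env_type <- "indeterminate"
    for (m in main$motif_rows) {
      if (identical(m$lineage, l$name)) { mt <- m$motifs; env_type <- m$env_type }
    }
    flags <- stats::setNames(as.list(
      motif_ids %in% (if (is.null(mt)) character() else mt$motif_id)),
      paste0("has_", motif_ids))
    n_solo <- sum(main$solos$is_solo & main$solos$lineage == l$name)
    base <- data.frame(
      lineage = l$name, genus = l$genus,
      n_copies = nrow(l$copies), n_solo = n_solo,
      n_full_length = length(l$members),
      age_min_mya = if (nrow(dat)) round(min(dat$T_mya), 2) else NA_real_,
      age_max_mya = if (nrow(dat)) round(max(dat$T_mya), 2) else NA_real_,
      env_type = env_type, stringsAsFactors = FALSE)
    cbind(base, as.data.frame(flags))
  })
  out <- do.call(rbind, rows)
  out$n_orthologs <- if (is.null(orthologs)) 0L else
    sum(orthologs$verdict == "ortholog")
  out
}
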