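test_that("background generation is reproducible and respects GC content", {
  a <- make_background(10000, gc = 0.5, seed = 7)
  b <- make_background(10000, gc = 0.5, seed = 7)
  expect_identical(a$contigs, b$contigs)

  g <- make_background(100000, gc = 0.5, seed = 8)
  v <- strsplit(g$contigs[[1]], "")[[1]]
  gc_obs <- mean(v %in% c("G", "C"))
  sd3 <- 3 * sqrt(0.25 / 100000)
  expect_lt(abs(gc_obs - 0.5), sd3)

  at <- make_background(1000, gc = 0, seed = 9)
  expect_false(grepl("[GC]", at$contigs[[1]]))
  expect_error(make_background(0), "length > 0")
})

test_that("K2P forward simulation matches its expected divergence", {
  set.seed(30)
  ltr <- random_dna_str(600)
  expect_identical(mutate_k2p(ltr, 0), ltr)

  # 600 bp at R = 2.2e-9/site/yr for 10 Myr: expected mismatch fraction
  # about 1 - exp(-0.022) = 0.02176 per site
  fr <- replicate(600, {
    m <- mutate_k2p(ltr, 10)
    mean(strsplit(m, "")[[1]] != strsplit(ltr, "")[[1]])
  })
  expected <- 1 - exp(-2.2e-9 * 1e7)
  se <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - expected), 3 * se + 2e-4)

  # extreme kappa: every change is a transition
  m <- mutate_k2p(strrep("ACGT", 500), 100, rate = 1e-8, kappa = 1e6)
  a <- strsplit(strrep("ACGT", 500), "")[[1]]
  b <- strsplit(m, "")[[1]]
  ch <- which(a != b)
  expect_gt(length(ch), 0)
  pairs <- paste0(pmin(a[ch], b[ch]), pmax(a[ch], b[ch]))
  expect_true(all(pairs %in% c("AG", "CT")))
})

test_that("observed transition/transversion ratio converges to kappa", {
  set.seed(31)
  s <- random_dna_str(100000)
  m <- mutate_k2p(s, 5, rate = 2e-8, kappa = 2)  # ~10% of sites hit
  a <- strsplit(s, "")[[1]]; b <- strsplit(m, "")[[1]]
  ch <- which(a != b)
  pairs <- paste0(pmin(a[ch], b[ch]), pmax(a[ch], b[ch]))
  ts <- sum(pairs %in% c("AG", "CT")); tv <- length(ch) - ts
  ratio <- ts / tv
  se3 <- 3 * sqrt(1 / ts + 1 / tv) * ratio
  expect_lt(abs(ratio - 2), se3 + 0.15)
})

test_that("planting inserts a TSD-flanked element with age-dependent LTR divergence", {
  set.seed(32)
  tpl <- provirus_template("T1", ltr_len = 600, trna = "Pro")
  g <- make_background(60000)
  res <- plant(g, tpl, "chr1", 30000, age_myr = 0, state = "intact")
  tr <- res$truth
  seq <- res$genome$contigs[[1]]
  ltr5 <- substr(seq, tr$start + 1, tr$start + 600)
  ltr3 <- substr(seq, tr$end - 600 + 1, tr$end)
  expect_identical(ltr5, ltr3)  # age 0: byte-identical LTRs
  left <- substr(seq, tr$start - nchar(tr$tsd) + 1, tr$start)
  right <- substr(seq, tr$end + 1, tr$end + nchar(tr$tsd))
  expect_identical(left, tr$tsd)
  expect_identical(right, tr$tsd)

  # truth loci agree with where sequence was modified
  expect_identical(substr(seq, 1, tr$start - nchar(tr$tsd)),
                   substr(g$contigs[[1]], 1, tr$start - nchar(tr$tsd)))
  expect_identical(substr(seq, tr$end + nchar(tr$tsd) + 1, nchar(seq)),
                   substr(g$contigs[[1]], tr$start + 1, nchar(g$contigs[[1]])))
})

test_that("mean paired-LTR divergence of planted elements matches 2*R*t", {
  set.seed(33)
  tpl <- provirus_template("T1", ltr_len = 600, trna = "Pro")
  ds <- replicate(50, {
    g <- make_background(20000)
    res <- plant(g, tpl, "chr1", 10000, age_myr = 10, state = "intact")
    tr <- res$truth
    seq <- res$genome$contigs[[1]]
    k2p_distance(substr(seq, tr$start + 1, tr$start + 600),
                 substr(seq, tr$end - 600 + 1, tr$end))$D
  })
  se <- sd(ds) / sqrt(length(ds))
  expect_lt(abs(mean(ds) - 0.044), 3 * se + 1e-3)
})

test_that("degraded, solo and nested states have their defining structure", {
  set.seed(34)
  tpl <- provirus_template("T1", ltr_len = 600, trna = "Pro")
  g <- make_background(80000)
  res <- plant(g, tpl, "chr1", 15000, age_myr = 0, state = "degraded")
  tr <- res$truth[1, ]
  elem <- substr(res$genome$contigs[[1]], tr$start + 1, tr$end)
  # every ORF of a degraded element carries a premature stop
  orfs <- find_orfs(elem, min_nt = 900)
  expect_false(any(orfs$aa_len >= 700))  # longest template ORF is broken

  res <- plant(res$genome, tpl, "chr1", 45000, age_myr = 0, state = "solo")
  tr2 <- res$truth[res$truth$state == "solo", ]
  expect_equal(tr2$end - tr2$start, 600L)
  sol <- substr(res$genome$contigs[[1]], tr2$start + 1, tr2$end)
  expect_equal(sol, tpl$ltr)

  res <- plant(res$genome, tpl, "chr1", 65000, age_myr = 0, state = "nested")
  tr3 <- res$truth[res$truth$state == "nested", ]
  # nested cassette lengthens the element beyond the template
  expect_gt(tr3$end - tr3$start, tpl$length + 1500)

  # overlap refusal
  expect_error(plant(res$genome, tpl, "chr1", tr3$start + 100, 0, "intact"),
               "overlap")
})

test_that("species pair simulation shares ancestral insertions and ages them", {
  set.seed(35)
  tpl <- default_templates()
  anc_plan <- data.frame(lineage = c("GammaA", "BetaA"), age_myr = c(1, 2),
                         state = "intact", strand = "+",
                         stringsAsFactors = FALSE)
  anc <- simulate_genome(anc_plan, tpl)
  pr <- simulate_species_pair(anc, speciation_myr = 0)
  expect_identical(pr$genome_a$contigs, pr$genome_b$contigs)

  pr <- simulate_species_pair(anc, speciation_myr = 8,
                              private_a = data.frame(
                                lineage = "GammaA", age_myr = 3,
                                state = "intact", strand = "+",
                                stringsAsFactors = FALSE))
  expect_equal(length(pr$ortholog_groups), 2L)
  ta <- pr$truth[pr$truth$species_tag == "SpA", ]
  expect_equal(nrow(ta), 3L)
  shared <- ta[!is.na(ta$ortholog_group), ]
  expect_equal(sort(shared$true_age_myr), c(9, 10))
  # orthologous coordinates identical in both species absent private inserts in B
  tb <- pr$truth[pr$truth$species_tag == "SpB", ]
  expect_equal(shared$start, tb$start[match(shared$ortholog_group,
                                            tb$ortholog_group)])
})

test_that("truth table BED export is 0-based with one row per element", {
  sm <- small_sim()
  f <- withr::local_tempfile(fileext = ".bed")
  write_truth_bed(sm$sim$truth, f)
  bed <- utils::read.delim(f, header = FALSE)
  expect_equal(nrow(bed), nrow(sm$sim$truth))
  expect_equal(bed$V2, sm$sim$truth$start)
})

test_that("template geometry satisfies the detection window constraints", {
  set.seed(36)
  for (tpl in default_templates()) {
    expect_gte(tpl$ltr_len, 100)
    expect_lte(tpl$ltr_len, 7000)
    off <- tpl$offsets
    d <- off$start[off$feature == "ltr3"] - off$start[off$feature == "ltr5"]
    expect_gte(d, 1000)
    expect_lte(d, 15000)
    expect_lte(tpl$length, 15000 + tpl$ltr_len)
    # PBS is the reverse complement of the labeled tRNA 18-mer
    lib <- trna_library()
    expect_equal(tpl$pbs, revcomp(lib$trna18[lib$label == tpl$trna_label]))
    # PPT is purine
    expect_false(grepl("[CT]", tpl$ppt))
  }
})
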