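test_that("copy retrieval applies the 4 kb / 80% identity gates", {
  sm <- small_sim()
  truth <- sm$sim$truth
  tpl <- sm$templates$GammaA
  copies <- find_copies(tpl$element, sm$sim$genome)
  ga <- truth[truth$lineage_id == "GammaA" & truth$state != "solo", ]
  expect_equal(nrow(copies), nrow(ga))
  for (i in seq_len(nrow(ga))) {
    expect_true(any(copies$start < ga$end[i] & copies$end > ga$start[i]))
  }
  expect_true(all(copies$identity >= 0.80))
  expect_true(all(copies$aln_len > 4000))
  # solo LTR never retrieved (600 bp < 4 kb gate)
  solo <- truth[truth$state == "solo", ]
  for (i in seq_len(nrow(solo))) {
    expect_false(any(copies$start < solo$end[i] & copies$end > solo$start[i]))
  }
  expect_error(find_copies(random_dna_str(3000), sm$sim$genome), "4 kb")
})

test_that("single-linkage clustering chains through intermediate copies", {
  set.seed(60)
  a <- random_dna_str(1500)
  b <- mutate_to_identity(a, 0.93)   # a~b above threshold
  c <- mutate_to_identity(b, 0.93)   # b~c above, a~c below (roughly 0.87)
  cl <- cluster_lineages(c(a, b, c), min_identity = 0.90)
  expect_equal(length(unique(cl)), 1L)
  # two unrelated lineages split
  d <- random_dna_str(1500)
  cl2 <- cluster_lineages(c(a, b, d), min_identity = 0.90)
  expect_equal(cl2, c(1L, 1L, 2L))
  # singleton passes through
  expect_equal(cluster_lineages(a), 1L)
})

test_that("consensus building recovers the ancestral sequence by majority vote", {
  set.seed(61)
  anc <- random_dna_str(3000)
  expect_identical(build_consensus(c(anc, anc, anc)), anc)
  copies <- replicate(10, mutate_to_identity(anc, 0.98))
  cons <- build_consensus(copies)
  idt <- local_align(cons, anc, mode = "nucleotide", type = "global")$identity
  expect_gte(idt, 0.999)
  # explicit majority column: A,A,G -> A
  s <- random_dna_str(400)
  v <- s
  substr(v, 200, 200) <- if (substr(s, 200, 200) == "G") "A" else "G"
  cons2 <- build_consensus(c(s, s, v))
  expect_identical(cons2, s)
})

test_that("consensus identity to every member stays above the lineage threshold", {
  set.seed(62)
  anc <- random_dna_str(2500)
  copies <- replicate(6, mutate_to_identity(anc, 0.96))
  cons <- build_consensus(copies)
  for (cp in copies) {
    idt <- local_align(cons, cp, mode = "nucleotide", type = "global")$identity
    expect_gt(idt, 0.90)
  }
})

test_that("solo LTR classification separates solos, pairs and remnants", {
  sm <- small_sim()
  truth <- sm$sim$truth
  tpl <- sm$templates$BetaA
  remnants <- rbind(
    do.call(rbind, lapply(sm$catalog, function(p) {
      data.frame(contig = p$contig, start = min(p$ltr5$start, p$ltr3$start),
                 end = max(p$ltr5$end, p$ltr3$end), stringsAsFactors = FALSE)
    })),
    sm$cands[, c("contig", "start", "end")])
  queries <- c(BetaA = tpl$ltr, GammaA = sm$templates$GammaA$ltr,
               GammaB = sm$templates$GammaB$ltr)
  solos <- classify_solo_ltrs(queries, sm$sim$genome, remnants)
  truth_solo <- truth[truth$state == "solo", ]
  called <- solos[solos$is_solo, ]
  expect_equal(nrow(called), nrow(truth_solo))
  for (i in seq_len(nrow(truth_solo))) {
    expect_true(any(called$start < truth_solo$end[i] &
                      called$end > truth_solo$start[i]))
  }
  # LTRs of intact proviruses are rejected with a reason
  not_solo <- solos[!solos$is_solo, ]
  expect_true(all(not_solo$reason %in%
                    c("paired_ltr_nearby", "internal_remnant_nearby")))
  intact <- truth[truth$state != "solo", ]
  for (i in seq_len(nrow(not_solo))) {
    expect_true(any(intact$start - 100 < not_solo$end[i] &
                      intact$end + 100 > not_solo$start[i]))
  }
})

test_that("nomenclature assignment orders lineages by size then position", {
  copies <- data.frame(
    cluster = c(rep(1, 7), rep(2, 3)),
    genus = "Gamma",
    contig = "chr1",
    start = c(sort(sample(1e6, 7)), sort(sample(1e6, 3))),
    stringsAsFactors = FALSE)
  named <- assign_names(copies, host = "Msyn")
  big <- named[named$cluster == 1, ]
  expect_equal(unique(big$lineage_name), "ERV-Gamma.a-Msyn")
  expect_equal(big$copy_name[order(big$start)],
               sprintf("ERV-Gamma.a%d-Msyn", 1:7))
  small <- named[named$cluster == 2, ]
  expect_equal(unique(small$lineage_name), "ERV-Gamma.b-Msyn")

  # solo prefix
  solo <- assign_names(copies[8:10, ], host = "Msyn", solo = TRUE)
  expect_equal(solo$copy_name, sprintf("SoloLTR-Gamma.a%d-Msyn", 1:3))

  # equal sizes: letter by leftmost coordinate
  tie <- data.frame(cluster = c(1, 1, 2, 2), genus = "Beta", contig = "chr1",
                    start = c(5000, 9000, 100, 200), stringsAsFactors = FALSE)
  named2 <- assign_names(tie, host = "Msyn")
  expect_equal(named2$lineage_name[named2$cluster == 2][1], "ERV-Beta.a-Msyn")

  # every emitted name parses and is unique
  all_names <- c(named$copy_name, solo$copy_name)
  expect_false(anyDuplicated(all_names) > 0)
  for (nm in all_names) {
    p <- parse_erv_name(nm)
    expect_true(p$genus %in% c("Gamma", "Beta"))
    expect_false(is.na(p$number))
  }
  expect_error(parse_erv_name("not-a-name"), "scheme")
})

test_that("letter sequence extends past 26 lineages", {
  l <- ervatlas:::lineage_letters(30)
  expect_equal(l[1:3], c("a", "b", "c"))
  expect_equal(l[27], "aa")
  expect_equal(anyDuplicated(l), 0L)
})
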