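make_ltr_window <- function(ltr_len = 600, internal_len = 3000, age = 0,
                            flank = 2000, tsd = "GATCA") {
  ltr <- random_dna_str(ltr_len)
  internal <- random_dna_str(internal_len)
  l5 <- mutate_k2p(ltr, age)
  l3 <- mutate_k2p(ltr, age)
  window <- paste0(random_dna_str(flank), tsd, l5, internal, l3, tsd,
                   random_dna_str(flank))
  list(window = window, start = flank + nchar(tsd),
       ltr_len = ltr_len, internal_len = internal_len,
       end = flank + nchar(tsd) + 2 * ltr_len + internal_len)
}

test_that("an identical planted pair is found at exact boundaries", {
  set.seed(40)
  w <- make_ltr_window(age = 0)
  pairs <- find_ltr_pairs(w$window)
  expect_equal(nrow(pairs), 1L)
  expect_equal(pairs$similarity, 1)
  expect_lte(abs(pairs$ltr5_start - w$start), 5)
  expect_lte(abs(pairs$ltr3_end - w$end), 5)
  expect_lte(abs(pairs$ltr5_len - w$ltr_len), 5)
})

test_that("pairs beyond the similarity floor are mostly rejected", {
  set.seed(41)
  # 40 Myr: expected LTR-LTR divergence ~0.176, observed similarity just
  # under the 0.85 floor; 1.5 kb repeats keep the sampling noise small
  found <- sum(replicate(20, nrow(find_ltr_pairs(
    make_ltr_window(age = 40, ltr_len = 1500)$window)) > 0))
  expect_lte(found, 9)
  # and clearly younger pairs are found
  found10 <- sum(replicate(10, nrow(find_ltr_pairs(make_ltr_window(age = 10)$window)) > 0))
  expect_gte(found10, 9)
})

test_that("pure background yields no LTR pairs", {
  set.seed(42)
  empty <- sum(replicate(20, nrow(find_ltr_pairs(random_dna_str(8000))) == 0))
  expect_gte(empty, 19)
  expect_error(find_ltr_pairs(random_dna_str(800)), "1200")
})

test_that("emitted pairs always satisfy the geometry invariants", {
  set.seed(43)
  for (age in c(0, 5, 12)) {
    w <- make_ltr_window(age = age,
                         ltr_len = sample(c(200, 600, 1000), 1),
                         internal_len = sample(c(2000, 5000), 1))
    pairs <- find_ltr_pairs(w$window)
    for (i in seq_len(nrow(pairs))) {
      expect_gte(pairs$ltr5_len[i], 100)
      expect_lte(pairs$ltr5_len[i], 7000)
      d <- pairs$ltr3_start[i] - pairs$ltr5_start[i]
      expect_gte(d, 1000)
      expect_lte(d, 15000)
      expect_gte(pairs$similarity[i], 0.85)
      expect_lte(pairs$ltr5_end[i], pairs$ltr3_start[i])
      # reported similarity equals the global identity of the two repeats
      sim2 <- local_align(
        substr(w$window, pairs$ltr5_start[i] + 1, pairs$ltr5_end[i]),
        substr(w$window, pairs$ltr3_start[i] + 1, pairs$ltr3_end[i]),
        mode = "nucleotide", type = "global")$identity
      expect_equal(pairs$similarity[i], sim2, tolerance = 1e-9)
    }
  }
})

test_that("TSD finding prefers longer duplications and requires exact flanks", {
  # 5-bp duplication flanking [10, 20)
  s <- paste0("AAAGAGCGTC", "ACGTA", "TTTTTGGGGG", "ACGTA", "CCGATGGTAC")
  t <- find_tsd(s, 15, 25)
  expect_equal(t$sequence, "ACGTA")
  expect_equal(t$left, c(10, 15))
  expect_equal(t$right, c(25, 30))
  # no shared flanking 4-mer: nothing reported
  s2 <- paste0("AAAAAAAAAA", "ACGT", "TTTTTGGGGG", "CCGA", "TTTTTTTTTT")
  expect_null(find_tsd(s2, 14, 24))
  # 6-bp beats 4-bp when both flank the same span
  s3 <- paste0("AAAA", "TACGTA", "GGGGGGGGGG", "TACGTA", "CCCC")
  t3 <- find_tsd(s3, 10, 20)
  expect_equal(t3$sequence, "TACGTA")
})

test_that("PBS detection reports the best tRNA with mismatch count", {
  set.seed(44)
  lib <- trna_library()
  pbs <- revcomp(lib$trna18[lib$label == "Lys"])
  elem <- paste0(random_dna_str(300), pbs, random_dna_str(300))
  hit <- find_pbs(elem, 300, lib)
  expect_equal(hit$trna_label, "Lys")
  expect_equal(hit$mismatches, 0L)
  expect_equal(hit$start, 300L)

  # two mutations still detected at the cap
  mut <- pbs
  substr(mut, 3, 3) <- if (substr(mut, 3, 3) == "A") "C" else "A"
  substr(mut, 9, 9) <- if (substr(mut, 9, 9) == "A") "C" else "A"
  elem2 <- paste0(random_dna_str(300), mut, random_dna_str(300))
  hit2 <- find_pbs(elem2, 300, lib, mismatch_max = 2)
  expect_equal(hit2$mismatches, 2L)

  # PBS deleted: nothing within the scan window
  elem3 <- paste0(random_dna_str(300), random_dna_str(300))
  expect_null(find_pbs(elem3, 300, lib))
})

test_that("PPT detection finds the purine tract abutting the 3' LTR", {
  set.seed(45)
  base <- strrep("CT", 200)  # pyrimidine background, no chance tracts
  elem <- paste0(base, "AGGAAGGGGA", "CC")
  hit <- find_ppt(elem, nchar(elem))
  expect_equal(hit$purine_fraction, 1)
  expect_equal(hit$end, nchar(elem) - 2)
  # pyrimidine-rich junction: nothing
  expect_null(find_ppt(strrep("CT", 300), 600))
  # two qualifying tracts: the one closest to the LTR wins
  elem2 <- paste0(strrep("CT", 100), "AGGAAGGGGA", strrep("CT", 4),
                  "GGGAAAGGGA")
  hit2 <- find_ppt(elem2, nchar(elem2))
  expect_equal(hit2$end, nchar(elem2))
})

test_that("provirus assembly gates full-length status on paired LTRs + internal", {
  pair <- data.frame(ltr5_start = 100, ltr5_end = 700, ltr3_start = 4000,
                     ltr3_end = 4600, similarity = 0.97)
  pv <- assemble_provirus("e1", "chr1", "+", pair)
  expect_s3_class(pv, "ProvirusCandidate")
  expect_true(pv$full_length)
  expect_equal(pv$ltr5$start, 100)
  expect_equal(pv$ltr3$end, 4600)

  # minus strand: element-5' repeat is the forward-right one
  pv2 <- assemble_provirus("e2", "chr1", "-", pair)
  expect_equal(pv2$ltr5$start, 4000)
  expect_equal(pv2$ltr5$strand, "-")

  # PBS is optional: absence does not revoke full-length status
  expect_true(assemble_provirus("e3", "chr1", "+", pair, pbs = NULL)$full_length)

  # pair not containing the candidate: rejected
  cand <- locus("chr1", 9000, 9500)
  cand$id <- "c1"
  expect_warning(out <- assemble_provirus("e4", "chr1", "+", pair,
                                          candidate = cand), "rejected")
  expect_null(out)

  # short internal region: annotated but not full length
  pair2 <- data.frame(ltr5_start = 100, ltr5_end = 1300, ltr3_start = 1400,
                      ltr3_end = 2600, similarity = 0.99)
  expect_false(assemble_provirus("e5", "chr1", "+", pair2)$full_length)
})

test_that("annotation recovers planted structure on the small fixture", {
  sm <- small_sim()
  truth <- sm$sim$truth
  nonsolo <- truth[truth$state != "solo", ]
  expect_equal(length(sm$catalog), nrow(nonsolo))
  for (pv in sm$catalog) {
    tr <- truth_row_for(truth, pv)
    expect_false(is.null(tr))
    expect_lte(abs(pv$span$start - tr$start), 5)
    expect_lte(abs(pv$span$end - tr$end), 5)
    expect_equal(pv$strand, tr$strand)
    expect_true(pv$full_length)
    expect_equal(pv$tsd$sequence, tr$tsd)
    expect_false(is.null(pv$ppt))
  }
})
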