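#' Default parameters for paired-LTR detection
#'
#' Geometry mirrors the standard LTR-finding parameter set: LTR length
#' 100..7000 bp, distance between 5' and 3' LTR starts 1000..15000 bp,
#' similarity floor 0.85.
#'
#' @return Named list of tunables.
#' @export
ltr_params <- function() {
  list(min_ltr = 100L, max_ltr = 7000L,
       min_dist = 1000L, max_dist = 15000L,
       min_sim = 0.85,
       word_size = 13L, band_width = 16L, chain_gap = 500L,
       min_seeds = 3L, pad = 60L, group_cap = 60L,
       pbs_offset_max = 20L, pbs_mismatch_max = 2L,
       ppt_offset_max = 20L, ppt_min_len = 10L, ppt_min_purine = 0.9,
       tsd_min = 4L, tsd_max = 6L, min_internal = 500L,
       window_flank = 16000L)
}

#' Find paired LTRs (direct repeats) in a window
#'
#' Self-comparison by exact k-mer seeding restricted to same-strand direct
#' repeats whose offset satisfies the geometry constraints, followed by
#' gapped local alignment of the two repeat copies and exact-match
#' boundary extension.  Overlapping candidate pairs are resolved by
#' (highest similarity, then longest LTR, then leftmost).
#'
#' @param window DNA string (>= 1200 bp).
#' @param params Parameter list from [ltr_params()].
#' @return Data frame with 0-based half-open window coordinates
#'   `ltr5_start`/`ltr5_end`/`ltr3_start`/`ltr3_end`, `similarity`,
#'   `ltr5_len`, `ltr3_len`.
#' @export
find_ltr_pairs <- function(window, params = ltr_params()) {
  if (nchar(window) < 1200) stop("window shorter than 1200 bp")
  k <- params$word_size
  km <- seq_kmers(window, k)
  groups <- split(seq_along(km), km)
  groups <- groups[lengths(groups) >= 2 & lengths(groups) <= params$group_cap]
  if (length(groups) == 0) return(empty_ltr_pairs())
  pr <- lapply(groups, function(p) {
    cmb <- utils::combn(sort(p), 2)
    data.frame(i = cmb[1, ], j = cmb[2, ])
  })
  pr <- do.call(rbind, pr)
  d <- pr$j - pr$i
  keep <- d >= params$min_dist - params$band_width &
    d <= params$max_dist + params$band_width
  pr <- pr[keep, , drop = FALSE]
  if (nrow(pr) == 0) return(empty_ltr_pairs())
  # cluster by offset (diagonal), then by position gaps
  pairs <- data.frame(q = pr$i, s = pr$j)
  chains <- chain_seeds(pairs, params$band_width, params$chain_gap)
  cand <- list()
  n <- nchar(window)
  for (ch in chains) {
    if (nrow(ch) < params$min_seeds) next
    imin <- min(ch$q); imax <- max(ch$q) + k - 1L
    if (imax - imin + 1L > params$max_ltr + 200L) next
    a0 <- max(0L, imin - 1L - params$pad)
    a1 <- min(n, imax + params$pad)
    jmin <- min(ch$s); jmax <- max(ch$s) + k - 1L
    b0 <- max(0L, jmin - 1L - params$pad)
    b1 <- min(n, jmax + params$pad)
    if (b0 < a1) { b0 <- a1 }  # repeat copies must not overlap
    if (b1 - b0 < params$min_ltr %/% 2) next
    al <- local_align(substr(window, a0 + 1L, a1),
                      substr(window, b0 + 1L, b1), mode = "nucleotide",
                      keep_aln = TRUE)
    if (al$score <= 0) next
    tr <- trim_noisy_ends(al$a_aln, al$b_aln)
    if (is.null(tr)) next
    l5s <- a0 + al$a_start + tr$a_left; l5e <- a0 + al$a_end - tr$a_right
    l3s <- b0 + al$b_start + tr$b_left; l3e <- b0 + al$b_end - tr$b_right
    if (l5e <= l5s || l3e <= l3s) next
    # joint boundary extension: continue through matches, and jump an
    # isolated mismatch when the next `look` columns outward still match
    # at >= `need` positions (repeat copies diverge point-wise, flanks
    # are unrelated, so the lookahead separates the two cleanly)
    ext <- extend_pair_ends(window, l5s, l5e, l3s, l3e)
    l5s <- ext$l5s; l5e <- ext$l5e; l3s <- ext$l3s; l3e <- ext$l3e
    len5 <- l5e - l5s; len3 <- l3e - l3s
    dist <- l3s - l5s
    if (len5 < params$min_ltr || len5 > params$max_ltr) next
    if (len3 < params$min_ltr || len3 > params$max_ltr) next
    if (dist < params$min_dist || dist > params$max_dist) next
    if (l5e > l3s) next
    sim <- local_align(substr(window, l5s + 1L, l5e),
                       substr(window, l3s + 1L, l3e),
                       mode = "nucleotide", type = "global")$identity
    if (is.na(sim) || sim < params$min_sim) next
    cand[[length(cand) + 1L]] <- data.frame(
      ltr5_start = l5s, ltr5_end = l5e, ltr3_start = l3s, ltr3_end = l3e,
      similarity = sim, ltr5_len = len5, ltr3_len = len3,
      stringsAsFactors = FALSE)
  }
  if (length(cand) == 0) return(empty_ltr_pairs())
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$similarity, -cand$ltr5_len, cand$ltr5_start), ,
               drop = FALSE]
  keep <- rep(TRUE, nrow(cand))
  for (i in seq_len(nrow(cand))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (cand$ltr3_end[i] > cand$ltr5_start[j] &&
          cand$ltr3_end[j] > cand$ltr5_start[i]) { keep[i] <- FALSE; break }
    }
  }
  out <- cand[keep, , drop = FALSE]
  out <- out[order(out$ltr5_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Mismatch-tolerant joint extension of a direct-repeat pair.  Coordinates
# are 0-based repeat boundaries within `window`.
extend_pair_ends <- function(window, l5s, l5e, l3s, l3e,
                             look = 6L, need = 4L) {
  n <- nchar(window)
  cmp_run <- function(a0, b0, len, dir) {
    # matches among `len` columns starting just outside (a0,b0), walking
    # outward in direction dir (-1 left, +1 right); a0/b0 are 1-based
    # positions of the first column to compare
    ia <- a0 + dir * (0:(len - 1L))
    ib <- b0 + dir * (0:(len - 1L))
    if (any(ia < 1L) || any(ib < 1L) || any(ia > n) || any(ib > n)) return(-1L)
    av <- strsplit(substr(window, min(ia), max(ia)), "", fixed = TRUE)[[1]]
    bv <- strsplit(substr(window, min(ib), max(ib)), "", fixed = TRUE)[[1]]
    sum(av == bv & av != "N")
  }
  repeat {
    if (l5s <= 0 || l3s <= l5e) break
    ca <- substr(window, l5s, l5s); cb <- substr(window, l3s, l3s)
    if (ca == cb && ca != "N") { l5s <- l5s - 1L; l3s <- l3s - 1L; next }
    m <- cmp_run(l5s - 1L, l3s - 1L, look, -1L)
    if (m >= need) { l5s <- l5s - 1L; l3s <- l3s - 1L; next }
    break
  }
  repeat {
    if (l3e >= n || l5e >= l3s) break
    ca <- substr(window, l5e + 1L, l5e + 1L); cb <- substr(window, l3e + 1L, l3e + 1L)
    if (ca == cb && ca != "N") { l5e <- l5e + 1L; l3e <- l3e + 1L; next }
    m <- cmp_run(l5e + 2L, l3e + 2L, look, 1L)
    if (m >= need) { l5e <- l5e + 1L; l3e <- l3e + 1L; next }
    break
  }
  list(l5s = l5s, l5e = l5e, l3s = l3s, l3e = l3e)
}

# Trim noisy alignment ends.  A true LTR-LTR alignment is (near) gap-free
# close to its boundaries; spurious extension of the local alignment into
# the flanks tends to use gaps to stitch chance matches.  From each end,
# columns are dropped until no gap column remains within `lookahead`
# columns of the boundary, then leading/trailing mismatch columns are
# dropped so the boundary sits on an exact match.  Returns the number of
# non-gap bases trimmed from each sequence at each end (NULL when nothing
# is left).
trim_noisy_ends <- function(a_aln, b_aln, lookahead = 15L) {
  av <- strsplit(a_aln, "", fixed = TRUE)[[1]]
  bv <- strsplit(b_aln, "", fixed = TRUE)[[1]]
  nc <- length(av)
  gapcol <- av == "-" | bv == "-"
  matchcol <- !gapcol & av == bv & av != "N"
  run <- 5L  # boundary must sit on a clean run of exact matches
  ks <- 1L
  repeat {
    w <- which(gapcol[ks:min(nc, ks + lookahead - 1L)])
    if (length(w) == 0) break
    ks <- ks + max(w)
    if (ks > nc) return(NULL)
  }
  repeat {
    if (ks + run - 1L > nc) return(NULL)
    w <- which(!matchcol[ks:(ks + run - 1L)])
    if (length(w) == 0) break
    ks <- ks + max(w)
  }
  ke <- nc
  repeat {
    w <- which(gapcol[max(1L, ke - lookahead + 1L):ke])
    if (length(w) == 0) break
    ke <- max(1L, ke - lookahead + 1L) + min(w) - 2L
    if (ke < ks) return(NULL)
  }
  repeat {
    if (ke - run + 1L < ks) return(NULL)
    w <- which(!matchcol[(ke - run + 1L):ke])
    if (length(w) == 0) break
    ke <- ke - run + min(w) - 1L
  }
  if (ke < ks) return(NULL)
  list(a_left = sum(av[seq_len(ks - 1L)] != "-"),
       b_left = sum(bv[seq_len(ks - 1L)] != "-"),
       a_right = sum(av[seq(ke + 1L, length.out = nc - ke)] != "-"),
       b_right = sum(bv[seq(ke + 1L, length.out = nc - ke)] != "-"))
}

empty_ltr_pairs <- function() {
  data.frame(ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             similarity = numeric(), ltr5_len = integer(),
             ltr3_len = integer(), stringsAsFactors = FALSE)
}

# TSD-aware boundary refinement.  Chance matches between the bases that
# precede (or follow) the two repeat copies can shift both boundaries of
# the alignment in lockstep by a few bases; integration leaves an exact
# 4-6 bp duplication abutting the true element ends, so among small joint
# shifts we take the one that exposes
# the longest flanking duplication (ties: smallest shift).
refine_pair_by_tsd <- function(wseq, pair, params, max_shift = 6L) {
  best <- NULL
  for (ds in -max_shift:max_shift) {
    for (de in -max_shift:max_shift) {
      span_s <- pair$ltr5_start + ds
      span_e <- pair$ltr3_end - de
      if (span_e <= span_s) next
      tsd <- find_tsd(wseq, span_s, span_e, params$tsd_min, params$tsd_max)
      if (is.null(tsd)) next
      len <- nchar(tsd$sequence)
      shift <- abs(ds) + abs(de)
      if (is.null(best) || len > best$len ||
          (len == best$len && shift < best$shift)) {
        best <- list(ds = ds, de = de, len = len, shift = shift)
      }
    }
  }
  if (is.null(best) || (best$ds == 0 && best$de == 0)) return(pair)
  pair$ltr5_start <- pair$ltr5_start + best$ds
  pair$ltr3_start <- pair$ltr3_start + best$ds
  pair$ltr5_end <- pair$ltr5_end - best$de
  pair$ltr3_end <- pair$ltr3_end - best$de
  pair$ltr5_len <- pair$ltr5_end - pair$ltr5_start
  pair$ltr3_len <- pair$ltr3_end - pair$ltr3_start
  pair
}

#' Find the target-site duplication flanking an element span
#'
#' Looks for the longest exact duplication of length `tsd_max` down to
#' `tsd_min` immediately flanking the span (longer wins; both copies must
#' abut the element).
#'
#' @param seq Sequence containing the element (window or contig).
#' @param start,end 0-based half-open element span within `seq`.
#' @param tsd_min,tsd_max Length bounds (default 4..6).
#' @return List with `sequence`, `left` / `right` 0-based ranges, or NULL.
#' @export
find_tsd <- function(seq, start, end, tsd_min = 4L, tsd_max = 6L) {
  for (len in seq(tsd_max, tsd_min)) {
    if (start - len < 0 || end + len > nchar(seq)) next
    left <- substr(seq, start - len + 1L, start)
    right <- substr(seq, end + 1L, end + len)
    if (left == right && !grepl("N", left, fixed = TRUE)) {
      return(list(sequence = left,
                  left = c(start - len, start), right = c(end, end + len)))
    }
  }
  NULL
}

#' Find the primer binding site downstream of the 5' LTR
#'
#' Scans the region just inside the 5' LTR end for the reverse complement
#' of each tRNA 3' 18-mer, allowing up to `mismatch_max` mismatches; the
#' best hit (fewest mismatches, then closest to the LTR) is reported with
#' its tRNA label.
#'
#' @param element Element sequence (element orientation).
#' @param ltr5_end 0-based position where the 5' LTR ends.
#' @param trna_lib Data frame like [trna_library()].
#' @param offset_max Scan width beyond the LTR end (bp).
#' @param mismatch_max Maximum mismatches.
#' @return List with `start`, `end` (element-relative), `trna_label`,
#'   `mismatches`, or NULL.
#' @export
find_pbs <- function(element, ltr5_end, trna_lib = trna_library(),
                     offset_max = 20L, mismatch_max = 2L, backoff = 6L) {
  if (nrow(trna_lib) == 0) stop("empty tRNA library")
  targets <- revcomp(trna_lib$trna18)
  best <- NULL
  # scan starts a few bases inside the called LTR end: the internal
  # 5'-LTR boundary can sit a base or two past the true repeat end
  for (s in max(0L, ltr5_end - backoff) + 0:(offset_max + backoff - 1L)) {
    if (s + 18L > nchar(element)) break
    cand <- substr(element, s + 1L, s + 18L)
    cv <- strsplit(cand, "", fixed = TRUE)[[1]]
    for (t in seq_along(targets)) {
      tv <- strsplit(targets[t], "", fixed = TRUE)[[1]]
      mm <- sum(cv != tv | cv == "N")
      if (mm <= mismatch_max &&
          (is.null(best) || mm < best$mismatches)) {
        best <- list(start = s, end = s + 18L,
                     trna_label = trna_lib$label[t], mismatches = mm)
      }
    }
  }
  best
}

#' Find the polypurine tract upstream of the 3' LTR
#'
#' Reports the longest window of purine fraction >= `min_purine` and
#' length >= `min_len` ending within `offset_max` of the 3' LTR start;
#' ties go to the window closest to the LTR.
#'
#' @param element Element sequence (element orientation).
#' @param ltr3_start 0-based position where the 3' LTR starts.
#' @param offset_max Maximum distance of the tract end from the LTR start.
#' @param min_len Minimum tract length.
#' @param min_purine Minimum A+G fraction.
#' @param scan_len How far upstream to consider (bp).
#' @return List with `start`, `end`, `purine_fraction`, or NULL.
#' @export
find_ppt <- function(element, ltr3_start, offset_max = 20L, min_len = 10L,
                     min_purine = 0.9, scan_len = 60L) {
  if (ltr3_start <= min_len) stop("3' LTR start too close to element start")
  region_start <- max(0L, ltr3_start - offset_max - scan_len)
  v <- strsplit(substr(element, region_start + 1L, ltr3_start), "",
                fixed = TRUE)[[1]]
  is_pur <- v %in% c("A", "G")
  pur <- cumsum(is_pur)
  nreg <- length(v)
  best <- NULL
  for (e in seq(nreg, max(min_len, nreg - offset_max + 1L))) {
    if (!is_pur[e]) next   # a tract cannot end on a pyrimidine
    for (s in seq(1L, e - min_len + 1L)) {
      if (!is_pur[s]) next
      len <- e - s + 1L
      frac <- (pur[e] - if (s > 1) pur[s - 1L] else 0L) / len
      if (frac >= min_purine) {
        if (is.null(best) || len > best$len ||
            (len == best$len && e > best$e)) {
          best <- list(s = s, e = e, len = len, frac = frac)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  list(start = region_start + best$s - 1L, end = region_start + best$e,
       purine_fraction = best$frac)
}

#' Assemble a provirus candidate record
#'
#' Combines an LTR pair with its PBS/PPT/TSD annotations into the
#' pipeline's central record.  An element is `full_length` iff it has
#' paired LTRs and an internal region of at least `min_internal` bp;
#' PBS, PPT and TSD are annotations, not gating requirements.
#'
#' @param id Element identifier.
#' @param contig Contig id.
#' @param strand Element strand.
#' @param pair One row of the [find_ltr_pairs()] table, in absolute
#'   forward-strand contig coordinates.
#' @param pbs,ppt,tsd Annotation records (or NULL), as returned by the
#'   respective finders, in absolute coordinates.
#' @param candidate Optional `CandidateLocus`-style locus the pair must
#'   contain (assembly is rejected otherwise).
#' @param min_internal Minimum internal-region length for full-length
#'   status.
#' @return A `ProvirusCandidate` (list), or NULL with a warning when the
#'   pair does not contain the candidate hit.
#' @export
assemble_provirus <- function(id, contig, strand, pair, pbs = NULL,
                              ppt = NULL, tsd = NULL, candidate = NULL,
                              min_internal = 500L) {
  span <- locus(contig, pair$ltr5_start, pair$ltr3_end, strand)
  if (!is.null(candidate)) {
    if (candidate$contig != contig ||
        candidate$end <= span$start || candidate$start >= span$end) {
      warning("LTR pair does not contain the candidate hit; assembly rejected")
      return(NULL)
    }
  }
  internal_len <- pair$ltr3_start - pair$ltr5_end
  # label the element-5' repeat as ltr5: on "-" elements that is the
  # rightmost repeat in forward coordinates
  if (strand == "+") {
    l5 <- locus(contig, pair$ltr5_start, pair$ltr5_end, "+")
    l3 <- locus(contig, pair$ltr3_start, pair$ltr3_end, "+")
  } else {
    l5 <- locus(contig, pair$ltr3_start, pair$ltr3_end, "-")
    l3 <- locus(contig, pair$ltr5_start, pair$ltr5_end, "-")
  }
  structure(list(
    id = id, contig = contig, strand = strand, span = span,
    ltr5 = l5, ltr3 = l3, similarity = pair$similarity,
    pbs = pbs, ppt = ppt, tsd = tsd,
    internal_len = internal_len,
    full_length = internal_len >= min_internal,
    lineage = NULL), class = "ProvirusCandidate")
}

#' Annotate candidate loci with paired-LTR structure
#'
#' For each candidate ERV locus, extracts a window around the hit, runs
#' [find_ltr_pairs()], keeps the pair overlapping the candidate, and
#' annotates TSD, PBS and PPT.  Minus-strand candidates are analyzed on
#' the reverse complement of the window and coordinates are mapped back.
#'
#' @param genome A `ContigSet`.
#' @param candidates Data frame of candidate loci (columns contig, start,
#'   end, strand, id) from the discovery stage.
#' @param params Parameter list from [ltr_params()].
#' @param trna_lib tRNA library for PBS annotation.
#' @return List of `ProvirusCandidate` records (NULL entries dropped);
#'   candidates without a qualifying pair are returned with
#'   `full_length = FALSE` and no LTR coordinates in the `unpaired`
#'   attribute.
#' @export
annotate_candidates <- function(genome, candidates, params = ltr_params(),
                                trna_lib = trna_library()) {
  out <- list()
  unpaired <- character()
  for (i in seq_len(nrow(candidates))) {
    cd <- candidates[i, ]
    clen <- nchar(genome$contigs[[cd$contig]])
    w0 <- max(0L, cd$start - params$window_flank)
    w1 <- min(clen, cd$end + params$window_flank)
    window <- substr(genome$contigs[[cd$contig]], w0 + 1L, w1)
    strand <- if (!is.null(cd$strand)) cd$strand else "+"
    wseq <- if (strand == "-") revcomp(window) else window
    wlen <- nchar(wseq)
    pairs <- find_ltr_pairs(wseq, params)
    if (nrow(pairs) == 0) { unpaired <- c(unpaired, cd$id); next }
    # candidate hit range in analysis-window coordinates
    if (strand == "-") {
      c0 <- wlen - (cd$end - w0); c1 <- wlen - (cd$start - w0)
    } else {
      c0 <- cd$start - w0; c1 <- cd$end - w0
    }
    ov <- pmin(pairs$ltr3_end, c1) - pmax(pairs$ltr5_start, c0)
    if (max(ov) <= 0) { unpaired <- c(unpaired, cd$id); next }
    pair <- pairs[which.max(ov), ]
    pair <- refine_pair_by_tsd(wseq, pair, params)
    elem <- substr(wseq, pair$ltr5_start + 1L, pair$ltr3_end)
    rel <- pair
    rel$ltr5_end <- pair$ltr5_end - pair$ltr5_start
    rel$ltr3_start <- pair$ltr3_start - pair$ltr5_start
    rel$ltr3_end <- pair$ltr3_end - pair$ltr5_start
    rel$ltr5_start <- 0L
    tsd <- find_tsd(wseq, pair$ltr5_start, pair$ltr3_end,
                    params$tsd_min, params$tsd_max)
    pbs <- find_pbs(elem, rel$ltr5_end, trna_lib,
                    params$pbs_offset_max, params$pbs_mismatch_max)
    ppt <- find_ppt(elem, rel$ltr3_start, params$ppt_offset_max,
                    params$ppt_min_len, params$ppt_min_purine)
    # map analysis-window coords back to absolute forward coords; abs_pair
    # uses forward-sorted naming (ltr5_* = leftmost repeat on the forward
    # strand); assemble_provirus relabels by element orientation
    to_abs <- function(p0, p1) {
      if (strand == "-") c(w0 + wlen - p1, w0 + wlen - p0) else c(w0 + p0, w0 + p1)
    }
    f5 <- if (strand == "+") to_abs(pair$ltr5_start, pair$ltr5_end) else
      to_abs(pair$ltr3_start, pair$ltr3_end)
    f3 <- if (strand == "+") to_abs(pair$ltr3_start, pair$ltr3_end) else
      to_abs(pair$ltr5_start, pair$ltr5_end)
    abs_pair <- data.frame(
      ltr5_start = f5[1], ltr5_end = f5[2],
      ltr3_start = f3[1], ltr3_end = f3[2],
      similarity = pair$similarity, stringsAsFactors = FALSE)
    abs_ann <- function(x) {
      if (is.null(x)) return(NULL)
      r <- to_abs(pair$ltr5_start + x$start, pair$ltr5_start + x$end)
      x$start <- r[1]; x$end <- r[2]
      x
    }
    if (!is.null(tsd)) {
      lr <- to_abs(tsd$left[1], tsd$left[2])
      rr <- to_abs(tsd$right[1], tsd$right[2])
      if (strand == "-") {
        tmp <- lr; lr <- rr; rr <- tmp
        tsd$sequence <- revcomp(tsd$sequence)  # report forward-strand site
      }
      tsd$left <- lr; tsd$right <- rr
    }
    pv <- assemble_provirus(cd$id, cd$contig, strand, abs_pair,
                            pbs = abs_ann(pbs), ppt = abs_ann(ppt), tsd = tsd,
                            candidate = cd, min_internal = params$min_internal)
    if (!is.null(pv)) out[[length(out) + 1L]] <- pv
  }
  attr(out, "unpaired") <- unpaired
  out
}

#' Provirus catalog as a feature table
#' @param catalog List of `ProvirusCandidate`s.
#' @return Data frame suitable for [write_gff3()] (SO feature types).
#' @export
catalog_features <- function(catalog) {
  rows <- list()
  for (pv in catalog) {
    rows[[length(rows) + 1L]] <- data.frame(
      contig = pv$contig, start = pv$span$start, end = pv$span$end,
      strand = pv$strand, type = "LTR_retrotransposon", ID = pv$id,
      similarity = round(pv$similarity, 4), stringsAsFactors = FALSE)
    for (lt in list(pv$ltr5, pv$ltr3)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = pv$contig, start = lt$start, end = lt$end,
        strand = pv$strand, type = "long_terminal_repeat",
        ID = NA_character_, similarity = NA_real_, stringsAsFactors = FALSE)
    }
    if (!is.null(pv$pbs)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = pv$contig, start = pv$pbs$start, end = pv$pbs$end,
        strand = pv$strand, type = "primer_binding_site",
        ID = NA_character_, similarity = NA_real_, stringsAsFactors = FALSE)
    }
    if (!is.null(pv$ppt)) {
      rows[[length(rows) + 1L]] <- data.frame(
        contig = pv$contig, start = pv$ppt$start, end = pv$ppt$end,
        strand = pv$strand, type = "RR_tract",
        ID = NA_character_, similarity = NA_real_, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      type = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}
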