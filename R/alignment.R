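#' Six-frame translation with coordinate bookkeeping
#'
#' Translates a nucleotide sequence in all six reading frames under the
#' standard genetic code.  Stop codons are rendered as `*`; codons
#' containing N become `X`.  Frame +1..+3 read the forward strand starting
#' at offsets 0..2; frames -1..-3 read the reverse complement likewise.
#'
#' @param nt DNA string (length >= 3).
#' @return Data frame with columns `frame` (1,2,3,-1,-2,-3), `offset`
#'   (0-based offset on the read strand) and `protein`.
#' @export
translate_six_frames <- function(nt) {
  if (nchar(nt) < 3) stop("sequence shorter than one codon")
  strands <- list(fwd = nt, rev = revcomp(nt))
  out <- lapply(1:3, function(f) {
    lapply(c(1, -1), function(sgn) {
      s <- if (sgn > 0) strands$fwd else strands$rev
      off <- f - 1L
      usable <- nchar(s) - off
      usable <- usable - usable %% 3L
      if (usable < 3) return(NULL)
      sub <- substr(s, off + 1L, off + usable)
      p <- as.character(Biostrings::translate(Biostrings::DNAString(sub),
                                              if.fuzzy.codon = "X"))
      data.frame(frame = sgn * f, offset = off, protein = p,
                 stringsAsFactors = FALSE)
    })
  })
  do.call(rbind, unlist(out, recursive = FALSE))
}

# Map a 1-based aa range [aa_start, aa_end] in a given frame/offset back to
# 0-based half-open nucleotide coordinates on the forward strand of the
# original sequence of length L.
aa_to_nt_range <- function(frame, offset, aa_start, aa_end, L) {
  p0 <- offset + 3L * (aa_start - 1L)          # 0-based start on read strand
  p1 <- offset + 3L * aa_end                   # 0-based exclusive end
  if (frame > 0) {
    c(start = p0, end = p1, strand = "+")
  } else {
    c(start = L - p1, end = L - p0, strand = "-")
  }
}

# Scoring schemes.  The nucleotide scheme mirrors blastn defaults
# (+2/-3, gap 5+2L); N scores as a mismatch against everything including N.
nuc_matrix <- function(match = 2, mismatch = -3) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- match
  m["N", "N"] <- mismatch
  m
}

scoring_scheme <- function(mode = c("nucleotide", "protein")) {
  mode <- match.arg(mode)
  if (mode == "nucleotide") {
    list(matrix = nuc_matrix(), gap_open = 5, gap_ext = 2,
         lambda = 0.625, K = 0.41)
  } else {
    # BLOSUM62 with gap 11+1L; Karlin-Altschul parameters are the published
    # gapped approximations for that scheme.
    b62 <- get_blosum62()
    list(matrix = b62, gap_open = 11, gap_ext = 1,
         lambda = 0.267, K = 0.041)
  }
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

aln_identity <- function(a_aln, b_aln, mode = "nucleotide") {
  av <- strsplit(a_aln, "", fixed = TRUE)[[1]]
  bv <- strsplit(b_aln, "", fixed = TRUE)[[1]]
  nongap <- av != "-" & bv != "-"
  n <- sum(nongap)
  if (n == 0) return(list(matches = 0L, cols = 0L, identity = NA_real_))
  # wildcards never count as matches: assembly N for DNA, X for protein
  # (N is asparagine there)
  wild <- if (mode == "nucleotide") "N" else c("X", "*")
  m <- sum(av[nongap] == bv[nongap] & !av[nongap] %in% wild)
  list(matches = m, cols = n, identity = m / n)
}

#' Optimal local alignment (Smith-Waterman, affine gaps)
#'
#' Wraps the dynamic-programming aligner with the package's two scoring
#' schemes.  The score of the empty alignment is 0, so sequences with no
#' positively scoring local match return score 0 and no coordinates.
#'
#' @param a,b Sequences (DNA or protein depending on `mode`).
#' @param mode `"nucleotide"` (+2/-3, gap 5+2L) or `"protein"` (BLOSUM62,
#'   gap 11+1L).
#' @param type Alignment type passed through (`"local"` default; `"global"`
#'   and `"overlap"` are used internally for consensus building and dating).
#' @param keep_aln Return the aligned strings (`a_aln`/`b_aln`); skipping
#'   them (the default for local alignments on clean sequences) avoids a
#'   costly extraction when only scores and ranges are needed.
#' @return List with `score`, `identity` (matching fraction of aligned
#'   non-gap columns; N/X never match), `matches`, `aln_cols`, 0-based
#'   half-open ranges `a_start`/`a_end`/`b_start`/`b_end`, and the aligned
#'   strings `a_aln`, `b_aln`.
#' @export
local_align <- function(a, b, mode = c("nucleotide", "protein"),
                        type = "local", keep_aln = (type != "local")) {
  mode <- match.arg(mode)
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  sc <- scoring_scheme(mode)
  pa <- Biostrings::pairwiseAlignment(a, b, type = type,
                                      substitutionMatrix = sc$matrix,
                                      gapOpening = sc$gap_open,
                                      gapExtension = sc$gap_ext)
  s <- Biostrings::score(pa)
  if (type == "local" && s <= 0) {
    return(list(score = 0, identity = NA_real_, matches = 0L, aln_cols = 0L,
                a_start = NA_integer_, a_end = NA_integer_,
                b_start = NA_integer_, b_end = NA_integer_,
                a_aln = "", b_aln = ""))
  }
  wild <- if (mode == "nucleotide") "N" else c("X", "*")
  has_wild <- any(vapply(wild, function(w)
    grepl(w, a, fixed = TRUE) || grepl(w, b, fixed = TRUE), logical(1)))
  if (!keep_aln && !has_wild) {
    # match counts straight from the alignment object; the aligned-string
    # extraction is only needed when a caller consumes the strings or a
    # wildcard-aware identity is required
    matches <- Biostrings::nmatch(pa)
    cols <- matches + Biostrings::nmismatch(pa)
    return(list(score = s, identity = matches / cols, matches = matches,
                aln_cols = cols,
                a_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
                a_end = Biostrings::end(Biostrings::pattern(pa)),
                b_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
                b_end = Biostrings::end(Biostrings::subject(pa)),
                a_aln = NULL, b_aln = NULL))
  }
  a_aln <- as.character(Biostrings::alignedPattern(pa))
  b_aln <- as.character(Biostrings::alignedSubject(pa))
  idt <- aln_identity(a_aln, b_aln, mode)
  list(score = s, identity = idt$identity, matches = idt$matches,
       aln_cols = idt$cols,
       a_start = Biostrings::start(Biostrings::pattern(pa)) - 1L,
       a_end = Biostrings::end(Biostrings::pattern(pa)),
       b_start = Biostrings::start(Biostrings::subject(pa)) - 1L,
       b_end = Biostrings::end(Biostrings::subject(pa)),
       a_aln = a_aln, b_aln = b_aln)
}

#' Estimate an E-value from a raw alignment score
#'
#' Karlin-Altschul form `E = K * m * n * exp(-lambda * score)` with (K,
#' lambda) fixed per scoring scheme.  These are approximations to the
#' external-search statistics the filter thresholds were written against;
#' the thresholds, not raw E-value agreement, are the contract.
#'
#' @param score Raw alignment score (>= 0).
#' @param m Query length.
#' @param n Search-space (subject/database) length.
#' @param mode Scoring scheme name, or supply `lambda` and `K` directly.
#' @param lambda,K Optional explicit Karlin-Altschul parameters.
#' @return E-value (numeric).
#' @export
estimate_evalue <- function(score, m, n, mode = c("nucleotide", "protein"),
                            lambda = NULL, K = NULL) {
  if (any(score < 0)) stop("score must be >= 0")
  if (is.null(lambda) || is.null(K)) {
    sc <- scoring_scheme(match.arg(mode))
    lambda <- sc$lambda
    K <- sc$K
  }
  K * m * n * exp(-lambda * score)
}

#' Default parameters for [seeded_search()]
#' @param mode Search mode.
#' @return Named list of tunables.
#' @export
seeded_search_params <- function(mode = c("nucleotide", "protein-vs-translated",
                                          "discontiguous-nucleotide")) {
  mode <- match.arg(mode)
  p <- list(
    word_size = if (mode == "protein-vs-translated") 5L else 11L,
    band_width = 16L,      # diagonal tolerance when clustering seeds
    chain_gap = 400L,      # max subject gap between seeds of one chain
    min_seeds = 2L,        # two-hit requirement per chain
    pad = 60L,             # window padding around seed span before extension
    evalue_max = 10,
    dedupe_overlap = 0.5,  # subject-overlap fraction that triggers dedupe
    kmer_cap = 5000L,      # cap on seed pairs per k-mer (low-complexity guard)
    both_strands = TRUE
  )
  p$mode <- mode
  p
}

# spaced seed for the discontiguous dialect: 28 columns, 21 care positions
# (every third of the first 21 is a wildcard; a coding-style template).
dc_care_positions <- function() {
  setdiff(1:28, c(3L, 6L, 9L, 12L, 15L, 18L, 21L))
}

#' Precompute a reusable search index for a genome
#'
#' Builds the per-contig k-mer table (nucleotide modes) or the six-frame
#' translations plus their k-mer tables (protein mode) once, so repeated
#' [seeded_search()] calls against the same genome skip the indexing cost.
#'
#' @param genome A `ContigSet`.
#' @param mode Search mode the index is for.
#' @param word_size Seed word size (must match the search params).
#' @return An opaque index list accepted by [seeded_search()].
#' @export
genome_index <- function(genome, mode = c("nucleotide",
                                          "protein-vs-translated",
                                          "discontiguous-nucleotide"),
                         word_size = NULL) {
  mode <- match.arg(mode)
  if (is.null(word_size)) word_size <- seeded_search_params(mode)$word_size
  if (mode == "protein-vs-translated") {
    frames <- lapply(genome$contigs, translate_six_frames)
    kmers <- lapply(frames, function(fr)
      lapply(fr$protein, seq_kmers, k = word_size))
    total_aa <- sum(vapply(frames, function(fr) sum(nchar(fr$protein)), numeric(1)))
    list(mode = mode, word_size = word_size, frames = frames,
         kmers = kmers, total_aa = total_aa)
  } else if (mode == "discontiguous-nucleotide") {
    list(mode = mode, word_size = word_size,
         kmers = lapply(genome$contigs, spaced_kmers))
  } else {
    list(mode = mode, word_size = word_size,
         kmers = lapply(genome$contigs, seq_kmers, k = word_size))
  }
}

# All k-mers of s as a character vector (positions 1..n-k+1); k-mers
# containing N are set NA so they never seed.
seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  km <- substring(s, 1:(n - k + 1L), k:n)
  km[grepl("N", km, fixed = TRUE) | grepl("X", km, fixed = TRUE)] <- NA_character_
  km
}

# Spaced k-mers under the dc template.
spaced_kmers <- function(s, care = dc_care_positions()) {
  n <- nchar(s)
  span <- max(care)
  if (n < span) return(character(0))
  starts <- 1:(n - span + 1L)
  cols <- lapply(care, function(cp) substring(s, starts + cp - 1L, starts + cp - 1L))
  km <- do.call(paste0, cols)
  km[grepl("N", km, fixed = TRUE)] <- NA_character_
  km
}

# Match query k-mers against subject k-mers; returns data.frame(q, s) of
# 1-based positions of seed matches.
seed_pairs <- function(qk, sk, cap = 5000L) {
  qs <- split(seq_along(qk), qk)          # drops NA automatically
  g <- match(sk, names(qs))
  hit <- which(!is.na(g))
  if (length(hit) == 0) return(data.frame(q = integer(), s = integer()))
  counts <- lengths(qs)[g[hit]]
  spos <- rep(hit, counts)
  qpos <- unlist(qs[g[hit]], use.names = FALSE)
  if (length(spos) > 0) {
    # guard against low-complexity blowups: cap pairs per k-mer string
    key <- sk[spos]
    keep <- stats::ave(seq_along(key), key, FUN = seq_along) <= cap
    spos <- spos[keep]; qpos <- qpos[keep]
  }
  data.frame(q = qpos, s = spos)
}

# Cluster seed pairs into chains: group by diagonal (within band_width),
# then split chains at subject gaps > chain_gap.  Returns a list of
# data.frames of seed pairs.
chain_seeds <- function(pairs, band_width, chain_gap) {
  if (nrow(pairs) == 0) return(list())
  pairs$diag <- pairs$s - pairs$q
  pairs <- pairs[order(pairs$diag, pairs$s), ]
  dsplit <- cumsum(c(TRUE, diff(pairs$diag) > band_width))
  out <- list()
  for (grp in split(pairs, dsplit)) {
    grp <- grp[order(grp$s), ]
    ssplit <- cumsum(c(TRUE, diff(grp$s) > chain_gap))
    out <- c(out, split(grp, ssplit))
  }
  out
}

# Greedy overlap dedupe: hits sorted by (evalue, score desc); drop a hit if
# its subject range overlaps a kept hit on the same contig/strand by more
# than frac of the shorter range.
dedupe_hits <- function(hits, frac) {
  if (nrow(hits) <= 1) return(hits)
  hits <- hits[order(hits$evalue, -hits$score, hits$contig, hits$s_start), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (hits$contig[i] != hits$contig[j] || hits$strand[i] != hits$strand[j]) next
      ov <- min(hits$s_end[i], hits$s_end[j]) - max(hits$s_start[i], hits$s_start[j])
      if (ov <= 0) next
      shorter <- min(hits$s_end[i] - hits$s_start[i], hits$s_end[j] - hits$s_start[j])
      if (ov / shorter > frac) { keep[i] <- FALSE; break }
    }
  }
  hits[keep, , drop = FALSE]
}

empty_hits <- function() {
  data.frame(query_id = character(), contig = character(),
             s_start = integer(), s_end = integer(), strand = character(),
             frame = integer(), q_start = integer(), q_end = integer(),
             identity = numeric(), coverage = numeric(), matches = integer(),
             aln_cols = integer(), score = numeric(), evalue = numeric(),
             stringsAsFactors = FALSE)
}

#' Seeded local similarity search (BLAST-like)
#'
#' K-mer (protein / nucleotide) or spaced-seed (discontiguous nucleotide)
#' seeding, diagonal chaining with a two-hit requirement, then gapped
#' Smith-Waterman extension over the seeded window.  Every hit carries
#' identity, query coverage, raw score and an E-value; hits are sorted by
#' E-value then coordinates, and near-duplicate hits on overlapping subject
#' ranges are collapsed to the best-scoring one.
#'
#' @param query Query sequence: protein for `protein-vs-translated`, DNA
#'   otherwise.
#' @param genome A `ContigSet` to search.
#' @param mode Search dialect.
#' @param params Parameter list from [seeded_search_params()]; pass
#'   modified entries to tune.
#' @param query_id Label carried into the hit table.
#' @return Data frame of hits with 0-based half-open subject coordinates on
#'   the forward strand (`s_start`, `s_end`), hit `strand`, reading `frame`
#'   (protein mode), 0-based query range, `identity`, `coverage`, `score`
#'   and `evalue`.
#' @export
seeded_search <- function(query, genome, mode = c("nucleotide",
                                                  "protein-vs-translated",
                                                  "discontiguous-nucleotide"),
                          params = NULL, query_id = "query", index = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "ContigSet"))
  if (!nzchar(query)) stop("empty query")
  if (is.null(params)) params <- seeded_search_params(mode)
  for (nm in names(seeded_search_params(mode)))
    if (is.null(params[[nm]])) params[[nm]] <- seeded_search_params(mode)[[nm]]
  k <- params$word_size
  if (mode != "discontiguous-nucleotide" && k > nchar(query))
    stop("word size exceeds query length")
  if (mode == "discontiguous-nucleotide" && nchar(query) < 28)
    stop("query shorter than the spaced-seed template")
  genome_n <- sum(nchar(genome$contigs))

  if (!is.null(index) &&
      (index$mode != mode || index$word_size != params$word_size))
    stop("index mode/word_size does not match the search parameters")
  hits <- if (mode == "protein-vs-translated") {
    search_protein(query, genome, params, genome_n, index)
  } else {
    search_nucleotide(query, genome, params, genome_n,
                      spaced = mode == "discontiguous-nucleotide",
                      index = index)
  }
  if (nrow(hits) == 0) return(empty_hits())
  hits$query_id <- query_id
  hits <- hits[hits$evalue <= params$evalue_max, , drop = FALSE]
  if (nrow(hits) == 0) return(empty_hits())
  hits <- dedupe_hits(hits, params$dedupe_overlap)
  hits <- hits[order(hits$evalue, hits$contig, hits$s_start), ]
  rownames(hits) <- NULL
  hits[, names(empty_hits())]
}

# Optimal gap-free local alignment along one diagonal (maximal-scoring
# subsegment, +2/-3), used when a seed chain sits on a single diagonal:
# equivalent to the full Smith-Waterman result for substitution-only
# homology at a fraction of the cost.  `d` is the subject offset
# (1-based subject position of query position i is i + d).
fast_diag_align <- function(qseq, subj, d) {
  nq <- nchar(qseq); ns <- nchar(subj)
  q0 <- max(1L, 1L - d); q1 <- min(nq, ns - d)
  if (q1 - q0 + 1L < 4L) return(NULL)
  qv <- strsplit(substr(qseq, q0, q1), "", fixed = TRUE)[[1]]
  sv <- strsplit(substr(subj, q0 + d, q1 + d), "", fixed = TRUE)[[1]]
  eq <- qv == sv & qv != "N"
  sc <- ifelse(eq, 2, -3)
  pre <- c(0, cumsum(sc))
  n <- length(sc)
  mins <- cummin(pre[1:n])
  vals <- pre[2:(n + 1)] - mins
  jstar <- which.max(vals)
  best <- vals[jstar]
  if (best <= 0) return(NULL)
  istar <- which(pre[1:jstar] == mins[jstar])[1]   # segment = istar..jstar
  matches <- sum(eq[istar:jstar])
  cols <- jstar - istar + 1L
  a_start <- q0 + istar - 2L                        # 0-based
  a_end <- q0 + jstar - 1L
  list(score = best, identity = matches / cols, matches = matches,
       aln_cols = cols, a_start = a_start, a_end = a_end,
       b_start = a_start + d, b_end = a_end + d)
}

search_nucleotide <- function(query, genome, params, genome_n, spaced = FALSE,
                              index = NULL) {
  nq <- nchar(query)
  kmer_fun <- if (spaced) {
    function(s) spaced_kmers(s)
  } else {
    function(s) seq_kmers(s, params$word_size)
  }
  klen <- if (spaced) 28L else params$word_size
  strands <- if (params$both_strands) c("+", "-") else "+"
  out <- list()
  for (cid in names(genome$contigs)) {
    subj <- genome$contigs[[cid]]
    sk <- if (!is.null(index)) index$kmers[[cid]] else kmer_fun(subj)
    for (std in strands) {
      qseq <- if (std == "+") query else revcomp(query)
      qk <- kmer_fun(qseq)
      pairs <- seed_pairs(qk, sk, params$kmer_cap)
      chains <- chain_seeds(pairs, params$band_width, params$chain_gap)
      for (ch in chains) {
        if (nrow(ch) < params$min_seeds) next
        w0 <- max(0L, min(ch$s) - 1L - params$pad - min(ch$q))
        w1 <- min(nchar(subj), max(ch$s) - 1L + klen + params$pad + (nq - max(ch$q)))
        win <- substr(subj, w0 + 1L, w1)
        spread <- max(ch$diag) - min(ch$diag)
        al <- if (spread == 0L) {
          fast_diag_align(qseq, win, ch$diag[1] - w0)
        } else {
          local_align(qseq, win, mode = "nucleotide")
        }
        if (is.null(al) || al$score <= 0) next
        q0 <- al$a_start; q1 <- al$a_end
        if (std == "-") { tmp <- q0; q0 <- nq - q1; q1 <- nq - tmp }
        ev <- estimate_evalue(al$score, nq, genome_n, mode = "nucleotide")
        out[[length(out) + 1L]] <- data.frame(
          contig = cid, s_start = w0 + al$b_start, s_end = w0 + al$b_end,
          strand = std, frame = NA_integer_,
          q_start = q0, q_end = q1,
          identity = al$identity, coverage = (al$a_end - al$a_start) / nq,
          matches = al$matches, aln_cols = al$aln_cols,
          score = al$score, evalue = ev, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) empty_hits()[0, setdiff(names(empty_hits()), "query_id")] else do.call(rbind, out)
}

search_protein <- function(query, genome, params, genome_n, index = NULL) {
  nq <- nchar(query)
  qk <- seq_kmers(query, params$word_size)
  out <- list()
  if (is.null(index)) {
    frames_by_contig <- lapply(genome$contigs, translate_six_frames)
    frame_kmers <- lapply(frames_by_contig, function(fr)
      lapply(fr$protein, seq_kmers, k = params$word_size))
    total_aa <- sum(vapply(frames_by_contig,
                           function(fr) sum(nchar(fr$protein)), numeric(1)))
  } else {
    frames_by_contig <- index$frames
    frame_kmers <- index$kmers
    total_aa <- index$total_aa
  }
  for (cid in names(genome$contigs)) {
    L <- nchar(genome$contigs[[cid]])
    fr <- frames_by_contig[[cid]]
    for (i in seq_len(nrow(fr))) {
      subj <- fr$protein[i]
      sk <- frame_kmers[[cid]][[i]]
      pairs <- seed_pairs(qk, sk, params$kmer_cap)
      chains <- chain_seeds(pairs, params$band_width, params$chain_gap)
      for (ch in chains) {
        if (nrow(ch) < params$min_seeds) next
        w0 <- max(0L, min(ch$s) - 1L - params$pad - min(ch$q))
        w1 <- min(nchar(subj), max(ch$s) - 1L + params$word_size + params$pad +
                    (nq - max(ch$q)))
        win <- substr(subj, w0 + 1L, w1)
        al <- local_align(query, win, mode = "protein")
        if (al$score <= 0) next
        aa_start <- w0 + al$b_start + 1L   # 1-based aa on this frame
        aa_end <- w0 + al$b_end
        ntr <- aa_to_nt_range(fr$frame[i], fr$offset[i], aa_start, aa_end, L)
        ev <- estimate_evalue(al$score, nq, total_aa, mode = "protein")
        out[[length(out) + 1L]] <- data.frame(
          contig = cid,
          s_start = as.integer(ntr[["start"]]), s_end = as.integer(ntr[["end"]]),
          strand = ntr[["strand"]], frame = fr$frame[i],
          q_start = al$a_start, q_end = al$a_end,
          identity = al$identity, coverage = (al$a_end - al$a_start) / nq,
          matches = al$matches, aln_cols = al$aln_cols,
          score = al$score, evalue = ev, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) empty_hits()[0, setdiff(names(empty_hits()), "query_id")] else do.call(rbind, out)
}

#' Export hits in a BLAST outfmt-6-like table
#' @param hits Hit table from [seeded_search()].
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_hits_tsv <- function(hits, path) {
  tab <- data.frame(
    query = hits$query_id, subject = hits$contig,
    pident = round(100 * hits$identity, 2), length = hits$aln_cols,
    mismatches = hits$aln_cols - hits$matches, gapopens = NA_integer_,
    qstart = hits$q_start + 1L, qend = hits$q_end,
    sstart = hits$s_start + 1L, send = hits$s_end,
    evalue = signif(hits$evalue, 3), bitscore = hits$score,
    stringsAsFactors = FALSE)
  write_tsv(tab, path)
}
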