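#' Retrieve genome-wide copies of a full-length element
#'
#' Nucleotide search with the full-length element (or lineage consensus)
#' as query; loci whose chained aligned length exceeds `min_len` at
#' identity >= `min_identity` are copies of the lineage.
#'
#' @param full_length_query DNA query (>= 4 kb).
#' @param genome A `ContigSet`.
#' @param min_len Minimum aligned length (bp; strict >).
#' @param min_identity Minimum identity.
#' @param index Optional precomputed [genome_index()] (nucleotide mode).
#' @return Data frame of copy loci (contig/start/end/strand/identity/
#'   aln_len).
#' @export
find_copies <- function(full_length_query, genome, min_len = 4000L,
                        min_identity = 0.80, index = NULL) {
  if (nchar(full_length_query) < 4000)
    stop("copy retrieval requires a query of at least 4 kb")
  hits <- seeded_search(full_length_query, genome, mode = "nucleotide",
                        index = index)
  hits <- hits[hits$aln_cols > min_len & hits$identity >= min_identity, ,
               drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), aln_len = integer(),
                      stringsAsFactors = FALSE))
  }
  out <- data.frame(contig = hits$contig, start = hits$s_start,
                    end = hits$s_end, strand = hits$strand,
                    identity = hits$identity, aln_len = hits$aln_cols,
                    stringsAsFactors = FALSE)
  out <- out[order(out$contig, out$start), ]
  rownames(out) <- NULL
  out
}

# Dominant diagonal between two sequences from shared k-mer positions;
# returns NULL when no diagonal carries >= min_frac of the seed matches
# (i.e. the pair is not a simple substitution-only homolog).
dominant_diagonal <- function(a, b, k = 11L, min_frac = 0.5) {
  pairs <- seed_pairs(seq_kmers(a, k), seq_kmers(b, k))
  if (nrow(pairs) < 10) return(NULL)
  d <- pairs$s - pairs$q
  tab <- table(d)
  top <- as.integer(names(tab)[which.max(tab)])
  if (max(tab) / nrow(pairs) < min_frac) return(NULL)
  top
}

# Global-alignment identity of two copies; for substitution-only pairs
# (one dominant diagonal) a direct positional comparison over the
# overlapping range replaces the quadratic alignment.
pair_identity <- function(a, b) {
  d <- dominant_diagonal(a, b)
  if (!is.null(d)) {
    al <- fast_diag_align(a, b, d)
    if (!is.null(al)) {
      # identity over the full overlap, not just the best segment, to
      # mirror a global alignment of the two copies
      q0 <- max(1L, 1L - d); q1 <- min(nchar(a), nchar(b) - d)
      av <- strsplit(substr(a, q0, q1), "", fixed = TRUE)[[1]]
      bv <- strsplit(substr(b, q0 + d, q1 + d), "", fixed = TRUE)[[1]]
      return(sum(av == bv & av != "N") / length(av))
    }
  }
  al <- local_align(a, b, mode = "nucleotide", type = "global")
  if (is.na(al$identity)) 0 else al$identity
}

# Pairwise global identity with a shared-k-mer prefilter (clearly
# dissimilar pairs are never aligned).
pairwise_identity_matrix <- function(seqs, k = 11L, prefilter = 0.05) {
  n <- length(seqs)
  ksets <- lapply(seqs, function(s) unique(seq_kmers(s, k)))
  m <- diag(1, n)
  if (n < 2) return(m)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      shared <- length(intersect(ksets[[i]], ksets[[j]])) /
        max(1L, min(length(ksets[[i]]), length(ksets[[j]])))
      idt <- if (shared < prefilter) 0 else pair_identity(seqs[[i]], seqs[[j]])
      m[i, j] <- m[j, i] <- idt
    }
  }
  m
}

#' Cluster copies into lineages by single linkage
#'
#' Single-linkage clustering at pairwise global-alignment identity above
#' `min_identity`; cluster ids are numbered by their leftmost (first)
#' member for deterministic ordering.
#'
#' @param seqs Character vector of copy sequences (in genomic order).
#' @param min_identity Linkage threshold (strict >; default 0.90).
#' @return Integer vector of cluster assignments (1-based, ordered by
#'   first member).
#' @export
cluster_lineages <- function(seqs, min_identity = 0.90) {
  n <- length(seqs)
  if (n == 0) stop("at least one copy is required")
  if (n == 1) return(1L)
  m <- pairwise_identity_matrix(seqs)
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (m[i, j] > min_identity) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Majority-vote consensus of lineage copies
#'
#' Star alignment: every copy is globally aligned to the longest member,
#' columns gapped in more than half of the copies are dropped, and each
#' remaining column takes the majority base (ties broken by the
#' earliest copy).
#'
#' @param seqs Character vector of copies (>= 1; singleton passes
#'   through).
#' @return Consensus DNA string.
#' @export
build_consensus <- function(seqs) {
  n <- length(seqs)
  if (n == 0) stop("no copies")
  if (n == 1) return(seqs[[1]])
  ref_i <- which.max(nchar(seqs))
  ref <- seqs[[ref_i]]
  reflen <- nchar(ref)
  mat <- matrix("-", nrow = n, ncol = reflen)
  mat[ref_i, ] <- strsplit(ref, "", fixed = TRUE)[[1]]
  for (i in setdiff(seq_len(n), ref_i)) {
    d <- dominant_diagonal(ref, seqs[[i]])
    if (!is.null(d)) {
      # substitution-only member: place by offset
      q0 <- max(1L, 1L - d); q1 <- min(reflen, nchar(seqs[[i]]) - d)
      mat[i, q0:q1] <- strsplit(substr(seqs[[i]], q0 + d, q1 + d), "",
                                fixed = TRUE)[[1]]
    } else {
      al <- local_align(ref, seqs[[i]], mode = "nucleotide", type = "global")
      rv <- strsplit(al$a_aln, "", fixed = TRUE)[[1]]
      sv <- strsplit(al$b_aln, "", fixed = TRUE)[[1]]
      refcols <- which(rv != "-")
      mat[i, seq_along(refcols)] <- sv[refcols]
    }
  }
  keep <- colSums(mat == "-") <= n / 2
  cols <- which(keep)
  out <- character(length(cols))
  for (ci in seq_along(cols)) {
    col <- mat[, cols[ci]]
    col_nogap <- col[col != "-" & col != "N"]
    if (length(col_nogap) == 0) { out[ci] <- "N"; next }
    tab <- table(col_nogap)
    topn <- max(tab)
    tied <- names(tab)[tab == topn]
    if (length(tied) == 1) {
      out[ci] <- tied
    } else {
      # earliest copy holding one of the tied bases decides
      idx <- which(col %in% tied)[1]
      out[ci] <- col[idx]
    }
  }
  paste(out, collapse = "")
}

#' Classify solo LTRs
#'
#' LTR-consensus hits at E <= `evalue_max`, coverage > `min_coverage` and
#' identity > `min_identity` are solo iff no second qualifying LTR hit
#' lies within `window` bp (no pair partner) and no internal-region
#' remnant locus lies within `window` bp on either side.  Survivors are
#' grouped at > `group_identity` identity into named solo lineages.
#'
#' @param ltr_queries Named character vector: lineage -> consensus LTR.
#' @param genome A `ContigSet`.
#' @param remnant_loci Data frame of internal-region/remnant loci
#'   (contig/start/end), e.g. provirus internal regions plus POL-screen
#'   candidates.
#' @param evalue_max,min_coverage,min_identity Hit filters.
#' @param index Optional precomputed [genome_index()] (nucleotide mode).
#' @param window Pair/remnant exclusion distance (bp).
#' @param group_identity Copy-grouping threshold.
#' @return Data frame of LTR hits with `is_solo`, `reason`, `lineage`
#'   (seeding query), `cluster` (among solos).
#' @export
classify_solo_ltrs <- function(ltr_queries, genome, remnant_loci,
                               evalue_max = 1e-5, min_coverage = 0.10,
                               min_identity = 0.80, window = 15000L,
                               group_identity = 0.90, index = NULL) {
  hits <- lapply(names(ltr_queries), function(q) {
    seeded_search(ltr_queries[[q]], genome, mode = "nucleotide",
                  query_id = q, index = index)
  })
  hits <- do.call(rbind, hits)
  hits <- hits[hits$evalue <= evalue_max & hits$coverage > min_coverage &
                 hits$identity > min_identity, , drop = FALSE]
  if (nrow(hits) == 0) {
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      identity = numeric(), lineage = character(),
                      is_solo = logical(), reason = character(),
                      cluster = integer(), stringsAsFactors = FALSE))
  }
  # the same genomic LTR can be hit by several lineage queries: collapse
  # to the best (identity, then evalue) per overlapping location
  hits <- hits[order(-hits$identity, hits$evalue), ]
  keep <- rep(TRUE, nrow(hits))
  for (i in seq_len(nrow(hits))[-1]) {
    for (j in which(keep[seq_len(i - 1)])) {
      if (hits$contig[i] == hits$contig[j] &&
          hits$s_start[i] < hits$s_end[j] && hits$s_start[j] < hits$s_end[i]) {
        keep[i] <- FALSE; break
      }
    }
  }
  hits <- hits[keep, , drop = FALSE]
  hits <- hits[order(hits$contig, hits$s_start), ]
  n <- nrow(hits)
  is_solo <- logical(n)
  reason <- character(n)
  for (i in seq_len(n)) {
    near_ltr <- which(seq_len(n) != i &
                        hits$contig == hits$contig[i] &
                        hits$s_start < hits$s_end[i] + window &
                        hits$s_end > hits$s_start[i] - window)
    if (length(near_ltr) > 0) {
      is_solo[i] <- FALSE; reason[i] <- "paired_ltr_nearby"; next
    }
    if (nrow(remnant_loci) > 0) {
      near_rem <- remnant_loci$contig == hits$contig[i] &
        remnant_loci$start < hits$s_end[i] + window &
        remnant_loci$end > hits$s_start[i] - window
      if (any(near_rem)) {
        is_solo[i] <- FALSE; reason[i] <- "internal_remnant_nearby"; next
      }
    }
    is_solo[i] <- TRUE; reason[i] <- "solo"
  }
  out <- data.frame(contig = hits$contig, start = hits$s_start,
                    end = hits$s_end, strand = hits$strand,
                    identity = hits$identity, lineage = hits$query_id,
                    is_solo = is_solo, reason = reason,
                    cluster = NA_integer_, stringsAsFactors = FALSE)
  solo_idx <- which(out$is_solo)
  if (length(solo_idx) > 0) {
    seqs <- vapply(solo_idx, function(i) {
      extract_locus(genome, locus(out$contig[i], out$start[i], out$end[i],
                                  out$strand[i]))$seq
    }, character(1))
    out$cluster[solo_idx] <- cluster_lineages(seqs, group_identity)
  }
  rownames(out) <- NULL
  out
}

# letter sequence a, b, ..., z, aa, ab, ...
lineage_letters <- function(n) {
  if (n <= 26) return(letters[seq_len(n)])
  extra <- n - 26
  c(letters, paste0(rep(letters, each = 26), letters)[seq_len(extra)])
}

#' Assign ERV nomenclature to clustered copies
#'
#' Names follow the `ERV-<Genus>.<letter><n>-<host>` scheme (solo
#' lineages prefixed `SoloLTR-`): lineage letters are assigned by
#' descending copy number (ties by leftmost genomic coordinate) and
#' copies are numbered 1..n in genomic order.
#'
#' @param copies Data frame with columns `cluster`, `genus`, `contig`,
#'   `start`.
#' @param host Host suffix (e.g. `"Mpen"`).
#' @param solo Prefix names with `SoloLTR-` instead of `ERV-`.
#' @return The input with `lineage_name` and `copy_name` columns.
#' @export
assign_names <- function(copies, host, solo = FALSE) {
  prefix <- if (solo) "SoloLTR" else "ERV"
  copies$lineage_name <- NA_character_
  copies$copy_name <- NA_character_
  for (g in unique(copies$genus)) {
    gi <- which(copies$genus == g)
    sizes <- table(copies$cluster[gi])
    leftmost <- vapply(names(sizes), function(cl) {
      min(copies$start[gi][copies$cluster[gi] == as.integer(cl)])
    }, numeric(1))
    ord <- order(-as.integer(sizes), leftmost)
    lets <- lineage_letters(length(ord))
    for (r in seq_along(ord)) {
      cl <- as.integer(names(sizes)[ord[r]])
      idx <- gi[copies$cluster[gi] == cl]
      idx <- idx[order(copies$contig[idx], copies$start[idx])]
      lname <- sprintf("%s-%s.%s-%s", prefix, g, lets[r], host)
      copies$lineage_name[idx] <- lname
      copies$copy_name[idx] <- sprintf("%s-%s.%s%d-%s", prefix, g, lets[r],
                                       seq_along(idx), host)
    }
  }
  copies
}

#' Parse a name from the ERV nomenclature scheme
#' @param name Copy or lineage name.
#' @return List with `prefix`, `genus`, `letter`, `number` (NA for
#'   lineage names), `host`; errors on names outside the scheme.
#' @export
parse_erv_name <- function(name) {
  m <- regmatches(name, regexec(
    "^(ERV|SoloLTR)-([A-Za-z]+)\\.([a-z]+?)([0-9]+)?-([A-Za-z0-9]+)$", name))[[1]]
  if (length(m) == 0) stop("name does not parse under the ERV scheme: ", name)
  list(prefix = m[2], genus = m[3], letter = m[4],
       number = if (nzchar(m[5])) as.integer(m[5]) else NA_integer_,
       host = m[6])
}
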