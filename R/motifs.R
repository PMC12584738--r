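#' Motif pattern registry
#'
#' Degenerate patterns used to characterize retroviral GAG/POL/ENV
#' products.  In a pattern, `.` matches any residue except a stop (`*`);
#' bracketed sets are alternatives.  Matching never crosses a stop codon.
#'
#' @return Named character vector of regular expressions.
#' @export
motif_patterns <- function() {
  c(
    CysHis = "C[^*]{2}C[^*]{4}H[^*]{4}C",     # Cys-His box, capsid NC zinc knuckle
    PPPY   = "PPPY",                          # late domain, particle assembly
    MHR    = "QG[^*]{2}E[^*]{4}F[^*]{2}",     # major homology region
    Furin  = "[KR][^*][KR]R",                 # furin cleavage site K/R-X-K/R-R
    CX6CC  = "C[^*]{6}CC",                    # gamma-type envelope TM motif
    CX6C   = "C[^*]{6}C",                     # beta-type counterpart
    YXXL   = "Y[^*]{2}L",                     # cytoplasmic tail, Env incorporation
    RBM    = "SDGGG[^*]{2}D[^*]{2}R"          # RDR-group receptor-binding motif
  )
}

#' Scan a protein for retroviral motifs
#'
#' Reports every (possibly overlapping) occurrence of each pattern.
#' `CX6C` is reported only at anchors where `CX6CC` does not also match,
#' so the beta/gamma envelope distinction stays unambiguous.
#'
#' @param protein Protein string (20-letter alphabet plus X and `*`).
#' @param patterns Pattern set (default [motif_patterns()]).
#' @return Data frame: `motif_id`, `position` (0-based), `match`.
#' @export
scan_motifs <- function(protein, patterns = motif_patterns()) {
  out <- list()
  for (id in names(patterns)) {
    pat <- patterns[[id]]
    m <- gregexpr(paste0("(?=(", pat, "))"), protein, perl = TRUE)[[1]]
    if (m[1] == -1) next
    starts <- as.integer(m)
    lens <- attr(m, "capture.length")[, 1]
    out[[id]] <- data.frame(motif_id = id, position = starts - 1L,
                            match = substring(protein, starts, starts + lens - 1L),
                            stringsAsFactors = FALSE)
  }
  hits <- if (length(out)) do.call(rbind, out) else
    data.frame(motif_id = character(), position = integer(),
               match = character(), stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  # CX6C suppressed where CX6CC matches at the same anchor
  if (any(hits$motif_id == "CX6C")) {
    cc_pos <- hits$position[hits$motif_id == "CX6CC"]
    hits <- hits[!(hits$motif_id == "CX6C" & hits$position %in% cc_pos), ,
                 drop = FALSE]
    rownames(hits) <- NULL
  }
  hits
}

#' Classify an envelope as gamma-type or beta-type
#'
#' Gamma-type envelopes carry CX6CC in the TM subunit; a CX6C without the
#' second cysteine indicates a beta-type envelope; neither motif leaves
#' the call indeterminate.  (An immunosuppressive-domain similarity score
#' can be layered on when a reference ISD peptide is configured; the call
#' itself rests on the cysteine motif.)
#'
#' @param env_motifs Motif hits from [scan_motifs()] on one ENV product.
#' @return `"gamma_type"`, `"beta_type"` or `"indeterminate"`.
#' @export
classify_env_type <- function(env_motifs) {
  if (any(env_motifs$motif_id == "CX6CC")) return("gamma_type")
  if (any(env_motifs$motif_id == "CX6C")) return("beta_type")
  "indeterminate"
}

#' Find open reading frames in all six frames
#'
#' ORFs run from a start codon (first ATG after the previous stop, when
#' `require_atg`) to the next stop codon or the end of the element.  The
#' reported nucleotide length includes the stop codon when present, and
#' only ORFs longer than `min_nt` are returned.
#'
#' @param element DNA string.
#' @param min_nt Minimum ORF length in nucleotides (strictly greater
#'   than; default 180).
#' @param require_atg Require an ATG start (default TRUE).
#' @return Data frame: `start`/`end` (0-based half-open, element forward
#'   strand), `strand`, `frame`, `aa_len`, `nt_len`, `protein` (without
#'   the stop), `has_stop`.
#' @export
find_orfs <- function(element, min_nt = 180L, require_atg = TRUE) {
  if (nchar(element) < 3) stop("element shorter than one codon")
  fr <- translate_six_frames(element)
  L <- nchar(element)
  out <- list()
  for (i in seq_len(nrow(fr))) {
    prot <- fr$protein[i]
    segs <- orf_segments(prot, require_atg)
    for (s in segs) {
      aa_len <- s$aa_end - s$aa_start + 1L
      nt_len <- 3L * aa_len + if (s$has_stop) 3L else 0L
      if (nt_len <= min_nt) next
      aa_last <- s$aa_end + if (s$has_stop) 1L else 0L
      ntr <- aa_to_nt_range(fr$frame[i], fr$offset[i], s$aa_start, aa_last, L)
      out[[length(out) + 1L]] <- data.frame(
        start = as.integer(ntr[["start"]]), end = as.integer(ntr[["end"]]),
        strand = ntr[["strand"]], frame = fr$frame[i],
        aa_len = aa_len, nt_len = nt_len,
        protein = substr(prot, s$aa_start, s$aa_end),
        has_stop = s$has_stop, stringsAsFactors = FALSE)
    }
  }
  orfs <- if (length(out)) do.call(rbind, out) else
    data.frame(start = integer(), end = integer(), strand = character(),
               frame = integer(), aa_len = integer(), nt_len = integer(),
               protein = character(), has_stop = logical(),
               stringsAsFactors = FALSE)
  orfs <- orfs[order(orfs$start, orfs$end, orfs$frame), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}

# Split a frame translation into ORF segments; returns list of
# (aa_start, aa_end [1-based, inclusive, stop excluded], has_stop).
orf_segments <- function(prot, require_atg) {
  n <- nchar(prot)
  stops <- c(0L, which(strsplit(prot, "", fixed = TRUE)[[1]] == "*"), n + 1L)
  stops <- unique(stops)
  segs <- list()
  for (j in seq_len(length(stops) - 1L)) {
    from <- stops[j] + 1L
    to <- stops[j + 1L] - 1L
    if (to < from) next
    has_stop <- stops[j + 1L] <= n
    if (require_atg) {
      seg <- substr(prot, from, to)
      m <- regexpr("M", seg, fixed = TRUE)
      if (m == -1) next
      from <- from + as.integer(m) - 1L
    }
    if (to < from) next
    segs[[length(segs) + 1L]] <- list(aa_start = from, aa_end = to,
                                      has_stop = has_stop)
  }
  segs
}

#' Guess GAG/POL/ENV identity of ORFs
#'
#' When reference proteins are supplied the best BLOSUM62 local-alignment
#' score decides; otherwise the three longest forward-strand ORFs are
#' labeled GAG, POL, ENV by positional order.
#'
#' @param orfs ORF table from [find_orfs()].
#' @param references Optional named list of reference proteins
#'   (`GAG`/`POL`/`ENV`).
#' @param min_score Minimum alignment score to accept a homology label.
#' @return The ORF table with a `gene_guess` column.
#' @export
assign_gene_guess <- function(orfs, references = NULL, min_score = 100) {
  orfs$gene_guess <- "other"
  if (nrow(orfs) == 0) return(orfs)
  if (!is.null(references)) {
    for (i in seq_len(nrow(orfs))) {
      scores <- vapply(references, function(ref) {
        local_align(orfs$protein[i], ref, mode = "protein")$score
      }, numeric(1))
      if (max(scores) >= min_score)
        orfs$gene_guess[i] <- names(references)[which.max(scores)]
    }
  } else {
    fwd <- which(orfs$strand == "+")
    big <- fwd[order(-orfs$aa_len[fwd])][seq_len(min(3L, length(fwd)))]
    big <- big[order(orfs$start[big])]
    orfs$gene_guess[big] <- c("GAG", "POL", "ENV")[seq_along(big)]
  }
  orfs
}

#' Filter lineage proteins for phylogenetic use
#'
#' Retains long products only: GAG > 500 aa, POL > 600 aa, ENV > 400 aa
#' (strict inequalities), the lengths at which tree estimates are stable.
#'
#' @param proteins Data frame with columns `gene` and `protein` (and any
#'   id columns, carried through).
#' @return The retained rows.
#' @export
select_phylo_candidates <- function(proteins) {
  mins <- c(GAG = 500L, POL = 600L, ENV = 400L)
  keep <- vapply(seq_len(nrow(proteins)), function(i) {
    g <- proteins$gene[i]
    g %in% names(mins) && nchar(proteins$protein[i]) > mins[[g]]
  }, logical(1))
  proteins[keep, , drop = FALSE]
}
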