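#' Construct a contig set
#'
#' A `ContigSet` is the in-memory genome: a named set of uppercase DNA
#' sequences (alphabet A/C/G/T/N) plus a short species tag that downstream
#' reports carry along (e.g. `"Mpen"`).
#'
#' @param contigs Named character vector of DNA sequences.
#' @param species Short species label attached to every record derived from
#'   this genome.
#' @return An object of class `ContigSet`.
#' @export
contig_set <- function(contigs, species = "") {
  if (length(contigs) == 0) stop("contig set must contain at least one sequence")
  ids <- names(contigs)
  if (is.null(ids) || any(!nzchar(ids))) stop("all contigs must have non-empty ids")
  if (anyDuplicated(ids)) stop("duplicate contig ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(contigs))) stop("empty contig sequence")
  contigs <- toupper(contigs)
  bad <- vapply(contigs, function(s) grepl("[^ACGTN]", s), logical(1))
  if (any(bad)) stop("contig contains characters outside A/C/G/T/N after case folding")
  structure(list(contigs = contigs, species = species), class = "ContigSet")
}

#' @export
print.ContigSet <- function(x, ...) {
  cat(sprintf("ContigSet [%s]: %d contig(s), %s bp total\n",
              if (nzchar(x$species)) x$species else "unnamed",
              length(x$contigs),
              format(sum(nchar(x$contigs)), big.mark = ",")))
  invisible(x)
}

#' Contig lengths of a ContigSet
#' @param genome A `ContigSet`.
#' @return Named integer vector of contig lengths.
#' @export
contig_lengths <- function(genome) {
  stopifnot(inherits(genome, "ContigSet"))
  vapply(genome$contigs, nchar, integer(1))
}

#' Read a FASTA file into a ContigSet
#'
#' Lowercase bases are folded to uppercase; IUPAC ambiguity codes other than
#' N are collapsed to N (assemblies routinely contain them and N never
#' counts as a match downstream).  The number of collapsed characters is
#' reported with a message.
#'
#' @param path Path to a FASTA file.
#' @param species Species tag to attach.
#' @return A `ContigSet`.
#' @export
read_fasta <- function(path, species = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  if (length(ss) == 0) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids)) stop("duplicate FASTA ids in ", path)
  seqs <- toupper(as.character(ss))
  n_before <- sum(vapply(seqs, function(s) lengths(regmatches(s, gregexpr("[^ACGTN]", s))), integer(1)))
  if (n_before > 0) {
    seqs <- vapply(seqs, function(s) gsub("[^ACGTN]", "N", s), character(1))
    message(sprintf("read_fasta: collapsed %d ambiguous base(s) to N", n_before))
  }
  names(seqs) <- ids
  contig_set(seqs, species = species)
}

#' Write sequences to FASTA
#' @param seqs Named character vector of sequences, or a `ContigSet`.
#' @param path Output path.
#' @param width Line wrap width.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  if (inherits(seqs, "ContigSet")) seqs <- seqs$contigs
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Construct a genomic locus
#'
#' Internal coordinates are 0-based half-open (`start` inclusive, `end`
#' exclusive); emitted GFF3 is 1-based inclusive.  No locus may span
#' contigs.
#'
#' @param contig Contig id.
#' @param start 0-based inclusive start.
#' @param end 0-based exclusive end.
#' @param strand `"+"` or `"-"`.
#' @return A one-row `data.frame` with columns contig/start/end/strand.
#' @export
locus <- function(contig, start, end, strand = "+") {
  stopifnot(length(contig) == length(start), length(start) == length(end))
  if (any(start < 0) || any(end <= start)) stop("invalid locus: require 0 <= start < end")
  if (any(!strand %in% c("+", "-"))) stop("strand must be '+' or '-'")
  data.frame(contig = as.character(contig), start = as.integer(start),
             end = as.integer(end), strand = as.character(strand),
             stringsAsFactors = FALSE)
}

check_locus <- function(genome, loc) {
  stopifnot(inherits(genome, "ContigSet"))
  if (!loc$contig %in% names(genome$contigs))
    stop("locus refers to unknown contig: ", loc$contig)
  len <- nchar(genome$contigs[[loc$contig]])
  if (loc$start < 0 || loc$end > len || loc$start >= loc$end)
    stop(sprintf("locus [%d,%d) outside contig %s (length %d)", loc$start, loc$end, loc$contig, len))
  invisible(len)
}

#' Reverse complement of DNA strings
#' @param s Character vector of DNA (A/C/G/T/N).
#' @return Character vector of reverse complements.
#' @export
revcomp <- function(s) {
  comp <- chartr("ACGTN", "TGCAN", s)
  vapply(comp, function(x) {
    paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Extract the sequence of a locus, with optional flanks
#'
#' Flanks are clipped at contig bounds and the achieved flank lengths are
#' reported.  On the minus strand the whole extracted window is
#' reverse-complemented, so the returned sequence reads 5' to 3' on the
#' feature's own strand.
#'
#' @param genome A `ContigSet`.
#' @param loc A locus (one-row data.frame from [locus()]).
#' @param flank Non-negative flank length added on both sides.
#' @return List with `seq`, `left_flank`, `right_flank` (achieved lengths,
#'   in contig orientation).
#' @export
extract_locus <- function(genome, loc, flank = 0L) {
  stopifnot(flank >= 0)
  len <- check_locus(genome, loc)
  a <- max(0L, loc$start - flank)
  b <- min(len, loc$end + flank)
  s <- substr(genome$contigs[[loc$contig]], a + 1L, b)
  if (loc$strand == "-") s <- revcomp(s)
  list(seq = s, left_flank = loc$start - a, right_flank = b - loc$end)
}

#' Write features to GFF3
#'
#' Features are an internal 0-based data.frame with at least
#' contig/start/end/strand plus `type` and optional attribute columns; the
#' file is standard 1-based inclusive GFF3, sorted by (contig, start, end,
#' type) for stable output.
#'
#' @param features Data frame of features (may be empty).
#' @param path Output path.
#' @param source Value of the GFF3 source column.
#' @return Invisibly, `path`.
#' @export
write_gff3 <- function(features, path, source = "ervatlas") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (is.null(features) || nrow(features) == 0) return(invisible(path))
  if (!"type" %in% names(features)) features$type <- "region"
  o <- order(features$contig, features$start, features$end, features$type)
  features <- features[o, , drop = FALSE]
  core <- c("contig", "start", "end", "strand", "type")
  attr_cols <- setdiff(names(features), core)
  attrs <- vapply(seq_len(nrow(features)), function(i) {
    kv <- vapply(attr_cols, function(cl) {
      v <- features[[cl]][i]
      if (is.na(v)) return(NA_character_)
      paste0(cl, "=", gsub("[;=\t\n]", "_", as.character(v)))
    }, character(1))
    kv <- kv[!is.na(kv)]
    if (length(kv) == 0) "." else paste(kv, collapse = ";")
  }, character(1))
  lines <- sprintf("%s\t%s\t%s\t%d\t%d\t.\t%s\t.\t%s",
                   features$contig, source, features$type,
                   features$start + 1L, features$end, features$strand, attrs)
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#' @param path Path to a GFF3 file.
#' @return Data frame with contig/start/end/strand/type and attribute columns
#'   (internal 0-based coordinates).
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(lines) == 0) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), type = character(), stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  df <- data.frame(
    contig = vapply(parts, `[`, "", 1L),
    start = as.integer(vapply(parts, `[`, "", 4L)) - 1L,
    end = as.integer(vapply(parts, `[`, "", 5L)),
    strand = vapply(parts, `[`, "", 7L),
    type = vapply(parts, `[`, "", 3L),
    stringsAsFactors = FALSE)
  attrs <- vapply(parts, `[`, "", 9L)
  kvs <- lapply(attrs, function(a) {
    if (a == ".") return(character())
    kv <- strsplit(strsplit(a, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, "", 2L), vapply(kv, `[`, "", 1L))
  })
  keys <- unique(unlist(lapply(kvs, names)))
  for (k in keys) {
    df[[k]] <- vapply(kvs, function(x) if (k %in% names(x)) x[[k]] else NA_character_, character(1))
  }
  df
}

#' Write a report table as TSV
#' @param records Data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tsv <- function(records, path) {
  utils::write.table(records, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV written by [write_tsv()]
#' @param path Path to the TSV.
#' @return Data frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}
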