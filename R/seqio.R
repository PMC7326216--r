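#' Read a FASTA file
#'
#' @param path input FASTA.
#' @param circular circularity flag applied to every record.
#' @return a list of `reference_sequence` objects, in file order.
#' @export
read_fasta <- function(path, circular = FALSE) {
  xs <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(xs))
  if (anyDuplicated(ids)) stop("duplicate sequence ids in ", path)
  if (any(Biostrings::width(xs) == 0L)) stop("empty sequence record in ", path)
  lapply(seq_along(xs), function(i)
    reference_sequence(ids[i], as.character(xs[[i]]), circular = circular))
}

#' Write sequences as FASTA
#'
#' @param seqs a `reference_sequence`, a list of them, or a named character
#'   vector.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (inherits(seqs, "reference_sequence")) seqs <- list(seqs)
  if (is.character(seqs)) {
    xs <- Biostrings::DNAStringSet(seqs)
  } else {
    xs <- Biostrings::DNAStringSet(vapply(seqs, `[[`, character(1), "bases"))
    names(xs) <- vapply(seqs, `[[`, character(1), "id")
  }
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}

# parse one CIGAR string into ops/lengths
parse_cigar <- function(cigar) {
  ops <- gregexpr("[0-9]+[MIDNSHP=X]", cigar)[[1]]
  if (ops[1] == -1L) stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, gregexpr("[0-9]+[MIDNSHP=X]", cigar))[[1]]
  list(len = as.integer(sub("[A-Z=]$", "", toks)),
       op = sub("^[0-9]+", "", toks))
}

#' Read aligned reads from a SAM file
#'
#' Reads the minimal single-end SAM dialect used throughout this package:
#' mandatory columns, `@SQ`-declared references, full-match or soft-clipped
#' CIGARs (soft-clipped bases are trimmed on read; indel CIGARs are
#' rejected because the pileup assumes column-aligned reads). Unmapped
#' records are skipped; their count is reported in a message and attached
#' as attribute `n_unmapped`.
#'
#' @param path input SAM.
#' @return data.frame of aligned reads with columns `name`, `ref_id`,
#'   `start` (0-based), `end` (exclusive), `strand`, `mapq`, `bases`,
#'   `duplicate`.
#' @export
read_sam <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "@")]
  body <- lines[!startsWith(lines, "@") & nzchar(lines)]
  sq <- hdr[startsWith(hdr, "@SQ")]
  declared <- sub(".*SN:([^\t]+).*", "\\1", sq)
  if (length(body) == 0L) {
    out <- data.frame(name = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      bases = character(0), duplicate = logical(0))
    attr(out, "n_unmapped") <- 0L
    return(out)
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  flag <- vapply(f, function(x) as.integer(x[2]), integer(1))
  unmapped <- bitwAnd(flag, 4L) != 0L
  n_unmapped <- sum(unmapped)
  if (n_unmapped > 0L)
    message(n_unmapped, " unmapped record(s) skipped")
  f <- f[!unmapped]
  flag <- flag[!unmapped]
  if (length(f) == 0L) {
    out <- data.frame(name = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      bases = character(0), duplicate = logical(0))
    attr(out, "n_unmapped") <- n_unmapped
    return(out)
  }
  rname <- vapply(f, `[`, character(1), 3L)
  if (length(declared) && !all(rname %in% declared))
    stop("record references undeclared reference id: ",
         paste(unique(setdiff(rname, declared)), collapse = ", "))
  pos <- vapply(f, function(x) as.integer(x[4]), integer(1))
  seqcol <- vapply(f, function(x) if (length(x) >= 10L) x[10] else x[7],
                   character(1))
  cigars <- vapply(f, `[`, character(1), 6L)
  trimmed <- character(length(f))
  alen <- integer(length(f))
  for (i in seq_along(f)) {
    cg <- parse_cigar(cigars[i])
    if (any(cg$op %in% c("I", "D", "N")))
      stop("indel CIGAR not supported by the column-aligned pileup: ",
           cigars[i])
    if (!all(cg$op %in% c("M", "=", "X", "S", "H")))
      stop("unsupported CIGAR op in ", cigars[i])
    s <- seqcol[i]
    if (cg$op[1] == "S") s <- substring(s, cg$len[1] + 1L)
    k <- length(cg$op)
    if (cg$op[k] == "S") s <- substring(s, 1L, nchar(s) - cg$len[k])
    trimmed[i] <- s
    alen[i] <- sum(cg$len[cg$op %in% c("M", "=", "X")])
  }
  out <- data.frame(name = vapply(f, `[`, character(1), 1L),
                    ref_id = rname,
                    start = pos - 1L,
                    end = pos - 1L + alen,
                    strand = ifelse(bitwAnd(flag, 16L) != 0L, "-", "+"),
                    mapq = vapply(f, function(x) as.integer(x[5]), integer(1)),
                    bases = trimmed,
                    duplicate = bitwAnd(flag, 1024L) != 0L)
  attr(out, "n_unmapped") <- n_unmapped
  out
}

#' Write aligned reads as SAM
#'
#' Emits the standard 11 mandatory columns with full-length-match CIGARs,
#' 1-based positions, strand on flag bit 0x10 and the duplicate mark on
#' flag bit 0x400.
#'
#' @param reads data.frame of aligned reads.
#' @param ref the `reference_sequence` the reads are mapped to (for the
#'   `@SQ` header line).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_sam <- function(reads, ref, path) {
  stopifnot(inherits(ref, "reference_sequence"))
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", ref$id, seq_length(ref)))
  flag <- ifelse(reads$strand == "-", 16L, 0L) +
    ifelse(reads$duplicate, 1024L, 0L)
  rec <- sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
                 reads$name, flag, reads$ref_id, reads$start + 1L,
                 reads$mapq, reads$end - reads$start, reads$bases)
  writeLines(c(hdr, rec), path)
  invisible(path)
}

#' Filter reads on mapping quality
#'
#' Retains exactly the reads with `mapq >= min_mapq` (the conventional
#' "remove MAPQ below Q30" filter by default), preserving input order.
#'
#' @param reads data.frame of aligned reads.
#' @param min_mapq minimum retained mapping quality (default 30).
#' @return the filtered data.frame.
#' @export
filter_mapq <- function(reads, min_mapq = 30L) {
  reads[reads$mapq >= min_mapq, , drop = FALSE]
}

#' Write a window table as BED
#'
#' BED uses 0-based half-open coordinates; extra numeric columns follow the
#' three coordinate columns.
#'
#' @param windows data.frame with `start` and `end` columns plus any score
#'   columns.
#' @param ref_id chromosome/contig name.
#' @param path output file.
#' @param score_cols names of columns appended after the coordinates.
#' @return the path, invisibly.
#' @export
write_bed <- function(windows, ref_id, path,
                      score_cols = intersect(c("divergence", "depth_capture",
                                               "depth_shotgun"),
                                             names(windows))) {
  df <- cbind(data.frame(chrom = ref_id, start = windows$start,
                         end = windows$end),
              windows[, score_cols, drop = FALSE])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
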