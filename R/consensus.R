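#' Consensus-calling parameters
#'
#' Depth/majority rule for base calling: a position is called only when its
#' depth reaches `min_depth` and a single state reaches the `majority`
#' fraction of that depth. The defaults (3x, 90%) implement a stringent
#' rule under which positions carrying a co-enriched second haplotype (for
#' example a numt) above 10% of reads are left as N rather than
#' incorporated.
#'
#' @param min_depth minimum read depth for a call (default 3).
#' @param majority required majority fraction, in (0.5, 1\] (default 0.90;
#'   applied as `>=`, so a 9-of-10 column is called).
#' @return an object of class `consensus_params`.
#' @export
consensus_params <- function(min_depth = 3L, majority = 0.90) {
  stopifnot(min_depth >= 1, majority > 0.5, majority <= 1)
  structure(list(min_depth = as.integer(min_depth), majority = majority),
            class = "consensus_params")
}

PILEUP_STATES <- c("A", "C", "G", "T", "-", "N")

#' Build a per-position pileup from column-aligned reads
#'
#' Tallies the read bases overlapping every reference position. N bases
#' are tallied but never count toward depth; `-` characters in read bases
#' are tallied as observed deletions and do count toward depth.
#'
#' @param reads data.frame of aligned reads (typically MAPQ-filtered and
#'   deduplicated first; the pipeline enforces that order).
#' @param ref_length reference length in bp.
#' @return an object of class `pileup`: list with `counts` (6 x
#'   `ref_length` integer matrix, rows A/C/G/T/-/N) and `depth` (integer
#'   vector, the non-N tally).
#' @export
pileup <- function(reads, ref_length) {
  ref_length <- as.integer(ref_length)
  counts <- matrix(0L, nrow = 6L, ncol = ref_length,
                   dimnames = list(PILEUP_STATES, NULL))
  if (nrow(reads) > 0L) {
    if (any(reads$start < 0L) || any(reads$end > ref_length))
      stop("read coordinates exceed reference length")
    lens <- reads$end - reads$start
    if (any(nchar(reads$bases) != lens))
      stop("read length does not match its placement (full-match mode)")
    pos <- sequence(lens) + rep(reads$start, lens)   # 1-based positions
    base <- explode(reads$bases)
    state <- match(toupper(base), PILEUP_STATES)
    state[is.na(state)] <- 6L                        # unknown -> N
    tal <- tabulate((pos - 1L) * 6L + state, nbins = 6L * ref_length)
    counts[] <- as.integer(tal)
  }
  structure(list(counts = counts,
                 depth = as.integer(colSums(counts[1:5, , drop = FALSE]))),
            class = "pileup")
}

#' @export
print.pileup <- function(x, ...) {
  cat(sprintf("<pileup> %d positions, mean depth %.1f\n",
              length(x$depth), mean(x$depth)))
  invisible(x)
}

#' Call a consensus sequence with a depth/majority rule
#'
#' A position is called X (X in A/C/G/T/deletion) iff depth >= `min_depth`
#' and `count(X)/depth >= majority`; otherwise N. Mixed positions below the
#' majority are deliberately N: this is the numt safeguard, which keeps
#' sites with a co-enriched minority haplotype out of the consensus.
#' Consensus deletions are kept in `calls` (as `-`) and excised from the
#' reported `sequence`.
#'
#' @param pile a `pileup`.
#' @param params a `consensus_params`.
#' @param ref_id name for the consensus sequence.
#' @return an object of class `consensus_sequence`: `ref_id`, `calls`
#'   (character vector over A/C/G/T/-/N, one per reference position),
#'   `sequence` (calls with deletions excised, as one string), `depth`.
#' @export
call_consensus <- function(pile, params = consensus_params(),
                           ref_id = "consensus") {
  stopifnot(inherits(pile, "pileup"), inherits(params, "consensus_params"))
  cc <- pile$counts[1:5, , drop = FALSE]
  depth <- pile$depth
  top <- apply(cc, 2L, which.max)
  topn <- cc[cbind(top, seq_along(depth))]
  # small epsilon so exact-boundary columns (e.g. 9 of 10 at 0.90) are not
  # lost to floating-point representation of the majority fraction
  ok <- depth >= params$min_depth & topn + 1e-9 >= params$majority * depth
  calls <- rep("N", length(depth))
  calls[ok] <- PILEUP_STATES[top[ok]]
  structure(list(ref_id = ref_id, calls = calls,
                 sequence = paste(calls[calls != "-"], collapse = ""),
                 depth = depth),
            class = "consensus_sequence")
}

#' @export
print.consensus_sequence <- function(x, ...) {
  cat(sprintf("<consensus_sequence> %s: %d positions, %.1f%% called\n",
              x$ref_id, length(x$calls), 100 * mean(x$calls != "N")))
  invisible(x)
}

#' Write a consensus depth vector as bedGraph-style text
#'
#' Runs of equal depth are merged into 0-based half-open intervals with a
#' fourth depth column.
#'
#' @param cons a `consensus_sequence`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_depth_bedgraph <- function(cons, path) {
  stopifnot(inherits(cons, "consensus_sequence"))
  d <- cons$depth
  brk <- c(0L, which(diff(d) != 0L), length(d))
  df <- data.frame(chrom = cons$ref_id,
                   start = brk[-length(brk)],
                   end = brk[-1],
                   depth = d[brk[-length(brk)] + 1L])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Recovery statistics for a consensus
#'
#' The two headline per-sample statistics of a capture experiment: the
#' portion of the reference recovered at or above the calling depth, and
#' the average read depth over all positions.
#'
#' @param cons a `consensus_sequence`.
#' @param params a `consensus_params` (its `min_depth` sets the threshold).
#' @return list with `fraction_at_min_depth` and `mean_depth`.
#' @export
completeness <- function(cons, params = consensus_params()) {
  stopifnot(inherits(cons, "consensus_sequence"))
  if (length(cons$depth) == 0L) stop("empty consensus")
  list(fraction_at_min_depth = mean(cons$depth >= params$min_depth),
       mean_depth = mean(cons$depth))
}

#' Screen coding sequences for internal stop codons
#'
#' Translates each annotated CDS with the vertebrate mitochondrial code
#' (where AGA and AGG are stops) and reports every stop codon strictly
#' before the terminal codon. Internal stops in a mitochondrial consensus
#' are the classic signature of co-assembled numt sequence. Codons
#' containing N are skipped and counted separately.
#'
#' @param seq a nucleotide string, `reference_sequence` or
#'   `consensus_sequence`.
#' @param cds data.frame with columns `name`, `start`, `end` (0-based
#'   half-open), `strand`; minus-strand CDS are reverse-complemented before
#'   translation.
#' @param genetic_code named character vector mapping codons to amino
#'   acids; default is the vertebrate mitochondrial table.
#' @return data.frame of violations (`cds`, `codon_index` 0-based,
#'   `codon`), with attribute `n_ambiguous` (codons skipped for N).
#' @export
screen_stop_codons <- function(seq, cds,
                               genetic_code = Biostrings::getGeneticCode("2")) {
  if (inherits(seq, "reference_sequence")) seq <- seq$bases
  if (inherits(seq, "consensus_sequence")) seq <- seq$sequence
  cds <- as.data.frame(cds)
  out <- data.frame(cds = character(0), codon_index = integer(0),
                    codon = character(0))
  n_amb <- 0L
  for (i in seq_len(nrow(cds))) {
    s <- substring(seq, cds$start[i] + 1L, cds$end[i])
    if (nchar(s) %% 3L != 0L)
      stop("CDS length not divisible by 3: ", cds$name[i])
    if (identical(cds$strand[i], "-")) s <- revcomp(s)
    n_codon <- nchar(s) / 3L
    codons <- substring(s, 3L * seq_len(n_codon) - 2L, 3L * seq_len(n_codon))
    amb <- grepl("[^ACGT]", codons)
    n_amb <- n_amb + sum(amb)
    aa <- rep(NA_character_, n_codon)
    aa[!amb] <- unname(genetic_code[codons[!amb]])
    bad <- which(!is.na(aa) & aa == "*" & seq_len(n_codon) < n_codon)
    if (length(bad))
      out <- rbind(out, data.frame(cds = cds$name[i], codon_index = bad - 1L,
                                   codon = codons[bad]))
  }
  attr(out, "n_ambiguous") <- n_amb
  out
}

#' Remove alignment columns with missing data
#'
#' Retains exactly the columns where every row is an unambiguous base
#' (A/C/G/T), in order. Run before pairwise-difference and network
#' computations so that missing data cannot masquerade as divergence.
#'
#' @param alignment named character vector of equal-length sequences.
#' @return character vector of the same names with only complete columns.
#' @export
strip_missing_columns <- function(alignment) {
  n <- length(alignment)
  stopifnot(n >= 1L)
  w <- unique(nchar(alignment))
  if (length(w) != 1L) stop("ragged alignment: unequal row lengths")
  m <- matrix(explode(toupper(alignment)), nrow = n, byrow = TRUE)
  keep <- colSums(matrix(m %in% DNA_BASES, nrow = n)) == n
  if (!any(keep)) {
    warning("every column contains missing data; empty alignment returned")
    return(setNames(rep("", n), names(alignment)))
  }
  setNames(apply(m[, keep, drop = FALSE], 1L, paste, collapse = ""),
           names(alignment))
}
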