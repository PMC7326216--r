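#' Remove PCR duplicates by joint fragment-end coordinates
#'
#' Reads are grouped by the joint key (reference, 5' start, 3' end,
#' strand); each group is one presumptive template molecule and exactly one
#' representative is retained. Keying on both ends distinguishes genuine
#' duplicates from distinct molecules that merely share a start, which
#' matters for the short, variably-sized fragments of degraded specimens.
#' The representative is the read with the most informative (fewest N)
#' bases, ties broken by input order. Strand is part of the key: reads on
#' opposite strands derive from different template strands and are never
#' duplicates of one another.
#'
#' @param reads data.frame of aligned reads mapped to a single reference.
#' @return list with `unique` (representative reads, input order,
#'   `duplicate = FALSE`), `n_unique` and `n_duplicates`
#'   (`n_unique + n_duplicates` equals the input count).
#' @export
mark_duplicates_start_end <- function(reads) {
  if (nrow(reads) == 0L)
    return(list(unique = reads, n_unique = 0L, n_duplicates = 0L))
  if (length(unique(reads$ref_id)) > 1L)
    stop("reads span multiple references; group by reference first")
  key <- paste(reads$start, reads$end, reads$strand, sep = ":")
  n_info <- nchar(reads$bases) -
    nchar(gsub("[ACGTacgt-]", "", reads$bases, perl = TRUE))
  # within each key keep the most informative read, earliest on ties
  ord <- order(key, -n_info, seq_len(nrow(reads)))
  first <- !duplicated(key[ord])
  keep_idx <- sort(ord[first])
  uniq <- reads[keep_idx, , drop = FALSE]
  uniq$duplicate <- FALSE
  rownames(uniq) <- NULL
  list(unique = uniq, n_unique = nrow(uniq),
       n_duplicates = nrow(reads) - nrow(uniq))
}
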