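#' Tile capture baits across a reference
#'
#' Baits of fixed length are anchored every `step` bp along the reference
#' (dense 2 bp tiling by default, as used on high-feature-count capture
#' arrays). If the final regular anchor does not reach the 3' end, one
#' extra bait is anchored at `L - bait_length` so the whole sequence is
#' covered.
#'
#' @param ref a `reference_sequence` (typically the reconstructed ancestral
#'   mitogenome).
#' @param bait_length probe length in bp (default 60).
#' @param step tiling step in bp (default 2).
#' @return an object of class `bait_set` with fields `source_id`,
#'   `bait_length`, `step` and `baits` (data.frame `start`, `sequence`).
#' @export
design_baits <- function(ref, bait_length = 60L, step = 2L) {
  stopifnot(inherits(ref, "reference_sequence"), step >= 1)
  L <- seq_length(ref)
  if (bait_length > L) stop("bait_length exceeds reference length")
  starts <- seq.int(0L, L - bait_length, by = step)
  if (starts[length(starts)] != L - bait_length)
    starts <- c(starts, L - bait_length)
  baits <- data.frame(start = as.integer(starts),
                      sequence = substring(ref$bases, starts + 1L,
                                           starts + bait_length))
  structure(list(source_id = ref$id, bait_length = as.integer(bait_length),
                 step = as.integer(step), baits = baits),
            class = "bait_set")
}

#' @export
print.bait_set <- function(x, ...) {
  cat(sprintf("<bait_set> %d baits of %d bp tiled at %d bp step from %s\n",
              nrow(x$baits), x$bait_length, x$step, x$source_id))
  invisible(x)
}

#' Best ungapped identity of fragments against a bait set
#'
#' For each query fragment, the maximum over all baits, both orientations
#' and all ungapped offsets of (matching positions / compared positions),
#' where `min(fragment length, bait length)` positions are compared.
#' Ambiguous bases (N) always count as mismatches. This drives the
#' simulator's capture-retention model and can score real reads against a
#' bait design.
#'
#' @param fragments character vector of fragment sequences.
#' @param baits a `bait_set`.
#' @return numeric vector of identities in \[0, 1\].
#' @export
best_bait_identity <- function(fragments, baits) {
  stopifnot(inherits(baits, "bait_set"))
  if (nrow(baits$baits) == 0L) stop("empty bait set")
  if (length(fragments) == 0L) return(numeric(0))
  if (any(!nzchar(fragments))) stop("fragments must be non-empty")
  .bait_identity_cpp(toupper(fragments), baits$baits$sequence)
}

#' Write a bait set as FASTA
#'
#' Headers follow the pattern `source_id:start-end` with 0-based half-open
#' coordinates.
#'
#' @param baits a `bait_set`.
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_baits_fasta <- function(baits, path) {
  stopifnot(inherits(baits, "bait_set"))
  xs <- Biostrings::DNAStringSet(baits$baits$sequence)
  names(xs) <- sprintf("%s:%d-%d", baits$source_id, baits$baits$start,
                       baits$baits$start + baits$bait_length)
  Biostrings::writeXStringSet(xs, path)
  invisible(path)
}
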