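#' Reference sequence container
#'
#' A named nucleotide sequence with an optional circularity flag and CDS
#' annotations, used as ancestor (bait source), descendant target, or
#' mapping reference. Genomes are treated as circular molecules linearized
#' at position 0: all downstream coordinates are linear and simulated
#' fragments never span the origin.
#'
#' @param id sequence name.
#' @param bases nucleotide string over A/C/G/T (N tolerated in consensus
#'   products, not in simulation references).
#' @param circular logical; biological circularity flag (bookkeeping only).
#' @param cds optional data.frame with columns `name`, `start`, `end`
#'   (0-based half-open), `strand` ("+"/"-").
#' @return an object of class `reference_sequence`.
#' @export
reference_sequence <- function(id, bases, circular = FALSE, cds = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  bases <- toupper(as.character(bases))
  if (!nzchar(bases)) stop("bases must be non-empty")
  L <- nchar(bases)
  if (!is.null(cds)) {
    cds <- as.data.frame(cds)
    stopifnot(all(c("name", "start", "end", "strand") %in% names(cds)))
    if (any(cds$start < 0L) || any(cds$end > L) || any(cds$start >= cds$end))
      stop("CDS intervals must lie within [0, sequence length)")
  }
  structure(list(id = id, bases = bases, circular = isTRUE(circular), cds = cds),
            class = "reference_sequence")
}

#' @export
print.reference_sequence <- function(x, ...) {
  cat(sprintf("<reference_sequence> %s: %d bp%s, %d CDS\n", x$id,
              nchar(x$bases), if (x$circular) " (circular)" else "",
              if (is.null(x$cds)) 0L else nrow(x$cds)))
  invisible(x)
}

seq_length <- function(ref) nchar(ref$bases)

#' Divergence track
#'
#' An ordered set of segments tiling a sequence, each with a target
#' substitution fraction. The default track emulates the divergence profile
#' of a descendant mitogenome relative to an ancestral bait sequence:
#' per-segment divergence spanning 0 to ~27% with a genome-wide mean of 12%.
#'
#' @param segments data.frame with columns `start`, `end` (0-based
#'   half-open, tiling the sequence) and `divergence` in \[0, 0.5\].
#' @return an object of class `divergence_track`.
#' @export
divergence_track <- function(segments) {
  segments <- as.data.frame(segments)
  stopifnot(all(c("start", "end", "divergence") %in% names(segments)))
  segments <- segments[order(segments$start), , drop = FALSE]
  if (nrow(segments) == 0L) stop("track must have at least one segment")
  if (any(segments$divergence < 0) || any(segments$divergence > 0.5))
    stop("divergence values must lie in [0, 0.5]")
  if (any(segments$start >= segments$end)) stop("empty track segment")
  if (nrow(segments) > 1L &&
      any(segments$end[-nrow(segments)] != segments$start[-1L]))
    stop("segments must tile the sequence without gaps or overlap")
  rownames(segments) <- NULL
  structure(list(segments = segments), class = "divergence_track")
}

#' Default divergence track: 0--27% across the analysis region, mean 12%
#'
#' Divides the central analysis region (by default 2--15 kb, the
#' protein-coding part of a mitogenome) into `n_segments` equal segments
#' whose divergence targets are a power-law grid from 0 to `max_divergence`
#' with discrete mean exactly `mean_divergence`; segment order interleaves
#' low and high values so every sub-region sees the full range. The flanks
#' outside the region (rRNA/control-region analog) are set to
#' `mean_divergence`, so the genome-wide mean equals the region mean.
#'
#' @param length genome length in bp.
#' @param max_divergence largest segment target.
#' @param mean_divergence genome-wide mean target.
#' @param n_segments number of graded segments inside the region.
#' @param region integer pair; analysis region (0-based half-open). Default
#'   scales the 2--15 kb region of a 16.5 kb mitogenome.
#' @return a `divergence_track`.
#' @export
default_divergence_track <- function(length = 16500L, max_divergence = 0.27,
                                     mean_divergence = 0.12, n_segments = 20L,
                                     region = NULL) {
  if (is.null(region))
    region <- c(floor(length * 2000 / 16500), floor(length * 15000 / 16500))
  stopifnot(region[1] >= 0, region[2] <= length, region[1] < region[2])
  u <- seq(0, 1, length.out = n_segments)
  # exponent giving discrete mean = mean_divergence on this grid
  a <- stats::uniroot(function(a) mean(u^a) * max_divergence - mean_divergence,
                      c(0.1, 10))$root
  lev <- max_divergence * u^a
  # interleave: lowest, highest, next-lowest, next-highest, ...
  half <- ceiling(n_segments / 2)
  ord <- as.vector(rbind(seq_len(half), n_segments + 1 - seq_len(half)))
  lev <- lev[ord[seq_len(n_segments)]]
  cuts <- round(seq(region[1], region[2], length.out = n_segments + 1))
  seg <- data.frame(start = cuts[-length(cuts)], end = cuts[-1],
                    divergence = lev)
  if (region[1] > 0)
    seg <- rbind(data.frame(start = 0, end = region[1],
                            divergence = mean_divergence), seg)
  if (region[2] < length)
    seg <- rbind(seg, data.frame(start = region[2], end = length,
                                 divergence = mean_divergence))
  divergence_track(seg)
}

#' Generate a random ancestral genome
#'
#' Bases are drawn i.i.d.: G/C with total probability `gc` (split equally),
#' A/T otherwise.
#'
#' @param length genome length in bp (default emulates a ~16.5 kb
#'   mitogenome).
#' @param gc GC fraction in \[0, 1\].
#' @param seed integer seed; identical inputs give identical sequences.
#' @param id sequence name.
#' @param circular circularity flag (genomes are linearized at position 0).
#' @return a `reference_sequence`.
#' @export
generate_ancestral <- function(length = 16500L, gc = 0.4, seed = 1L,
                               id = "ancestor", circular = TRUE) {
  if (length < 1) stop("length must be positive")
  if (gc < 0 || gc > 1) stop("gc must lie in [0, 1]")
  with_seed(seed, {
    p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
    bases <- sample(DNA_BASES, length, replace = TRUE, prob = p)
    reference_sequence(id, paste(bases, collapse = ""), circular = circular)
  })
}

#' Evolve a descendant genome along a divergence track
#'
#' Each site in a segment is substituted independently with the segment's
#' target probability; the substituted base is uniform over the three
#' alternatives. The returned truth map records every substituted site.
#' With `indel_rate > 0`, short deletions are additionally introduced and
#' the aligned ancestor/descendant rows (with `-` gap characters) are
#' returned; this mode exists to exercise window gap-flagging.
#'
#' @param ancestor a `reference_sequence`.
#' @param track a `divergence_track` tiling the ancestor.
#' @param seed integer seed.
#' @param indel_rate per-site deletion-start probability (default 0:
#'   substitutions only).
#' @param id name for the descendant sequence.
#' @return list with `descendant` (`reference_sequence`), `truth`
#'   (data.frame `pos` 0-based, `ref`, `alt`), and `alignment` (list of two
#'   equal-length rows `ancestor`/`descendant`; gap-free when
#'   `indel_rate = 0`).
#' @export
evolve_descendant <- function(ancestor, track, seed = 1L, indel_rate = 0,
                              id = "descendant") {
  stopifnot(inherits(ancestor, "reference_sequence"),
            inherits(track, "divergence_track"))
  L <- seq_length(ancestor)
  seg <- track$segments
  if (seg$start[1] != 0 || seg$end[nrow(seg)] != L)
    stop("track does not tile the sequence")
  with_seed(seed, {
    anc <- explode(ancestor$bases)
    des <- anc
    hit <- logical(L)
    for (i in seq_len(nrow(seg))) {
      idx <- (seg$start[i] + 1):seg$end[i]
      h <- runif(length(idx)) < seg$divergence[i]
      hit[idx[h]] <- TRUE
    }
    pos <- which(hit)
    if (length(pos)) {
      # uniform over the three non-ancestral bases
      shift <- sample.int(3L, length(pos), replace = TRUE)
      cur <- match(anc[pos], DNA_BASES)
      des[pos] <- DNA_BASES[((cur - 1L + shift) %% 4L) + 1L]
    }
    truth <- data.frame(pos = pos - 1L, ref = anc[pos], alt = des[pos])
    anc_row <- des_row <- NULL
    if (indel_rate > 0) {
      del_start <- which(runif(L) < indel_rate)
      del <- integer(0)
      for (s in del_start) del <- union(del, s:min(L, s + sample.int(4L, 1L)))
      des_aln <- des
      des_aln[del] <- "-"
      anc_row <- ancestor$bases
      des_row <- paste(des_aln, collapse = "")
      des <- des[-del]
    }
    descendant <- reference_sequence(id, paste(des, collapse = ""),
                                     circular = ancestor$circular)
    alignment <- if (is.null(anc_row))
      list(ancestor = ancestor$bases, descendant = descendant$bases)
    else list(ancestor = anc_row, descendant = des_row)
    list(descendant = descendant, truth = truth, alignment = alignment)
  })
}

#' Fragment length model for degraded libraries
#'
#' Lognormal fragment lengths (given as mean/SD on the natural scale)
#' truncated below at `min_length`, the read-length floor applied after
#' adapter trimming in degraded-specimen pipelines.
#'
#' @param n_fragments number of fragments to draw.
#' @param length_mean,length_sd mean and SD of fragment length in bp.
#' @param min_length smallest retained fragment (default 30 bp).
#' @return an object of class `fragment_model`.
#' @export
fragment_model <- function(n_fragments, length_mean = 70, length_sd = 25,
                           min_length = 30L) {
  stopifnot(n_fragments >= 0, min_length >= 1, length_mean >= min_length)
  structure(list(n_fragments = as.integer(n_fragments),
                 length_mean = length_mean, length_sd = length_sd,
                 min_length = as.integer(min_length)),
            class = "fragment_model")
}

lnorm_pars <- function(m, s) {
  sdlog <- sqrt(log(1 + (s / m)^2))
  c(meanlog = log(m) - sdlog^2 / 2, sdlog = sdlog)
}

#' Terminal deamination damage model
#'
#' Postmortem cytosine deamination is read as C->T substitutions near the
#' 5' end of degraded fragments. Position k (0-based from the 5' end) of a
#' read is converted with probability `rate_5prime * decay^k`.
#'
#' @param rate_5prime conversion probability at the first position.
#' @param decay per-position geometric decay factor in (0, 1\].
#' @param enabled logical; a disabled model is the identity.
#' @return an object of class `damage_model`.
#' @export
damage_model <- function(rate_5prime = 0.3, decay = 0.5, enabled = TRUE) {
  stopifnot(rate_5prime >= 0, rate_5prime <= 1, decay > 0, decay <= 1)
  structure(list(rate_5prime = rate_5prime, decay = decay,
                 enabled = isTRUE(enabled)),
            class = "damage_model")
}

#' Apply terminal deamination damage to fragment sequences
#'
#' @param bases character vector of fragment sequences in read (5'->3')
#'   orientation.
#' @param model a `damage_model`.
#' @param seed integer seed (optional).
#' @return character vector of damaged sequences.
#' @export
apply_damage <- function(bases, model, seed = NULL) {
  stopifnot(inherits(model, "damage_model"))
  if (!model$enabled || length(bases) == 0L) return(bases)
  with_seed(seed, {
    vapply(bases, function(s) {
      if (!nzchar(s)) return(s)
      v <- explode(s)
      k <- seq_along(v) - 1L
      conv <- v == "C" & runif(length(v)) < model$rate_5prime * model$decay^k
      v[conv] <- "T"
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
  })
}

#' Logistic capture-retention model
#'
#' Probability that a library fragment survives hybridisation capture as a
#' function of its best ungapped identity to any bait:
#' `p(identity) = p_max / (1 + exp(-slope * (identity - id_50)))`.
#' The defaults (p_max 0.95, id_50 0.80, slope 40) make retention
#' near-maximal below ~10% bait-to-fragment divergence and near zero above
#' ~20%, the qualitative enrichment pattern seen in ancestral-capture
#' experiments.
#'
#' @param p_max maximal retention probability, in (0, 1\].
#' @param id_50 identity at half-maximal retention, in (0, 1).
#' @param slope logistic steepness (dimensionless, per identity unit).
#' @return an object of class `capture_model`.
#' @export
capture_model <- function(p_max = 0.95, id_50 = 0.80, slope = 40) {
  stopifnot(p_max > 0, p_max <= 1, id_50 > 0, id_50 < 1, slope > 0)
  structure(list(p_max = p_max, id_50 = id_50, slope = slope),
            class = "capture_model")
}

#' Retention probability under a capture model
#' @param identity numeric vector of best bait identities.
#' @param model a `capture_model`.
#' @return numeric vector of retention probabilities.
#' @export
retention_prob <- function(identity, model) {
  model$p_max * plogis(model$slope * (identity - model$id_50))
}

#' Simulate a capture or shotgun sequencing library
#'
#' Fragments are drawn uniformly along the (linearized) genome with
#' truncated-lognormal lengths and random strand, optionally damaged at
#' their 5' ends, then retained according to the library mode: shotgun
#' libraries keep every fragment, capture libraries keep each fragment
#' independently with the logistic retention probability of its best bait
#' identity. Retained fragments receive `1 + Geometric(dup_rate)` PCR
#' copies. Every read carries its truth placement.
#'
#' @param genome a `reference_sequence` (the library's source individual).
#' @param frag a `fragment_model`.
#' @param damage a `damage_model` (use `damage_model(enabled = FALSE)` for
#'   undamaged libraries).
#' @param mode "shotgun" or "capture".
#' @param baits a `bait_set` (capture mode only).
#' @param capture a `capture_model` (capture mode only).
#' @param dup_rate PCR duplication rate in \[0, 1): expected extra copies
#'   per retained fragment is `dup_rate / (1 - dup_rate)`.
#' @param seed integer seed.
#' @param sample_id library name.
#' @param mapq mapping quality assigned to simulated reads.
#' @param target_content,molarity library quality descriptors carried to
#'   the pooling step.
#' @return an object of class `capture_library`: fields `sample_id`,
#'   `mode`, `reads` (data.frame of aligned reads), `target_content`,
#'   `molarity`, plus the per-fragment truth table `fragments` with the
#'   drawn placement, best bait identity (capture mode) and retention flag.
#' @export
simulate_library <- function(genome, frag, damage = damage_model(enabled = FALSE),
                             mode = c("shotgun", "capture"), baits = NULL,
                             capture = NULL, dup_rate = 0, seed = 1L,
                             sample_id = "S1", mapq = 60L,
                             target_content = 1, molarity = 1) {
  mode <- match.arg(mode)
  stopifnot(inherits(genome, "reference_sequence"),
            inherits(frag, "fragment_model"))
  if (dup_rate < 0 || dup_rate >= 1) stop("dup_rate must lie in [0, 1)")
  if (mode == "capture" && (is.null(baits) || is.null(capture)))
    stop("capture mode requires a bait set and a capture model")
  L <- seq_length(genome)
  n <- frag$n_fragments

  empty_reads <- data.frame(name = character(0), ref_id = character(0),
                            start = integer(0), end = integer(0),
                            strand = character(0), mapq = integer(0),
                            bases = character(0), duplicate = logical(0))
  if (n == 0L)
    return(structure(list(sample_id = sample_id, mode = mode,
                          reads = empty_reads, target_content = target_content,
                          molarity = molarity,
                          fragments = data.frame()), class = "capture_library"))

  with_seed(seed, {
    lp <- lnorm_pars(frag$length_mean, frag$length_sd)
    lens <- integer(0)
    while (length(lens) < n) {
      draw <- round(rlnorm(n, lp["meanlog"], lp["sdlog"]))
      lens <- c(lens, draw[draw >= frag$min_length & draw <= L])
    }
    lens <- as.integer(lens[seq_len(n)])
    starts <- as.integer(floor(runif(n) * (L - lens + 1)))
    strands <- sample(c("+", "-"), n, replace = TRUE)

    fwd <- substring(genome$bases, starts + 1L, starts + lens)
    read_seq <- fwd
    minus <- strands == "-"
    if (any(minus)) read_seq[minus] <- revcomp(fwd[minus])
    read_seq <- apply_damage(read_seq, damage)

    if (mode == "capture") {
      identity <- best_bait_identity(read_seq, baits)
      keep <- runif(n) < retention_prob(identity, capture)
    } else {
      identity <- rep(NA_real_, n)
      keep <- rep(TRUE, n)
    }

    fragments <- data.frame(fragment = sprintf("frag%06d", seq_len(n)),
                            start = starts, end = starts + lens,
                            strand = strands, identity = identity,
                            retained = keep)

    idx <- which(keep)
    copies <- if (dup_rate > 0)
      1L + rgeom(length(idx), prob = 1 - dup_rate) else rep(1L, length(idx))
    rid <- rep(idx, copies)
    copy_no <- sequence(copies)
    name <- ifelse(copy_no == 1L, fragments$fragment[rid],
                   sprintf("%s.dup%d", fragments$fragment[rid], copy_no - 1L))

    ref_seq <- read_seq
    if (any(minus)) ref_seq[minus] <- revcomp(read_seq[minus])

    reads <- data.frame(name = name, ref_id = genome$id,
                        start = starts[rid], end = starts[rid] + lens[rid],
                        strand = strands[rid],
                        mapq = as.integer(mapq), bases = ref_seq[rid],
                        duplicate = FALSE)
    structure(list(sample_id = sample_id, mode = mode, reads = reads,
                   target_content = target_content, molarity = molarity,
                   fragments = fragments), class = "capture_library")
  })
}

#' @export
print.capture_library <- function(x, ...) {
  cat(sprintf("<capture_library> %s (%s): %d reads from %d retained fragments\n",
              x$sample_id, x$mode, nrow(x$reads),
              if (nrow(x$fragments)) sum(x$fragments$retained) else 0L))
  invisible(x)
}
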