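# shared fixtures and brute-force oracles, built in code at test time

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_reads <- function(starts, ends, strand = "+", ref_id = "ref",
                       bases = NULL, mapq = 60L, name = NULL) {
  n <- length(starts)
  if (n == 0L)
    return(data.frame(name = character(0), ref_id = character(0),
                      start = integer(0), end = integer(0),
                      strand = character(0), mapq = integer(0),
                      bases = character(0), duplicate = logical(0)))
  if (is.null(bases))
    bases <- vapply(ends - starts, random_dna, character(1))
  data.frame(name = if (is.null(name)) sprintf("r%03d", seq_len(n)) else name,
             ref_id = ref_id, start = as.integer(starts),
             end = as.integer(ends),
             strand = rep_len(strand, n), mapq = rep_len(as.integer(mapq), n),
             bases = bases, duplicate = FALSE)
}

# random read set over a reference, for oracle comparisons
random_reads <- function(n, ref_length, len_range = c(5L, 20L), seed = 1L,
                         with_N = FALSE) {
  set.seed(seed)
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  starts <- vapply(lens, function(l) sample.int(ref_length - l + 1L, 1L) - 1L,
                   integer(1))
  bases <- vapply(lens, function(l) {
    alpha <- if (with_N) c("A", "C", "G", "T", "N") else c("A", "C", "G", "T")
    paste(sample(alpha, l, replace = TRUE), collapse = "")
  }, character(1))
  make_reads(starts, starts + lens, strand = sample(c("+", "-"), n, TRUE),
             bases = bases)
}

# position-by-position pileup recount (oracle for pileup())
oracle_pileup_counts <- function(reads, ref_length) {
  states <- c("A", "C", "G", "T", "-", "N")
  m <- matrix(0L, 6L, ref_length, dimnames = list(states, NULL))
  for (i in seq_len(nrow(reads))) {
    b <- strsplit(reads$bases[i], "")[[1]]
    for (k in seq_along(b)) {
      s <- match(b[k], states)
      if (is.na(s)) s <- 6L
      p <- reads$start[i] + k
      m[s, p] <- m[s, p] + 1L
    }
  }
  m
}

# per-window mean depth by direct per-position counting (oracle)
oracle_window_depth <- function(reads, windows, ref_length) {
  depth <- integer(ref_length)
  for (i in seq_len(nrow(reads))) {
    idx <- (reads$start[i] + 1L):reads$end[i]
    depth[idx] <- depth[idx] + 1L
  }
  vapply(seq_len(nrow(windows)), function(w)
    mean(depth[(windows$start[w] + 1L):windows$end[w]]), numeric(1))
}

# hash-based duplicate grouping (oracle for mark_duplicates_start_end)
oracle_dedup_keys <- function(reads) {
  unique(paste(reads$ref_id, reads$start, reads$end, reads$strand))
}

# column-by-column difference count (oracle for pairwise_differences)
oracle_pairwise_diff <- function(alignment) {
  n <- length(alignment)
  rows <- strsplit(alignment, "")
  D <- matrix(0L, n, n, dimnames = list(names(alignment), names(alignment)))
  for (i in seq_len(n))
    for (j in seq_len(n))
      D[i, j] <- sum(rows[[i]] != rows[[j]])
  D
}

# full (unbanded) Needleman-Wunsch/Gotoh global alignment score oracle;
# gap of length L costs gap_open + L * gap_extend
oracle_global_score <- function(a, b, match = 1, mismatch = -1,
                                gap_open = -5, gap_extend = -1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e18
  M <- X <- Y <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  for (j in seq_len(m) + 1L) Y[1, j] <- gap_open + (j - 1) * gap_extend
  for (i in seq_len(n) + 1L) X[i, 1] <- gap_open + (i - 1) * gap_extend
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      s <- if (av[i - 1] == bv[j - 1]) match else mismatch
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] + gap_open + gap_extend,
                     X[i - 1, j] + gap_extend,
                     Y[i - 1, j] + gap_open + gap_extend)
      Y[i, j] <- max(M[i, j - 1] + gap_open + gap_extend,
                     Y[i, j - 1] + gap_extend,
                     X[i, j - 1] + gap_open + gap_extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

# brute-force best bait identity (oracle for the packed C++ scan)
oracle_best_identity <- function(fragment, baits) {
  rc <- function(s) {
    v <- rev(strsplit(s, "")[[1]])
    paste(c(A = "T", C = "G", G = "C", T = "A", N = "N")[v], collapse = "")
  }
  f <- nchar(fragment)
  B <- baits$bait_length
  cmp <- min(f, B)
  best <- 0
  for (ori in c(fragment, rc(fragment))) {
    fv <- strsplit(ori, "")[[1]]
    for (bs in baits$baits$sequence) {
      bv <- strsplit(bs, "")[[1]]
      if (f >= B) {
        for (o in 0:(f - B)) {
          w <- fv[(o + 1):(o + B)]
          best <- max(best, sum(w == bv & w %in% c("A", "C", "G", "T")) / cmp)
        }
      } else {
        for (o in 0:(B - f)) {
          w <- bv[(o + 1):(o + f)]
          best <- max(best, sum(w == fv & w %in% c("A", "C", "G", "T")) / cmp)
        }
      }
    }
  }
  best
}

# small genome + bait fixture reused across tests
tiny_study <- function(L = 3000L, seed = 11L) {
  anc <- generate_ancestral(L, gc = 0.4, seed = seed)
  trk <- default_divergence_track(L, region = c(round(L * 0.12),
                                                round(L * 0.91)))
  evo <- evolve_descendant(anc, trk, seed = seed + 1L)
  list(ancestor = anc, track = trk, descendant = evo$descendant,
       truth = evo$truth, alignment = evo$alignment,
       baits = design_baits(anc))
}
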