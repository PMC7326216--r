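test_that("pileup tallies match read placements", {
  p0 <- pileup(make_reads(integer(0), integer(0))[0, ], 50)
  expect_true(all(p0$depth == 0L))

  r <- make_reads(10, 70, bases = random_dna(60, seed = 1))
  p <- pileup(r, 100)
  expect_true(all(p$depth[11:70] == 1L))
  expect_true(all(p$depth[-(11:70)] == 0L))

  expect_error(pileup(make_reads(90, 120, bases = random_dna(30, 2)), 100),
               "exceed")
})

test_that("pileup matches the per-position brute-force recount", {
  for (seed in c(3, 4)) {
    reads <- random_reads(200, 150, seed = seed, with_N = TRUE)
    p <- pileup(reads, 150)
    expect_identical(unname(p$counts), unname(oracle_pileup_counts(reads, 150)))
    # N never counts toward depth
    expect_identical(p$depth,
                     as.integer(colSums(p$counts[1:5, , drop = FALSE])))
  }
})

test_that("consensus applies the depth-3 / 90%-majority rule", {
  mk <- function(...) {
    # build a pileup for a single position from base counts
    counts <- matrix(0L, 6, 1, dimnames = list(c("A","C","G","T","-","N"), NULL))
    v <- c(...)
    counts[names(v), 1] <- v
    structure(list(counts = counts,
                   depth = sum(counts[1:5, 1])), class = "pileup")
  }
  pars <- consensus_params(3, 0.90)
  # depth 2, unanimous -> still N (below minimum depth)
  expect_identical(call_consensus(mk(A = 2L), pars)$calls, "N")
  # depth 10, 9 A + 1 G -> A (>= majority)
  expect_identical(call_consensus(mk(A = 9L, G = 1L), pars)$calls, "A")
  # depth 10, 8 A + 2 G -> N (mixed below majority: numt safeguard)
  expect_identical(call_consensus(mk(A = 8L, G = 2L), pars)$calls, "N")
  # deletions compete in the vote and are excised from the sequence
  cons <- call_consensus(mk(`-` = 5L), pars)
  expect_identical(cons$calls, "-")
  expect_identical(cons$sequence, "")
  # N reads do not dilute the majority: 3 A + 4 N -> A
  expect_identical(call_consensus(mk(A = 3L, N = 4L), pars)$calls, "A")
})

test_that("raising min_depth never converts an N into a call", {
  reads <- random_reads(300, 120, seed = 6)
  p <- pileup(reads, 120)
  prev <- call_consensus(p, consensus_params(1, 0.9))$calls
  for (md in 2:8) {
    cur <- call_consensus(p, consensus_params(md, 0.9))$calls
    expect_true(all(cur == prev | cur == "N"))
    prev <- cur
  }
})

test_that("completeness reports portion at depth and mean depth", {
  cons <- structure(list(ref_id = "x", calls = rep("A", 10),
                         sequence = paste(rep("A", 10), collapse = ""),
                         depth = rep(5L, 10)), class = "consensus_sequence")
  comp <- completeness(cons, consensus_params(3, 0.9))
  expect_equal(comp$fraction_at_min_depth, 1.0)
  expect_equal(comp$mean_depth, 5.0)

  cons$depth <- c(rep(5L, 5), rep(0L, 5))
  comp <- completeness(cons, consensus_params(3, 0.9))
  expect_equal(comp$fraction_at_min_depth, 0.5)
  expect_equal(comp$mean_depth, 2.5)

  # against a brute-force recount on a simulated library
  st <- tiny_study()
  lib <- simulate_library(st$descendant, fragment_model(800), seed = 7)
  p <- pileup(lib$reads, nchar(st$descendant$bases))
  cons <- call_consensus(p)
  depth <- integer(nchar(st$descendant$bases))
  for (i in seq_len(nrow(lib$reads)))
    depth[(lib$reads$start[i] + 1):lib$reads$end[i]] <-
      depth[(lib$reads$start[i] + 1):lib$reads$end[i]] + 1L
  comp <- completeness(cons)
  expect_equal(comp$fraction_at_min_depth, mean(depth >= 3))
  expect_equal(comp$mean_depth, mean(depth))
})

test_that("error-free deep simulation recovers the descendant exactly", {
  st <- tiny_study(L = 4000L, seed = 51)
  lib <- simulate_library(st$descendant, fragment_model(3000),
                          damage_model(enabled = FALSE), seed = 52)
  dd <- mark_duplicates_start_end(filter_mapq(lib$reads))
  cons <- call_consensus(pileup(dd$unique, 4000))
  truth <- strsplit(st$descendant$bases, "")[[1]]
  called <- cons$calls != "N"
  expect_gt(mean(called), 0.98)
  expect_identical(cons$calls[called], truth[called])
})

test_that("a 20% second haplotype is called N at every informative site", {
  st <- tiny_study(L = 2000L, seed = 61)
  # numt-like contaminant: a diverged copy of the target
  numt <- evolve_descendant(st$descendant,
                            divergence_track(data.frame(start = 0, end = 2000,
                                                        divergence = 0.10)),
                            seed = 62)
  lib <- simulate_library(st$descendant, fragment_model(2000),
                          damage_model(enabled = FALSE), seed = 63)
  spike <- simulate_library(numt$descendant, fragment_model(500),
                            damage_model(enabled = FALSE), seed = 64)
  spike$reads$name <- paste0("numt_", spike$reads$name)
  reads <- rbind(lib$reads, spike$reads)
  reads$ref_id <- "target"
  cons <- call_consensus(pileup(reads, 2000))
  # informative sites: numt differs from target and contaminant fraction
  # among covered reads is materially above 1 - majority
  p <- pileup(reads, 2000)
  ps <- pileup(spike$reads, 2000)
  site <- numt$truth$pos + 1L
  frac <- ps$depth[site] / pmax(p$depth[site], 1L)
  informative <- frac >= 0.15 & p$depth[site] >= 3L
  expect_gt(sum(informative), 20)
  expect_true(all(cons$calls[site[informative]] == "N"))
})

test_that("stop-codon screening uses the vertebrate mitochondrial code", {
  cds <- function(name, s) data.frame(name = name, start = 0L,
                                      end = nchar(s), strand = "+")
  # stop only at the terminus -> clean
  expect_equal(nrow(screen_stop_codons("ATGAAATAA", cds("ok", "ATGAAATAA"))), 0L)
  # internal TAA
  v <- screen_stop_codons("ATGTAAAAA", cds("bad", "ATGTAAAAA"))
  expect_equal(v$codon_index, 1L)
  # AGA is a stop in the vertebrate mitochondrial table (not in the
  # standard code)
  v <- screen_stop_codons("ATGAGAAAA", cds("mito", "ATGAGAAAA"))
  expect_equal(v$codon_index, 1L)
  expect_equal(nrow(screen_stop_codons(
    "ATGAGAAAA", cds("std", "ATGAGAAAA"),
    genetic_code = Biostrings::getGeneticCode("1"))), 0L)
  # minus strand translated after reverse complement:
  # revcomp(TTTTCTCAT) = ATGAGAAAA -> internal AGA stop at codon 1
  d <- data.frame(name = "m", start = 0L, end = 9L, strand = "-")
  v <- screen_stop_codons("TTTTCTCAT", d)
  expect_equal(v$codon_index, 1L)
  # codons with N are skipped and counted
  v <- screen_stop_codons("ATGTNAAAA", cds("amb", "ATGTNAAAA"))
  expect_equal(nrow(v), 0L)
  expect_equal(attr(v, "n_ambiguous"), 1L)
  # frame violation rejected
  expect_error(screen_stop_codons("ATGAA", data.frame(name = "x", start = 0L,
                                                      end = 5L, strand = "+")),
               "divisible")
})

test_that("strip_missing_columns keeps exactly the complete columns", {
  aln <- c(s1 = "ACGT", s2 = "ANGT", s3 = "ACGT")
  out <- strip_missing_columns(aln)
  expect_identical(unname(out), c("AGT", "AGT", "AGT"))

  clean <- c(a = "ACGT", b = "TGCA")
  expect_identical(strip_missing_columns(clean), clean)

  allbad <- c(a = "NC", b = "CN")
  expect_warning(out <- strip_missing_columns(allbad), "missing")
  expect_identical(unname(out), c("", ""))

  expect_error(strip_missing_columns(c("ACGT", "ACG")), "ragged")
})
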