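test_that("generate_ancestral respects length, composition and seed", {
  # forced composition at gc = 1
  g1 <- generate_ancestral(500, gc = 1.0, seed = 1)
  expect_equal(nchar(g1$bases), 500L)
  expect_true(grepl("^[GC]+$", g1$bases))

  # seeded determinism
  a <- generate_ancestral(2000, gc = 0.4, seed = 7)
  b <- generate_ancestral(2000, gc = 0.4, seed = 7)
  expect_identical(a$bases, b$bases)
  expect_false(identical(a$bases,
                         generate_ancestral(2000, gc = 0.4, seed = 8)$bases))

  # GC fraction within 3 binomial SD of the target
  g <- generate_ancestral(10000, gc = 0.4, seed = 3)
  obs <- mean(strsplit(g$bases, "")[[1]] %in% c("G", "C"))
  expect_lt(abs(obs - 0.4), 3 * sqrt(0.4 * 0.6 / 10000))

  expect_error(generate_ancestral(0, 0.4, 1), "positive")
  expect_error(generate_ancestral(100, 1.2, 1), "gc")
})

test_that("divergence track validates tiling and default track hits its targets", {
  expect_error(divergence_track(data.frame(start = c(0, 10), end = c(5, 20),
                                           divergence = 0.1)),
               "tile")
  expect_error(divergence_track(data.frame(start = 0, end = 10,
                                           divergence = 0.6)),
               "0.5")
  trk <- default_divergence_track(16500)
  seg <- trk$segments
  expect_equal(seg$start[1], 0)
  expect_equal(seg$end[nrow(seg)], 16500)
  expect_equal(max(seg$divergence), 0.27, tolerance = 1e-9)
  # length-weighted genome mean is the headline 12%
  expect_equal(with(seg, sum(divergence * (end - start))) / 16500, 0.12,
               tolerance = 0.002)
})

test_that("evolve_descendant realizes segment targets and a faithful truth map", {
  anc <- generate_ancestral(12000, gc = 0.45, seed = 5)
  trk <- divergence_track(data.frame(start = c(0, 4000, 8000),
                                     end = c(4000, 8000, 12000),
                                     divergence = c(0, 0.12, 0.27)))
  evo <- evolve_descendant(anc, trk, seed = 9)
  av <- strsplit(anc$bases, "")[[1]]
  dv <- strsplit(evo$descendant$bases, "")[[1]]

  # zero-rate segment untouched
  expect_identical(av[1:4000], dv[1:4000])

  # realized per-segment divergence within 3 binomial SD of the target
  for (i in 2:3) {
    idx <- (trk$segments$start[i] + 1):trk$segments$end[i]
    p <- trk$segments$divergence[i]
    expect_lt(abs(mean(av[idx] != dv[idx]) - p), 3 * sqrt(p * (1 - p) / 4000))
  }

  # truth map is exactly the mismatch set
  expect_identical(evo$truth$pos, which(av != dv) - 1L)
  expect_identical(evo$truth$ref, av[evo$truth$pos + 1L])
  expect_identical(evo$truth$alt, dv[evo$truth$pos + 1L])
  expect_true(all(evo$truth$ref != evo$truth$alt))

  # mis-tiling track rejected
  short <- divergence_track(data.frame(start = 0, end = 100, divergence = 0.1))
  expect_error(evolve_descendant(anc, short, 1), "tile")
})

test_that("genome-wide divergence of the default track is ~12%", {
  anc <- generate_ancestral(16500, gc = 0.4, seed = 2)
  evo <- evolve_descendant(anc, default_divergence_track(16500), seed = 3)
  p <- nrow(evo$truth) / 16500
  # binomial-scale slack around the 12% design mean
  expect_lt(abs(p - 0.12), 3 * sqrt(0.12 * 0.88 / 16500) + 0.005)
})

test_that("apply_damage converts 5' cytosines at the modelled rate", {
  frags <- rep("CCCCCCCCCC", 5)
  expect_identical(apply_damage(frags, damage_model(enabled = FALSE)), frags)

  # saturating rate with no decay converts every C
  out <- apply_damage("CACGTC", damage_model(1, 1, TRUE), seed = 1)
  expect_identical(out, "TATGTT")

  # first-position conversion frequency within 3 SD of rate_5prime
  n <- 10000
  out <- apply_damage(rep("CAAA", n), damage_model(0.3, 0.5, TRUE), seed = 4)
  hits <- mean(substr(out, 1, 1) == "T")
  expect_lt(abs(hits - 0.3), 3 * sqrt(0.3 * 0.7 / n))
  # second C position (if present) would convert at rate * decay
  out2 <- apply_damage(rep("CCAA", n), damage_model(0.3, 0.5, TRUE), seed = 5)
  hits2 <- mean(substr(out2, 2, 2) == "T")
  expect_lt(abs(hits2 - 0.15), 3 * sqrt(0.15 * 0.85 / n))
})

test_that("simulate_library honours mode, retention and duplication", {
  st <- tiny_study()
  empty <- simulate_library(st$descendant, fragment_model(0), seed = 1)
  expect_equal(nrow(empty$reads), 0L)

  expect_error(simulate_library(st$descendant, fragment_model(10),
                                mode = "capture", seed = 1),
               "bait")
  expect_error(simulate_library(st$descendant, fragment_model(10),
                                dup_rate = 1, seed = 1),
               "dup_rate")

  # shotgun retains every fragment; reads match their truth placement
  lib <- simulate_library(st$descendant, fragment_model(400), seed = 2)
  expect_equal(nrow(lib$reads), 400L)
  expect_true(all(lib$fragments$retained))
  ref <- st$descendant$bases
  expect_identical(lib$reads$bases,
                   substring(ref, lib$reads$start + 1, lib$reads$end))
  expect_true(all(nchar(lib$reads$bases) >= 30))

  # seeded determinism is byte-identical
  lib2 <- simulate_library(st$descendant, fragment_model(400), seed = 2)
  expect_identical(lib, lib2)

  # PCR duplicates: copies share coordinates with their parent fragment
  libd <- simulate_library(st$descendant, fragment_model(500), dup_rate = 0.4,
                           seed = 3)
  expect_gt(nrow(libd$reads), 500)
  dups <- grepl("\\.dup", libd$reads$name)
  parent <- sub("\\.dup.*", "", libd$reads$name)
  key <- paste(libd$reads$start, libd$reads$end, libd$reads$strand)
  expect_identical(key[dups], key[match(parent[dups], libd$reads$name)])
})

test_that("capture retention matches the closed-form probability on the bait source", {
  # fragments drawn from the bait source itself: identity 1 everywhere
  anc <- generate_ancestral(4000, gc = 0.4, seed = 21)
  baits <- design_baits(anc)
  cm <- capture_model(p_max = 0.95, id_50 = 0.80, slope = 40)
  n <- 4000
  lib <- simulate_library(anc, fragment_model(n),
                          damage_model(enabled = FALSE), mode = "capture",
                          baits = baits, capture = cm, seed = 6)
  p <- 0.95 * stats::plogis(40 * (1 - 0.80))
  obs <- mean(lib$fragments$retained)
  expect_lt(abs(obs - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("shotgun coverage is Poisson-flat across windows", {
  anc <- generate_ancestral(8000, gc = 0.4, seed = 30)
  n <- 50000
  lib <- simulate_library(anc, fragment_model(n), seed = 31)
  reads <- lib$reads
  w <- 60L
  starts <- seq(500L, 7000L, by = w)
  # number of fragments overlapping each window ~ Poisson(mu)
  mu <- n * (mean(reads$end - reads$start) + w - 1) / 8000
  overl <- vapply(starts, function(s)
    sum(reads$end > s & reads$start < s + w), numeric(1))
  z <- abs(overl - mu) / sqrt(mu)
  expect_gt(mean(z < 3), 0.99)
  expect_true(all(z < 5))
})

test_that("capture retention is non-increasing in source divergence", {
  st <- tiny_study(L = 6000L, seed = 41)
  cm <- capture_model()
  lib <- simulate_library(st$descendant, fragment_model(20000),
                          damage_model(enabled = FALSE), mode = "capture",
                          baits = st$baits, capture = cm, seed = 42)
  fr <- lib$fragments
  seg <- st$track$segments
  # realized (not target) per-segment divergence: short segments can
  # realize noticeably off their binomial target, and retention follows
  # what was actually simulated
  av <- strsplit(st$ancestor$bases, "")[[1]]
  dv <- strsplit(st$descendant$bases, "")[[1]]
  seg$realized <- vapply(seq_len(nrow(seg)), function(i) {
    idx <- (seg$start[i] + 1):seg$end[i]
    mean(av[idx] != dv[idx])
  }, numeric(1))
  # attribute only fragments lying fully inside one segment, so boundary
  # straddling does not smear adjacent divergence levels
  seg_lo <- findInterval(fr$start, seg$start)
  seg_hi <- findInterval(fr$end - 1L, seg$start)
  inside <- seg_lo == seg_hi
  bin <- floor(seg$realized[seg_lo[inside]] / 0.02)
  ret <- tapply(fr$retained[inside], bin, mean)
  nbin <- tapply(fr$retained[inside], bin, length)
  div <- as.numeric(names(ret))
  ord <- order(div)
  keep <- as.numeric(nbin[ord]) >= 100
  r <- as.numeric(ret[ord])[keep]
  se <- (sqrt(pmax(r * (1 - r), 0.002)) /
           sqrt(as.numeric(nbin[ord])[keep]))
  # monotone non-increasing within sampling error
  expect_true(all(diff(r) <= 3 * (se[-1] + se[-length(se)])))
  # and globally strongly decreasing
  expect_lt(stats::cor(div[keep], r, method = "spearman"), -0.8)
})
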