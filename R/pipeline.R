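#' Default pipeline configuration
#'
#' One nested list drives the whole study analog; every stage reads its
#' parameters from here and nowhere else. See the methods vignette for the
#' rationale behind each default.
#'
#' @param seed master seed; all stage seeds are derived from it.
#' @return nested configuration list.
#' @export
default_config <- function(seed = 42L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      genome_length = 16500L,
      gc = 0.4,
      track = list(max_divergence = 0.27, mean_divergence = 0.12,
                   n_segments = 20L),
      fragment = list(n_capture = 20000L, n_shotgun = 20000L,
                      length_mean = 70, length_sd = 25, min_length = 30L),
      damage = list(rate_5prime = 0.3, decay = 0.5, enabled = TRUE),
      capture = list(p_max = 0.95, id_50 = 0.80, slope = 40),
      dup_rate = 0.15,
      samples = list(n_samples = 8L, n_matriline_b = 4L,
                     between_divergence = 0.005, within_divergence = 5e-4,
                     n_fragments = 4000L, dup_rate = 0.05)
    ),
    analysis = list(
      min_depth = 3L, majority = 0.90, min_mapq = 30L,
      bait_length = 60L, bait_step = 2L,
      window = 60L, step = 30L, region = c(2000L, 15000L),
      bin_width = 0.02, n_boot = 100L
    )
  )
}

#' Read a pipeline configuration from YAML
#'
#' Values present in the file override the defaults; everything else keeps
#' its default.
#'
#' @param path YAML file with optional top-level keys `seed`, `simulate`,
#'   `analysis`.
#' @return configuration list.
#' @export
read_config <- function(path) {
  usr <- yaml::read_yaml(path)
  cfg <- default_config(if (!is.null(usr$seed)) usr$seed else 42L)
  merge_list <- function(base, over) {
    for (nm in names(over)) {
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge_list(base[[nm]], over[[nm]]) else over[[nm]]
    }
    base
  }
  merge_list(cfg, usr)
}

uniform_track <- function(length, divergence) {
  divergence_track(data.frame(start = 0L, end = length,
                              divergence = divergence))
}

# simulate -> filter -> dedup -> pileup -> consensus for one library
process_library <- function(lib, ref_length, min_mapq, params) {
  filt <- filter_mapq(lib$reads, min_mapq)
  dd <- mark_duplicates_start_end(filt)
  pile <- pileup(dd$unique, ref_length)
  cons <- call_consensus(pile, params, ref_id = lib$sample_id)
  comp <- completeness(cons, params)
  list(library = lib, unique_reads = dd$unique, n_raw = nrow(lib$reads),
       n_unique = dd$n_unique, n_duplicates = dd$n_duplicates,
       pileup = pile, consensus = cons, completeness = comp)
}

#' Run the full capture-study analog
#'
#' Executes the stages in fixed order: simulate ancestor and descendant,
#' design baits, simulate capture and shotgun libraries, MAPQ-filter,
#' deduplicate, pileup and consensus, sliding-window divergence/depth
#' analysis with capture-model recovery, and a per-sample haplotype
#' network over two simulated matrilines. Rerunning with the same
#' configuration reproduces all outputs exactly.
#'
#' @param config configuration list from [default_config()] or
#'   [read_config()].
#' @param outdir optional directory; when given, intermediate artifacts
#'   (FASTA, SAM, BED and tab-separated tables) are written there.
#' @param quiet suppress stage progress messages.
#' @return an object of class `run_report`; see the fields below.
#'   * `samples`: per-library recovery rows (raw/unique read counts,
#'     portion at >= min_depth, mean depth)
#'   * `windows`, `response`, `trend`: the divergence analysis
#'   * `fit`: read-level capture-model recovery; `fit_windows`: the
#'     window-ratio fit (attenuated; see the methods vignette)
#'   * `network`: the haplotype network with its matriline partition
#'   * `truth`: generator ground truth for validation
#' @export
run_capture_study <- function(config = default_config(), outdir = NULL,
                              quiet = FALSE) {
  t0 <- Sys.time()
  say <- function(...) if (!quiet) message(sprintf(...))
  sim <- config$simulate
  an <- config$analysis
  seed <- config$seed
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)
  art <- function(name) if (is.null(outdir)) NULL else file.path(outdir, name)

  say("[1/7] simulating ancestor and descendant (L = %d)", sim$genome_length)
  ancestor <- generate_ancestral(sim$genome_length, sim$gc,
                                 seed = subseed(seed, 1L))
  track <- default_divergence_track(sim$genome_length,
                                    max_divergence = sim$track$max_divergence,
                                    mean_divergence = sim$track$mean_divergence,
                                    n_segments = sim$track$n_segments)
  evo <- evolve_descendant(ancestor, track, seed = subseed(seed, 2L))
  descendant <- evo$descendant
  if (!is.null(outdir)) {
    write_fasta(list(ancestor, descendant), art("genomes.fasta"))
    write_tsv(evo$truth, art("substitutions.tsv"))
  }

  say("[2/7] designing baits (%d bp, %d bp step)", an$bait_length, an$bait_step)
  baits <- design_baits(ancestor, an$bait_length, an$bait_step)
  if (!is.null(outdir)) write_baits_fasta(baits, art("baits.fasta"))

  say("[3/7] simulating libraries (capture %d, shotgun %d fragments)",
      sim$fragment$n_capture, sim$fragment$n_shotgun)
  dmg <- damage_model(sim$damage$rate_5prime, sim$damage$decay,
                      sim$damage$enabled)
  cmod <- capture_model(sim$capture$p_max, sim$capture$id_50,
                        sim$capture$slope)
  frag_cap <- fragment_model(sim$fragment$n_capture, sim$fragment$length_mean,
                             sim$fragment$length_sd, sim$fragment$min_length)
  frag_sg <- fragment_model(sim$fragment$n_shotgun, sim$fragment$length_mean,
                            sim$fragment$length_sd, sim$fragment$min_length)
  lib_cap <- simulate_library(descendant, frag_cap, dmg, mode = "capture",
                              baits = baits, capture = cmod,
                              dup_rate = sim$dup_rate,
                              seed = subseed(seed, 3L), sample_id = "capture")
  lib_sg <- simulate_library(descendant, frag_sg, dmg, mode = "shotgun",
                             dup_rate = sim$dup_rate,
                             seed = subseed(seed, 4L), sample_id = "shotgun")
  if (!is.null(outdir)) {
    write_sam(lib_cap$reads, descendant, art("capture.sam"))
    write_sam(lib_sg$reads, descendant, art("shotgun.sam"))
  }

  say("[4/7] filtering, deduplicating, calling consensus")
  cpar <- consensus_params(an$min_depth, an$majority)
  L <- seq_length(descendant)
  pc <- process_library(lib_cap, L, an$min_mapq, cpar)
  ps <- process_library(lib_sg, L, an$min_mapq, cpar)
  samples <- data.frame(
    sample_id = c(pc$library$sample_id, ps$library$sample_id),
    mode = c("capture", "shotgun"),
    n_reads = c(pc$n_raw, ps$n_raw),
    n_unique = c(pc$n_unique, ps$n_unique),
    n_duplicates = c(pc$n_duplicates, ps$n_duplicates),
    fraction_at_min_depth = c(pc$completeness$fraction_at_min_depth,
                              ps$completeness$fraction_at_min_depth),
    mean_depth = c(pc$completeness$mean_depth, ps$completeness$mean_depth))
  if (!is.null(outdir)) {
    write_fasta(setNames(pc$consensus$sequence, "capture_consensus"),
                art("consensus.fasta"))
    write_depth_bedgraph(pc$consensus, art("consensus_depth.bedgraph"))
    write_tsv(samples, art("samples.tsv"))
  }

  say("[5/7] sliding-window divergence and depth analysis")
  wpar <- window_params(an$window, an$step,
                        pmin(an$region, sim$genome_length), an$bin_width)
  win <- window_identity(evo$alignment$ancestor, evo$alignment$descendant,
                         wpar)
  win <- window_depth(win, pc$unique_reads, L, which = "capture")
  win <- window_depth(win, ps$unique_reads, L, which = "shotgun")
  resp <- divergence_response(win, wpar)
  trend <- loess_trend((win$divergence[!win$has_gap]),
                       (win$depth_capture / pmax(win$depth_shotgun,
                                                 1e-9))[!win$has_gap])
  if (!is.null(outdir)) {
    write_bed(win, descendant$id, art("windows.bed"))
    write_tsv(resp, art("divergence_response.tsv"))
  }

  say("[6/7] recovering the capture model (%d bootstrap replicates)",
      an$n_boot)
  fit <- fit_capture_model_reads(pc$unique_reads, ps$unique_reads, baits,
                                 bin_width = an$bin_width, n_boot = an$n_boot,
                                 seed = subseed(seed, 5L))
  fit_windows <- fit_capture_model(win, bin_width = an$bin_width,
                                   n_boot = an$n_boot,
                                   seed = subseed(seed, 5L))

  say("[7/7] matriline simulation and haplotype network (%d samples)",
      sim$samples$n_samples)
  ns <- sim$samples$n_samples
  nb <- sim$samples$n_matriline_b
  founder_b <- evolve_descendant(
    descendant, uniform_track(L, sim$samples$between_divergence),
    seed = subseed(seed, 6L), id = "founderB")$descendant
  matriline <- rep(c("A", "B"), c(ns - nb, nb))
  cons_seqs <- character(ns)
  sample_ids <- sprintf("PL%02d", seq_len(ns))
  for (i in seq_len(ns)) {
    founder <- if (matriline[i] == "A") descendant else founder_b
    hap <- evolve_descendant(founder,
                             uniform_track(L, sim$samples$within_divergence),
                             seed = subseed(seed, 10L + i),
                             id = sample_ids[i])$descendant
    libi <- simulate_library(hap,
                             fragment_model(sim$samples$n_fragments,
                                            sim$fragment$length_mean,
                                            sim$fragment$length_sd,
                                            sim$fragment$min_length),
                             dmg, mode = "shotgun",
                             dup_rate = sim$samples$dup_rate,
                             seed = subseed(seed, 30L + i),
                             sample_id = sample_ids[i])
    pi <- process_library(libi, L, an$min_mapq, cpar)
    cons_seqs[i] <- paste(pi$consensus$calls, collapse = "")
  }
  names(cons_seqs) <- sample_ids
  aln <- strip_missing_columns(cons_seqs)
  net <- haplotype_network(aln)
  if (!is.null(outdir))
    write_network(net, art("network_edges.tsv"), art("matrilines.tsv"))

  report <- structure(list(
    config = config,
    samples = samples,
    windows = win,
    response = resp,
    trend = trend,
    fit = fit,
    fit_windows = fit_windows,
    network = net,
    truth = list(track = track, substitutions = evo$truth,
                 capture_fragments = lib_cap$fragments,
                 shotgun_fragments = lib_sg$fragments,
                 matriline = setNames(matriline, sample_ids)),
    objects = list(ancestor = ancestor, descendant = descendant,
                   baits = baits, capture = pc, shotgun = ps),
    elapsed = as.numeric(difftime(Sys.time(), t0, units = "secs"))),
    class = "run_report")
  if (!is.null(outdir)) {
    rep_df <- data.frame(quantity = c("mean_window_divergence",
                                      "max_window_divergence",
                                      "fitted_id_50", "fitted_slope"),
                         value = c(mean(win$divergence, na.rm = TRUE),
                                   max(win$divergence, na.rm = TRUE),
                                   fit$estimate["id_50"],
                                   fit$estimate["slope"]))
    write_tsv(rep_df, art("report_summary.tsv"))
  }
  say("done in %.1f s", report$elapsed)
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat("Per-library recovery:\n")
  print(x$samples, row.names = FALSE)
  cat(sprintf("\nWindows: %d (%d gap-flagged); divergence mean %.3f, max %.3f\n",
              nrow(x$windows), sum(x$windows$has_gap),
              mean(x$windows$divergence, na.rm = TRUE),
              max(x$windows$divergence, na.rm = TRUE)))
  print(x$fit)
  if (!is.null(x$network$partition))
    cat(sprintf("Matriline split (%d differences): {%s} | {%s}\n",
                x$network$split_weight,
                paste(x$network$partition[[1]], collapse = ","),
                paste(x$network$partition[[2]], collapse = ",")))
  invisible(x)
}
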