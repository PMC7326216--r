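#' Sliding-window parameters
#'
#' @param window window length in bp (default 60).
#' @param step step between window starts in bp (default 30).
#' @param region analysis region (0-based half-open); the default 2--15 kb
#'   restricts a ~16.5 kb mitogenome to its protein-coding part, avoiding
#'   the indel-rich rRNAs and control region. Windows are clipped to lie
#'   entirely inside the region.
#' @param bin_width divergence bin width for the response table.
#' @return an object of class `window_params`.
#' @export
window_params <- function(window = 60L, step = 30L, region = c(2000L, 15000L),
                          bin_width = 0.02) {
  stopifnot(step >= 1, step <= window, length(region) == 2L,
            region[1] < region[2], bin_width > 0, bin_width <= 0.1)
  structure(list(window = as.integer(window), step = as.integer(step),
                 region = as.integer(region), bin_width = bin_width),
            class = "window_params")
}

#' Banded global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment restricted to a diagonal band, suitable
#' for collinear mitogenomes. A gap of length L costs
#' `gap_open + L * gap_extend`. If the optimal path touches the band
#' boundary (or the length difference exceeds the band), the band is
#' widened automatically with a warning and the alignment recomputed.
#' Identity is matched columns over columns compared, excluding columns in
#' terminal gap runs.
#'
#' @param a,b nucleotide strings or `reference_sequence` objects.
#' @param band_width band half-width in bp (default 200).
#' @param match,mismatch,gap_open,gap_extend scoring scheme.
#' @return an object of class `pairwise_alignment`: `aligned_a`,
#'   `aligned_b` (equal-length rows with `-` gaps), `score`, `identity`,
#'   `band_width` actually used.
#' @export
align_banded <- function(a, b, band_width = 200L, match = 1, mismatch = -1,
                         gap_open = -5, gap_extend = -1) {
  if (inherits(a, "reference_sequence")) a <- a$bases
  if (inherits(b, "reference_sequence")) b <- b$bases
  a <- toupper(a); b <- toupper(b)
  band <- max(band_width, abs(nchar(a) - nchar(b)) + 10L)
  if (band > band_width)
    warning("band widened to ", band, " to accommodate the length difference")
  repeat {
    res <- .banded_align_cpp(a, b, band, match, mismatch, gap_open, gap_extend)
    # does the optimal path touch the band boundary?
    ga <- explode(res$aligned_a) != "-"
    gb <- explode(res$aligned_b) != "-"
    offset <- cumsum(ga) - cumsum(gb)
    if (max(abs(offset)) < band) break
    band <- band * 2L
    warning("alignment path hit the band boundary; widening band to ", band)
  }
  aa <- explode(res$aligned_a)
  bb <- explode(res$aligned_b)
  ncol_aln <- length(aa)
  lead <- 0L
  while (lead < ncol_aln && (aa[lead + 1L] == "-" || bb[lead + 1L] == "-"))
    lead <- lead + 1L
  trail <- ncol_aln
  while (trail > lead && (aa[trail] == "-" || bb[trail] == "-"))
    trail <- trail - 1L
  core <- if (trail > lead) seq.int(lead + 1L, trail) else integer(0)
  ident <- if (length(core))
    mean(aa[core] == bb[core] & aa[core] %in% DNA_BASES) else NA_real_
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, identity = ident, band_width = band),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %d columns, score %.1f, identity %.4f\n",
              nchar(x$aligned_a), x$score, x$identity))
  invisible(x)
}

#' Sliding-window identity between two aligned sequences
#'
#' Windows are anchored at the region start and advance by `step` while
#' `start + window <= region end`. Identity in a window is matches over
#' the columns where both rows are unambiguous bases; windows containing
#' any gap or N are flagged (`has_gap`) so they can be excluded downstream.
#'
#' @param a,b equal-length (pre-aligned) sequences, strings or a
#'   `pairwise_alignment` passed as `a`.
#' @param params a `window_params`.
#' @return data.frame of window statistics: `start`, `end`, `identity`,
#'   `divergence`, `has_gap`, and placeholder depth columns
#'   `depth_capture`/`depth_shotgun` (NA until filled by
#'   [window_depth()]).
#' @export
window_identity <- function(a, b = NULL, params = window_params()) {
  if (inherits(a, "pairwise_alignment")) {
    b <- a$aligned_b
    a <- a$aligned_a
  }
  stopifnot(is.character(a), is.character(b), nchar(a) == nchar(b))
  L <- nchar(a)
  reg <- pmin(params$region, L)
  if (reg[1] >= L) stop("region lies outside the sequence")
  if (params$window > reg[2] - reg[1]) stop("window longer than region")
  starts <- seq.int(reg[1], reg[2] - params$window, by = params$step)
  va <- explode(toupper(a))
  vb <- explode(toupper(b))
  good <- va %in% DNA_BASES & vb %in% DNA_BASES
  eq <- va == vb & good
  cum_eq <- cumsum(eq)
  cum_good <- cumsum(good)
  n_eq <- cum_eq[starts + params$window] - c(0, cum_eq)[starts + 1L]
  n_good <- cum_good[starts + params$window] - c(0, cum_good)[starts + 1L]
  identity <- ifelse(n_good > 0, n_eq / n_good, NA_real_)
  data.frame(start = starts, end = starts + params$window,
             identity = identity, divergence = 1 - identity,
             has_gap = n_good < params$window,
             depth_capture = NA_real_, depth_shotgun = NA_real_)
}

# per-position coverage from read intervals, as a numeric vector
coverage_vector <- function(reads, ref_length) {
  if (nrow(reads) == 0L) return(numeric(ref_length))
  add <- tabulate(reads$start + 1L, nbins = ref_length)
  rem <- tabulate(reads$end + 1L, nbins = ref_length)
  cumsum(add - rem)
}

#' Fill per-window mean sequencing depth
#'
#' For each window, the mean over its positions of the per-position read
#' depth (equivalently, window base coverage divided by window length).
#'
#' @param windows data.frame from [window_identity()].
#' @param reads data.frame of aligned reads on the same reference.
#' @param ref_length reference length in bp.
#' @param which which depth column to fill: "capture" or "shotgun".
#' @return `windows` with the chosen depth column filled.
#' @export
window_depth <- function(windows, reads, ref_length,
                         which = c("capture", "shotgun")) {
  which <- match.arg(which)
  if (nrow(windows) && (any(windows$start < 0) || any(windows$end > ref_length)))
    stop("windows outside reference")
  cov <- coverage_vector(reads, ref_length)
  ccov <- c(0, cumsum(cov))
  md <- (ccov[windows$end + 1L] - ccov[windows$start + 1L]) /
    (windows$end - windows$start)
  windows[[paste0("depth_", which)]] <- md
  windows
}

#' Divergence-response table: enrichment efficiency by divergence bin
#'
#' Bins gap-free windows by bait-to-target divergence and reports, per bin,
#' the proportion of windows, the proportion of capture and of shotgun
#' sequencing depth, and their ratio (the enrichment response). A shotgun
#' library should be flat in divergence; a capture library concentrates its
#' depth in the low-divergence bins.
#'
#' @param windows data.frame with `divergence`, `has_gap`, `depth_capture`,
#'   `depth_shotgun` filled.
#' @param params a `window_params` (its `bin_width` sets the bins).
#' @param min_windows bins with fewer windows trigger a warning.
#' @return data.frame with `bin_lo`, `bin_hi`, `n_windows`,
#'   `prop_windows`, `prop_capture`, `prop_shotgun`, `ratio` (NA where the
#'   bin has no shotgun depth).
#' @export
divergence_response <- function(windows, params = window_params(),
                                min_windows = 5L) {
  w <- windows[!windows$has_gap & !is.na(windows$divergence), , drop = FALSE]
  if (nrow(w) == 0L) stop("all windows are gap-flagged")
  bin <- floor(pmin(w$divergence, 1 - 1e-12) / params$bin_width)
  lv <- sort(unique(bin))
  n <- as.integer(table(factor(bin, levels = lv)))
  cap <- tapply(w$depth_capture, factor(bin, levels = lv), sum)
  sg <- tapply(w$depth_shotgun, factor(bin, levels = lv), sum)
  cap[is.na(cap)] <- 0
  sg[is.na(sg)] <- 0
  out <- data.frame(bin_lo = lv * params$bin_width,
                    bin_hi = (lv + 1) * params$bin_width,
                    n_windows = n,
                    prop_windows = n / sum(n),
                    prop_capture = if (sum(cap) > 0) cap / sum(cap) else cap * 0,
                    prop_shotgun = if (sum(sg) > 0) sg / sum(sg) else sg * 0)
  out$ratio <- ifelse(out$prop_shotgun > 0,
                      out$prop_capture / out$prop_shotgun, NA_real_)
  rownames(out) <- NULL
  if (any(out$n_windows < min_windows))
    warning(sum(out$n_windows < min_windows),
            " divergence bin(s) contain fewer than ", min_windows, " windows")
  out
}

#' Local-regression trendline (tricube-weighted local linear fit)
#'
#' Smooths y over x with degree-1 loess (tricube weights, direct surface),
#' evaluated on a regular grid. Local linear fitting reproduces a straight
#' line exactly when the inputs are collinear.
#'
#' @param x,y numeric vectors (at least 5 points).
#' @param span loess span in (0, 1\].
#' @param grid evaluation points (default: 101 points over `range(x)`).
#' @return data.frame with `x` (grid) and `fitted`.
#' @export
loess_trend <- function(x, y, span = 0.5, grid = NULL) {
  stopifnot(length(x) == length(y), span > 0, span <= 1)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5L) stop("need at least 5 points for a local fit")
  if (is.null(grid)) grid <- seq(min(x), max(x), length.out = 101L)
  fit <- loess(y ~ x, span = span, degree = 1, family = "gaussian",
               surface = "direct",
               control = loess.control(statistics = "none"))
  data.frame(x = grid, fitted = predict(fit, newdata = data.frame(x = grid)))
}

#' Fit the logistic capture-retention curve to windowed data
#'
#' Least-squares fit of `ratio = A / (1 + exp(-slope * (identity - id_50)))`
#' to per-window capture/shotgun depth ratios, recovering the retention
#' midpoint and steepness that the simulator (or a real capture
#' experiment) imposed. The amplitude A absorbs `p_max` and the libraries'
#' relative sequencing effort, so only its product is identifiable from
#' depth ratios. Uncertainty is assessed by a window-resampling bootstrap.
#'
#' @param windows data.frame with `identity`, `has_gap`, `depth_capture`,
#'   `depth_shotgun` filled.
#' @param bin_width used only to check that windows span at least 3
#'   divergence bins with nonzero shotgun depth.
#' @param n_boot bootstrap replicates (default 200).
#' @param conf confidence level for percentile intervals.
#' @param seed integer seed for the bootstrap resampling.
#' @return an object of class `capture_fit`: `estimate` (named vector
#'   `id_50`, `slope`, `amplitude`), `ci` (matrix of percentile bounds),
#'   `n_windows`, `boot` (replicate estimates).
#' @export
fit_capture_model <- function(windows, bin_width = 0.02, n_boot = 200L,
                              conf = 0.95, seed = NULL) {
  w <- windows[!windows$has_gap & !is.na(windows$identity) &
                 !is.na(windows$depth_shotgun) & windows$depth_shotgun > 0, ,
               drop = FALSE]
  if (nrow(w) < 5L) stop("too few usable windows")
  d <- data.frame(id = w$identity, y = w$depth_capture / w$depth_shotgun)
  bins <- unique(floor((1 - d$id) / bin_width))
  if (length(bins) < 3L)
    stop("degenerate spread: windows span fewer than 3 divergence bins")
  if (sd(d$id) < 1e-9 || diff(range(d$y)) < 1e-8 * max(abs(d$y), 1))
    stop("degenerate spread: no divergence response to fit")

  fit1 <- function(dd) {
    # midpoint start: identity at which y first drops below half its max
    ymax <- max(dd$y)
    below <- dd$id[dd$y < ymax / 2]
    start <- list(A = ymax,
                  id50 = if (length(below)) max(below) else stats::median(dd$id),
                  slope = 20)
    f <- minpack.lm::nlsLM(y ~ A * plogis(slope * (id - id50)),
                           data = dd, start = start,
                           lower = c(A = 0, id50 = 0.01, slope = 0.1),
                           upper = c(A = Inf, id50 = 0.999, slope = 1000),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    coef(f)[c("id50", "slope", "A")]
  }
  est <- fit1(d)
  boot <- NULL
  ci <- NULL
  if (n_boot > 0L) {
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(i) {
        idx <- sample.int(nrow(d), nrow(d), replace = TRUE)
        tryCatch(fit1(d[idx, , drop = FALSE]),
                 error = function(e) c(id50 = NA_real_, slope = NA_real_,
                                       A = NA_real_))
      }, numeric(3)))
    })
    al <- (1 - conf) / 2
    ci <- apply(boot, 2L, quantile, probs = c(al, 1 - al), na.rm = TRUE)
    colnames(ci) <- c("id_50", "slope", "amplitude")
  }
  structure(list(estimate = setNames(unname(est),
                                     c("id_50", "slope", "amplitude")),
                 ci = ci, n_windows = nrow(d), boot = boot),
            class = "capture_fit")
}

#' Fit the capture-retention curve from read-level identities
#'
#' Scores every unique read of the capture and shotgun libraries against
#' the bait set, bins reads by their own best bait identity, and fits the
#' logistic retention curve to the per-bin capture/shotgun read-count
#' ratio. Because the shotgun library samples the pre-capture identity
#' distribution and both libraries are scored on the identical identity
#' scale that hybridisation acts on, this ratio estimates the retention
#' curve without the attenuation that affects the window-ratio fit
#' ([fit_capture_model()]), whose window identities are a noisy, offset
#' proxy for the per-fragment identity. With equal sequencing effort the
#' amplitude estimates `p_max` directly.
#'
#' @param capture_reads,shotgun_reads data.frames of unique (deduplicated)
#'   aligned reads from the capture and shotgun libraries of the same
#'   individual.
#' @param baits the `bait_set` used for the capture.
#' @param bin_width identity bin width (default 0.02).
#' @param min_shotgun bins with fewer shotgun reads are dropped (default
#'   20).
#' @param n_boot bootstrap replicates over reads (default 200).
#' @param conf confidence level for percentile intervals.
#' @param seed integer seed for the bootstrap.
#' @return a `capture_fit` (see [fit_capture_model()]).
#' @export
fit_capture_model_reads <- function(capture_reads, shotgun_reads, baits,
                                    bin_width = 0.02, min_shotgun = 20L,
                                    n_boot = 200L, conf = 0.95, seed = NULL) {
  stopifnot(nrow(capture_reads) > 0L, nrow(shotgun_reads) > 0L)
  idc <- best_bait_identity(capture_reads$bases, baits)
  ids <- best_bait_identity(shotgun_reads$bases, baits)
  make_d <- function(ic, is) {
    bc <- floor(pmin(ic, 1 - 1e-12) / bin_width)
    bs <- floor(pmin(is, 1 - 1e-12) / bin_width)
    lv <- sort(unique(bs))
    ns <- as.integer(table(factor(bs, levels = lv)))
    nc <- as.integer(table(factor(bc, levels = lv)))
    keep <- ns >= min_shotgun
    data.frame(id = (lv[keep] + 0.5) * bin_width, y = nc[keep] / ns[keep])
  }
  d <- make_d(idc, ids)
  if (nrow(d) < 4L)
    stop("degenerate spread: too few populated identity bins")
  if (diff(range(d$y)) < 1e-8 * max(abs(d$y), 1))
    stop("degenerate spread: no identity response to fit")
  fit1 <- function(dd) {
    ymax <- max(dd$y)
    below <- dd$id[dd$y < ymax / 2]
    f <- minpack.lm::nlsLM(y ~ A * plogis(slope * (id - id50)),
                           data = dd,
                           start = list(A = ymax,
                                        id50 = if (length(below)) max(below)
                                               else stats::median(dd$id),
                                        slope = 20),
                           lower = c(A = 0, id50 = 0.01, slope = 0.1),
                           upper = c(A = Inf, id50 = 0.999, slope = 1000),
                           control = minpack.lm::nls.lm.control(maxiter = 200))
    coef(f)[c("id50", "slope", "A")]
  }
  est <- fit1(d)
  boot <- NULL
  ci <- NULL
  if (n_boot > 0L) {
    boot <- with_seed(seed, {
      t(vapply(seq_len(n_boot), function(i) {
        bc <- sample(idc, length(idc), replace = TRUE)
        bs <- sample(ids, length(ids), replace = TRUE)
        dd <- make_d(bc, bs)
        tryCatch(fit1(dd), error = function(e)
          c(id50 = NA_real_, slope = NA_real_, A = NA_real_))
      }, numeric(3)))
    })
    al <- (1 - conf) / 2
    ci <- apply(boot, 2L, quantile, probs = c(al, 1 - al), na.rm = TRUE)
    colnames(ci) <- c("id_50", "slope", "amplitude")
  }
  structure(list(estimate = setNames(unname(est),
                                     c("id_50", "slope", "amplitude")),
                 ci = ci, n_windows = nrow(d), boot = boot),
            class = "capture_fit")
}

#' @export
print.capture_fit <- function(x, ...) {
  cat(sprintf("<capture_fit> id_50 = %.3f, slope = %.1f, amplitude = %.2f (%d support points)\n",
              x$estimate["id_50"], x$estimate["slope"], x$estimate["amplitude"],
              x$n_windows))
  if (!is.null(x$ci)) {
    cat(sprintf("  id_50 CI [%.3f, %.3f], slope CI [%.1f, %.1f]\n",
                x$ci[1, "id_50"], x$ci[2, "id_50"],
                x$ci[1, "slope"], x$ci[2, "slope"]))
  }
  invisible(x)
}

#' Plot the divergence-response table
#'
#' Bars show the proportion of windows per divergence bin; curves show the
#' proportion of capture and shotgun depth (local-regression trendlines).
#'
#' @param response data.frame from [divergence_response()].
#' @param path optional output file (PDF); when NULL the plot object is
#'   returned.
#' @return a ggplot object, invisibly.
#' @export
plot_divergence_response <- function(response, path = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting")
  mid <- (response$bin_lo + response$bin_hi) / 2
  df <- data.frame(divergence = mid, windows = response$prop_windows,
                   capture = response$prop_capture,
                   shotgun = response$prop_shotgun)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = divergence)) +
    ggplot2::geom_col(ggplot2::aes(y = windows), fill = "grey70",
                      width = 0.8 * (response$bin_hi - response$bin_lo)[1]) +
    ggplot2::geom_smooth(ggplot2::aes(y = capture, colour = "capture"),
                         method = "loess", formula = y ~ x, se = FALSE,
                         span = 0.5) +
    ggplot2::geom_smooth(ggplot2::aes(y = shotgun, colour = "shotgun"),
                         method = "loess", formula = y ~ x, se = FALSE,
                         span = 0.5) +
    ggplot2::scale_colour_manual(NULL, values = c(capture = "darkorange",
                                                  shotgun = "black")) +
    ggplot2::labs(x = "sequence divergence from bait",
                  y = "proportion (windows / depth)") +
    ggplot2::theme_minimal()
  if (!is.null(path)) ggplot2::ggsave(path, p, width = 7, height = 4)
  invisible(p)
}
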