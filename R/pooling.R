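#' Pre-capture pooling plan
#'
#' When several libraries are enriched on one array, libraries rich in
#' target molecules can overwhelm poorer ones. Pooling inversely to the
#' product of target content (the on-target fraction estimated from
#' low-level shotgun sequencing) and molarity equalizes the expected
#' number of on-target molecules each library contributes:
#' `volume_fraction_i` proportional to `1 / (target_content_i * molarity_i)`,
#' so `content * molarity * volume` is identical across libraries.
#'
#' An optional per-library cap (default 0.5) prevents one very poor
#' library from dominating the pool; capped libraries are reported with a
#' warning since exact equalization no longer holds for them.
#'
#' @param libraries data.frame with columns `sample_id`, `target_content`
#'   (fraction in (0, 1\]) and `molarity` (relative concentration, > 0).
#' @param cap maximum volume fraction per library (default 0.5; use 1 to
#'   disable).
#' @return an object of class `pool_plan`: the input table extended with
#'   `volume_fraction` (summing to 1) and `expected_on_target` (each
#'   library's share of expected on-target molecules, summing to 1).
#' @export
plan_pool <- function(libraries, cap = 0.5) {
  libraries <- as.data.frame(libraries)
  stopifnot(all(c("sample_id", "target_content", "molarity") %in%
                  names(libraries)),
            cap > 0, cap <= 1)
  bad <- libraries$target_content <= 0 | libraries$molarity <= 0 |
    is.na(libraries$target_content) | is.na(libraries$molarity)
  if (any(bad))
    stop("unpoolable library (non-positive target content or molarity): ",
         paste(libraries$sample_id[bad], collapse = ", "))
  n <- nrow(libraries)
  if (n * cap < 1)
    stop("cap too small: ", n, " libraries cannot sum to 1 at cap ", cap)
  w <- 1 / (libraries$target_content * libraries$molarity)
  frac <- w / sum(w)
  capped <- logical(n)
  # water-filling: fix capped libraries at the cap, re-normalize the rest
  repeat {
    over <- frac > cap + 1e-12 & !capped
    if (!any(over)) break
    capped <- capped | over
    rest <- 1 - sum(capped) * cap
    frac[capped] <- cap
    frac[!capped] <- w[!capped] / sum(w[!capped]) * rest
  }
  if (any(capped))
    warning("volume cap applied to: ",
            paste(libraries$sample_id[capped], collapse = ", "),
            "; equal representation no longer exact for capped libraries")
  on_target <- libraries$target_content * libraries$molarity * frac
  out <- cbind(libraries,
               volume_fraction = frac,
               expected_on_target = on_target / sum(on_target))
  class(out) <- c("pool_plan", "data.frame")
  out
}

#' Read a pooling input table
#'
#' Tab-separated table with a header line and columns `sample_id`,
#' `target_content`, `molarity`.
#'
#' @param path input file.
#' @return data.frame.
#' @export
read_pool_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
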