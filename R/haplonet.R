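#' Collapse identical sequences into haplotypes
#'
#' @param alignment named character vector of equal-length sequences
#'   (typically consensus sequences after [strip_missing_columns()]).
#' @return list with `haplotypes` (named character vector, one per
#'   distinct sequence; each haplotype is named after its
#'   lexicographically smallest member), `multiplicity` (integer vector)
#'   and `members` (list of sample names per haplotype).
#' @export
collapse_haplotypes <- function(alignment) {
  stopifnot(length(alignment) >= 1L)
  if (is.null(names(alignment)))
    names(alignment) <- sprintf("S%d", seq_along(alignment))
  groups <- split(names(alignment), factor(alignment, levels = unique(alignment)))
  reps <- vapply(groups, function(g) sort(g)[1], character(1))
  ord <- order(reps)
  haps <- setNames(names(groups)[ord], reps[ord])  # seq string, named by rep
  list(haplotypes = setNames(unname(haps), names(haps)),
       multiplicity = setNames(lengths(groups)[ord], reps[ord]),
       members = setNames(unname(groups[ord]), reps[ord]))
}

#' Pairwise difference matrix for an alignment
#'
#' Entry (i, j) is the number of columns at which rows i and j differ. The
#' alignment is assumed pre-processed with [strip_missing_columns()], so
#' every column is informative in every row.
#'
#' @param alignment named character vector of equal-length sequences.
#' @return symmetric integer matrix with zero diagonal.
#' @export
pairwise_differences <- function(alignment) {
  n <- length(alignment)
  if (length(unique(nchar(alignment))) != 1L)
    stop("ragged alignment: unequal row lengths")
  m <- matrix(explode(alignment), nrow = nchar(alignment[1]))
  D <- matrix(0L, n, n, dimnames = list(names(alignment), names(alignment)))
  if (n > 1L)
    for (i in seq_len(n - 1L))
      for (j in (i + 1L):n)
        D[i, j] <- D[j, i] <- sum(m[, i] != m[, j])
  D
}

#' Build a minimum spanning haplotype network
#'
#' Kruskal's algorithm over the pairwise-difference matrix with
#' deterministic tie-breaking (ascending weight, then lexicographic node
#' pair). The deepest split -- the matriline partition in a mitochondrial
#' dataset -- is obtained by deleting the single largest edge of the
#' spanning tree; by the MST cut property this edge separates the two most
#' divergent haplotype clusters.
#'
#' @param D symmetric difference matrix with zero diagonal (named
#'   dimnames).
#' @param multiplicity optional integer vector of haplotype multiplicities
#'   (defaults to 1 each).
#' @return an object of class `haplotype_network`: `nodes` (data.frame
#'   `id`, `multiplicity`), `edges` (data.frame `from`, `to`, `weight`,
#'   spanning-tree edges), `partition` (list of two character vectors, or
#'   NULL for a single node), `split_weight`.
#' @export
build_msn <- function(D, multiplicity = NULL) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  if (is.null(rownames(D)))
    rownames(D) <- colnames(D) <- sprintf("H%d", seq_len(nrow(D)))
  if (!isTRUE(all.equal(unname(D), unname(t(D)))) || any(diag(D) != 0))
    stop("difference matrix must be symmetric with zero diagonal")
  ids <- rownames(D)
  n <- length(ids)
  if (is.null(multiplicity)) multiplicity <- setNames(rep(1L, n), ids)
  nodes <- data.frame(id = ids, multiplicity = as.integer(multiplicity[ids]))
  if (n < 2L)
    return(structure(list(nodes = nodes,
                          edges = data.frame(from = character(0),
                                             to = character(0),
                                             weight = numeric(0)),
                          partition = NULL, split_weight = NA_real_),
                     class = "haplotype_network"))
  # candidate edges sorted by (weight, from, to); from < to lexicographically
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  from <- pmin(ids[pairs[, 1]], ids[pairs[, 2]])
  to <- pmax(ids[pairs[, 1]], ids[pairs[, 2]])
  wt <- D[pairs]
  ord <- order(wt, from, to)
  parent <- setNames(seq_len(n), ids)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  sel <- integer(0)
  for (k in ord) {
    ri <- find(match(from[k], ids))
    rj <- find(match(to[k], ids))
    if (ri != rj) {
      parent[ri] <- rj
      sel <- c(sel, k)
      if (length(sel) == n - 1L) break
    }
  }
  edges <- data.frame(from = from[sel], to = to[sel], weight = wt[sel])
  # deepest split: remove the largest edge (ties: lexicographically largest
  # pair among the maxima, a fixed deterministic choice)
  emax <- which(edges$weight == max(edges$weight))
  cut <- emax[order(edges$from[emax], edges$to[emax])]
  cut <- cut[length(cut)]
  keep <- edges[-cut, , drop = FALSE]
  comp <- setNames(seq_len(n), ids)
  for (k in seq_len(nrow(keep))) {
    ci <- comp[keep$from[k]]
    cj <- comp[keep$to[k]]
    comp[comp == cj] <- ci
  }
  side_a <- ids[comp == comp[edges$from[cut]]]
  side_b <- ids[comp == comp[edges$to[cut]]]
  structure(list(nodes = nodes, edges = edges,
                 partition = list(sort(side_a), sort(side_b)),
                 split_weight = edges$weight[cut]),
            class = "haplotype_network")
}

#' @export
print.haplotype_network <- function(x, ...) {
  cat(sprintf("<haplotype_network> %d haplotypes (%d samples), %d edges\n",
              nrow(x$nodes), sum(x$nodes$multiplicity), nrow(x$edges)))
  if (!is.null(x$partition))
    cat(sprintf("  deepest split: %d differences, {%s} | {%s}\n",
                x$split_weight, paste(x$partition[[1]], collapse = ","),
                paste(x$partition[[2]], collapse = ",")))
  invisible(x)
}

#' Haplotype network from an alignment
#'
#' Convenience wrapper: collapse identical sequences, compute pairwise
#' differences, and build the minimum spanning network.
#'
#' @param alignment named character vector of equal-length sequences with
#'   no missing data (apply [strip_missing_columns()] first).
#' @return a `haplotype_network`.
#' @export
haplotype_network <- function(alignment) {
  col <- collapse_haplotypes(alignment)
  D <- pairwise_differences(col$haplotypes)
  net <- build_msn(D, multiplicity = col$multiplicity)
  net$members <- col$members
  net
}

#' Write a haplotype network as edge list and partition tables
#'
#' @param net a `haplotype_network`.
#' @param edge_path tab-separated edge list (from, to, weight).
#' @param partition_path optional two-column table (node, matriline).
#' @return `edge_path`, invisibly.
#' @export
write_network <- function(net, edge_path, partition_path = NULL) {
  write_tsv(net$edges, edge_path)
  if (!is.null(partition_path) && !is.null(net$partition)) {
    part <- data.frame(node = c(net$partition[[1]], net$partition[[2]]),
                       matriline = rep(c("A", "B"),
                                       lengths(net$partition)))
    write_tsv(part, partition_path)
  }
  invisible(edge_path)
}
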