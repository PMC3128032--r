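# Constrained Max-k-Cut: partition the haplotype vertices into k clusters
# maximizing the total soft-edge weight across clusters, with every hard edge
# forced onto the cut.  Solved by a randomized greedy algorithm (best of
# `restarts` independent runs); a brute-force enumerator serves as the exact
# oracle for small instances.

new_partition <- function(graph, k, assignment) {
  nv <- graph$n_vertices
  assignment <- as.integer(assignment)
  if (length(assignment) != nv || anyNA(assignment)) {
    stop("every vertex must be assigned a cluster")
  }
  if (any(assignment < 1L | assignment > k)) {
    stop("cluster labels must lie in 1..k")
  }
  if (nrow(graph$hard) > 0L) {
    viol <- assignment[graph$hard[, 1L]] == assignment[graph$hard[, 2L]]
    if (any(viol)) stop("partition violates a hard edge")
  }
  structure(list(k = as.integer(k),
                 assignment = assignment,
                 cut_value = cut_weight(graph, assignment)),
            class = "Partition")
}

#' @export
print.Partition <- function(x, ...) {
  cat("Partition into k =", x$k, "clusters, cut value", x$cut_value, "\n")
  invisible(x)
}

#' Soft cut weight of a cluster assignment
#'
#' Sum of soft-edge weights over vertex pairs placed in different clusters.
#' Hard-edge weights never contribute (hard edges act purely as constraints).
#'
#' @param graph A `CNVGraph`.
#' @param assignment Integer cluster label per vertex (no `NA`).
#' @return Non-negative cut weight.
#' @export
cut_weight <- function(graph, assignment) {
  stopifnot(inherits(graph, "CNVGraph"))
  if (length(assignment) != graph$n_vertices || anyNA(assignment)) {
    stop("cut_weight: every vertex must be assigned")
  }
  across <- outer(assignment, assignment, `!=`)
  sum(graph$soft[across]) / 2
}

# One randomized greedy run (consumes the current RNG stream).
greedy_maxkcut_once <- function(graph, k) {
  nv <- graph$n_vertices
  soft <- graph$soft
  partner <- graph$partner
  assignment <- rep(NA_integer_, nv)

  init <- sample.int(nv, k)          # k distinct seed vertices, one per cluster
  assignment[init] <- seq_len(k)

  for (v in shuffle(setdiff(seq_len(nv), init))) {
    placed <- which(!is.na(assignment))
    w <- soft[v, placed]
    in_cluster <- vapply(seq_len(k),
                         function(j) sum(w[assignment[placed] == j]),
                         numeric(1L))
    gain <- sum(w) - in_cluster      # cut added by joining each cluster
    p <- partner[v]
    if (!is.na(p) && !is.na(assignment[p])) {
      gain[assignment[p]] <- -Inf    # hard edge: partner's cluster forbidden
    }
    # ties (several clusters give equal gain) go to the lowest cluster index;
    # this keeps zero-distance (identical) haplotypes together instead of
    # scattering them, while seeds and vertex order stay randomized per run
    assignment[v] <- which.max(gain)
  }
  new_partition(graph, k, assignment)
}

#' Randomized greedy algorithm for constrained Max-k-Cut
#'
#' Each run randomly picks `k` distinct vertices to seed the clusters, then
#' assigns the remaining vertices in random order, each to the cluster that
#' maximizes the soft cut without violating a hard edge (equal-gain ties go to
#' the lowest cluster index, which keeps identical haplotypes together).  The
#' best of `restarts` independent runs is returned; for
#' `k > 2` the result is guaranteed within a factor `(k - 2)/(k - 1)` of the
#' optimum.
#'
#' @param graph A `CNVGraph`.
#' @param k Number of clusters, `2 <= k <= ` vertex count.
#' @param restarts Number of independent randomized runs (default 10).
#' @param seed Optional integer seed; the master seed spawns one sub-seed per
#'   restart, so results are reproducible and the best-of-r sequence is
#'   monotone in `restarts`.
#' @return A `Partition` with fields `k`, `assignment`, `cut_value`.
#' @export
greedy_constrained_maxkcut <- function(graph, k, restarts = 10L, seed = NULL) {
  stopifnot(inherits(graph, "CNVGraph"), is_count(k), is_count(restarts),
            restarts >= 1)
  if (k < 2L) stop("k must be >= 2")
  if (k > graph$n_vertices) stop("k exceeds the number of vertices")
  seeds <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    part <- with_local_seed(seeds[r], greedy_maxkcut_once(graph, k))
    if (is.null(best) || part$cut_value > best$cut_value) best <- part
  }
  best
}

#' Exact constrained Max-k-Cut by enumeration (test oracle)
#'
#' Enumerates every k-labeling respecting the hard edges.  Refuses instances
#' with more than 12 vertices or more than ~4 million labelings.
#'
#' @inheritParams greedy_constrained_maxkcut
#' @return The optimal `Partition`.
#' @export
brute_force_maxkcut <- function(graph, k) {
  stopifnot(inherits(graph, "CNVGraph"), is_count(k))
  nv <- graph$n_vertices
  if (k < 2L) stop("k must be >= 2")
  if (k > nv) stop("k exceeds the number of vertices")
  if (nv > 12L) stop("brute_force_maxkcut: refusing > 12 vertices")
  if (k^nv > 4.2e6) stop("brute_force_maxkcut: labeling space too large")

  labs <- as.matrix(expand.grid(rep(list(seq_len(k)), nv),
                                KEEP.OUT.ATTRS = FALSE))
  keep <- rep(TRUE, nrow(labs))
  if (nrow(graph$hard) > 0L) {
    for (e in seq_len(nrow(graph$hard))) {
      keep <- keep & (labs[, graph$hard[e, 1L]] != labs[, graph$hard[e, 2L]])
    }
  }
  labs <- labs[keep, , drop = FALSE]  # always non-empty: hard edges are
                                      # vertex-disjoint and k >= 2
  cut <- numeric(nrow(labs))
  for (i in seq_len(nv - 1L)) {
    for (j in seq(i + 1L, nv)) {
      w <- graph$soft[i, j]
      if (w > 0) cut <- cut + w * (labs[, i] != labs[, j])
    }
  }
  new_partition(graph, k, labs[which.max(cut), ])
}
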