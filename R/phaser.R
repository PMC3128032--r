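# Per-CNV orchestration: loop over the number of clusters k, keep the best
# cluster/value combination by satisfied-constraint count, then run the
# randomized adjustment pass until every individual's sum constraint holds
# (or is provably unsatisfiable under the frozen cluster values).

#' Maximum number of clusters to explore
#'
#' With observed totals `2, 3, 4` the possible chromosome-specific copies
#' range over `0..4`, so up to five clusters are explored.  The value is
#' capped at the vertex count (two haplotypes per individual) and floored at
#' two.
#'
#' @param totals Non-empty integer totals observed at the CNV.
#' @param n_vertices Optional cap (2 x number of individuals).
#' @return `k_max`.
#' @examples
#' max_clusters(c(2, 3, 4))  # 5
#' @export
max_clusters <- function(totals, n_vertices = NULL) {
  totals <- totals[!is.na(totals)]
  if (length(totals) == 0L) stop("max_clusters: no non-missing totals")
  k <- max(totals) + 1L
  if (!is.null(n_vertices)) k <- min(k, n_vertices)
  max(as.integer(k), 2L)
}

#' Adjust the clustering for individuals with violated constraints
#'
#' Cluster values are frozen; for each individual whose haplotype pair does
#' not sum to its total, every re-placement of its two haplotypes into valued
#' clusters whose values sum to the total is enumerated and the one with the
#' maximum soft cut is taken.  The whole pass is repeated `restarts` times
#' with random individual order and the best final configuration (most
#' individuals satisfied, then largest cut) is kept.  Individuals for whom no
#' value pair sums to their total are flagged unresolved (`-1, -1`).
#'
#' @param graph The `CNVGraph` for the CNV.
#' @param partition The selected `Partition`.
#' @param assignment The `CSPAssignment` giving each cluster's copy value.
#' @param totals Integer totals per individual (vertex order `2i-1, 2i`).
#' @param restarts Randomized passes (default 10).
#' @param seed Optional integer seed.
#' @return List with the adjusted `partition`, integer matrix `copies`
#'   (columns copy_hapA/copy_hapB, `-1` for unresolved), logical `satisfied`
#'   per individual, and `unresolved` indices.
#' @export
adjust_unsatisfied <- function(graph, partition, assignment, totals,
                               restarts = 10L, seed = NULL) {
  stopifnot(inherits(graph, "CNVGraph"), inherits(partition, "Partition"),
            inherits(assignment, "CSPAssignment"))
  n_ind <- length(totals)
  values <- values_to_na(assignment$values)
  valued <- which(!is.na(values))

  ind_sat <- function(assign) {
    va <- values[assign[2L * seq_len(n_ind) - 1L]]
    vb <- values[assign[2L * seq_len(n_ind)]]
    !is.na(va) & !is.na(vb) & (va + vb == totals)
  }
  # candidate ordered cluster pairs (j1, j2) with values summing to T; an odd
  # T always yields distinct clusters, so hard edges stay cut
  candidates_for <- function(T) {
    if (length(valued) == 0L) return(NULL)
    grid <- expand.grid(j1 = valued, j2 = valued)
    grid <- grid[values[grid$j1] + values[grid$j2] == T, , drop = FALSE]
    if (nrow(grid) == 0L) NULL else grid
  }

  unsat0 <- which(!ind_sat(partition$assignment))
  if (length(unsat0) == 0L) {
    copies <- cbind(copy_hapA = values[partition$assignment[2L * seq_len(n_ind) - 1L]],
                    copy_hapB = values[partition$assignment[2L * seq_len(n_ind)]])
    return(list(partition = partition, copies = copies,
                satisfied = rep(TRUE, n_ind), unresolved = integer()))
  }

  cand_cache <- lapply(unique(totals[unsat0]), candidates_for)
  names(cand_cache) <- as.character(unique(totals[unsat0]))

  seeds <- derive_seeds(seed, restarts)
  best <- NULL
  for (r in seq_len(restarts)) {
    res <- with_local_seed(seeds[r], {
      assign <- partition$assignment
      unresolved <- integer()
      for (i in shuffle(unsat0)) {
        cand <- cand_cache[[as.character(totals[i])]]
        if (is.null(cand)) {
          unresolved <- c(unresolved, i)
          next
        }
        v1 <- 2L * i - 1L
        v2 <- 2L * i
        cuts <- vapply(seq_len(nrow(cand)), function(ci) {
          trial <- assign
          trial[v1] <- cand$j1[ci]
          trial[v2] <- cand$j2[ci]
          cut_weight(graph, trial)
        }, numeric(1L))
        pick <- sample1(which(cuts == max(cuts)))
        assign[v1] <- cand$j1[pick]
        assign[v2] <- cand$j2[pick]
      }
      list(assign = assign,
           n_resolved = length(unsat0) - length(unresolved),
           cut = cut_weight(graph, assign),
           unresolved = unresolved)
    })
    if (is.null(best) || res$n_resolved > best$n_resolved ||
        (res$n_resolved == best$n_resolved && res$cut > best$cut)) {
      best <- res
    }
  }

  part <- new_partition(graph, partition$k, best$assign)
  copies <- cbind(copy_hapA = values[best$assign[2L * seq_len(n_ind) - 1L]],
                  copy_hapB = values[best$assign[2L * seq_len(n_ind)]])
  sat <- ind_sat(best$assign)
  if (length(best$unresolved)) {
    copies[best$unresolved, ] <- NA_integer_
    message("adjust: ", length(best$unresolved),
            " individual(s) unresolved (no value pair sums to their total)")
  }
  list(partition = part, copies = copies, satisfied = sat,
       unresolved = best$unresolved)
}

#' Infer chromosome-specific copy numbers at one CNV
#'
#' Runs the full per-CNV pipeline: build the hard/soft haplotype graph, solve
#' constrained Max-k-Cut and the unique-value Max-2-CSP for every `k` from 2
#' to [max_clusters()], keep the `k` with the most satisfied constraints
#' (ties: smaller `k`, then larger cut), and finish with the randomized
#' adjustment pass.  Individuals with missing totals are excluded from this
#' CNV only.
#'
#' @param local A `LocalHaplotypeSet` from [select_window()].
#' @param totals A [cnv_record()] or (named) vector of totals.
#' @param restarts Randomized restarts used by every stage (default 10).
#' @param seed Optional integer seed; the run is fully deterministic given it.
#' @return An object of class `DiplotypeCallSet`: `calls` (data.frame with
#'   sample_id, copy_hapA, copy_hapB, total, satisfied), `chosen_k`,
#'   `n_satisfied`, `cluster_labels` (per haplotype vertex) and
#'   `cluster_values`.
#' @export
infer_cnv <- function(local, totals, restarts = 10L, seed = NULL) {
  stopifnot(inherits(local, "LocalHaplotypeSet"))
  if (inherits(totals, "CNVRecord")) totals <- totals$totals
  if (!is.null(names(totals))) totals <- totals[local$sample_ids]
  if (length(totals) != length(local$sample_ids)) {
    stop("need one total per individual")
  }
  keep <- !is.na(totals)
  if (!any(keep)) stop("no individual with a non-missing total")
  if (local$n_snps < 1L) stop("empty SNP window")
  if (!all(keep)) local <- local_subset(local, local$sample_ids[keep])
  totals <- as.integer(totals[keep])

  graph <- build_graph(local, totals)
  k_max <- max_clusters(totals, graph$n_vertices)
  ks <- seq(2L, k_max)
  seeds <- derive_seeds(seed, 2L * length(ks) + 1L)

  best <- NULL
  for (idx in seq_along(ks)) {
    k <- ks[idx]
    part <- greedy_constrained_maxkcut(graph, k, restarts,
                                       seed = seeds[2L * idx - 1L])
    cs <- build_constraints(part, totals)
    asg <- solve_unique_max2csp(cs, restarts, seed = seeds[2L * idx])
    if (is.null(best) || asg$satisfied_count > best$sat) {
      best <- list(k = k, part = part, asg = asg, sat = asg$satisfied_count)
    }
  }

  adj <- adjust_unsatisfied(graph, best$part, best$asg, totals,
                            restarts, seed = seeds[length(seeds)])
  copies <- adj$copies
  copies[is.na(copies)] <- -1L
  calls <- data.frame(sample_id = local$sample_ids,
                      copy_hapA = copies[, 1L],
                      copy_hapB = copies[, 2L],
                      total = totals,
                      satisfied = adj$satisfied,
                      stringsAsFactors = FALSE)
  labels <- adj$partition$assignment
  names(labels) <- paste0(rep(local$sample_ids, each = 2L), c(".A", ".B"))
  structure(list(cnv_id = local$cnv_id,
                 calls = calls,
                 chosen_k = best$k,
                 n_satisfied = sum(adj$satisfied),
                 cluster_labels = labels,
                 cluster_values = best$asg$values,
                 cut_value = adj$partition$cut_value),
            class = "DiplotypeCallSet")
}

#' @export
print.DiplotypeCallSet <- function(x, ...) {
  cat("DiplotypeCallSet", x$cnv_id, "- k =", x$chosen_k, ",",
      x$n_satisfied, "of", nrow(x$calls), "individuals satisfied\n")
  invisible(x)
}

#' Phase every CNV in a panel
#'
#' Loops [select_window()] + [infer_cnv()] over a list of CNVs.  CNVs whose
#' window holds fewer than `min_snps` SNPs are skipped (flanking SNPs that
#' sparse are uninformative about LD), as are CNVs without any non-missing
#' total; skip reasons are reported in the summary.
#'
#' @param panel A [haplotype_panel()].
#' @param cnvs A [cnv_record()] or list of them.
#' @param extension_factor Flank multiplier passed to [select_window()].
#' @param min_snps Minimum SNPs required in the window (default 10).
#' @param restarts Randomized restarts per stage (default 10).
#' @param seed Optional master seed; one sub-seed is derived per CNV so
#'   results are independent of processing order.
#' @return List with `calls` (named list of `DiplotypeCallSet`), `table`
#'   (combined call table) and `summary` (per-CNV status data.frame).
#' @export
phase_cnvs <- function(panel, cnvs, extension_factor = 1.0, min_snps = 10L,
                       restarts = 10L, seed = NULL) {
  if (inherits(cnvs, "CNVRecord")) cnvs <- list(cnvs)
  seeds <- derive_seeds(seed, length(cnvs))
  calls <- list()
  summary_rows <- list()
  for (i in seq_along(cnvs)) {
    cnv <- cnvs[[i]]
    local <- select_window(panel, cnv, extension_factor)
    status <- "ok"
    cs <- NULL
    if (local$n_snps < min_snps) {
      status <- paste0("skipped: <", min_snps, " SNPs (", local$n_snps, ")")
    } else if (all(is.na(cnv$totals[local$sample_ids]))) {
      status <- "skipped: no non-missing totals"
    } else {
      cs <- infer_cnv(local, cnv, restarts, seed = seeds[i])
      calls[[cnv$cnv_id]] <- cs
    }
    summary_rows[[i]] <- data.frame(
      cnv_id = cnv$cnv_id,
      status = status,
      n_snps = local$n_snps,
      chosen_k = if (is.null(cs)) NA_integer_ else cs$chosen_k,
      n_satisfied = if (is.null(cs)) NA_integer_ else cs$n_satisfied,
      n_individuals = if (is.null(cs)) NA_integer_ else nrow(cs$calls),
      stringsAsFactors = FALSE)
  }
  list(calls = calls,
       table = if (length(calls)) calls_table(calls) else NULL,
       summary = do.call(rbind, summary_rows))
}
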