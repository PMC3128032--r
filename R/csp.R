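# Unique Max-2-CSP: assign pairwise-distinct integers from D = {0..d} to the
# cluster variables X_1..X_n so that a maximum number of two-variable sum
# constraints X_a + X_b = T (with multiplicities) is satisfied.  Solved by a
# seeded-propagation solution-table heuristic; a brute-force enumerator is the
# exact oracle for small instances.

#' Construct a constraint set
#'
#' @param n_vars Number of cluster variables `X_1..X_n`.
#' @param constraints data.frame with columns `a`, `b` (variable indices,
#'   `a == b` allowed), `T` (non-negative target sum) and optionally `N`
#'   (multiplicity, default 1).  Identical `(a, b, T)` rows are collapsed by
#'   summing multiplicities.
#' @param individuals Optional data.frame `(a, b, T)` with one row per
#'   individual, used for per-individual satisfaction flags.
#' @return An object of class `ConstraintSet` with the collapsed constraint
#'   table, `c_max` (largest observed total) and domain bound
#'   `d = max(c_max, n_vars - 1)`.
#' @export
constraint_set <- function(n_vars, constraints, individuals = NULL) {
  stopifnot(is_count(n_vars), n_vars >= 1)
  cn <- constraints
  if (nrow(cn) > 0L) {
    stopifnot(all(c("a", "b", "T") %in% names(cn)))
    if (is.null(cn$N)) cn$N <- 1L
    if (any(cn$T < 0)) stop("constraint targets must be non-negative")
    if (any(cn$N < 1)) stop("constraint multiplicities must be >= 1")
    if (any(cn$a < 1 | cn$a > n_vars | cn$b < 1 | cn$b > n_vars)) {
      stop("constraint variable index out of range")
    }
    a <- pmin(cn$a, cn$b)
    b <- pmax(cn$a, cn$b)
    agg <- stats::aggregate(cn$N, by = list(a = a, b = b, T = cn$T), FUN = sum)
    cn <- data.frame(a = as.integer(agg$a), b = as.integer(agg$b),
                     T = as.integer(agg$T), N = as.integer(agg$x))
    cn <- cn[order(cn$a, cn$b, cn$T), , drop = FALSE]
    rownames(cn) <- NULL
  } else {
    cn <- data.frame(a = integer(), b = integer(), T = integer(),
                     N = integer())
  }
  c_max <- if (nrow(cn)) max(cn$T) else 0L
  structure(list(n_vars = as.integer(n_vars),
                 constraints = cn,
                 individuals = individuals,
                 c_max = as.integer(c_max),
                 d = as.integer(max(c_max, n_vars - 1L))),
            class = "ConstraintSet")
}

#' @export
print.ConstraintSet <- function(x, ...) {
  cat("ConstraintSet:", x$n_vars, "variables,", nrow(x$constraints),
      "constraint type(s), total multiplicity", sum(x$constraints$N),
      ", D = {0..", x$d, "}\n", sep = " ")
  invisible(x)
}

#' Build sum constraints from a haplotype partition
#'
#' For individual `i` with haplotypes clustered into `X_a` and `X_b` and total
#' copy number `Total(i)`, emits the constraint `X_a + X_b = Total(i)`
#' (`a == b` when both haplotypes fell in one cluster); identical constraints
#' are collapsed with multiplicities.
#'
#' @param partition A `Partition` over the individuals' haplotype vertices.
#' @param totals Integer total copy number per individual (order matching the
#'   vertex layout `2i-1`, `2i`).
#' @return A [constraint_set()] carrying per-individual rows for satisfaction
#'   flags.
#' @export
build_constraints <- function(partition, totals) {
  stopifnot(inherits(partition, "Partition"))
  n_ind <- length(totals)
  if (length(partition$assignment) != 2L * n_ind) {
    stop("partition must cover both haplotypes of each individual")
  }
  a <- partition$assignment[2L * seq_len(n_ind) - 1L]
  b <- partition$assignment[2L * seq_len(n_ind)]
  ind <- data.frame(a = pmin(a, b), b = pmax(a, b), T = as.integer(totals))
  constraint_set(partition$k, data.frame(a = ind$a, b = ind$b, T = ind$T),
                 individuals = ind)
}

# Normalize a value vector: -1 means unassigned, stored as NA internally.
values_to_na <- function(values) {
  values <- as.integer(values)
  values[values == -1L] <- NA_integer_
  values
}

#' Count satisfied constraints under a value assignment
#'
#' @param cs A [constraint_set()].
#' @param values Integer vector over the variables; `-1` or `NA` marks an
#'   unassigned variable (which satisfies nothing).
#' @return Total satisfied multiplicity.
#' @export
count_satisfied <- function(cs, values) {
  stopifnot(inherits(cs, "ConstraintSet"))
  cn <- cs$constraints
  if (nrow(cn) == 0L) return(0L)
  v <- values_to_na(values)
  if (length(v) != cs$n_vars) stop("need one value per variable")
  va <- v[cn$a]
  vb <- v[cn$b]
  ok <- !is.na(va) & !is.na(vb) & (va + vb == cn$T)
  sum(cn$N[ok])
}

# Group the a != b constraint types by unordered variable pair; used for the
# majority-T propagation rule.
pair_groups <- function(cn) {
  prop <- cn[cn$a != cn$b, , drop = FALSE]
  if (nrow(prop) == 0L) {
    return(list(a = integer(), b = integer(), T = list(), N = list()))
  }
  key <- paste(prop$a, prop$b)
  ord <- !duplicated(key)
  list(a = prop$a[ord], b = prop$b[ord],
       T = split(prop$T, key)[unique(key)],
       N = split(prop$N, key)[unique(key)])
}

# One propagation round from seed X_i = c; consumes the RNG.  Constraints with
# exactly one assigned endpoint are picked in random order; the unknown
# endpoint gets majority-T minus the known value, unless that value is outside
# D or collides with an already-used value (conflict: the variable stays
# unassigned and the pair is not retried).
propagate_seed <- function(cs, groups, i, c) {
  vals <- rep(NA_integer_, cs$n_vars)
  vals[i] <- c
  np <- length(groups$a)
  if (np > 0L) {
    failed <- logical(np)
    repeat {
      asg <- !is.na(vals)
      elig <- which(!failed & xor(asg[groups$a], asg[groups$b]))
      if (length(elig) == 0L) break
      p <- sample1(elig)
      ga <- groups$a[p]
      gb <- groups$b[p]
      known <- if (asg[ga]) ga else gb
      unknown <- if (asg[ga]) gb else ga
      Ts <- groups$T[[p]]
      Ns <- groups$N[[p]]
      tmax <- Ts[Ns == max(Ns)]
      tpick <- sample1(tmax)                 # majority T, ties at random
      x <- tpick - vals[known]
      if (x < 0L || x > cs$d || x %in% vals) {
        failed[p] <- TRUE                    # conflict: leave unassigned
      } else {
        vals[unknown] <- x
      }
    }
  }
  vals
}

#' Solution-table heuristic for Unique Max-2-CSP
#'
#' For every variable `i` and seed value `c` in `0..c_max`, the solver sets
#' `X_i = c`, propagates through constraints with a single assigned endpoint
#' using the majority target-sum rule, and repeats with `restarts` random
#' constraint orders, recording the best round as row `(i, c)` of a solution
#' table.  Rows are then greedily unioned in order of satisfied count; values
#' merged later may never overwrite earlier assignments and distinctness is
#' enforced throughout.  Variables left without a value are reported as `-1`.
#'
#' @param cs A [constraint_set()].
#' @param restarts Randomized propagation rounds per table row (default 10).
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `CSPAssignment` with `values` (`-1` =
#'   unassigned), `satisfied_count`, per-individual `satisfied_flags` when the
#'   constraint set carries individuals, and `above_c_max` flags for values
#'   forced above the largest observed total by the `d >= n - 1` domain
#'   requirement.
#' @export
solve_unique_max2csp <- function(cs, restarts = 10L, seed = NULL) {
  stopifnot(inherits(cs, "ConstraintSet"), is_count(restarts), restarts >= 1)
  nv <- cs$n_vars
  if (nrow(cs$constraints) == 0L) {
    return(new_csp_assignment(cs, rep(NA_integer_, nv)))
  }
  with_local_seed(seed, {
    groups <- pair_groups(cs$constraints)
    seeds_c <- 0:cs$c_max
    tab_vals <- list()
    tab_sat <- integer()
    for (i in seq_len(nv)) {
      for (c in seeds_c) {
        best_v <- NULL
        best_s <- -1L
        for (r in seq_len(restarts)) {
          v <- propagate_seed(cs, groups, i, c)
          s <- count_satisfied(cs, v)
          if (s > best_s) {
            best_s <- s
            best_v <- v
          }
        }
        tab_vals[[length(tab_vals) + 1L]] <- best_v
        tab_sat[length(tab_sat) + 1L] <- best_s
      }
    }
    n_assigned <- vapply(tab_vals, function(v) sum(!is.na(v)), integer(1L))
    ord <- order(-tab_sat, -n_assigned, seq_along(tab_sat))

    global <- rep(NA_integer_, nv)
    cur <- 0L
    repeat {
      improved <- FALSE
      for (r in ord) {
        cand <- global
        rv <- tab_vals[[r]]
        for (j in which(!is.na(rv))) {
          if (is.na(cand[j]) && !(rv[j] %in% cand)) cand[j] <- rv[j]
        }
        s <- count_satisfied(cs, cand)
        if (s > cur) {
          global <- cand
          cur <- s
          improved <- TRUE
        }
      }
      if (!improved) break
    }
    new_csp_assignment(cs, global)
  })
}

new_csp_assignment <- function(cs, values) {
  assigned <- values[!is.na(values)]
  if (anyDuplicated(assigned)) stop("assignment violates distinctness")
  sat <- count_satisfied(cs, values)
  flags <- NULL
  if (!is.null(cs$individuals)) {
    v <- values
    va <- v[cs$individuals$a]
    vb <- v[cs$individuals$b]
    flags <- !is.na(va) & !is.na(vb) & (va + vb == cs$individuals$T)
  }
  out <- values
  out[is.na(out)] <- -1L
  structure(list(values = out,
                 satisfied_count = as.integer(sat),
                 satisfied_flags = flags,
                 above_c_max = !is.na(values) & values > cs$c_max,
                 n_vars = cs$n_vars),
            class = "CSPAssignment")
}

#' @export
print.CSPAssignment <- function(x, ...) {
  cat("CSPAssignment: values (", paste(x$values, collapse = ", "),
      "), satisfied multiplicity ", x$satisfied_count, "\n", sep = "")
  invisible(x)
}

# n! x n matrix of permutation indices, recursive.
perm_indices <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- perm_indices(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub)))
  }))
}

#' Exact Unique Max-2-CSP by enumeration (test oracle)
#'
#' Enumerates every injective assignment of `n` distinct values from
#' `D = {0..d}`; refuses instances with more than 6 variables or a domain
#' larger than 9 values.
#'
#' @param cs A [constraint_set()].
#' @return A `CSPAssignment` attaining the exact optimum.
#' @export
brute_force_max2csp <- function(cs) {
  stopifnot(inherits(cs, "ConstraintSet"))
  nv <- cs$n_vars
  if (nv > 6L) stop("brute_force_max2csp: refusing > 6 variables")
  if (cs$d > 8L) stop("brute_force_max2csp: refusing |D| > 9")
  if (nrow(cs$constraints) == 0L) {
    return(new_csp_assignment(cs, rep(NA_integer_, nv)))
  }
  D <- 0:cs$d
  subsets <- utils::combn(D, nv)
  pidx <- perm_indices(nv)
  A <- do.call(rbind, lapply(seq_len(ncol(subsets)), function(s) {
    matrix(subsets[, s][pidx], nrow(pidx))
  }))
  cn <- cs$constraints
  sat <- numeric(nrow(A))
  for (r in seq_len(nrow(cn))) {
    sat <- sat + cn$N[r] * (A[, cn$a[r]] + A[, cn$b[r]] == cn$T[r])
  }
  new_csp_assignment(cs, A[which.max(sat), ])
}
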