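# Weighted-graph formulation: each haplotype occurrence is a vertex, edge
# weights are hamming distances, and the edge between the two haplotypes of an
# individual with an odd total copy number is "hard" (its endpoints must end
# up in different clusters; its weight is excluded from the soft-cut
# objective).

#' Hamming distance between two haplotypes
#'
#' @param h1,h2 Binary strings (e.g. `"0101"`) or equal-length vectors.
#' @return Number of differing positions.
#' @examples
#' hamming("0101", "0110")  # 2
#' @export
hamming <- function(h1, h2) {
  if (is.character(h1) && length(h1) == 1L) h1 <- strsplit(h1, "")[[1L]]
  if (is.character(h2) && length(h2) == 1L) h2 <- strsplit(h2, "")[[1L]]
  if (length(h1) != length(h2)) {
    stop("hamming: haplotypes differ in length (", length(h1), " vs ",
         length(h2), ")")
  }
  sum(h1 != h2)
}

# All-pairs hamming distances for a 0/1 matrix (rows = haplotypes).
hamming_matrix <- function(A) {
  storage.mode(A) <- "double"
  if (ncol(A) == 0L) {
    return(matrix(0, nrow(A), nrow(A)))
  }
  d <- tcrossprod(A, 1 - A)  # d[i,j] = #(i==1 & j==0)
  d + t(d)
}

# Shared constructor; weights is a dense symmetric matrix over 2*n_ind
# vertices, vertex 2i-1 / 2i = haplotype A / B of individual i.
new_cnv_graph <- function(weights, totals, sample_ids, cnv_id,
                          haplotype_strings = NULL) {
  n_ind <- length(totals)
  nv <- 2L * n_ind
  weights <- as.matrix(weights)
  if (nrow(weights) != nv || ncol(weights) != nv) {
    stop("weight matrix must be ", nv, " x ", nv, " for ", n_ind,
         " individuals")
  }
  if (any(weights < 0)) stop("edge weights must be non-negative")
  if (any(abs(weights - t(weights)) > 1e-9)) stop("weights must be symmetric")
  if (any(diag(weights) != 0)) stop("self-weights must be zero")
  if (anyNA(totals)) stop("all included individuals need a non-missing total")

  odd <- which(totals %% 2L == 1L)
  hard <- cbind(u = 2L * odd - 1L, v = 2L * odd)
  partner <- rep(NA_integer_, nv)
  partner[hard[, 1L]] <- hard[, 2L]
  partner[hard[, 2L]] <- hard[, 1L]

  soft <- weights
  if (nrow(hard) > 0L) {
    soft[hard] <- 0
    soft[hard[, c(2L, 1L), drop = FALSE]] <- 0
  }
  structure(
    list(n_vertices = nv,
         n_individuals = n_ind,
         weights = weights,
         soft = soft,
         hard = hard,
         partner = partner,
         totals = as.integer(totals),
         sample_ids = sample_ids,
         cnv_id = cnv_id,
         haplotype_strings = haplotype_strings,
         W = sum(soft) / 2),
    class = "CNVGraph"
  )
}

#' Construct a CNV haplotype graph from an explicit weight matrix
#'
#' Low-level constructor, mainly for simulation studies of the optimizer:
#' vertices `2i-1` and `2i` are the two haplotypes of individual `i`, and the
#' edge between them is hard whenever `totals[i]` is odd.
#'
#' @param weights Symmetric non-negative matrix over `2 * length(totals)`
#'   vertices with zero diagonal.
#' @param totals Integer total copy number per individual.
#' @param sample_ids Optional individual identifiers.
#' @param cnv_id Identifier used in downstream call sets.
#' @return An object of class `CNVGraph` with fields `weights` (all pairwise
#'   distances), `soft` (weights with hard edges zeroed), `hard` (matrix of
#'   hard vertex pairs), and `W` (total soft weight).
#' @export
cnv_graph <- function(weights, totals, sample_ids = NULL, cnv_id = "cnv") {
  if (is.null(sample_ids)) {
    sample_ids <- sprintf("ind%02d", seq_along(totals))
  }
  new_cnv_graph(weights, totals, sample_ids, cnv_id)
}

#' Build the weighted graph for one CNV
#'
#' Transforms a windowed haplotype set plus per-individual totals into the
#' hard/soft edge graph: one vertex per haplotype occurrence, soft edge
#' weights equal to pairwise hamming distances (identical haplotypes from
#' different individuals become distinct vertices at distance zero), and a
#' hard edge between the two haplotypes of every odd-total individual.
#'
#' @param local A `LocalHaplotypeSet` from [select_window()].
#' @param totals A [cnv_record()] or a vector of totals (recycled against
#'   `local$sample_ids` by name when named).
#' @return A `CNVGraph`.
#' @export
build_graph <- function(local, totals) {
  stopifnot(inherits(local, "LocalHaplotypeSet"))
  if (inherits(totals, "CNVRecord")) totals <- totals$totals
  if (!is.null(names(totals))) {
    totals <- totals[local$sample_ids]
  }
  if (length(totals) != length(local$sample_ids)) {
    stop("need one total per individual in the local set")
  }
  D <- hamming_matrix(local$hap_matrix)
  new_cnv_graph(D, totals, local$sample_ids, local$cnv_id,
                haplotype_strings = local$haplotype_strings)
}

#' @export
print.CNVGraph <- function(x, ...) {
  cat("CNVGraph", x$cnv_id, "-", x$n_vertices, "vertices,",
      nrow(x$hard), "hard edge(s), total soft weight W =", x$W, "\n")
  invisible(x)
}

#' Dump a CNV graph as an edge-list table
#'
#' @param graph A `CNVGraph`.
#' @return data.frame with columns u, v, weight, type (`hard`/`soft`).
#' @export
as_edge_table <- function(graph) {
  stopifnot(inherits(graph, "CNVGraph"))
  nv <- graph$n_vertices
  pairs <- which(upper.tri(matrix(0, nv, nv)), arr.ind = TRUE)
  hard_key <- paste(graph$hard[, 1L], graph$hard[, 2L])
  key <- paste(pairs[, 1L], pairs[, 2L])
  data.frame(u = pairs[, 1L], v = pairs[, 2L],
             weight = graph$weights[pairs],
             type = ifelse(key %in% hard_key, "hard", "soft"),
             stringsAsFactors = FALSE)
}
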