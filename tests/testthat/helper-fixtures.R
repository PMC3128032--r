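# Shared fixtures: all inputs are built in code at test time.

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# A tiny handmade panel: 2 individuals, 3 SNPs on chr1.
tiny_panel <- function() {
  haplotype_panel(
    sample_ids = c("s1", "s2"),
    snp_ids = c("rs1", "rs2", "rs3"),
    positions = c(9000L, 10500L, 13500L),
    alleles = rbind(c(0L, 1L, 0L),
                    c(0L, 0L, 1L),
                    c(1L, 1L, 0L),
                    c(0L, 0L, 0L)),
    chrom = "chr1")
}

tiny_cnv <- function(totals = c(s1 = 2L, s2 = 2L)) {
  cnv_record("cnv1", "chr1", 10000L, 12000L, totals)
}

# LocalHaplotypeSet straight from haplotype strings (one CNV, window = all).
local_from_strings <- function(strings, sample_ids = NULL, cnv_id = "cnv1") {
  n <- length(strings) / 2L
  stopifnot(n == round(n))
  if (is.null(sample_ids)) sample_ids <- sprintf("ind%02d", seq_len(n))
  m <- nchar(strings[1L])
  hap <- do.call(rbind, lapply(strsplit(strings, ""), as.integer))
  structure(list(cnv_id = cnv_id,
                 sample_ids = sample_ids,
                 haplotype_strings = strings,
                 hap_matrix = hap,
                 snp_ids = sprintf("rs%02d", seq_len(m)),
                 positions = seq_len(m) * 10L,
                 window = c(lo = 0, hi = m * 10 + 1),
                 n_snps = m),
            class = "LocalHaplotypeSet")
}

# Random optimizer instance: integer weights 0..5 over 2*n_ind vertices,
# random subset of individuals odd (hard edges).
random_graph <- function(n_ind, max_w = 5L) {
  nv <- 2L * n_ind
  w <- matrix(0L, nv, nv)
  ut <- upper.tri(w)
  w[ut] <- sample(0:max_w, sum(ut), replace = TRUE)
  w <- w + t(w)
  odd <- sample(c(TRUE, FALSE), n_ind, replace = TRUE)
  totals <- ifelse(odd, 3L, 2L)
  cnv_graph(w, totals)
}

# Independent re-derivation of the soft cut value by a double loop.
naive_cut <- function(graph, assignment) {
  total <- 0
  nv <- graph$n_vertices
  for (i in seq_len(nv - 1L)) {
    for (j in seq(i + 1L, nv)) {
      if (assignment[i] != assignment[j]) total <- total + graph$soft[i, j]
    }
  }
  total
}

# Minimal stand-ins for objects whose full construction is irrelevant to the
# operation under test.
fake_partition <- function(k, assignment) {
  structure(list(k = as.integer(k), assignment = as.integer(assignment),
                 cut_value = NA_real_),
            class = "Partition")
}

fake_assignment <- function(values) {
  structure(list(values = as.integer(values)), class = "CSPAssignment")
}

# Random constraint set over n_vars variables.
random_cs <- function(n_vars, n_types = sample(1:6, 1L), t_max = 6L) {
  a <- sample.int(n_vars, n_types, replace = TRUE)
  b <- sample.int(n_vars, n_types, replace = TRUE)
  constraint_set(n_vars,
                 data.frame(a = a, b = b,
                            T = sample(0:t_max, n_types, replace = TRUE),
                            N = sample(1:3, n_types, replace = TRUE)))
}

# Consistent constraint set planted from a hidden distinct-value assignment,
# with a connected chain so propagation from any correct seed reaches all
# variables; the optimum satisfies every constraint.
planted_cs <- function(n_vars) {
  vals <- shuffle(0:(n_vars - 1L))   # keeps c_max within the oracle's bounds
  a <- seq_len(n_vars - 1L)
  b <- a + 1L
  extra <- if (n_vars > 2L) {
    ea <- sample.int(n_vars, 2L)
    eb <- sample.int(n_vars, 2L)
    data.frame(a = ea, b = eb, T = vals[ea] + vals[eb],
               N = sample(1:3, 2L, replace = TRUE))
  } else NULL
  cn <- rbind(data.frame(a = a, b = b, T = vals[a] + vals[b],
                         N = sample(1:3, n_vars - 1L, replace = TRUE)),
              extra)
  list(cs = constraint_set(n_vars, cn), values = vals)
}

# Full pipeline on a simulated panel: returns calls + truth + graph facts.
run_sim_pipeline <- function(sim, seed, restarts = 10L) {
  local <- select_window(sim$panel, sim$cnv, 1.0)
  infer_cnv(local, sim$cnv, restarts = restarts, seed = seed)
}
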