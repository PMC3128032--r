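# Synthetic-panel generator.  Emulates the evaluation designs the method was
# studied under: diplotype configurations drawn under exact (chi-square P =
# 1.0) or slightly perturbed Hardy-Weinberg equilibrium, flanking SNP
# haplotypes in perfect-to-decayed LD with each copy-number allele (LD decay
# by i.i.d. allele flipping), X-chromosome-style random pairing of haploid
# copies, 1/1-only panels with non-informative replacement, and trio
# inheritance.

#' Simulation configuration
#'
#' Defaults mirror the study conditions used throughout the package's tests:
#' 16 individuals, a deletion allele at frequency 0.25 against the one-copy
#' allele at 0.75, 20 tag SNPs, perfect LD (no flips) and exact HWE counts.
#'
#' @param n_individuals Number of diploid individuals.
#' @param copy_freqs Named numeric vector of haploid copy-allele frequencies
#'   (names are copy numbers); must sum to 1.
#' @param n_snps Number of flanking SNPs simulated.
#' @param ld_flip_fraction Per-allele i.i.d. flip probability in `[0, 1]`;
#'   0 keeps each copy allele in perfect LD (`r^2 = 1`) with its tag SNPs.
#' @param hwe_mode `"complete"` (exact HWE counts, chi-square P = 1) or
#'   `"perturbed"` (single copy alleles are added/deleted until the chi-square
#'   P first drops to `target_hwe_p`).
#' @param target_hwe_p Target P for `"perturbed"` mode (default 0.98).
#' @param chrom,cnv_start,cnv_end Coordinates of the simulated CNV.
#' @param seed Optional integer seed.
#' @return A list of class `SimConfig`.
#' @export
sim_config <- function(n_individuals = 16L,
                       copy_freqs = c("0" = 0.25, "1" = 0.75),
                       n_snps = 20L,
                       ld_flip_fraction = 0,
                       hwe_mode = c("complete", "perturbed"),
                       target_hwe_p = 0.98,
                       chrom = "chr1",
                       cnv_start = 10000L,
                       cnv_end = 12000L,
                       seed = NULL) {
  hwe_mode <- match.arg(hwe_mode)
  if (abs(sum(copy_freqs) - 1) > 1e-8) stop("copy_freqs must sum to 1")
  if (ld_flip_fraction < 0 || ld_flip_fraction > 1) {
    stop("ld_flip_fraction must lie in [0, 1]")
  }
  if (is.null(names(copy_freqs))) stop("copy_freqs must be named by copy number")
  structure(list(n_individuals = as.integer(n_individuals),
                 copy_freqs = copy_freqs,
                 n_snps = as.integer(n_snps),
                 ld_flip_fraction = ld_flip_fraction,
                 hwe_mode = hwe_mode,
                 target_hwe_p = target_hwe_p,
                 chrom = chrom,
                 cnv_start = as.integer(cnv_start),
                 cnv_end = as.integer(cnv_end),
                 seed = seed),
            class = "SimConfig")
}

#' Exact Hardy-Weinberg diplotype counts
#'
#' Rounds `n * p` per unordered diplotype class to integers summing to `n`
#' by largest remainder.
#'
#' @param n Number of individuals.
#' @param freqs Named haploid allele frequencies.
#' @return data.frame with columns a, b (allele copy numbers, `a <= b`),
#'   expected proportion `p`, and integer `count`.
#' @export
hwe_diplotype_counts <- function(n, freqs) {
  alleles <- as.integer(names(freqs))
  ord <- order(alleles)
  alleles <- alleles[ord]
  p <- as.numeric(freqs)[ord]
  classes <- expand.grid(ai = seq_along(alleles), bi = seq_along(alleles))
  classes <- classes[classes$ai <= classes$bi, , drop = FALSE]
  prob <- ifelse(classes$ai == classes$bi,
                 p[classes$ai]^2,
                 2 * p[classes$ai] * p[classes$bi])
  expected <- n * prob
  count <- floor(expected)
  short <- n - sum(count)
  if (short > 0L) {
    frac <- expected - count
    extra <- order(-frac, seq_along(frac))[seq_len(short)]
    count[extra] <- count[extra] + 1L
  }
  data.frame(a = alleles[classes$ai], b = alleles[classes$bi],
             p = prob, count = as.integer(count))
}

#' Chi-square Hardy-Weinberg P value for observed diplotypes
#'
#' Expected class counts are computed from the realized allele frequencies;
#' the statistic is summed over all diplotype classes formed by the observed
#' alleles, with `m(m-1)/2` degrees of freedom for `m` alleles.
#'
#' @param pairs Two-column matrix (or data.frame) of per-individual allele
#'   pairs.
#' @return P value in `[0, 1]`; exact-HWE counts give 1.
#' @export
hwe_pvalue <- function(pairs) {
  pairs <- as.matrix(pairs)
  stopifnot(ncol(pairs) == 2L)
  n <- nrow(pairs)
  alleles <- sort(unique(as.vector(pairs)))
  m <- length(alleles)
  if (m < 2L) return(1)
  p <- vapply(alleles, function(a) mean(pairs == a), numeric(1L))
  key <- paste(pmin(pairs[, 1L], pairs[, 2L]), pmax(pairs[, 1L], pairs[, 2L]))
  classes <- expand.grid(ai = seq_len(m), bi = seq_len(m))
  classes <- classes[classes$ai <= classes$bi, , drop = FALSE]
  expected <- n * ifelse(classes$ai == classes$bi,
                         p[classes$ai]^2,
                         2 * p[classes$ai] * p[classes$bi])
  observed <- vapply(seq_len(nrow(classes)), function(i) {
    sum(key == paste(alleles[classes$ai[i]], alleles[classes$bi[i]]))
  }, numeric(1L))
  use <- expected > 0
  x2 <- sum((observed[use] - expected[use])^2 / expected[use])
  df <- m * (m - 1L) / 2L
  stats::pchisq(x2, df, lower.tail = FALSE)
}

# One maximally separated tag haplotype per copy allele (pairwise hamming
# >= n_snps/2 where achievable), so LD decay by flipping is the only noise
# source.  Consumes the RNG.
make_tag_haplotypes <- function(n_alleles, n_snps) {
  tags <- matrix(0L, n_alleles, n_snps)
  tags[1L, ] <- stats::rbinom(n_snps, 1L, 0.5)
  if (n_alleles == 1L) return(tags)
  thr <- floor(n_snps / 2)
  for (j in 2:n_alleles) {
    repeat {
      found <- FALSE
      for (try in seq_len(500L)) {
        cand <- stats::rbinom(n_snps, 1L, 0.5)
        dmin <- min(vapply(seq_len(j - 1L),
                           function(i) sum(cand != tags[i, ]), numeric(1L)))
        if (dmin >= thr) {
          tags[j, ] <- cand
          found <- TRUE
          break
        }
      }
      if (found) break
      thr <- thr - 1L   # relax when n_snps is too short for the separation
    }
  }
  tags
}

new_sim_truth <- function(sample_ids, pair_mat, hap_copies,
                          achieved_hwe_p = NA_real_, achieved_r2 = NA_real_,
                          tags = NULL) {
  calls <- data.frame(sample_id = sample_ids,
                      copy_hapA = pmin(pair_mat[, 1L], pair_mat[, 2L]),
                      copy_hapB = pmax(pair_mat[, 1L], pair_mat[, 2L]),
                      stringsAsFactors = FALSE)
  structure(list(calls = calls,
                 hap_copies = hap_copies,
                 achieved_hwe_p = achieved_hwe_p,
                 achieved_r2 = achieved_r2,
                 tags = tags),
            class = "SimTruth")
}

#' @export
print.SimTruth <- function(x, ...) {
  cat("SimTruth:", nrow(x$calls), "individuals; achieved HWE P =",
      signif(x$achieved_hwe_p, 3), "; mean r^2 =",
      signif(x$achieved_r2, 3), "\n")
  invisible(x)
}

# Assemble panel + CNV record + truth from per-row copy labels and an allele
# matrix.  Positions are spread inside the CNV so any extension factor >= 0
# captures them.
assemble_sim <- function(cfg, sample_ids, hap_copies, alleles,
                         achieved_hwe_p, tags, cnv_id = "cnv1") {
  n_snps <- ncol(alleles)
  len <- cfg$cnv_end - cfg$cnv_start
  positions <- cfg$cnv_start + floor(len * seq_len(n_snps) / (n_snps + 1L))
  panel <- haplotype_panel(sample_ids,
                           snp_ids = sprintf("rs%03d", seq_len(n_snps)),
                           positions = positions,
                           alleles = alleles,
                           chrom = cfg$chrom)
  n <- length(sample_ids)
  pair_mat <- cbind(hap_copies[2L * seq_len(n) - 1L],
                    hap_copies[2L * seq_len(n)])
  totals <- pair_mat[, 1L] + pair_mat[, 2L]
  names(totals) <- sample_ids
  cnv <- cnv_record(cnv_id, cfg$chrom, cfg$cnv_start, cfg$cnv_end, totals)
  truth <- new_sim_truth(sample_ids, pair_mat, hap_copies,
                         achieved_hwe_p = achieved_hwe_p, tags = tags)
  local <- select_window(panel, cnv, 0)
  truth$achieved_r2 <- cnv_snp_r2(local, hap_copies)
  list(panel = panel, cnv = cnv, truth = truth)
}

#' Simulate a CNV panel with HWE diplotypes and LD-tagged haplotypes
#'
#' Draws per-individual diplotype configurations matching Hardy-Weinberg
#' counts exactly (or perturbed to a target chi-square P), gives every copy
#' allele a distinct tag haplotype, then decays LD by flipping each emitted
#' allele independently with probability `ld_flip_fraction`.
#'
#' @param cfg A [sim_config()].
#' @return List with `panel` ([haplotype_panel()]), `cnv` ([cnv_record()]
#'   whose totals are the true pair sums) and `truth` (`SimTruth`: true
#'   unordered pairs, per-haplotype copy labels, achieved HWE P and mean
#'   r^2 of the emitted panel).
#' @export
simulate_panel <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "SimConfig"))
  with_local_seed(cfg$seed, {
    n <- cfg$n_individuals
    counts <- hwe_diplotype_counts(n, cfg$copy_freqs)
    pairs <- do.call(rbind, lapply(seq_len(nrow(counts)), function(i) {
      if (counts$count[i] == 0L) NULL
      else matrix(rep(c(counts$a[i], counts$b[i]), counts$count[i]),
                  ncol = 2L, byrow = TRUE)
    }))
    pairs <- pairs[shuffle(seq_len(nrow(pairs))), , drop = FALSE]

    if (cfg$hwe_mode == "perturbed") {
      alleles <- as.integer(names(cfg$copy_freqs))
      p <- hwe_pvalue(pairs)
      guard <- 0L
      while (p > cfg$target_hwe_p && guard < 1000L) {
        i <- sample.int(n, 1L)
        slot <- sample.int(2L, 1L)
        repl <- sample1(setdiff(alleles, pairs[i, slot]))
        pairs[i, slot] <- repl
        p <- hwe_pvalue(pairs)
        guard <- guard + 1L
      }
      achieved_p <- p
    } else {
      achieved_p <- hwe_pvalue(pairs)
    }

    # random haplotype slot (A/B) per individual
    flip_slot <- stats::runif(n) < 0.5
    pairs[flip_slot, ] <- pairs[flip_slot, c(2L, 1L), drop = FALSE]

    allele_set <- sort(unique(as.vector(pairs)))
    tags <- make_tag_haplotypes(length(allele_set), cfg$n_snps)
    rownames(tags) <- as.character(allele_set)

    hap_copies <- as.vector(t(pairs))
    alleles_mat <- tags[as.character(hap_copies), , drop = FALSE]
    if (cfg$ld_flip_fraction > 0) {
      flips <- matrix(stats::runif(length(alleles_mat)) < cfg$ld_flip_fraction,
                      nrow = nrow(alleles_mat))
      alleles_mat[flips] <- 1L - alleles_mat[flips]
    }
    rownames(alleles_mat) <- NULL
    assemble_sim(cfg, sprintf("ind%02d", seq_len(n)), hap_copies,
                 alleles_mat, achieved_p, tags)
  })
}

#' Simulate a diploid panel by pairing haploid X-chromosome calls
#'
#' On the X chromosome of males the measured total copy number is directly
#' the chromosome-specific copy number; pairing two male X haplotypes at
#' random yields a synthetic diploid panel with known truth.
#'
#' @param haploid_calls data.frame with columns `hap` (equal-length binary
#'   strings) and `copy` (non-negative integers).
#' @param cfg A [sim_config()] supplying coordinates (its frequency/HWE fields
#'   are ignored); pairing randomness uses `cfg$seed`.
#' @return List `(panel, cnv, truth)` as in [simulate_panel()].  An odd number
#'   of records drops the last shuffled record with a warning.
#' @export
simulate_x_pairs <- function(haploid_calls, cfg = sim_config()) {
  stopifnot(is.data.frame(haploid_calls),
            all(c("hap", "copy") %in% names(haploid_calls)))
  if (nrow(haploid_calls) < 2L) stop("need at least two haploid records")
  with_local_seed(cfg$seed, {
    idx <- shuffle(seq_len(nrow(haploid_calls)))
    if (length(idx) %% 2L == 1L) {
      warning("odd number of haploid records; dropping the last one")
      idx <- idx[-length(idx)]
    }
    n <- length(idx) / 2L
    hap_strings <- haploid_calls$hap[idx]
    hap_copies <- as.integer(haploid_calls$copy[idx])
    alleles_mat <- do.call(rbind, lapply(strsplit(hap_strings, ""),
                                         as.integer))
    assemble_sim(cfg, sprintf("xp%02d", seq_len(n)), hap_copies,
                 alleles_mat, NA_real_, NULL)
  })
}

#' Simulate a 1/1-only panel with non-informative haplotype replacement
#'
#' Every individual truly carries one copy on each chromosome (no CNV, total
#' 2 everywhere) and shares a single copy-1 tag haplotype; a fraction of the
#' haplotype rows is then replaced by uniform-random binary strings.  Used to
#' measure how often 1/1 configurations are miscalled as 0/2 when the
#' haplotype background loses LD information.
#'
#' @param n_individuals Number of individuals (default 16).
#' @param frac_noninformative Fraction of the `2 * n` haplotype rows replaced;
#'   the count is `round(frac * 2 * n)`.
#' @param n_snps SNPs per haplotype (default 20).
#' @param seed Optional integer seed.
#' @return List `(panel, cnv, truth)`; all truth pairs are (1, 1).
#' @export
simulate_oneone_panel <- function(n_individuals = 16L,
                                  frac_noninformative = 0,
                                  n_snps = 20L, seed = NULL) {
  stopifnot(frac_noninformative >= 0, frac_noninformative <= 1)
  cfg <- sim_config(n_individuals = n_individuals, n_snps = n_snps)
  with_local_seed(seed, {
    n <- as.integer(n_individuals)
    tag <- stats::rbinom(n_snps, 1L, 0.5)
    alleles_mat <- matrix(rep(tag, 2L * n), nrow = 2L * n, byrow = TRUE)
    n_replace <- round(frac_noninformative * 2L * n)
    if (n_replace > 0L) {
      rows <- sample.int(2L * n, n_replace)
      alleles_mat[rows, ] <- matrix(stats::rbinom(n_replace * n_snps, 1L, 0.5),
                                    nrow = n_replace)
    }
    hap_copies <- rep(1L, 2L * n)
    out <- assemble_sim(cfg, sprintf("ind%02d", seq_len(n)), hap_copies,
                        alleles_mat, 1, matrix(tag, 1L))
    out$truth$n_replaced <- n_replace
    out
  })
}

#' Simulate parent-offspring trios
#'
#' Parents are drawn as in [simulate_panel()]; each child inherits one
#' (haplotype row, copy value) unit from each parent uniformly at random, so
#' inheritance is Mendelian by construction.
#'
#' @param n_trios Number of trios.
#' @param cfg A [sim_config()]; `n_individuals` is overridden by
#'   `2 * n_trios` parents.
#' @return List with `panel` (fathers, mothers, then children), `cnv`,
#'   `truth`, and `pedigree` (data.frame child/father/mother).  `n_trios = 0`
#'   yields empty outputs.
#' @export
simulate_trios <- function(n_trios, cfg = sim_config()) {
  stopifnot(is_count(n_trios), n_trios >= 0)
  if (n_trios == 0L) {
    return(list(panel = NULL, cnv = NULL, truth = NULL,
                pedigree = data.frame(child = character(),
                                      father = character(),
                                      mother = character())))
  }
  seeds <- derive_seeds(cfg$seed, 2L)
  cfg_par <- cfg
  cfg_par$n_individuals <- 2L * as.integer(n_trios)
  cfg_par$seed <- seeds[1L]
  parents <- simulate_panel(cfg_par)

  with_local_seed(seeds[2L], {
    fathers <- sprintf("f%02d", seq_len(n_trios))
    mothers <- sprintf("m%02d", seq_len(n_trios))
    children <- sprintf("c%02d", seq_len(n_trios))
    par_alleles <- parents$panel$alleles
    par_copies <- parents$truth$hap_copies

    child_rows <- matrix(0L, 2L * n_trios, ncol(par_alleles))
    child_copies <- integer(2L * n_trios)
    for (t in seq_len(n_trios)) {
      f_slot <- sample.int(2L, 1L)
      m_slot <- sample.int(2L, 1L)
      f_row <- 2L * t - 2L + f_slot
      m_row <- 2L * (n_trios + t) - 2L + m_slot
      child_rows[2L * t - 1L, ] <- par_alleles[f_row, ]
      child_rows[2L * t, ] <- par_alleles[m_row, ]
      child_copies[2L * t - 1L] <- par_copies[f_row]
      child_copies[2L * t] <- par_copies[m_row]
    }
    sample_ids <- c(fathers, mothers, children)
    alleles_mat <- rbind(par_alleles, child_rows)
    rownames(alleles_mat) <- NULL
    hap_copies <- c(par_copies, child_copies)
    out <- assemble_sim(cfg, sample_ids, hap_copies, alleles_mat,
                        parents$truth$achieved_hwe_p, parents$truth$tags)
    out$pedigree <- data.frame(child = children, father = fathers,
                               mother = mothers, stringsAsFactors = FALSE)
    out
  })
}
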