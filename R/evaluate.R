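# Scoring of inferred diplotype configurations against simulated truth or a
# trio pedigree, plus population-level copy-number distributions.  All
# comparisons use unordered pairs: the method infers which configuration an
# individual carries, not which physical chromosome carries which copy.

calls_pairs <- function(calls) {
  tab <- if (inherits(calls, "DiplotypeCallSet")) calls$calls else calls
  stopifnot(all(c("sample_id", "copy_hapA", "copy_hapB") %in% names(tab)))
  data.frame(sample_id = tab$sample_id,
             lo = pmin(tab$copy_hapA, tab$copy_hapB),
             hi = pmax(tab$copy_hapA, tab$copy_hapB),
             stringsAsFactors = FALSE)
}

#' Accuracy of inferred diplotype configurations
#'
#' Fraction of individuals whose unordered inferred pair equals the unordered
#' true pair (`C_correct / C_total`).  Unresolved calls (`-1, -1`) count as
#' incorrect.
#'
#' @param calls A `DiplotypeCallSet` or call table for one CNV.
#' @param truth A `SimTruth` (or data.frame with sample_id, copy_hapA,
#'   copy_hapB).
#' @return Accuracy in `[0, 1]`.
#' @export
accuracy <- function(calls, truth) {
  got <- calls_pairs(calls)
  want <- calls_pairs(if (inherits(truth, "SimTruth")) truth$calls else truth)
  if (!setequal(got$sample_id, want$sample_id)) {
    stop("calls and truth cover different individuals")
  }
  want <- want[match(got$sample_id, want$sample_id), ]
  mean(got$lo == want$lo & got$hi == want$hi)
}

#' Rate at which true 1/1 configurations are called 0/2
#'
#' @param calls Calls for a panel whose true configuration is 1/1 everywhere.
#' @param truth The matching truth; an error is raised if any true pair is
#'   not (1, 1).
#' @return Fraction of individuals called as the 0/2 configuration.
#' @export
miscall_rate_oneone <- function(calls, truth) {
  want <- calls_pairs(if (inherits(truth, "SimTruth")) truth$calls else truth)
  if (!all(want$lo == 1L & want$hi == 1L)) {
    stop("miscall_rate_oneone requires all-1/1 truth")
  }
  got <- calls_pairs(calls)
  if (!setequal(got$sample_id, want$sample_id)) {
    stop("calls and truth cover different individuals")
  }
  mean(got$lo == 0L & got$hi == 2L)
}

# One trio is Mendelian-consistent iff the child's unordered pair can be
# formed by taking one copy value from the father's pair and one from the
# mother's.
trio_consistent <- function(child, father, mother) {
  for (f in father) {
    for (m in mother) {
      if (min(f, m) == child[1L] && max(f, m) == child[2L]) return(TRUE)
    }
  }
  FALSE
}

#' Mendelian consistency of calls within trios
#'
#' @param calls Call table (possibly spanning several CNVs; must contain a
#'   `cnv_id` column) or a `DiplotypeCallSet`.
#' @param pedigree data.frame with columns child, father, mother.
#' @return data.frame per CNV: `rate` (consistent / called trios),
#'   `n_consistent`, `n_called`, `n_excluded` (trios with a missing or
#'   unresolved member).
#' @export
mendelian_rate <- function(calls, pedigree) {
  tab <- calls_table(calls)
  stopifnot(all(c("child", "father", "mother") %in% names(pedigree)))
  out <- lapply(split(tab, tab$cnv_id), function(sub) {
    pairs <- calls_pairs(sub)
    rownames(pairs) <- pairs$sample_id
    n_cons <- 0L
    n_called <- 0L
    n_excl <- 0L
    for (t in seq_len(nrow(pedigree))) {
      ids <- c(pedigree$child[t], pedigree$father[t], pedigree$mother[t])
      if (!all(ids %in% pairs$sample_id)) {
        n_excl <- n_excl + 1L
        next
      }
      trio <- pairs[ids, ]
      if (any(trio$lo < 0)) {
        n_excl <- n_excl + 1L
        next
      }
      n_called <- n_called + 1L
      if (trio_consistent(c(trio$lo[1L], trio$hi[1L]),
                          c(trio$lo[2L], trio$hi[2L]),
                          c(trio$lo[3L], trio$hi[3L]))) {
        n_cons <- n_cons + 1L
      }
    }
    data.frame(cnv_id = sub$cnv_id[1L],
               rate = if (n_called > 0L) n_cons / n_called else NA_real_,
               n_consistent = n_cons, n_called = n_called,
               n_excluded = n_excl, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Haploid and diploid copy-number distributions
#'
#' Pools all resolved calls: the haploid table counts chromosome-specific
#' copy values over both haplotype slots, the diploid table counts unordered
#' configurations (`"0/2"`, `"1/1"`, ...).  Both are normalized to sum to 1.
#'
#' @param calls Call table or `DiplotypeCallSet`(s).
#' @return List with named numeric vectors `haploid` and `diploid`.
#' @export
copy_distributions <- function(calls) {
  tab <- calls_table(calls)
  ok <- tab$copy_hapA >= 0 & tab$copy_hapB >= 0
  tab <- tab[ok, , drop = FALSE]
  if (nrow(tab) == 0L) stop("no resolved calls to summarize")
  hap <- c(tab$copy_hapA, tab$copy_hapB)
  haploid <- table(hap) / length(hap)
  dip_lab <- paste0(pmin(tab$copy_hapA, tab$copy_hapB), "/",
                    pmax(tab$copy_hapA, tab$copy_hapB))
  diploid <- table(dip_lab) / nrow(tab)
  list(haploid = c(haploid), diploid = c(diploid))
}

#' Mean r^2 between flanking SNPs and the CNV copy allele
#'
#' For each SNP, the squared correlation between the SNP allele (0/1 across
#' haplotype rows) and an indicator of the most frequent non-1 copy allele is
#' computed; monomorphic SNPs are skipped.  Low mean r^2 marks CNVs (for
#' example recurrent ones) whose haplotype background is uninformative.
#'
#' @param local A `LocalHaplotypeSet`.
#' @param hap_copies Chromosome-specific copy label per haplotype row (truth
#'   or inferred).
#' @return Mean r^2 over informative SNPs, or `NA` if every haplotype carries
#'   copy 1 or no SNP is informative.
#' @export
cnv_snp_r2 <- function(local, hap_copies) {
  stopifnot(inherits(local, "LocalHaplotypeSet"))
  hap_copies <- as.integer(hap_copies)
  if (length(hap_copies) != nrow(local$hap_matrix)) {
    stop("need one copy label per haplotype row")
  }
  non1 <- hap_copies[hap_copies != 1L]
  if (length(non1) == 0L) {
    return(NA_real_)
  }
  tab <- sort(table(non1), decreasing = TRUE)
  focal <- as.integer(names(tab)[1L])
  ind <- as.numeric(hap_copies == focal)
  if (stats::var(ind) == 0) return(NA_real_)
  r2 <- apply(local$hap_matrix, 2L, function(col) {
    if (stats::var(col) == 0) return(NA_real_)
    stats::cor(col, ind)^2
  })
  if (all(is.na(r2))) return(NA_real_)
  mean(r2, na.rm = TRUE)
}
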