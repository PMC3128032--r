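# Readers, writers and window selection for haplotype panels, CNV total-copy
# tables, pedigrees and diplotype calls.
#
# Coordinate conventions: CNV intervals are BED-style 0-based half-open
# [start, end).  SNP positions are stored 0-based; VCF POS (1-based) is
# converted on input.

# ---------------------------------------------------------------------------
# HaplotypePanel

#' Construct a phased haplotype panel
#'
#' A `HaplotypePanel` holds phased biallelic SNP haplotypes for a set of
#' individuals: two allele rows per individual (haplotype A then haplotype B),
#' one column per SNP, alleles coded 0/1.
#'
#' @param sample_ids Character vector of individual identifiers.
#' @param snp_ids Character vector of SNP identifiers.
#' @param positions Integer base-pair positions (0-based), strictly increasing.
#' @param alleles Integer matrix of 0/1 alleles with `2 * length(sample_ids)`
#'   rows (two consecutive rows per individual) and one column per SNP.
#' @param chrom Chromosome label, or `NA` if unknown.
#' @return An object of class `HaplotypePanel`.
#' @export
haplotype_panel <- function(sample_ids, snp_ids, positions, alleles,
                            chrom = NA_character_) {
  alleles <- as.matrix(alleles)
  storage.mode(alleles) <- "integer"
  n <- length(sample_ids)
  m <- length(snp_ids)
  if (nrow(alleles) != 2L * n) {
    stop("allele matrix must have two rows per individual (got ",
         nrow(alleles), " rows for ", n, " individuals)")
  }
  if (ncol(alleles) != m || length(positions) != m) {
    stop("snp_ids, positions and allele columns must agree in length")
  }
  if (m > 1L && any(diff(positions) <= 0)) {
    stop("SNP positions must be strictly increasing")
  }
  if (m > 0L && !all(alleles %in% c(0L, 1L))) {
    stop("alleles must be coded 0/1")
  }
  rownames(alleles) <- paste0(rep(sample_ids, each = 2L), c(".A", ".B"))
  colnames(alleles) <- snp_ids
  structure(
    list(sample_ids = as.character(sample_ids),
         snp_ids = as.character(snp_ids),
         positions = as.integer(positions),
         alleles = alleles,
         chrom = chrom),
    class = "HaplotypePanel"
  )
}

#' @export
print.HaplotypePanel <- function(x, ...) {
  cat("HaplotypePanel:", length(x$sample_ids), "individuals,",
      length(x$snp_ids), "SNPs",
      if (!is.na(x$chrom)) paste0("(", x$chrom, ")") else "", "\n")
  invisible(x)
}

# Recode one allele column so that the major symbol becomes 0 (ties broken by
# sort order).  Hamming distances are invariant to this coding.
recode_major_minor <- function(col) {
  tab <- sort(table(col), decreasing = TRUE)
  syms <- names(tab)
  if (length(syms) > 2L) {
    stop("more than two allele symbols observed at one SNP: ",
         paste(syms, collapse = ","))
  }
  if (length(syms) == 2L && tab[[1L]] == tab[[2L]]) {
    syms <- sort(syms)
  }
  as.integer(col != syms[1L])
}

#' Read phased haplotypes
#'
#' Reads a haplotype panel either from the simple whitespace-delimited
#' "hap-matrix" dialect or from a VCF with phased genotypes.
#'
#' The hap-matrix dialect has an optional `#chrom=<label>` comment, a header
#' line `sample_ids <id1> <id2> ...`, then one line per SNP:
#' `<snp_id> <position> <allele> ...` with two adjacent allele columns per
#' individual (haplotype A then B).  Arbitrary biallelic symbols are accepted
#' and recoded so that the major allele is 0.
#'
#' For VCF input, only biallelic records whose genotypes are all phased
#' (`|` separator) are used; other records are skipped and the skip count is
#' reported via `message()`.  VCF positions (1-based) are converted to the
#' package's 0-based convention.
#'
#' @param path Path to the input file.
#' @param format `"hapmatrix"` or `"vcf"`.
#' @param chrom Optional chromosome label overriding the one found in the file.
#' @return A [haplotype_panel()].
#' @export
read_haplotypes <- function(path, format = c("hapmatrix", "vcf"),
                            chrom = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "hapmatrix") {
    read_hapmatrix(path, chrom = chrom)
  } else {
    read_hap_vcf(path, chrom = chrom)
  }
}

read_hapmatrix <- function(path, chrom = NULL) {
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) stop("empty haplotype file: ", path)

  file_chrom <- NA_character_
  is_comment <- startsWith(lines, "#")
  for (cl in lines[is_comment]) {
    if (grepl("^#chrom=", cl)) file_chrom <- sub("^#chrom=", "", cl)
  }
  lineno <- lineno[!is_comment]
  lines <- lines[!is_comment]
  if (length(lines) == 0L) stop("no header line in haplotype file: ", path)

  header <- strsplit(trimws(lines[1L]), "[ \t]+")[[1L]]
  if (header[1L] != "sample_ids" || length(header) < 2L) {
    stop("line ", lineno[1L],
         ": expected header 'sample_ids <id> ...', got: ", lines[1L])
  }
  sample_ids <- header[-1L]
  n <- length(sample_ids)

  body <- lines[-1L]
  body_no <- lineno[-1L]
  if (length(body) == 0L) stop("haplotype file has no SNP lines: ", path)

  snp_ids <- character(length(body))
  positions <- integer(length(body))
  allele_chr <- matrix("", nrow = 2L * n, ncol = length(body))
  for (i in seq_along(body)) {
    tok <- strsplit(trimws(body[i]), "[ \t]+")[[1L]]
    if (length(tok) != 2L + 2L * n) {
      stop("line ", body_no[i], ": expected ", 2L + 2L * n,
           " fields (id, position, ", 2L * n, " alleles), got ", length(tok))
    }
    pos <- suppressWarnings(as.integer(tok[2L]))
    if (is.na(pos)) stop("line ", body_no[i], ": bad position '", tok[2L], "'")
    snp_ids[i] <- tok[1L]
    positions[i] <- pos
    allele_chr[, i] <- tok[-(1:2)]
  }
  if (length(positions) > 1L && any(diff(positions) <= 0)) {
    bad <- which(diff(positions) <= 0)[1L]
    stop("line ", body_no[bad + 1L], ": positions not strictly increasing")
  }
  alleles <- vapply(seq_len(ncol(allele_chr)),
                    function(j) recode_major_minor(allele_chr[, j]),
                    integer(2L * n))
  if (!is.matrix(alleles)) alleles <- matrix(alleles, nrow = 2L * n)
  haplotype_panel(sample_ids, snp_ids, positions, alleles,
                  chrom = chrom %||% file_chrom)
}

read_hap_vcf <- function(path, chrom = NULL) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  if (nrow(fix) == 0L) stop("VCF contains no records: ", path)
  gt <- vcfR::extract.gt(v, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(NULL, names(gt)))

  biallelic <- !is.na(fix[, "ALT"]) & !grepl(",", fix[, "ALT"], fixed = TRUE)
  phased <- apply(gt, 1L, function(g) all(grepl("^[01]\\|[01]$", g)))
  keep <- biallelic & phased
  n_skip <- sum(!keep)
  if (n_skip > 0L) {
    message("read_haplotypes: skipped ", n_skip,
            " multiallelic/unphased/incomplete VCF record(s)")
  }
  if (!any(keep)) stop("no usable phased biallelic records in VCF: ", path)

  gt <- gt[keep, , drop = FALSE]
  fix <- fix[keep, , drop = FALSE]
  sample_ids <- colnames(gt)
  n <- length(sample_ids)
  alleles <- matrix(0L, nrow = 2L * n, ncol = nrow(gt))
  for (j in seq_len(n)) {
    parts <- strsplit(gt[, j], "|", fixed = TRUE)
    alleles[2L * j - 1L, ] <- as.integer(vapply(parts, `[`, "", 1L))
    alleles[2L * j, ] <- as.integer(vapply(parts, `[`, "", 2L))
  }
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <-
    paste0("snp", which(is.na(ids) | ids == "."))
  haplotype_panel(sample_ids, ids,
                  positions = as.integer(fix[, "POS"]) - 1L,
                  alleles = alleles,
                  chrom = chrom %||% fix[1L, "CHROM"])
}

#' Write a haplotype panel in the hap-matrix dialect
#'
#' @param panel A [haplotype_panel()].
#' @param path Output file path.
#' @export
write_haplotypes <- function(panel, path) {
  stopifnot(inherits(panel, "HaplotypePanel"))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.na(panel$chrom)) writeLines(paste0("#chrom=", panel$chrom), con)
  writeLines(paste(c("sample_ids", panel$sample_ids), collapse = " "), con)
  for (i in seq_along(panel$snp_ids)) {
    writeLines(paste(c(panel$snp_ids[i], panel$positions[i],
                       panel$alleles[, i]), collapse = " "), con)
  }
  invisible(path)
}

# ---------------------------------------------------------------------------
# CNVRecord

#' Construct a CNV record
#'
#' @param cnv_id CNV identifier.
#' @param chrom Chromosome label.
#' @param start,end 0-based half-open interval of the CNV.
#' @param totals Named integer vector of per-individual total copy numbers;
#'   `NA` marks a missing measurement.
#' @return An object of class `CNVRecord`.
#' @export
cnv_record <- function(cnv_id, chrom, start, end, totals) {
  if (end <= start) stop("CNV end must exceed start")
  nm <- names(totals)
  totals <- round(as.numeric(totals))
  if (any(totals < 0, na.rm = TRUE)) stop("total copy numbers must be >= 0")
  storage.mode(totals) <- "integer"
  names(totals) <- nm
  if (is.null(names(totals))) stop("totals must be named by sample id")
  structure(list(cnv_id = as.character(cnv_id), chrom = as.character(chrom),
                 start = as.integer(start), end = as.integer(end),
                 totals = totals),
            class = "CNVRecord")
}

#' @export
print.CNVRecord <- function(x, ...) {
  cat("CNVRecord ", x$cnv_id, ": ", x$chrom, ":[", x$start, ",", x$end,
      "), totals for ", length(x$totals), " individuals (",
      sum(is.na(x$totals)), " missing)\n", sep = "")
  invisible(x)
}

#' Read a CNV total-copy-number table
#'
#' Expects a header `cnv_id chrom start end <sample1> <sample2> ...` and one
#' row per CNV.  Cells must be non-negative integers; `.` or `NA` marks a
#' missing total (the individual is excluded from that CNV downstream but kept
#' for others).
#'
#' @param path Path to a tab- or space-delimited table.
#' @return A list of [cnv_record()] objects, named by CNV id.
#' @export
read_cnv_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, colClasses = "character",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 5L) stop("CNV table needs cnv_id chrom start end + >=1 sample")
  if (!identical(tolower(names(df)[1:4]),
                 c("cnv_id", "chrom", "start", "end"))) {
    stop("CNV table header must start with: cnv_id chrom start end")
  }
  samples <- names(df)[-(1:4)]
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    cells <- as.character(df[i, -(1:4)])
    cells[cells %in% c(".", "NA", "")] <- NA_character_
    bad <- !is.na(cells) & !grepl("^-?[0-9]+$", cells)
    if (any(bad)) {
      stop("CNV table row ", i, ": non-integer total '",
           cells[which(bad)[1L]], "'")
    }
    totals <- as.integer(cells)
    if (any(totals < 0, na.rm = TRUE)) {
      stop("CNV table row ", i, ": negative total copy number")
    }
    names(totals) <- samples
    out[[i]] <- cnv_record(df$cnv_id[i], df$chrom[i],
                           as.integer(df$start[i]), as.integer(df$end[i]),
                           totals)
  }
  names(out) <- vapply(out, function(x) x$cnv_id, "")
  out
}

#' Write a CNV total-copy-number table
#'
#' @param cnvs A `CNVRecord` or list of them (samples must agree).
#' @param path Output file path.
#' @export
write_cnv_table <- function(cnvs, path) {
  if (inherits(cnvs, "CNVRecord")) cnvs <- list(cnvs)
  samples <- names(cnvs[[1L]]$totals)
  rows <- lapply(cnvs, function(x) {
    tot <- as.character(x$totals[samples])
    tot[is.na(tot)] <- "."
    c(x$cnv_id, x$chrom, x$start, x$end, tot)
  })
  tab <- do.call(rbind, rows)
  colnames(tab) <- c("cnv_id", "chrom", "start", "end", samples)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Pedigree

#' Read a trio pedigree table (`child father mother`)
#'
#' @param path Path to a whitespace-delimited table with header.
#' @param sample_ids Optional vector of known sample ids; if given, all
#'   pedigree ids must resolve to it.
#' @return A data.frame with columns child, father, mother.
#' @export
read_pedigree <- function(path, sample_ids = NULL) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("child", "father", "mother") %in% names(df))) {
    stop("pedigree must have columns: child father mother")
  }
  df <- df[, c("child", "father", "mother")]
  if (any(df$child == df$father | df$child == df$mother)) {
    stop("pedigree contains an individual who is their own parent")
  }
  if (!is.null(sample_ids)) {
    unknown <- setdiff(unlist(df), sample_ids)
    if (length(unknown)) {
      stop("pedigree ids not present in panel: ",
           paste(unknown, collapse = ", "))
    }
  }
  df
}

# ---------------------------------------------------------------------------
# Window selection

#' Select the SNP window around a CNV
#'
#' Restricts a panel to SNPs with position in `[start - f*L, end + f*L)` where
#' `L = end - start` and `f` is the extension factor.  The default `f = 1`
#' (one-fold extension, i.e. the window spans three times the CNV length)
#' is the setting at which inference accuracy is highest on simulated data.
#' Alleles are recoded per window so the major allele is 0 (hamming distances
#' are unaffected).
#'
#' @param panel A [haplotype_panel()].
#' @param cnv A [cnv_record()] on the same chromosome.
#' @param extension_factor Non-negative flank multiplier `f` (default 1).
#' @return An object of class `LocalHaplotypeSet` with fields `cnv_id`,
#'   `sample_ids`, `haplotype_strings` (two per individual),
#'   `hap_matrix`, `snp_ids`, `positions`, `window`, `n_snps`.  A window
#'   containing zero SNPs is returned with `n_snps = 0` so the caller can
#'   widen or skip.
#' @export
select_window <- function(panel, cnv, extension_factor = 1.0) {
  stopifnot(inherits(panel, "HaplotypePanel"), inherits(cnv, "CNVRecord"))
  if (extension_factor < 0) stop("extension_factor must be >= 0")
  if (!is.na(panel$chrom) && panel$chrom != cnv$chrom) {
    stop("panel chromosome (", panel$chrom, ") differs from CNV chromosome (",
         cnv$chrom, ")")
  }
  len <- cnv$end - cnv$start
  lo <- cnv$start - extension_factor * len
  hi <- cnv$end + extension_factor * len
  idx <- which(panel$positions >= lo & panel$positions < hi)
  hap <- panel$alleles[, idx, drop = FALSE]
  # per-window major/minor recode
  if (length(idx) > 0L) {
    flip <- colMeans(hap) > 0.5
    hap[, flip] <- 1L - hap[, flip, drop = FALSE]
  }
  strings <- apply(hap, 1L, paste0, collapse = "")
  if (length(idx) == 0L) strings <- rep("", nrow(panel$alleles))
  structure(
    list(cnv_id = cnv$cnv_id,
         sample_ids = panel$sample_ids,
         haplotype_strings = strings,
         hap_matrix = hap,
         snp_ids = panel$snp_ids[idx],
         positions = panel$positions[idx],
         window = c(lo = lo, hi = hi),
         n_snps = length(idx)),
    class = "LocalHaplotypeSet"
  )
}

#' @export
print.LocalHaplotypeSet <- function(x, ...) {
  cat("LocalHaplotypeSet for", x$cnv_id, "-", length(x$sample_ids),
      "individuals,", x$n_snps, "SNPs in window [",
      x$window[1L], ",", x$window[2L], ")\n")
  invisible(x)
}

# Restrict a LocalHaplotypeSet to a subset of samples (used to drop
# individuals with missing totals from one CNV without touching others).
local_subset <- function(local, keep) {
  stopifnot(inherits(local, "LocalHaplotypeSet"))
  idx <- match(keep, local$sample_ids)
  if (anyNA(idx)) stop("unknown sample id in subset")
  rows <- as.vector(rbind(2L * idx - 1L, 2L * idx))
  local$sample_ids <- local$sample_ids[idx]
  local$haplotype_strings <- local$haplotype_strings[rows]
  local$hap_matrix <- local$hap_matrix[rows, , drop = FALSE]
  local
}

# ---------------------------------------------------------------------------
# Diplotype call I/O

# Canonical call table columns.
CALL_COLUMNS <- c("cnv_id", "sample_id", "copy_hapA", "copy_hapB",
                  "total", "satisfied", "k")

#' Coerce diplotype calls to their canonical table form
#'
#' @param calls A `DiplotypeCallSet`, a list of them, or a data.frame already
#'   in table form.
#' @return A data.frame with columns cnv_id, sample_id, copy_hapA, copy_hapB,
#'   total, satisfied, k.  Unresolved copies are coded -1.
#' @export
calls_table <- function(calls) {
  if (is.data.frame(calls)) {
    stopifnot(all(CALL_COLUMNS %in% names(calls)))
    return(calls[, CALL_COLUMNS])
  }
  if (inherits(calls, "DiplotypeCallSet")) calls <- list(calls)
  do.call(rbind, lapply(calls, function(cs) {
    data.frame(cnv_id = cs$cnv_id,
               sample_id = cs$calls$sample_id,
               copy_hapA = cs$calls$copy_hapA,
               copy_hapB = cs$calls$copy_hapB,
               total = cs$calls$total,
               satisfied = cs$calls$satisfied,
               k = cs$chosen_k,
               stringsAsFactors = FALSE)
  }))
}

#' Write diplotype calls to a TSV file
#'
#' Unresolved copy numbers (coded -1) are serialized as `NA` with a warning.
#' `read_calls()` restores them, so write/read round-trips are lossless.
#'
#' @param calls A `DiplotypeCallSet`, list of them, or call table.
#' @param path Output file path.
#' @export
write_calls <- function(calls, path) {
  tab <- calls_table(calls)
  if (any(tab$copy_hapA < 0 | tab$copy_hapB < 0)) {
    warning("unresolved calls (-1) serialized as NA")
    tab$copy_hapA[tab$copy_hapA < 0] <- NA_integer_
    tab$copy_hapB[tab$copy_hapB < 0] <- NA_integer_
  }
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a diplotype call table written by [write_calls()]
#'
#' @param path Path to the TSV file.
#' @return The canonical call table (see [calls_table()]).
#' @export
read_calls <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  stopifnot(all(CALL_COLUMNS %in% names(df)))
  df$copy_hapA[is.na(df$copy_hapA)] <- -1L
  df$copy_hapB[is.na(df$copy_hapB)] <- -1L
  df$copy_hapA <- as.integer(df$copy_hapA)
  df$copy_hapB <- as.integer(df$copy_hapB)
  df$satisfied <- as.logical(df$satisfied)
  df[, CALL_COLUMNS]
}
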