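## Omics bookkeeping: MS identification acceptance filters, fold-change
## threshold subsetting of differential comparisons, and up/down overlap
## counting.
##
## Fold changes are SIGNED LINEAR values (+2 = twofold up, -3 = threefold
## down); values in (-1, 1) do not occur under this convention. Converters to
## and from log2 ratios are provided.

#' Read an interactome identification table
#'
#' Expects the column schema of a mass-spectrometry identification list:
#' protein_name, gene_symbol, theoretical_mass_da, n_peptides, coverage_pct,
#' optionally protein_probability and peptide_probability. Malformed rows
#' (non-numeric counts/masses, out-of-range coverage) are reported with their
#' file line numbers and dropped.
#'
#' The packaged fixture `ho1_interactome.csv` (see
#' `system.file("extdata", package = "ZipperQuant")`) holds the 56-protein
#' HO-1 co-immunoprecipitation list used throughout the examples.
#'
#' @param path CSV file path.
#' @return data.frame of identification records; dropped rows are reported in
#'   attribute `malformed` (integer file line numbers).
#' @examples
#' tab <- readInteractomeTable(system.file("extdata",
#'   "ho1_interactome.csv", package = "ZipperQuant"))
#' nrow(tab)
#' @export
readInteractomeTable <- function(path) {
  mandatory <- c("protein_name", "gene_symbol", "theoretical_mass_da",
                 "n_peptides", "coverage_pct")
  d <- utils::read.csv(path, stringsAsFactors = FALSE,
                       colClasses = "character")
  miss <- setdiff(mandatory, names(d))
  if (length(miss))
    stop(sprintf("missing mandatory column(s): %s", paste(miss, collapse = ", ")))
  if (nrow(d) == 0L) {
    out <- data.frame(protein_name = character(), gene_symbol = character(),
                      theoretical_mass_da = numeric(), n_peptides = integer(),
                      coverage_pct = numeric())
    attr(out, "malformed") <- integer()
    return(out)
  }
  num <- function(x) suppressWarnings(as.numeric(x))
  mass <- num(d$theoretical_mass_da)
  pep <- num(d$n_peptides)
  cov <- num(d$coverage_pct)
  bad <- !is.finite(mass) | mass <= 0 | !is.finite(pep) | pep < 1 |
    pep != round(pep) | !is.finite(cov) | cov <= 0 | cov > 100
  if (any(bad)) {
    warning(sprintf("dropping %d malformed row(s) at file line(s): %s",
                    sum(bad), paste(which(bad) + 1L, collapse = ", ")))
  }
  out <- data.frame(protein_name = d$protein_name[!bad],
                    gene_symbol = d$gene_symbol[!bad],
                    theoretical_mass_da = mass[!bad],
                    n_peptides = as.integer(pep[!bad]),
                    coverage_pct = cov[!bad],
                    stringsAsFactors = FALSE)
  for (opt in c("protein_probability", "peptide_probability")) {
    if (opt %in% names(d)) out[[opt]] <- num(d[[opt]])[!bad]
  }
  attr(out, "malformed") <- which(bad) + 1L
  out
}

#' Apply MS identification acceptance filters
#'
#' A record is kept iff its protein probability is strictly above
#' `minProteinProb`, its peptide probability strictly above `minPeptideProb`
#' (each filter applied only when the corresponding column is present), and
#' it has at least `minPeptides` identified peptides (inclusive >=). These
#' mirror the usual ProteinProphet/PeptideProphet acceptance convention
#' (protein > 99%, peptide > 95%, >= 2 peptides), and are configurable:
#' published identification lists often retain curated single-peptide
#' entries, so the peptide filter is a parameter rather than a constant.
#'
#' @param records data.frame from [readInteractomeTable()].
#' @param minProteinProb protein-probability threshold in [0, 1] (strict >).
#' @param minPeptideProb peptide-probability threshold in [0, 1] (strict >).
#' @param minPeptides minimum number of identified peptides (inclusive >=).
#' @return the accepted subset of `records`.
#' @export
acceptIdentifications <- function(records, minProteinProb = 0.99,
                                  minPeptideProb = 0.95, minPeptides = 2L) {
  assertScalar(minProteinProb, "minProteinProb", 0, upper = 1)
  assertScalar(minPeptideProb, "minPeptideProb", 0, upper = 1)
  assertScalar(minPeptides, "minPeptides", 0, integer = TRUE)
  keep <- records$n_peptides >= minPeptides
  if ("protein_probability" %in% names(records)) {
    keep <- keep & records$protein_probability > minProteinProb
  }
  if ("peptide_probability" %in% names(records)) {
    keep <- keep & records$peptide_probability > minPeptideProb
  }
  out <- records[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Validate a differential-expression table
#' @keywords internal
#' @noRd
checkDETable <- function(table) {
  need <- c("gene", "fold_change", "p_value")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("DE table missing column(s): %s", paste(miss, collapse = ", ")))
  if (any(!is.finite(table$fold_change)) || any(!is.finite(table$p_value)))
    stop("fold_change and p_value must be finite")
  if (any(abs(table$fold_change) < 1))
    stop("signed linear fold changes cannot lie in (-1, 1)")
  invisible(table)
}

#' Threshold a DE table into up/down gene sets at multiple cutoffs
#'
#' Up set at cutoff c: genes with `fold_change >= c` and `p_value < pMax`
#' (inclusive fold-change boundary, strict p boundary). Down set: genes with
#' `fold_change <= -c` and `p_value < pMax`. Sets are nested across
#' increasing cutoffs by construction.
#'
#' @param table data.frame with columns gene, fold_change (signed linear),
#'   p_value.
#' @param cutoffs linear fold-change cutoffs, all >= 1.
#' @param pMax p-value threshold (strict <).
#' @return a list with elements `up` and `down`, each a named list of
#'   character gene sets keyed by cutoff, plus `cutoffs` and `pMax`.
#' @examples
#' tab <- data.frame(gene = c("a", "b"), fold_change = c(2, -5),
#'                   p_value = c(0.01, 0.2))
#' thresholdDE(tab)$up[["2"]]
#' @export
thresholdDE <- function(table, cutoffs = c(2, 3, 5, 8), pMax = 0.05) {
  checkDETable(table)
  if (any(cutoffs < 1)) stop("cutoffs must be >= 1")
  assertScalar(pMax, "pMax", 0, upper = 1, strict_lower = TRUE)
  cutoffs <- sort(unique(as.numeric(cutoffs)))
  sig <- table$p_value < pMax
  up <- lapply(cutoffs, function(c) sort(table$gene[sig & table$fold_change >= c]))
  down <- lapply(cutoffs, function(c) sort(table$gene[sig & table$fold_change <= -c]))
  names(up) <- names(down) <- as.character(cutoffs)
  list(up = up, down = down, cutoffs = cutoffs, pMax = pMax)
}

#' Overlap of thresholded gene sets between two comparisons
#'
#' For each cutoff, intersects the up sets and the down sets of the two
#' comparisons (same-threshold subsets on both sides).
#'
#' @param setsA,setsB results of [thresholdDE()] with identical cutoffs.
#' @return a list with `summary` (data.frame: cutoff, n_up_a, n_up_b,
#'   n_up_overlap, n_down_a, n_down_b, n_down_overlap) and `sets` (per-cutoff
#'   list with up_overlap and down_overlap gene vectors).
#' @export
overlapComparisons <- function(setsA, setsB) {
  if (!identical(setsA$cutoffs, setsB$cutoffs))
    stop("the two comparisons use different cutoffs")
  keys <- as.character(setsA$cutoffs)
  sets <- lapply(keys, function(k) {
    list(up_overlap = intersect(setsA$up[[k]], setsB$up[[k]]),
         down_overlap = intersect(setsA$down[[k]], setsB$down[[k]]))
  })
  names(sets) <- keys
  summary <- data.frame(
    cutoff = setsA$cutoffs,
    n_up_a = vapply(keys, function(k) length(setsA$up[[k]]), integer(1L)),
    n_up_b = vapply(keys, function(k) length(setsB$up[[k]]), integer(1L)),
    n_up_overlap = vapply(keys, function(k) length(sets[[k]]$up_overlap),
                          integer(1L)),
    n_down_a = vapply(keys, function(k) length(setsA$down[[k]]), integer(1L)),
    n_down_b = vapply(keys, function(k) length(setsB$down[[k]]), integer(1L)),
    n_down_overlap = vapply(keys, function(k) length(sets[[k]]$down_overlap),
                            integer(1L)),
    row.names = NULL)
  list(summary = summary, sets = sets)
}

#' Convert signed linear fold changes to log2 ratios
#'
#' Signed linear convention: a ratio r >= 1 is reported as +r, a ratio r < 1
#' as -1/r. Hence +2 -> 1, -2 -> -1.
#'
#' @param fc signed linear fold changes (|fc| >= 1).
#' @return log2 ratios.
#' @export
foldChangeToLog2 <- function(fc) {
  if (any(abs(fc) < 1)) stop("signed linear fold changes cannot lie in (-1, 1)")
  sign(fc) * log2(abs(fc))
}

#' Convert log2 ratios to signed linear fold changes
#' @param l2 log2 ratios.
#' @return signed linear fold changes (+r for l2 >= 0, -r for l2 < 0).
#' @export
log2ToFoldChange <- function(l2) {
  ifelse(l2 >= 0, 2^l2, -(2^(-l2)))
}

#' Read a DE table from CSV
#' @param path CSV with columns gene, fold_change, p_value.
#' @return validated data.frame.
#' @export
readDETable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  checkDETable(d)
  d
}
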