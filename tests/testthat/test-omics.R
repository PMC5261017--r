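# MS acceptance filtering, fold-change thresholding and set overlaps.

fixturePath <- function() {
  system.file("extdata", "ho1_interactome.csv", package = "ZipperQuant")
}

test_that("the packaged interactome table parses to 56 records", {
  tab <- readInteractomeTable(fixturePath())
  expect_identical(nrow(tab), 56L)
  expect_identical(length(attr(tab, "malformed")), 0L)
})

test_that("known fixture rows carry their printed values", {
  tab <- readInteractomeTable(fixturePath())
  mkln1 <- tab[tab$gene_symbol == "MKLN1", ]
  expect_identical(mkln1$n_peptides, 11L)
  expect_identical(mkln1$coverage_pct, 17)
  expect_identical(mkln1$theoretical_mass_da, 84713)
})

test_that("the fixture round-trips through write/read without loss", {
  tab <- readInteractomeTable(fixturePath())
  tmp <- tempfile(fileext = ".csv")
  utils::write.csv(tab, tmp, row.names = FALSE)
  tab2 <- readInteractomeTable(tmp)
  attr(tab, "malformed") <- NULL; attr(tab2, "malformed") <- NULL
  expect_identical(tab, tab2)
})

test_that("header-only files parse to zero records without error", {
  tmp <- tempfile(fileext = ".csv")
  writeLines("protein_name,gene_symbol,theoretical_mass_da,n_peptides,coverage_pct",
             tmp)
  expect_identical(nrow(readInteractomeTable(tmp)), 0L)
})

test_that("missing mandatory columns and malformed rows are reported", {
  tmp <- tempfile(fileext = ".csv")
  writeLines(c("protein_name,gene_symbol,n_peptides,coverage_pct",
               "p,G,2,10"), tmp)
  expect_error(readInteractomeTable(tmp), "theoretical_mass_da")
  tmp2 <- tempfile(fileext = ".csv")
  writeLines(c("protein_name,gene_symbol,theoretical_mass_da,n_peptides,coverage_pct",
               "good,G1,1000,2,10",
               "bad,G2,notamass,2,10",
               "good2,G3,500,1,5"), tmp2)
  expect_warning(tab <- readInteractomeTable(tmp2), "line")
  expect_identical(nrow(tab), 2L)
  expect_identical(attr(tab, "malformed"), 3L)  # file line of the bad row
})

test_that("acceptance filters mirror a row-by-row oracle", {
  set.seed(23)
  n <- 20
  rec <- data.frame(protein_name = sprintf("p%02d", 1:n),
                    gene_symbol = sprintf("G%02d", 1:n),
                    theoretical_mass_da = stats::runif(n, 1e4, 2e5),
                    n_peptides = sample(1:6, n, replace = TRUE),
                    coverage_pct = stats::runif(n, 1, 60),
                    protein_probability = stats::runif(n, 0.9, 1),
                    peptide_probability = stats::runif(n, 0.9, 1))
  acc <- acceptIdentifications(rec)
  oracleKeep <- logical(n)
  for (i in 1:n) {  # exhaustive row-by-row check
    oracleKeep[i] <- rec$protein_probability[i] > 0.99 &&
      rec$peptide_probability[i] > 0.95 && rec$n_peptides[i] >= 2
  }
  expect_identical(acc$protein_name, rec$protein_name[oracleKeep])
})

test_that("single-peptide records are excluded at minPeptides = 2 and kept at 1", {
  rec <- data.frame(protein_name = "p", gene_symbol = "G",
                    theoretical_mass_da = 1e4, n_peptides = 1L,
                    coverage_pct = 5)
  expect_identical(nrow(acceptIdentifications(rec)), 0L)
  expect_identical(nrow(acceptIdentifications(rec, minPeptides = 1)), 1L)
  expect_error(acceptIdentifications(rec, minProteinProb = 1.2), "minProteinProb")
})

test_that("fold-change boundaries are inclusive and the p boundary strict", {
  tab <- data.frame(gene = c("a", "b", "c"),
                    fold_change = c(2, 5, -3),
                    p_value = c(0.01, 0.2, 0.05))
  sets <- thresholdDE(tab)
  expect_identical(sets$up[["2"]], "a")     # fc = 2 is included at cutoff 2
  expect_identical(sets$up[["3"]], character(0))
  expect_true(all(lengths(sets$down) == 0)) # p = 0.05 fails strict <
  expect_identical(sets$up[["5"]], character(0))  # p = 0.2 fails
  expect_error(thresholdDE(tab, cutoffs = 0.5), ">= 1")
  bad <- data.frame(gene = "x", fold_change = 0.5, p_value = 0.1)
  expect_error(thresholdDE(bad), "fold change")
})

test_that("random tables threshold identically to an exhaustive scan", {
  set.seed(24)
  for (rep in 1:20) {
    n <- 200
    tab <- data.frame(
      gene = sprintf("g%03d", 1:n),
      fold_change = sample(c(-1, 1), n, TRUE) * stats::runif(n, 1, 10),
      p_value = stats::runif(n))
    sets <- thresholdDE(tab)
    for (cf in c(2, 3, 5, 8)) {
      upOracle <- sort(tab$gene[tab$fold_change >= cf & tab$p_value < 0.05])
      dnOracle <- sort(tab$gene[tab$fold_change <= -cf & tab$p_value < 0.05])
      expect_identical(sets$up[[as.character(cf)]], upOracle)
      expect_identical(sets$down[[as.character(cf)]], dnOracle)
    }
    # nesting across increasing cutoffs
    for (k in 1:3) {
      expect_true(all(sets$up[[k + 1]] %in% sets$up[[k]]))
      expect_true(all(sets$down[[k + 1]] %in% sets$down[[k]]))
    }
  }
})

test_that("overlaps: self-overlap, disjoint inputs and symmetry", {
  de <- simulateDETables(300, 0.1, 0.1, seed = 4)
  a <- thresholdDE(de$tables[[1]])
  selfOv <- overlapComparisons(a, a)
  expect_identical(selfOv$sets[["2"]]$up_overlap, a$up[["2"]])
  tabB <- data.frame(gene = sprintf("other%03d", 1:50),
                     fold_change = rep(4, 50), p_value = rep(0.001, 50))
  b <- thresholdDE(tabB)
  expect_true(all(lengths(lapply(overlapComparisons(a, b)$sets,
                                 `[[`, "up_overlap")) == 0))
  ab <- overlapComparisons(a, b)$summary
  ba <- overlapComparisons(b, a)$summary
  expect_identical(ab$n_up_overlap, ba$n_up_overlap)
  bDiff <- thresholdDE(tabB, cutoffs = c(2, 4))
  expect_error(overlapComparisons(a, bDiff), "different cutoffs")
})

test_that("signed linear fold changes round-trip through log2", {
  fc <- c(2, -2, 3.5, -8, 1)
  expect_equal(log2ToFoldChange(foldChangeToLog2(fc)), fc)
  expect_equal(foldChangeToLog2(c(2, -2)), c(1, -1))
  expect_error(foldChangeToLog2(0.5), "fold changes")
})
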