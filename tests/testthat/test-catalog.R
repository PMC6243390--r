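test_that("packaged catalog loads with one record per chromatographic peak", {
  cat <- load_catalog()
  expect_s3_class(cat, "compound_catalog")
  expect_equal(nrow(cat), 71)
  expect_equal(sum(cat$name != "Unknown"), 53)
  expect_false(anyDuplicated(cat$peak_no) > 0)
  # fragment list-column parses mz|label pairs
  rg1 <- cat$fragments[[which(cat$peak_no == 27)]]
  expect_equal(nrow(rg1), 4)
  expect_equal(rg1$mz[2], 637.4392)
  expect_match(rg1$label[2], "Glc")
})

test_that("malformed catalog files are rejected", {
  bad <- tempfile(fileext = ".csv")
  writeLines("peak_no,name\n1,foo", bad)
  expect_error(load_catalog(bad), "missing required column")
  dup <- read.csv(system.file("extdata", "wxkl_catalog.csv",
                              package = "cardioscreen"))
  dup$peak_no[2] <- dup$peak_no[1]
  f <- tempfile(fileext = ".csv")
  write.csv(dup, f, row.names = FALSE)
  expect_error(load_catalog(f), "duplicate peak_no")
  empty <- tempfile(fileext = ".csv")
  writeLines("", empty)
  expect_error(load_catalog(empty))
  expect_error(load_catalog(tempfile()), "not found")
})

test_that("catalog validation recomputes printed ppm errors", {
  rep <- validate_catalog(load_catalog())
  row <- function(p) rep[rep$peak_no == p, ]
  # deprotonated-ion rows
  expect_equal(row(27)$adduct, "[M-H]-")
  expect_equal(row(27)$recomputed_ppm, 1.2)
  expect_equal(row(27)$status, "verified")
  expect_equal(row(26)$recomputed_ppm, 1.5)
  expect_equal(row(24)$recomputed_ppm, 1.0)
  expect_equal(row(28)$recomputed_ppm, -1.6)
  # lobetyol's detected m/z is the formate adduct
  expect_equal(row(66)$adduct, "[M-H+FA]-")
  expect_equal(row(66)$status, "verified")
  # peak 10's formula is inconsistent with its detected mass
  expect_equal(row(10)$status, "unverifiable")
})

test_that("most formula-bearing rows verify; failures are known discrepancies", {
  rep <- validate_catalog(load_catalog())
  cat <- load_catalog()
  has_claim <- nzchar(cat$formula) &
    !is.na(suppressWarnings(as.numeric(cat$error_ppm)))
  claimed <- rep[rep$peak_no %in% cat$peak_no[has_claim], ]
  expect_gte(mean(claimed$status == "verified"), 0.8)
  failing <- claimed$peak_no[claimed$status != "verified"]
  expect_true(all(failing %in% known_discrepancies()$peak_no))
})

test_that("validation report writes a readable CSV", {
  rep <- validate_catalog(load_catalog())
  f <- tempfile(fileext = ".csv")
  write_validation_report(rep, f)
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(rep))
  expect_equal(back$recomputed_ppm[back$peak_no == 27], 1.2)
})

test_that("fragment annotation identifies glycoside losses", {
  # ginsenoside Rg1: loss of one glucosyl unit
  ann <- annotate_fragment("C42H72O14", 637.4392)
  expect_true(ann$matched)
  expect_equal(ann$loss_composition, "Glc")
  # ginsenoside Re: glucosyl + rhamnosyl
  ann2 <- annotate_fragment("C48H82O18", 637.4377)
  expect_true(ann2$matched)
  expect_setequal(ann2$loss_composition, c("Glc", "Rha"))
  # the precursor ion itself needs no loss
  self <- annotate_fragment("C42H72O14",
                            adduct_mz(monoisotopic_mass("C42H72O14"),
                                      "[M-H]-"))
  expect_true(self$matched)
  expect_length(self$loss_composition, 0)
  # far-off mass does not match
  expect_false(annotate_fragment("C42H72O14", 100.0)$matched)
})

test_that("fragment annotation agrees with brute-force enumeration", {
  set.seed(21)
  for (i in 1:20) {
    counts <- random_formula()
    f <- stats::setNames(as.integer(counts), names(counts))
    class(f) <- "molecular_formula"
    # target a random loss multiset, jittered within tolerance
    k <- sample(0:3, 1)
    losses <- if (k) sample(names(neutral_losses), k, replace = TRUE)
              else character(0)
    target <- oracle_mass(counts) - 1.00727646 -
      sum(neutral_losses[losses]) + stats::runif(1, -0.015, 0.015)
    got <- annotate_fragment(f, target)
    want <- oracle_fragment(counts, target, neutral_losses)
    expect_equal(got$matched, !is.null(want))
    if (got$matched) {
      expect_equal(sort(got$loss_composition), want$losses)
      expect_equal(got$delta_da, want$delta, tolerance = 1e-9)
    }
  }
})
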