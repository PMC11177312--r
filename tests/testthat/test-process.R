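mutate_at_pos <- function(s, pos, to) {
  substr(s, pos, pos) <- to
  s
}

test_that("error-free libraries are recovered read-for-read from the truth sidecar", {
  for (name in c("AUCG", "DUCG")) {
    sys <- chemistry_system(name)
    spec <- construct_spec()
    m <- copying_model(sys, seq_error_rate = 0, seed = 21)
    td <- withr::local_tempdir()
    fq <- file.path(td, "lib.fastq"); tr <- file.path(td, "truth.tsv")
    simulate_library(m, spec, 2000, fq, tr)
    truth <- dplyr::as_tibble(utils::read.delim(tr, colClasses = c(
      classifications = "character", template = "character",
      product = "character")))
    truth$classifications[is.na(truth$classifications)] <- ""
    truth$product[is.na(truth$product)] <- ""
    out <- process_library(fq, spec, sys)
    expect_true(all(out$status == "pass"))
    expect_identical(out$template, truth$template)
    expect_identical(out$product, truth$product)
    expect_identical(out$classifications, truth$classifications)
    expect_identical(out$n_incorporated, truth$n_incorporated)
  }
})

test_that("anchor, length, quality and ambiguity filters fire with the right reasons", {
  spec <- construct_spec()
  sys <- chemistry_system("DUCG")
  scaffold <- nchar(spec$handle5) + spec$template_len
  clean <- paste0(spec$handle5, "ATCGAT", spec$loop, "TAGC")
  q <- strrep("I", nchar(clean))

  # two substitutions inside handle5 exceed max_anchor_mismatches = 1
  broken <- mutate_at_pos(mutate_at_pos(clean, 1, "G"), 2, "T")
  r <- extract_regions(c(clean, broken), c(q, q), spec, sys)
  expect_identical(r$status, c("pass", "fail"))
  expect_identical(r$fail_reason[2], "anchor_mismatch")

  # product region longer than template_len
  long <- paste0(spec$handle5, "ATCGAT", spec$loop, strrep("A", 9))
  r <- extract_regions(long, strrep("I", nchar(long)), spec, sys)
  expect_identical(r$fail_reason, "length_anomaly")

  # N inside the template region
  amb <- mutate_at_pos(clean, nchar(spec$handle5) + 3, "N")
  r <- extract_regions(amb, q, spec, sys)
  expect_identical(r$fail_reason, "ambiguous_base")

  # low quality in the product region only
  lowq <- mutate_at_pos(q, nchar(clean), "#")
  r <- extract_regions(clean, lowq, spec, sys)
  expect_identical(r$fail_reason, "low_quality")

  # quality in the constant regions is exempt beyond anchor matching
  lowq_const <- mutate_at_pos(q, scaffold + 2, "#")
  r <- extract_regions(clean, lowq_const, spec, sys)
  expect_identical(r$status, "pass")

  # reads shorter than the scaffold cannot present both anchors
  r <- extract_regions(substr(clean, 1, 10), substr(q, 1, 10), spec, sys)
  expect_identical(r$fail_reason, "anchor_mismatch")
})

test_that("template region is reversed into copying order and decoded", {
  spec <- construct_spec()
  sys <- chemistry_system("DUCG")
  # template region in read orientation "GATCGA" -> copying order "AGCTAG"
  read <- paste0(spec$handle5, "GATCGA", spec$loop, "CT")
  r <- extract_regions(read, strrep("I", nchar(read)), spec, sys)
  expect_identical(r$template, decode_from_sequencer(sys, "AGCTAG"))
  expect_identical(r$product, decode_from_sequencer(sys, "CT"))
})

test_that("classification matches direct table lookup on an exhaustive mini-construct", {
  # template_len = 2: all 16 templates x all products of length 0..2
  spec <- construct_spec(handle5 = "ACGTACGT", template_len = 2L,
                         loop = "GGATCCGGAT")
  for (name in c("AUCG", "DUCG")) {
    sys <- chemistry_system(name)
    letters4 <- c("A", "C", "G", "T")
    templates <- apply(expand.grid(letters4, letters4), 1, paste, collapse = "")
    products <- c("", letters4,
                  apply(expand.grid(letters4, letters4), 1, paste, collapse = ""))
    cases <- expand.grid(tmpl = templates, prod = products,
                         stringsAsFactors = FALSE)
    reads <- paste0(spec$handle5, cases$tmpl, spec$loop, cases$prod)
    r <- extract_regions(reads, strrep("I", nchar(reads)), spec, sys)
    r <- classify_reads(r, sys)
    expect_true(all(r$status == "pass"))
    # independent oracle: direct per-position complement lookup
    expected <- vapply(seq_len(nrow(cases)), function(i) {
      tmpl <- decode_from_sequencer(
        sys, paste(rev(strsplit(cases$tmpl[i], "")[[1]]), collapse = ""))
      prod <- decode_from_sequencer(sys, cases$prod[i])
      if (!nzchar(prod)) return("")
      tb <- strsplit(tmpl, "")[[1]][seq_len(nchar(prod))]
      pb <- strsplit(prod, "")[[1]]
      paste(ifelse(unname(sys$complement[tb]) == pb,
                   "complementary", "mismatch"), collapse = ",")
    }, character(1))
    expect_identical(r$classifications, expected)
  }
})

test_that("hand-classified reads come out as expected", {
  sys <- chemistry_system("DUCG")
  pr <- tibble::tibble(
    read_id = c("a", "b"),
    template = c("GDCUCG", "GDCUCG"),
    product = c("CU", ""),
    classifications = NA_character_,
    n_incorporated = NA_integer_,
    status = "pass",
    fail_reason = NA_character_
  )
  out <- classify_reads(pr, sys)
  expect_identical(out$classifications, c("complementary,complementary", ""))
  expect_identical(out$n_incorporated, c(2L, 0L))
})

test_that("process_library accounts for every read and handles empty input", {
  spec <- construct_spec()
  sys <- chemistry_system("DUCG")
  td <- withr::local_tempdir()
  fq <- file.path(td, "noisy.fastq")
  m <- copying_model(sys, seq_error_rate = 0.25, seed = 31)
  simulate_library(m, spec, 500, fq)
  out <- process_library(fq, spec, sys)
  s <- processing_summary(out)
  expect_identical(sum(s$n_reads), 500L)
  expect_identical(nrow(out), 500L)
  # heavy substitution noise must cost reads at the anchors
  expect_lt(sum(s$n_reads[s$status == "pass"]), 500L)

  empty <- file.path(td, "empty.fastq")
  file.create(empty)
  out0 <- process_library(empty, spec, sys)
  expect_identical(nrow(out0), 0L)
})
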