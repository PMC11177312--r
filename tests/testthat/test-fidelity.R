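# minimal read tibbles in truth-sidecar shape
make_reads <- function(template, product) {
  tibble::tibble(
    read_id = sprintf("r%03d", seq_along(template)),
    template = template,
    product = product,
    classifications = NA_character_,
    n_incorporated = nchar(product),
    status = "pass",
    fail_reason = NA_character_
  ) |>
    classify_reads(chemistry_system("DUCG"))
}

sim_with <- function(..., n = 5000, seed = 1, system = "DUCG") {
  m <- copying_model(system, seq_error_rate = 0, seed = seed, ...)
  set.seed(seed)
  simulate_reads(m, construct_spec(), n)
}

test_that("position tally partitions the library and matches a hand count", {
  sys <- chemistry_system("DUCG")
  # reads stopping at 0, 1 and 2 incorporations, all complementary
  reads <- make_reads(
    template = c("GDCUCG", "GDCUCG", "GDCUCG"),
    product = c("", "C", "CU")
  )
  tally <- tally_positions(reads, sys)
  freq <- position_frequencies(tally)
  expect_equal(freq$f_comp, c(2 / 3, 1 / 3, 0, 0, 0, 0))
  expect_equal(freq$f_unextended, c(1 / 3, 2 / 3, 1, 1, 1, 1))
  expect_equal(freq$f_comp + freq$f_mismatch + freq$f_unextended, rep(1, 6))
})

test_that("tally frequencies sum to 1 at every position and unextended is non-decreasing", {
  sys <- chemistry_system("DUCG")
  sim <- sim_with(seed = 41, n = 3000)
  freq <- position_frequencies(tally_positions(sim, sys))
  expect_equal(freq$f_comp + freq$f_mismatch + freq$f_unextended,
               rep(1, 6), tolerance = 1e-12)
  expect_true(all(diff(freq$f_unextended) >= 0))
  expect_error(tally_positions(sim[0, ], sys), "no passing reads")
})

test_that("mismatch frequency matches hand arithmetic and edge cases", {
  tally <- tibble::tibble(
    position = rep(1:4, each = 2),
    class = rep(c("complementary", "D:C"), 4),
    n = c(90, 10, 80, 10, 70, 10, 60, 10)
  )
  # 40 mismatched of 340 total incorporations over positions 1-4
  expect_equal(mismatch_frequency(tally, 1:4), 40 / 340)

  all_comp <- tibble::tibble(position = 1:4, class = "complementary", n = 10)
  expect_equal(mismatch_frequency(all_comp, 1:4), 0)
  all_mis <- tibble::tibble(position = 1:4, class = "D:G", n = 10)
  expect_equal(mismatch_frequency(all_mis, 1:4), 1)
  empty <- tibble::tibble(position = 1:4, class = "unextended", n = 10)
  expect_error(mismatch_frequency(empty, 1:4), "undefined")
})

test_that("product-base distribution conditions on fully complementary reads", {
  sys <- chemistry_system("DUCG")
  # the mismatch at position 3 excludes read r002 from every row
  reads <- make_reads(
    template = c("GDCUCG", "GDCUCG"),
    product = c("CUGD", "CUUD")
  )
  pbd <- product_base_distribution(reads, sys)
  expect_equal(pbd$n_reads[1:4], rep(1L, 4))
  expect_equal(pbd$C[1], 1)
  expect_equal(pbd$U[2], 1)
  expect_equal(pbd$G[3], 1)
  expect_equal(pbd$D[4], 1)
  # no qualifying reads at positions 5-6: undefined, not zero
  expect_true(all(is.na(pbd$C[5:6])))
  expect_equal(pbd$n_reads[5:6], c(0L, 0L))
})

test_that("uniform error-free copying gives uniform product rows; biased templates force the complement", {
  sys <- chemistry_system("DUCG")
  sim <- sim_with(p_ext_initial = 1, p_ext_after_match = 1,
                  p_ext_after_mismatch = 1, seed = 43, n = 10000)
  pbd <- product_base_distribution(sim, sys)
  for (b in sys$alphabet) {
    expect_true(all(within_3se(pbd[[b]], 0.25, pbd$n_reads)))
  }
  # template concentrated on G -> product rows concentrated on C
  simG <- sim_with(template_dist = c(0.01, 0.01, 0.01, 0.97),
                   p_ext_initial = 1, p_ext_after_match = 1, seed = 44,
                   n = 2000)
  pbdG <- product_base_distribution(simG, sys)
  expect_true(all(pbdG$C[1:6] > 0.9))
})

test_that("bridged-dinucleotide inference counts adjacent pairs in alphabet order", {
  sys <- chemistry_system("DUCG")
  reads <- make_reads(template = "CDGUCG", product = "GUC")
  bd <- inferred_bridged_distribution(reads, sys)
  expect_identical(nrow(bd), 16L)
  expect_identical(
    bd$species,
    paste0(rep(sys$alphabet, each = 4), "*", sys$alphabet)
  )
  expect_equal(sum(bd$frequency), 1, tolerance = 1e-12)
  expect_equal(bd$frequency[bd$species == "G*U"], 0.5)
  expect_equal(bd$frequency[bd$species == "U*C"], 0.5)

  short <- make_reads(template = c("CDGUCG", "CDGUCG"), product = c("G", ""))
  expect_error(inferred_bridged_distribution(short, sys), "undefined")
})

test_that("mismatch composition covers the 12 labels and sums to 1 per position", {
  sys <- chemistry_system("DUCG")
  sim <- sim_with(seed = 45, n = 5000)
  mc <- mismatch_composition(tally_positions(sim, sys), sys)
  expect_setequal(unique(mc$label),
                  c("complementary", enumerate_mismatches(sys)$label))
  sums <- mc |>
    dplyr::filter(!is.na(frequency)) |>
    dplyr::group_by(position) |>
    dplyr::summarise(s = sum(frequency))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-9)
})

test_that("a propensity matrix elevating one mismatch makes its label dominate", {
  sys <- chemistry_system("DUCG")
  W <- matrix(0.02, 4, 4, dimnames = list(sys$alphabet, sys$alphabet))
  for (t in sys$alphabet) W[t, sys$complement[[t]]] <- 1
  W["D", "G"] <- 0.8 # template D, wrong G
  sim <- sim_with(propensity = W, seed = 46, n = 4000)
  mc <- mismatch_composition(tally_positions(sim, sys), sys)
  row1 <- mc |> dplyr::filter(position == 1, label != "complementary")
  expect_identical(row1$label[which.max(row1$n)], "D:G")
})

test_that("extension past a pair recovers the generator ratio and its null", {
  sys <- chemistry_system("DUCG")
  sim <- sim_with(p_ext_initial = 0.9, p_ext_after_match = 0.6,
                  p_ext_after_mismatch = 0.6, seed = 47, n = 20000,
                  post_mismatch_error_boost = 1)
  ep <- extension_past_pair(sim, sys)
  expect_true(abs(ep$ratio - 1) < 0.15)

  # all reads stop at position 1: both probabilities 0, ratio undefined
  stopped <- make_reads(template = c("GDCUCG", "GDCUCG"),
                        product = c("C", "G"))
  ep0 <- extension_past_pair(stopped, sys)
  expect_equal(ep0$p_ext_given_comp, 0)
  expect_equal(ep0$p_ext_given_mismatch, 0)
  expect_true(is.na(ep0$ratio))
})

test_that("per-mismatch stalling reports observed labels only, bounded below by 1", {
  sys <- chemistry_system("DUCG")
  sim <- sim_with(p_ext_initial = 0.9, p_ext_after_match = 0.8,
                  p_ext_after_mismatch = 0.2, seed = 48, n = 50000)
  pms <- per_mismatch_stalling(sim, sys)
  expect_true(all(pms$n > 0))
  expect_true(all(pms$label %in% enumerate_mismatches(sys)$label))
  # label-independent generator: finite S values cluster around the true ratio
  finite_s <- pms$S[is.finite(pms$S) & pms$n >= 200]
  expect_true(all(abs(finite_s / 4 - 1) < 0.5))
})

test_that("post-mismatch boost elevates the error rate after a mismatch", {
  sys <- chemistry_system("DUCG")
  sim <- sim_with(post_mismatch_error_boost = 5, p_ext_initial = 0.9,
                  p_ext_after_match = 0.7, p_ext_after_mismatch = 0.5,
                  seed = 49, n = 20000)
  pme <- post_mismatch_error(sim, sys)
  expect_gt(pme$error_freq_after_mismatch, pme$overall_m)

  clean <- make_reads(template = "GDCUCG", product = "CUG")
  expect_error(post_mismatch_error(clean, sys), "undefined")
})

test_that("every statistic is invariant under read order", {
  sys <- chemistry_system("DUCG")
  sim <- sim_with(seed = 50, n = 3000)
  rep1 <- fidelity_report(sim, sys)
  set.seed(99)
  rep2 <- fidelity_report(sim[sample(nrow(sim)), ], sys)
  expect_equal(tidy(rep1), tidy(rep2))
  expect_equal(glance(rep1) |> dplyr::select(-n_reads),
               glance(rep2) |> dplyr::select(-n_reads))
  expect_identical(glance(rep1)$n_reads, glance(rep2)$n_reads)
})

test_that("system_ratio aligns D with A and flags undefined cells", {
  ducg <- chemistry_system("DUCG")
  aucg <- chemistry_system("AUCG")
  sim_d <- sim_with(seed = 51, n = 8000, system = "DUCG",
                    p_ext_initial = 0.8, p_ext_after_match = 0.8)
  sim_a0 <- sim_with(seed = 51, n = 8000, system = "AUCG",
                     p_ext_initial = 0.8, p_ext_after_match = 0.8)
  rep_d <- fidelity_report(sim_d, ducg)
  rep_a <- fidelity_report(sim_a0, aucg)
  sr <- system_ratio(rep_d, rep_a)
  # labels come from the numerator system; D row is matched against A
  expect_true("D" %in% sr$product_base$base)
  expect_false("A" %in% sr$product_base$base)
  expect_identical(nrow(sr$tp_pair), 16L)
  expect_identical(nrow(sr$bridged), 16L)

  # identical reports give all-ones ratios
  sr_self <- system_ratio(rep_d, rep_d)
  expect_true(all(abs(sr_self$product_base$ratio[
    !sr_self$product_base$undefined] - 1) < 1e-12))
  expect_true(all(abs(sr_self$tp_pair$ratio[!sr_self$tp_pair$undefined] - 1) <
                    1e-12))

  # zero denominator -> flagged undefined, not infinite
  rep_a_zero <- rep_a
  rep_a_zero$product_base_distribution$A <- 0
  sr0 <- system_ratio(rep_d, rep_a_zero)
  dcells <- sr0$product_base[sr0$product_base$base == "D", ]
  expect_true(all(dcells$undefined))
  expect_true(all(is.na(dcells$ratio)))
})
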