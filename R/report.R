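#' Consolidated fidelity report for a processed library
#'
#' Runs every sequencing-derived statistic on a set of processed reads:
#' position-wise yield/fidelity frequencies, the mismatch frequency m,
#' the product-base distribution among fully complementary products, the
#' inferred bridged-dinucleotide distribution, the position-dependent
#' mismatch composition, the overall template:product pair distribution,
#' extension probabilities past complementary versus mismatched pairs
#' with per-mismatch stalling factors, and the post-mismatch error
#' frequency.
#'
#' Statistics whose conditioning set is empty in a given library (e.g.
#' the bridged distribution when no product reaches length 2) are stored
#' as `NULL` rather than aborting the report.
#'
#' @inheritParams pair_positions
#' @param m_positions Position window for the mismatch frequency
#'   (default 1-4).
#' @param stalling_position Conditioning position for the stalling
#'   statistics (default 1).
#' @return An object of class `fidelity_report`: a list with elements
#'   `system`, `n_reads`, `m_positions`, `stalling_position`,
#'   `position_frequencies`, `mismatch_frequency`,
#'   `product_base_distribution`, `bridged_distribution`,
#'   `mismatch_composition`, `tp_pair_distribution`,
#'   `extension_past_pair`, `per_mismatch_stalling`,
#'   `post_mismatch_error`.
#' @seealso [system_ratio()] to compare two reports, [tidy.fidelity_report()]
#'   and [glance.fidelity_report()].
#' @export
fidelity_report <- function(reads, system, m_positions = 1:4,
                            stalling_position = 1L) {
  assert_system(system)
  reads <- passing(reads)
  tally <- tally_positions(reads, system)
  maybe <- function(expr) tryCatch(expr, error = function(e) NULL)
  structure(
    list(
      system = system$name,
      n_reads = nrow(reads),
      m_positions = m_positions,
      stalling_position = stalling_position,
      position_frequencies = position_frequencies(tally),
      mismatch_frequency = maybe(mismatch_frequency(tally, m_positions)),
      product_base_distribution = product_base_distribution(reads, system),
      bridged_distribution = maybe(inferred_bridged_distribution(reads, system)),
      mismatch_composition = mismatch_composition(tally, system),
      tp_pair_distribution = maybe(tp_pair_distribution(reads, system)),
      extension_past_pair = maybe(extension_past_pair(reads, system,
                                                      stalling_position)),
      per_mismatch_stalling = maybe(per_mismatch_stalling(reads, system,
                                                          stalling_position)),
      post_mismatch_error = maybe(post_mismatch_error(reads, system,
                                                      m_positions))
    ),
    class = "fidelity_report"
  )
}

#' @export
print.fidelity_report <- function(x, ...) {
  cat("<fidelity_report> system ", x$system, ", ", x$n_reads,
      " passing reads\n", sep = "")
  if (!is.null(x$mismatch_frequency)) {
    cat(sprintf("  mismatch frequency m (positions %s): %.4f\n",
                paste(range(x$m_positions), collapse = "-"),
                x$mismatch_frequency))
  }
  if (!is.null(x$extension_past_pair)) {
    cat(sprintf("  extension past comp/mismatch at position %d: %.3f / %.3f (ratio %.2f)\n",
                x$stalling_position,
                x$extension_past_pair$p_ext_given_comp,
                x$extension_past_pair$p_ext_given_mismatch,
                x$extension_past_pair$ratio))
  }
  invisible(x)
}

#' Tidy a fidelity report into one long tibble
#'
#' Stacks every frequency in the report into a single long tibble, one
#' row per (table, position, label) combination — convenient for joining,
#' filtering and plotting across libraries.
#'
#' @param x A [fidelity_report()].
#' @param ... Unused.
#' @return A tibble with `table`, `position` (`NA` for pooled tables),
#'   `label` and `frequency`.
#' @export
tidy.fidelity_report <- function(x, ...) {
  out <- list()
  out$position <- x$position_frequencies |>
    tidyr::pivot_longer(-"position", names_to = "label",
                        values_to = "frequency") |>
    dplyr::mutate(table = "position_frequencies")
  out$product <- x$product_base_distribution |>
    dplyr::select(-"n_reads") |>
    tidyr::pivot_longer(-"position", names_to = "label",
                        values_to = "frequency") |>
    dplyr::mutate(table = "product_base_distribution")
  if (!is.null(x$bridged_distribution)) {
    out$bridged <- x$bridged_distribution |>
      dplyr::transmute(position = NA_integer_, label = .data$species,
                       frequency = .data$frequency,
                       table = "bridged_distribution")
  }
  out$composition <- x$mismatch_composition |>
    dplyr::select("position", "label", "frequency") |>
    dplyr::mutate(table = "mismatch_composition")
  if (!is.null(x$tp_pair_distribution)) {
    out$tp <- x$tp_pair_distribution |>
      dplyr::transmute(position = NA_integer_, label = .data$label,
                       frequency = .data$frequency,
                       table = "tp_pair_distribution")
  }
  dplyr::bind_rows(out) |>
    dplyr::select("table", "position", "label", "frequency")
}

#' One-row summary of a fidelity report
#'
#' @param x A [fidelity_report()].
#' @param ... Unused.
#' @return A one-row tibble with the library-level scalars: `system`,
#'   `n_reads`, `m`, extension probabilities past complementary and
#'   mismatched pairs and their ratio, and the post-mismatch error
#'   frequency.
#' @export
glance.fidelity_report <- function(x, ...) {
  tibble::tibble(
    system = x$system,
    n_reads = x$n_reads,
    m = x$mismatch_frequency %||% NA_real_,
    p_ext_given_comp = x$extension_past_pair$p_ext_given_comp %||% NA_real_,
    p_ext_given_mismatch = x$extension_past_pair$p_ext_given_mismatch %||% NA_real_,
    stalling_ratio = x$extension_past_pair$ratio %||% NA_real_,
    error_freq_after_mismatch =
      x$post_mismatch_error$error_freq_after_mismatch %||% NA_real_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

align_base <- function(base, from_alpha, to_alpha) {
  to_alpha[match(base, from_alpha)]
}

ratio_or_na <- function(num, den) {
  ifelse(!is.na(den) & den > 0 & !is.na(num), num / den, NA_real_)
}

#' Compare two systems by element-wise frequency ratios
#'
#' Builds numerator/denominator ratio tables for the product-base
#' distribution, the overall template:product pair distribution and the
#' inferred bridged-dinucleotide distribution of two fidelity reports —
#' typically DUCG over AUCG, so that ratios above 1 mark enrichment in
#' the noncanonical system. The two purines are aligned by alphabet
#' position (D in DUCG corresponds to A in AUCG); labels in the output
#' are written in the numerator system's alphabet. Cells with a zero or
#' undefined denominator are flagged `undefined` and carry `NA` ratios.
#'
#' @param report_num,report_den [fidelity_report()] objects for the
#'   numerator (e.g. DUCG) and denominator (e.g. AUCG) systems. Position
#'   ranges must match.
#' @return A list of class `system_ratio` with tibbles `product_base`,
#'   `tp_pair` and `bridged` (the latter `NULL` when either report lacks
#'   it), each holding `frequency_num`, `frequency_den`, `ratio`,
#'   `undefined`.
#' @export
system_ratio <- function(report_num, report_den) {
  stopifnot(inherits(report_num, "fidelity_report"),
            inherits(report_den, "fidelity_report"))
  sys_n <- chemistry_system(report_num$system)
  sys_d <- chemistry_system(report_den$system)

  long_pbd <- function(rep, sys) {
    rep$product_base_distribution |>
      dplyr::select(-"n_reads") |>
      tidyr::pivot_longer(-"position", names_to = "base",
                          values_to = "frequency") |>
      dplyr::mutate(slot = match(.data$base, sys$alphabet))
  }
  a <- long_pbd(report_num, sys_n)
  b <- long_pbd(report_den, sys_d)
  if (!identical(sort(unique(a$position)), sort(unique(b$position)))) {
    stop("reports were built over different position ranges", call. = FALSE)
  }
  product_base <- dplyr::inner_join(
    a, b, by = c("position", "slot"), suffix = c("_num", "_den")
  ) |>
    dplyr::transmute(
      position = .data$position,
      base = .data$base_num,
      frequency_num = .data$frequency_num,
      frequency_den = .data$frequency_den,
      ratio = ratio_or_na(.data$frequency_num, .data$frequency_den),
      undefined = is.na(.data$ratio)
    )

  pair_slots <- function(tp, sys) {
    tp |>
      dplyr::mutate(
        t_slot = match(.data$template_base, sys$alphabet),
        p_slot = match(.data$product_base, sys$alphabet)
      )
  }
  tp_pair <- NULL
  if (!is.null(report_num$tp_pair_distribution) &&
      !is.null(report_den$tp_pair_distribution)) {
    tp_pair <- dplyr::inner_join(
      pair_slots(report_num$tp_pair_distribution, sys_n),
      pair_slots(report_den$tp_pair_distribution, sys_d),
      by = c("t_slot", "p_slot"), suffix = c("_num", "_den")
    ) |>
      dplyr::transmute(
        label = .data$label_num,
        status = .data$status_num,
        frequency_num = .data$frequency_num,
        frequency_den = .data$frequency_den,
        ratio = ratio_or_na(.data$frequency_num, .data$frequency_den),
        undefined = is.na(.data$ratio)
      )
  }

  bridged <- NULL
  if (!is.null(report_num$bridged_distribution) &&
      !is.null(report_den$bridged_distribution)) {
    slots <- function(bd, sys) {
      dplyr::mutate(bd,
                    f_slot = match(.data$first, sys$alphabet),
                    s_slot = match(.data$second, sys$alphabet))
    }
    bridged <- dplyr::inner_join(
      slots(report_num$bridged_distribution, sys_n),
      slots(report_den$bridged_distribution, sys_d),
      by = c("f_slot", "s_slot"), suffix = c("_num", "_den")
    ) |>
      dplyr::transmute(
        species = .data$species_num,
        frequency_num = .data$frequency_num,
        frequency_den = .data$frequency_den,
        ratio = ratio_or_na(.data$frequency_num, .data$frequency_den),
        undefined = is.na(.data$ratio)
      )
  }

  structure(
    list(system_num = report_num$system, system_den = report_den$system,
         product_base = product_base, tp_pair = tp_pair, bridged = bridged),
    class = "system_ratio"
  )
}

#' @export
print.system_ratio <- function(x, ...) {
  cat("<system_ratio> ", x$system_num, " / ", x$system_den, "\n", sep = "")
  print(x$product_base)
  invisible(x)
}
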