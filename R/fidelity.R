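passing <- function(reads) {
  if ("status" %in% names(reads)) {
    reads <- dplyr::filter(reads, .data$status == "pass")
  }
  reads
}

add_zero_cols <- function(df, cols) {
  for (col in setdiff(cols, names(df))) df[[col]] <- 0
  df
}

template_length <- function(reads) {
  L <- unique(nchar(reads$template))
  if (length(L) != 1) {
    stop("reads must share a single template length", call. = FALSE)
  }
  as.integer(L)
}

#' Long table of incorporated template:product pairs
#'
#' One row per incorporated position of each passing read, with the pair
#' classification in copying order. Most fidelity statistics are grouped
#' summaries of this table.
#'
#' @param reads A tibble of reads with `template`, `product` and
#'   `n_incorporated` columns (from [process_library()] or
#'   [simulate_reads()]); failed reads are dropped.
#' @param system A [chemistry_system()].
#' @return A tibble with `read_id`, `position`, `template_base`,
#'   `product_base`, `status`, `label`.
#' @export
pair_positions <- function(reads, system) {
  assert_system(system)
  reads <- passing(reads)
  L <- template_length(reads)
  comp <- system$complement
  out <- vector("list", L)
  for (i in seq_len(L)) {
    sub <- reads[reads$n_incorporated >= i, c("read_id", "template", "product")]
    if (nrow(sub) == 0) next
    tb <- substr(sub$template, i, i)
    pb <- substr(sub$product, i, i)
    out[[i]] <- tibble::tibble(
      read_id = sub$read_id,
      position = i,
      template_base = tb,
      product_base = pb,
      status = ifelse(unname(comp[tb]) == pb, "complementary", "mismatch"),
      label = paste0(tb, ":", pb)
    )
  }
  dplyr::bind_rows(out)
}

#' Per-position incorporation tally
#'
#' Counts, at every templating position, the passing reads whose product
#' at that position is complementary, mismatched (broken down by the 12
#' template:product mismatch labels) or absent (`unextended`, reads that
#' stopped before reaching the position). At each position the three
#' categories partition the library:
#' `n_comp + sum(n_mismatch) + n_unextended = n_total`.
#'
#' @inheritParams pair_positions
#' @return A tibble with `position`, `class` (`"complementary"`, a
#'   mismatch label, or `"unextended"`) and `n`, carrying the library size
#'   as attribute `n_total` and the template length as `template_len`.
#' @export
tally_positions <- function(reads, system) {
  assert_system(system)
  reads <- passing(reads)
  if (nrow(reads) == 0) stop("no passing reads to tally", call. = FALSE)
  L <- template_length(reads)
  pp <- pair_positions(reads, system)
  inc <- pp |>
    dplyr::mutate(
      class = ifelse(.data$status == "complementary",
                     "complementary", .data$label)
    ) |>
    dplyr::count(.data$position, .data$class)
  unext <- tibble::tibble(
    position = seq_len(L),
    class = "unextended",
    n = vapply(seq_len(L),
               function(i) sum(reads$n_incorporated < i), numeric(1))
  )
  out <- dplyr::bind_rows(inc, unext) |>
    dplyr::arrange(.data$position)
  attr(out, "n_total") <- nrow(reads)
  attr(out, "template_len") <- L
  out
}

#' Position-wise yield and fidelity frequencies
#'
#' Collapses a tally into the per-position frequencies of complementary
#' incorporation, mismatched incorporation and no extension; the three sum
#' to 1 at every position.
#'
#' @param tally A tibble from [tally_positions()].
#' @return A tibble with `position`, `f_comp`, `f_mismatch`,
#'   `f_unextended`.
#' @export
position_frequencies <- function(tally) {
  n_total <- attr(tally, "n_total")
  tally |>
    dplyr::mutate(group = dplyr::case_when(
      .data$class == "complementary" ~ "f_comp",
      .data$class == "unextended" ~ "f_unextended",
      TRUE ~ "f_mismatch"
    )) |>
    dplyr::group_by(.data$position, .data$group) |>
    dplyr::summarise(f = sum(.data$n) / n_total, .groups = "drop") |>
    tidyr::pivot_wider(names_from = "group", values_from = "f",
                       values_fill = 0) |>
    add_zero_cols(c("f_comp", "f_mismatch", "f_unextended")) |>
    dplyr::select(dplyr::all_of(
      c("position", "f_comp", "f_mismatch", "f_unextended")))
}

#' Mismatch frequency over a position window
#'
#' The fraction of mismatched over total incorporations in the window
#' (default positions 1-4, the window attached to the reported per-library
#' mismatch frequency m).
#'
#' @param tally A tibble from [tally_positions()].
#' @param positions Integer vector of positions to pool.
#' @return A single number in \[0, 1\].
#' @export
mismatch_frequency <- function(tally, positions = 1:4) {
  win <- tally[tally$position %in% positions & tally$class != "unextended", ]
  n_inc <- sum(win$n)
  if (n_inc == 0) {
    stop("mismatch frequency undefined: no incorporations in the window",
         call. = FALSE)
  }
  sum(win$n[win$class != "complementary"]) / n_inc
}

fully_complementary <- function(reads) {
  reads <- passing(reads)
  reads[!grepl("mismatch", reads$classifications, fixed = TRUE) &
          reads$n_incorporated > 0, ]
}

#' Product-base distribution among fully complementary products
#'
#' Restricted to reads whose every incorporated base is complementary to
#' its template base, the frequency of each product base at each position
#' (over reads extended at least that far). A read with any mismatch
#' contributes to no position. Positions with no qualifying reads are
#' reported with `NA` frequencies (undefined, not zero).
#'
#' @inheritParams pair_positions
#' @return A tibble with `position`, one frequency column per alphabet
#'   base, and `n_reads` (qualifying reads at that position). Base rows
#'   sum to 1 where defined.
#' @export
product_base_distribution <- function(reads, system) {
  assert_system(system)
  fc <- fully_complementary(reads)
  L <- template_length(passing(reads))
  counts <- tidyr::expand_grid(
    position = seq_len(L),
    product_base = system$alphabet
  ) |>
    dplyr::left_join(
      if (nrow(fc) > 0) {
        dplyr::count(pair_positions(fc, system),
                     .data$position, .data$product_base)
      } else {
        tibble::tibble(position = integer(), product_base = character(),
                       n = integer())
      },
      by = c("position", "product_base")
    ) |>
    tidyr::replace_na(list(n = 0L))
  counts |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(
      n_reads = sum(.data$n),
      frequency = ifelse(.data$n_reads > 0, .data$n / .data$n_reads, NA_real_)
    ) |>
    dplyr::ungroup() |>
    dplyr::select(-"n") |>
    tidyr::pivot_wider(names_from = "product_base",
                       values_from = "frequency") |>
    dplyr::relocate("n_reads", .after = dplyr::last_col())
}

#' Inferred bridged-dinucleotide distribution
#'
#' Nonenzymatic primer extension proceeds mainly through 5'-5'
#' imidazolium-bridged dinucleotides that bind the template via two base
#' pairs, so each adjacent pair of incorporated bases in a correctly
#' copied product reflects one reacted bridged species. Every adjacent
#' pair `(product[i], product[i+1])` within fully complementary reads
#' contributes one count to species `N1*N2`; the 16 counts are normalized
#' to sum 1.
#'
#' @inheritParams pair_positions
#' @return A 16-row tibble with `species` (e.g. `"D*U"`), `first`,
#'   `second`, `n` and `frequency`, in alphabet-order indexing.
#' @export
inferred_bridged_distribution <- function(reads, system) {
  assert_system(system)
  fc <- fully_complementary(reads)
  fc <- fc[fc$n_incorporated >= 2, ]
  if (nrow(fc) == 0) {
    stop("bridged-dinucleotide distribution undefined: no adjacent pairs",
         call. = FALSE)
  }
  pairs <- purrr::map(seq_len(max(fc$n_incorporated) - 1L), function(i) {
    sub <- fc[fc$n_incorporated >= i + 1L, ]
    tibble::tibble(first = substr(sub$product, i, i),
                   second = substr(sub$product, i + 1L, i + 1L))
  }) |>
    dplyr::bind_rows()
  tidyr::expand_grid(first = system$alphabet, second = system$alphabet) |>
    dplyr::left_join(dplyr::count(pairs, .data$first, .data$second),
                     by = c("first", "second")) |>
    tidyr::replace_na(list(n = 0L)) |>
    dplyr::mutate(
      species = paste0(.data$first, "*", .data$second),
      frequency = .data$n / sum(.data$n)
    ) |>
    dplyr::select("species", "first", "second", "n", "frequency")
}

#' Position-dependent mismatch composition
#'
#' The frequency of each of the 12 mismatch labels among incorporations
#' at each position; together with the complementary frequency the 13
#' classes sum to 1 per position.
#'
#' @param tally A tibble from [tally_positions()].
#' @param system A [chemistry_system()].
#' @return A tibble with `position`, `label` (12 mismatch labels plus
#'   `"complementary"`), `n` and `frequency` (share of incorporations at
#'   that position).
#' @export
mismatch_composition <- function(tally, system) {
  assert_system(system)
  labels <- c("complementary", enumerate_mismatches(system)$label)
  L <- attr(tally, "template_len")
  inc <- tally[tally$class != "unextended", ]
  tidyr::expand_grid(position = seq_len(L), label = labels) |>
    dplyr::left_join(
      dplyr::select(inc, "position", label = "class", "n"),
      by = c("position", "label")
    ) |>
    tidyr::replace_na(list(n = 0L)) |>
    dplyr::group_by(.data$position) |>
    dplyr::mutate(frequency = .data$n / dplyr::na_if(sum(.data$n), 0)) |>
    dplyr::ungroup()
}

#' Probability of extension past a complementary versus mismatched pair
#'
#' Among reads extended at least to `position`, the probability of
#' incorporating at `position + 1` conditioned on the status of the pair
#' at `position`, and their ratio — the sequencing analogue of the
#' rate-ratio stalling factor.
#'
#' @inheritParams pair_positions
#' @param position Conditioning position (default 1).
#' @return A one-row tibble with `p_ext_given_comp`,
#'   `p_ext_given_mismatch`, `ratio`, and the conditioning counts
#'   `n_comp`, `n_mismatch`. An empty conditioning side yields `NA` for
#'   its probability and the ratio.
#' @export
extension_past_pair <- function(reads, system, position = 1L) {
  assert_system(system)
  reads <- passing(reads)
  at <- reads[reads$n_incorporated >= position, ]
  if (nrow(at) == 0) {
    stop("no reads extended to the conditioning position", call. = FALSE)
  }
  comp <- system$complement
  tb <- substr(at$template, position, position)
  pb <- substr(at$product, position, position)
  is_comp <- unname(comp[tb]) == pb
  extended <- at$n_incorporated >= position + 1L
  n_comp <- sum(is_comp)
  n_mis <- sum(!is_comp)
  p_c <- if (n_comp > 0) mean(extended[is_comp]) else NA_real_
  p_m <- if (n_mis > 0) mean(extended[!is_comp]) else NA_real_
  tibble::tibble(
    position = position,
    p_ext_given_comp = p_c,
    p_ext_given_mismatch = p_m,
    ratio = ifelse(!is.na(p_c) && !is.na(p_m) && p_m > 0,
                   p_c / p_m, NA_real_),
    n_comp = n_comp,
    n_mismatch = n_mis
  )
}

#' Per-mismatch extension probability and stalling factor
#'
#' For each mismatch label observed at the conditioning position, the
#' probability of extending to the next position and the stalling factor
#' `S(label) = p_ext_given_comp / p_ext(label)`. Labels with zero
#' occurrences at the position are absent from the result.
#'
#' @inheritParams extension_past_pair
#' @return A tibble with `label`, `n` (occurrences at the position),
#'   `p_ext` and `S`.
#' @export
per_mismatch_stalling <- function(reads, system, position = 1L) {
  assert_system(system)
  reads <- passing(reads)
  at <- reads[reads$n_incorporated >= position, ]
  if (nrow(at) == 0) {
    stop("no reads extended to the conditioning position", call. = FALSE)
  }
  comp <- system$complement
  tb <- substr(at$template, position, position)
  pb <- substr(at$product, position, position)
  is_comp <- unname(comp[tb]) == pb
  extended <- at$n_incorporated >= position + 1L
  p_c <- if (any(is_comp)) mean(extended[is_comp]) else NA_real_
  tibble::tibble(
    label = paste0(tb, ":", pb)[!is_comp],
    extended = extended[!is_comp]
  ) |>
    dplyr::group_by(.data$label) |>
    dplyr::summarise(n = dplyr::n(), p_ext = mean(.data$extended),
                     .groups = "drop") |>
    dplyr::mutate(S = ifelse(.data$p_ext > 0, p_c / .data$p_ext, Inf)) |>
    dplyr::arrange(.data$label)
}

#' Error frequency after a mismatch versus overall mismatch frequency
#'
#' Among transitions where position `i` is mismatched and position
#' `i + 1` was incorporated, the fraction of mismatched `i + 1`
#' incorporations, paired with the overall mismatch frequency for
#' comparison. A mismatched priming pair elevates the error rate of the
#' next incorporation when this exceeds `overall_m`.
#'
#' @inheritParams pair_positions
#' @param m_positions Window for the overall mismatch frequency.
#' @return A one-row tibble with `error_freq_after_mismatch`,
#'   `n_transitions` and `overall_m`.
#' @export
post_mismatch_error <- function(reads, system, m_positions = 1:4) {
  assert_system(system)
  reads <- passing(reads)
  pp <- pair_positions(reads, system)
  trans <- pp |>
    dplyr::group_by(.data$read_id) |>
    dplyr::arrange(.data$position, .by_group = TRUE) |>
    dplyr::mutate(prev_status = dplyr::lag(.data$status)) |>
    dplyr::ungroup() |>
    dplyr::filter(.data$prev_status == "mismatch")
  if (nrow(trans) == 0) {
    stop("post-mismatch error undefined: no extensions past a mismatch",
         call. = FALSE)
  }
  overall_m <- mismatch_frequency(tally_positions(reads,
                                                  system), m_positions)
  tibble::tibble(
    error_freq_after_mismatch = mean(trans$status == "mismatch"),
    n_transitions = nrow(trans),
    overall_m = overall_m
  )
}

#' Overall template:product pair distribution
#'
#' Frequency of each of the 16 ordered template:product pairs among all
#' incorporations (complementary plus mismatched), pooled over positions.
#'
#' @inheritParams pair_positions
#' @return A 16-row tibble with `label`, `template_base`, `product_base`,
#'   `status`, `n`, `frequency`.
#' @export
tp_pair_distribution <- function(reads, system) {
  assert_system(system)
  pp <- pair_positions(reads, system)
  if (nrow(pp) == 0) stop("no incorporations", call. = FALSE)
  tidyr::expand_grid(
    template_base = system$alphabet,
    product_base = system$alphabet
  ) |>
    dplyr::mutate(
      label = paste0(.data$template_base, ":", .data$product_base),
      status = ifelse(
        unname(system$complement[.data$template_base]) == .data$product_base,
        "complementary", "mismatch")
    ) |>
    dplyr::left_join(dplyr::count(pp, .data$label), by = "label") |>
    tidyr::replace_na(list(n = 0L)) |>
    dplyr::mutate(frequency = .data$n / sum(.data$n)) |>
    dplyr::select("label", "template_base", "product_base", "status",
                  "n", "frequency")
}
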