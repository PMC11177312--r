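#' Recover template and product from hairpin reads
#'
#' Locates the two constant anchors of the construct in each read at their
#' fixed offsets (`handle5` at 0, `loop` immediately after the template
#' region), extracts the randomized template region and the trailing
#' product region, reverses the template into copying order, and decodes
#' both from cDNA letters into the declared system alphabet.
#'
#' Filters, applied in this order per read:
#' \describe{
#'   \item{`anchor_mismatch`}{either anchor differs from its expected
#'     sequence by more than `max_anchor_mismatches` substitutions
#'     (fixed-offset Hamming distance; no indel alignment), or the read is
#'     shorter than the constant scaffold.}
#'   \item{`length_anomaly`}{the product region is longer than
#'     `template_len`.}
#'   \item{`low_quality`}{any base in the template or product region has
#'     Phred quality below `min_quality`.}
#'   \item{`ambiguous_base`}{an `N` in the template or product region.}
#' }
#' Reads failing any filter are excluded from all downstream statistics.
#'
#' @param reads Character vector of cDNA read sequences.
#' @param quals Character vector of Phred+33 quality strings (same
#'   lengths), or `NULL` to skip the quality filter.
#' @param spec A [construct_spec()].
#' @param system A [chemistry_system()] declaring the alphabet to decode
#'   into.
#' @param max_anchor_mismatches Maximum substitutions tolerated in each
#'   anchor (default 1).
#' @param min_quality Minimum per-base Phred quality inside the template
#'   and product regions (default 20).
#' @param read_id Optional read identifiers.
#'
#' @return A tibble with one row per read: `read_id`, `template` and
#'   `product` (copying order, system alphabet; `NA` for failed reads),
#'   `classifications`, `n_incorporated`, `status` (`"pass"`/`"fail"`),
#'   `fail_reason`.
#' @export
extract_regions <- function(reads, quals = NULL, spec = construct_spec(),
                            system = chemistry_system("DUCG"),
                            max_anchor_mismatches = 1L,
                            min_quality = 20L,
                            read_id = NULL) {
  assert_system(system)
  stopifnot(inherits(spec, "construct_spec"))
  n <- length(reads)
  if (is.null(read_id)) read_id <- sprintf("read_%06d", seq_len(n))
  L <- spec$template_len
  nh <- nchar(spec$handle5)
  nl <- nchar(spec$loop)
  scaffold <- nh + L + nl

  lens <- nchar(reads)
  fail <- rep(NA_character_, n)

  too_short <- lens < scaffold
  # anchors at fixed offsets; short reads cannot present both anchors
  hd_handle <- hamming_at(reads, spec$handle5, offset = 0L)
  hd_loop <- hamming_at(reads, spec$loop, offset = nh + L)
  bad_anchor <- too_short | hd_handle > max_anchor_mismatches |
    hd_loop > max_anchor_mismatches
  fail[bad_anchor] <- "anchor_mismatch"

  prod_len <- pmax(lens - scaffold, 0L)
  bad_len <- is.na(fail) & prod_len > L
  fail[bad_len] <- "length_anomaly"

  tmpl_dna <- substr(reads, nh + 1L, nh + L)
  prod_dna <- substr(reads, scaffold + 1L, lens)

  if (!is.null(quals)) {
    tq <- substr(quals, nh + 1L, nh + L)
    pq <- substr(quals, scaffold + 1L, lens)
    minq <- pmin(min_phred(tq), min_phred(pq))
    low_q <- is.na(fail) & minq < min_quality
    fail[low_q] <- "low_quality"
  }

  has_n <- is.na(fail) &
    (grepl("N", tmpl_dna, fixed = TRUE) | grepl("N", prod_dna, fixed = TRUE))
  fail[has_n] <- "ambiguous_base"

  pass <- is.na(fail)
  template <- rep(NA_character_, n)
  product <- rep(NA_character_, n)
  template[pass] <- decode_from_sequencer(
    system, stringi::stri_reverse(tmpl_dna[pass]))
  product[pass] <- decode_from_sequencer(system, prod_dna[pass])

  tibble::tibble(
    read_id = read_id,
    template = template,
    product = product,
    classifications = NA_character_,
    n_incorporated = ifelse(pass, nchar(product), NA_integer_),
    status = ifelse(pass, "pass", "fail"),
    fail_reason = fail
  )
}

hamming_at <- function(reads, anchor, offset) {
  k <- nchar(anchor)
  d <- integer(length(reads))
  for (j in seq_len(k)) {
    d <- d + (substr(reads, offset + j, offset + j) != substr(anchor, j, j))
  }
  d
}

min_phred <- function(qual_strings) {
  # minimum Phred+33 score per string; empty string -> +Inf (no bases)
  vapply(qual_strings, function(q) {
    if (!nzchar(q)) return(Inf)
    min(utf8ToInt(q)) - 33
  }, numeric(1), USE.NAMES = FALSE)
}

#' Classify every incorporated position of processed reads
#'
#' Fills `classifications` (comma-separated `"complementary"`/`"mismatch"`
#' per incorporated position) for passing reads, matching template and
#' product base-by-base in copying order under the system's complement
#' rules.
#'
#' @param processed A tibble from [extract_regions()].
#' @inheritParams extract_regions
#' @return The input tibble with `classifications` and `n_incorporated`
#'   filled for passing reads.
#' @export
classify_reads <- function(processed, system = chemistry_system("DUCG")) {
  assert_system(system)
  pass <- processed$status == "pass"
  processed$classifications[pass] <- classification_strings(
    system, processed$template[pass], processed$product[pass])
  processed$n_incorporated[pass] <- nchar(processed$product[pass])
  processed
}

classification_strings <- function(system, template, product) {
  if (length(template) == 0) return(character(0))
  L <- max(nchar(product), 1L)
  out <- rep("", length(template))
  comp <- system$complement
  for (i in seq_len(L)) {
    p_i <- substr(product, i, i)
    has <- nzchar(p_i)
    if (!any(has)) break
    t_i <- substr(template, i, i)
    st <- ifelse(unname(comp[t_i[has]]) == p_i[has],
                 "complementary", "mismatch")
    out[has] <- ifelse(out[has] == "", st, paste(out[has], st, sep = ","))
  }
  out
}

#' Read a FASTQ file into a tibble
#'
#' @param path Path to a FASTQ file (gzip allowed).
#' @return A tibble with `read_id`, `read`, `quality`.
#' @export
read_fastq <- function(path) {
  x <- withCallingHandlers(
    Biostrings::readQualityScaledDNAStringSet(path),
    # Biostrings warns about dropping per-read metadata columns it never
    # uses; irrelevant for plain FASTQ input
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  )
  tibble::tibble(
    read_id = sub("\\s.*$", "", names(x)),
    read = as.character(x),
    quality = as.character(Biostrings::quality(x))
  )
}

#' Process a FASTQ library end to end
#'
#' Reads a FASTQ file, extracts and filters template/product regions, and
#' classifies every incorporated position. Every input read yields exactly
#' one output row.
#'
#' @param fastq Path to a FASTQ file.
#' @inheritParams extract_regions
#' @return A tibble of processed reads (see [extract_regions()]), with a
#'   `"summary"` attribute: a tibble of read counts by status and fail
#'   reason. Retrieve it with `attr(x, "summary")` or
#'   [processing_summary()].
#' @export
process_library <- function(fastq, spec = construct_spec(),
                            system = chemistry_system("DUCG"),
                            max_anchor_mismatches = 1L,
                            min_quality = 20L) {
  fq <- read_fastq(fastq)
  processed <- extract_regions(
    fq$read, fq$quality, spec, system,
    max_anchor_mismatches = max_anchor_mismatches,
    min_quality = min_quality,
    read_id = fq$read_id
  )
  processed <- classify_reads(processed, system)
  summary <- processed |>
    dplyr::count(.data$status, .data$fail_reason, name = "n_reads") |>
    dplyr::arrange(dplyr::desc(.data$status == "pass"))
  attr(processed, "summary") <- summary
  processed
}

#' @rdname process_library
#' @param processed A tibble returned by [process_library()].
#' @export
processing_summary <- function(processed) {
  s <- attr(processed, "summary")
  if (is.null(s)) {
    s <- dplyr::count(processed, .data$status, .data$fail_reason,
                      name = "n_reads")
  }
  s
}
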