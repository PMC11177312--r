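#' Genetic alphabet systems for nonenzymatic template copying
#'
#' A chemistry system bundles a four-letter genetic alphabet with its
#' Watson-Crick complement rules and the letter map used by the sequencer.
#' Two systems are supported: the canonical `"AUCG"` RNA alphabet and the
#' noncanonical `"DUCG"` alphabet in which 2,6-diaminopurine (D) replaces
#' adenine and pairs with U through three hydrogen bonds.
#'
#' Reverse transcription renders both A and D as A in cDNA, and U as T, so
#' reads live in DNA letters; the sequencer-letter map records this encoding.
#' Within a declared system the map is invertible (D and A never coexist).
#'
#' @param name `"AUCG"` or `"DUCG"`.
#'
#' @return An object of class `chemistry_system`: a list with `name`,
#'   `alphabet` (ordered character vector of 4 base symbols), `complement`
#'   (named character vector), and `sequencer_letter` (named character
#'   vector mapping base symbols to `{A,C,G,T}`).
#'
#' @examples
#' sys <- chemistry_system("DUCG")
#' sys$complement[["D"]] # "U"
#' encode_for_sequencer(sys, "DUCG") # "ATCG"
#' @export
chemistry_system <- function(name = c("AUCG", "DUCG")) {
  name <- match.arg(name)
  alphabet <- if (name == "AUCG") c("A", "U", "C", "G") else c("D", "U", "C", "G")
  purine <- alphabet[1] # A or D; pairs with U
  complement <- stats::setNames(
    c("U", purine, "G", "C"),
    c(purine, "U", "C", "G")
  )[alphabet]
  sequencer_letter <- stats::setNames(c("A", "T", "C", "G"), alphabet)
  structure(
    list(
      name = name,
      alphabet = alphabet,
      complement = complement,
      sequencer_letter = sequencer_letter
    ),
    class = "chemistry_system"
  )
}

#' @export
print.chemistry_system <- function(x, ...) {
  cat("<chemistry_system> ", x$name, "\n", sep = "")
  cat("  alphabet:   ", paste(x$alphabet, collapse = " "), "\n", sep = "")
  cat("  complement: ",
      paste(names(x$complement), x$complement, sep = ":", collapse = " "),
      "\n", sep = "")
  invisible(x)
}

assert_system <- function(system) {
  if (!inherits(system, "chemistry_system")) {
    stop("`system` must be a chemistry_system object; see chemistry_system().",
         call. = FALSE)
  }
  invisible(system)
}

check_bases <- function(system, bases, what = "base") {
  bad <- setdiff(unique(bases), system$alphabet)
  if (length(bad) > 0) {
    stop(sprintf("invalid %s symbol(s) for %s system: %s",
                 what, system$name, paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  invisible(bases)
}

#' Classify a template:product base pair
#'
#' A pair is complementary when the product base is the Watson-Crick
#' partner of the template base under the system's complement rules;
#' every other ordered pair is one of the 12 possible mismatches.
#'
#' @param system A [chemistry_system()].
#' @param template_base,product_base Single base symbols from the system
#'   alphabet.
#'
#' @return A one-row tibble with columns `template_base`, `product_base`,
#'   `status` (`"complementary"` or `"mismatch"`) and `label`
#'   (template:product, e.g. `"D:C"`).
#'
#' @examples
#' classify_pair(chemistry_system("DUCG"), "D", "C")
#' @export
classify_pair <- function(system, template_base, product_base) {
  assert_system(system)
  stopifnot(length(template_base) == 1, length(product_base) == 1)
  check_bases(system, c(template_base, product_base))
  status <- if (identical(unname(system$complement[[template_base]]), product_base)) {
    "complementary"
  } else {
    "mismatch"
  }
  tibble::tibble(
    template_base = template_base,
    product_base = product_base,
    status = status,
    label = paste0(template_base, ":", product_base)
  )
}

#' Enumerate the 12 possible mismatches of a system
#'
#' Every ordered template:product pair that is not complementary, in a
#' deterministic order: template base in alphabet order, then product base
#' in alphabet order.
#'
#' @inheritParams classify_pair
#' @return A 12-row tibble with the same columns as [classify_pair()].
#' @examples
#' enumerate_mismatches(chemistry_system("AUCG"))
#' @export
enumerate_mismatches <- function(system) {
  assert_system(system)
  grid <- tidyr::expand_grid(
    template_base = system$alphabet,
    product_base = system$alphabet
  )
  grid |>
    dplyr::mutate(
      status = ifelse(
        unname(system$complement[.data$template_base]) == .data$product_base,
        "complementary", "mismatch"
      ),
      label = paste0(.data$template_base, ":", .data$product_base)
    ) |>
    dplyr::filter(.data$status == "mismatch")
}

#' Encode a base string into sequencer (cDNA) letters
#'
#' Applies the system's sequencer-letter map character-wise: U is read as
#' T, and D (like A) is read as A because reverse transcriptase
#' incorporates T opposite diaminopurine.
#'
#' @inheritParams classify_pair
#' @param seq Character vector of base strings over the system alphabet.
#' @return Character vector of DNA strings, lengths preserved.
#' @examples
#' encode_for_sequencer(chemistry_system("DUCG"), "DUCG") # "ATCG"
#' @export
encode_for_sequencer <- function(system, seq) {
  assert_system(system)
  chars <- unique(unlist(strsplit(seq[nzchar(seq)], "", fixed = TRUE)))
  check_bases(system, chars)
  stringi::stri_trans_char(seq,
                           paste(system$alphabet, collapse = ""),
                           paste(system$sequencer_letter, collapse = ""))
}

#' Decode sequencer (cDNA) letters into system bases
#'
#' Inverse of [encode_for_sequencer()] under a declared system: T becomes
#' U, and in DUCG mode A becomes D (the read cannot distinguish the two, so
#' the declared alphabet resolves the ambiguity). `N` is preserved as an
#' ambiguity marker.
#'
#' @inheritParams classify_pair
#' @param dna Character vector of DNA strings over `{A,C,G,T,N}`.
#' @return Character vector of base strings over the system alphabet
#'   (plus `N`).
#' @examples
#' decode_from_sequencer(chemistry_system("DUCG"), "ATCG") # "DUCG"
#' @export
decode_from_sequencer <- function(system, dna) {
  assert_system(system)
  chars <- unique(unlist(strsplit(dna[nzchar(dna)], "", fixed = TRUE)))
  bad <- setdiff(chars, c("A", "C", "G", "T", "N"))
  if (length(bad) > 0) {
    stop(sprintf("invalid DNA letter(s): %s", paste(bad, collapse = ", ")),
         call. = FALSE)
  }
  stringi::stri_trans_char(dna,
                           paste(c(system$sequencer_letter, "N"), collapse = ""),
                           paste(c(system$alphabet, "N"), collapse = ""))
}
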