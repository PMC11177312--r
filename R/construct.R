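#' Self-priming hairpin construct layout
#'
#' Describes the read layout of the hairpin construct used for
#' nonenzymatic primer extension sequencing. In read (cDNA) orientation a
#' read is `handle5 + template_region + loop + product_region`, where the
#' template region holds `template_len` randomized bases and the product
#' region holds the 0..`template_len` bases that were nonenzymatically
#' incorporated opposite them.
#'
#' Copying proceeds from the template base adjacent to the primer, so the
#' template region appears in the read in *reverse* copying order:
#' templating position `i` (position 1 = first incorporated nucleotide)
#' sits at template-region index `template_len - i + 1`.
#'
#' The default constant sequences are synthetic stand-ins chosen so that
#' `handle5` and `loop` share no 6-mer; supply the published construct
#' sequences to process real libraries.
#'
#' @param handle5 Constant 5' DNA sequence preceding the template region.
#' @param template_len Length of the randomized template region (default 6).
#' @param loop Constant DNA sequence (hairpin loop plus primer) between the
#'   template and product regions.
#'
#' @return An object of class `construct_spec`.
#' @examples
#' construct_spec()
#' @export
construct_spec <- function(handle5 = "ACGACTCTAGCA",
                           template_len = 6L,
                           loop = "TTGGTGAGTCCGTAACCAAC") {
  stopifnot(is.character(handle5), length(handle5) == 1, nzchar(handle5),
            is.character(loop), length(loop) == 1, nzchar(loop))
  if (grepl("[^ACGT]", handle5) || grepl("[^ACGT]", loop)) {
    stop("handle5 and loop must be DNA strings over {A,C,G,T}", call. = FALSE)
  }
  template_len <- as.integer(template_len)
  stopifnot(template_len >= 1)
  structure(
    list(handle5 = handle5, template_len = template_len, loop = loop),
    class = "construct_spec"
  )
}

#' @export
print.construct_spec <- function(x, ...) {
  cat("<construct_spec> ", x$handle5, " + [", x$template_len, "N] + ",
      x$loop, " + [product 0..", x$template_len, "]\n", sep = "")
  invisible(x)
}

default_propensity <- function(system, mismatch_weight = 0.04) {
  n <- length(system$alphabet)
  W <- matrix(mismatch_weight, n, n,
              dimnames = list(system$alphabet, system$alphabet))
  for (t in system$alphabet) W[t, system$complement[[t]]] <- 1
  W
}

#' Generative model of nonenzymatic template copying
#'
#' Parameterizes the stochastic read simulator. A template is drawn
#' i.i.d. from `template_dist`; the product is built left to right in
#' copying order. At step `i` the primer extends with probability
#' `p_ext_initial` (i = 1) or, for later steps, `p_ext_after_match` /
#' `p_ext_after_mismatch` according to the status of the previous pair
#' (the generative counterpart of the stalling factor,
#' `S_gen = p_ext_after_match / p_ext_after_mismatch`). Given extension
#' opposite template base `t`, the incorporated base is sampled with
#' relative weights `propensity[t, ]`; when the previous pair was a
#' mismatch, the mismatch weights are first multiplied by
#' `post_mismatch_error_boost` (error elevation after a mismatch).
#' Copying stops at the first non-extension or after `template_len`
#' incorporations.
#'
#' Sequencing substitutions are applied in cDNA space at `seq_error_rate`
#' per base. `rt_error_rate` is the probability that reverse transcription
#' miscalls a diaminopurine (D) position as a random non-A letter; the
#' fidelity of MMLV RT opposite D is high, so it defaults to 0.
#'
#' @param system A [chemistry_system()] (or its name).
#' @param template_dist Probability 4-vector over the system alphabet
#'   (default uniform).
#' @param propensity Strictly positive 4x4 matrix of relative
#'   incorporation weights, rows = template base, columns = product base,
#'   in alphabet order. Rows are normalized internally. The default
#'   favours the complementary base 25:1 over each mismatch.
#' @param p_ext_initial Probability that the first incorporation occurs.
#' @param p_ext_after_match,p_ext_after_mismatch Probability of extending
#'   past a complementary / mismatched terminal pair.
#' @param post_mismatch_error_boost Multiplier (>= 1) on mismatch weights
#'   for the incorporation immediately following a mismatch.
#' @param seq_error_rate Per-base substitution probability in cDNA space.
#' @param rt_error_rate Per-base probability of an RT miscall at D
#'   positions (DUCG only).
#' @param seed Integer seed for [simulate_library()].
#'
#' @return An object of class `copying_model`.
#' @examples
#' copying_model("DUCG", p_ext_initial = 0.5)
#' @export
copying_model <- function(system = "DUCG",
                          template_dist = NULL,
                          propensity = NULL,
                          p_ext_initial = 0.5,
                          p_ext_after_match = 0.7,
                          p_ext_after_mismatch = 0.12,
                          post_mismatch_error_boost = 3,
                          seq_error_rate = 0.001,
                          rt_error_rate = 0,
                          seed = 1L) {
  if (is.character(system)) system <- chemistry_system(system)
  assert_system(system)
  n <- length(system$alphabet)
  if (is.null(template_dist)) template_dist <- rep(1 / n, n)
  template_dist <- stats::setNames(as.numeric(template_dist), system$alphabet)
  if (abs(sum(template_dist) - 1) > 1e-12 || any(template_dist < 0)) {
    stop("template_dist must be a probability vector summing to 1",
         call. = FALSE)
  }
  if (is.null(propensity)) propensity <- default_propensity(system)
  propensity <- as.matrix(propensity)
  dimnames(propensity) <- list(system$alphabet, system$alphabet)
  if (any(propensity <= 0)) {
    stop("propensity matrix must be strictly positive", call. = FALSE)
  }
  probs <- c(p_ext_initial, p_ext_after_match, p_ext_after_mismatch,
             seq_error_rate, rt_error_rate)
  if (any(probs < 0) || any(probs > 1)) {
    stop("extension and error probabilities must lie in [0, 1]", call. = FALSE)
  }
  if (post_mismatch_error_boost < 1) {
    stop("post_mismatch_error_boost must be >= 1", call. = FALSE)
  }
  structure(
    list(system = system,
         template_dist = template_dist,
         propensity = propensity,
         p_ext_initial = p_ext_initial,
         p_ext_after_match = p_ext_after_match,
         p_ext_after_mismatch = p_ext_after_mismatch,
         post_mismatch_error_boost = post_mismatch_error_boost,
         seq_error_rate = seq_error_rate,
         rt_error_rate = rt_error_rate,
         seed = as.integer(seed)),
    class = "copying_model"
  )
}

#' @export
print.copying_model <- function(x, ...) {
  cat("<copying_model> system ", x$system$name,
      "; p_ext init/match/mismatch = ", x$p_ext_initial, "/",
      x$p_ext_after_match, "/", x$p_ext_after_mismatch,
      "; boost = ", x$post_mismatch_error_boost,
      "; seq_error_rate = ", x$seq_error_rate, "\n", sep = "")
  invisible(x)
}

# Row-normalized incorporation probabilities, plain and post-mismatch
# boosted. comp_idx[t] is the column index of the complementary base.
model_sampling_tables <- function(model) {
  sys <- model$system
  n <- length(sys$alphabet)
  comp_idx <- match(unname(sys$complement[sys$alphabet]), sys$alphabet)
  W <- model$propensity
  Wb <- W
  for (t in seq_len(n)) {
    mis <- setdiff(seq_len(n), comp_idx[t])
    Wb[t, mis] <- Wb[t, mis] * model$post_mismatch_error_boost
  }
  list(
    W = W / rowSums(W),
    Wb = Wb / rowSums(Wb),
    comp_idx = comp_idx
  )
}

# Vectorized copying engine: templates and products as integer matrices
# (alphabet indices, copying order), NA where not incorporated.
simulate_truth_matrices <- function(model, spec, n_reads) {
  sys <- model$system
  L <- spec$template_len
  tabs <- model_sampling_tables(model)
  tmat <- matrix(
    sample.int(4L, n_reads * L, replace = TRUE, prob = model$template_dist),
    nrow = n_reads, ncol = L
  )
  pmat <- matrix(NA_integer_, n_reads, L)
  active <- rep(TRUE, n_reads)
  prev_mismatch <- rep(FALSE, n_reads)
  for (i in seq_len(L)) {
    p_ext <- if (i == 1L) {
      rep(model$p_ext_initial, n_reads)
    } else {
      ifelse(prev_mismatch, model$p_ext_after_mismatch, model$p_ext_after_match)
    }
    active <- active & (stats::runif(n_reads) < p_ext)
    if (!any(active)) break
    for (t in 1:4) {
      for (boosted in c(FALSE, TRUE)) {
        sel <- active & tmat[, i] == t & (prev_mismatch == boosted)
        k <- sum(sel)
        if (k == 0) next
        row <- if (boosted) tabs$Wb[t, ] else tabs$W[t, ]
        pmat[sel, i] <- sample.int(4L, k, replace = TRUE, prob = row)
      }
    }
    prev_mismatch[active] <- pmat[active, i] != tabs$comp_idx[tmat[active, i]]
  }
  list(tmat = tmat, pmat = pmat, comp_idx = tabs$comp_idx)
}

collapse_rows <- function(mat, letters) {
  # integer matrix (NA-padded) -> character vector of strings
  ch <- matrix("", nrow(mat), ncol(mat))
  ok <- !is.na(mat)
  ch[ok] <- letters[mat[ok]]
  do.call(paste0, asplit(ch, 2))
}

apply_substitutions <- function(reads, rate) {
  if (rate <= 0) return(reads)
  letters4 <- c("A", "C", "G", "T")
  others <- rbind(c("C", "G", "T"), c("A", "G", "T"),
                  c("A", "C", "T"), c("A", "C", "G"))
  chars <- strsplit(reads, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  hit <- stats::runif(length(flat)) < rate
  if (any(hit)) {
    orig <- match(flat[hit], letters4)
    pick <- sample.int(3L, sum(hit), replace = TRUE)
    flat[hit] <- others[cbind(orig, pick)]
  }
  vapply(split(flat, rep.int(seq_along(lens), lens)),
         paste, character(1), collapse = "")
}

#' Simulate nonenzymatic primer-extension reads
#'
#' Draws `n_reads` hairpin reads under a [copying_model()] and
#' [construct_spec()], returning both the ground truth (template, product
#' and per-position classification in copying order) and the cDNA read as
#' it would be sequenced. The read is
#' `handle5 + encode(reverse(template)) + loop + encode(product)` with
#' i.i.d. substitution errors at `seq_error_rate` and constant Q40
#' qualities.
#'
#' @param model A [copying_model()].
#' @param spec A [construct_spec()].
#' @param n_reads Number of reads (>= 1).
#'
#' @return A tibble with one row per read: `read_id`, `template`,
#'   `product`, `classifications` (comma-separated T:P status labels),
#'   `n_incorporated`, `read` (cDNA sequence) and `quality`.
#' @seealso [simulate_library()] to write FASTQ plus a truth sidecar.
#' @examples
#' set.seed(1)
#' simulate_reads(copying_model("DUCG"), construct_spec(), 5)
#' @export
simulate_reads <- function(model, spec = construct_spec(), n_reads = 1L) {
  stopifnot(inherits(model, "copying_model"), inherits(spec, "construct_spec"))
  n_reads <- as.integer(n_reads)
  if (is.na(n_reads) || n_reads < 1) stop("n_reads must be >= 1", call. = FALSE)
  sys <- model$system
  mats <- simulate_truth_matrices(model, spec, n_reads)

  template <- collapse_rows(mats$tmat, sys$alphabet)
  product <- collapse_rows(mats$pmat, sys$alphabet)
  n_inc <- rowSums(!is.na(mats$pmat))

  status_mat <- matrix("", n_reads, spec$template_len)
  ok <- !is.na(mats$pmat)
  is_comp <- matrix(FALSE, n_reads, spec$template_len)
  is_comp[ok] <- mats$pmat[ok] ==
    mats$comp_idx[mats$tmat[ok]]
  status_mat[ok & is_comp] <- "complementary"
  status_mat[ok & !is_comp] <- "mismatch"
  classifications <- vapply(seq_len(n_reads), function(r) {
    k <- n_inc[r]
    if (k == 0) return("")
    paste(status_mat[r, seq_len(k)], collapse = ",")
  }, character(1))

  template_cdna <- encode_for_sequencer(sys, stringi::stri_reverse(template))
  product_cdna <- encode_for_sequencer(sys, product)
  if (model$rt_error_rate > 0 && sys$name == "DUCG") {
    # RT miscall at D positions: flip encoded-A-from-D to a random other letter
    template_cdna <- rt_miscall(template_cdna, stringi::stri_reverse(template),
                                model$rt_error_rate)
    product_cdna <- rt_miscall(product_cdna, product, model$rt_error_rate)
  }
  reads <- paste0(spec$handle5, template_cdna, spec$loop, product_cdna)
  reads <- apply_substitutions(reads, model$seq_error_rate)

  tibble::tibble(
    read_id = sprintf("read_%06d", seq_len(n_reads)),
    template = template,
    product = product,
    classifications = classifications,
    n_incorporated = as.integer(n_inc),
    read = reads,
    quality = strrep("I", nchar(reads))
  )
}

rt_miscall <- function(cdna, bases, rate) {
  chars <- strsplit(cdna, "", fixed = TRUE)
  srcs <- strsplit(bases, "", fixed = TRUE)
  lens <- lengths(chars)
  flat <- unlist(chars, use.names = FALSE)
  src <- unlist(srcs, use.names = FALSE)
  hit <- src == "D" & stats::runif(length(flat)) < rate
  if (any(hit)) {
    flat[hit] <- c("C", "G", "T")[sample.int(3L, sum(hit), replace = TRUE)]
  }
  vapply(split(flat, rep.int(seq_along(lens), lens)),
         paste, character(1), collapse = "")
}

#' Simulate a sequencing library with a ground-truth sidecar
#'
#' Seeds the RNG from `model$seed`, simulates `n_reads` reads, and writes
#' a standard 4-line FASTQ together with a tab-separated truth table
#' (columns `read_id`, `template`, `product`, `classifications`,
#' `n_incorporated`). Re-running with the same model and spec is
#' byte-identical.
#'
#' @inheritParams simulate_reads
#' @param fastq,truth Output paths; directories must exist.
#' @return Invisibly, the truth tibble (with read sequences).
#' @examples
#' td <- tempdir()
#' simulate_library(copying_model("AUCG", seed = 7), construct_spec(), 100,
#'                  fastq = file.path(td, "lib.fastq"),
#'                  truth = file.path(td, "truth.tsv"))
#' @export
simulate_library <- function(model, spec = construct_spec(), n_reads,
                             fastq, truth = NULL) {
  stopifnot(inherits(model, "copying_model"))
  set.seed(model$seed)
  sim <- simulate_reads(model, spec, n_reads)
  write_fastq(sim$read, sim$quality, sim$read_id, fastq)
  if (!is.null(truth)) {
    utils::write.table(
      sim[, c("read_id", "template", "product", "classifications",
              "n_incorporated")],
      truth, sep = "\t", quote = FALSE, row.names = FALSE
    )
  }
  invisible(sim)
}

write_fastq <- function(seqs, quals, ids, path) {
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- ids
  reads <- Biostrings::QualityScaledDNAStringSet(
    dna, Biostrings::PhredQuality(quals)
  )
  Biostrings::writeQualityScaledXStringSet(reads, path)
  invisible(path)
}
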