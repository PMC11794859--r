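#' Design parameters for transcribed barcode sets
#'
#' Bundles the constraints a barcode set must satisfy: sequence length,
#' candidate pool size, minimum pairwise Hamming distance, target set size,
#' the stop codons excluded from sequence ends, and the longest tolerated
#' homopolymer run.
#'
#' @param length Barcode length in nucleotides.
#' @param n_candidates Number of random candidates to generate.
#' @param min_hamming Minimum pairwise Hamming distance between any two
#'   barcodes in a selected set.
#' @param k_select Number of barcodes to select from the candidate pool.
#' @param stop_codons Character vector of 3-mers excluded from the first and
#'   last three bases of a barcode.
#' @param max_homopolymer Longest permitted run of identical bases; runs of
#'   `max_homopolymer + 1` or more are rejected.
#' @param seed Integer seed for candidate generation.
#'
#' @return An object of class `design_params` (a validated list).
#' @export
design_params <- function(length = 15L, n_candidates = 10000L, min_hamming = 5L,
                          k_select = 18L, stop_codons = c("TAA", "TAG", "TGA"),
                          max_homopolymer = 3L, seed = 1L) {
  length <- as.integer(length)
  n_candidates <- as.integer(n_candidates)
  min_hamming <- as.integer(min_hamming)
  k_select <- as.integer(k_select)
  max_homopolymer <- as.integer(max_homopolymer)
  stopifnot(length > 0L, n_candidates > 0L, k_select > 0L,
            min_hamming >= 0L, max_homopolymer >= 1L)
  if (min_hamming > length)
    stop("min_hamming must not exceed the barcode length")
  stop_codons <- toupper(stop_codons)
  if (any(nchar(stop_codons) != 3L))
    stop("stop_codons must all be 3-mers")
  structure(list(length = length, n_candidates = n_candidates,
                 min_hamming = min_hamming, k_select = k_select,
                 stop_codons = stop_codons, max_homopolymer = max_homopolymer,
                 seed = as.integer(seed)),
            class = "design_params")
}

.check_dna <- function(seqs, what = "sequence") {
  seqs <- toupper(seqs)
  bad <- grepl("[^ACGT]", seqs)
  if (any(bad))
    stop(sprintf("%s contains characters outside A/C/G/T: %s",
                 what, seqs[bad][1]))
  seqs
}

#' Hamming distance between two equal-length DNA strings
#'
#' @param a,b DNA strings of equal length.
#' @return Non-negative integer count of mismatched positions.
#' @examples
#' hamming_distance("ACGT", "ACGT") # 0
#' hamming_distance("AAAA", "AAAT") # 1
#' @export
hamming_distance <- function(a, b) {
  if (nchar(a) != nchar(b))
    stop("hamming_distance: sequences differ in length (",
         nchar(a), " vs ", nchar(b), ")")
  sum(utf8ToInt(toupper(a)) != utf8ToInt(toupper(b)))
}

# Pairwise Hamming distance matrix over a character vector of sequences.
.hamming_matrix <- function(seqs) {
  n <- length(seqs)
  chars <- do.call(rbind, strsplit(toupper(seqs), "", fixed = TRUE))
  d <- matrix(0L, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(chars[i, ] != chars[j, ])
    }
  }
  d
}

#' Generate random barcode candidates
#'
#' Draws `n_candidates` sequences of the configured length with each base
#' sampled independently and uniformly from A/C/G/T.
#'
#' @param params A [design_params()] object.
#' @return Character vector of candidate sequences; reproducible for a fixed
#'   `params$seed`.
#' @export
generate_candidates <- function(params = design_params()) {
  stopifnot(inherits(params, "design_params"))
  rng <- .seeded_rng(params$seed)
  on.exit(rng$restore())
  bases <- c("A", "C", "G", "T")
  draws <- sample(bases, params$n_candidates * params$length, replace = TRUE)
  mat <- matrix(draws, nrow = params$n_candidates, ncol = params$length)
  apply(mat, 1L, paste0, collapse = "")
}

#' Test a sequence against the barcode composition filters
#'
#' A sequence fails if it starts or ends with a stop codon, or contains a
#' homopolymer run longer than `params$max_homopolymer`. All applicable
#' violation codes are reported.
#'
#' @param seq A DNA string of length at least 3.
#' @param params A [design_params()] object.
#' @return A list with `pass` (logical) and `violations` (character vector
#'   drawn from `"START_STOP"`, `"END_STOP"`, `"HOMOPOLYMER"`).
#' @export
passes_filters <- function(seq, params = design_params()) {
  seq <- .check_dna(seq)
  n <- nchar(seq)
  if (n < 3L) stop("sequence shorter than 3 nt")
  codes <- character(0)
  if (substr(seq, 1L, 3L) %in% params$stop_codons)
    codes <- c(codes, "START_STOP")
  if (substr(seq, n - 2L, n) %in% params$stop_codons)
    codes <- c(codes, "END_STOP")
  runs <- rle(strsplit(seq, "", fixed = TRUE)[[1]])
  if (max(runs$lengths) > params$max_homopolymer)
    codes <- c(codes, "HOMOPOLYMER")
  list(pass = length(codes) == 0L, violations = codes)
}

#' Construct a barcode set object
#'
#' @param sequences Character vector of DNA sequences.
#' @param ids Barcode labels; defaults to `BC01`, `BC02`, ...
#' @param params The [design_params()] the set is claimed to satisfy.
#' @param provenance Either `"designed"` or `"loaded"`.
#' @return A `barcode_set` object (data frame of id/sequence plus attributes).
#' @export
barcode_set <- function(sequences, ids = NULL, params = design_params(),
                        provenance = c("loaded", "designed")) {
  provenance <- match.arg(provenance)
  sequences <- .check_dna(sequences)
  if (is.null(ids)) ids <- sprintf("BC%02d", seq_along(sequences))
  stopifnot(length(ids) == length(sequences))
  if (anyDuplicated(ids)) stop("barcode ids must be unique")
  structure(data.frame(id = as.character(ids), sequence = sequences,
                       stringsAsFactors = FALSE),
            params = params, provenance = provenance,
            class = c("barcode_set", "data.frame"))
}

#' Greedily select a barcode set from a candidate pool
#'
#' Scans the candidates in input order, discards any that fail the
#' composition filters, and admits a candidate only if its Hamming distance
#' to every barcode already admitted is at least `params$min_hamming`,
#' stopping once `params$k_select` barcodes are held.
#'
#' @param candidates Character vector of equal-length DNA sequences.
#' @param params A [design_params()] object.
#' @return A `barcode_set` with provenance `"designed"`. If fewer than
#'   `k_select` admissible candidates exist the maximal greedy set is
#'   returned with attribute `shortfall = TRUE` and a warning.
#' @export
select_barcode_set <- function(candidates, params = design_params()) {
  if (length(candidates) == 0L) stop("empty candidate list")
  candidates <- .check_dna(candidates)
  if (any(nchar(candidates) != params$length))
    stop("all candidates must have length params$length")
  chosen <- character(0)
  chosen_chars <- list()
  for (cand in candidates) {
    if (length(chosen) >= params$k_select) break
    if (!passes_filters(cand, params)$pass) next
    cc <- utf8ToInt(cand)
    ok <- TRUE
    for (prev in chosen_chars) {
      if (sum(cc != prev) < params$min_hamming) { ok <- FALSE; break }
    }
    if (ok && !cand %in% chosen) {
      chosen <- c(chosen, cand)
      chosen_chars[[length(chosen)]] <- cc
    }
  }
  shortfall <- length(chosen) < params$k_select
  if (shortfall)
    warning(sprintf("only %d of %d requested barcodes admissible",
                    length(chosen), params$k_select))
  set <- barcode_set(chosen, params = params, provenance = "designed")
  attr(set, "shortfall") <- shortfall
  set
}

#' Validate a barcode set against its design constraints
#'
#' Checks uniqueness, common length, pairwise minimum Hamming distance, and
#' the per-barcode composition filters, reporting each observation.
#'
#' @param set A `barcode_set`.
#' @param params Optional [design_params()] overriding the set's own.
#' @return A list of class `barcode_validation` with elements `pass`,
#'   `n_barcodes`, `n_unique`, `common_length` (or `NA` with code
#'   `LENGTH_MIXED`), `min_hamming` (observed), `filter_violations`
#'   (named list per barcode) and `codes` (all failure codes).
#' @export
validate_barcode_set <- function(set, params = NULL) {
  stopifnot(inherits(set, "barcode_set"), nrow(set) >= 1L)
  if (is.null(params)) params <- attr(set, "params")
  seqs <- set$sequence
  codes <- character(0)
  n_unique <- length(unique(seqs))
  if (n_unique < length(seqs)) codes <- c(codes, "DUPLICATE")
  lens <- unique(nchar(seqs))
  if (length(lens) > 1L) {
    codes <- c(codes, "LENGTH_MIXED")
    common_length <- NA_integer_
  } else {
    common_length <- lens
    if (common_length != params$length) codes <- c(codes, "LENGTH")
  }
  min_h <- NA_integer_
  if (length(lens) == 1L && length(seqs) >= 2L) {
    d <- .hamming_matrix(seqs)
    min_h <- min(d[upper.tri(d)])
    if (min_h < params$min_hamming) codes <- c(codes, "MIN_DIST")
  }
  fv <- lapply(seqs, function(s) passes_filters(s, params)$violations)
  names(fv) <- set$id
  if (any(lengths(fv) > 0L)) codes <- c(codes, "FILTER")
  structure(list(pass = length(codes) == 0L,
                 n_barcodes = nrow(set), n_unique = n_unique,
                 common_length = common_length, min_hamming = min_h,
                 filter_violations = fv[lengths(fv) > 0L], codes = codes),
            class = "barcode_validation")
}

#' @export
print.barcode_validation <- function(x, ...) {
  cat("Barcode set validation:", if (x$pass) "PASS" else "FAIL", "\n")
  cat(sprintf("  barcodes: %d (%d unique), length: %s, min Hamming: %s\n",
              x$n_barcodes, x$n_unique,
              ifelse(is.na(x$common_length), "mixed", x$common_length),
              ifelse(is.na(x$min_hamming), "NA", x$min_hamming)))
  if (length(x$codes)) cat("  codes:", paste(x$codes, collapse = ", "), "\n")
  invisible(x)
}

#' Default cassette flank configuration
#'
#' The transcribed barcode sits inside a cassette of
#' EcoRV 3' half - MluI site - partial Read2 adaptor (reverse complement) -
#' barcode - MluI-complementary overhang. The partial Read2 reverse
#' complement is truncated so the full single-stranded oligo stays at or
#' under 60 nt; all flanks are configuration, not fixed constants.
#'
#' @param ecoRV_3bp 3' three bases of the EcoRV site (GATATC).
#' @param mluI_site MluI recognition sequence.
#' @param read2_rc Reverse complement of the partial Read2 adaptor.
#' @param mluI_complement Overhang completing the MluI site at the 3' end.
#' @return Named list of flank sequences.
#' @export
cassette_flanks <- function(ecoRV_3bp = "ATC", mluI_site = "ACGCGT",
                            read2_rc = "ACTGGAGTTCAGACGTGTGCTCTTCCGATCT",
                            mluI_complement = "CGCGT") {
  lapply(list(ecoRV_3bp = ecoRV_3bp, mluI_site = mluI_site,
              read2_rc = read2_rc, mluI_complement = mluI_complement),
         .check_dna)
}

#' Assemble a barcode expression cassette
#'
#' Concatenates the configured flanks around a barcode and records the
#' 0-based half-open offsets of every segment.
#'
#' @param id Barcode label.
#' @param sequence Barcode DNA sequence.
#' @param flanks A [cassette_flanks()] configuration.
#' @param expected_length Barcode length to enforce (default 15).
#' @return A list of class `cassette` with `barcode_id`, `sequence` and a
#'   `layout` data frame (segment, start, end).
#' @export
assemble_cassette <- function(id, sequence, flanks = cassette_flanks(),
                              expected_length = 15L) {
  sequence <- .check_dna(sequence)
  if (nchar(sequence) != expected_length)
    stop(sprintf("barcode %s has length %d, expected %d",
                 id, nchar(sequence), expected_length))
  segs <- c(flanks[c("ecoRV_3bp", "mluI_site", "read2_rc")],
            list(barcode = sequence),
            flanks["mluI_complement"])
  lens <- vapply(segs, nchar, integer(1))
  ends <- cumsum(lens)
  layout <- data.frame(segment = names(segs),
                       start = c(0L, ends[-length(ends)]),
                       end = ends, row.names = NULL)
  structure(list(barcode_id = id,
                 sequence = paste0(unlist(segs), collapse = ""),
                 layout = layout),
            class = "cassette")
}

#' Assemble cassettes for every barcode in a set
#'
#' @param set A `barcode_set`.
#' @inheritParams assemble_cassette
#' @return A named list of `cassette` objects.
#' @export
assemble_cassettes <- function(set, flanks = cassette_flanks()) {
  stopifnot(inherits(set, "barcode_set"))
  out <- Map(assemble_cassette, set$id, set$sequence,
             MoreArgs = list(flanks = flanks,
                             expected_length = attr(set, "params")$length))
  names(out) <- set$id
  out
}

#' The 18 packaged iPSC multiplexing barcodes
#'
#' Returns the 18 transcribed genomic barcodes (BC01-BC18) integrated at the
#' AAVS1 locus of the barcoded iPSC lines used for multiplexed
#' differentiation experiments. The set satisfies the default design
#' constraints: 15 nt, unique, minimum pairwise Hamming distance of at least
#' 5, no terminal stop codons, no homopolymer run of 4 or more.
#'
#' @return A `barcode_set` with provenance `"loaded"`.
#' @export
ipsc_barcodes <- function() {
  path <- system.file("extdata", "ipsc_barcodes.fasta", package = "triagemux")
  read_barcode_fasta(path)
}
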