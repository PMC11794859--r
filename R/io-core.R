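# Shared IO, configuration and provenance helpers used across modules.

# Run a block of code under a fixed seed without clobbering the caller's RNG
# stream. Returns a handle whose $restore() puts the previous state back.
.seeded_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(as.integer(seed))
  list(restore = function() {
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
}

#' Read a barcode set from FASTA
#'
#' @param path FASTA file; record names become barcode ids.
#' @param params Design constraints to attach; default [design_params()].
#' @return A `barcode_set` with provenance `"loaded"`.
#' @export
read_barcode_fasta <- function(path, params = design_params()) {
  x <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(x))
  barcode_set(as.character(x), ids = ids, params = params,
              provenance = "loaded")
}

#' Write barcodes or cassettes to FASTA
#'
#' @param x A `barcode_set`, or a list of `cassette` objects.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_barcode_fasta <- function(x, path) {
  if (inherits(x, "barcode_set")) {
    seqs <- Biostrings::DNAStringSet(x$sequence)
    names(seqs) <- x$id
    p <- attr(x, "params")
    names(seqs) <- sprintf("%s length=%d min_hamming=%d", x$id,
                           p$length, p$min_hamming)
  } else {
    seqs <- Biostrings::DNAStringSet(vapply(x, `[[`, "", "sequence"))
    names(seqs) <- vapply(x, `[[`, "", "barcode_id")
  }
  Biostrings::writeXStringSet(seqs, filepath = path)
  invisible(path)
}

#' Read candidate sequences from a one-per-line text file
#'
#' @param path Text file with one DNA sequence per line; blank lines and
#'   lines starting with `#` are skipped.
#' @return Character vector of uppercase sequences.
#' @export
read_sequence_lines <- function(path) {
  x <- readLines(path)
  x <- trimws(x)
  x <- x[nzchar(x) & !startsWith(x, "#")]
  .check_dna(x, what = basename(path))
}

.read_id_column <- function(path, what) {
  ids <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE)[[1]]
  if (anyDuplicated(ids))
    stop(sprintf("duplicate ids in %s: %s", what,
                 ids[duplicated(ids)][1]))
  as.character(ids)
}

#' Read a count matrix from MTX-with-sidecars or dense CSV
#'
#' Accepts either a directory containing `matrix.mtx`, `features.tsv` (row
#' ids) and `barcodes.tsv` (column ids); a path to a `.mtx` file with
#' sibling `*.rows.tsv` / `*.cols.tsv`; or a dense `.csv` whose first column
#' holds row ids and whose header holds column ids.
#'
#' @param path Directory, `.mtx` file, or `.csv` file.
#' @return A base matrix with dimnames (rows x columns as stored on disk).
#' @export
read_count_matrix <- function(path) {
  if (dir.exists(path)) {
    mtx <- file.path(path, "matrix.mtx")
    rows <- file.path(path, "features.tsv")
    cols <- file.path(path, "barcodes.tsv")
    if (!file.exists(mtx)) stop("no matrix.mtx in directory ", path)
    m <- as.matrix(Matrix::readMM(mtx))
    rownames(m) <- .read_id_column(rows, rows)
    colnames(m) <- .read_id_column(cols, cols)
  } else if (grepl("\\.mtx$", path)) {
    m <- as.matrix(Matrix::readMM(path))
    stem <- sub("\\.mtx$", "", path)
    rownames(m) <- .read_id_column(paste0(stem, ".rows.tsv"), path)
    colnames(m) <- .read_id_column(paste0(stem, ".cols.tsv"), path)
  } else if (grepl("\\.csv$", path)) {
    df <- utils::read.csv(path, row.names = 1, check.names = FALSE)
    m <- as.matrix(df)
    if (anyDuplicated(rownames(m))) stop("duplicate row ids in ", path)
  } else {
    stop("unrecognised count-matrix path: ", path)
  }
  if (nrow(m) != length(unique(rownames(m))) ||
      ncol(m) != length(unique(colnames(m))))
    stop("duplicate ids in ", path)
  if (any(!is.finite(m)) || any(m < 0))
    stop("count matrix contains NaN/negative entries: ", path)
  m
}

#' Write a count matrix as MTX-with-sidecars or dense CSV
#'
#' @param m Matrix with dimnames.
#' @param path Directory (MTX triplet written inside), `.mtx` path
#'   (sidecar `.rows.tsv`/`.cols.tsv` written next to it) or `.csv` path.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(m, path) {
  stopifnot(!is.null(rownames(m)), !is.null(colnames(m)))
  if (grepl("\\.csv$", path)) {
    utils::write.csv(as.data.frame(as.matrix(m)), path)
  } else if (grepl("\\.mtx$", path)) {
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"), path)
    stem <- sub("\\.mtx$", "", path)
    writeLines(rownames(m), paste0(stem, ".rows.tsv"))
    writeLines(colnames(m), paste0(stem, ".cols.tsv"))
  } else {
    dir.create(path, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(methods::as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    file.path(path, "matrix.mtx"))
    writeLines(rownames(m), file.path(path, "features.tsv"))
    writeLines(colnames(m), file.path(path, "barcodes.tsv"))
  }
  invisible(path)
}

#' Read / write per-cell label tables
#'
#' Two-column tab-separated files: cell id, label.
#'
#' @param path TSV path.
#' @return Named character vector of labels (names are cell ids).
#' @export
read_labels <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE)
  stats::setNames(as.character(df[[2]]), df[[1]])
}

#' @rdname read_labels
#' @param labels Named character vector of per-cell labels.
#' @export
write_labels <- function(labels, path) {
  utils::write.table(data.frame(cell_id = names(labels), label = unname(labels)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gene -> repressive tendency score table
#'
#' @param path Two-column CSV (gene, rts).
#' @return Named numeric vector of non-negative scores.
#' @export
read_rts_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  rts_table(stats::setNames(as.numeric(df[[2]]), df[[1]]))
}

#' Layered flat key=value configuration
#'
#' Merges `defaults < file < overrides`, rejecting unknown keys (with a
#' nearest-match suggestion) and coercing values to the type of the default.
#'
#' @param defaults Named list of default values (defines the schema).
#' @param path Optional path to a `key = value` text file (`#` comments).
#' @param overrides Optional named list (e.g. parsed CLI flags).
#' @return Named list of effective parameter values.
#' @export
load_config <- function(defaults, path = NULL, overrides = list()) {
  stopifnot(is.list(defaults), !is.null(names(defaults)))
  eff <- defaults
  apply_layer <- function(eff, layer, origin) {
    for (key in names(layer)) {
      if (!key %in% names(defaults)) {
        sugg <- agrep(key, names(defaults), max.distance = 0.3, value = TRUE)
        hint <- if (length(sugg)) paste0(" (did you mean '", sugg[1], "'?)") else ""
        stop(sprintf("unknown config key '%s' in %s%s", key, origin, hint))
      }
      val <- layer[[key]]
      proto <- defaults[[key]]
      if (is.numeric(proto)) {
        val <- suppressWarnings(as.numeric(val))
        if (is.na(val)) stop(sprintf("config key '%s' must be numeric", key))
        if (is.integer(proto)) val <- as.integer(val)
      } else if (is.logical(proto)) {
        val <- as.logical(val)
        if (is.na(val)) stop(sprintf("config key '%s' must be logical", key))
      } else {
        val <- as.character(val)
      }
      eff[[key]] <- val
    }
    eff
  }
  if (!is.null(path)) {
    lines <- readLines(path)
    lines <- trimws(sub("#.*$", "", lines))
    lines <- lines[nzchar(lines)]
    kv <- strsplit(lines, "\\s*=\\s*")
    bad <- lengths(kv) != 2L
    if (any(bad)) stop("malformed config line in ", path, ": ", lines[bad][1])
    layer <- stats::setNames(lapply(kv, `[[`, 2L), vapply(kv, `[[`, "", 1L))
    eff <- apply_layer(eff, layer, path)
  }
  apply_layer(eff, overrides, "overrides")
}

#' Build a provenance record for a run
#'
#' @param params Named list of effective parameters.
#' @param seed Integer seed used for any randomness.
#' @param inputs Character vector of input file paths (digested with MD5).
#' @return A list suitable for embedding in JSON outputs.
#' @export
run_provenance <- function(params = list(), seed = NA_integer_,
                           inputs = character(0)) {
  digests <- if (length(inputs)) as.list(tools::md5sum(inputs)) else list()
  list(tool = "triagemux",
       version = as.character(utils::packageVersion("triagemux")),
       timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
       seed = seed, params = params, input_md5 = digests)
}
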