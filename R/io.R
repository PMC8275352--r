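MODEL_FORMAT <- "bmf-model"
MODEL_VERSION <- 1L

#' Read sequences from FASTA or plain text
#'
#' FASTA records keep their header lines as identifiers; plain format (one
#' sequence per line) assigns `seq_<line>` identifiers. All sequences are
#' normalized (uppercase, `T -> U`). Empty records are skipped with a
#' warning. `format = "auto"` sniffs for a leading `>`.
#'
#' @param path Readable file path.
#' @param format `"auto"`, `"fasta"` or `"plain"`.
#' @return Named character vector of sequences (names are record ids).
#' @export
read_sequences <- function(path, format = c("auto", "fasta", "plain")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("cannot read sequence file: ", path)
  if (format == "auto") {
    first <- readLines(path, n = 1L)
    format <- if (length(first) && startsWith(first, ">")) "fasta" else "plain"
  }
  if (format == "fasta") {
    set <- Biostrings::readBStringSet(path)
    seqs <- as.character(set)
    ids <- names(set)
  } else {
    seqs <- readLines(path)
    ids <- paste0("seq_", seq_along(seqs))
  }
  empty <- !nzchar(seqs)
  if (any(empty)) {
    warning(sprintf("skipping %d empty record(s) in %s", sum(empty), path))
    seqs <- seqs[!empty]
    ids <- ids[!empty]
  }
  stats::setNames(normalize_sequence(seqs), ids)
}

#' Write sequences as FASTA
#'
#' @param seqs Character vector of sequences; names (if any) become record
#'   identifiers.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.null(names(seqs))) names(seqs) <- paste0("seq_", seq_along(seqs))
  Biostrings::writeXStringSet(Biostrings::BStringSet(seqs), path)
  invisible(path)
}

#' Model file persistence
#'
#' Models are stored as a structured JSON document: format tag, version,
#' core length, the two energy vectors in lexicographic k-mer order, the
#' unconstrained spacer parameters, and training metadata (seed, iteration
#' count, termination reason, tool version). Numbers are written with full
#' precision (17 significant digits), so a write/read round trip
#' reproduces every parameter exactly.
#'
#' @param model A [bmf_model()].
#' @param path File path.
#' @param trace Optional `bmf_trace` whose metadata is embedded.
#' @return `write_model()`: `path` invisibly. `read_model()`: a list with
#'   `model` ([bmf_model()]) and `metadata`.
#' @export
write_model <- function(model, path, trace = NULL) {
  stopifnot(inherits(model, "bmf_model"))
  doc <- list(
    format = MODEL_FORMAT,
    version = MODEL_VERSION,
    k = model$k,
    energies_a = model$core_a$energies,
    energies_b = model$core_b$energies,
    rho = model$spacer$rho,
    pi = model$spacer$pi,
    log_s = model$spacer$log_s,
    metadata = list(
      seed = if (is.null(trace)) NA else trace$seed,
      iterations = if (is.null(trace)) NA else trace$iterations,
      termination = if (is.null(trace)) NA else trace$termination,
      tool_version = as.character(packageVersion("bmf"))))
  # I(17) = 17 *significant* digits: lossless for IEEE doubles
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) stop("cannot read model file: ", path)
  doc <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                  error = function(e) {
                    stop("unparseable model file ", path, ": ",
                         conditionMessage(e))
                  })
  if (!identical(doc$format, MODEL_FORMAT)) {
    stop("not a bmf model file: ", path)
  }
  if (!identical(as.integer(doc$version), MODEL_VERSION)) {
    stop(sprintf("unsupported model file version %s (this build reads %d)",
                 doc$version, MODEL_VERSION))
  }
  needed <- c("k", "energies_a", "energies_b", "rho", "pi", "log_s")
  missing <- setdiff(needed, names(doc))
  if (length(missing)) {
    stop("truncated model file, missing field(s): ",
         paste(missing, collapse = ", "))
  }
  k <- as.integer(doc$k)
  # -Inf (S = 0) survives JSON as the string "-Inf"
  log_s <- if (is.null(doc$log_s)) -Inf else as.numeric(doc$log_s)
  model <- bmf_model(energy_table(doc$energies_a, k),
                     energy_table(doc$energies_b, k),
                     spacer_params(doc$rho, doc$pi, log_s))
  list(model = model, metadata = doc$metadata)
}

# Window start positions (1-based) for the sliding-window score: starts at
# 1, stride apart, plus a final right-anchored window ending at L so the
# sequence is fully covered; duplicates are emitted once.
window_starts <- function(L, window, stride) {
  if (L <= window) return(1L)
  starts <- seq.int(1L, L - window + 1L, by = stride)
  unique(c(starts, L - window + 1L))
}

#' Sliding-window binding scores
#'
#' Sequences no longer than `window` get a single score, the binding
#' probability of the whole sequence. Longer sequences are cut into
#' `window`-length fragments starting every `stride` nucleotides (plus a
#' final right-anchored fragment ending at the last position, so the
#' sequence is fully covered); the score is the arithmetic mean of the
#' per-fragment binding probabilities. Empty sequences score 0.
#'
#' @param model A [bmf_model()].
#' @param sequences Character vector (names used as ids when present).
#' @param window Fragment length (default 50).
#' @param stride Fragment spacing (default 20).
#' @return Data frame with columns `id`, `score` and `n_windows`.
#' @export
predict_scores <- function(model, sequences, window = 50, stride = 20) {
  stopifnot(inherits(model, "bmf_model"), length(sequences) > 0,
            window >= 1, stride >= 1)
  sequences <- normalize_sequence(sequences)
  ids <- names(sequences) %||% paste0("seq_", seq_along(sequences))
  if (any(!nzchar(sequences))) {
    message(sprintf("%d empty sequence(s) scored as 0",
                    sum(!nzchar(sequences))))
  }
  starts <- lapply(nchar(sequences), window_starts, window = window,
                   stride = stride)
  frags <- unlist(mapply(function(s, st) {
    substring(s, st, pmin(st + window - 1L, nchar(s)))
  }, sequences, starts, SIMPLIFY = FALSE), use.names = FALSE)
  p <- binding_probability(frags, model)
  n_win <- lengths(starts)
  grp <- rep(seq_along(sequences), n_win)
  data.frame(id = ids,
             score = as.numeric(tapply(p, grp, mean)),
             n_windows = as.integer(n_win),
             stringsAsFactors = FALSE)
}

#' Write binding scores as TSV
#'
#' @param scores Data frame from [predict_scores()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_scores <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
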