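#' Binary alteration matrix
#'
#' Constructs the universal input container of the package: a tumors-by-events
#' 0/1 matrix with unique sample identifiers as row names and unique event
#' (gene) labels as column names.
#'
#' @param values numeric/integer matrix or data frame with entries in
#'   \{0, 1\}; rows are samples, columns are events.
#' @param sample_ids optional character vector of sample identifiers;
#'   defaults to existing row names or `S1..Sn`.
#' @param event_names optional character vector of event labels; defaults to
#'   existing column names.
#' @return An object of class `alteration_matrix`: an integer matrix with
#'   dimnames, entries 0/1.
#' @export
alteration_matrix <- function(values, sample_ids = NULL, event_names = NULL) {
  values <- as.matrix(values)
  if (nrow(values) < 1L || ncol(values) < 1L)
    stop("alteration matrix must have at least one sample and one event")
  if (is.null(sample_ids))
    sample_ids <- if (!is.null(rownames(values))) rownames(values)
                  else paste0("S", seq_len(nrow(values)))
  if (is.null(event_names)) event_names <- colnames(values)
  if (is.null(event_names))
    stop("event names are required (column names or `event_names`)")
  sample_ids <- as.character(sample_ids)
  event_names <- as.character(event_names)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  if (anyDuplicated(event_names))
    stop("duplicate event names: ",
         paste(unique(event_names[duplicated(event_names)]), collapse = ", "))
  storage.mode(values) <- "double"
  if (anyNA(values))
    stop("missing values are not supported in alteration matrices")
  bad <- which(!(values %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[1L], dim(values))
    stop(sprintf("non-binary entry %s at row '%s', column '%s'",
                 format(values[bad[1L]]), sample_ids[rc[1L]],
                 event_names[rc[2L]]))
  }
  storage.mode(values) <- "integer"
  dimnames(values) <- list(sample_ids, event_names)
  structure(values, class = c("alteration_matrix", "matrix", "array"))
}

#' @export
print.alteration_matrix <- function(x, ...) {
  cat(sprintf("Binary alteration matrix: %d samples x %d events\n",
              nrow(x), ncol(x)))
  cat("Events:", paste(colnames(x), collapse = ", "), "\n")
  invisible(x)
}

#' Read a binary alteration matrix from disk
#'
#' Two dialects are supported.  `binary_tsv` is a tab-separated table with a
#' header row of event names, a first column of sample identifiers, and 0/1
#' entries.  `gistic_thresholded` is a genes-by-samples table of integer
#' copy-number calls in -2..2 (GISTIC "all_thresholded.by_genes" style); it
#' is transposed on read and binarized by `|call| >= call_threshold`.
#'
#' @param path path to the input file.
#' @param dialect `"binary_tsv"` (default) or `"gistic_thresholded"`.
#' @param call_threshold integer in 1..2; a call `x` becomes 1 iff
#'   `|x| >= call_threshold`.  Default 2 (high-level amplification / deep
#'   deletion only).
#' @param sep field separator, default tab (use "," for CSV).
#' @return An [alteration_matrix()].
#' @export
read_matrix <- function(path, dialect = c("binary_tsv", "gistic_thresholded"),
                        call_threshold = 2L, sep = "\t") {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("input file not found: ", path)
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           check.names = FALSE, row.names = 1L,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab)
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (dialect == "gistic_thresholded") {
    if (any(m != round(m)) || any(abs(m) > 2))
      stop("gistic_thresholded dialect requires integer calls in -2..2")
    if (!(call_threshold %in% 1:2))
      stop("call_threshold must be 1 or 2")
    m <- t(m)  # genes-by-samples on disk -> samples-by-events
    m <- (abs(m) >= call_threshold) + 0L
  }
  alteration_matrix(m)
}

#' Write a binary alteration matrix as TSV
#'
#' @param matrix an [alteration_matrix()].
#' @param path output path.
#' @export
write_matrix <- function(matrix, path) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  df <- data.frame(sample = rownames(matrix), unclass(matrix),
                   check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# round half away from zero -- the rule consistent with all printed cohort
# percentages (e.g. 342/963 = 35.51 -> 36, 12.5 -> 13)
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Per-event and any-event frequency summary
#'
#' Counts, per event, the samples carrying the alteration, plus the number of
#' samples carrying at least one event, with integer percentages (rounded
#' half away from zero).
#'
#' @param matrix an [alteration_matrix()].
#' @return A list with `n`, `events` (data frame: event, count, percent) and
#'   `any` (list: count, percent), of class `freq_summary`.
#' @export
frequency_summary <- function(matrix) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  n <- nrow(matrix)
  counts <- colSums(matrix)
  any_count <- sum(rowSums(matrix) > 0L)
  res <- list(
    n = n,
    events = data.frame(
      event = colnames(matrix),
      count = as.integer(counts),
      percent = as.integer(round_half_up(100 * counts / n)),
      row.names = NULL, stringsAsFactors = FALSE),
    any = list(count = as.integer(any_count),
               percent = as.integer(round_half_up(100 * any_count / n))))
  class(res) <- "freq_summary"
  res
}

#' @export
print.freq_summary <- function(x, ...) {
  cat(sprintf("Alteration frequencies (n = %d samples)\n", x$n))
  for (i in seq_len(nrow(x$events)))
    cat(sprintf("  %-10s %4d  (%d%%)\n", x$events$event[i],
                x$events$count[i], x$events$percent[i]))
  cat(sprintf("  %-10s %4d  (%d%%)\n", "any event", x$any$count,
              x$any$percent))
  invisible(x)
}

#' Serialize a frequency summary to JSON
#'
#' Schema: `{event: {count, percent}, ..., any: {count, percent}, n}`.
#'
#' @param x a `freq_summary`.
#' @param path optional output path; if `NULL` the JSON string is returned.
#' @export
freq_summary_json <- function(x, path = NULL) {
  stopifnot(inherits(x, "freq_summary"))
  obj <- stats::setNames(
    lapply(seq_len(nrow(x$events)), function(i)
      list(count = x$events$count[i], percent = x$events$percent[i])),
    x$events$event)
  obj$any <- list(count = x$any$count, percent = x$any$percent)
  obj$n <- x$n
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(path)
}

#' Smoothed marginal and joint event probabilities
#'
#' Empirical marginal probabilities `p_i = count_i / n` and joint
#' probabilities `p_ij = co-count_ij / n`, clamped into
#' `[1/(2n), 1 - 1/(2n)]` so that log-weights stay finite, with the joint
#' re-capped at `min(p_i, p_j)` after clamping.
#'
#' @param matrix an [alteration_matrix()] with at least 2 samples.
#' @return An object of class `freq_estimates`: list with `n`, `marginal`
#'   (named vector), `joint` (k x k symmetric matrix, diagonal = marginal),
#'   and `pseudo_floor = 1/(2n)`.
#' @export
estimate_probabilities <- function(matrix) {
  stopifnot(inherits(matrix, "alteration_matrix"))
  n <- nrow(matrix)
  if (n < 2L) stop("at least 2 samples are required")
  floor_ <- 1 / (2 * n)
  clamp <- function(p) pmin(pmax(p, floor_), 1 - floor_)
  m <- unclass(matrix)
  marginal <- clamp(colSums(m) / n)
  joint <- clamp(crossprod(m) / n)
  # enforce p_ij <= min(p_i, p_j) after clamping; restore diagonal
  cap <- outer(marginal, marginal, pmin)
  joint <- pmin(joint, cap)
  diag(joint) <- marginal
  structure(list(n = n, marginal = marginal, joint = joint,
                 pseudo_floor = floor_),
            class = "freq_estimates")
}

#' @export
print.freq_estimates <- function(x, ...) {
  cat(sprintf("Event probability estimates (n = %d, clamp floor = %g)\n",
              x$n, x$pseudo_floor))
  print(round(x$marginal, 4))
  invisible(x)
}

# validation used by downstream fitters
check_freq <- function(freq) {
  stopifnot(inherits(freq, "freq_estimates"))
  if (any(freq$marginal <= 0) || any(freq$marginal > 1))
    stop("marginal probabilities out of (0, 1]")
  if (any(abs(freq$joint - t(freq$joint)) > 1e-12))
    stop("joint probability matrix is not symmetric")
  invisible(freq)
}
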