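#' Boolean stimulus-by-signal experiment matrix
#'
#' Represents a single-treatment experimental design: rows are stimuli used
#' to perturb the cells, columns are measured signals, and each entry is a
#' Boolean state change (1 = activated phosphorylation, 0 = unchanged).
#' Discretization of raw readouts is the caller's responsibility; only 0/1
#' entries are accepted.
#'
#' @param x a numeric matrix of 0/1 entries, `length(stimuli)` rows by
#'   `length(signals)` columns.
#' @param stimuli,signals character vectors naming the rows and columns.
#' @return an object of class `"experiment_matrix"`: list with `stimuli`,
#'   `signals`, `x` (integer matrix with dimnames), `n_st`, `n_sig`, and
#'   `n_s = n_st * n_sig` (the total measurement count).
#' @examples
#' m <- experiment_matrix(rbind(c(1, 1), c(0, 1)), c("EGF", "TNFA"), c("ERK", "AP1"))
#' m$n_s
#' @export
experiment_matrix <- function(x, stimuli, signals) {
  x <- as.matrix(x)
  stimuli <- trimws(as.character(stimuli))
  signals <- trimws(as.character(signals))
  if (anyDuplicated(stimuli)) stop("duplicate stimulus names")
  if (anyDuplicated(signals)) stop("duplicate signal names")
  if (nrow(x) != length(stimuli) || ncol(x) != length(signals)) {
    stop(sprintf("data matrix is %d x %d but %d stimuli and %d signals were given",
                 nrow(x), ncol(x), length(stimuli), length(signals)))
  }
  bad <- which(!(x %in% c(0, 1)))
  if (length(bad)) {
    rc <- arrayInd(bad[[1L]], dim(x))
    stop(sprintf("non-Boolean entry %s at row %d, column %d",
                 format(x[bad[[1L]]]), rc[1L], rc[2L]))
  }
  both <- intersect(stimuli, signals)
  if (length(both)) {
    warning("name(s) used both as stimulus and as signal: ",
            paste(both, collapse = ", "))
  }
  storage.mode(x) <- "integer"
  dimnames(x) <- list(stimuli, signals)
  structure(
    list(stimuli = stimuli, signals = signals, x = x,
         n_st = length(stimuli), n_sig = length(signals),
         n_s = length(stimuli) * length(signals)),
    class = "experiment_matrix"
  )
}

#' @export
print.experiment_matrix <- function(x, ...) {
  cat(sprintf("experiment matrix: %d stimuli x %d signals (%d measurements, %d activations)\n",
              x$n_st, x$n_sig, x$n_s, sum(x$x)))
  print(x$x)
  invisible(x)
}

read_name_file <- function(file = NULL, text = NULL, what = "name") {
  if (is.null(text) == is.null(file)) stop("supply exactly one of file/text")
  lines <- if (is.null(text)) {
    if (!file.exists(file)) stop(what, " file not found: ", file)
    readLines(file, warn = FALSE)
  } else unlist(strsplit(text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- trimws(sub("\r$", "", lines))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (!length(lines)) stop(what, " list is empty")
  lines
}

#' Parse the three experiment files into an experiment matrix
#'
#' The stimuli and signals files hold one node name per line; the data file
#' is a whitespace- or tab-delimited 0/1 grid with one row per stimulus and
#' one column per signal. An optional header row and/or leading name column
#' are auto-detected when the names match the stimuli/signals lists, and
#' checked for order when present.
#'
#' @param stimuli_file,signals_file,data_file paths to the three files.
#' @param stimuli_text,signals_text,data_text alternatively, file contents as
#'   strings (exactly one of each file/text pair must be supplied).
#' @return an [experiment_matrix].
#' @export
parse_experiment <- function(stimuli_file = NULL, signals_file = NULL,
                             data_file = NULL, stimuli_text = NULL,
                             signals_text = NULL, data_text = NULL) {
  stimuli <- read_name_file(stimuli_file, stimuli_text, "stimuli")
  signals <- read_name_file(signals_file, signals_text, "signals")
  rows <- read_name_file(data_file, data_text, "data")
  cells <- lapply(rows, function(l) strsplit(trimws(l), "[ \t]+")[[1L]])

  # header row: first line's trailing fields reproduce the signal names
  has_header <- length(cells) == length(stimuli) + 1L &&
    identical(utils::tail(cells[[1L]], length(signals)), signals)
  if (has_header) cells <- cells[-1L]
  if (length(cells) != length(stimuli)) {
    stop(sprintf("data file has %d data row(s) but %d stimuli were listed",
                 length(cells), length(stimuli)))
  }
  widths <- lengths(cells)
  has_rownames <- all(widths == length(signals) + 1L) &&
    identical(vapply(cells, `[[`, "", 1L), stimuli)
  if (has_rownames) cells <- lapply(cells, `[`, -1L)
  widths <- lengths(cells)
  if (any(widths != length(signals))) {
    bad <- which(widths != length(signals))[[1L]]
    stop(sprintf("data row %d has %d column(s); expected %d signals",
                 bad, widths[[bad]], length(signals)))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    pos <- which(is.na(vals))[[1L]]
    stop(sprintf("non-numeric data entry at row %d, column %d",
                 (pos - 1L) %/% length(signals) + 1L,
                 (pos - 1L) %% length(signals) + 1L))
  }
  experiment_matrix(matrix(vals, nrow = length(stimuli), byrow = TRUE),
                    stimuli, signals)
}

#' Extract stimulus-to-signal dependencies from the data matrix
#'
#' Every activation (`x[r, c] == 1`) implies a causal dependency: the
#' trained network must connect stimulus r to signal c. Dependencies are
#' enumerated row-major (all of row 1, then row 2, ...) and indexed `k`
#' in that order.
#'
#' @param m an [experiment_matrix].
#' @return a data frame with columns `k`, `stimulus`, `signal`; zero rows
#'   for an all-zero matrix.
#' @examples
#' m <- experiment_matrix(rbind(c(1, 0)), "EGF", c("ERK", "AP1"))
#' extract_dependencies(m)
#' @export
extract_dependencies <- function(m) {
  stopifnot(inherits(m, "experiment_matrix"))
  on <- which(t(m$x) == 1L)  # transpose => row-major enumeration
  sig_i <- (on - 1L) %% m$n_sig + 1L
  st_i <- (on - 1L) %/% m$n_sig + 1L
  data.frame(k = seq_along(on),
             stimulus = m$stimuli[st_i],
             signal = m$signals[sig_i],
             stringsAsFactors = FALSE)
}

#' Conflict nodes of a stimulus row
#'
#' Signals measured as unchanged (`x[r, c] == 0`) under a given stimulus:
#' their presence as intermediates on a path used for that stimulus would
#' contradict the data. Conflicts are strictly per-row; a node measured 0
#' under one stimulus does not constrain other stimuli's paths.
#'
#' @param m an [experiment_matrix].
#' @param stimulus a row name of `m`.
#' @return character vector of signal names (possibly empty).
#' @export
conflict_nodes <- function(m, stimulus) {
  stopifnot(inherits(m, "experiment_matrix"))
  r <- match(stimulus, m$stimuli)
  if (is.na(r)) stop("unknown stimulus: ", stimulus)
  m$signals[m$x[r, ] == 0L]
}

#' Conflicts introduced by a path
#'
#' Intersects a path's nodes beyond the source stimulus with a conflict set,
#' excluding the dependency's own target (which is measured active by
#' construction). Unmeasured intermediates are never conflicts.
#'
#' @param path character vector of node names (source first).
#' @param conflicts conflict set, e.g. from [conflict_nodes()].
#' @param target the dependency's signal, excluded from the result.
#' @return character vector of conflict nodes on the path.
#' @export
path_conflicts <- function(path, conflicts, target) {
  stopifnot(length(path) >= 1L)
  setdiff(intersect(path[-1L], conflicts), target)
}
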