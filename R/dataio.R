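#' Construct a multichannel fNIRS dataset
#'
#' Container for a block of oxygenated-hemoglobin time series organized as
#' participants x channels x samples, together with per-participant binary
#' group labels (1 = patient, 0 = control) and the sampling rate.
#'
#' @param signals Numeric 3-d array, participants x channels x samples,
#'   concentration-change units (arbitrary mM.mm scale).
#' @param sampling_rate Sampling rate in Hz (> 0).
#' @param labels Integer vector of 0/1 group labels, one per participant.
#'   1 marks the patient group so that sensitivity is the patient recall.
#' @param channel_ids Optional integer vector of 1-based channel ids;
#'   defaults to `1:n_channels`. Must be strictly increasing and unique.
#' @return An object of class `fnirs_dataset` with elements `signals`,
#'   `sampling_rate`, `labels`, `channel_ids`.
#' @export
fnirs_dataset <- function(signals, sampling_rate, labels,
                          channel_ids = NULL) {
  if (!is.array(signals) || length(dim(signals)) != 3L) {
    stop_("signals must be a 3-d array (participants x channels x samples)")
  }
  d <- dim(signals)
  if (any(d == 0L)) {
    stop_("degenerate dataset: dimensions %s contain a zero extent",
          paste(d, collapse = " x "))
  }
  bad <- which(!is.finite(signals))
  if (length(bad)) {
    idx <- arrayInd(bad[1L], d)
    stop_(paste0("non-finite signal value at participant %d, channel %d, ",
                 "sample %d"), idx[1], idx[2], idx[3])
  }
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0) {
    stop_("sampling_rate must be a single positive number (Hz)")
  }
  labels <- as.integer(labels)
  if (length(labels) != d[1L]) {
    stop_("label count %d != participants %d", length(labels), d[1L])
  }
  if (!all(labels %in% c(0L, 1L))) stop_("labels must be 0 (control) or 1 (patient)")
  if (is.null(channel_ids)) channel_ids <- seq_len(d[2L])
  channel_ids <- as.integer(channel_ids)
  if (length(channel_ids) != d[2L] || anyDuplicated(channel_ids) ||
      is.unsorted(channel_ids, strictly = TRUE)) {
    stop_("channel_ids must be %d unique, strictly increasing integers", d[2L])
  }
  structure(list(signals = signals, sampling_rate = sampling_rate,
                 labels = labels, channel_ids = channel_ids),
            class = "fnirs_dataset")
}

#' @export
print.fnirs_dataset <- function(x, ...) {
  d <- dim(x$signals)
  cat(sprintf(
    "fnirs_dataset: %d participants x %d channels x %d samples @ %g Hz\n",
    d[1], d[2], d[3], x$sampling_rate))
  cat(sprintf("  labels: %d patient / %d control\n",
              sum(x$labels == 1L), sum(x$labels == 0L)))
  invisible(x)
}

#' @export
dim.fnirs_dataset <- function(x) dim(x$signals)

n_participants <- function(x) dim(x$signals)[1L]
n_channels <- function(x) dim(x$signals)[2L]
n_samples <- function(x) dim(x$signals)[3L]

#' Read a dataset from delimited text
#'
#' The signal file is either a single delimited-text file with a two-line
#' `#` header (`#dims P C S` and `#sampling_rate H`) followed by the
#' participant-major flattening — row `(p-1)*C + c` holds the S samples of
#' participant p, channel c — or a directory of per-participant files, each
#' a channels x samples table, read in lexicographic filename order.
#' The labels file holds one 0/1 label per line in participant order.
#'
#' @param signal_path Path to the signal file or directory.
#' @param labels_path Path to the labels file.
#' @param sampling_rate Sampling rate in Hz. Overrides any header value when
#'   given; required for directory input.
#' @return An [fnirs_dataset()].
#' @export
load_dataset <- function(signal_path, labels_path, sampling_rate = NULL) {
  if (!file.exists(signal_path)) stop_("signal file not found: %s", signal_path)
  if (!file.exists(labels_path)) stop_("labels file not found: %s", labels_path)
  labels <- read_labels(labels_path)
  if (dir.exists(signal_path)) {
    files <- sort(list.files(signal_path, full.names = TRUE))
    if (!length(files)) stop_("signal directory %s is empty", signal_path)
    mats <- lapply(files, function(f) {
      m <- as.matrix(utils::read.table(f, sep = delim_for(f)))
      storage.mode(m) <- "double"
      m
    })
    dims <- vapply(mats, dim, integer(2))
    if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
      stop_("per-participant files disagree on channels x samples shape")
    }
    sig <- aperm(simplify2array(mats), c(3L, 1L, 2L))
    dimnames(sig) <- NULL
    if (is.null(sampling_rate)) {
      stop_("sampling_rate is required for directory input")
    }
    fs <- sampling_rate
  } else {
    header <- readLines(signal_path, n = 2L)
    if (length(header) < 2L || !startsWith(header[1L], "#dims") ||
        !startsWith(header[2L], "#sampling_rate")) {
      stop_("signal file %s lacks the '#dims'/'#sampling_rate' header",
            signal_path)
    }
    dims <- as.integer(strsplit(trimws(sub("^#dims", "", header[1L])),
                                "[ \t,]+")[[1L]])
    if (length(dims) != 3L || anyNA(dims)) {
      stop_("malformed #dims header in %s", signal_path)
    }
    fs_hdr <- as.numeric(trimws(sub("^#sampling_rate", "", header[2L])))
    fs <- if (is.null(sampling_rate)) fs_hdr else sampling_rate
    m <- utils::read.table(signal_path, sep = delim_for(signal_path),
                           comment.char = "#",
                           colClasses = "character")
    m <- as.matrix(m)
    num <- suppressWarnings(array(as.numeric(m), dim = dim(m)))
    bad <- which(is.na(num) & !is.na(m))
    if (length(bad)) {
      idx <- arrayInd(bad[1L], dim(m))
      stop_("non-numeric cell '%s' at data row %d, column %d of %s",
            m[bad[1L]], idx[1], idx[2], signal_path)
    }
    if (nrow(num) != dims[1] * dims[2] || ncol(num) != dims[3]) {
      stop_("signal body is %d x %d but #dims declares %d x %d x %d",
            nrow(num), ncol(num), dims[1], dims[2], dims[3])
    }
    sig <- aperm(array(t(num), dim = c(dims[3], dims[2], dims[1])),
                 c(3L, 2L, 1L))
  }
  if (length(labels) != dim(sig)[1L]) {
    stop_("label count %d != participants %d", length(labels), dim(sig)[1L])
  }
  fnirs_dataset(sig, fs, labels)
}

read_labels <- function(path) {
  x <- trimws(readLines(path))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  v <- suppressWarnings(as.integer(x))
  if (anyNA(v)) stop_("non-integer label '%s' in %s", x[which(is.na(v))[1L]], path)
  v
}

#' Write a dataset to delimited text
#'
#' Inverse of [load_dataset()]: writes the single-file format with the
#' two-line header at full double precision, so that a save/load round trip
#' reproduces the dataset exactly.
#'
#' @param dataset An [fnirs_dataset()].
#' @param signal_path,labels_path Output paths; extension selects TSV/CSV.
#' @return Invisibly, `dataset`.
#' @export
save_dataset <- function(dataset, signal_path, labels_path) {
  stopifnot(inherits(dataset, "fnirs_dataset"))
  d <- dim(dataset$signals)
  sep <- delim_for(signal_path)
  flat <- matrix(aperm(dataset$signals, c(3L, 2L, 1L)),
                 nrow = d[1] * d[2], ncol = d[3], byrow = TRUE)
  con <- file(signal_path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(c(sprintf("#dims %d %d %d", d[1], d[2], d[3]),
               sprintf("#sampling_rate %.10g", dataset$sampling_rate)), con)
  utils::write.table(format(flat, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = sep, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  writeLines(as.character(dataset$labels), labels_path)
  invisible(dataset)
}

#' Channel-to-region montage
#'
#' The default montage maps the 52 channels of the standard prefrontal/
#' temporal probe set onto nine cortical region labels (rSFC, rDLPFC,
#' lDLPFC, lSFC, rSTC, rVLPFC, mPFC, lVLPFC, lSTC). The assignment is an
#' approximate reading of the published probe geometry — region boundaries
#' on a 10/11-channel row grid — and ships as an editable two-column
#' `channel,region` CSV under `extdata/` so users can substitute their own.
#'
#' @param path Optional path to a user-supplied `channel,region` CSV that
#'   overrides the packaged default.
#' @return A data.frame of class `fnirs_montage` with integer `channel`
#'   and character `region` columns.
#' @export
default_montage <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "montage52.csv", package = "fnirsopt",
                        mustWork = TRUE)
  }
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("channel", "region") %in% names(m))) {
    stop_("montage file must have 'channel' and 'region' columns")
  }
  m$channel <- as.integer(m$channel)
  if (anyDuplicated(m$channel)) stop_("montage assigns a channel twice")
  bad <- setdiff(unique(m$region), montage_regions())
  if (length(bad)) {
    stop_("unknown region label(s): %s", paste(bad, collapse = ", "))
  }
  m <- m[order(m$channel), , drop = FALSE]
  rownames(m) <- NULL
  class(m) <- c("fnirs_montage", "data.frame")
  m
}

#' @rdname default_montage
#' @export
montage_regions <- function() {
  c("rSFC", "rDLPFC", "lDLPFC", "lSFC", "rSTC", "rVLPFC", "mPFC",
    "lVLPFC", "lSTC")
}
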