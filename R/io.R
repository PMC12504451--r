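## Record I/O.  Three on-disk forms are supported: WFDB header+signal
## pairs (.hea + .dat, format 16, the PTB-XL style), single-matrix MAT v5
## files (the CinC-2017 / CPSC-2018 style), and plain delimited text (one
## column per lead, optional header row of lead names).  Amplitudes are
## normalized to millivolts on load using the file's gain metadata where
## available; delimited and MAT inputs are assumed to already be in mV.

POSITIONAL_LEADS <- c("I", "II", "III", "aVR", "aVL", "aVF", paste0("V", 1:6))

.positional_leads <- function(k) {
  if (k == 1L) "SL" else if (k <= 12L) POSITIONAL_LEADS[seq_len(k)]
  else stop_format("cannot assign default lead names to %d channels", k)
}

#' Load an ECG record
#'
#' @param path file path (for WFDB, the `.hea` file or the base name).
#' @param format `"wfdb"`, `"mat"` or `"delimited"`; default guesses from
#'   the file extension.
#' @param fs_hint sampling rate in Hz; required for delimited and MAT
#'   inputs whose format carries no rate.
#' @param label optional class label to attach (`"norm"`/`"afib"`).
#' @return an [ECGRecord-class]; lead names come from file metadata when
#'   present, else positional defaults (I, II, III, aVR, aVL, aVF, V1-V6
#'   for multi-lead files, `"SL"` for single-column ones).
#' @examples
#' p <- tempfile(fileext = ".csv")
#' writeRecord(synthRecord(synthConfig())$record, p, format = "delimited")
#' loadRecord(p, fs_hint = 100)
#' @export
loadRecord <- function(path, format = c("auto", "wfdb", "mat", "delimited"),
                       fs_hint = NULL, label = "unlabeled") {
  format <- match.arg(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      hea = "wfdb", dat = "wfdb", mat = "mat",
      csv = "delimited", tsv = "delimited", txt = "delimited",
      stop_format("cannot infer format from extension '.%s'; pass format=", ext))
  }
  switch(format,
    wfdb = .read_wfdb(path, label),
    mat = .read_mat_record(path, fs_hint, label),
    delimited = .read_delimited(path, fs_hint, label))
}

#' Extract one lead from a record
#'
#' A pure projection: the named signal is returned unchanged.  Matching is
#' case-insensitive.
#'
#' @param record an [ECGRecord-class].
#' @param lead lead name.
#' @return the requested [Signal-class].
#' @export
selectLead <- function(record, lead) {
  if (!is(record, "ECGRecord")) stop_argument("record must be an ECGRecord")
  leads <- leadNames(record)
  hit <- match(tolower(lead), tolower(leads))
  if (is.na(hit))
    stop_lookup("lead '%s' not present; available: %s", lead,
                paste(leads, collapse = ", "))
  record@signals[[hit]]
}

#' Write an ECG record
#'
#' @param record an [ECGRecord-class].
#' @param path output path (for WFDB, the `.hea` path; the `.dat` is
#'   written alongside).
#' @param format `"wfdb"`, `"mat"` or `"delimited"`.
#' @return `path`, invisibly.
#' @export
writeRecord <- function(record, path,
                        format = c("delimited", "wfdb", "mat")) {
  format <- match.arg(format)
  if (!is(record, "ECGRecord")) stop_argument("record must be an ECGRecord")
  switch(format,
    delimited = .write_delimited(record, path),
    wfdb = .write_wfdb(record, path),
    mat = .write_mat_record(record, path))
  invisible(path)
}

## delimited ---------------------------------------------------------------

.read_delimited <- function(path, fs_hint, label) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  if (is.null(fs_hint))
    stop_config("delimited input carries no sampling rate; fs_hint is required")
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first)) "\t" else if (grepl(",", first)) "," else ""
  has_header <- grepl("[A-Za-z]", first)
  df <- utils::read.table(path, header = has_header, sep = sep)
  leads <- if (has_header) colnames(df) else .positional_leads(ncol(df))
  sigs <- lapply(seq_len(ncol(df)), function(j) {
    v <- as.numeric(df[[j]])
    if (!all(is.finite(v)))
      stop_data("lead %s contains non-finite samples", leads[j])
    Signal(v, fs = fs_hint, lead = leads[j], source = basename(path))
  })
  ECGRecord(sigs, label = label,
            record_id = tools::file_path_sans_ext(basename(path)))
}

.write_delimited <- function(record, path) {
  df <- as.data.frame(lapply(record@signals, function(s) s@samples))
  colnames(df) <- leadNames(record)
  utils::write.table(df, path, sep = ",", row.names = FALSE,
                     col.names = TRUE, quote = FALSE)
}

## WFDB format 16 ----------------------------------------------------------

.read_wfdb <- function(path, label) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) stop_format("no such header file: %s", hea)
  lines <- trimws(readLines(hea))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  head_tok <- strsplit(lines[1], "\\s+")[[1]]
  if (length(head_tok) < 4L)
    stop_format("malformed WFDB header line in %s", hea)
  rec_id <- head_tok[1]
  nsig <- as.integer(head_tok[2])
  fs <- as.numeric(head_tok[3])
  nsamp <- as.integer(head_tok[4])
  if (!is.finite(fs) || fs <= 0)
    stop_config("header %s carries no usable sampling rate", hea)
  if (length(lines) < 1L + nsig)
    stop_format("header %s declares %d signals but lists fewer", hea, nsig)

  gains <- numeric(nsig); leads <- character(nsig); datfile <- NULL
  for (j in seq_len(nsig)) {
    tok <- strsplit(lines[1L + j], "\\s+")[[1]]
    if (length(tok) < 3L) stop_format("malformed signal line %d in %s", j, hea)
    datfile <- tok[1]
    if (tok[2] != "16")
      stop_format("only WFDB format 16 is supported (got '%s')", tok[2])
    g <- suppressWarnings(as.numeric(sub("[(/].*$", "", tok[3])))
    gains[j] <- if (is.finite(g) && g > 0) g else 200
    leads[j] <- if (length(tok) >= 9L) tok[length(tok)]
                else .positional_leads(nsig)[j]
  }
  dat <- file.path(dirname(hea), datfile)
  if (!file.exists(dat)) stop_format("no such signal file: %s", dat)
  raw <- readBin(dat, "integer", n = nsig * nsamp, size = 2L,
                 signed = TRUE, endian = "little")
  if (length(raw) < nsig * nsamp)
    stop_format("signal file %s shorter than header declares", dat)
  m <- matrix(raw, nrow = nsig)                     # interleaved samples
  sigs <- lapply(seq_len(nsig), function(j) {
    v <- m[j, ] / gains[j]
    if (!all(is.finite(v))) stop_data("lead %s contains non-finite samples", leads[j])
    Signal(v, fs = fs, lead = leads[j], source = basename(hea))
  })
  ECGRecord(sigs, label = label, record_id = rec_id)
}

.write_wfdb <- function(record, path, gain = 1000) {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  base <- tools::file_path_sans_ext(basename(hea))
  dat <- file.path(dirname(hea), paste0(base, ".dat"))
  nsig <- length(record@signals)
  nsamp <- length(record@signals[[1]]@samples)
  fs <- record@signals[[1]]@fs
  lines <- sprintf("%s %d %g %d", base, nsig, fs, nsamp)
  for (s in record@signals)
    lines <- c(lines, sprintf("%s.dat 16 %g/mV 16 0 0 0 0 %s",
                              base, gain, s@lead))
  writeLines(lines, hea)
  m <- vapply(record@signals,
              function(s) as.integer(round(s@samples * gain)),
              integer(nsamp))
  if (max(abs(m)) > 32767)
    stop_data("samples exceed the 16-bit range at gain %g", gain)
  writeBin(as.integer(t(m)), dat, size = 2L, endian = "little")
}

## MAT v5 (single 2-D numeric matrix, uncompressed) ------------------------

.read_mat_record <- function(path, fs_hint, label) {
  if (!file.exists(path)) stop_format("no such file: %s", path)
  if (is.null(fs_hint))
    stop_config("MAT input carries no sampling rate; fs_hint is required")
  con <- file(path, "rb")
  on.exit(close(con))
  header <- readBin(con, "raw", 124L)
  version <- readBin(con, "integer", 1L, size = 2L, endian = "little")
  magic <- rawToChar(readBin(con, "raw", 2L))
  if (magic != "IM")
    stop_format("%s is not a little-endian MAT v5 file", path)
  tag <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  if (tag[1] != 14L)
    stop_format("%s: expected an uncompressed miMATRIX element", path)
  readBin(con, "integer", 4L, size = 4L, endian = "little")  # array flags
  dim_tag <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  ndim <- dim_tag[2] %/% 4L
  dims <- readBin(con, "integer", ndim, size = 4L, endian = "little")
  if (ndim %% 2L == 1L) readBin(con, "integer", 1L, size = 4L)   # pad
  if (length(dims) != 2L)
    stop_format("%s: expected a 2-D matrix (got %d dims)", path, length(dims))
  # array name (possibly small-element format)
  nm_tag <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  if (bitwAnd(nm_tag, -65536L) != 0L) {          # small element: len in high bytes
    invisible(readBin(con, "raw", 4L))
  } else {
    nlen <- readBin(con, "integer", 1L, size = 4L, endian = "little")
    invisible(readBin(con, "raw", as.integer(8L * ceiling(nlen / 8))))
  }
  data_tag <- readBin(con, "integer", 2L, size = 4L, endian = "little")
  nel <- prod(dims)
  vals <- switch(as.character(data_tag[1]),
    "9" = readBin(con, "numeric", nel, size = 8L, endian = "little"),
    "3" = readBin(con, "integer", nel, size = 2L, signed = TRUE,
                  endian = "little") / 1000,     # int16 assumed 1000 units/mV
    stop_format("%s: unsupported MAT data type %d", path, data_tag[1]))
  m <- matrix(vals, nrow = dims[1], ncol = dims[2])
  if (nrow(m) < ncol(m)) m <- t(m)               # longer axis is time
  leads <- .positional_leads(ncol(m))
  sigs <- lapply(seq_len(ncol(m)), function(j) {
    if (!all(is.finite(m[, j])))
      stop_data("lead %s contains non-finite samples", leads[j])
    Signal(m[, j], fs = fs_hint, lead = leads[j], source = basename(path))
  })
  ECGRecord(sigs, label = label,
            record_id = tools::file_path_sans_ext(basename(path)))
}

.write_mat_record <- function(record, path) {
  m <- vapply(record@signals, function(s) s@samples,
              numeric(length(record@signals[[1]]@samples)))
  m <- t(as.matrix(m))                           # leads x samples, like CinC 'val'
  con <- file(path, "wb")
  on.exit(close(con))
  desc <- sprintf("MATLAB 5.0 MAT-file, written by slecg")
  hdr <- raw(124L)
  dr <- charToRaw(desc)
  hdr[seq_along(dr)] <- dr
  writeBin(hdr, con)
  writeBin(c(256L), con, size = 2L, endian = "little")         # version 0x0100
  writeBin(charToRaw("IM"), con)
  name <- "val"
  nbytes <- 16L +                                # array flags
    16L +                                        # dims (2 x int32 + tag)
    8L + 8L +                                    # name tag + padded name
    8L + 8L * length(m)                          # data tag + doubles
  writeBin(c(14L, nbytes), con, size = 4L, endian = "little")
  writeBin(c(6L, 8L, 6L, 0L), con, size = 4L, endian = "little")  # flags: double class
  writeBin(c(5L, 8L), con, size = 4L, endian = "little")
  writeBin(as.integer(dim(m)), con, size = 4L, endian = "little")
  writeBin(c(1L, nchar(name)), con, size = 4L, endian = "little")
  nm <- raw(8L)
  nm[seq_len(nchar(name))] <- charToRaw(name)
  writeBin(nm, con)
  writeBin(c(9L, 8L * length(m)), con, size = 4L, endian = "little")
  writeBin(as.numeric(m), con, size = 8L, endian = "little")
}
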