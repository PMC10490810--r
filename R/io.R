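# Record I/O: a simple CSV dialect and the WFDB binary format.
#
# CSV dialect: first line `fs=<Hz>`, then one sample (mV) per line; beat
# annotations live in a sidecar `<stem>.ann.csv` with header
# `sample_index,label` and 0-based sample indices.
#
# WFDB: `<stem>.hea` header + `<stem>.dat` signal (formats 212 and 16
# supported) + optional `<stem>.atr` MIT annotation file. Gain/baseline
# from the header are applied on read so samples are always mV in memory.

# MIT annotation code <-> symbol table (beat codes plus the common
# non-beat codes needed to round-trip typical files)
.atr_codes <- c("N" = 1, "L" = 2, "R" = 3, "a" = 4, "V" = 5, "F" = 6,
                "J" = 7, "A" = 8, "S" = 9, "E" = 10, "j" = 11, "/" = 12,
                "Q" = 13, "~" = 14, "|" = 16, "e" = 34, "n" = 35, "x" = 37,
                "f" = 38)

#' Read an ECG record
#'
#' @param path for `dialect = "csv"` the sample file; for `"wfdb"` the
#'   record stem (with or without `.hea`). `"auto"` picks by extension.
#' @param dialect `"auto"`, `"csv"` or `"wfdb"`.
#' @return an [ecg_record()]; annotations are attached when the sidecar
#'   (`.ann.csv`) or annotation file (`.atr`) exists.
#' @export
read_ecg <- function(path, dialect = c("auto", "csv", "wfdb")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", path)) "csv" else "wfdb"
  if (dialect == "csv") read_ecg_csv(path) else read_ecg_wfdb(path)
}

#' Write an ECG record
#'
#' Round-trips with [read_ecg()]: annotations and the sampling rate are
#' preserved exactly, samples within the format's precision (exact for
#' CSV, quantized by the ADC gain for WFDB).
#'
#' @param record an [ecg_record()].
#' @param path sample-file path (csv) or record stem (wfdb).
#' @param dialect `"csv"` or `"wfdb"`.
#' @param fmt WFDB signal storage format, 212 (default, MIT-BIH's) or 16.
#' @param gain WFDB ADC gain in units per mV.
#' @return `path`, invisibly.
#' @export
write_ecg <- function(record, path, dialect = c("csv", "wfdb"),
                      fmt = 212, gain = 200) {
  stopifnot(inherits(record, "ecg_record"))
  dialect <- match.arg(dialect)
  if (dialect == "csv") write_ecg_csv(record, path)
  else write_ecg_wfdb(record, path, fmt = fmt, gain = gain)
  invisible(path)
}

# CSV dialect -----------------------------------------------------------------

ann_sidecar_path <- function(path) sub("\\.csv$", ".ann.csv", path)

read_ecg_csv <- function(path) {
  if (!file.exists(path)) stop_invalid("file not found: %s", path)
  lines <- readLines(path)
  if (!length(lines) || !grepl("^fs=", lines[1]))
    stop_invalid("%s line 1: expected header 'fs=<Hz>', got '%s'",
                 path, if (length(lines)) lines[1] else "<empty>")
  fs <- suppressWarnings(as.numeric(sub("^fs=", "", lines[1])))
  if (is.na(fs) || fs <= 0)
    stop_invalid("%s line 1: invalid sampling rate '%s'", path, lines[1])
  body <- lines[-1]
  body <- body[nzchar(body)]
  samples <- suppressWarnings(as.numeric(body))
  if (anyNA(samples)) {
    bad <- which(is.na(samples))[1]
    stop_invalid("%s line %d: not a number: '%s'", path, bad + 1L, body[bad])
  }
  ann <- NULL
  sidecar <- ann_sidecar_path(path)
  if (file.exists(sidecar)) {
    tab <- read.csv(sidecar, stringsAsFactors = FALSE)
    if (!all(c("sample_index", "label") %in% names(tab)))
      stop_invalid("%s: expected columns sample_index,label", sidecar)
    idx <- as.integer(tab$sample_index) + 1L  # 0-based on disk
    if (anyNA(idx) || any(idx < 1L) || any(idx > length(samples)))
      stop_invalid("%s: annotation index out of range [0, %d)", sidecar,
                   length(samples))
    ann <- data.frame(sample = idx, symbol = as.character(tab$label),
                      stringsAsFactors = FALSE)
  }
  ecg_record(samples, fs,
             record_id = sub("\\.csv$", "", basename(path)),
             annotations = ann)
}

write_ecg_csv <- function(record, path) {
  writeLines(c(sprintf("fs=%.10g", record$fs),
               sprintf("%.8g", record$samples)), path)
  sidecar <- ann_sidecar_path(path)
  if (nrow(record$annotations)) {
    tab <- data.frame(sample_index = record$annotations$sample - 1L,
                      label = record$annotations$symbol)
    write.csv(tab, sidecar, row.names = FALSE, quote = FALSE)
  } else if (file.exists(sidecar)) {
    unlink(sidecar)  # stale sidecar would resurrect on read
  }
}

# WFDB ------------------------------------------------------------------------

wfdb_stem <- function(path) sub("\\.(hea|dat|atr)$", "", path)

read_ecg_wfdb <- function(path) {
  stem <- wfdb_stem(path)
  hea <- paste0(stem, ".hea")
  if (!file.exists(hea)) stop_invalid("file not found: %s", hea)
  lines <- readLines(hea)
  lines <- lines[!grepl("^#", lines) & nzchar(lines)]
  rec_line <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  if (length(rec_line) < 4)
    stop_invalid("%s line 1: malformed record line '%s'", hea, lines[1])
  n_sig <- as.integer(rec_line[2])
  fs <- as.numeric(rec_line[3])
  n_samp <- as.integer(rec_line[4])
  if (is.na(fs) || fs <= 0 || is.na(n_sig) || n_sig < 1)
    stop_invalid("%s line 1: invalid record line '%s'", hea, lines[1])
  sig_line <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (length(sig_line) < 3)
    stop_invalid("%s line 2: malformed signal line '%s'", hea, lines[2])
  dat_file <- file.path(dirname(hea), sig_line[1])
  fmt <- as.integer(sub("x.*$", "", sig_line[2]))
  gain_spec <- sig_line[3]
  baseline <- 0
  gain <- suppressWarnings(as.numeric(sub("[(/].*$", "", gain_spec)))
  if (grepl("\\(", gain_spec))
    baseline <- as.numeric(sub("^.*\\(([-0-9]+)\\).*$", "\\1", gain_spec))
  if (is.na(gain) || gain == 0) gain <- 200
  adc <- read_wfdb_dat(dat_file, fmt, n_sig, n_samp)
  samples <- (adc - baseline) / gain
  ann <- NULL
  atr <- paste0(stem, ".atr")
  if (file.exists(atr)) {
    ann <- read_wfdb_atr(atr)
    if (nrow(ann) && (min(ann$sample) < 1L || max(ann$sample) > length(samples)))
      stop_invalid("%s: annotation index out of range [0, %d)", atr,
                   length(samples))
  }
  ecg_record(samples, fs, record_id = basename(stem), annotations = ann)
}

read_wfdb_dat <- function(dat_file, fmt, n_sig, n_samp) {
  if (!file.exists(dat_file)) stop_invalid("file not found: %s", dat_file)
  raw <- readBin(dat_file, "raw", n = file.size(dat_file))
  total <- if (is.na(n_samp) || n_samp <= 0) NA_integer_ else n_sig * n_samp
  if (fmt == 16L) {
    v <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                 signed = TRUE, endian = "little")
  } else if (fmt == 212L) {
    b <- as.integer(raw)
    n_pairs <- length(b) %/% 3L
    i <- 3L * (seq_len(n_pairs) - 1L)
    s1 <- b[i + 1L] + bitwAnd(b[i + 2L], 0x0FL) * 256L
    s2 <- b[i + 3L] + bitwAnd(bitwShiftR(b[i + 2L], 4L), 0x0FL) * 256L
    v <- as.vector(rbind(s1, s2))
    v <- ifelse(v >= 2048L, v - 4096L, v)  # 12-bit two's complement
  } else {
    stop_invalid("unsupported WFDB signal format %d", fmt)
  }
  if (!is.na(total)) v <- v[seq_len(min(total, length(v)))]
  if (n_sig > 1L) v <- v[seq(1, length(v), by = n_sig)]  # first signal only
  v
}

write_ecg_wfdb <- function(record, stem, fmt = 212, gain = 200) {
  adc <- as.integer(round(record$samples * gain))
  lim <- if (fmt == 212) 2047L else 32767L
  adc <- pmax(pmin(adc, lim), -lim - 1L)
  storage.mode(adc) <- "integer"  # pmax/pmin may promote to double
  dat <- paste0(stem, ".dat")
  if (fmt == 16) {
    writeBin(adc, dat, size = 2, endian = "little")
  } else if (fmt == 212) {
    v <- adc
    if (length(v) %% 2L == 1L) v <- c(v, 0L)
    u <- ifelse(v < 0L, v + 4096L, v)
    s1 <- u[seq(1, length(u), 2)]
    s2 <- u[seq(2, length(u), 2)]
    bytes <- as.raw(rbind(s1 %% 256L,
                          (s1 %/% 256L) + 16L * (s2 %/% 256L),
                          s2 %% 256L))
    writeBin(bytes, dat)
  } else stop_invalid("unsupported WFDB signal format %d", fmt)
  hea <- c(sprintf("%s 1 %.10g %d", basename(stem), record$fs,
                   length(record$samples)),
           sprintf("%s.dat %d %g(0)/mV 12 0 0 0 0 ECG", basename(stem), fmt,
                   gain))
  writeLines(hea, paste0(stem, ".hea"))
  if (nrow(record$annotations))
    write_wfdb_atr(record$annotations, paste0(stem, ".atr"))
  else unlink(paste0(stem, ".atr"))
}

# MIT annotation format: little-endian 16-bit words; high 6 bits = code,
# low 10 bits = sample increment. SKIP (59) with increment 0 is followed
# by a 4-byte interval (high word first). code 0 terminates.
read_wfdb_atr <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  words <- readBin(raw, "integer", n = length(raw) %/% 2, size = 2,
                   signed = FALSE, endian = "little")
  code_of <- function(w) bitwShiftR(w, 10L)
  time_of <- function(w) bitwAnd(w, 1023L)
  samples <- integer(0); symbols <- character(0)
  t <- 0L
  i <- 1L
  sym_of <- setNames(names(.atr_codes), as.character(.atr_codes))
  while (i <= length(words)) {
    w <- words[i]
    code <- code_of(w)
    if (code == 0L && time_of(w) == 0L) break
    if (code == 59L) {            # SKIP: long interval follows
      if (time_of(w) == 0L) {
        hi <- words[i + 1L]; lo <- words[i + 2L]
        t <- t + hi * 65536L + lo
        i <- i + 3L
      } else {
        t <- t + time_of(w); i <- i + 1L
      }
      next
    }
    if (code == 63L) {            # AUX: skip payload
      len <- time_of(w)
      i <- i + 1L + (len + len %% 2L) %/% 2L
      next
    }
    if (code %in% c(60L, 61L, 62L)) { i <- i + 1L; next }  # NUM/SUB/CHN
    t <- t + time_of(w)
    sym <- sym_of[as.character(code)]
    if (is.na(sym))
      stop_invalid("%s: unknown annotation code %d at word %d", path, code, i)
    samples <- c(samples, t + 1L)  # file is 0-based
    symbols <- c(symbols, unname(sym))
    i <- i + 1L
  }
  data.frame(sample = samples, symbol = symbols, stringsAsFactors = FALSE)
}

write_wfdb_atr <- function(annotations, path) {
  codes <- .atr_codes[annotations$symbol]
  if (anyNA(codes))
    stop_invalid("cannot encode annotation symbol(s): %s",
                 paste(unique(annotations$symbol[is.na(codes)]), collapse = ", "))
  t0 <- annotations$sample - 1L  # 0-based on disk
  incr <- diff(c(0L, t0))
  words <- integer(0)
  for (i in seq_along(incr)) {
    dt <- incr[i]
    if (dt > 1023L) {
      words <- c(words, bitwShiftL(59L, 10L), dt %/% 65536L, dt %% 65536L)
      dt <- 0L
    }
    words <- c(words, bitwShiftL(as.integer(codes[i]), 10L) + dt)
  }
  words <- c(words, 0L)  # EOF
  bytes <- as.raw(rbind(words %% 256L, words %/% 256L))
  writeBin(bytes, path)
}
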