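#' Construct a single-lead ECG record
#'
#' Bundles a sampled voltage trace with its sampling rate and (optionally)
#' beat annotations. In memory, annotation sample positions are 1-based R
#' indices pointing at the annotated R-peak sample; on disk (CSV sidecar,
#' WFDB annotation file) they are written 0-based following the MIT-BIH
#' convention.
#'
#' @param samples numeric vector of voltages in mV.
#' @param fs sampling rate in Hz (> 0).
#' @param record_id short identifier used in file stems and provenance.
#' @param annotations `NULL` or a data.frame with columns `sample`
#'   (1-based integer index into `samples`, strictly increasing) and
#'   `symbol` (single-character MIT-BIH beat code such as "N", "L", "R",
#'   "V", "A", "F").
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, fs, record_id = "rec", annotations = NULL) {
  check_numeric_vector(samples, "samples")
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop_invalid("`fs` must be a single positive number (Hz)")
  if (is.null(annotations)) {
    annotations <- data.frame(sample = integer(0), symbol = character(0),
                              stringsAsFactors = FALSE)
  }
  annotations <- validate_annotations(annotations, length(samples))
  structure(
    list(samples = as.numeric(samples), fs = as.numeric(fs),
         record_id = as.character(record_id), annotations = annotations),
    class = "ecg_record")
}

validate_annotations <- function(ann, n) {
  if (!is.data.frame(ann) || !all(c("sample", "symbol") %in% names(ann)))
    stop_invalid("annotations must be a data.frame with columns `sample` and `symbol`")
  ann <- data.frame(sample = as.integer(ann$sample),
                    symbol = as.character(ann$symbol),
                    stringsAsFactors = FALSE)
  if (nrow(ann)) {
    if (anyNA(ann$sample) || any(ann$sample < 1L) || any(ann$sample > n))
      stop_invalid("annotation sample indices must lie in [1, %d]", n)
    if (is.unsorted(ann$sample, strictly = TRUE))
      stop_invalid("annotation sample indices must be strictly increasing")
    if (any(!nzchar(ann$symbol)))
      stop_invalid("annotation symbols must be non-empty")
  }
  rownames(ann) <- NULL
  ann
}

#' @export
print.ecg_record <- function(x, ...) {
  dur <- length(x$samples) / x$fs
  cat(sprintf("<ecg_record '%s'>  %d samples @ %g Hz (%.1f s), %d annotations\n",
              x$record_id, length(x$samples), x$fs, dur, nrow(x$annotations)))
  if (nrow(x$annotations)) {
    tab <- table(x$annotations$symbol)
    cat("  beats:", paste(sprintf("%s=%d", names(tab), tab), collapse = " "), "\n")
  }
  invisible(x)
}

#' Restrict a record's annotations to a set of beat symbols
#'
#' Samples are untouched; only annotations whose symbol is in `keep`
#' survive. This is how the four-class MIT-BIH problem (N, L, R, V) is
#' carved out of a fully annotated record.
#'
#' @param record an [ecg_record()].
#' @param keep non-empty character vector of symbols to retain.
#' @return the record with filtered annotations.
#' @export
filter_annotations <- function(record, keep) {
  stopifnot(inherits(record, "ecg_record"))
  if (length(keep) < 1L) stop_invalid("`keep` must be non-empty")
  record$annotations <- record$annotations[record$annotations$symbol %in% keep, ,
                                           drop = FALSE]
  rownames(record$annotations) <- NULL
  record
}
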