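#' Synthesize a labelled beat set
#'
#' Convenience generator for classifier experiments: one annotated record
#' per requested beat class (using the matching rhythm preset at sinus
#' rates), optional Gaussian noise, segmentation at the ground-truth
#' R-peaks, and trimming to `n_per_class` beats per class.
#'
#' @param n_per_class beats retained per class.
#' @param classes beat symbols; any of "N", "L", "R", "V", "A", "F".
#' @param noise_sd Gaussian noise s.d. in mV (0 = clean).
#' @param fs sampling rate (Hz).
#' @param seed integer seed.
#' @param records_per_class how many independent records to spread each
#'   class's beats over (>= 2 enables record-holdout splits).
#' @return a `beat_set` with `n_per_class * length(classes)` beats.
#' @export
synthetic_beat_set <- function(n_per_class = 600,
                               classes = c("N", "L", "R", "V"),
                               noise_sd = 0.05, fs = 360, seed = 1L,
                               records_per_class = 1L) {
  preset_of <- c(N = "normal", L = "lbbb", R = "rbbb", V = "pvc",
                 A = "apb", F = "fusion")
  bad <- setdiff(classes, names(preset_of))
  if (length(bad)) stop_invalid("no preset for class(es): %s",
                                paste(bad, collapse = ", "))
  sets <- list()
  for (ci in seq_along(classes)) {
    cl <- classes[ci]
    per_rec <- ceiling(n_per_class / records_per_class)
    for (r in seq_len(records_per_class)) {
      dur <- per_rec / 1.1 + 5  # sinus presets average ~80 BPM
      rec_seed <- seed * 1000L + ci * 10L + r
      rec <- simulate_ecg(preset_of[[cl]], duration = dur, fs = fs,
                          noise = noise_spec(gaussian_sd = noise_sd,
                                             seed = rec_seed),
                          seed = rec_seed)
      rec$record_id <- sprintf("%s-%s-%d", rec$record_id, cl, r)
      bs <- segment_beats(rec)
      keep <- seq_len(min(per_rec, nrow(bs$x)))
      bs$x <- bs$x[keep, , drop = FALSE]
      for (f in c("labels", "r_indices", "rr_prev", "rr_next", "record_id"))
        bs[[f]] <- bs[[f]][keep]
      sets[[length(sets) + 1L]] <- bs
    }
  }
  out <- bind_beat_sets(sets)
  # trim classes that overshot n_per_class
  keep <- unlist(lapply(classes, function(cl)
    head(which(out$labels == cl), n_per_class)))
  keep <- sort(keep)
  out$x <- out$x[keep, , drop = FALSE]
  for (f in c("labels", "r_indices", "rr_prev", "rr_next", "record_id"))
    out[[f]] <- out[[f]][keep]
  out
}
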