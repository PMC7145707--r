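#' Read and write trace sets as TSV
#'
#' Traces travel as long-format TSV with columns `molecule_id`, `frame`,
#' `I_D`, `I_A` (counts/frame, background-corrected). Numbers are written
#' with full precision so that a write/read round trip is lossless and a
#' re-run with the same seed is byte-identical.
#'
#' @param traces A [trace_set()].
#' @param path Output TSV path.
#' @return `path` invisibly (write) or a `trace_set` (read).
#' @export
write_traces <- function(traces, path) {
  stopifnot(inherits(traces, "trace_set"))
  n <- nrow(traces$i_d); tt <- ncol(traces$i_d)
  df <- data.frame(molecule_id = rep(traces$molecule_id, each = tt),
                   frame = rep(seq_len(tt), n),
                   I_D = as.vector(t(traces$i_d)),
                   I_A = as.vector(t(traces$i_a)))
  write_tsv(df, path)
  invisible(path)
}

#' @rdname write_traces
#' @param frame_interval Frame time in seconds (TSV carries no timing).
#' @export
read_traces <- function(path, frame_interval = 0.1) {
  df <- utils::read.delim(path, check.names = FALSE)
  need <- c("molecule_id", "frame", "I_D", "I_A")
  if (!all(need %in% names(df)))
    stop("trace TSV must have columns molecule_id, frame, I_D, I_A")
  ids <- unique(df$molecule_id)
  frames <- sort(unique(df$frame))
  df <- df[order(match(df$molecule_id, ids), df$frame), ]
  tt <- length(frames)
  if (nrow(df) != length(ids) * tt)
    stop("trace TSV is ragged: all molecules must share the frame grid")
  i_d <- matrix(df$I_D, length(ids), tt, byrow = TRUE)
  i_a <- matrix(df$I_A, length(ids), tt, byrow = TRUE)
  trace_set(i_d, i_a, frame_interval, molecule_id = ids,
            provenance = basename(path))
}

#' Write ground truth as plain-text tables
#'
#' Writes the per-molecule table (`<stem>_molecules.tsv`) and the per-frame
#' state table (`<stem>_states.tsv`, columns `molecule_id`, `frame`,
#' `state` with 1 = unwound, and `e_true`).
#'
#' @param truth A `ground_truth`.
#' @param stem Output path stem.
#' @return The two paths, invisibly.
#' @export
write_ground_truth <- function(truth, stem) {
  stopifnot(inherits(truth, "ground_truth"))
  p1 <- paste0(stem, "_molecules.tsv")
  p2 <- paste0(stem, "_states.tsv")
  write_tsv(truth$molecules, p1)
  n <- nrow(truth$states); tt <- ncol(truth$states)
  df <- data.frame(molecule_id = rep(truth$molecules$molecule_id, each = tt),
                   frame = rep(seq_len(tt), n),
                   state = as.vector(t(truth$states)),
                   e_true = as.vector(t(truth$e_true)))
  write_tsv(df, p2)
  invisible(c(p1, p2))
}

#' Write a spot table as TSV
#' @param spots A `spot_table`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_spots <- function(spots, path) {
  stopifnot(inherits(spots, "spot_table"))
  write_tsv(as.data.frame(spots), path)
  invisible(path)
}

#' Write an estimates table as TSV
#'
#' One row per fitted condition: `label`, `grna`, `n_pd`, `n_molecules`,
#' `f_unwound`, `sd`, `mean_e_low`, `mean_e_high`.
#'
#' @param fits A list of [fit_unwinding()] objects.
#' @param n_pd Integer vector of mismatch counts parallel to `fits`.
#' @param path Output TSV path.
#' @param grna gRNA design labels parallel to `fits` (recycled).
#' @return The table, invisibly.
#' @export
write_estimates <- function(fits, n_pd, path, grna = "X20") {
  stopifnot(all(vapply(fits, inherits, TRUE, "unwind_fit")))
  df <- data.frame(
    label = vapply(fits, function(f) if (is.null(f$label)) "" else f$label, ""),
    grna = rep_len(grna, length(fits)),
    n_pd = as.integer(n_pd),
    n_molecules = vapply(fits, function(f) f$n_molecules, 0L),
    f_unwound = vapply(fits, function(f) f$f_unwound, 0),
    sd = vapply(fits, function(f) f$sd, 0),
    mean_e_low = vapply(fits, function(f) f$mean_e_low, 0),
    mean_e_high = vapply(fits, function(f) f$mean_e_high, 0))
  write_tsv(df, path)
  invisible(df)
}

#' Read an estimates table written by [write_estimates()]
#' @param path TSV path.
#' @return A data frame.
#' @export
read_estimates <- function(path) {
  utils::read.delim(path, check.names = FALSE)
}

# Deterministic TSV writer: fixed 15-significant-digit formatting, no
# quoting, no row names. Byte-identical across runs for identical input.
write_tsv <- function(df, path) {
  for (j in seq_along(df)) {
    if (is.double(df[[j]])) {
      x <- df[[j]]
      s <- vapply(x, function(v)
        if (is.na(v)) "NA" else sprintf("%.15g", v), "")
      df[[j]] <- s
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}
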