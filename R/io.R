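#' Write and read trial tables as CSV
#'
#' Trial tables use the columns `session_id`, `trial_idx`, `image_id`,
#' `presentation`, `nback`, `off_nback`, `choice`, `correct`, `rt_ms`.
#'
#' @param trials Trial tibble.
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_trials_csv <- function(trials, path) {
  utils::write.csv(tibble::as_tibble(trials), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials_csv
#' @export
read_trials_csv <- function(path) {
  d <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  d$off_nback <- as.logical(d$off_nback)
  d
}

#' Write and read session spike counts
#'
#' Counts are stored as a plain CSV matrix (units x trials) with a JSON
#' sidecar holding the analysis window and trial-column mapping.
#'
#' @param session A `session_data`.
#' @param counts_path CSV path for the counts matrix.
#' @param meta_path JSON sidecar path (default: `counts_path` +
#'   `".meta.json"`).
#' @return `counts_path`, invisibly.
#' @export
write_session_counts <- function(session, counts_path,
                                 meta_path = paste0(counts_path,
                                                    ".meta.json")) {
  utils::write.table(session$counts, counts_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(window_ms = session$window,
         trial_idx = session$trials$trial_idx,
         session_id = session$trials$session_id[1]),
    meta_path, auto_unbox = TRUE)
  invisible(counts_path)
}

#' @rdname write_session_counts
#' @param trials Trial tibble matching the stored counts columns.
#' @export
read_session_counts <- function(counts_path, trials,
                                meta_path = paste0(counts_path,
                                                   ".meta.json")) {
  counts <- as.matrix(utils::read.table(counts_path, sep = ","))
  dimnames(counts) <- NULL
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  structure(
    list(trials = tibble::as_tibble(trials), counts = counts,
         expected = NULL, window = meta$window_ms,
         memory_units = NULL, config = NULL),
    class = "session_data")
}

#' Serialize a decoder model to JSON
#'
#' @param model A `decoder_model`.
#' @param path JSON path.
#' @return `path`, invisibly.
#' @export
write_decoder_json <- function(model, path) {
  jsonlite::write_json(
    list(kind = model$kind, w = model$w, b = model$b,
         selected = model$selected, N = model$N),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_decoder_json
#' @export
read_decoder_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  new_decoder_model(j$w, j$b, j$kind, j$selected, j$N)
}
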