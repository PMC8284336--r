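#' Write spike trains to the interchange CSV format
#'
#' Two columns: \code{cell_id}, \code{spike_time_s} (seconds, 0-based from
#' recording start), one row per spike, cells concatenated.
#'
#' @param trains a \linkS4class{SpikeTrain} or list of them.
#' @param path output file.
#' @return The path, invisibly.
#' @export
writeSpikesCSV <- function(trains, path) {
  if (methods::is(trains, "SpikeTrain")) trains <- list(trains)
  df <- do.call(rbind, lapply(trains, function(tr)
    if (nSpikes(tr))
      data.frame(cell_id = cellId(tr), spike_time_s = spikeTimes(tr))
    else NULL))
  if (is.null(df))
    df <- data.frame(cell_id = character(), spike_time_s = numeric())
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read spike trains from the interchange CSV format
#'
#' @param path CSV file with columns \code{cell_id}, \code{spike_time_s}.
#' @param duration recording duration in seconds (shared by all cells).
#' @return Named list of \linkS4class{SpikeTrain}.
#' @export
readSpikesCSV <- function(path, duration) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  ids <- unique(df$cell_id)
  out <- lapply(ids, function(id)
    spikeTrain(df$spike_time_s[df$cell_id == id], duration, id))
  names(out) <- ids
  out
}
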