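#' Time-series observation data
#'
#' Container for M observed trajectories, each a set of strictly increasing
#' timepoints with an observation matrix (one column per observed channel).
#'
#' @param times list of numeric vectors (one per trajectory), each strictly
#'   increasing.
#' @param y list of numeric matrices, \code{length(times[[i]]) x n_y}.
#' @return an object of class \code{lfns_timeseries}.
#' @export
timeseries_data <- function(times, y) {
  if (length(times) != length(y)) stop("times and y must have equal length")
  if (length(times) == 0) stop("need at least one trajectory")
  y <- lapply(y, function(m) if (is.matrix(m)) m else matrix(m, ncol = 1))
  n_y <- ncol(y[[1]])
  for (i in seq_along(times)) {
    t <- times[[i]]
    if (length(t) > 1 && any(diff(t) <= 0))
      stop(sprintf("timepoints of trajectory %d are not strictly increasing", i))
    if (nrow(y[[i]]) != length(t))
      stop(sprintf("trajectory %d: observation rows do not match timepoints", i))
    if (ncol(y[[i]]) != n_y)
      stop("all trajectories must share the same number of channels")
  }
  structure(list(times = times, y = y, M = length(times), n_y = n_y),
            class = "lfns_timeseries")
}

#' @export
print.lfns_timeseries <- function(x, ...) {
  cat(sprintf("Time-series data: %d trajectories, %d channel(s), %s timepoints each\n",
              x$M, x$n_y,
              paste(unique(vapply(x$times, length, integer(1))), collapse = "/")))
  invisible(x)
}

#' Read / write trajectory data
#'
#' CSV format with header \code{trajectory,time,y1..yK}; rows grouped by
#' trajectory id and sorted by time. Floats are written with 17 significant
#' digits so a write/read round trip is lossless.
#'
#' @param path file path.
#' @return \code{read_timeseries} returns an \code{lfns_timeseries}.
#' @export
read_timeseries <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (ncol(df) < 3 || names(df)[1] != "trajectory" || names(df)[2] != "time")
    stop("expected CSV header 'trajectory,time,y1..yK'")
  ids <- unique(df$trajectory)
  times <- vector("list", length(ids)); y <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    sub <- df[df$trajectory == ids[i], , drop = FALSE]
    sub <- sub[order(sub$time), , drop = FALSE]
    if (anyDuplicated(sub$time))
      stop(sprintf("duplicated timepoint in trajectory '%s'", ids[i]))
    times[[i]] <- sub$time
    y[[i]] <- as.matrix(sub[, -(1:2), drop = FALSE])
    dimnames(y[[i]]) <- NULL
  }
  timeseries_data(times, y)
}

#' @rdname read_timeseries
#' @param data an \code{lfns_timeseries}.
#' @export
write_timeseries <- function(data, path) {
  stopifnot(inherits(data, "lfns_timeseries"))
  rows <- lapply(seq_len(data$M), function(i) {
    df <- data.frame(trajectory = i, time = data$times[[i]])
    cbind(df, as.data.frame(data$y[[i]]))
  })
  df <- do.call(rbind, rows)
  names(df) <- c("trajectory", "time", paste0("y", seq_len(data$n_y)))
  fmt <- function(v) if (is.numeric(v)) sprintf("%.17g", v) else v
  df[] <- lapply(df, fmt)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
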