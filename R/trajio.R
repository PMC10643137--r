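#' Construct a single-particle trajectory
#'
#' A trajectory is an ordered run of localizations of one molecule recorded
#' at a uniform frame interval. Frames must be strictly consecutive (the
#' linker does no gap closing by default, so a detection gap starts a new
#' trajectory).
#'
#' @param id trajectory identifier (coerced to character).
#' @param dt frame interval in seconds.
#' @param frames integer vector of frame indices, strictly increasing and
#'   consecutive.
#' @param pos numeric matrix of positions in micrometres, one row per frame,
#'   2 or 3 columns (x, y\[, z\]).
#' @param intensity optional numeric vector of per-frame intensities.
#' @return An object of class `nd_trajectory`: a list with elements `id`,
#'   `dt`, `dim`, `frames`, `pos` and optionally `intensity`.
#' @examples
#' tr <- trajectory("t1", dt = 0.02, frames = 0:4,
#'                  pos = cbind(x = 1:5 / 10, y = 0, z = 0))
#' n_frames(tr)
#' @export
trajectory <- function(id, dt, frames, pos, intensity = NULL) {
  pos <- as.matrix(pos)
  storage.mode(pos) <- "double"
  frames <- as.integer(frames)
  if (length(frames) != nrow(pos)) stop("frames and pos disagree in length")
  if (nrow(pos) < 2L) stop("a trajectory needs at least 2 points")
  if (!ncol(pos) %in% c(2L, 3L)) stop("pos must have 2 or 3 columns")
  if (any(!is.finite(pos))) stop("non-finite coordinates in trajectory")
  if (any(frames < 0L)) stop("negative frame index")
  if (any(diff(frames) != 1L)) stop("frames must be consecutive")
  colnames(pos) <- c("x", "y", "z")[seq_len(ncol(pos))]
  out <- list(id = as.character(id), dt = as.numeric(dt),
              dim = ncol(pos), frames = frames, pos = pos)
  if (!is.null(intensity)) out$intensity <- as.numeric(intensity)
  class(out) <- "nd_trajectory"
  out
}

#' @rdname trajectory
#' @param x an `nd_trajectory`.
#' @export
n_frames <- function(x) length(x$frames)

#' @export
print.nd_trajectory <- function(x, ...) {
  cat(sprintf("<nd_trajectory '%s'> %d frames, %dD, dt = %g s, duration %g s\n",
              x$id, n_frames(x), x$dim, x$dt, (n_frames(x) - 1) * x$dt))
  invisible(x)
}

#' Duration of a trajectory in seconds
#' @param x an `nd_trajectory`.
#' @return `(n_frames - 1) * dt`.
#' @export
traj_duration <- function(x) (n_frames(x) - 1) * x$dt

#' Link per-frame localizations into trajectories
#'
#' Connects localizations in subsequent frames when they lie within
#' `max_jump` of each other (Euclidean distance over all available axes),
#' the rule used for single-molecule tracking at 800 nm (20 ms exposures)
#' or 500 nm (500 ms exposures). Within each consecutive frame pair,
#' candidate matches are resolved greedily in ascending distance order so
#' each track end and each new localization is used at most once; in the
#' sparse regime this equals the globally optimal assignment.
#'
#' @param locs data frame of localizations with columns `frame`, `x`, `y`,
#'   optionally `z` and `intensity`. Rows with non-finite coordinates are
#'   rejected with a warning.
#' @param max_jump maximum allowed displacement between consecutive frames
#'   (micrometres).
#' @param dt frame interval in seconds, stored on the output trajectories.
#' @param gap number of missed frames tolerated between linked
#'   localizations; the default 0 links subsequent frames only.
#' @param min_length minimum number of points for a trajectory to be kept
#'   (shorter fragments are discarded); default 2.
#' @return A list of [trajectory()] objects.
#' @examples
#' locs <- data.frame(frame = c(0, 1), x = c(0, 0.5), y = 0, z = 0)
#' link_localizations(locs, max_jump = 0.8, dt = 0.02)
#' @export
link_localizations <- function(locs, max_jump, dt, gap = 0L, min_length = 2L) {
  stopifnot(max_jump > 0, dt > 0, gap >= 0)
  if (nrow(locs) == 0L) return(list())
  req <- c("frame", "x", "y")
  miss <- setdiff(req, names(locs))
  if (length(miss)) stop("missing localization columns: ", paste(miss, collapse = ", "))
  axes <- intersect(c("x", "y", "z"), names(locs))
  ok <- Reduce(`&`, lapply(locs[axes], is.finite)) & is.finite(locs$frame)
  if (any(!ok)) {
    warning(sprintf("rejected %d localization(s) with non-finite coordinates", sum(!ok)))
    locs <- locs[ok, , drop = FALSE]
  }
  if (nrow(locs) == 0L) return(list())
  locs <- locs[order(locs$frame), , drop = FALSE]
  has_int <- "intensity" %in% names(locs)

  P <- as.matrix(locs[axes])
  fr <- as.integer(locs$frame)
  idx_by_frame <- split(seq_len(nrow(locs)), fr)
  frames_seen <- as.integer(names(idx_by_frame))

  # open tracks: list of integer vectors of row indices
  open <- list()
  open_last_frame <- integer(0)
  closed <- list()

  for (f in frames_seen) {
    cur <- idx_by_frame[[as.character(f)]]
    linkable <- which(open_last_frame >= f - 1L - gap & open_last_frame < f)
    assigned_cur <- rep(FALSE, length(cur))
    assigned_trk <- rep(FALSE, length(linkable))
    if (length(linkable) && length(cur)) {
      ends <- vapply(open[linkable], function(v) v[length(v)], 0L)
      D2 <- outer(rowSums(P[ends, , drop = FALSE]^2), rowSums(P[cur, , drop = FALSE]^2), "+") -
        2 * P[ends, , drop = FALSE] %*% t(P[cur, , drop = FALSE])
      D <- sqrt(pmax(D2, 0))
      cand <- which(D <= max_jump, arr.ind = TRUE)
      if (nrow(cand)) {
        cand <- cand[order(D[cand]), , drop = FALSE]
        for (r in seq_len(nrow(cand))) {
          i <- cand[r, 1L]; j <- cand[r, 2L]
          if (!assigned_trk[i] && !assigned_cur[j]) {
            ti <- linkable[i]
            open[[ti]] <- c(open[[ti]], cur[j])
            open_last_frame[ti] <- f
            assigned_trk[i] <- TRUE
            assigned_cur[j] <- TRUE
          }
        }
      }
    }
    # retire tracks that can no longer be extended
    stale <- which(open_last_frame < f - gap)
    if (length(stale)) {
      closed <- c(closed, open[stale])
      open <- open[-stale]
      open_last_frame <- open_last_frame[-stale]
    }
    # unmatched localizations seed new tracks
    new <- cur[!assigned_cur]
    if (length(new)) {
      open <- c(open, as.list(new))
      open_last_frame <- c(open_last_frame, rep(f, length(new)))
    }
  }
  closed <- c(closed, open)
  closed <- Filter(function(v) length(v) >= min_length, closed)
  if (!length(closed)) return(list())

  out <- vector("list", length(closed))
  for (k in seq_along(closed)) {
    v <- closed[[k]]
    if (gap > 0L && any(diff(fr[v]) != 1L)) {
      # with gap tolerance, re-split runs so stored trajectories stay
      # strictly consecutive in frame index
      splits <- cumsum(c(0L, diff(fr[v]) != 1L))
      pieces <- split(v, splits)
      pieces <- Filter(function(p) length(p) >= min_length, pieces)
      out[[k]] <- lapply(pieces, function(p) {
        trajectory(sprintf("traj%04d", k), dt, fr[p], P[p, , drop = FALSE],
                   intensity = if (has_int) locs$intensity[p])
      })
    } else {
      out[[k]] <- list(trajectory(sprintf("traj%04d", k), dt, fr[v], P[v, , drop = FALSE],
                                  intensity = if (has_int) locs$intensity[v]))
    }
  }
  out <- unlist(out, recursive = FALSE, use.names = FALSE)
  for (k in seq_along(out)) out[[k]]$id <- sprintf("traj%04d", k)
  out
}

#' Read a localization table
#'
#' Reads a delimited text file with named columns `frame`, `x`, `y`,
#' optionally `z` and `intensity`. Records with non-finite coordinates are
#' rejected (count kept in the `n_rejected` attribute).
#'
#' @param path file path.
#' @param units `"um"` (default) or `"nm"`; nm coordinates are converted to
#'   micrometres on read.
#' @param sep field separator (default tab).
#' @return A data frame of valid localizations with attribute `n_rejected`.
#' @export
read_localizations <- function(path, units = c("um", "nm"), sep = "\t") {
  units <- match.arg(units)
  df <- read.delim(path, sep = sep, header = TRUE, check.names = FALSE)
  req <- c("frame", "x", "y")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("localization file is missing column(s): ", paste(miss, collapse = ", "))
  axes <- intersect(c("x", "y", "z"), names(df))
  keep <- Reduce(`&`, lapply(df[axes], function(v) is.finite(as.numeric(v)))) &
    is.finite(as.numeric(df$frame))
  n_rej <- sum(!keep)
  if (n_rej) warning(sprintf("rejected %d record(s) with non-finite values", n_rej))
  df <- df[keep, , drop = FALSE]
  for (a in axes) df[[a]] <- as.numeric(df[[a]]) * if (units == "nm") 1e-3 else 1
  df$frame <- as.integer(df$frame)
  attr(df, "n_rejected") <- n_rej
  df
}

#' Write and read trajectory tables
#'
#' Trajectories are stored as tab-separated text with columns
#' `traj_id, frame, x, y[, z][, intensity], dt`. Values are written with 17
#' significant digits so that `read_trajectories(write_trajectories(x))`
#' reproduces the doubles bit-exactly.
#'
#' @param trajs list of [trajectory()] objects.
#' @param path output file path.
#' @return `write_trajectories` returns `path` invisibly;
#'   `read_trajectories` returns a list of trajectories.
#' @export
write_trajectories <- function(trajs, path) {
  stopifnot(length(trajs) > 0)
  dims <- vapply(trajs, function(t) t$dim, 0L)
  if (length(unique(dims)) != 1L) stop("mixed 2D/3D trajectories in one file")
  has_int <- all(vapply(trajs, function(t) !is.null(t$intensity), TRUE))
  rows <- lapply(trajs, function(t) {
    d <- data.frame(traj_id = t$id, frame = t$frames,
                    x = t$pos[, 1], y = t$pos[, 2],
                    stringsAsFactors = FALSE)
    if (t$dim == 3L) d$z <- t$pos[, 3]
    if (has_int) d$intensity <- t$intensity
    d$dt <- t$dt
    d
  })
  df <- do.call(rbind, rows)
  num <- vapply(df, is.numeric, TRUE) & names(df) != "frame"
  out <- df
  for (j in which(num)) out[[j]] <- sprintf("%.17g", df[[j]])
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectories
#' @export
read_trajectories <- function(path) {
  df <- read.delim(path, sep = "\t", header = TRUE, check.names = FALSE,
                   colClasses = "character")
  req <- c("traj_id", "frame", "x", "y", "dt")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("trajectory file is missing column(s): ", paste(miss, collapse = ", "))
  axes <- intersect(c("x", "y", "z"), names(df))
  has_z <- "z" %in% axes
  has_int <- "intensity" %in% names(df)
  if (has_z) {
    zval <- as.numeric(df$z)
    if (any(is.na(zval)) && !all(is.na(zval))) stop("mixed 2D/3D rows within one file")
    if (all(is.na(zval))) { has_z <- FALSE; axes <- setdiff(axes, "z") }
  }
  ids <- df$traj_id
  out <- lapply(split(seq_len(nrow(df)), factor(ids, levels = unique(ids))), function(i) {
    pos <- vapply(axes, function(a) as.numeric(df[[a]][i]), numeric(length(i)))
    trajectory(ids[i[1]], dt = as.numeric(df$dt[i[1]]),
               frames = as.integer(df$frame[i]),
               pos = matrix(pos, ncol = length(axes), dimnames = list(NULL, axes)),
               intensity = if (has_int) as.numeric(df$intensity[i]))
  })
  names(out) <- NULL
  out
}
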