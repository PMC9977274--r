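#' Behavior profiles for the tracking simulator
#'
#' A profile fixes one mouse's exploration dynamics. The per-step probability
#' of moving to a neighbouring antenna (rather than re-triggering the current
#' one) is \code{plogis(theta0 * exp(-decay * night))}: mice with
#' \code{decay = 0} keep a constant exploration breadth ("flat" roamers),
#' mice with \code{decay > 0} habituate and their territorial coverage — and
#' hence roaming entropy — declines over nights ("down" roamers).
#'
#' @param n_flat,n_down number of flat (decay = 0) and habituating mice.
#' @param theta0 baseline exploration breadth (> 0); larger values mean more
#'   movement between antennae per contact.
#' @param decay per-night habituation rate for the down class (>= 0).
#' @param events_per_night expected antenna contacts per mouse per night.
#' @return data.frame with columns \code{mouse_id}, \code{theta0},
#'   \code{decay}, \code{events_per_night}, \code{class_label}.
#' @examples
#' behavior_profiles(n_flat = 3, n_down = 3)
#' @export
behavior_profiles <- function(n_flat, n_down, theta0 = 2, decay = 0.05,
                              events_per_night = 200) {
  if (events_per_night <= 0) stop("events_per_night must be positive")
  if (theta0 <= 0) stop("theta0 must be positive")
  if (decay < 0) stop("decay must be nonnegative")
  n <- n_flat + n_down
  if (n < 1) stop("need at least one mouse")
  data.frame(
    mouse_id = sprintf("M%03d", seq_len(n)),
    theta0 = theta0,
    decay = rep(c(0, decay), c(n_flat, n_down)),
    events_per_night = events_per_night,
    class_label = rep(c("flat", "down"), c(n_flat, n_down)),
    stringsAsFactors = FALSE
  )
}

validate_profiles <- function(profiles) {
  need <- c("mouse_id", "theta0", "decay", "events_per_night")
  if (!all(need %in% names(profiles))) {
    stop("profiles need columns ", paste(need, collapse = ", "))
  }
  if (nrow(profiles) == 0) stop("profiles must be non-empty")
  if (any(profiles$events_per_night <= 0)) {
    stop("events_per_night must be positive for every mouse")
  }
  if (any(profiles$theta0 <= 0)) stop("theta0 must be positive")
  if (any(profiles$decay < 0)) stop("decay must be nonnegative")
  if (anyDuplicated(profiles$mouse_id)) stop("mouse ids must be unique")
  invisible(profiles)
}

#' Simulate an RFID antenna-contact event stream
#'
#' Each mouse performs a lazy random walk on the antenna graph during every
#' dark phase. Per night the contact count is Poisson with the profile's
#' rate; at each contact the mouse either re-triggers its current antenna or
#' steps to a uniformly chosen neighbour, with move probability
#' \code{plogis(theta0 * exp(-decay * (night - 1)))}. Timestamps are sorted
#' uniform draws inside the dark window, which may wrap midnight; nights are
#' indexed by the date on which the dark phase starts.
#'
#' @param topology a \code{\link{cage_topology}}.
#' @param profiles data.frame as from \code{\link{behavior_profiles}}.
#' @param n_nights number of nights to simulate (>= 1).
#' @param seed integer seed; identical seeds give identical streams.
#' @param start_date first night's date (the dark phase starting that
#'   evening), as \code{Date} or string.
#' @param dark_start,dark_end clock times "HH:MM" delimiting the dark phase
#'   (default 18:00 to 06:00, a 12-h lights-off window wrapping midnight).
#' @return data.frame with columns \code{datetime} (POSIXct, UTC),
#'   \code{antenna}, \code{mouse}, sorted by time.
#' @examples
#' topo <- cage_topology(9)
#' ev <- simulate_tracking(topo, behavior_profiles(2, 2), n_nights = 3,
#'                         seed = 1)
#' head(ev)
#' @export
simulate_tracking <- function(topology, profiles, n_nights, seed,
                              start_date = "2020-01-01",
                              dark_start = "18:00", dark_end = "06:00") {
  validate_topology(topology)
  validate_profiles(profiles)
  if (n_nights < 1) stop("n_nights must be >= 1")
  win <- parse_clock_window(dark_start, dark_end)
  g <- topology_graph(topology)
  # neighbour lookup in antenna_ids order
  nbr <- lapply(topology$antenna_ids, function(a) {
    igraph::neighbors(g, a)$name
  })
  names(nbr) <- topology$antenna_ids
  start_date <- as.Date(start_date)

  out <- local_seed(seed, {
    rows <- vector("list", n_nights * nrow(profiles))
    ix <- 0L
    for (night in seq_len(n_nights)) {
      night_date <- start_date + (night - 1)
      t0 <- as.POSIXct(paste(night_date, dark_start), tz = "UTC")
      dur <- win$length_sec
      for (m in seq_len(nrow(profiles))) {
        pr <- profiles[m, ]
        n_ev <- stats::rpois(1, pr$events_per_night)
        if (n_ev == 0) next
        p_move <- stats::plogis(pr$theta0 * exp(-pr$decay * (night - 1)))
        cur <- sample(topology$antenna_ids, 1)
        path <- character(n_ev)
        moves <- stats::runif(n_ev) < p_move
        for (e in seq_len(n_ev)) {
          if (moves[e]) {
            nb <- nbr[[cur]]
            cur <- nb[sample.int(length(nb), 1)]
          }
          path[e] <- cur
        }
        ts <- t0 + sort(stats::runif(n_ev, 0, dur))
        ix <- ix + 1L
        rows[[ix]] <- data.frame(
          datetime = ts, antenna = path, mouse = pr$mouse_id,
          stringsAsFactors = FALSE
        )
      }
    }
    do.call(rbind, rows[seq_len(ix)])
  })
  out <- out[order(out$datetime, out$mouse, out$antenna), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write / read an event-log CSV
#'
#' Columns: \code{datetime} (ISO-8601, UTC), \code{antenna}, \code{mouse}.
#'
#' @param events event data.frame as produced by
#'   \code{\link{simulate_tracking}}.
#' @param path file path.
#' @export
write_events <- function(events, path) {
  out <- data.frame(
    datetime = format(events$datetime, "%Y-%m-%dT%H:%M:%OS3", tz = "UTC"),
    antenna = events$antenna,
    mouse = events$mouse
  )
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Parse an RFID event-log CSV
#'
#' Reads, validates and time-sorts an antenna-contact log. Rows whose
#' antenna id is absent from \code{topology} (if given) are counted and
#' either kept or dropped.
#'
#' @param path event log CSV with header \code{datetime,antenna,mouse}.
#' @param topology optional \code{\link{cage_topology}} used to vet antenna
#'   ids.
#' @param unknown_antennae policy for ids not in the topology: \code{"keep"}
#'   or \code{"drop"}; either way a warning reports the count.
#' @return sorted event data.frame (\code{datetime}, \code{antenna},
#'   \code{mouse}).
#' @export
parse_events <- function(path, topology = NULL,
                         unknown_antennae = c("keep", "drop")) {
  unknown_antennae <- match.arg(unknown_antennae)
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("datetime", "antenna", "mouse") %in% names(df))) {
    stop("event log needs columns datetime, antenna, mouse")
  }
  if (nrow(df) == 0) stop("event log is empty: ", path)
  ts <- as.POSIXct(strptime(df$datetime, "%Y-%m-%dT%H:%M:%OS", tz = "UTC"))
  retry <- is.na(ts)
  if (any(retry)) {
    ts[retry] <- as.POSIXct(strptime(df$datetime[retry],
                                     "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  }
  bad <- which(is.na(ts))
  if (length(bad)) {
    stop("malformed timestamp at data line ", bad[1], ": ", df$datetime[bad[1]])
  }
  ev <- data.frame(datetime = ts, antenna = df$antenna, mouse = df$mouse,
                   stringsAsFactors = FALSE)
  if (!is.null(topology)) {
    alien <- !(ev$antenna %in% topology$antenna_ids)
    if (any(alien)) {
      warning(sum(alien), " events reference antennae outside the topology (",
              unknown_antennae, ")")
      if (unknown_antennae == "drop") ev <- ev[!alien, , drop = FALSE]
    }
  }
  ev <- ev[order(ev$datetime, ev$mouse, ev$antenna), , drop = FALSE]
  rownames(ev) <- NULL
  ev
}

# --- clock-window helpers (shared with the roaming module) ------------------

parse_clock_time <- function(x) {
  m <- regmatches(x, regexec("^([0-9]{1,2}):([0-9]{2})$", x))[[1]]
  if (length(m) != 3) stop("clock time must be HH:MM, got ", x)
  h <- as.integer(m[2]); mi <- as.integer(m[3])
  if (h > 23 || mi > 59) stop("invalid clock time ", x)
  h * 3600 + mi * 60
}

parse_clock_window <- function(start, end) {
  s <- parse_clock_time(start)
  e <- parse_clock_time(end)
  len <- (e - s) %% 86400
  if (len == 0) stop("dark-phase window must have positive length")
  list(start_sec = s, end_sec = e, length_sec = len, wraps = e <= s)
}

# Evaluate expr under a temporary RNG state seeded with `seed`, restoring
# whatever global state existed before (no global RNG side effects).
local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
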