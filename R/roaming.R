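#' Restrict events to the dark phase and assign nights
#'
#' Nocturnal mice are only active during lights-off, so entropy is computed
#' from dark-phase contacts alone. The window is a clock interval that may
#' wrap midnight (default 18:00-06:00); events in the after-midnight arm are
#' assigned to the night that started the previous evening, so one "night"
#' is one contiguous dark period indexed by its start date.
#'
#' @param events event data.frame (\code{datetime}, \code{antenna},
#'   \code{mouse}).
#' @param dark_start,dark_end clock times "HH:MM"; equal times are rejected.
#' @return the retained events with an added \code{night} column
#'   (\code{Date} of the dark phase onset).
#' @examples
#' topo <- cage_topology(6)
#' ev <- simulate_tracking(topo, behavior_profiles(1, 1), 2, seed = 1)
#' nrow(dark_phase_filter(ev))
#' @export
dark_phase_filter <- function(events, dark_start = "18:00",
                              dark_end = "06:00") {
  win <- parse_clock_window(dark_start, dark_end)
  lt <- as.POSIXlt(events$datetime, tz = "UTC")
  sec <- lt$hour * 3600 + lt$min * 60 + lt$sec
  date <- as.Date(events$datetime, tz = "UTC")
  if (win$wraps) {
    keep <- sec >= win$start_sec | sec < win$end_sec
    night <- ifelse(sec >= win$start_sec, date, date - 1)
  } else {
    keep <- sec >= win$start_sec & sec < win$end_sec
    night <- date
  }
  out <- events[keep, , drop = FALSE]
  out$night <- as.Date(night[keep], origin = "1970-01-01")
  rownames(out) <- NULL
  out
}

#' Shannon roaming entropy of one nightly antenna-contact distribution
#'
#' RE = -sum_j p_j log(p_j) / log(k), where p_j is the fraction of the
#' night's contacts registered at antenna j and k is the total antenna
#' count. Zero-probability terms contribute 0; the log(k) normalizer makes
#' the value base-invariant and confines it to [0, 1] (0 = the whole night
#' at one antenna, 1 = uniform use of all k antennae). A night with zero
#' contacts yields NA — absence of data, not zero roaming.
#'
#' @param counts nonnegative per-antenna contact counts, length k.
#' @param k total antenna count (>= 2); defaults to \code{length(counts)}.
#' @return RE in [0, 1], or NA if all counts are zero.
#' @examples
#' roaming_entropy(c(2, 2, 0, 0))   # 0.5
#' roaming_entropy(rep(5, 8))       # 1
#' @export
roaming_entropy <- function(counts, k = length(counts)) {
  if (k < 2) stop("need at least 2 antennae (k >= 2)")
  if (length(counts) != k) stop("counts must have length k")
  if (any(counts < 0)) stop("counts must be nonnegative")
  tot <- sum(counts)
  if (tot == 0) return(NA_real_)
  p <- counts / tot
  p <- p[p > 0]
  -sum(p * log(p)) / log(k)
}

#' Mouse-by-night roaming entropy matrix from an event log
#'
#' Applies the dark-phase filter, tabulates per-mouse nightly contacts over
#' the topology's antennae, and evaluates \code{\link{roaming_entropy}} for
#' every mouse-night. Nights are the consecutive calendar sequence from the
#' first to the last observed dark-phase onset; mouse-nights without any
#' contact are NA.
#'
#' @param events event data.frame.
#' @param topology \code{\link{cage_topology}} supplying the antenna set and
#'   count k.
#' @param dark_start,dark_end dark-phase clock window.
#' @return numeric matrix, rows = mice (sorted ids), columns = nights
#'   ("night_1", ...), entries RE in [0, 1] or NA.
#' @export
re_matrix <- function(events, topology, dark_start = "18:00",
                      dark_end = "06:00") {
  validate_topology(topology)
  ev <- dark_phase_filter(events, dark_start, dark_end)
  if (nrow(ev) == 0) stop("no events fall inside the dark phase")
  ev <- ev[ev$antenna %in% topology$antenna_ids, , drop = FALSE]
  nights <- seq(min(ev$night), max(ev$night), by = 1)
  mice <- sort(unique(ev$mouse))
  k <- topology$k
  re <- matrix(NA_real_, length(mice), length(nights),
               dimnames = list(mice, paste0("night_", seq_along(nights))))
  ev$antenna <- factor(ev$antenna, levels = topology$antenna_ids)
  for (i in seq_along(mice)) {
    evm <- ev[ev$mouse == mice[i], , drop = FALSE]
    tab <- table(factor(match(evm$night, nights)), evm$antenna)
    for (r in rownames(tab)) {
      re[i, as.integer(r)] <- roaming_entropy(as.numeric(tab[r, ]), k)
    }
  }
  re
}

#' Aggregate nightly RE into consecutive time blocks
#'
#' The study design averages nightly entropy into four 21-night blocks
#' (T1-T4). Block b covers nights ((b-1)*block_length, b*block_length];
#' block means ignore missing nights, and a block with no data is NA.
#'
#' @param re mouse-by-night RE matrix from \code{\link{re_matrix}}.
#' @param block_length nights per block (default 21).
#' @param n_blocks number of blocks (default 4).
#' @return mouse-by-block matrix of mean RE, columns "T1".."Tn".
#' @export
block_means <- function(re, block_length = 21, n_blocks = 4) {
  need <- block_length * n_blocks
  if (ncol(re) < need) {
    stop("need at least ", need, " nights for ", n_blocks, " blocks of ",
         block_length, "; have ", ncol(re))
  }
  out <- matrix(NA_real_, nrow(re), n_blocks,
                dimnames = list(rownames(re), paste0("T", seq_len(n_blocks))))
  for (b in seq_len(n_blocks)) {
    cols <- ((b - 1) * block_length + 1):(b * block_length)
    out[, b] <- rowMeans(re[, cols, drop = FALSE], na.rm = TRUE)
  }
  out[is.nan(out)] <- NA_real_
  out
}

#' Per-mouse linear slope of RE across time blocks
#'
#' Ordinary least-squares slope b = sum((x - mean(x))(y - mean(y))) /
#' sum((x - mean(x))^2) with x the block indices 1..n_blocks and y the block
#' mean RE. Mice with fewer than two non-missing blocks get NA and are
#' flagged.
#'
#' @param blocks mouse-by-block matrix from \code{\link{block_means}}.
#' @return data.frame: \code{mouse_id}, \code{slope} (RE units per block),
#'   \code{intercept}, \code{n_blocks_used}.
#' @examples
#' trajectory_slopes(rbind(m1 = c(0.1, 0.2, 0.3, 0.4)))$slope  # 0.1
#' @export
trajectory_slopes <- function(blocks) {
  x_all <- seq_len(ncol(blocks))
  res <- lapply(seq_len(nrow(blocks)), function(i) {
    y <- blocks[i, ]
    ok <- !is.na(y)
    if (sum(ok) < 2) {
      return(data.frame(mouse_id = rownames(blocks)[i], slope = NA_real_,
                        intercept = NA_real_, n_blocks_used = sum(ok)))
    }
    x <- x_all[ok]; y <- y[ok]
    b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    data.frame(mouse_id = rownames(blocks)[i], slope = b,
               intercept = mean(y) - b * mean(x), n_blocks_used = sum(ok))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  if (any(is.na(out$slope))) {
    warning(sum(is.na(out$slope)),
            " mice have < 2 non-missing blocks; slope set to NA")
  }
  out
}

#' Choose the number of k-means clusters by silhouette analysis
#'
#' Clusters mice in block-mean space with k-means (multiple restarts under a
#' fixed seed) and picks the k in \code{k_range} maximizing the mean
#' silhouette width.
#'
#' @param blocks mouse-by-block matrix (rows with any NA are dropped).
#' @param k_range candidate cluster counts, within [2, n_mice - 1].
#' @param seed integer seed for the k-means restarts.
#' @param nstart k-means restarts per k.
#' @return list: \code{best_k}, \code{silhouette} (named mean widths per k),
#'   \code{cluster} (assignment at best_k).
#' @export
choose_k_clusters <- function(blocks, k_range = 2:6, seed = 1, nstart = 25) {
  X <- blocks[stats::complete.cases(blocks), , drop = FALSE]
  n <- nrow(X)
  if (n < 3) stop("need at least 3 mice with complete blocks")
  d <- stats::dist(X)
  if (all(d == 0)) {
    stop("all mice have identical block means; clustering is degenerate")
  }
  if (any(k_range < 2) || any(k_range > n - 1)) {
    stop("k_range must lie within [2, n_mice - 1]")
  }
  local_seed(seed, {
    sil <- vapply(k_range, function(k) {
      cl <- stats::kmeans(X, centers = k, nstart = nstart)
      mean(cluster::silhouette(cl$cluster, d)[, "sil_width"])
    }, numeric(1))
    names(sil) <- k_range
    best_k <- k_range[which.max(sil)]
    cl <- stats::kmeans(X, centers = best_k, nstart = nstart)
    list(best_k = best_k, silhouette = sil, cluster = cl$cluster)
  })
}

#' Stratify mice into flat and down roamers by RE slope
#'
#' Two modes. \code{"threshold"} applies slope cutpoints: slopes at or below
#' \code{down_cut} are "down" (habituating), slopes inside
#' \code{flat_range} are "flat" (sustained), slopes strictly between
#' \code{down_cut} and \code{flat_range[1]} are excluded as intermediate,
#' and slopes above \code{flat_range[2]} are excluded as positive. The
#' defaults reproduce the study's cutpoints (down <= -0.006, flat in
#' [-0.003, 0.004]). \code{"rank"} is an objective alternative: the
#' \code{group_size} most negative slopes are "down", the \code{group_size}
#' slopes nearest zero among the rest are "flat", everything else is
#' excluded; ties break by mouse id order.
#'
#' @param slopes data.frame from \code{\link{trajectory_slopes}} (columns
#'   \code{mouse_id}, \code{slope}).
#' @param group_size intended size of each subgroup (default 15).
#' @param mode \code{"threshold"} or \code{"rank"}.
#' @param down_cut,flat_range threshold-mode cutpoints (RE units per block).
#' @return object of class \code{stratification}: data.frame
#'   (\code{mouse_id}, \code{slope}, \code{label}) plus attributes
#'   \code{cutpoints}, \code{group_size}, \code{mode}.
#' @export
stratify_slopes <- function(slopes, group_size = 15,
                            mode = c("threshold", "rank"),
                            down_cut = -0.006,
                            flat_range = c(-0.003, 0.004)) {
  mode <- match.arg(mode)
  ok <- is.finite(slopes$slope)
  if (sum(ok) < 2 * group_size) {
    stop("need at least ", 2 * group_size, " mice with finite slopes")
  }
  s <- slopes[ok, c("mouse_id", "slope")]
  s <- s[order(s$mouse_id), ]
  lab <- rep(NA_character_, nrow(s))
  if (mode == "threshold") {
    if (!(down_cut < flat_range[1] && flat_range[1] <= flat_range[2])) {
      stop("cutpoints must satisfy down_cut < flat_lo <= flat_hi")
    }
    lab[s$slope <= down_cut] <- "down"
    lab[s$slope >= flat_range[1] & s$slope <= flat_range[2]] <- "flat"
    lab[s$slope > down_cut & s$slope < flat_range[1]] <- "excluded_intermediate"
    lab[s$slope > flat_range[2]] <- "excluded_positive"
    nd <- sum(lab == "down"); nf <- sum(lab == "flat")
    if (nd != group_size || nf != group_size) {
      warning("threshold mode achieved groups of ", nd, " down / ", nf,
              " flat (requested ", group_size, " each)")
    }
    cut <- c(down_cut = down_cut, flat_lo = flat_range[1],
             flat_hi = flat_range[2])
  } else {
    ord_neg <- order(s$slope, s$mouse_id)           # most negative first
    down_ix <- ord_neg[seq_len(group_size)]
    rest <- setdiff(seq_len(nrow(s)), down_ix)
    ord_abs <- rest[order(abs(s$slope[rest]), s$mouse_id[rest])]
    flat_ix <- ord_abs[seq_len(group_size)]
    lab[down_ix] <- "down"
    lab[flat_ix] <- "flat"
    lab[is.na(lab)] <- ifelse(s$slope[is.na(lab)] > 0,
                              "excluded_positive", "excluded_intermediate")
    cut <- c(down_cut = max(s$slope[down_ix]),
             flat_lo = min(s$slope[flat_ix]),
             flat_hi = max(s$slope[flat_ix]))
  }
  out <- data.frame(mouse_id = s$mouse_id, slope = s$slope, label = lab,
                    stringsAsFactors = FALSE)
  structure(out, class = c("stratification", "data.frame"),
            cutpoints = cut, group_size = group_size, mode = mode)
}

#' @export
print.stratification <- function(x, ...) {
  cat("RE-slope stratification (", attr(x, "mode"), " mode)\n", sep = "")
  print(table(x$label))
  cat("cutpoints:", paste(names(attr(x, "cutpoints")),
                          signif(attr(x, "cutpoints"), 3),
                          sep = "=", collapse = ", "), "\n")
  invisible(x)
}
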