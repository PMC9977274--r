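#' Total brain volume per subject
#'
#' Sum of all atlas-ROI volumes for each subject.
#'
#' @param table volume data.frame (see \code{\link{read_volumes}}).
#' @return named numeric vector, mm^3 per subject.
#' @export
total_brain_volume <- function(table) {
  rowSums(volume_matrix(table))
}

#' Relative (percent-of-brain) volumes
#'
#' Each region volume divided by the subject's total brain volume, times
#' 100; every subject's row of relative volumes sums to 100.
#'
#' @param table volume data.frame.
#' @return volume data.frame of identical shape with region columns in
#'   percent of total brain volume.
#' @export
relative_volumes <- function(table) {
  m <- volume_matrix(table)
  tot <- rowSums(m)
  if (any(tot <= 0)) stop("total brain volume must be positive")
  rel <- sweep(m, 1, tot, "/") * 100
  out <- table
  out[, colnames(m)] <- rel
  out
}

#' Merge left/right hemisphere labels
#'
#' Combines paired left/right region columns into one bilateral column:
#' summed for volumes (the merged ROI volume) or averaged (the convention
#' for network node values). Regions absent from the map pass through
#' unchanged.
#'
#' @param table volume data.frame.
#' @param label_map data.frame with columns \code{left}, \code{right},
#'   \code{merged} giving column names.
#' @param combine \code{"sum"} (volumes) or \code{"mean"} (node values).
#' @return merged volume data.frame.
#' @export
merge_bilateral <- function(table, label_map, combine = c("sum", "mean")) {
  combine <- match.arg(combine)
  stopifnot(all(c("left", "right", "merged") %in% names(label_map)))
  regs <- setdiff(names(table), c("subject", "group", "subgroup"))
  missing <- setdiff(c(label_map$left, label_map$right), regs)
  if (length(missing)) {
    stop("label map references absent columns: ",
         paste(missing, collapse = ", "))
  }
  out <- table[, setdiff(names(table), c(label_map$left, label_map$right)),
               drop = FALSE]
  for (i in seq_len(nrow(label_map))) {
    v <- table[[label_map$left[i]]] + table[[label_map$right[i]]]
    if (combine == "mean") v <- v / 2
    out[[label_map$merged[i]]] <- v
  }
  out
}

#' Per-region Welch tests, FDR and standardized mean differences
#'
#' For every region, a two-tailed unequal-variance (Welch) t-test of the
#' test group against the reference group, Benjamini-Hochberg adjusted
#' q-values across regions, and the standardized mean difference
#' SMD = (mean(test) - mean(ref)) / sd(ref) — the reference-group SD is the
#' denominator, not a pooled SD. Regions where both groups are constant are
#' flagged degenerate with p = 1.
#'
#' @param table volume data.frame.
#' @param contrast length-2 character: c(test_group, reference_group), e.g.
#'   \code{c("ENR", "STD")}.
#' @param alpha FDR rate for the significance flag (default 0.05).
#' @return object of class \code{roi_stats}: data.frame with columns
#'   \code{region}, \code{t}, \code{df}, \code{p}, \code{q}, \code{smd},
#'   \code{direction}, \code{significant}.
#' @export
roi_group_stats <- function(table, contrast, alpha = 0.05) {
  stopifnot(length(contrast) == 2)
  m <- volume_matrix(table)
  a <- group_rows(table, contrast[1])
  b <- group_rows(table, contrast[2])
  if (sum(a) < 2 || sum(b) < 2) {
    stop("each contrast group needs at least 2 subjects")
  }
  res <- lapply(colnames(m), function(r) {
    x <- m[a, r]; y <- m[b, r]
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      return(data.frame(region = r, t = 0, df = NA_real_, p = 1,
                        smd = if (stats::sd(y) > 0)
                          (mean(x) - mean(y)) / stats::sd(y) else NA_real_,
                        degenerate = TRUE))
    }
    tt <- stats::t.test(x, y, var.equal = FALSE)
    sdy <- stats::sd(y)
    data.frame(region = r, t = unname(tt$statistic),
               df = unname(tt$parameter), p = tt$p.value,
               smd = if (sdy > 0) (mean(x) - mean(y)) / sdy else NA_real_,
               degenerate = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- fdr_adjust(out$p)
  out$direction <- ifelse(out$smd >= 0, paste0(contrast[1], ">", contrast[2]),
                          paste0(contrast[2], ">", contrast[1]))
  out$significant <- out$q < alpha
  out <- out[, c("region", "t", "df", "p", "q", "smd", "direction",
                 "significant", "degenerate")]
  rownames(out) <- NULL
  structure(out, class = c("roi_stats", "data.frame"),
            contrast = contrast, alpha = alpha)
}

#' Welch t-tests per region
#'
#' Convenience wrapper returning just region, t, df and p (see
#' \code{\link{roi_group_stats}} for the full table).
#'
#' @inheritParams roi_group_stats
#' @return data.frame: \code{region}, \code{t}, \code{df}, \code{p}.
#' @export
roi_welch_tests <- function(table, contrast) {
  s <- roi_group_stats(table, contrast)
  s[, c("region", "t", "df", "p")]
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up q-values controlling the FDR.
#'
#' @param pvals p-values in [0, 1].
#' @return q-values, same length and order.
#' @export
fdr_adjust <- function(pvals) {
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(pvals, method = "BH")
}

#' Standardized mean difference per region
#'
#' SMD = (mean(test) - mean(reference)) / sd(reference), in units of the
#' reference-group standard deviation.
#'
#' @inheritParams roi_group_stats
#' @return named numeric vector of SMDs (NA where the reference SD is 0,
#'   with a warning).
#' @export
smd <- function(table, contrast) {
  m <- volume_matrix(table)
  a <- group_rows(table, contrast[1])
  b <- group_rows(table, contrast[2])
  sds <- apply(m[b, , drop = FALSE], 2, stats::sd)
  out <- (colMeans(m[a, , drop = FALSE]) - colMeans(m[b, , drop = FALSE])) /
    sds
  if (any(sds == 0)) {
    warning(sum(sds == 0), " regions have zero reference-group SD; SMD NA")
    out[sds == 0] <- NA_real_
  }
  out
}

#' Select network nodes from ROI statistics
#'
#' Nodes for network-based statistics are the regions passing the FDR
#' threshold on a directional contrast (e.g. ENR > STD): q below alpha and,
#' if \code{direction} is given, the stated sign of the effect.
#'
#' @param stats a \code{\link{roi_group_stats}} result.
#' @param alpha FDR threshold (default 0.05).
#' @param direction optional \code{"greater"} (test > reference only),
#'   \code{"less"}, or \code{NULL} for both signs.
#' @return character vector of selected region names.
#' @export
select_nodes <- function(stats, alpha = 0.05, direction = "greater") {
  keep <- stats$q < alpha
  if (!is.null(direction)) {
    keep <- keep & if (direction == "greater") stats$smd > 0 else
      stats$smd < 0
  }
  sel <- stats$region[keep & !is.na(keep)]
  if (length(sel) == 0) {
    stop("no region passes q < ", alpha,
         " on this contrast; consider a different threshold")
  }
  sel
}

#' Correlate RE slopes with regional volumes
#'
#' ROI-level analogue of a voxel-wise slope regression: for each region, the
#' Pearson correlation between per-mouse RE trajectory slope and regional
#' volume across the subjects present in both inputs, with BH-FDR across
#' regions.
#'
#' @param slopes data.frame with \code{mouse_id} and \code{slope}
#'   (see \code{\link{trajectory_slopes}}); mouse ids must match volume
#'   table subjects.
#' @param table volume data.frame.
#' @return data.frame: \code{region}, \code{r}, \code{p}, \code{q},
#'   \code{n}.
#' @export
slope_volume_correlation <- function(slopes, table) {
  common <- intersect(slopes$mouse_id, table$subject)
  if (length(common) < 4) {
    stop("need at least 4 subjects with both slope and volumes")
  }
  s <- slopes$slope[match(common, slopes$mouse_id)]
  if (stats::sd(s) == 0) stop("slope vector is constant")
  m <- volume_matrix(table)[match(common, table$subject), , drop = FALSE]
  res <- lapply(colnames(m), function(r) {
    ct <- stats::cor.test(s, m[, r])
    data.frame(region = r, r = unname(ct$estimate), p = ct$p.value,
               n = length(common))
  })
  out <- do.call(rbind, res)
  out$q <- fdr_adjust(out$p)
  out <- out[, c("region", "r", "p", "q", "n")]
  rownames(out) <- NULL
  out
}
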