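#' Configuration for the synthetic volume-table generator
#'
#' Defines a multivariate-normal model for per-subject atlas-ROI volumes:
#' region means/SDs, per-group mean shifts in standardized-mean-difference
#' units, a background inter-regional correlation, and a planted
#' elevated-covariance subnetwork that can be confined to a subset of groups
#' (emulating the stronger "correlatedness" seen in sustained roamers).
#'
#' @param n_per_group named integer vector, subjects per group
#'   (e.g. \code{c(STD = 10, flat = 15, down = 15)}).
#' @param n_regions number of atlas regions (default 182, the merged
#'   bilateral DSURQE count); ignored if \code{region_names} given.
#' @param region_names optional character region names.
#' @param base_means,base_sds per-region mm^3 means and SDs (recycled).
#' @param group_mean_shifts named list: per group, a numeric vector of
#'   per-region shifts in units of \code{base_sds} (SMD units). Groups not
#'   listed get zero shift.
#' @param baseline_rho background correlation between all region pairs, in
#'   [0, 1); either a single value or a named vector with one entry per
#'   group (so groups can differ in overall "correlatedness", the contrast
#'   seen between sustained and habituating roamers).
#' @param planted_edges two-column matrix/data.frame of region-name pairs
#'   receiving elevated correlation; NULL for none.
#' @param planted_rho correlation on planted edges; must exceed
#'   \code{baseline_rho}.
#' @param planted_groups character vector of groups whose correlation matrix
#'   carries the planted edges (default: all groups).
#' @param seed integer seed used by \code{\link{simulate_volumes}}.
#' @return object of class \code{volume_sim_config}.
#' @examples
#' cfg <- volume_sim_config(c(STD = 10, ENR = 12), n_regions = 20,
#'                          baseline_rho = 0.1, seed = 1)
#' @export
volume_sim_config <- function(n_per_group, n_regions = 182,
                              region_names = NULL,
                              base_means = 2.5, base_sds = 0.25,
                              group_mean_shifts = list(),
                              baseline_rho = 0.1,
                              planted_edges = NULL, planted_rho = 0.6,
                              planted_groups = NULL, seed = 1) {
  if (is.null(names(n_per_group)) || any(names(n_per_group) == "")) {
    stop("n_per_group must be a named vector of group sizes")
  }
  if (any(n_per_group < 1)) stop("every group needs at least one subject")
  if (is.null(region_names)) {
    region_names <- sprintf("R%03d", seq_len(n_regions))
  }
  p <- length(region_names)
  if (anyDuplicated(region_names)) stop("region names must be unique")
  base_means <- rep_len(base_means, p)
  base_sds <- rep_len(base_sds, p)
  if (any(base_sds <= 0) || any(base_means <= 0)) {
    stop("base means and sds must be positive")
  }
  if (any(baseline_rho < 0) || any(baseline_rho >= 1)) {
    stop("baseline_rho must lie in [0, 1)")
  }
  if (!is.null(names(baseline_rho)) &&
      !all(names(baseline_rho) %in% names(n_per_group))) {
    stop("unknown group in baseline_rho")
  }
  if (!is.null(planted_edges)) {
    planted_edges <- as.matrix(planted_edges)
    if (ncol(planted_edges) != 2) stop("planted_edges needs two columns")
    if (!all(planted_edges %in% region_names)) {
      stop("planted edge refers to unknown region")
    }
    if (any(planted_edges[, 1] == planted_edges[, 2])) {
      stop("planted self-edges are not allowed")
    }
  }
  groups <- names(n_per_group)
  if (is.null(planted_groups)) planted_groups <- groups
  if (!all(planted_groups %in% groups)) stop("unknown group in planted_groups")
  if (!is.null(planted_edges) &&
      !(planted_rho > max(baseline_for(baseline_rho, planted_groups)) &&
        planted_rho < 1)) {
    stop("need baseline_rho < planted_rho < 1 for every planted group")
  }
  if (!all(names(group_mean_shifts) %in% groups)) {
    stop("unknown group in group_mean_shifts")
  }
  shifts <- lapply(stats::setNames(groups, groups), function(gr) {
    s <- group_mean_shifts[[gr]]
    if (is.null(s)) s <- 0
    rep_len(s, p)
  })
  cfg <- structure(
    list(n_per_group = n_per_group, region_names = region_names, p = p,
         base_means = base_means, base_sds = base_sds, shifts = shifts,
         baseline_rho = baseline_rho, planted_edges = planted_edges,
         planted_rho = planted_rho, planted_groups = planted_groups,
         seed = seed),
    class = "volume_sim_config"
  )
  # reject configs whose implied correlation matrices are not PSD
  for (gr in groups) {
    check_psd(group_cor_matrix(cfg, gr), gr)
  }
  cfg
}

# per-group baseline correlation (scalar recycles to all groups)
baseline_for <- function(baseline_rho, groups) {
  if (is.null(names(baseline_rho))) {
    return(rep(baseline_rho[1], length(groups)))
  }
  hit <- match(groups, names(baseline_rho))
  if (anyNA(hit)) {
    stop("baseline_rho must name every group; missing: ",
         paste(groups[is.na(hit)], collapse = ", "))
  }
  unname(baseline_rho[hit])
}

group_cor_matrix <- function(cfg, group) {
  R <- matrix(baseline_for(cfg$baseline_rho, group), cfg$p, cfg$p,
              dimnames = list(cfg$region_names, cfg$region_names))
  diag(R) <- 1
  if (!is.null(cfg$planted_edges) && group %in% cfg$planted_groups) {
    for (e in seq_len(nrow(cfg$planted_edges))) {
      a <- cfg$planted_edges[e, 1]; b <- cfg$planted_edges[e, 2]
      R[a, b] <- R[b, a] <- cfg$planted_rho
    }
  }
  R
}

check_psd <- function(R, label) {
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("implied correlation matrix for group '", label,
         "' is not positive semi-definite (min eigenvalue ",
         format(min(ev), digits = 4),
         "); adjust baseline_rho/planted_rho or the planted edge set")
  }
  invisible(R)
}

#' Simulate a subject-by-region volume table
#'
#' Draws each group's subjects from a multivariate normal with the
#' configured means, SDs and correlation structure. Negative draws (possible
#' only for extreme configurations) are truncated at a small positive floor
#' so downstream code can assume positive volumes.
#'
#' @param config a \code{\link{volume_sim_config}}.
#' @return data.frame: columns \code{subject}, \code{group}, then one
#'   numeric column per region (mm^3).
#' @examples
#' tab <- simulate_volumes(volume_sim_config(c(STD = 5, ENR = 5),
#'                                           n_regions = 8, seed = 3))
#' dim(tab)
#' @export
simulate_volumes <- function(config) {
  stopifnot(inherits(config, "volume_sim_config"))
  local_seed(config$seed, {
    blocks <- lapply(names(config$n_per_group), function(gr) {
      n <- config$n_per_group[[gr]]
      R <- group_cor_matrix(config, gr)
      ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
      if (min(ev) < 0) {
        # eigen-floor within tolerance (checked at construction): nudge
        R <- R + diag(-min(ev) + 1e-10, config$p)
        R <- stats::cov2cor(R)
      }
      S <- diag(config$base_sds) %*% R %*% diag(config$base_sds)
      mu <- config$base_means + config$shifts[[gr]] * config$base_sds
      X <- MASS::mvrnorm(n, mu = mu, Sigma = S)
      X <- pmax(X, 1e-6)
      colnames(X) <- config$region_names
      data.frame(subject = sprintf("%s_%02d", gr, seq_len(n)),
                 group = gr, X, check.names = FALSE,
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, blocks)
    rownames(out) <- NULL
    out
  })
}

#' Planted ground truth of a volume simulation
#'
#' Returns exactly what \code{\link{simulate_volumes}} embedded: the planted
#' elevated-correlation edge set and the per-group per-region true mean
#' shifts (SMD units).
#'
#' @param config a \code{\link{volume_sim_config}}.
#' @return list with \code{planted_edges} (two-column character matrix,
#'   possibly 0-row), \code{planted_rho}, \code{planted_groups},
#'   \code{shifts} (named list of per-region numeric vectors).
#' @export
ground_truth <- function(config) {
  stopifnot(inherits(config, "volume_sim_config"))
  pe <- config$planted_edges
  if (is.null(pe)) {
    pe <- matrix(character(0), ncol = 2)
  }
  list(planted_edges = pe, planted_rho = config$planted_rho,
       planted_groups = config$planted_groups, shifts = config$shifts)
}

#' Read / write a subject-by-region volume table
#'
#' CSV schema: first column \code{subject}, second \code{group}, optional
#' \code{subgroup}, remaining columns one per region (mm^3).
#'
#' @param path file path.
#' @return \code{read_volumes} returns the volume data.frame.
#' @export
read_volumes <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!all(c("subject", "group") %in% names(df))) {
    stop("volume table needs 'subject' and 'group' columns")
  }
  regs <- setdiff(names(df), c("subject", "group", "subgroup"))
  if (length(regs) == 0) stop("volume table has no region columns")
  for (r in regs) df[[r]] <- as.numeric(df[[r]])
  df
}

#' @rdname read_volumes
#' @param table volume data.frame.
#' @export
write_volumes <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

# rows whose group (or subgroup, if present) matches a label
group_rows <- function(table, label) {
  sel <- table$group == label
  if ("subgroup" %in% names(table)) {
    sel <- sel | (!is.na(table$subgroup) & table$subgroup == label)
  }
  sel
}

# numeric region matrix (subjects x regions) from a volume table
volume_matrix <- function(table) {
  regs <- setdiff(names(table), c("subject", "group", "subgroup"))
  m <- as.matrix(table[, regs, drop = FALSE])
  rownames(m) <- table$subject
  storage.mode(m) <- "double"
  m
}
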