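#' Edge-wise covariance-difference statistics
#'
#' For every pair of nodes, the two-sample Fisher-z statistic for a
#' difference in correlation between groups:
#' \deqn{z_{ij} = \frac{\mathrm{atanh}(r^{A}_{ij}) - \mathrm{atanh}(r^{B}_{ij})}
#'   {\sqrt{1/(n_A - 3) + 1/(n_B - 3)}}}
#' Positive values mean stronger covariance in group A (the directional
#' contrast A > B). Correlations at |r| = 1 are clamped with a warning.
#'
#' @param table volume data.frame.
#' @param group_a,group_b group labels (contrast group_a > group_b).
#' @param nodes regions to use as network nodes (must exist in the table);
#'   NULL uses all regions.
#' @param use_relative correlate relative volumes (default TRUE).
#' @return object of class \code{edge_statistics}: list with \code{nodes},
#'   \code{z} (m x m symmetric, zero diagonal), \code{n_a}, \code{n_b},
#'   \code{contrast}.
#' @export
covariance_edge_stats <- function(table, group_a, group_b, nodes = NULL,
                                  use_relative = TRUE) {
  regs <- setdiff(names(table), c("subject", "group", "subgroup"))
  if (is.null(nodes)) nodes <- regs
  if (!all(nodes %in% regs)) {
    stop("unknown node(s): ",
         paste(setdiff(nodes, regs), collapse = ", "))
  }
  if (use_relative) table <- relative_volumes(table)
  ma <- volume_matrix(table[group_rows(table, group_a), , drop = FALSE])
  mb <- volume_matrix(table[group_rows(table, group_b), , drop = FALSE])
  if (nrow(ma) < 4 || nrow(mb) < 4) stop("each group needs >= 4 subjects")
  edge_stats_from_matrices(ma[, nodes, drop = FALSE],
                           mb[, nodes, drop = FALSE],
                           contrast = paste(group_a, ">", group_b))
}

# z-statistic matrix from two subjects-x-nodes matrices (internal; the
# permutation loop calls this directly)
edge_stats_from_matrices <- function(ma, mb, contrast = "A > B",
                                     warn_clamp = TRUE) {
  ra <- stats::cor(ma); rb <- stats::cor(mb)
  clamp <- function(r) pmin(pmax(r, -0.999999), 0.999999)
  if (warn_clamp && any(abs(c(ra[upper.tri(ra)], rb[upper.tri(rb)])) >= 1)) {
    warning("|r| = 1 encountered; clamped before Fisher transform")
  }
  se <- sqrt(1 / (nrow(ma) - 3) + 1 / (nrow(mb) - 3))
  z <- (atanh(clamp(ra)) - atanh(clamp(rb))) / se
  diag(z) <- 0
  structure(
    list(nodes = colnames(ma), z = z, n_a = nrow(ma), n_b = nrow(mb),
         contrast = contrast),
    class = "edge_statistics"
  )
}

#' Convert an edge-wise alpha to a primary threshold
#'
#' The edge statistic is asymptotically standard normal, so an edge-level
#' alpha maps to its normal quantile: alpha = 0.001 one-sided gives 3.09
#' (the conventional "t = 3.1" primary threshold).
#'
#' @param alpha edge-level tail probability in (0, 1).
#' @param sidedness 1 (directional, default) or 2.
#' @return statistic threshold.
#' @export
alpha_to_threshold <- function(alpha, sidedness = 1) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  stats::qnorm(1 - alpha / sidedness)
}

#' Apply the primary threshold to edge statistics
#'
#' @param stats an \code{\link{covariance_edge_stats}} result.
#' @param threshold primary threshold (> 0); an edge is kept iff its
#'   statistic exceeds it (directional contrast).
#' @return symmetric logical adjacency matrix over the nodes.
#' @export
threshold_edges <- function(stats, threshold) {
  if (threshold <= 0) stop("primary threshold must be positive")
  adj <- stats$z > threshold
  diag(adj) <- FALSE
  adj  # z is symmetric, so adj already is
}

#' Connected components of a suprathreshold graph
#'
#' Components of the adjacency, sized by edge count ("structural
#' connections") and sorted by decreasing size; isolated nodes are not
#' reported.
#'
#' @param adjacency symmetric logical adjacency matrix with node names.
#' @return list of components, each a list with \code{nodes},
#'   \code{edges} (two-column character matrix), \code{size} (edge count).
#' @export
graph_components <- function(adjacency) {
  nodes <- colnames(adjacency)
  if (is.null(nodes)) nodes <- as.character(seq_len(ncol(adjacency)))
  g <- igraph::graph_from_adjacency_matrix(adjacency, mode = "undirected",
                                           diag = FALSE)
  memb <- igraph::components(g)$membership
  comps <- list()
  for (cid in unique(memb)) {
    vs <- which(memb == cid)
    if (length(vs) < 2) next
    sub <- adjacency[vs, vs, drop = FALSE]
    ij <- which(sub & upper.tri(sub), arr.ind = TRUE)
    if (nrow(ij) == 0) next
    comps[[length(comps) + 1]] <- list(
      nodes = nodes[vs],
      edges = cbind(nodes[vs][ij[, 1]], nodes[vs][ij[, 2]]),
      size = nrow(ij)
    )
  }
  comps[order(vapply(comps, `[[`, numeric(1), "size"), decreasing = TRUE)]
}

largest_component_size <- function(adjacency) {
  comps <- graph_components(adjacency)
  if (length(comps) == 0) 0L else comps[[1]]$size
}

#' Network-based statistics for group covariance differences
#'
#' The three NBS steps for structural covariance: (1) threshold the
#' edge-wise covariance-difference statistics at the primary threshold,
#' (2) extract connected components of the suprathreshold graph, (3) build
#' the null distribution of the maximum component size by permuting subject
#' group labels \code{n_perm} times (correlations and edge statistics are
#' recomputed per permutation; group sizes are preserved), and assign each
#' observed component the family-wise-error-corrected
#' \deqn{p_{FWE} = (1 + \#\{perm\ max \ge size\}) / (n_{perm} + 1).}
#' The component — not any single edge — carries the p-value. If the number
#' of distinct group assignments is at most \code{n_perm}, all of them are
#' enumerated instead and the result is flagged exhaustive.
#'
#' @param table volume data.frame.
#' @param group_a,group_b groups to contrast (covariance higher in group_a).
#' @param nodes node region names (e.g. from \code{\link{select_nodes}});
#'   NULL = all regions.
#' @param threshold primary threshold on the edge z-statistic.
#' @param n_perm permutations (default 10000, >= 100).
#' @param seed integer seed; results are reproducible.
#' @param use_relative correlate relative volumes (default TRUE).
#' @return object of class \code{nbs_result}: \code{components} (each with
#'   nodes, edges, size, p_fwe), \code{perm_max} (null max-size
#'   distribution), \code{threshold}, \code{edge_stats}, \code{config}.
#' @examples
#' \donttest{
#' cfg <- volume_sim_config(c(A = 15, B = 15), n_regions = 10, seed = 8)
#' tab <- simulate_volumes(cfg)
#' nbs_test(tab, "A", "B", threshold = 2.5, n_perm = 200, seed = 1)
#' }
#' @export
nbs_test <- function(table, group_a, group_b, nodes = NULL, threshold = 3.1,
                     n_perm = 10000, seed = 1, use_relative = TRUE) {
  if (n_perm < 100) stop("n_perm must be >= 100")
  if (threshold <= 0) stop("primary threshold must be positive")
  obs <- covariance_edge_stats(table, group_a, group_b, nodes,
                               use_relative = use_relative)
  adj <- threshold_edges(obs, threshold)
  comps <- graph_components(adj)

  in_a <- group_rows(table, group_a)
  in_b <- group_rows(table, group_b)
  sub <- table[in_a | in_b, , drop = FALSE]
  if (use_relative) sub <- relative_volumes(sub)
  m <- volume_matrix(sub)[, obs$nodes, drop = FALSE]
  is_a <- group_rows(sub, group_a)
  na <- sum(is_a); n <- nrow(m)

  exhaustive <- FALSE
  n_assign <- choose(n, na)
  if (n_assign <= n_perm) {
    perm_sets <- utils::combn(n, na, simplify = FALSE)
    exhaustive <- TRUE
  }
  perm_max <- local_seed(seed, {
    vapply(seq_len(if (exhaustive) n_assign else n_perm), function(b) {
      ia <- if (exhaustive) perm_sets[[b]] else sample.int(n, na)
      es <- edge_stats_from_matrices(m[ia, , drop = FALSE],
                                     m[-ia, , drop = FALSE],
                                     warn_clamp = FALSE)
      largest_component_size(es$z > threshold)
    }, numeric(1))
  })
  denom <- length(perm_max) + 1
  for (i in seq_along(comps)) {
    comps[[i]]$p_fwe <- (1 + sum(perm_max >= comps[[i]]$size)) / denom
  }
  structure(
    list(components = comps, perm_max = perm_max, threshold = threshold,
         edge_stats = obs, exhaustive = exhaustive,
         config = list(group_a = group_a, group_b = group_b,
                       n_perm = length(perm_max), seed = seed,
                       use_relative = use_relative)),
    class = "nbs_result"
  )
}

#' @export
print.nbs_result <- function(x, ...) {
  cat("NBS (", x$edge_stats$contrast, "), primary threshold ",
      x$threshold, ", ", x$config$n_perm, " permutation",
      if (x$exhaustive) "s (exhaustive)" else "s", "\n", sep = "")
  if (length(x$components) == 0) {
    cat("no suprathreshold components\n")
  } else {
    for (i in seq_along(x$components)) {
      co <- x$components[[i]]
      cat(sprintf("  component %d: %d connections over %d nodes, p_fwe = %.4g\n",
                  i, co$size, length(co$nodes), co$p_fwe))
    }
  }
  invisible(x)
}

#' @export
plot.nbs_result <- function(x, ...) {
  graphics::hist(x$perm_max, breaks = 30, col = "grey",
                 main = "Permutation null of max component size",
                 xlab = "largest component (edges)")
  if (length(x$components)) {
    graphics::abline(v = x$components[[1]]$size, col = "red", lwd = 2)
  }
  invisible(x)
}

#' Component size as a function of the primary threshold
#'
#' Largest observed suprathreshold component size for each threshold in an
#' ascending grid; the curve is monotone non-increasing.
#'
#' @inheritParams nbs_test
#' @param t_grid ascending numeric thresholds.
#' @return data.frame: \code{threshold}, \code{size}.
#' @export
threshold_sweep <- function(table, group_a, group_b, nodes = NULL, t_grid,
                            use_relative = TRUE) {
  if (is.unsorted(t_grid, strictly = TRUE)) {
    stop("t_grid must be strictly ascending")
  }
  obs <- covariance_edge_stats(table, group_a, group_b, nodes,
                               use_relative = use_relative)
  sizes <- vapply(t_grid, function(th) {
    largest_component_size(obs$z > th)
  }, numeric(1))
  data.frame(threshold = t_grid, size = sizes)
}

#' Export an NBS result as node and edge tables
#'
#' Writes a nodes CSV (\code{name}, \code{component}, plus any metadata
#' columns matched by name) and an edges CSV (\code{a}, \code{b},
#' \code{statistic}, \code{component}); empty results produce header-only
#' files. The pair of files round-trips the component structure.
#'
#' @param result an \code{\link{nbs_test}} result.
#' @param nodes_path,edges_path output CSV paths.
#' @param node_metadata optional data.frame with a \code{name} column and
#'   extra columns (coordinates, anatomical system, ...); unknown names
#'   trigger a warning.
#' @return invisibly, list of the two written data.frames.
#' @export
export_network <- function(result, nodes_path, edges_path,
                           node_metadata = NULL) {
  nd <- data.frame(name = character(0), component = integer(0))
  ed <- data.frame(a = character(0), b = character(0),
                   statistic = numeric(0), component = integer(0))
  z <- result$edge_stats$z
  for (i in seq_along(result$components)) {
    co <- result$components[[i]]
    nd <- rbind(nd, data.frame(name = co$nodes, component = i))
    ed <- rbind(ed, data.frame(
      a = co$edges[, 1], b = co$edges[, 2],
      statistic = z[cbind(co$edges[, 1], co$edges[, 2])], component = i))
  }
  if (!is.null(node_metadata)) {
    if (!"name" %in% names(node_metadata)) {
      stop("node_metadata needs a 'name' column")
    }
    unknown <- setdiff(node_metadata$name, result$edge_stats$nodes)
    if (length(unknown)) {
      warning("metadata for unknown node(s): ",
              paste(unknown, collapse = ", "))
    }
    nd <- merge(nd, node_metadata, by = "name", all.x = TRUE, sort = FALSE)
  }
  utils::write.csv(nd, nodes_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(ed, edges_path, row.names = FALSE, quote = FALSE)
  invisible(list(nodes = nd, edges = ed))
}
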