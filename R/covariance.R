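#' Group structural covariance network
#'
#' Across-subject Pearson correlation between all pairs of region volumes
#' within one group — the group-level structural covariance network. By
#' default correlations are computed on relative (percent-of-brain) volumes.
#' Regions with zero variance in the group get NA rows/columns and a
#' warning.
#'
#' @param table volume data.frame.
#' @param group group label to subset on (NULL uses all subjects).
#' @param use_relative correlate relative volumes (default) or absolute.
#' @return object of class \code{covariance_network}: list with
#'   \code{regions}, \code{matrix} (p x p correlations, unit diagonal),
#'   \code{n} (subjects), \code{group}.
#' @examples
#' tab <- simulate_volumes(volume_sim_config(c(STD = 8), n_regions = 6,
#'                                           seed = 2))
#' net <- structural_covariance(tab, "STD")
#' net$n
#' @export
structural_covariance <- function(table, group = NULL, use_relative = TRUE) {
  if (!is.null(group)) {
    sel <- table$group == group
    if ("subgroup" %in% names(table)) {
      sel <- sel | (!is.na(table$subgroup) & table$subgroup == group)
    }
    table <- table[sel, , drop = FALSE]
    if (nrow(table) == 0) stop("no subjects in group ", group)
  }
  if (nrow(table) < 4) stop("need at least 4 subjects for covariance")
  if (use_relative) table <- relative_volumes(table)
  m <- volume_matrix(table)
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning(sum(sds == 0), " zero-variance regions; correlations set NA")
  }
  R <- suppressWarnings(stats::cor(m))
  diag(R) <- 1
  structure(
    list(regions = colnames(m), matrix = R, n = nrow(m),
         group = if (is.null(group)) "all" else group),
    class = "covariance_network"
  )
}

#' @export
print.covariance_network <- function(x, ...) {
  off <- x$matrix[upper.tri(x$matrix)]
  cat("Structural covariance network (group ", x$group, "): ",
      length(x$regions), " regions, n = ", x$n, "\n", sep = "")
  cat("mean |off-diagonal r| =", round(mean(abs(off), na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Region display order by hierarchical clustering
#'
#' Leaf order of average-linkage hierarchical clustering on distance
#' 1 - r of one network (conventionally the enriched group), reusable
#' across all groups so matrices are directly comparable by eye. Ties in
#' the distance matrix are resolved deterministically by the region-name
#' ordering of the input.
#'
#' @param network a \code{\link{structural_covariance}} result.
#' @return integer permutation of the regions.
#' @export
cluster_order <- function(network) {
  R <- network$matrix
  if (any(is.na(R))) stop("network has missing rows; cannot order")
  if (nrow(R) < 2) return(seq_len(nrow(R)))
  h <- stats::hclust(stats::as.dist(1 - R), method = "average")
  h$order
}

#' Chi-square test for equality of two correlation matrices
#'
#' Tests whether two groups share one population correlation structure.
#' The default \code{"fisher"} variant sums squared Fisher-z differences
#' over the p(p-1)/2 distinct pairs, each scaled by its sampling variance:
#' \deqn{\chi^2 = \sum_{i<j} \frac{(z^{(1)}_{ij} - z^{(2)}_{ij})^2}
#'   {1/(n_1 - 3) + 1/(n_2 - 3)}}
#' with z = atanh(r), referred to a chi-square with df = p(p-1)/2. It is
#' usable when p exceeds the group sizes, the regime of atlas-wide
#' covariance (182 regions, tens of mice). The \code{"jennrich"} variant is
#' the classical pooled-inverse test and requires an invertible pooled
#' correlation matrix, i.e. p well below n.
#'
#' @param net1,net2 \code{\link{structural_covariance}} results over the
#'   same region set.
#' @param variant \code{"fisher"} (default) or \code{"jennrich"}.
#' @return object of classes \code{matrix_equality} and \code{htest} with
#'   \code{statistic} (chi2), \code{parameter} (df), \code{p.value} and the
#'   variant in \code{method}.
#' @examples
#' cfg <- volume_sim_config(c(A = 12, B = 12), n_regions = 6, seed = 5)
#' tab <- simulate_volumes(cfg)
#' t <- matrix_equality_test(structural_covariance(tab, "A"),
#'                           structural_covariance(tab, "B"))
#' t$parameter  # 15 pairs
#' @export
matrix_equality_test <- function(net1, net2,
                                 variant = c("fisher", "jennrich")) {
  variant <- match.arg(variant)
  if (!identical(net1$regions, net2$regions)) {
    stop("networks must cover the same regions in the same order")
  }
  if (net1$n < 4 || net2$n < 4) stop("need n >= 4 in both groups")
  R1 <- net1$matrix; R2 <- net2$matrix
  p <- nrow(R1)
  df <- p * (p - 1) / 2
  if (variant == "fisher") {
    ut <- upper.tri(R1)
    r1 <- R1[ut]; r2 <- R2[ut]
    if (any(abs(c(r1, r2)) >= 1)) {
      warning("|r| = 1 encountered; clamped before Fisher transform")
      r1 <- pmin(pmax(r1, -0.999999), 0.999999)
      r2 <- pmin(pmax(r2, -0.999999), 0.999999)
    }
    v <- 1 / (net1$n - 3) + 1 / (net2$n - 3)
    chi2 <- sum((atanh(r1) - atanh(r2))^2) / v
    method <- "Correlation-matrix equality (Fisher-z sum)"
  } else {
    n1 <- net1$n; n2 <- net2$n
    Rbar <- (n1 * R1 + n2 * R2) / (n1 + n2)
    Rinv <- tryCatch(solve(Rbar), error = function(e) NULL)
    if (is.null(Rinv) || kappa(Rbar) > 1e10) {
      stop("pooled correlation matrix is (near-)singular; the jennrich ",
           "variant needs p well below n — use variant = \"fisher\"")
    }
    c0 <- n1 * n2 / (n1 + n2)
    Z <- sqrt(c0) * Rinv %*% (R1 - R2)
    S <- diag(p) + Rbar * Rinv
    chi2 <- sum(diag(Z %*% Z)) / 2 -
      drop(t(diag(Z)) %*% solve(S, diag(Z)))
    method <- "Correlation-matrix equality (Jennrich)"
  }
  structure(
    list(statistic = c(chi2 = chi2), parameter = c(df = df),
         p.value = stats::pchisq(chi2, df, lower.tail = FALSE),
         method = method,
         data.name = paste(net1$group, "vs", net2$group,
                           sprintf("(n = %d, %d; p = %d)",
                                   net1$n, net2$n, p))),
    class = c("matrix_equality", "htest")
  )
}

#' Per-region coefficient of variation within a group
#'
#' CV = sample SD / mean (n - 1 denominator) of each region's volumes
#' across the group's subjects; dimensionless, requires positive means.
#'
#' @param table volume data.frame.
#' @param group group label (NULL = all subjects).
#' @return named numeric vector of CVs.
#' @export
coefficient_of_variation <- function(table, group = NULL) {
  if (!is.null(group)) {
    sel <- table$group == group
    if ("subgroup" %in% names(table)) {
      sel <- sel | (!is.na(table$subgroup) & table$subgroup == group)
    }
    table <- table[sel, , drop = FALSE]
  }
  if (nrow(table) < 2) stop("need at least 2 subjects")
  m <- volume_matrix(table)
  mu <- colMeans(m)
  if (any(mu <= 0)) stop("region means must be positive for CV")
  apply(m, 2, stats::sd) / mu
}

#' Mean coefficient of variation across regions
#'
#' @param profile named CV vector from
#'   \code{\link{coefficient_of_variation}}.
#' @return scalar mean CV.
#' @export
mean_cv <- function(profile) {
  if (length(profile) == 0) stop("empty CV profile")
  mean(profile)
}

#' Mann-Whitney rank comparison of two CV profiles
#'
#' Two-sided Mann-Whitney U (Wilcoxon rank-sum) test comparing per-region
#' variability between groups; U is reported for the first profile. For
#' small samples the exact permutation p-value is computed by enumerating
#' group assignments (valid with ties); larger samples use the normal
#' approximation with tie correction.
#'
#' @param profile_a,profile_b CV vectors over the same region set.
#' @param exact force (\code{TRUE}) or suppress (\code{FALSE}) enumeration;
#'   default enumerates when \code{choose(n, n_a) <= 20000}.
#' @return list: \code{u} (first group), \code{p}, \code{exact}.
#' @export
cv_rank_test <- function(profile_a, profile_b, exact = NULL) {
  a <- as.numeric(profile_a); b <- as.numeric(profile_b)
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) stop("both profiles must be non-empty")
  u_stat <- function(x, y) {
    # pairs where x beats y, ties count one half
    sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  }
  u <- u_stat(a, b)
  all_tied <- length(unique(c(a, b))) == 1
  if (is.null(exact)) exact <- choose(na + nb, na) <= 20000
  if (all_tied) {
    return(list(u = u, p = 1, exact = TRUE, tied = TRUE))
  }
  if (exact) {
    pool <- c(a, b)
    idx <- utils::combn(na + nb, na)
    dev_obs <- abs(u - na * nb / 2)
    cnt <- 0L
    for (j in seq_len(ncol(idx))) {
      ua <- u_stat(pool[idx[, j]], pool[-idx[, j]])
      if (abs(ua - na * nb / 2) >= dev_obs - 1e-9) cnt <- cnt + 1L
    }
    p <- cnt / ncol(idx)
  } else {
    w <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE,
                                             correct = FALSE))
    p <- w$p.value
  }
  list(u = u, p = p, exact = exact, tied = FALSE)
}
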