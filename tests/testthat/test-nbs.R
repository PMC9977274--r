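test_that("edge statistics match the closed form and are antisymmetric", {
  # identical groups: all statistics zero
  cfg <- volume_sim_config(c(A = 10), n_regions = 5, seed = 41)
  tab <- simulate_volumes(cfg)
  tab2 <- tab
  tab2$group <- "B"
  tab2$subject <- paste0("b", 1:10)
  both <- rbind(tab, tab2)
  es <- covariance_edge_stats(both, "A", "B", use_relative = FALSE)
  expect_true(all(abs(es$z) < 1e-12))
  # closed form: rA = 0.8, rB = 0 at n = 15/15 gives atanh(0.8)/sqrt(2/12)
  za <- (atanh(0.8) - atanh(0)) / sqrt(1 / 12 + 1 / 12)
  expect_equal(za, 2.691, tolerance = 1e-3)
  # construct data achieving those exact sample correlations on one edge
  set.seed(61)
  x <- scale(rnorm(15)); e <- scale(residuals(lm(rnorm(15) ~ x)))
  ya <- 0.8 * x + sqrt(1 - 0.64) * e
  tabA <- data.frame(subject = paste0("a", 1:15), group = "A",
                     r1 = as.numeric(x), r2 = as.numeric(ya))
  xb <- scale(rnorm(15)); eb <- scale(residuals(lm(rnorm(15) ~ xb)))
  tabB <- data.frame(subject = paste0("b", 1:15), group = "B",
                     r1 = as.numeric(xb), r2 = as.numeric(eb))
  es2 <- covariance_edge_stats(rbind(tabA, tabB), "A", "B",
                               use_relative = FALSE)
  expect_equal(es2$z["r1", "r2"], za, tolerance = 1e-6)
  # swapping the groups flips the sign
  es3 <- covariance_edge_stats(rbind(tabA, tabB), "B", "A",
                               use_relative = FALSE)
  expect_equal(es3$z, -es2$z)
  expect_error(covariance_edge_stats(both, "A", "B", nodes = "nope"),
               "unknown node")
})

test_that("alpha-to-threshold is the normal quantile with a round trip", {
  expect_equal(alpha_to_threshold(0.001), 3.09, tolerance = 0.001)
  expect_equal(alpha_to_threshold(0.5), 0)
  th <- alpha_to_threshold(0.013)
  expect_equal(pnorm(th, lower.tail = FALSE), 0.013)
  expect_error(alpha_to_threshold(0), "0, 1")
})

test_that("thresholding keeps exactly the suprathreshold edges", {
  z <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  z["a", "b"] <- z["b", "a"] <- 3.5
  z["b", "c"] <- z["c", "b"] <- 2.6
  z["c", "d"] <- z["d", "c"] <- 1.0
  es <- structure(list(nodes = letters[1:4], z = z, n_a = 10, n_b = 10,
                       contrast = "A > B"), class = "edge_statistics")
  adj <- threshold_edges(es, 2.4)
  expect_equal(sum(adj) / 2, 2)
  expect_true(adj["a", "b"] && adj["b", "c"] && !adj["c", "d"])
  expect_equal(sum(threshold_edges(es, 10)), 0)
  # threshold just above zero keeps every positive edge
  expect_equal(sum(threshold_edges(es, 1e-9)) / 2, 3)
  expect_error(threshold_edges(es, -1), "positive")
})

test_that("component extraction agrees with the reachability oracle", {
  # exhaustively over every graph on up to 4 nodes
  for (n in 2:4) {
    for (adj in all_graphs(n)) {
      dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
      comps <- graph_components(adj)
      memb <- components_oracle(adj)
      nontrivial <- table(memb)
      expected_sizes <- sort(vapply(
        names(nontrivial)[nontrivial > 1], function(cid) {
          vs <- which(memb == as.integer(cid))
          sum(adj[vs, vs]) / 2
        }, numeric(1)), decreasing = TRUE)
      expect_equal(vapply(comps, `[[`, numeric(1), "size"),
                   unname(expected_sizes))
      for (co in comps) {
        ids <- match(co$nodes, rownames(adj))
        expect_equal(length(unique(memb[ids])), 1)
      }
    }
  }
  # random graphs on 5-8 nodes
  set.seed(71)
  for (i in 1:60) {
    n <- sample(5:8, 1)
    adj <- matrix(runif(n * n) < 0.3, n, n)
    adj <- adj | t(adj); diag(adj) <- FALSE
    dimnames(adj) <- list(paste0("v", 1:n), paste0("v", 1:n))
    comps <- graph_components(adj)
    memb <- components_oracle(adj)
    expect_equal(sum(vapply(comps, `[[`, numeric(1), "size")),
                 sum(adj) / 2)
    for (co in comps) {
      ids <- match(co$nodes, rownames(adj))
      expect_equal(length(unique(memb[ids])), 1)
      # maximality: no edges leave the component
      expect_false(any(adj[ids, -ids, drop = FALSE]))
    }
  }
  # two disjoint triangles; a path of four nodes
  tri2 <- matrix(FALSE, 6, 6, dimnames = rep(list(paste0("v", 1:6)), 2))
  tri2[cbind(c(1, 2, 3, 4, 5, 6), c(2, 3, 1, 5, 6, 4))] <- TRUE
  tri2 <- tri2 | t(tri2)
  cs <- graph_components(tri2)
  expect_equal(vapply(cs, `[[`, numeric(1), "size"), c(3, 3))
  path4 <- matrix(FALSE, 4, 4, dimnames = rep(list(paste0("v", 1:4)), 2))
  path4[cbind(1:3, 2:4)] <- TRUE
  path4 <- path4 | t(path4)
  expect_equal(graph_components(path4)[[1]]$size, 3)
})

test_that("NBS is deterministic, bounded below, and permutation-sane", {
  cfg <- volume_sim_config(c(A = 8, B = 8), n_regions = 8,
                           baseline_rho = 0.1, seed = 43)
  tab <- simulate_volumes(cfg)
  r1 <- nbs_test(tab, "A", "B", threshold = 2, n_perm = 150, seed = 5,
                 use_relative = FALSE)
  r2 <- nbs_test(tab, "A", "B", threshold = 2, n_perm = 150, seed = 5,
                 use_relative = FALSE)
  expect_identical(r1$perm_max, r2$perm_max)
  expect_identical(vapply(r1$components, `[[`, numeric(1), "p_fwe"),
                   vapply(r2$components, `[[`, numeric(1), "p_fwe"))
  for (co in r1$components) {
    expect_gte(co$p_fwe, 1 / (r1$config$n_perm + 1))
    expect_lte(co$p_fwe, 1)
    # every component edge exceeds the threshold
    expect_true(all(r1$edge_stats$z[co$edges] > r1$threshold))
  }
  expect_equal(length(r1$perm_max), r1$config$n_perm)
  # sizes are reported in descending order
  sizes <- vapply(r1$components, `[[`, numeric(1), "size")
  expect_false(is.unsorted(rev(sizes)))
  expect_error(nbs_test(tab, "A", "B", threshold = 2, n_perm = 10),
               ">= 100")
})

test_that("small designs switch to exhaustive enumeration", {
  cfg <- volume_sim_config(c(A = 5, B = 5), n_regions = 5,
                           baseline_rho = 0.1, seed = 47)
  tab <- simulate_volumes(cfg)
  r <- nbs_test(tab, "A", "B", threshold = 2, n_perm = 500, seed = 1,
                use_relative = FALSE)
  expect_true(r$exhaustive)
  expect_equal(length(r$perm_max), choose(10, 5))
})

test_that("node relabeling permutes but does not change NBS results", {
  cfg <- volume_sim_config(c(A = 10, B = 10), n_regions = 6,
                           baseline_rho = 0.1, seed = 49)
  tab <- simulate_volumes(cfg)
  r1 <- nbs_test(tab, "A", "B", threshold = 1.5, n_perm = 120, seed = 3,
                 use_relative = FALSE)
  tab2 <- tab
  regs <- setdiff(names(tab2), c("subject", "group"))
  names(tab2)[match(regs, names(tab2))] <- paste0("X_", regs)
  r2 <- nbs_test(tab2, "A", "B", threshold = 1.5, n_perm = 120, seed = 3,
                 use_relative = FALSE)
  expect_equal(vapply(r1$components, `[[`, numeric(1), "size"),
               vapply(r2$components, `[[`, numeric(1), "size"))
  expect_equal(vapply(r1$components, `[[`, numeric(1), "p_fwe"),
               vapply(r2$components, `[[`, numeric(1), "p_fwe"))
})

test_that("threshold sweep is monotone and vanishes beyond the max statistic", {
  cfg <- volume_sim_config(c(A = 10, B = 10), n_regions = 8,
                           baseline_rho = 0.1, seed = 53)
  tab <- simulate_volumes(cfg)
  sw <- threshold_sweep(tab, "A", "B", t_grid = seq(0.5, 6, by = 0.5),
                        use_relative = FALSE)
  expect_false(is.unsorted(rev(sw$size)))
  es <- covariance_edge_stats(tab, "A", "B", use_relative = FALSE)
  expect_equal(sw$size[sw$threshold > max(es$z)],
               rep(0, sum(sw$threshold > max(es$z))))
  expect_error(threshold_sweep(tab, "A", "B", t_grid = c(2, 1)),
               "ascending")
})

test_that("network export writes round-trippable node and edge tables", {
  cfg <- volume_sim_config(c(A = 12, B = 12), n_regions = 6,
                           baseline_rho = 0.1,
                           planted_edges = rbind(c("R001", "R002"),
                                                 c("R002", "R003")),
                           planted_rho = 0.6, planted_groups = "A",
                           seed = 59)
  tab <- simulate_volumes(cfg)
  r <- nbs_test(tab, "A", "B", threshold = 1.5, n_perm = 120, seed = 2,
                use_relative = FALSE)
  np <- withr::local_tempfile(fileext = ".csv")
  ep <- withr::local_tempfile(fileext = ".csv")
  out <- export_network(r, np, ep)
  nodes <- read.csv(np); edges <- read.csv(ep)
  n_edges <- sum(vapply(r$components, `[[`, numeric(1), "size"))
  expect_equal(nrow(edges), n_edges)
  expect_setequal(unique(c(edges$a, edges$b)), nodes$name)
  expect_true(all(edges$statistic > r$threshold))
  # empty result: header-only files
  r0 <- r
  r0$components <- list()
  export_network(r0, np, ep)
  expect_equal(nrow(read.csv(np)), 0)
  expect_equal(nrow(read.csv(ep)), 0)
  # unknown metadata nodes warn
  expect_warning(export_network(r, np, ep,
                                node_metadata = data.frame(name = "zzz")),
                 "unknown")
})
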