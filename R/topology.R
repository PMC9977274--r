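#' Cage antenna topology
#'
#' Describes the RFID antenna network of a multi-cage enclosure: antennae sit
#' in the tunnels connecting sub-cages, so the natural representation is a
#' connected graph whose vertices are antennae and whose edges are tunnel
#' adjacencies a mouse can traverse in one move.
#'
#' @param n_antennae total antenna count \code{k} (>= 2).
#' @param layout wiring scheme: \code{"grid"} arranges antennae on a near-square
#'   lattice (default, loosely mimicking an array of interconnected cages),
#'   \code{"ring"} on a single cycle.
#' @param antenna_ids optional character ids; defaults to \code{"A001"}, ...
#' @return An object of class \code{cage_topology}: list with
#'   \code{antenna_ids}, \code{edges} (two-column character matrix), \code{k}.
#' @examples
#' topo <- cage_topology(12)
#' topo$k
#' @export
cage_topology <- function(n_antennae, layout = c("grid", "ring"),
                          antenna_ids = NULL) {
  layout <- match.arg(layout)
  if (n_antennae < 2) stop("need at least 2 antennae")
  if (is.null(antenna_ids)) {
    antenna_ids <- sprintf("A%03d", seq_len(n_antennae))
  }
  if (anyDuplicated(antenna_ids)) stop("antenna ids must be unique")
  if (length(antenna_ids) != n_antennae) {
    stop("length of antenna_ids must equal n_antennae")
  }
  if (layout == "ring") {
    g <- igraph::make_ring(n_antennae)
  } else {
    nr <- floor(sqrt(n_antennae))
    nc <- ceiling(n_antennae / nr)
    g <- igraph::make_lattice(c(nr, nc))
    g <- igraph::induced_subgraph(g, seq_len(n_antennae))
    if (igraph::components(g)$no > 1) {
      # trailing lattice cells can detach when n is not a multiple of nr
      g <- igraph::add_edges(g, c(n_antennae - 1, n_antennae))
    }
  }
  e <- igraph::as_edgelist(g)
  edges <- cbind(antenna_ids[e[, 1]], antenna_ids[e[, 2]])
  new_cage_topology(antenna_ids, edges)
}

new_cage_topology <- function(antenna_ids, edges) {
  obj <- structure(
    list(antenna_ids = antenna_ids, edges = edges,
         k = length(antenna_ids)),
    class = "cage_topology"
  )
  validate_topology(obj)
  obj
}

validate_topology <- function(topo) {
  if (any(topo$edges[, 1] == topo$edges[, 2])) {
    stop("topology contains self-loops")
  }
  if (!all(topo$edges %in% topo$antenna_ids)) {
    stop("edge list refers to unknown antenna ids")
  }
  g <- topology_graph(topo)
  if (igraph::components(g)$no != 1) {
    stop("antenna graph must be connected")
  }
  invisible(topo)
}

topology_graph <- function(topo) {
  # vertices are named from the character edge matrix
  igraph::graph_from_edgelist(topo$edges, directed = FALSE)
}

#' @export
print.cage_topology <- function(x, ...) {
  cat("Cage topology:", x$k, "antennae,", nrow(x$edges), "tunnel edges\n")
  invisible(x)
}

#' Read / write an antenna topology edge list
#'
#' CSV with header \code{antenna_a,antenna_b}, one tunnel per row.
#'
#' @param path file path.
#' @return \code{read_topology} returns a \code{cage_topology}.
#' @export
read_topology <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  if (!all(c("antenna_a", "antenna_b") %in% names(df))) {
    stop("topology file needs columns antenna_a, antenna_b")
  }
  ids <- sort(unique(c(df$antenna_a, df$antenna_b)))
  new_cage_topology(ids, cbind(df$antenna_a, df$antenna_b))
}

#' @rdname read_topology
#' @param topo a \code{cage_topology}.
#' @export
write_topology <- function(topo, path) {
  utils::write.csv(
    data.frame(antenna_a = topo$edges[, 1], antenna_b = topo$edges[, 2]),
    path, row.names = FALSE, quote = FALSE
  )
  invisible(path)
}
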