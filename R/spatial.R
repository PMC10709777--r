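#' County adjacency structures for conditional autoregressive models
#'
#' An `adjacency` object stores the undirected county neighbour graph used by
#' the intrinsic conditional autoregressive (ICAR) prior: per-county neighbour
#' lists, degrees, and the connected-component labelling that determines how
#' many sum-to-zero constraints the improper prior needs.
#'
#' @name adjacency
NULL

new_adjacency <- function(county_ids, edges) {
  n <- length(county_ids)
  neighbors <- vector("list", n)
  if (nrow(edges) > 0) {
    for (e in seq_len(nrow(edges))) {
      a <- edges[e, 1L]; b <- edges[e, 2L]
      neighbors[[a]] <- c(neighbors[[a]], b)
      neighbors[[b]] <- c(neighbors[[b]], a)
    }
  }
  neighbors <- lapply(neighbors, function(x) sort(unique(x)))
  degree <- vapply(neighbors, length, integer(1))
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  comp <- igraph::components(g)
  structure(
    list(
      county_ids = county_ids,
      neighbors = neighbors,
      n_neighbors = degree,
      component = comp$membership[seq_len(n)],
      n_components = comp$no,
      edges = edges
    ),
    class = "adjacency"
  )
}

#' @export
print.adjacency <- function(x, ...) {
  cat(sprintf(
    "County adjacency: %d counties, %d edges, %d connected component(s)\n",
    length(x$county_ids), nrow(x$edges), x$n_components
  ))
  iso <- sum(x$n_neighbors == 0L)
  if (iso > 0) cat(sprintf("  %d isolated count%s\n", iso, if (iso == 1) "y" else "ies"))
  invisible(x)
}

#' Build an adjacency structure from an undirected edge list
#'
#' @param edges Either a path to a delimited edge-list file (two columns,
#'   `county_id_a,county_id_b`, one undirected pair per line, header optional)
#'   or a two-column character matrix / data frame of county id pairs.
#' @param county_ids Character vector of all county ids in the analysis panel;
#'   defines the vertex set and its order. Counties without any edge are kept
#'   as isolated vertices (their spatial effect is fixed at zero by the
#'   per-component centering).
#'
#' @return An object of class `adjacency`.
#'
#' @details Self-loops and references to unknown county ids are rejected.
#'   Duplicate pairs (in either orientation) are collapsed. Isolated counties
#'   are permitted but reported by `print()`, since they receive no spatial
#'   smoothing.
#' @export
load_adjacency <- function(edges, county_ids) {
  county_ids <- as.character(county_ids)
  if (anyDuplicated(county_ids)) stop("county_ids must be unique")
  if (is.character(edges) && length(edges) == 1L) {
    df <- utils::read.csv(edges, header = FALSE, colClasses = "character",
                          strip.white = TRUE)
    # tolerate a header line
    if (nrow(df) > 0 && !(df[1, 1] %in% county_ids) && !(df[1, 2] %in% county_ids)) {
      df <- df[-1, , drop = FALSE]
    }
    edges <- df
  }
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  storage.mode(edges) <- "character"
  if (nrow(edges) > 0) {
    if (any(edges[, 1] == edges[, 2])) {
      stop("self-loop in adjacency edge list: ",
           paste(unique(edges[edges[, 1] == edges[, 2], 1]), collapse = ", "))
    }
    ia <- match(edges[, 1], county_ids)
    ib <- match(edges[, 2], county_ids)
    if (anyNA(ia) || anyNA(ib)) {
      bad <- unique(c(edges[, 1][is.na(ia)], edges[, 2][is.na(ib)]))
      stop("adjacency references unknown county ids: ",
           paste(utils::head(bad, 5), collapse = ", "))
    }
    idx <- cbind(pmin(ia, ib), pmax(ia, ib))
    idx <- unique(idx)
  } else {
    idx <- matrix(integer(0), ncol = 2)
  }
  new_adjacency(county_ids, idx)
}

#' Rook adjacency for a rectangular lattice of synthetic counties
#'
#' @param n_rows,n_cols Lattice dimensions.
#' @param county_ids Optional ids (default zero-padded FIPS-like codes in
#'   row-major order).
#' @return An `adjacency` object with `2*n_rows*n_cols - n_rows - n_cols`
#'   undirected edges.
#' @export
lattice_adjacency <- function(n_rows, n_cols, county_ids = NULL) {
  n <- n_rows * n_cols
  if (is.null(county_ids)) county_ids <- sprintf("%05d", seq_len(n))
  stopifnot(length(county_ids) == n)
  # row-major index: county (r, c) -> (r-1)*n_cols + c
  idx <- function(r, c) (r - 1L) * n_cols + c
  e <- list()
  for (r in seq_len(n_rows)) {
    for (c in seq_len(n_cols)) {
      if (c < n_cols) e[[length(e) + 1L]] <- c(idx(r, c), idx(r, c + 1L))
      if (r < n_rows) e[[length(e) + 1L]] <- c(idx(r, c), idx(r + 1L, c))
    }
  }
  edges <- if (length(e)) do.call(rbind, e) else matrix(integer(0), ncol = 2)
  new_adjacency(county_ids, edges)
}

#' ICAR pairwise-difference penalty
#'
#' Computes the quadratic form of the intrinsic CAR prior,
#' \eqn{\sum_{i \sim j, i < j} (e_i - e_j)^2}, equal to \eqn{e^\top (D - W) e}
#' where \eqn{D} is the degree matrix and \eqn{W} the adjacency matrix.
#'
#' @param effects Numeric vector, one value per county in `structure`.
#' @param structure An `adjacency` object.
#' @return Non-negative scalar. Invariant under adding a constant to all
#'   effects within a connected component (the prior's flat direction).
#' @export
icar_quadratic_form <- function(effects, structure) {
  stopifnot(inherits(structure, "adjacency"))
  if (length(effects) != length(structure$county_ids)) {
    stop("effects must have one value per county (expected ",
         length(structure$county_ids), ", got ", length(effects), ")")
  }
  e <- structure$edges
  if (nrow(e) == 0) return(0)
  sum((effects[e[, 1]] - effects[e[, 2]])^2)
}

#' Sparse adjacency (W) matrix of an adjacency structure
#' @noRd
adjacency_matrix <- function(structure) {
  n <- length(structure$county_ids)
  e <- structure$edges
  if (nrow(e) == 0) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(n, n)))
  }
  Matrix::sparseMatrix(i = c(e[, 1], e[, 2]), j = c(e[, 2], e[, 1]),
                       x = 1, dims = c(n, n))
}

#' Greedy proper colouring of the county graph
#'
#' Counties sharing a colour have no edge between them, so their single-site
#' Metropolis updates have conditionally independent acceptance decisions and
#' can be vectorised. A rook lattice is 2-colourable (checkerboard).
#' @noRd
graph_coloring <- function(structure) {
  n <- length(structure$county_ids)
  color <- integer(n)
  ord <- order(-structure$n_neighbors)
  for (i in ord) {
    used <- color[structure$neighbors[[i]]]
    c0 <- 1L
    while (c0 %in% used) c0 <- c0 + 1L
    color[i] <- c0
  }
  color
}

#' Restrict an adjacency structure to a subset of counties
#' @noRd
subset_adjacency <- function(structure, keep_ids) {
  keep <- match(keep_ids, structure$county_ids)
  if (anyNA(keep)) stop("unknown county ids in subset")
  e <- structure$edges
  sel <- e[, 1] %in% keep & e[, 2] %in% keep
  remap <- match(seq_along(structure$county_ids), keep)
  e2 <- cbind(remap[e[sel, 1]], remap[e[sel, 2]])
  if (!is.matrix(e2)) e2 <- matrix(e2, ncol = 2)
  new_adjacency(structure$county_ids[keep], e2)
}

#' Sample a zero-centred intrinsic CAR field on a county graph
#'
#' Draws from the constrained Gaussian with pseudo-inverse covariance
#' proportional to \eqn{(D - W)^+}, scaled so the geometric mean of the
#' marginal variances equals `sd^2` (the conventional scaling that makes the
#' dispersion parameter comparable across graphs). Each connected component is
#' centred to sum to zero; singleton components get effect 0.
#'
#' @param structure An `adjacency` object.
#' @param sd Marginal standard-deviation scale of the field.
#' @return Numeric vector of length `n counties`.
#' @export
icar_sample <- function(structure, sd) {
  n <- length(structure$county_ids)
  u <- numeric(n)
  if (sd == 0 || n == 0) return(u)
  W <- as.matrix(adjacency_matrix(structure))
  for (cc in seq_len(structure$n_components)) {
    members <- which(structure$component == cc)
    m <- length(members)
    if (m < 2) next
    Q <- diag(structure$n_neighbors[members]) - W[members, members, drop = FALSE]
    eg <- eigen(Q, symmetric = TRUE)
    pos <- eg$values > max(eg$values) * 1e-10
    ev <- eg$values[pos]
    V <- eg$vectors[, pos, drop = FALSE]
    # generalized-inverse marginal variances, then geometric-mean scaling
    Qplus_diag <- rowSums(sweep(V^2, 2, ev, "/"))
    scale_fac <- exp(mean(log(Qplus_diag)))
    z <- stats::rnorm(length(ev), 0, 1 / sqrt(ev))
    ui <- as.vector(V %*% z) / sqrt(scale_fac) * sd
    u[members] <- ui - mean(ui)
  }
  u
}

#' Write an adjacency edge list to a delimited text file
#'
#' @param structure An `adjacency` object.
#' @param path Output file path.
#' @export
write_adjacency <- function(structure, path) {
  e <- structure$edges
  df <- data.frame(
    county_id_a = structure$county_ids[e[, 1]],
    county_id_b = structure$county_ids[e[, 2]]
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
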