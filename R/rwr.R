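#' Column-normalized transition matrix of an undirected graph
#'
#' Divides each column of the (unweighted) adjacency matrix by the node's
#' degree, so `W[i, j] = 1/degree(j)` for every edge and each column sums to
#' exactly 1. Isolated nodes have no outgoing probability and are dropped
#' with a warning before normalization.
#'
#' @param g An `lclmn`, `triple_network` or undirected igraph object.
#'
#' @return A sparse column-stochastic `Matrix` with node names as dimnames.
#' @export
column_normalize <- function(g) {
  ig <- to_igraph_input(g)
  deg <- igraph::degree(ig)
  if (any(deg == 0L)) {
    warning(sprintf("dropping %d isolated node(s)", sum(deg == 0L)))
    ig <- igraph::delete_vertices(ig, which(deg == 0L))
    deg <- igraph::degree(ig)
    if (any(deg == 0L)) {
      stop("isolated nodes remain after filtering", call. = FALSE)
    }
  }
  if (igraph::vcount(ig) == 0L) {
    stop("the graph has no connected nodes", call. = FALSE)
  }
  A <- igraph::as_adjacency_matrix(ig, sparse = TRUE)
  W <- A %*% Matrix::Diagonal(x = 1 / deg)
  dimnames(W) <- list(igraph::V(ig)$name, igraph::V(ig)$name)
  W
}

#' Random walk with restart: steady-state probability vector
#'
#' Iterates `p <- (1 - r) W p + r p0` from the seed distribution `p0`
#' (probability `1/n_seeds` on each seed node, 0 elsewhere) until the L1
#' difference between successive iterates falls below `tol`. Since `W` is
#' column-stochastic and `p0` sums to 1, every iterate (and the fixed point)
#' sums to 1.
#'
#' @param W Column-stochastic transition matrix from [column_normalize()].
#' @param seed_genes Character vector of seed node ids; ids absent from the
#'   graph are dropped with a warning, and an empty effective seed set is an
#'   error.
#' @param r Restart probability in `(0, 1)`, default 0.5.
#' @param tol L1 convergence threshold, default 1e-10.
#' @param max_iter Safety bound on iterations.
#'
#' @return Named numeric vector of steady-state probabilities.
#' @export
rwr_propagate <- function(W, seed_genes, r = 0.5, tol = 1e-10,
                          max_iter = 10000L) {
  stopifnot(r > 0, r < 1, tol > 0)
  nodes <- colnames(W)
  seeds <- intersect(seed_genes, nodes)
  if (length(seeds) < length(unique(seed_genes))) {
    warning(sprintf("%d seed gene(s) absent from the graph were dropped",
                    length(unique(seed_genes)) - length(seeds)))
  }
  if (length(seeds) == 0L) {
    stop("no seed gene is present in the graph", call. = FALSE)
  }
  p0 <- stats::setNames(numeric(length(nodes)), nodes)
  p0[seeds] <- 1 / length(seeds)
  p <- p0
  for (iter in seq_len(max_iter)) {
    p_new <- as.numeric((1 - r) * (W %*% p) + r * p0)
    if (sum(abs(p_new - p)) < tol) {
      return(stats::setNames(p_new, nodes))
    }
    p <- p_new
  }
  stop(sprintf(
    "random walk did not converge within %d iterations (last L1 change %.3g)",
    max_iter, sum(abs(p_new - p))), call. = FALSE)
}

#' RWR prioritization of candidate lncRNAs with permutation significance
#'
#' Runs the random walk with restart from disease seed genes (mRNA-side
#' nodes) on the bipartite ceRNA network and assesses each candidate lncRNA
#' empirically: for each of `n_perm` permutations a pseudo-seed set of the
#' same size is drawn uniformly without replacement (by default from the
#' network's mRNA nodes, leaving the topology untouched), the walk is rerun,
#' and `m_exceed` counts how often the permuted score strictly exceeds the
#' observed one. The permutation p-value is `m_exceed / n_perm`; a score
#' above every permuted value therefore gets p = 0.
#'
#' @param g An `lclmn` object or an igraph with a `class` vertex attribute
#'   distinguishing `"lncRNA"` from `"mRNA"` nodes.
#' @param seed_genes Character vector of seed gene ids; members absent from
#'   the network are dropped with a warning.
#' @param r Restart probability, default 0.5.
#' @param tol L1 convergence threshold, default 1e-10.
#' @param max_iter Iteration bound for each walk.
#' @param n_perm Number of permutations, default 5000.
#' @param rng_seed RNG seed making the permutations reproducible.
#' @param scheme `"seed_resample"` (default) redraws pseudo-seed sets on the
#'   fixed network; `"rewire"` instead rewires the network degree-preservingly
#'   each permutation and reruns the walk from the true seeds.
#'
#' @return An object of class `rwr_result`: list with `scores` (data frame
#'   `node`, `class`, `steady_prob` for every node) and `candidates` (data
#'   frame `node`, `steady_prob`, `m_exceed`, `perm_p` for lncRNA nodes,
#'   sorted ascending by `perm_p`), plus the configuration used.
#' @export
rwr_significance <- function(g, seed_genes, r = 0.5, tol = 1e-10,
                             max_iter = 10000L, n_perm = 5000L,
                             rng_seed = 1L,
                             scheme = c("seed_resample", "rewire")) {
  scheme <- match.arg(scheme)
  stopifnot(n_perm >= 1L)
  ig <- to_igraph_input(g)
  if (!"class" %in% igraph::vertex_attr_names(ig)) {
    stop("the graph needs a 'class' vertex attribute", call. = FALSE)
  }
  W <- column_normalize(ig)
  nodes <- colnames(W)
  node_class <- stats::setNames(igraph::V(ig)$class, igraph::V(ig)$name)
  node_class <- node_class[nodes]
  candidates <- nodes[node_class == "lncRNA"]
  eligible <- nodes[node_class == "mRNA"]

  obs <- rwr_propagate(W, seed_genes, r = r, tol = tol, max_iter = max_iter)
  n_seed <- length(intersect(seed_genes, nodes))
  if (scheme == "seed_resample" && length(eligible) < n_seed) {
    stop("fewer eligible mRNA nodes than seed genes; permutation infeasible",
         call. = FALSE)
  }

  m_exceed <- stats::setNames(integer(length(candidates)), candidates)
  with_seed(rng_seed, {
    for (b in seq_len(n_perm)) {
      perm <- if (scheme == "seed_resample") {
        rwr_propagate(W, sample(eligible, n_seed), r = r, tol = tol,
                      max_iter = max_iter)
      } else {
        rw <- igraph::rewire(
          ig, igraph::keeping_degseq(niter = 10L * igraph::ecount(ig)))
        rwr_propagate(column_normalize(rw), intersect(seed_genes, nodes),
                      r = r, tol = tol, max_iter = max_iter)
      }
      m_exceed <- m_exceed + (perm[candidates] > obs[candidates])
    }
  })

  cand <- data.frame(
    node = candidates,
    steady_prob = unname(obs[candidates]),
    m_exceed = unname(m_exceed),
    perm_p = unname(m_exceed) / n_perm,
    stringsAsFactors = FALSE
  )
  cand <- cand[order(cand$perm_p, -cand$steady_prob, cand$node), ,
               drop = FALSE]
  rownames(cand) <- NULL
  structure(
    list(
      scores = data.frame(node = nodes, class = unname(node_class),
                          steady_prob = unname(obs),
                          stringsAsFactors = FALSE),
      candidates = cand,
      seed_genes = intersect(seed_genes, nodes),
      r = r, tol = tol, n_perm = n_perm, rng_seed = rng_seed,
      scheme = scheme
    ),
    class = "rwr_result"
  )
}

#' @export
print.rwr_result <- function(x, ...) {
  cat(sprintf(
    "RWR prioritization: %d seeds, restart %.2g, %d permutations (%s)\n",
    length(x$seed_genes), x$r, x$n_perm, x$scheme))
  cat(sprintf("  %d candidate lncRNAs, %d at permutation p < 0.05\n",
              nrow(x$candidates), sum(x$candidates$perm_p < 0.05)))
  invisible(x)
}
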