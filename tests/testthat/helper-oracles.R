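# Independent brute-force oracles, deliberately written without reusing any
# package internals.

# upper-tail shared-miRNA probability by exhaustive subset enumeration:
# draw an n-subset from m miRNAs, count how often >= r fall in the mRNA's
# t-partner set
enum_hypergeom_tail <- function(t, n, r, m) {
  if (n == 0L) return(as.numeric(r == 0L))
  sets <- utils::combn(m, n)
  overlaps <- colSums(sets <= t)
  mean(overlaps >= r)
}

# all-pairs BFS with shortest-path counting; returns degree, unnormalized
# betweenness over unordered pairs, and reciprocal-sum closeness over the
# reachable set
brute_centralities <- function(edges, nodes) {
  n <- length(nodes)
  adj <- rep(list(integer(0)), n)
  for (row in seq_len(nrow(edges))) {
    a <- match(edges[row, 1L], nodes)
    b <- match(edges[row, 2L], nodes)
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  dist <- matrix(Inf, n, n)
  sigma <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); sg <- rep(0, n)
    d[s] <- 0; sg[s] <- 1
    frontier <- s
    while (length(frontier) > 0L) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- c(nxt, w)
          }
          if (d[w] == d[v] + 1) sg[w] <- sg[w] + sg[v]
        }
      }
      frontier <- unique(nxt)
    }
    dist[s, ] <- d
    sigma[s, ] <- sg
  }
  btw <- numeric(n)
  if (n >= 3L) {
    for (v in seq_len(n)) {
      tot <- 0
      for (s in seq_len(n - 1L)) {
        for (t in (s + 1L):n) {
          if (s == v || t == v || is.infinite(dist[s, t])) next
          if (dist[s, v] + dist[v, t] == dist[s, t]) {
            tot <- tot + sigma[s, v] * sigma[v, t] / sigma[s, t]
          }
        }
      }
      btw[v] <- tot
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    s <- sum(dist[v, is.finite(dist[v, ])])
    if (s > 0) 1 / s else 0
  }, numeric(1))
  data.frame(node = nodes, degree = lengths(adj), betweenness = btw,
             closeness = clo, stringsAsFactors = FALSE)
}

# from-scratch Pearson correlation and t-transform p-value
pearson_oracle <- function(x, y) {
  n <- length(x)
  cv <- sum((x - mean(x)) * (y - mean(y))) / (n - 1)
  r <- cv / (sd(x) * sd(y))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), df = n - 2))
}

# direct linear solve of the RWR fixed point (I - (1-r) W) p = r p0
rwr_solve_oracle <- function(W, seeds, r) {
  nodes <- colnames(W)
  p0 <- numeric(length(nodes))
  p0[match(seeds, nodes)] <- 1 / length(seeds)
  p <- solve(diag(length(nodes)) - (1 - r) * as.matrix(W), r * p0)
  stats::setNames(as.numeric(p), nodes)
}

# full enumeration of the 2^k sign-flip SAM null: one column per flip vector
enum_sam_null <- function(diffs, s0) {
  k <- ncol(diffs)
  flips <- as.matrix(expand.grid(rep(list(c(-1, 1)), k)))
  out <- matrix(0, nrow(diffs), nrow(flips))
  for (i in seq_len(nrow(flips))) {
    f <- flips[i, ]
    out[, i] <- apply(diffs, 1L, function(x) {
      xf <- x * f
      denom <- sd(xf) / sqrt(k) + s0
      if (denom == 0) 0 else mean(xf) / denom
    })
  }
  out
}

# random connected graph: spanning tree plus extra random edges
random_connected_graph <- function(n, extra = n) {
  tree <- cbind(2:n, vapply(2:n, function(v) sample.int(v - 1L, 1L), 1L))
  more <- cbind(sample.int(n, extra, replace = TRUE),
                sample.int(n, extra, replace = TRUE))
  more <- more[more[, 1L] != more[, 2L], , drop = FALSE]
  g <- igraph::graph_from_edgelist(rbind(tree, more), directed = FALSE)
  g <- igraph::simplify(g)
  igraph::V(g)$name <- sprintf("V%03d", seq_len(n))
  g
}

# random connected bipartite lncRNA/mRNA graph with class attributes
random_connected_bipartite <- function(n_lnc, n_mrna, p = 0.2) {
  repeat {
    g <- igraph::sample_bipartite(n_lnc, n_mrna, p = p)
    if (igraph::is_connected(g)) break
  }
  igraph::V(g)$name <- c(sprintf("L%02d", seq_len(n_lnc)),
                         sprintf("G%02d", seq_len(n_mrna)))
  igraph::V(g)$class <- rep(c("lncRNA", "mRNA"), c(n_lnc, n_mrna))
  g
}

# wrap an explicit lncRNA-mRNA edge list as an lclmn object
toy_lclmn <- function(lnc, mrna) {
  pairs <- data.frame(lnc = lnc, mrna = mrna, t = 1L, n = 1L, r = 1L,
                      m = 1L, p = 0, adjusted_p = 0,
                      stringsAsFactors = FALSE)
  build_lclmn(structure(pairs, class = c("cerna_pairs", "data.frame")),
              alpha = 0.5)
}
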