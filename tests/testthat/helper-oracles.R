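# Independent brute-force oracles for graph metrics, coded against plain
# adjacency matrices with no use of igraph or package internals.

# random undirected simple graph as a 0/1 adjacency matrix with named nodes
random_adjacency <- function(n, p = 0.25) {
  a <- matrix(0L, n, n)
  ids <- sprintf("n%02d", seq_len(n))
  dimnames(a) <- list(ids, ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (runif(1) < p) a[i, j] <- a[j, i] <- 1L
    }
  }
  a
}

adjacency_to_graph <- function(a, sign = "positive") {
  edges <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  social_graph(rownames(a),
               cbind(rownames(a)[edges[, 1]], rownames(a)[edges[, 2]]),
               sign = sign)
}

# Floyd-Warshall all-pairs shortest paths
oracle_distances <- function(a) {
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  d[a == 1] <- 1
  diag(d) <- 0
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
      }
    }
  }
  d
}

oracle_farness <- function(a, unreachable = nrow(a)) {
  d <- oracle_distances(a)
  d[is.infinite(d)] <- unreachable
  diag(d) <- 0
  setNames(rowSums(d), rownames(a))
}

# all simple paths from s to t by depth-first enumeration
all_simple_paths_brute <- function(a, s, t) {
  out <- list()
  walk <- function(path) {
    last <- path[length(path)]
    if (last == t) {
      out[[length(out) + 1]] <<- path
      return(invisible())
    }
    for (nb in which(a[last, ] == 1)) {
      if (!(nb %in% path)) walk(c(path, nb))
    }
  }
  walk(s)
  out
}

# Freeman betweenness with fractional credit, via exhaustive geodesic
# enumeration over unordered pairs
oracle_betweenness <- function(a) {
  n <- nrow(a)
  btw <- setNames(numeric(n), rownames(a))
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      paths <- all_simple_paths_brute(a, s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1))
      geodesics <- paths[lens == min(lens)]
      for (g in geodesics) {
        interior <- setdiff(g, c(s, t))
        btw[interior] <- btw[interior] + 1 / length(geodesics)
      }
    }
  }
  btw
}

oracle_components <- function(a) {
  n <- nrow(a)
  comp <- rep(0L, n)
  cur <- 0L
  for (start in seq_len(n)) {
    if (comp[start] > 0) next
    cur <- cur + 1L
    queue <- start
    comp[start] <- cur
    while (length(queue) > 0) {
      v <- queue[1]; queue <- queue[-1]
      for (nb in which(a[v, ] == 1)) {
        if (comp[nb] == 0) {
          comp[nb] <- cur
          queue <- c(queue, nb)
        }
      }
    }
  }
  comp
}

# articulation points by node-removal: removing v must increase the number
# of components among the remaining nodes
oracle_cutpoints <- function(a) {
  n <- nrow(a)
  base <- max(oracle_components(a))
  out <- setNames(integer(n), rownames(a))
  for (v in seq_len(n)) {
    sub <- a[-v, -v, drop = FALSE]
    if (nrow(sub) == 0) next
    out[v] <- as.integer(max(oracle_components(sub)) > base)
  }
  out
}

# biconnected components: edges are in the same block iff some simple cycle
# contains both; bridges are singleton blocks. Blocks returned as sorted
# node-identifier vectors, ordered by smallest member.
oracle_blocks <- function(a) {
  edges <- which(a == 1 & upper.tri(a), arr.ind = TRUE)
  m <- nrow(edges)
  if (m == 0) return(list())
  edge_id <- function(i, j) paste(min(i, j), max(i, j))
  key <- apply(edges, 1, function(e) edge_id(e[1], e[2]))
  parent <- seq_len(m)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  union_ <- function(x, y) parent[find(x)] <<- find(y)
  # every cycle through edge (u,v) = edge (u,v) + a simple path v->u that
  # does not use that edge
  for (e in seq_len(m)) {
    u <- edges[e, 1]; v <- edges[e, 2]
    a2 <- a
    a2[u, v] <- a2[v, u] <- 0
    for (path in all_simple_paths_brute(a2, v, u)) {
      cyc <- c(path, v)
      for (k in seq_len(length(cyc) - 1)) {
        other <- match(edge_id(cyc[k], cyc[k + 1]), key)
        union_(e, other)
      }
    }
  }
  classes <- split(seq_len(m), vapply(seq_len(m), find, integer(1)))
  blocks <- lapply(classes, function(es) {
    sort(unique(rownames(a)[as.vector(edges[es, , drop = FALSE])]))
  })
  unname(blocks[order(vapply(blocks, paste, character(1),
                             collapse = "\r"))])
}

# independent permutation enumeration (distinct algorithm from the package:
# recursive head-insertion vs the package's append-based builder)
oracle_permutations <- function(n) {
  if (n == 0) return(list(integer()))
  do.call(c, lapply(seq_len(n), function(k) {
    lapply(oracle_permutations(n - 1), function(p) {
      rest <- seq_len(n)[-k]
      c(k, rest[p])
    })
  }))
}

# exact Mantel p by full enumeration, coded independently
oracle_mantel_exact <- function(a, b) {
  n <- nrow(a)
  off <- !diag(n)
  r_obs <- cor(a[off], b[off])
  rs <- vapply(oracle_permutations(n), function(p) {
    cor(a[off], b[p, p][off])
  }, numeric(1))
  list(r = r_obs, p = sum(rs >= r_obs) / length(rs))
}

# random scan dataset on a grid of coordinates
random_scan_dataset <- function(n_ind = 8, days = 2, scans = 5, arena = 30) {
  ids <- sprintf("A%02d", seq_len(n_ind))
  grid <- expand.grid(day = seq_len(days), scan = seq_len(scans),
                      individual = ids, stringsAsFactors = FALSE)
  grid$x <- round(runif(nrow(grid), 0, arena), 3)
  grid$y <- round(runif(nrow(grid), 0, arena), 3)
  scan_data(grid)
}

random_count_matrix <- function(n, lambda = 6) {
  m <- matrix(rpois(n * n, lambda), n, n)
  diag(m) <- 0
  dimnames(m) <- list(sprintf("i%d", 1:n), sprintf("i%d", 1:n))
  m
}
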