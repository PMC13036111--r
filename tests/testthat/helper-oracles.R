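# Brute-force bridge-centrality oracle, independent of the package's
# igraph/Brandes code path: enumerates every simple path between every node
# pair by depth-first search, takes the minimum total length (edge length
# 1/|w|), and counts minimal paths directly. Exponential, so p <= 10 only.
oracle_bridge_indices <- function(network, tol = 1e-9) {
  W <- network$weights
  p <- nrow(W)
  comm <- network$community
  len <- ifelse(abs(W) > 0, 1 / abs(W), Inf)
  adj <- lapply(seq_len(p), function(i) which(abs(W[i, ]) > 0))

  # all simple paths s -> t: list of (length, interior nodes)
  enum_paths <- function(s, t) {
    out <- list()
    walk <- function(v, visited, d) {
      for (u in adj[[v]]) {
        if (u == t) {
          out[[length(out) + 1]] <<- list(d = d + len[v, u],
                                          interior = setdiff(visited, s))
        } else if (!(u %in% visited)) {
          walk(u, c(visited, u), d + len[v, u])
        }
      }
    }
    walk(s, s, 0)
    out
  }

  D <- matrix(Inf, p, p); diag(D) <- 0
  bb <- numeric(p)
  for (s in seq_len(p - 1)) {
    for (t in (s + 1):p) {
      paths <- enum_paths(s, t)
      if (!length(paths)) next
      ds <- vapply(paths, `[[`, numeric(1), "d")
      dmin <- min(ds)
      D[s, t] <- D[t, s] <- dmin
      if (comm[s] != comm[t]) {
        minimal <- paths[ds <= dmin + tol * (1 + dmin)]
        for (v in seq_len(p)) {
          through <- sum(vapply(minimal, function(pt) v %in% pt$interior, logical(1)))
          bb[v] <- bb[v] + through / length(minimal)
        }
      }
    }
  }

  cross <- outer(comm, comm, "!=")
  bc <- vapply(seq_len(p), function(i) {
    m <- mean(D[i, cross[i, ]])
    if (is.finite(m) && m > 0) 1 / m else 0
  }, numeric(1))
  list(
    expected_influence = rowSums(W),
    bridge_strength = rowSums(abs(W) * cross),
    bridge_expected_influence = rowSums(W * cross),
    bridge_betweenness = bb,
    bridge_closeness = bc
  )
}

# Step-up Benjamini-Hochberg adjustment written out directly (the hand
# oracle): sort, scale by m/i, enforce monotonicity from the largest p down.
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}
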