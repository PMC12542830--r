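# Independent oracles, deliberately naive: an O(n^2) Dijkstra over an
# explicit arc list, an exhaustive sliding-window BIVAT, and a
# linear-algebra point-in-tet test.  These share no path-search code with
# the package.

brute_dijkstra <- function(n, from, to, w, sources, onsets = NULL) {
  if (is.null(onsets)) onsets <- rep(0, length(sources))
  dist <- rep(Inf, n)
  dist[sources] <- pmin(dist[sources], onsets)
  done <- rep(FALSE, n)
  adj <- split(seq_along(from), from)
  repeat {
    u <- which(!done & is.finite(dist))
    if (!length(u)) break
    u <- u[which.min(dist[u])]
    done[u] <- TRUE
    ed <- adj[[as.character(u)]]
    for (k in ed) {
      v <- to[k]
      if (dist[u] + w[k] < dist[v]) dist[v] <- dist[u] + w[k]
    }
  }
  dist
}

brute_bivat <- function(times, fraction = 0.9) {
  st <- sort(times)
  n <- length(st)
  m <- ceiling(fraction * n)
  best <- Inf
  for (k in seq_len(n - m + 1))
    best <- min(best, st[k + m - 1] - st[k])
  best
}

# barycentric point-in-tet via solve(); boundary counts as inside
brute_point_in_tet <- function(p, v) {
  A <- cbind(v[2, ] - v[1, ], v[3, ] - v[1, ], v[4, ] - v[1, ])
  if (abs(det(A)) < 1e-12) return(FALSE)
  lam <- solve(A, p - v[1, ])
  all(lam >= -1e-9) && sum(lam) <= 1 + 1e-9
}

brute_edges_in_core <- function(tree, mesh, core) {
  mid <- (tree$nodes[tree$edges$a, , drop = FALSE] +
          tree$nodes[tree$edges$b, , drop = FALSE]) / 2
  out <- logical(nrow(mid))
  ct <- mesh$tets[core, , drop = FALSE]
  v1 <- mesh$nodes[ct[, 1], , drop = FALSE]
  v2 <- mesh$nodes[ct[, 2], , drop = FALSE]
  v3 <- mesh$nodes[ct[, 3], , drop = FALSE]
  v4 <- mesh$nodes[ct[, 4], , drop = FALSE]
  blo <- pmin(v1, v2, v3, v4); bhi <- pmax(v1, v2, v3, v4)
  for (e in seq_len(nrow(mid))) {
    p <- mid[e, ]
    cand <- which(blo[, 1] <= p[1] + 1e-9 & bhi[, 1] >= p[1] - 1e-9 &
                  blo[, 2] <= p[2] + 1e-9 & bhi[, 2] >= p[2] - 1e-9 &
                  blo[, 3] <= p[3] + 1e-9 & bhi[, 3] >= p[3] - 1e-9)
    for (t in cand) {
      v <- rbind(v1[t, ], v2[t, ], v3[t, ], v4[t, ])
      if (brute_point_in_tet(p, v)) { out[e] <- TRUE; break }
    }
  }
  out
}
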