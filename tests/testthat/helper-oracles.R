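# Independent brute-force oracles. These deliberately avoid the package's
# roster/join machinery and igraph: presence indicator matrices, pair-by-
# pair BFS, and exhaustive hypergeometric enumeration.

# Edge weights by brute force: a 0/1 admission x (unit, day) presence
# matrix; co-presence counts are its crossproduct. Checks every admission
# pair x every day x every unit.
oracle_edge_weights <- function(bundle, hospital, window) {
  adm <- bundle$admissions[bundle$admissions$hospital_id == hospital, ]
  stays <- bundle$stays[bundle$stays$admission_id %in% adm$admission_id, ]
  n_days <- as.integer(window[2] - window[1]) + 1L
  units <- sort(unique(stays$unit_id))
  ids <- sort(unique(adm$admission_id))
  # one column per (unit, day) cell
  P <- matrix(0L,
    nrow = length(ids), ncol = length(units) * n_days,
    dimnames = list(ids, NULL)
  )
  for (r in seq_len(nrow(stays))) {
    s <- stays[r, ]
    day_lo <- max(1L, as.integer(s$entry_date - window[1]) + 1L)
    day_hi <- min(n_days, as.integer(s$exit_date - window[1]) + 1L)
    if (day_lo > day_hi) next
    u <- match(s$unit_id, units)
    P[s$admission_id, (u - 1L) * n_days + (day_lo:day_hi)] <- 1L
  }
  W <- P %*% t(P)
  out <- list()
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (i < j && W[i, j] > 0) {
        out[[length(out) + 1]] <- data.frame(
          admission_a = ids[i], admission_b = ids[j], weight = W[i, j]
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(
      admission_a = character(), admission_b = character(), weight = integer()
    ))
  }
  res <- do.call(rbind, out)
  res[order(res$admission_a, res$admission_b), ]
}

# All-pairs BFS distances and shortest-path counts from one source on an
# adjacency matrix.
bfs_paths <- function(A, s) {
  n <- nrow(A)
  dist <- rep(Inf, n)
  sigma <- rep(0, n)
  dist[s] <- 0
  sigma[s] <- 1
  frontier <- s
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in which(A[v, ] == 1)) {
        if (is.infinite(dist[w])) {
          dist[w] <- dist[v] + 1
          nxt <- c(nxt, w)
        }
        if (dist[w] == dist[v] + 1) {
          sigma[w] <- sigma[w] + sigma[v]
        }
      }
    }
    frontier <- unique(nxt)
  }
  list(dist = dist, sigma = sigma)
}

# Betweenness of every vertex by explicit pair enumeration: for each
# unordered pair (s, t) and interior vertex v, add
# sigma_s(v) * sigma_t(v) / sigma_s(t) when v lies on a shortest path.
oracle_betweenness <- function(A) {
  n <- nrow(A)
  bfs <- lapply(seq_len(n), function(s) bfs_paths(A, s))
  btw <- rep(0, n)
  for (s in seq_len(n - 1)) {
    for (t in (s + 1):n) {
      if (is.infinite(bfs[[s]]$dist[t])) next
      dst <- bfs[[s]]$dist[t]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        if (bfs[[s]]$dist[v] + bfs[[t]]$dist[v] == dst) {
          btw[v] <- btw[v] + bfs[[s]]$sigma[v] * bfs[[t]]$sigma[v] / bfs[[s]]$sigma[t]
        }
      }
    }
  }
  btw
}

# Normalized closeness (n-1)/sum(d) on a connected adjacency matrix.
oracle_closeness <- function(A) {
  n <- nrow(A)
  vapply(seq_len(n), function(s) {
    dist <- bfs_paths(A, s)$dist
    (n - 1) / sum(dist[-s])
  }, numeric(1))
}

oracle_diameter <- function(A) {
  n <- nrow(A)
  max(vapply(seq_len(n), function(s) max(bfs_paths(A, s)$dist), numeric(1)))
}

# Base-R adjacency matrix of the simple unweighted graph of a network.
adjacency_of <- function(net) {
  ids <- net$nodes$admission_id
  A <- matrix(0L, length(ids), length(ids), dimnames = list(ids, ids))
  for (r in seq_len(nrow(net$edges))) {
    A[net$edges$admission_a[r], net$edges$admission_b[r]] <- 1L
    A[net$edges$admission_b[r], net$edges$admission_a[r]] <- 1L
  }
  A
}

# Largest connected component of an adjacency matrix, by BFS reachability.
giant_adjacency <- function(A) {
  n <- nrow(A)
  seen <- rep(FALSE, n)
  comps <- list()
  for (s in seq_len(n)) {
    if (seen[s]) next
    reach <- which(is.finite(bfs_paths(A, s)$dist))
    seen[reach] <- TRUE
    comps[[length(comps) + 1]] <- reach
  }
  giant <- comps[[which.max(lengths(comps))]]
  A[giant, giant, drop = FALSE]
}

# Two-sided Fisher exact p for a 2x2 table by exhaustive hypergeometric
# enumeration over all tables with the observed margins.
oracle_fisher_2x2 <- function(m) {
  stopifnot(all(dim(m) == c(2, 2)))
  r1 <- sum(m[1, ])
  c1 <- sum(m[, 1])
  n <- sum(m)
  lo <- max(0, c1 - (n - r1))
  hi <- min(r1, c1)
  probs <- stats::dhyper(lo:hi, r1, n - r1, c1)
  p_obs <- stats::dhyper(m[1, 1], r1, n - r1, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
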