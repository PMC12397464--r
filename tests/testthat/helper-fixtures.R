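# Shared fixtures, built in code.

# small random weighted undirected network (positive weights, symmetric)
random_network <- function(n, p_edge = 0.5, seed = 1) {
  set.seed(seed)
  w <- matrix(0, n, n)
  ut <- upper.tri(w)
  edges <- ut & (matrix(runif(n * n), n, n) < p_edge)
  w[edges] <- runif(sum(edges), 0.1, 1)
  w <- w + t(w)
  dimnames(w) <- list(paste0("N", 1:n), paste0("N", 1:n))
  structure(
    list(sparsity = 1, weights = w, n = n,
         retained_edges = sum(w[upper.tri(w)] > 0),
         subject_id = "fix", roi_names = rownames(w)),
    class = "netmed_network"
  )
}

# wrap a plain weight matrix as a netmed_network
as_network <- function(w) {
  dimnames(w) <- list(paste0("N", seq_len(nrow(w))), paste0("N", seq_len(nrow(w))))
  structure(
    list(sparsity = 1, weights = w, n = nrow(w),
         retained_edges = sum(w[upper.tri(w)] > 0),
         subject_id = "fix", roi_names = rownames(w)),
    class = "netmed_network"
  )
}

# independent Floyd–Warshall all-pairs shortest paths (edge length 1/weight)
fw_distances <- function(w) {
  n <- nrow(w)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[w > 0] <- 1 / w[w > 0]
  for (k in 1:n) for (i in 1:n) for (j in 1:n) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

# exhaustive simple-path enumeration oracle for weighted betweenness:
# enumerate all simple paths per pair, keep minimum-length ones, split
# credit fractionally among interior nodes. Only feasible for tiny n.
bf_betweenness <- function(w, tol = 1e-9) {
  n <- nrow(w)
  btw <- numeric(n)
  paths_between <- function(s, t) {
    out <- list()
    walk <- function(path, len) {
      last <- path[length(path)]
      if (last == t) {
        out[[length(out) + 1L]] <<- list(path = path, len = len)
        return()
      }
      for (v in which(w[last, ] > 0)) {
        if (!(v %in% path)) walk(c(path, v), len + 1 / w[last, v])
      }
    }
    walk(s, 0)
    out
  }
  for (s in 1:(n - 1)) for (t in (s + 1):n) {
    ps <- paths_between(s, t)
    if (length(ps) == 0) next
    lens <- vapply(ps, `[[`, numeric(1), "len")
    short <- ps[lens <= min(lens) + tol]
    for (sp in short) {
      interior <- setdiff(sp$path, c(s, t))
      # each shortest path contributes 1/(#shortest paths) to its interior nodes
      btw[interior] <- btw[interior] + 1 / length(short)
    }
  }
  btw
}

# small cohort for pipeline-level tests (fast: few subjects/ROIs/volumes)
tiny_cohort <- function(seed = 1, n_subjects = 12, n_rois = 10, n_volumes = 80) {
  simulate_cohort(n_subjects = n_subjects, n_rois = n_rois,
                  n_volumes = n_volumes, seed = seed)
}
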