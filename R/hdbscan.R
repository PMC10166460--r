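# Compact HDBSCAN for small 2-D point sets (dense distances).
#
# Pipeline: core distances (distance to the min_samples-th nearest other
# point) -> mutual reachability distances -> minimum spanning tree (Prim)
# -> single-linkage hierarchy -> condensed tree (clusters smaller than
# min_cluster_size fall out as noise spurs) -> excess-of-mass cluster
# selection (the root may be selected, so a fully degenerate point set
# forms one cluster). Lambda = 1/distance, capped for zero distances.

hdbscan_labels <- function(X, min_cluster_size, min_samples) {
  n <- nrow(X)
  D <- as.matrix(stats::dist(X))
  k <- min(min_samples, n - 1L)
  core <- apply(D, 1L, function(r) sort(r)[k + 1L])  # self (0) is first
  # mutual reachability
  MR <- pmax(D, outer(core, core, pmax))
  diag(MR) <- 0

  # Prim MST on dense MR
  in_tree <- logical(n)
  in_tree[1] <- TRUE
  best_d <- MR[1, ]
  best_from <- rep(1L, n)
  edges_a <- integer(n - 1L); edges_b <- integer(n - 1L)
  edges_w <- numeric(n - 1L)
  for (e in seq_len(n - 1L)) {
    cand <- which(!in_tree)
    v <- cand[which.min(best_d[cand])]
    edges_a[e] <- best_from[v]; edges_b[e] <- v; edges_w[e] <- best_d[v]
    in_tree[v] <- TRUE
    upd <- !in_tree & MR[v, ] < best_d
    best_d[upd] <- MR[v, upd]
    best_from[upd] <- v
  }

  # single-linkage hierarchy via union-find over sorted MST edges;
  # internal nodes n+1 .. 2n-1 with children and merge heights
  ord <- order(edges_w, edges_a, edges_b)  # deterministic tie-break
  parent <- seq_len(2L * n - 1L)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  node_of <- seq_len(n)          # current hierarchy node of each component
  child1 <- integer(n - 1L); child2 <- integer(n - 1L)
  height <- numeric(n - 1L)
  sizes <- c(rep(1L, n), integer(n - 1L))
  for (e in seq_len(n - 1L)) {
    i <- edges_a[ord[e]]; j <- edges_b[ord[e]]
    ri <- find(i); rj <- find(j)
    new_node <- n + e
    child1[e] <- node_of[ri]; child2[e] <- node_of[rj]
    height[e] <- edges_w[ord[e]]
    sizes[new_node] <- sizes[node_of[ri]] + sizes[node_of[rj]]
    parent[ri] <- rj
    node_of[rj] <- new_node
    node_of[ri] <- new_node
  }

  lam <- function(d) 1 / max(d, .Machine$double.eps)

  # condense: walk from the root, tracking the current condensed cluster
  # of each hierarchy node
  cc_parent <- integer(0)     # condensed-tree parent of each condensed id
  cc_birth <- numeric(0)      # birth lambda
  cc_stab <- numeric(0)       # accumulated stability
  new_cc <- function(parent_id, birth) {
    cc_parent <<- c(cc_parent, parent_id)
    cc_birth <<- c(cc_birth, birth)
    cc_stab <<- c(cc_stab, 0)
    length(cc_parent)
  }
  point_cc <- integer(n)      # condensed cluster each point fell out of
  point_lambda <- numeric(n)

  root_cc <- new_cc(0L, lam(height[n - 1L]))
  # stack of (hierarchy node, condensed id)
  stack_node <- c(2L * n - 1L)
  stack_cc <- c(root_cc)
  # collect all leaf points under a hierarchy node
  points_under <- function(node) {
    out <- integer(0); st <- node
    while (length(st) > 0) {
      x <- st[length(st)]; st <- st[-length(st)]
      if (x <= n) out <- c(out, x)
      else { e <- x - n; st <- c(st, child1[e], child2[e]) }
    }
    out
  }
  drop_points <- function(node, cc, lambda) {
    pts <- points_under(node)
    point_cc[pts] <<- cc
    point_lambda[pts] <<- lambda
    cc_stab[cc] <<- cc_stab[cc] + sum(pmin(lambda, Inf) - cc_birth[cc])
  }
  while (length(stack_node) > 0) {
    node <- stack_node[length(stack_node)]
    cc <- stack_cc[length(stack_cc)]
    stack_node <- stack_node[-length(stack_node)]
    stack_cc <- stack_cc[-length(stack_cc)]
    if (node <= n) { # singleton reaching max density inside cc
      point_cc[node] <- cc
      point_lambda[node] <- Inf
      next
    }
    e <- node - n
    l <- lam(height[e])
    c1 <- child1[e]; c2 <- child2[e]
    s1 <- sizes[c1]; s2 <- sizes[c2]
    big1 <- s1 >= min_cluster_size
    big2 <- s2 >= min_cluster_size
    if (big1 && big2) {
      # true split: cc dies here, two children are born
      pts <- points_under(node)
      cc_stab[cc] <- cc_stab[cc] + length(pts) * (l - cc_birth[cc])
      # points will be (re)assigned below the children; clear the split
      # contribution by tracking departure at the split lambda
      k1 <- new_cc(cc, l); k2 <- new_cc(cc, l)
      stack_node <- c(stack_node, c1, c2)
      stack_cc <- c(stack_cc, k1, k2)
    } else if (big1 && !big2) {
      drop_points(c2, cc, l)
      stack_node <- c(stack_node, c1)
      stack_cc <- c(stack_cc, cc)
    } else if (!big1 && big2) {
      drop_points(c1, cc, l)
      stack_node <- c(stack_node, c2)
      stack_cc <- c(stack_cc, cc)
    } else {
      drop_points(c1, cc, l)
      drop_points(c2, cc, l)
    }
  }

  # Stability bookkeeping: a cluster that splits credited each point up to
  # the split; points dropped later from child clusters accrue to those.
  # Fix double counting: points under a split were credited to cc via the
  # split term and will also be credited to descendants from their birth.
  # (The split term above already used departure lambda = split lambda, so
  # no double counting occurs.)

  n_cc <- length(cc_parent)
  # children lists
  kids <- vector("list", n_cc)
  for (kk in seq_len(n_cc)) {
    p <- cc_parent[kk]
    if (p > 0) kids[[p]] <- c(kids[[p]], kk)
  }
  sel_stab <- numeric(n_cc)
  selected <- logical(n_cc)
  # process deepest-first (ids increase with depth by construction)
  for (kk in rev(seq_len(n_cc))) {
    ch <- kids[[kk]]
    if (length(ch) == 0) {
      sel_stab[kk] <- cc_stab[kk]
      selected[kk] <- TRUE
    } else {
      child_sum <- sum(sel_stab[ch])
      if (cc_stab[kk] >= child_sum) {
        # ties favour the parent, so a fully degenerate point set (all
        # stabilities equal) condenses to the root: one cluster
        sel_stab[kk] <- cc_stab[kk]
        selected[kk] <- TRUE
      } else {
        sel_stab[kk] <- child_sum
      }
    }
  }
  # a selected ancestor deselects all descendants
  deselect_below <- function(kk) {
    for (ch in kids[[kk]]) {
      selected[ch] <<- FALSE
      deselect_below(ch)
    }
  }
  for (kk in seq_len(n_cc)) if (selected[kk]) deselect_below(kk)

  # label: nearest selected ancestor-or-self of the cluster the point
  # fell out of; none -> noise
  sel_ids <- which(selected)
  lab_of_cc <- integer(n_cc)
  for (kk in seq_len(n_cc)) {
    x <- kk
    lab <- 0L
    while (x > 0) {
      if (selected[x]) { lab <- match(x, sel_ids); break }
      x <- cc_parent[x]
    }
    lab_of_cc[kk] <- lab
  }
  labs <- lab_of_cc[point_cc]
  # renumber contiguously by first appearance for determinism
  nz <- labs != 0L
  labs[nz] <- as.integer(factor(labs[nz], levels = unique(labs[nz])))
  labs
}
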