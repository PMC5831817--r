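# Independent reference implementations used as oracles. Deliberately written
# in the most literal textbook form (full three-matrix DP, exhaustive
# enumeration) so they share no code with the package kernels.

# Affine-gap local alignment score: explicit H/E/F matrices, no recurrence
# sharing with the package's linear-space kernel. Gap of length k costs
# gap_open + k * gap_extend.
sw_oracle <- function(a, b, scheme = scoring_scheme()) {
  A <- parahoxmap:::aa_encode(a) + 1L
  B <- parahoxmap:::aa_encode(b) + 1L
  sub <- scheme$matrix
  go <- scheme$gap_open
  ge <- scheme$gap_extend
  n <- length(A)
  m <- length(B)
  H <- matrix(0, n + 1, m + 1)
  E <- matrix(-Inf, n + 1, m + 1)
  F <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n) + 1L) {
    for (j in seq_len(m) + 1L) {
      E[i, j] <- max(E[i, j - 1] - ge, H[i, j - 1] - go - ge)
      F[i, j] <- max(F[i - 1, j] - ge, H[i - 1, j] - go - ge)
      H[i, j] <- max(0, H[i - 1, j - 1] + sub[A[i - 1], B[j - 1]],
                     E[i, j], F[i, j])
      if (H[i, j] > best) best <- H[i, j]
    }
  }
  best
}

random_protein <- function(len, alphabet = AMINO_ACIDS) {
  paste0(sample(alphabet, len, replace = TRUE), collapse = "")
}

random_seqs <- function(n, len_range = c(30, 60), prefix = "s") {
  lens <- sample(len_range[1]:len_range[2], n, replace = TRUE)
  annotated_seqs(sprintf("%s%02d", prefix, seq_len(n)),
                 vapply(lens, random_protein, character(1)))
}

# --- exhaustive-search NJ oracle helpers (6-taxon additive matrices) -------

# all unrooted binary topologies over `labels`, as newick strings, built by
# inserting each new taxon on every edge of every smaller topology
all_topologies <- function(labels) {
  stopifnot(length(labels) >= 3)
  base <- list(list(edges = rbind(c("I1", labels[1]), c("I1", labels[2]),
                                  c("I1", labels[3])),
                    n_internal = 1L))
  trees <- base
  for (t in labels[-(1:3)]) {
    nxt <- list()
    for (tr in trees) {
      for (e in seq_len(nrow(tr$edges))) {
        ed <- tr$edges
        u <- ed[e, 1]; v <- ed[e, 2]
        new_int <- paste0("I", tr$n_internal + 1L)
        ed2 <- rbind(ed[-e, , drop = FALSE],
                     c(u, new_int), c(new_int, v), c(new_int, t))
        nxt[[length(nxt) + 1L]] <- list(edges = ed2,
                                        n_internal = tr$n_internal + 1L)
      }
    }
    trees <- nxt
  }
  trees
}

# leaf set under each edge (rooted arbitrarily at I1) -> canonical split key
topology_splits <- function(tr, labels) {
  edges <- tr$edges
  children <- split(edges[, 2], edges[, 1])
  below <- function(node) {
    if (!node %in% names(children)) return(node)
    unlist(lapply(children[[node]], below), use.names = FALSE)
  }
  keys <- vapply(seq_len(nrow(edges)), function(e) {
    s <- sort(below(edges[e, 2]))
    if (length(s) < 2 || length(s) > length(labels) - 2) return(NA_character_)
    comp <- sort(setdiff(labels, s))
    if (paste(s, collapse = ",") < paste(comp, collapse = ","))
      paste(s, collapse = ",") else paste(comp, collapse = ",")
  }, character(1))
  sort(keys[!is.na(keys)])
}

# per-pair path indicator matrix over the topology's edges
topology_design <- function(tr, labels) {
  edges <- tr$edges
  nodes <- unique(c(edges))
  adj <- lapply(setNames(vector("list", length(nodes)), nodes), identity)
  for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], e)
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], e)
  }
  other_end <- function(e, node) {
    if (edges[e, 1] == node) edges[e, 2] else edges[e, 1]
  }
  path_edges <- function(from, to) {
    # DFS over the tree
    stack <- list(list(node = from, used = integer(0), prev = ""))
    while (length(stack)) {
      cur <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      if (cur$node == to) return(cur$used)
      for (e in adj[[cur$node]]) {
        nx <- other_end(e, cur$node)
        if (nx != cur$prev) {
          stack[[length(stack) + 1L]] <-
            list(node = nx, used = c(cur$used, e), prev = cur$node)
        }
      }
    }
    stop("disconnected topology")
  }
  pairs <- t(combn(labels, 2))
  X <- matrix(0, nrow(pairs), nrow(edges))
  for (p in seq_len(nrow(pairs))) {
    X[p, path_edges(pairs[p, 1], pairs[p, 2])] <- 1
  }
  list(X = X, pairs = pairs)
}

# exhaustive least-squares search: the topology whose OLS fit to the distance
# matrix has the smallest residual sum of squares
exhaustive_nj_oracle <- function(D) {
  labels <- rownames(D)
  trees <- all_topologies(labels)
  pairs <- t(combn(labels, 2))
  d <- apply(pairs, 1, function(p) D[p[1], p[2]])
  rss <- vapply(trees, function(tr) {
    des <- topology_design(tr, labels)
    fit <- qr(des$X)
    sum((d - des$X %*% qr.coef(fit, d))^2)
  }, numeric(1))
  trees[[which.min(rss)]]
}

# splits of an ape phylo tree, same canonical keys as topology_splits
phylo_splits <- function(phylo) {
  tips <- phylo$tip.label
  n_tip <- length(tips)
  below <- vector("list", n_tip + phylo$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tips[i]
  ord <- ape::reorder.phylo(ape::unroot(phylo), "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    below[[ord[k, 1]]] <- c(below[[ord[k, 1]]], below[[ord[k, 2]]])
  }
  keys <- vapply(seq_len(nrow(ord)), function(k) {
    s <- sort(below[[ord[k, 2]]])
    if (length(s) < 2 || length(s) > n_tip - 2) return(NA_character_)
    comp <- sort(setdiff(tips, s))
    if (paste(s, collapse = ",") < paste(comp, collapse = ","))
      paste(s, collapse = ",") else paste(comp, collapse = ",")
  }, character(1))
  sort(unique(keys[!is.na(keys)]))
}

# random additive 6-taxon distance matrix plus its generating splits
random_additive_matrix <- function(labels = paste0("t", 1:6)) {
  trees <- all_topologies(labels)
  tr <- trees[[sample.int(length(trees), 1)]]
  bl <- runif(nrow(tr$edges), 0.05, 1)
  des <- topology_design(tr, labels)
  d <- as.numeric(des$X %*% bl)
  D <- matrix(0, length(labels), length(labels),
              dimnames = list(labels, labels))
  for (p in seq_len(nrow(des$pairs))) {
    D[des$pairs[p, 1], des$pairs[p, 2]] <- d[p]
    D[des$pairs[p, 2], des$pairs[p, 1]] <- d[p]
  }
  list(D = D, splits = topology_splits(tr, labels))
}
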