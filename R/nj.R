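#' Domain-window p-distance matrix
#'
#' Extracts each sequence's best-scoring 60-column domain window (a fixed
#' window, so extraction is an implicit alignment) and computes the pairwise
#' mismatch fraction over those columns. Uncorrected p-distances saturate
#' for fast-evolving groups and can violate the triangle inequality; that is
#' deliberate — it is the mechanism behind the long-branch-attraction
#' demonstration.
#'
#' @param seqs `annotated_seqs` data frame.
#' @param profile calibrated `profile_model`.
#' @return A `distance_matrix`: symmetric numeric matrix with zero diagonal
#'   and seq_id dimnames.
#' @export
domain_distance <- function(seqs, profile) {
  wins <- vapply(seq_len(nrow(seqs)), function(i) {
    h <- scan_sequence(profile, seqs$residues[i], seqs$seq_id[i])
    if (nrow(h) == 0) {
      stop("no domain hit in sequence: ", seqs$seq_id[i], call. = FALSE)
    }
    best <- h[which.max(h$score), ]
    substr(seqs$residues[i], best$start + 1, best$end)
  }, character(1))
  mat <- do.call(rbind, strsplit(wins, "", fixed = TRUE))
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(seqs$seq_id, seqs$seq_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      pd <- mean(mat[i, ] != mat[j, ])
      d[i, j] <- d[j, i] <- pd
    }
  }
  structure(d, class = c("distance_matrix", "matrix"))
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard NJ agglomeration via the Q-criterion
#' `Q(i,j) = (N-2) d(i,j) - r_i - r_j`; ties in the minimisation are broken
#' by the lexicographically smallest (sorted) label pair, so the result is
#' deterministic and invariant to input ordering up to leaf naming.
#' Negative branch lengths are clamped to zero by default (the clamp is
#' recorded in the result).
#'
#' @param D symmetric matrix with labels as dimnames and zero diagonal
#'   (>= 3 labels).
#' @param clamp_negative clamp negative branch lengths to zero?
#' @return An `inferred_tree`: list with `newick`, `phylo` (an [ape] tree)
#'   and `clamped_negative`.
#' @export
neighbor_joining <- function(D, clamp_negative = TRUE) {
  D <- unclass(D)
  if (nrow(D) < 3) stop("need at least 3 labels", call. = FALSE)
  if (max(abs(D - t(D))) > 1e-12) stop("non-symmetric distance matrix",
                                       call. = FALSE)
  labels <- rownames(D)
  sub <- setNames(labels, labels)           # label -> newick subtree
  clamped <- FALSE
  bl <- function(x) {
    if (x < 0 && clamp_negative) { clamped <<- TRUE; 0 } else x
  }
  fmt <- function(x) sprintf("%.10g", x)
  while (nrow(D) > 3) {
    N <- nrow(D)
    r <- rowSums(D)
    Q <- (N - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q <= qmin + 1e-12 & upper.tri(Q), arr.ind = TRUE)
    keys <- apply(cand, 1, function(ij) {
      p <- sort(c(rownames(D)[ij[1]], rownames(D)[ij[2]]))
      paste(p, collapse = "\r")
    })
    pick <- cand[order(keys)[1], ]
    i <- pick[1]; j <- pick[2]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (N - 2))
    vj <- D[i, j] - vi
    li <- rownames(D)[i]; lj <- rownames(D)[j]
    new_lab <- paste0("(", sub[[li]], ":", fmt(bl(vi)), ",",
                      sub[[lj]], ":", fmt(bl(vj)), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(N), c(i, j))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    u <- paste0("u", N)
    rownames(D2) <- colnames(D2) <- c(rownames(D)[keep], u)
    sub <- c(sub[rownames(D)[keep]], setNames(new_lab, u))
    D <- D2
  }
  # closed-form three-point resolution
  l <- rownames(D)
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  vc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  newick <- paste0("(", sub[[l[1]]], ":", fmt(bl(va)), ",",
                   sub[[l[2]]], ":", fmt(bl(vb)), ",",
                   sub[[l[3]]], ":", fmt(bl(vc)), ");")
  structure(list(newick = newick,
                 phylo = ape::read.tree(text = newick),
                 clamped_negative = clamped),
            class = "inferred_tree")
}

# leaf sets on each side of every internal edge of an unrooted tree
tree_bipartitions <- function(phylo) {
  tips <- phylo$tip.label
  n_tip <- length(tips)
  below <- vector("list", n_tip + phylo$Nnode)
  for (i in seq_len(n_tip)) below[[i]] <- tips[i]
  ord <- ape::reorder.phylo(phylo, "postorder")$edge
  for (k in seq_len(nrow(ord))) {
    p <- ord[k, 1]; ch <- ord[k, 2]
    below[[p]] <- c(below[[p]], below[[ch]])
  }
  sides <- lapply(seq_len(nrow(phylo$edge)), function(k) {
    below[[phylo$edge[k, 2]]]
  })
  c(sides, lapply(sides, function(s) setdiff(tips, s)))
}

#' Test whether two groups are attracted into an exclusive clade
#'
#' True iff the smallest bipartition side of the (unrooted) tree containing
#' every leaf of both groups contains no leaf from outside them — i.e. the
#' two groups form each other's exclusive neighborhood, the signature of
#' long-branch attraction when the generating topology kept them apart.
#'
#' @param tree `inferred_tree` (or an [ape] `phylo`).
#' @param group_a,group_b disjoint leaf label sets, each of size >= 2.
#' @param other_leaves leaves counting as intruders; default: every leaf not
#'   in `group_a` or `group_b`.
#' @return list with `attracted` (logical), `side` (the minimal side found)
#'   and `extra_leaves` (intruders inside it).
#' @export
attraction_check <- function(tree, group_a, group_b, other_leaves = NULL) {
  phylo <- if (inherits(tree, "inferred_tree")) tree$phylo else tree
  tips <- phylo$tip.label
  unknown <- setdiff(c(group_a, group_b), tips)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (length(intersect(group_a, group_b))) {
    stop("groups must be disjoint", call. = FALSE)
  }
  stopifnot(length(group_a) >= 2, length(group_b) >= 2)
  target <- union(group_a, group_b)
  if (is.null(other_leaves)) other_leaves <- setdiff(tips, target)
  sides <- tree_bipartitions(phylo)
  containing <- sides[vapply(sides, function(s) all(target %in% s),
                             logical(1))]
  smallest <- containing[[which.min(vapply(containing, length, integer(1)))]]
  extra <- intersect(setdiff(smallest, target), other_leaves)
  list(attracted = length(extra) == 0, side = sort(smallest),
       extra_leaves = sort(extra))
}
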