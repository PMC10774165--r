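# Distance-based phylogenetics for transporter clade assignment:
# Poisson-corrected pairwise-deletion distances, neighbor joining,
# bootstrap bipartition support, and clade assignment of unlabeled leaves.
# Trees are ape "phylo" objects throughout; Newick I/O goes through ape.

AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V")
MISSING_CHARS <- c("-", "X")   # gaps and ambiguous residues: deleted pairwise

#' Read an aligned amino-acid FASTA file
#'
#' Wrapped and case-insensitive input is accepted; sequences are upper-cased
#' and must all have the same (aligned) length.
#'
#' @param path FASTA path.
#' @return Named character vector of aligned sequences.
#' @export
read_fasta_alignment <- function(path) {
  ss <- Biostrings::readBStringSet(path)
  aln <- toupper(as.character(ss))
  validate_alignment(aln)
  aln
}

#' Write an aligned FASTA file
#'
#' @param aln Named character vector of equal-length sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta_alignment <- function(aln, path) {
  validate_alignment(aln)
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln), path, width = 60L)
  invisible(path)
}

validate_alignment <- function(aln) {
  if (is.null(names(aln)) || anyDuplicated(names(aln)))
    stop("alignment sequences must have unique names")
  if (length(unique(nchar(aln))) != 1L)
    stop("aligned sequences must all have the same length")
  invisible(aln)
}

alignment_matrix <- function(aln) {
  validate_alignment(aln)
  m <- do.call(rbind, strsplit(toupper(unname(aln)), ""))
  rownames(m) <- names(aln)
  m
}

#' Poisson-corrected distance between two aligned sequences
#'
#' Sites where either sequence carries a gap (`-`) or ambiguity (`X`) are
#' excluded for this pair (pairwise deletion). With `p` the proportion of
#' differing sites among those compared, the Poisson multiple-hit correction
#' gives `d = -ln(1 - p)`. Saturated pairs (`p >= p_cap`) are capped at
#' `-ln(1 - p_cap)` and flagged instead of erroring, so that very distant
#' pairs in a diverse transporter set keep a finite distance.
#'
#' @param a,b Aligned sequences (equal-length strings).
#' @param p_cap Saturation cap on p (default 0.99).
#' @return List with `d`, `p`, `n_sites` (sites compared), `capped`.
#' @export
poisson_distance <- function(a, b, p_cap = 0.99) {
  av <- strsplit(toupper(a), "")[[1L]]
  bv <- strsplit(toupper(b), "")[[1L]]
  if (length(av) != length(bv)) stop("sequences differ in aligned length")
  ok <- !(av %in% MISSING_CHARS) & !(bv %in% MISSING_CHARS)
  n <- sum(ok)
  if (n == 0L) stop("no overlapping sites after pairwise deletion")
  p <- sum(av[ok] != bv[ok]) / n
  capped <- p >= p_cap
  d <- -log(1 - min(p, p_cap))
  list(d = d, p = p, n_sites = n, capped = capped)
}

#' Poisson distance matrix for an alignment
#'
#' All pairwise [poisson_distance()] values, symmetric by construction.
#'
#' @param aln Named character vector of aligned sequences.
#' @param p_cap Saturation cap on p.
#' @return Symmetric numeric matrix with attributes `n_sites` (matrix of
#'   sites compared per pair) and `capped` (logical matrix).
#' @export
poisson_distance_matrix <- function(aln, p_cap = 0.99) {
  M <- alignment_matrix(aln)
  n <- nrow(M)
  if (n < 2L) stop("need >= 2 sequences")
  miss <- matrix(M %in% MISSING_CHARS, n, ncol(M))
  d <- matrix(0, n, n, dimnames = list(rownames(M), rownames(M)))
  ns <- matrix(ncol(M), n, n, dimnames = dimnames(d))
  cap <- matrix(FALSE, n, n, dimnames = dimnames(d))
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !miss[i, ] & !miss[j, ]
    m <- sum(ok)
    if (m == 0L)
      stop("no overlapping sites for pair ", rownames(M)[i], " / ",
           rownames(M)[j])
    p <- sum(M[i, ok] != M[j, ok]) / m
    cap[i, j] <- cap[j, i] <- p >= p_cap
    d[i, j] <- d[j, i] <- -log(1 - min(p, p_cap))
    ns[i, j] <- ns[j, i] <- m
  }
  attr(d, "n_sites") <- ns
  attr(d, "capped") <- cap
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration: repeatedly join the pair minimizing
#' `Q(i, j) = (n - 2) d(i, j) - sum_k d(i, k) - sum_k d(j, k)`, with branch
#' lengths from the standard formulas. Q-ties are broken by the smallest
#' index pair, negative estimated branch lengths are clamped to zero (the
#' `n_clamped` attribute counts them), and the returned tree is unrooted.
#' NJ is consistent: on additive distances it reproduces the generating tree
#' exactly.
#'
#' @param d Symmetric distance matrix (or `dist`) with labels; `n >= 2`
#'   (`n = 2` yields the single-edge tree).
#' @return An unrooted ape `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (inherits(d, "dist")) d <- as.matrix(d)
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("d must be square")
  if (!isSymmetric(unname(d), tol = 1e-8)) stop("distance matrix is not symmetric")
  n <- nrow(d)
  labels <- rownames(d) %||% paste0("t", seq_len(n))
  if (n < 2L) stop("need >= 2 taxa")
  n_clamped <- 0L
  clamp <- function(x) {
    if (x < 0) { n_clamped <<- n_clamped + 1L; 0 } else x
  }
  fmt <- function(x) sprintf("%.15g", x)
  sub <- labels                       # Newick fragment per active node
  D <- unname(d)
  if (n == 2L) {
    txt <- paste0("(", sub[1L], ":", fmt(D[1, 2] / 2), ",", sub[2L], ":",
                  fmt(D[1, 2] / 2), ");")
    tr <- ape::read.tree(text = txt)
    attr(tr, "n_clamped") <- 0L
    return(tr)
  }
  while (length(sub) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    cand <- cand[order(cand[, 1L], cand[, 2L]), , drop = FALSE]
    i <- cand[1L, 1L]; j <- cand[1L, 2L]
    li <- clamp(D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2)))
    lj <- clamp(D[i, j] - (D[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))))
    newsub <- paste0("(", sub[i], ":", fmt(li), ",", sub[j], ":", fmt(lj), ")")
    du <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], du[keep]), c(du[keep], 0))
    sub <- c(sub[keep], newsub)
  }
  # final three-way join at the central node
  la <- clamp((D[1, 2] + D[1, 3] - D[2, 3]) / 2)
  lb <- clamp((D[1, 2] + D[2, 3] - D[1, 3]) / 2)
  lc <- clamp((D[1, 3] + D[2, 3] - D[1, 2]) / 2)
  txt <- paste0("(", sub[1L], ":", fmt(la), ",", sub[2L], ":", fmt(lb), ",",
                sub[3L], ":", fmt(lc), ");")
  tr <- ape::read.tree(text = txt)
  attr(tr, "n_clamped") <- n_clamped
  tr
}

# Non-trivial bipartitions of an unrooted tree as canonical strings.
# Each internal edge splits the leaves in two; the side not containing the
# alphabetically first label, sorted and joined, is the canonical key.
tree_bipartitions <- function(tree) {
  n <- length(tree$tip.label)
  if (is.null(tree$edge)) return(character(0))
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  anchor <- sort(tree$tip.label)[1L]
  keys <- character(0)
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2L]
    if (ch <= n) next                       # trivial split
    side <- tree$tip.label[desc[[ch]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Resamples alignment columns with replacement, recomputes the Poisson
#' distance matrix and NJ tree per replicate, and scores each internal edge
#' of the original tree by the fraction of replicate trees containing the
#' same leaf bipartition (classical bootstrap on the displayed tree, not a
#' consensus tree). Replicates in which some pair loses all overlapping
#' sites are skipped with a warning and removed from the denominator.
#'
#' @param aln Named character vector of aligned sequences.
#' @param n_reps Number of bootstrap replicates (default 1000).
#' @param seed Integer seed; identical seeds give identical supports.
#' @param p_cap Saturation cap passed to the distance computation.
#' @return The original NJ `phylo` tree with internal `node.label` set to
#'   support in `[0, 1]` (root label empty) and attributes `support`
#'   (named vector keyed by bipartition) and `n_effective_reps`.
#' @export
bootstrap_support <- function(aln, n_reps = 1000, seed = 1, p_cap = 0.99) {
  validate_alignment(aln)
  if (n_reps < 1L) stop("n_reps must be >= 1")
  d0 <- poisson_distance_matrix(aln, p_cap)
  tree <- neighbor_joining(d0)
  orig <- tree_bipartitions(tree)
  counts <- stats::setNames(numeric(length(orig)), orig)
  L <- nchar(aln[[1L]])
  M <- alignment_matrix(aln)
  eff <- 0L
  withr::with_seed(seed, {
    for (rep in seq_len(n_reps)) {
      cols <- sample.int(L, L, replace = TRUE)
      rep_aln <- apply(M[, cols, drop = FALSE], 1L, paste, collapse = "")
      names(rep_aln) <- rownames(M)
      dres <- tryCatch(poisson_distance_matrix(rep_aln, p_cap),
                       error = function(e) NULL)
      if (is.null(dres)) {
        warning("bootstrap replicate ", rep,
                " skipped: a pair has no overlapping sites")
        next
      }
      eff <- eff + 1L
      bp <- tree_bipartitions(neighbor_joining(dres))
      hit <- orig %in% bp
      counts[hit] <- counts[hit] + 1
    }
  })
  support <- if (eff > 0L) counts / eff else counts * NA_real_
  # map support onto internal nodes via each node's bipartition key
  n <- length(tree$tip.label)
  node_keys <- node_bipartition_keys(tree)
  lab <- character(tree$Nnode)
  for (k in seq_len(tree$Nnode)) {
    key <- node_keys[[k]]
    lab[k] <- if (!is.null(key) && key %in% names(support))
      format(support[[key]], digits = 4) else ""
  }
  tree$node.label <- lab
  attr(tree, "support") <- support
  attr(tree, "n_effective_reps") <- eff
  tree
}

# bipartition key per internal node (index within node.label ordering),
# NULL for nodes whose edge defines a trivial split (or the root)
node_bipartition_keys <- function(tree) {
  n <- length(tree$tip.label)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  anchor <- sort(tree$tip.label)[1L]
  keys <- vector("list", tree$Nnode)
  for (node in (n + 1L):(n + tree$Nnode)) {
    side <- tree$tip.label[desc[[node]]]
    if (length(side) <= 1L || length(side) >= n - 1L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys[[node - n]] <- paste(sort(side), collapse = "|")
  }
  keys
}

#' Assign uncharacterized leaves to reference clades
#'
#' A query leaf is assigned clade X when its smallest enclosing clade-pure
#' subtree — a side of some tree edge that contains the query and at least
#' one reference leaf, all of whose reference leaves belong to clade X, with
#' the subtending edge's bootstrap support at or above `threshold` — exists
#' and is unambiguous: if several pure subtrees of that minimal size give
#' conflicting clades (the situation of a query attached to the backbone
#' between clades), the query is returned as `"unplaced"`, as it is when no
#' qualifying subtree exists at all. Edges without a support value
#' (including trivial splits) are treated as support 1.
#'
#' @param tree A `phylo` tree, optionally with supports from
#'   [bootstrap_support()].
#' @param reference Named character vector: leaf name -> clade label. Must
#'   cover at least two clades; query names must not collide with it.
#' @param threshold Minimum support of the subtending edge (default 0.5).
#' @return Named character vector query leaf -> clade or `"unplaced"`.
#' @export
assign_clades <- function(tree, reference, threshold = 0.5) {
  tips <- tree$tip.label
  if (!all(names(reference) %in% tips))
    stop("reference labels not in tree: ",
         paste(setdiff(names(reference), tips), collapse = ", "))
  if (length(unique(reference)) < 2L)
    stop("reference must cover >= 2 clades")
  queries <- setdiff(tips, names(reference))
  if (any(queries %in% names(reference)))
    stop("query names collide with reference names")
  n <- length(tips)
  po <- ape::reorder.phylo(tree, "postorder")
  desc <- vector("list", n + tree$Nnode)
  for (i in seq_len(n)) desc[[i]] <- i
  for (e in seq_len(nrow(po$edge))) {
    p <- po$edge[e, 1L]; ch <- po$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  node_support <- function(node) {
    if (node <= n || is.null(tree$node.label)) return(1)
    lab <- tree$node.label[node - n]
    if (is.na(lab) || !nzchar(lab)) return(1)
    as.numeric(lab)
  }
  # candidate subtrees: for every edge, both sides; support is the edge's
  sides <- list()
  for (e in seq_len(nrow(po$edge))) {
    ch <- po$edge[e, 2L]
    inside <- tips[desc[[ch]]]
    sup <- node_support(ch)
    sides[[length(sides) + 1L]] <- list(tips = inside, support = sup)
    sides[[length(sides) + 1L]] <- list(tips = setdiff(tips, inside),
                                        support = sup)
  }
  out <- stats::setNames(rep("unplaced", length(queries)), queries)
  for (q in queries) {
    best_size <- Inf; best_clades <- character(0)
    for (s in sides) {
      if (!(q %in% s$tips)) next
      refs <- intersect(s$tips, names(reference))
      if (length(refs) == 0L) next
      clades <- unique(unname(reference[refs]))
      if (length(clades) != 1L) next
      if (s$support < threshold) next
      if (length(s$tips) < best_size) {
        best_size <- length(s$tips); best_clades <- clades
      } else if (length(s$tips) == best_size) {
        best_clades <- union(best_clades, clades)
      }
    }
    # ambiguous minimal subtrees (conflicting clades) leave the query unplaced
    if (length(best_clades) == 1L) out[q] <- best_clades
  }
  out
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` tree (internal node labels, e.g. bootstrap
#'   supports, are preserved).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#'
#' @param path Newick file path.
#' @return A `phylo` tree.
#' @export
read_newick <- function(path) {
  ape::read.tree(path)
}
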