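# Distance-based phylogeny: p-distances, Saitou-Nei neighbor joining with
# deterministic tie-breaking, column-bootstrap supports, and
# reference-guided subfamily assignment.

#' Pairwise p-distance matrix from a protein alignment
#'
#' Proportion of differing residues over columns where both rows are
#' ungapped (pairwise deletion).
#'
#' @param aln A `MultipleAlignment` (or named character vector of
#'   equal-length gapped rows).
#' @param correction `"none"` for raw p-distance (default) or `"poisson"`
#'   for -log(1 - p).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  rows <- if (inherits(aln, "MultipleAlignment")) aln$rows else aln
  if (length(rows) < 2L) stop("need at least 2 aligned rows")
  mat <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(mat) <- names(rows)
  n <- nrow(mat)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- mat[i, ] != "-" & mat[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable columns between ", names(rows)[i], " and ",
             names(rows)[j])
      }
      p <- mean(mat[i, ok] != mat[j, ok])
      if (correction == "poisson") {
        if (p >= 1) stop("Poisson correction undefined at p = 1")
        p <- -log(1 - p)
      }
      d[i, j] <- d[j, i] <- p
    }
  }
  d
}

#' Neighbor-joining tree (Saitou-Nei)
#'
#' Joins the pair minimizing the Q criterion; ties are broken by the
#' smallest (i, j) index pair in the current matrix order, so the result is
#' deterministic. Negative branch lengths are clamped to zero with the
#' deficit transferred to the sibling branch (path lengths through the new
#' node are preserved).
#'
#' @param dm Symmetric distance matrix with row/col names (n >= 3).
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(dm) {
  if (!isSymmetric(unname(dm), tol = 1e-8)) {
    stop("distance matrix must be symmetric")
  }
  n <- nrow(dm)
  if (n < 3L) stop("need at least 3 taxa")
  ids <- rownames(dm)
  if (is.null(ids)) stop("distance matrix must carry taxon names")
  frag <- ids                 # newick fragment per active cluster
  D <- dm
  while (nrow(D) > 3L) {
    m <- nrow(D)
    r <- rowSums(D)
    Q <- (m - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1L] < idx[, 2L], , drop = FALSE]
    idx <- idx[order(idx[, 1L], idx[, 2L]), , drop = FALSE]
    a <- idx[1L, 1L]; b <- idx[1L, 2L]
    la <- D[a, b] / 2 + (r[a] - r[b]) / (2 * (m - 2))
    lb <- D[a, b] - la
    cl <- .clamp_pair(la, lb)
    newfrag <- sprintf("(%s:%.10g,%s:%.10g)", frag[a], cl[1L],
                       frag[b], cl[2L])
    dnew <- (D[a, ] + D[b, ] - D[a, b]) / 2
    keep <- setdiff(seq_len(m), c(a, b))
    D2 <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
                c(dnew[keep], 0))
    frag <- c(frag[keep], newfrag)
    rownames(D2) <- colnames(D2) <- seq_len(m - 1L)
    D <- D2
  }
  # resolve the final three clusters around the central node exactly
  la <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  lb <- (D[1, 2] + D[2, 3] - D[1, 3]) / 2
  lc <- (D[1, 3] + D[2, 3] - D[1, 2]) / 2
  l <- pmax(c(la, lb, lc), 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);", frag[1L], l[1L],
                 frag[2L], l[2L], frag[3L], l[3L])
  ape::read.tree(text = nwk)
}

.clamp_pair <- function(la, lb) {
  if (la < 0) { lb <- lb + la; la <- 0 }
  if (lb < 0) { la <- max(0, la + lb); lb <- 0 }
  c(la, lb)
}

# canonical bipartition keys of the non-trivial splits of a tree
.tree_splits <- function(tree, all_tips = sort(tree$tip.label)) {
  nt <- length(tree$tip.label)
  internal <- setdiff(unique(tree$edge[, 2L]), seq_len(nt))
  keys <- character(0)
  for (node in internal) {
    tips <- ape::extract.clade(tree, node)$tip.label
    if (length(tips) <= 1L || length(tips) >= nt - 1L) next
    side <- sort(tips)
    if (all_tips[1L] %in% side) side <- setdiff(all_tips, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  stats::setNames(keys, internal)
}

#' Bootstrap supports for a neighbor-joining protein tree
#'
#' Columns of the alignment are resampled with replacement `n_reps` times;
#' each replicate alignment yields a p-distance NJ tree, and the support of
#' each internal bipartition of the original tree is the percentage of
#' replicate trees containing it. Fully seed-deterministic.
#'
#' @param aln A `MultipleAlignment` with at least 10 columns.
#' @param n_reps Number of bootstrap replicates.
#' @param seed Integer RNG seed.
#' @return List of class `PhyloTree`: `tree` (`ape::phylo`, node labels
#'   carry supports), `supports` (named percentage vector keyed by
#'   bipartition), `n_reps`.
#' @export
bootstrap_supports <- function(aln, n_reps = 1000L, seed = 1L) {
  stopifnot(inherits(aln, "MultipleAlignment"))
  width <- nchar(aln$rows[[1L]])
  if (width < 10L) stop("alignment has fewer than 10 columns")
  mat <- do.call(rbind, strsplit(unname(aln$rows), ""))
  rownames(mat) <- names(aln$rows)
  base_tree <- neighbor_joining(p_distance(aln))
  all_tips <- sort(names(aln$rows))
  base_splits <- .tree_splits(base_tree, all_tips)
  counts <- stats::setNames(numeric(length(base_splits)), base_splits)
  set.seed(seed)
  done <- 0L
  for (rep in seq_len(n_reps)) {
    cols <- sample.int(width, width, replace = TRUE)
    rows <- apply(mat[, cols, drop = FALSE], 1L, paste, collapse = "")
    tr <- tryCatch(neighbor_joining(p_distance(rows)),
                   error = function(e) NULL)
    if (is.null(tr)) next
    done <- done + 1L
    reps <- unique(.tree_splits(tr, all_tips))
    hit <- base_splits %in% reps
    counts[base_splits[hit]] <- counts[base_splits[hit]] + 1
  }
  supports <- 100 * counts / max(1L, done)
  tree <- base_tree
  nt <- length(tree$tip.label)
  labs <- rep(NA_character_, tree$Nnode)
  for (i in seq_along(base_splits)) {
    node <- as.integer(names(base_splits)[i])
    labs[node - nt] <- sprintf("%.0f", supports[i])
  }
  tree$node.label <- labs
  structure(list(tree = tree, supports = supports, n_reps = done),
            class = "PhyloTree")
}

#' @export
print.PhyloTree <- function(x, ...) {
  cat(sprintf("<PhyloTree> %d tips, %d bootstrap replicates\n",
              length(x$tree$tip.label), x$n_reps))
  invisible(x)
}

#' Assign subfamilies and names by homology to labeled references
#'
#' Each candidate receives the subfamily/subgroup of its highest-identity
#' labeled reference (global-alignment identity). Candidates below
#' `min_identity` to every reference are left unclassified; candidates
#' whose two best references come from different subfamilies within
#' `ambiguity_margin` percentage points are flagged ambiguous and, when a
#' tree over candidates and references is supplied, resolved by the nearest
#' reference in patristic distance. Assigned names are
#' `<prefix><subgroup>.<rank>` with ranks ordered by descending identity
#' within each subgroup.
#'
#' @param candidates Named character vector of candidate proteins.
#' @param references data.frame with columns `ref_id`, `subfamily`,
#'   `subgroup`, `sequence`.
#' @param prefix Name prefix (e.g. `"Pgr"`).
#' @param tree Optional `ape::phylo` containing candidate and reference
#'   tips, used to resolve ambiguous calls.
#' @param min_identity Percent identity below which a candidate is
#'   unclassified.
#' @param ambiguity_margin Percentage-point margin defining ambiguity.
#' @return data.frame: `gene_id`, `subfamily`, `subgroup`, `assigned_name`,
#'   `best_reference`, `identity`, `ambiguous`, `classified`.
#' @export
assign_subfamilies <- function(candidates, references, prefix = "Aqp",
                               tree = NULL, min_identity = 25,
                               ambiguity_margin = 1) {
  stopifnot(all(c("ref_id", "subfamily", "subgroup", "sequence") %in%
                  names(references)), length(candidates) > 0L)
  idm <- matrix(NA_real_, length(candidates), nrow(references),
                dimnames = list(names(candidates), references$ref_id))
  for (i in seq_along(candidates)) {
    for (j in seq_len(nrow(references))) {
      idm[i, j] <- global_identity(candidates[[i]], references$sequence[j])
    }
  }
  patristic <- if (!is.null(tree)) stats::cophenetic(tree) else NULL
  rows <- lapply(seq_along(candidates), function(i) {
    id <- names(candidates)[i]
    ord <- order(-idm[i, ])
    best <- ord[1L]
    best_idty <- idm[i, best]
    if (best_idty < min_identity) {
      return(data.frame(gene_id = id, subfamily = NA_character_,
                        subgroup = NA_character_,
                        assigned_name = NA_character_,
                        best_reference = references$ref_id[best],
                        identity = best_idty, ambiguous = FALSE,
                        classified = FALSE, stringsAsFactors = FALSE))
    }
    fam <- references$subfamily[best]
    grp <- references$subgroup[best]
    ref <- references$ref_id[best]
    amb <- FALSE
    other <- ord[references$subfamily[ord] != fam][1L]
    if (!is.na(other) && best_idty - idm[i, other] < ambiguity_margin) {
      amb <- TRUE
      if (!is.null(patristic) && id %in% rownames(patristic)) {
        refs_in_tree <- intersect(references$ref_id, colnames(patristic))
        if (length(refs_in_tree) > 0L) {
          nearest <- refs_in_tree[which.min(patristic[id, refs_in_tree])]
          k <- match(nearest, references$ref_id)
          fam <- references$subfamily[k]; grp <- references$subgroup[k]
          ref <- nearest
        }
      }
    }
    data.frame(gene_id = id, subfamily = fam, subgroup = grp,
               assigned_name = NA_character_, best_reference = ref,
               identity = best_idty, ambiguous = amb, classified = TRUE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  for (grp in unique(out$subgroup[out$classified])) {
    sel <- which(out$classified & out$subgroup == grp)
    sel <- sel[order(-out$identity[sel])]
    out$assigned_name[sel] <- paste0(prefix, grp, ".", seq_along(sel))
  }
  out
}
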