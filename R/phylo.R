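# substitution matrix for alignment scoring: BLOSUM62 for proteins, a
# simple +2/-1 matrix for nucleotide input
phylo_submat <- function(seqs) {
  if (all(!grepl("[^ACGTN-]", seqs))) {
    nt_submat(2, -1)
  } else {
    getdata <- function(nm) {
      e <- new.env()
      utils::data(list = nm, package = "Biostrings", envir = e)
      get(nm, envir = e)
    }
    getdata("BLOSUM62")
  }
}

#' Progressive multiple alignment
#'
#' CLUSTALW-style progressive alignment: a guide tree is built by
#' average-linkage (UPGMA) clustering of k-mer distances, and profiles
#' are merged in guide-tree order by pairwise affine-gap (Gotoh)
#' profile alignment under BLOSUM62 (or +2/-1 for nucleotide input).
#' Entirely deterministic.
#'
#' @param seqs Named character vector of >= 2 sequences.
#' @param gap_open,gap_ext Affine gap penalties (defaults 10 and 1).
#' @param k K-mer size for the guide-tree distance (default 3).
#' @return Object of class `"msa"`: list with `taxa` and `rows`
#'   (named, equal-length gapped strings in input order).
#' @export
progressive_align <- function(seqs, gap_open = 10, gap_ext = 1, k = 3L) {
  if (length(seqs) < 2L) stop("need at least 2 sequences")
  if (is.null(names(seqs)))
    names(seqs) <- paste0("seq", seq_along(seqs))
  sub <- phylo_submat(seqs)
  n <- length(seqs)
  if (n == 2L) {
    prof <- profile_align(t(matrix(strsplit(seqs[[1]], "")[[1]])),
                          t(matrix(strsplit(seqs[[2]], "")[[1]])),
                          sub, gap_open, gap_ext)
    rows <- apply(prof, 1, paste, collapse = "")
    names(rows) <- names(seqs)
    return(structure(list(taxa = names(seqs), rows = rows), class = "msa"))
  }
  km <- lapply(seqs, function(s) table(seq_words(s, k)))
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    shared <- sum(pmin(
      as.integer(km[[i]][intersect(names(km[[i]]), names(km[[j]]))]),
      as.integer(km[[j]][intersect(names(km[[i]]), names(km[[j]]))])))
    d[i, j] <- d[j, i] <- 1 - shared / min(sum(km[[i]]), sum(km[[j]]))
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  profiles <- list()  # per merge step: list(mat, taxa)
  leaf_prof <- function(i) {
    list(mat = t(matrix(strsplit(seqs[[i]], "")[[1]])),
         taxa = names(seqs)[i])
  }
  for (step in seq_len(nrow(hc$merge))) {
    get_p <- function(x) if (x < 0) leaf_prof(-x) else profiles[[x]]
    pa <- get_p(hc$merge[step, 1]); pb <- get_p(hc$merge[step, 2])
    mat <- profile_align(pa$mat, pb$mat, sub, gap_open, gap_ext)
    profiles[[step]] <- list(mat = mat, taxa = c(pa$taxa, pb$taxa))
  }
  final <- profiles[[length(profiles)]]
  rows <- apply(final$mat, 1, paste, collapse = "")
  names(rows) <- final$taxa
  rows <- rows[names(seqs)]
  structure(list(taxa = names(seqs), rows = rows), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat(sprintf("<msa> %d sequences, %d columns\n", length(x$rows),
              nchar(x$rows[[1]])))
  invisible(x)
}

# mean pairwise substitution score between two profile columns
# (gap characters contribute 0)
col_score <- function(ca, cb, sub) {
  tot <- 0; cnt <- 0L
  for (x in ca) for (y in cb) {
    cnt <- cnt + 1L
    if (x != "-" && y != "-") tot <- tot + sub[x, y]
  }
  tot / cnt
}

# affine-gap (Gotoh) global alignment of two profiles (character
# matrices, rows = sequences); returns the merged profile matrix
profile_align <- function(A, B, sub, gap_open, gap_ext) {
  la <- ncol(A); lb <- ncol(B)
  S <- matrix(0, la, lb)
  for (i in seq_len(la)) for (j in seq_len(lb))
    S[i, j] <- col_score(A[, i], B[, j], sub)
  NEG <- -1e9
  M <- X <- Y <- matrix(NEG, la + 1L, lb + 1L)
  M[1, 1] <- 0
  for (i in seq_len(la)) X[i + 1L, 1] <- -gap_open - gap_ext * (i - 1L)
  for (j in seq_len(lb)) Y[1, j + 1L] <- -gap_open - gap_ext * (j - 1L)
  for (i in seq_len(la)) {
    for (j in seq_len(lb)) {
      M[i + 1L, j + 1L] <- max(M[i, j], X[i, j], Y[i, j]) + S[i, j]
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - gap_open,
                               X[i, j + 1L] - gap_ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - gap_open,
                               Y[i + 1L, j] - gap_ext)
    }
  }
  # traceback
  i <- la; j <- lb
  state <- which.max(c(M[i + 1L, j + 1L], X[i + 1L, j + 1L],
                       Y[i + 1L, j + 1L]))
  cols <- list()
  gapA <- rep("-", nrow(A)); gapB <- rep("-", nrow(B))
  while (i > 0L || j > 0L) {
    if (state == 1L && i > 0L && j > 0L) {
      cols[[length(cols) + 1L]] <- c(A[, i], B[, j])
      prev <- c(M[i, j], X[i, j], Y[i, j])
      i <- i - 1L; j <- j - 1L
      state <- which.max(prev)
    } else if (state == 2L && i > 0L) {
      cols[[length(cols) + 1L]] <- c(A[, i], gapB)
      from_m <- M[i, j + 1L] - gap_open
      from_x <- X[i, j + 1L] - gap_ext
      i <- i - 1L
      state <- if (from_m >= from_x) 1L else 2L
    } else if (j > 0L) {
      cols[[length(cols) + 1L]] <- c(gapA, B[, j])
      from_m <- M[i + 1L, j] - gap_open
      from_y <- Y[i + 1L, j] - gap_ext
      j <- j - 1L
      state <- if (from_m >= from_y) 1L else 3L
    } else {
      cols[[length(cols) + 1L]] <- c(A[, i], gapB)
      i <- i - 1L
      state <- 2L
    }
  }
  do.call(cbind, rev(cols))
}

#' Pairwise p-distance matrix from an alignment
#'
#' `d(i, j)` is the fraction of mismatching residues over columns where
#' neither sequence has a gap (pairwise deletion).
#'
#' @param aln An [progressive_align()] result, or a named character
#'   vector of equal-length gapped sequences.
#' @param correction `"none"` (p-distance, default) or `"poisson"`
#'   (`-log(1 - p)`).
#' @return Symmetric numeric matrix with zero diagonal.
#' @export
p_distance_matrix <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  rows <- if (inherits(aln, "msa")) aln$rows else aln
  if (length(unique(nchar(rows))) != 1L)
    stop("alignment rows differ in length")
  chars <- do.call(rbind, strsplit(rows, ""))
  n <- nrow(chars)
  d <- matrix(0, n, n, dimnames = list(names(rows), names(rows)))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    ok <- chars[i, ] != "-" & chars[j, ] != "-"
    if (!any(ok)) stop("no comparable columns between ", names(rows)[i],
                       " and ", names(rows)[j])
    p <- mean(chars[i, ok] != chars[j, ok])
    if (correction == "poisson") {
      if (p >= 1) stop("saturated distance; Poisson correction undefined")
      p <- -log(1 - p)
    }
    d[i, j] <- d[j, i] <- p
  }
  d
}

#' Neighbor-joining tree
#'
#' Canonical Saitou-Nei agglomeration.  Negative branch lengths are
#' clamped to zero with the deficit transferred to the sister branch,
#' so the path length between the joined pair is preserved.  On an
#' additive distance matrix the generating topology and branch lengths
#' are recovered exactly.
#'
#' @param d Symmetric distance matrix with zero diagonal (>= 3 taxa);
#'   dimnames give the tip labels.
#' @return Unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(d) {
  d <- as.matrix(d)
  n <- nrow(d)
  if (n < 3L) stop("need at least 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix not symmetric")
  if (any(diag(d) != 0)) stop("nonzero diagonal")
  labels <- rownames(d)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  # nodes are newick subtree strings; join until three remain
  nodes <- labels
  fmt <- function(x) format(x, digits = 12, scientific = FALSE, trim = TRUE)
  while (length(nodes) > 3L) {
    m <- length(nodes)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    ij <- which(q == min(q), arr.ind = TRUE)[1, ]
    i <- min(ij); j <- max(ij)
    li <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- d[i, j] - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    new_node <- sprintf("(%s:%s,%s:%s)", nodes[i], fmt(li),
                        nodes[j], fmt(lj))
    dk <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], dk[keep]),
                c(dk[keep], 0))
    nodes <- c(nodes[keep], new_node)
    d <- d2
  }
  lx <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  ly <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  lz <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  lens <- pmax(c(lx, ly, lz), 0)
  txt <- sprintf("(%s:%s,%s:%s,%s:%s);", nodes[1], fmt(lens[1]),
                 nodes[2], fmt(lens[2]), nodes[3], fmt(lens[3]))
  ape::read.tree(text = txt)
}

#' Bootstrap majority-rule consensus tree
#'
#' Alignment columns are resampled with replacement in each replicate,
#' a neighbor-joining tree is built from the replicate's p-distance
#' matrix, and the majority-rule (> 50 percent) consensus is returned
#' with internal-node labels giving the percentage of replicates
#' containing each bipartition.  Deterministic under the seed.
#'
#' @param aln An [progressive_align()] result (or named gapped
#'   character vector) with >= 4 taxa.
#' @param reps Number of bootstrap replicates (default 100).
#' @param seed Integer seed.
#' @param correction Distance correction, see [p_distance_matrix()].
#' @return [ape::phylo] consensus tree; `node.label` holds integer
#'   support percentages (root label empty), and attribute
#'   `"trees"` the replicate trees as a `multiPhylo`.
#' @export
bootstrap_consensus <- function(aln, reps = 100L, seed = 1L,
                                correction = "none") {
  rows <- if (inherits(aln, "msa")) aln$rows else aln
  if (length(rows) < 4L) stop("need >= 4 taxa for bootstrap consensus")
  if (reps <= 0L) stop("reps must be positive")
  chars <- do.call(rbind, strsplit(rows, ""))
  rownames(chars) <- names(rows)
  ncol_ <- ncol(chars)
  trees <- with_seed(seed, {
    lapply(seq_len(reps), function(rep_i) {
      idx <- sample.int(ncol_, ncol_, replace = TRUE)
      sub_rows <- apply(chars[, idx, drop = FALSE], 1, paste,
                        collapse = "")
      nj_tree(p_distance_matrix(sub_rows, correction))
    })
  })
  class(trees) <- "multiPhylo"
  cons <- ape::consensus(trees, p = 0.5)
  counts <- ape::prop.clades(cons, trees, rooted = FALSE)
  supp <- round(100 * counts / reps)
  supp[is.na(supp)] <- 0L
  lab <- as.character(supp)
  lab[1] <- ""  # root of the unrooted representation
  cons$node.label <- lab
  attr(cons, "trees") <- trees
  cons
}
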