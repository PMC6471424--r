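# score an msa's induced pairwise global alignment under the package's
# gap convention (open charged on the first gap column, extend after)
msa_pair_score <- function(aln, gap_open = 10, gap_ext = 1) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sub <- get("BLOSUM62", envir = e)
  a <- strsplit(aln$rows[[1]], "")[[1]]
  b <- strsplit(aln$rows[[2]], "")[[1]]
  s <- 0; in_gap <- FALSE
  for (k in seq_along(a)) {
    if (a[k] == "-" || b[k] == "-") {
      s <- s - if (in_gap) gap_ext else gap_open
      in_gap <- TRUE
    } else {
      s <- s + sub[a[k], b[k]]
      in_gap <- FALSE
    }
  }
  s
}

test_that("progressive alignment handles identical and pairwise cases", {
  seqs <- c(a = "MKVLHEAG", b = "MKVLHEAG", c = "MKVLHEAG")
  aln <- progressive_align(seqs)
  expect_equal(unname(nchar(aln$rows)), rep(8L, 3))
  expect_false(any(grepl("-", aln$rows, fixed = TRUE)))

  # two sequences: the profile aligner attains the optimal global
  # score (checked against an equivalent-parameter reference aligner)
  set.seed(60)
  for (i in 1:3) {
    a <- r_protein(80); b <- r_protein(70)
    aln2 <- progressive_align(c(x = a, y = b), gap_open = 10, gap_ext = 1)
    # same convention as gapOpening 9 / gapExtension 1 in Biostrings
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
      substitutionMatrix = "BLOSUM62", gapOpening = 9, gapExtension = 1)
    expect_equal(msa_pair_score(aln2), Biostrings::score(ref))
  }
  expect_error(progressive_align(c(a = "MKV")), "at least 2")
})

test_that("progressive alignment recovers known homologous columns", {
  # four descendants of one ancestor with recorded indels: two share a
  # deletion at 41-45, one has an insertion after column 80
  set.seed(61)
  anc <- r_protein(120)
  s1 <- mutate_family(anc, 0.9)
  s2 <- paste0(substr(mutate_family(anc, 0.9), 1, 40),
               substr(anc, 46, 120))
  s3 <- paste0(substr(mutate_family(anc, 0.9), 1, 40),
               substr(mutate_family(anc, 0.92), 46, 120))
  s4 <- paste0(substr(mutate_family(anc, 0.9), 1, 80), "WWWWW",
               substr(mutate_family(anc, 0.9), 81, 120))
  aln <- progressive_align(c(a = s1, b = s2, c = s3, d = s4))
  # residue k of s1 and residue k of the corresponding region of s2/s3
  # are homologous; count how many end up in the same column
  cols <- function(row) which(strsplit(aln$rows[[row]], "")[[1]] != "-")
  ca <- cols("a"); cb <- cols("b")
  # s2's residues map to ancestor columns 1..40, 46..120
  anc_b <- c(1:40, 46:120)
  same <- sum(ca[anc_b] == cb)
  expect_gte(same / length(anc_b), 0.9)
})

test_that("p-distances use pairwise deletion and satisfy metric checks", {
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAA"))["a", "b"], 0)
  expect_equal(p_distance_matrix(c(a = "AAAA", b = "AAAT"))["a", "b"],
               0.25)
  # gap columns are deleted pairwise
  expect_equal(p_distance_matrix(c(a = "AA-A", b = "AATT"))["a", "b"],
               1 / 3)
  expect_error(p_distance_matrix(c(a = "----", b = "AAAA")),
               "no comparable")
  set.seed(62)
  for (i in 1:5) {
    rows <- vapply(1:4, function(j) r_protein(60), "")
    names(rows) <- letters[1:4]
    d <- p_distance_matrix(rows)
    expect_equal(d, t(d))
    expect_true(all(diag(d) == 0))
    expect_true(all(d >= 0))
    # triangle inequality
    for (x in 1:4) for (y in 1:4) for (z in 1:4) {
      expect_lte(d[x, y], d[x, z] + d[z, y] + 1e-12)
    }
  }
})

test_that("NJ solves the three-taxon closed form exactly", {
  d <- matrix(c(0, 0.3, 0.5,
                0.3, 0, 0.6,
                0.5, 0.6, 0), 3, 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- nj_tree(d)
  expect_equal(ape::Ntip(tr), 3L)
  lens <- setNames(tr$edge.length[match(seq_len(3), tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(lens[["A"]], (0.3 + 0.5 - 0.6) / 2)
  expect_equal(lens[["B"]], (0.3 + 0.6 - 0.5) / 2)
  expect_equal(lens[["C"]], (0.5 + 0.6 - 0.3) / 2)
  expect_equal(sum(tr$edge.length), (0.3 + 0.5 + 0.6) / 2)
  expect_error(nj_tree(d[1:2, 1:2]), "at least 3")
  dbad <- d; dbad[1, 2] <- 0.9
  expect_error(nj_tree(dbad), "symmetric")
})

test_that("NJ inverts tree-to-distance generation on additive matrices", {
  set.seed(63)
  for (i in 1:5) {
    true <- ape::rtree(sample(5:8, 1), rooted = FALSE)
    true$edge.length <- stats::runif(nrow(true$edge), 0.05, 1)
    d <- ape::cophenetic.phylo(true)
    d <- d[true$tip.label, true$tip.label]
    tr <- nj_tree(d)
    # topology identical (RF distance zero) and lengths recovered
    expect_equal(ape::dist.topo(tr, true), structure(0L, .Dim = NULL),
                 ignore_attr = TRUE)
    d2 <- ape::cophenetic.phylo(tr)[true$tip.label, true$tip.label]
    expect_equal(d2, d, tolerance = 1e-8)
  }
})

test_that("NJ agrees with an independent implementation", {
  set.seed(64)
  for (i in 1:4) {
    n <- sample(5:9, 1)
    rows <- vapply(seq_len(n), function(j) r_protein(80), "")
    names(rows) <- paste0("t", seq_len(n))
    d <- p_distance_matrix(rows)
    mine <- nj_tree(d)
    ref <- ape::nj(stats::as.dist(d))
    expect_equal(ape::dist.topo(mine, ref), structure(0L),
                 ignore_attr = TRUE)
  }
})

test_that("NJ on an ultrametric matrix matches UPGMA topology", {
  set.seed(65)
  true <- ape::rcoal(6)  # coalescent trees are ultrametric
  d <- ape::cophenetic.phylo(true)
  tr <- nj_tree(d)
  up <- stats::hclust(stats::as.dist(d), method = "average")
  up_phylo <- ape::as.phylo(up)
  expect_equal(ape::dist.topo(ape::unroot(up_phylo), tr),
               structure(0L), ignore_attr = TRUE)
})

test_that("bootstrap consensus is seeded, bounded and signal-driven", {
  # two clean clades: (a, b) vs (c, d, e) separated by many columns
  set.seed(66)
  anc <- r_protein(250)
  cl1 <- mutate_family(anc, 0.6, seed = 1)
  seqs <- c(a = mutate_family(cl1, 0.95, seed = 2),
            b = mutate_family(cl1, 0.95, seed = 3),
            c = mutate_family(anc, 0.95, seed = 4),
            d = mutate_family(anc, 0.95, seed = 5),
            e = mutate_family(anc, 0.97, seed = 6))
  aln <- progressive_align(seqs)
  tr <- bootstrap_consensus(aln, reps = 50, seed = 9)
  labs <- suppressWarnings(as.integer(tr$node.label))
  expect_true(all(labs[!is.na(labs)] >= 0 & labs[!is.na(labs)] <= 100))
  # the (a, b) clade has maximal support
  ab_node <- ape::getMRCA(tr, c("a", "b"))
  ab_supp <- as.integer(tr$node.label[ab_node - ape::Ntip(tr)])
  expect_equal(ab_supp, 100L)
  # determinism under seed; single replicate gives all-or-nothing
  tr2 <- bootstrap_consensus(aln, reps = 50, seed = 9)
  expect_identical(ape::write.tree(tr), ape::write.tree(tr2))
  tr3 <- bootstrap_consensus(aln, reps = 50, seed = 10)
  expect_identical(sort(tr3$tip.label), sort(tr$tip.label))
  tr1 <- bootstrap_consensus(aln, reps = 1, seed = 3)
  l1 <- suppressWarnings(as.integer(tr1$node.label))
  expect_true(all(l1[!is.na(l1)] %in% c(0L, 100L)))
  expect_error(bootstrap_consensus(aln, reps = 0), "positive")
  expect_error(bootstrap_consensus(aln$rows[1:3]), "4 taxa")
})

test_that("bootstrap support rises with alignment length", {
  set.seed(67)
  anc_long <- r_protein(300)
  cl <- mutate_family(anc_long, 0.75, seed = 11)
  mk <- function(len) {
    seqs <- c(a = mutate_family(substr(cl, 1, len), 0.97, seed = 12),
              b = mutate_family(substr(cl, 1, len), 0.97, seed = 13),
              c = mutate_family(substr(anc_long, 1, len), 0.97, seed = 14),
              d = mutate_family(substr(anc_long, 1, len), 0.97, seed = 15))
    aln <- progressive_align(seqs)
    tr <- bootstrap_consensus(aln, reps = 60, seed = 16)
    node <- ape::getMRCA(tr, c("a", "b"))
    if (is.null(node) || node <= ape::Ntip(tr)) return(0L)
    supp <- suppressWarnings(as.integer(tr$node.label[node - ape::Ntip(tr)]))
    if (is.na(supp)) 0L else supp
  }
  expect_lte(mk(20), mk(300))
})
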