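# Karlin-Altschul parameters for BLOSUM62 with affine gaps 11/1
# (published gapped constants)
KA_LAMBDA <- 0.267
KA_K <- 0.041

#' Optimal local protein alignment with an E-value
#'
#' Smith-Waterman under BLOSUM62 with affine gaps (open 11, extend 1);
#' the E-value uses the Karlin-Altschul formula with the gapped
#' BLOSUM62 constants and an effective database size that defaults to
#' the subject length (pass `db_size` to model a whole proteome).
#'
#' @param a,b Protein sequences.
#' @param gap_open,gap_ext Affine gap penalties.
#' @param db_size Effective database length in residues (default
#'   `nchar(b)`).
#' @return List of class `"protein_match"`: `score`, `bitscore`,
#'   `evalue`, `identity` (percentage over the aligned region),
#'   `aligned_length`.
#' @export
align_protein_pair <- function(a, b, gap_open = 11, gap_ext = 1,
                               db_size = NULL) {
  if (!nzchar(a) || !nzchar(b)) stop("empty protein sequence")
  if (grepl("[^A-Z*]", paste0(a, b)))
    stop("illegal characters in protein sequence")
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = "BLOSUM62", gapOpening = gap_open,
    gapExtension = gap_ext)
  s <- Biostrings::score(al)
  bits <- (KA_LAMBDA * s - log(KA_K)) / log(2)
  n <- if (is.null(db_size)) nchar(b) else db_size
  evalue <- nchar(a) * n * 2^(-bits)
  alen <- Biostrings::nchar(al)
  structure(list(score = s, bitscore = bits, evalue = evalue,
                 identity = if (alen > 0) 100 * Biostrings::nmatch(al) / alen
                            else 0,
                 aligned_length = alen),
            class = "protein_match")
}

#' @export
print.protein_match <- function(x, ...) {
  cat(sprintf("<protein_match> score %.0f, %.1f bits, E = %.2e, %.1f%% id over %d aa\n",
              x$score, x$bitscore, x$evalue, x$identity, x$aligned_length))
  invisible(x)
}

#' Map homologs between two annotated proteomes
#'
#' All-versus-all local alignment, one-to-one assignment by best
#' bitscore (ties broken by lower E-value, then lower locus index).
#' Pairs are accepted outright at the strict E-value threshold;
#' borderline pairs (strict < E <= relaxed) are additionally accepted
#' when a conserved gene neighborhood supports them: at least one of
#' the two loci within distance 2 on genome A already has a strict
#' match to a locus within distance 2 of the candidate partner on
#' genome B.  Loci without an accepted match are orphans.  Synteny
#' blocks are maximal runs of accepted pairs consecutive on A whose
#' partners advance consecutively on B in a consistent orientation.
#'
#' @param proteins_a,proteins_b Named character vectors of protein
#'   sequences, in genome order (names = locus tags).
#' @param strict Strict E-value threshold (default 1e-10).
#' @param relaxed Relaxed threshold for neighborhood rescue (default
#'   1e-5).
#' @param neighborhood Neighborhood radius in loci (default 2).
#' @return Object of class `"homology_map"`: `matches` (data.frame
#'   locus_a, locus_b, identity, bitscore, evalue, aligned_length,
#'   accepted_via, block), `orphans_a`, `orphans_b`, `secondary`
#'   (above-threshold pairs beaten in the one-to-one assignment).
#' @export
map_homologs <- function(proteins_a, proteins_b, strict = 1e-10,
                         relaxed = 1e-5, neighborhood = 2L) {
  if (!length(proteins_a) || !length(proteins_b)) stop("empty proteome")
  na <- length(proteins_a); nb <- length(proteins_b)
  db <- sum(nchar(proteins_b))
  all_pairs <- do.call(rbind, lapply(seq_len(na), function(i) {
    do.call(rbind, lapply(seq_len(nb), function(j) {
      pm <- align_protein_pair(proteins_a[[i]], proteins_b[[j]],
                               db_size = db)
      data.frame(ia = i, ib = j, identity = pm$identity,
                 bitscore = pm$bitscore, evalue = pm$evalue,
                 aligned_length = pm$aligned_length)
    }))
  }))
  cand <- all_pairs[all_pairs$evalue <= relaxed, , drop = FALSE]
  cand <- cand[order(-cand$bitscore, cand$evalue, cand$ia, cand$ib), ,
               drop = FALSE]
  # one-to-one assignment, best bitscore first
  a_taken <- logical(na); b_taken <- logical(nb)
  chosen <- logical(nrow(cand))
  for (k in seq_len(nrow(cand))) {
    if (!a_taken[cand$ia[k]] && !b_taken[cand$ib[k]]) {
      chosen[k] <- TRUE
      a_taken[cand$ia[k]] <- TRUE
      b_taken[cand$ib[k]] <- TRUE
    }
  }
  assigned <- cand[chosen, , drop = FALSE]
  secondary <- cand[!chosen, , drop = FALSE]
  accepted <- assigned[assigned$evalue <= strict, , drop = FALSE]
  accepted$accepted_via <- rep("strict", nrow(accepted))
  border <- assigned[assigned$evalue > strict, , drop = FALSE]
  repeat {
    if (!nrow(border)) break
    support <- vapply(seq_len(nrow(border)), function(k) {
      any(abs(accepted$ia - border$ia[k]) <= neighborhood &
          abs(accepted$ib - border$ib[k]) <= neighborhood)
    }, logical(1))
    if (!any(support)) break
    rescued <- border[support, , drop = FALSE]
    rescued$accepted_via <- "neighborhood"
    accepted <- rbind(accepted, rescued)
    border <- border[!support, , drop = FALSE]
  }
  accepted <- accepted[order(accepted$ia), , drop = FALSE]
  # synteny blocks: consecutive on A, partners stepping +-1 on B
  block <- integer(nrow(accepted))
  if (nrow(accepted)) {
    block[1] <- 1L
    dirn <- 0L
    if (nrow(accepted) > 1) for (k in 2:nrow(accepted)) {
      da <- accepted$ia[k] - accepted$ia[k - 1L]
      db_ <- accepted$ib[k] - accepted$ib[k - 1L]
      same <- da == 1L && abs(db_) == 1L && (dirn == 0L || db_ == dirn)
      if (same) {
        block[k] <- block[k - 1L]
        dirn <- db_
      } else {
        block[k] <- block[k - 1L] + 1L
        dirn <- 0L
      }
    }
  }
  matches <- data.frame(locus_a = names(proteins_a)[accepted$ia],
                        locus_b = names(proteins_b)[accepted$ib],
                        accepted[, c("identity", "bitscore", "evalue",
                                     "aligned_length", "accepted_via")],
                        block = block)
  rownames(matches) <- NULL
  sec <- data.frame(locus_a = names(proteins_a)[secondary$ia],
                    locus_b = names(proteins_b)[secondary$ib],
                    secondary[, c("identity", "bitscore", "evalue",
                                  "aligned_length")])
  rownames(sec) <- NULL
  structure(list(matches = matches,
                 orphans_a = setdiff(names(proteins_a), matches$locus_a),
                 orphans_b = setdiff(names(proteins_b), matches$locus_b),
                 secondary = sec),
            class = "homology_map")
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf(
    "<homology_map> %d accepted match(es) in %d block(s); %d + %d orphan(s)\n",
    nrow(x$matches),
    if (nrow(x$matches)) max(x$matches$block) else 0L,
    length(x$orphans_a), length(x$orphans_b)))
  invisible(x)
}

# translations of the six reading frames; returns list of
# list(aa, strand, off) where nucleotide position of aa residue i is
# off + 3*(i-1) + 1 on the top strand (for -, counted on revcomp)
six_frames <- function(g) {
  n <- genome_length(g)
  rc <- rev_comp(g$seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") g$seq else rc
    for (off in 0:2) {
      len <- 3L * ((n - off) %/% 3L)
      if (len < 3L) next
      aa <- as.character(Biostrings::translate(
        Biostrings::DNAString(substr(s, off + 1L, off + len)),
        if.fuzzy.codon = "X"))
      out[[length(out) + 1L]] <- list(aa = aa, strand = strand, off = off)
    }
  }
  out
}

#' Translated similarity segments between two genomes
#'
#' A tBLASTx-style comparison: all six reading frames of both genomes
#' are translated, genome A's frames are cut into non-overlapping
#' 100-codon tiles, every tile is locally aligned against every frame
#' of genome B, and tile hits at or above the identity floor are
#' merged into collinear segments reported in nucleotide coordinates.
#' The scan is run in both directions (A tiled against B and B tiled
#' against A) and reconciled, so the result is symmetric.  A segment is
#' `inverted` when the matching frames lie on opposite strands.
#'
#' @param a,b [genome] objects (>= 1 kb).
#' @param min_identity Identity floor in percent (default 30).
#' @param min_aa Minimum aligned residues per tile hit (default 30).
#' @param tile Tile length in codons (default 100).
#' @param max_evalue Karlin-Altschul E-value cutoff per tile hit
#'   (default 1e-3); it suppresses the short low-identity alignments
#'   that arise by chance between compositionally biased sequences.
#' @return Data.frame of class `"shading_segments"`: `a_start`,
#'   `a_end`, `b_start`, `b_end` (nt, top strand), `identity`,
#'   `orientation` (`direct`/`inverted`).
#' @export
similarity_segments <- function(a, b, min_identity = 30, min_aa = 30,
                                tile = 100L, max_evalue = 1e-3) {
  if (genome_length(a) < 1000L || genome_length(b) < 1000L)
    stop("genomes must be at least 1 kb")
  hits_ab <- tile_scan(a, b, min_identity, min_aa, tile, max_evalue)
  hits_ba <- tile_scan(b, a, min_identity, min_aa, tile, max_evalue)
  if (nrow(hits_ba)) {
    hits_ba <- data.frame(a_start = hits_ba$b_start, a_end = hits_ba$b_end,
                          b_start = hits_ba$a_start, b_end = hits_ba$a_end,
                          identity = hits_ba$identity,
                          orientation = hits_ba$orientation)
  }
  segs <- rbind(hits_ab, hits_ba)
  segs <- merge_segments(segs)
  class(segs) <- c("shading_segments", "data.frame")
  segs
}

# tile-based translated scan of a against b
tile_scan <- function(a, b, min_identity, min_aa, tile, max_evalue) {
  fa <- six_frames(a); fb <- six_frames(b)
  na <- genome_length(a); nb <- genome_length(b)
  empty <- data.frame(a_start = integer(0), a_end = integer(0),
                      b_start = integer(0), b_end = integer(0),
                      identity = numeric(0), orientation = character(0))
  rows <- list()
  for (FA in fa) {
    n_aa <- nchar(FA$aa)
    tstarts <- seq(1L, n_aa, by = tile)
    for (ts in tstarts) {
      te <- min(ts + tile - 1L, n_aa)
      if (te - ts + 1L < min_aa) next
      tseq <- substr(FA$aa, ts, te)
      if (grepl("^X+$", tseq)) next
      for (FB in fb) {
        al <- Biostrings::pairwiseAlignment(
          Biostrings::AAString(tseq), Biostrings::AAString(FB$aa),
          type = "local", substitutionMatrix = "BLOSUM62",
          gapOpening = 11, gapExtension = 1)
        alen <- Biostrings::nchar(al)
        if (alen < min_aa) next
        ident <- 100 * Biostrings::nmatch(al) / alen
        if (ident < min_identity) next
        bits <- (KA_LAMBDA * Biostrings::score(al) - log(KA_K)) / log(2)
        if (nchar(tseq) * nchar(FB$aa) * 2^(-bits) > max_evalue) next
        # aligned residue ranges -> nucleotide coordinates
        pa <- Biostrings::pattern(al); pb <- Biostrings::subject(al)
        a_res <- c(Biostrings::start(pa) + ts - 1L,
                   Biostrings::end(pa) + ts - 1L)
        b_res <- c(Biostrings::start(pb), Biostrings::end(pb))
        a_nt <- aa_to_nt(a_res, FA, na)
        b_nt <- aa_to_nt(b_res, FB, nb)
        rows[[length(rows) + 1L]] <- data.frame(
          a_start = min(a_nt), a_end = max(a_nt),
          b_start = min(b_nt), b_end = max(b_nt),
          identity = ident,
          orientation = if (FA$strand == FB$strand) "direct" else "inverted")
      }
    }
  }
  if (!length(rows)) return(empty)
  do.call(rbind, rows)
}

# residue index range (on a frame) -> top-strand nucleotide bounds
aa_to_nt <- function(res_range, frame, n) {
  nt <- c(frame$off + 3L * (res_range[1] - 1L) + 1L,
          frame$off + 3L * res_range[2])
  if (frame$strand == "-") nt <- n - nt + 1L
  nt
}

# merge overlapping same-orientation segments (identity-weighted)
merge_segments <- function(segs) {
  if (!nrow(segs)) return(segs)
  segs <- segs[order(segs$orientation, segs$a_start, segs$a_end), ,
               drop = FALSE]
  out <- list()
  cur <- segs[1, ]
  for (k in seq_len(nrow(segs))[-1]) {
    row <- segs[k, ]
    if (row$orientation == cur$orientation &&
        row$a_start <= cur$a_end + 1L &&
        row$b_start <= cur$b_end + 1L && row$b_end >= cur$b_start - 1L) {
      w1 <- cur$a_end - cur$a_start + 1L
      w2 <- row$a_end - row$a_start + 1L
      cur$identity <- (cur$identity * w1 + row$identity * w2) / (w1 + w2)
      cur$a_end <- max(cur$a_end, row$a_end)
      cur$b_start <- min(cur$b_start, row$b_start)
      cur$b_end <- max(cur$b_end, row$b_end)
    } else {
      out[[length(out) + 1L]] <- cur
      cur <- row
    }
  }
  out[[length(out) + 1L]] <- cur
  out <- do.call(rbind, out)
  out <- out[order(out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect invertible (tail-fiber) regions
#'
#' Looks for paralogous CDS pairs in opposite orientations flanking an
#' integrase/recombinase gene, the hallmark of the invertible
#' tail-fiber module of myohaloviruses; CDS of mobile elements
#' (transposases) lying inside the region are listed with it.
#'
#' @param ft A [feature_table].
#' @param selfmap A [map_homologs()] result of the proteome against
#'   itself (paralog pairs appear among its `secondary` matches).
#' @return Data.frame of class `"invertible_regions"` with one row per
#'   region: `start`, `end`, `locus_a`, `locus_b` (the paralog pair),
#'   `integrase`, `mobile_elements` (comma-separated locus tags),
#'   `identity`.  Zero rows when nothing is found.
#' @export
detect_invertible_region <- function(ft, selfmap) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      locus_a = character(0), locus_b = character(0),
                      integrase = character(0),
                      mobile_elements = character(0),
                      identity = numeric(0))
  class(empty) <- c("invertible_regions", "data.frame")
  pairs <- selfmap$secondary
  pairs <- pairs[pairs$locus_a != pairs$locus_b, , drop = FALSE]
  if (!nrow(pairs)) return(empty)
  # dedupe unordered pairs
  key <- apply(cbind(pmin(pairs$locus_a, pairs$locus_b),
                     pmax(pairs$locus_a, pairs$locus_b)), 1, paste,
               collapse = "|")
  pairs <- pairs[!duplicated(key), , drop = FALSE]
  is_int <- grepl("integrase|recombinase", paste(ft$gene, ft$product),
                  ignore.case = TRUE)
  is_mob <- grepl("transposase|insertion sequence|\\bIS[A-Z]?\\d",
                  paste(ft$gene, ft$product), ignore.case = TRUE)
  rows <- list()
  for (k in seq_len(nrow(pairs))) {
    ia <- match(pairs$locus_a[k], ft$locus_tag)
    ib <- match(pairs$locus_b[k], ft$locus_tag)
    if (is.na(ia) || is.na(ib)) next
    if (ft$strand[ia] == ft$strand[ib]) next
    lo <- min(ft$start[ia], ft$start[ib])
    hi <- max(ft$stop[ia], ft$stop[ib])
    inside <- ft$start > lo & ft$stop < hi
    if (!any(is_int & inside)) next
    mob <- ft$locus_tag[is_mob & inside]
    rows[[length(rows) + 1L]] <- data.frame(
      start = lo, end = hi,
      locus_a = pairs$locus_a[k], locus_b = pairs$locus_b[k],
      integrase = ft$locus_tag[which(is_int & inside)[1]],
      mobile_elements = paste(mob, collapse = ","),
      identity = pairs$identity[k])
  }
  if (!length(rows)) return(empty)
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  # overlapping reports describe one physical region: merge them
  merged <- list()
  cur <- out[1, ]
  for (k in seq_len(nrow(out))[-1]) {
    row <- out[k, ]
    if (row$start <= cur$end) {
      cur$end <- max(cur$end, row$end)
      cur$identity <- max(cur$identity, row$identity)
      mob <- union(strsplit(cur$mobile_elements, ",")[[1]],
                   strsplit(row$mobile_elements, ",")[[1]])
      cur$mobile_elements <- paste(mob[nzchar(mob)], collapse = ",")
    } else {
      merged[[length(merged) + 1L]] <- cur
      cur <- row
    }
  }
  merged[[length(merged) + 1L]] <- cur
  out <- do.call(rbind, merged)
  rownames(out) <- NULL
  class(out) <- c("invertible_regions", "data.frame")
  out
}

#' Translate every CDS of a feature table
#' @param g A [genome].
#' @param ft A [feature_table].
#' @param skip_disrupted Skip records whose product marks them
#'   nonfunctional (they need not translate cleanly)?
#' @return Named character vector of protein sequences in genome
#'   order.
#' @export
proteome <- function(g, ft, skip_disrupted = FALSE) {
  idx <- seq_len(nrow(ft))
  if (skip_disrupted)
    idx <- idx[!grepl("nonfunctional", ft$product)]
  out <- vapply(idx, function(i) {
    tryCatch(translate_cds(g, ft[i, ]), error = function(e) NA_character_)
  }, "")
  names(out) <- ft$locus_tag[idx]
  out[!is.na(out)]
}
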