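# nucleotide substitution matrix and gap penalties used for the
# fragment alignments (exposed through anib() arguments)
nt_submat <- function(match = 1, mismatch = -1) {
  m <- matrix(mismatch, 5, 5,
              dimnames = list(c("A", "C", "G", "T", "N"),
                              c("A", "C", "G", "T", "N")))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0
  m
}

#' Fragment-based average nucleotide identity (ANIb)
#'
#' The query genome is chopped into consecutive fragments of
#' `frag` nt; each fragment is locally aligned to the reference (both
#' strands, the better-scoring one kept) and retained when the
#' alignment covers at least `min_cov` of the fragment at
#' `min_id` identity or better.  ANIb is the mean identity of
#' retained fragments, in percent; the measure is asymmetric
#' (query against reference).
#'
#' @param query,ref [genome] objects, both at least `frag` nt.
#' @param frag Fragment length (default 1020, the standard
#'   fragment-based convention).
#' @param min_id Identity floor for retaining a fragment (fraction,
#'   default 0.3).
#' @param min_cov Coverage floor (fraction of the fragment aligned,
#'   default 0.7).
#' @param match,mismatch,gap_open,gap_ext Local-alignment scoring.
#' @return Object of class `"anib_result"`: list with `anib`
#'   (percentage, `NA` if no fragment was retained), `fragments`
#'   (per-fragment data.frame: start, identity, coverage, retained),
#'   `query_id`, `ref_id`, `fragment_length`.
#' @export
anib <- function(query, ref, frag = 1020L, min_id = 0.3, min_cov = 0.7,
                 match = 1, mismatch = -1, gap_open = 5, gap_ext = 2) {
  nq <- genome_length(query)
  if (nq < frag || genome_length(ref) < frag)
    stop("both genomes must be at least one fragment long")
  starts <- seq(1L, nq - frag + 1L, by = frag)
  subj_f <- Biostrings::DNAString(ref$seq)
  subj_r <- Biostrings::reverseComplement(subj_f)
  mat <- nt_submat(match, mismatch)
  res <- lapply(starts, function(s) {
    p <- Biostrings::DNAString(substr(query$seq, s, s + frag - 1L))
    af <- Biostrings::pairwiseAlignment(p, subj_f, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = gap_open,
                                        gapExtension = gap_ext)
    ar <- Biostrings::pairwiseAlignment(p, subj_r, type = "local",
                                        substitutionMatrix = mat,
                                        gapOpening = gap_open,
                                        gapExtension = gap_ext)
    a <- if (Biostrings::score(ar) > Biostrings::score(af)) ar else af
    alen <- Biostrings::nchar(a)
    ident <- if (alen > 0) Biostrings::nmatch(a) / alen else 0
    cov <- Biostrings::width(Biostrings::pattern(a)) / frag
    c(identity = ident, coverage = cov)
  })
  res <- do.call(rbind, res)
  fragments <- data.frame(start = starts,
                          identity = res[, "identity"],
                          coverage = res[, "coverage"])
  fragments$retained <- fragments$coverage >= min_cov &
    fragments$identity >= min_id
  value <- if (any(fragments$retained))
    100 * mean(fragments$identity[fragments$retained]) else NA_real_
  structure(list(anib = value, fragments = fragments,
                 query_id = query$id, ref_id = ref$id,
                 fragment_length = as.integer(frag)),
            class = "anib_result")
}

#' @export
print.anib_result <- function(x, ...) {
  cat(sprintf("<anib_result> %s vs %s: ANIb = %s%% (%d/%d fragments retained)\n",
              x$query_id, x$ref_id,
              if (is.na(x$anib)) "undefined" else sprintf("%.1f", x$anib),
              sum(x$fragments$retained), nrow(x$fragments)))
  invisible(x)
}

# all k-mer start positions of words in seq, as a character vector
seq_words <- function(seq, word) {
  n <- nchar(seq)
  if (n < word) return(character(0))
  substring(seq, 1:(n - word + 1L), word:n)
}

#' Exact-match dotplot segments between two genomes
#'
#' Maximal exact matches of at least `min_len` nt, found by anchoring
#' on shared words of `word` nt and merging runs of consecutive
#' anchors on the same diagonal; both strands are searched.
#'
#' @param a,b [genome] objects.
#' @param word Word (anchor) size, >= 8.
#' @param min_len Minimum reported segment length.
#' @return Data.frame with columns `a_start`, `b_start`, `length`,
#'   `strand` (`"+"` for same-strand, `"-"` for inverted; `b_start` is
#'   the top-strand leftmost coordinate of the segment on b).
#' @export
dotplot_segments <- function(a, b, word = 12L, min_len = 50L) {
  if (word < 8L) stop("word must be >= 8")
  wa <- seq_words(a$seq, word)
  run_strand <- function(bseq, strand) {
    wb <- seq_words(bseq, word)
    idx <- split(seq_along(wb), wb)
    hits_a <- which(wa %in% names(idx))
    if (!length(hits_a)) return(NULL)
    anchors <- do.call(rbind, lapply(hits_a, function(i) {
      js <- idx[[wa[i]]]
      cbind(i = rep.int(i, length(js)), j = js)
    }))
    d <- anchors[, "j"] - anchors[, "i"]
    segs <- do.call(rbind, lapply(split(anchors[, "i"], d), function(ii) {
      ii <- sort(ii)
      brk <- c(0L, which(diff(ii) != 1L), length(ii))
      do.call(rbind, lapply(seq_len(length(brk) - 1L), function(k) {
        run <- ii[(brk[k] + 1L):brk[k + 1L]]
        c(a_start = run[1L], len = run[length(run)] - run[1L] + word)
      }))
    }))
    diag_of <- rep(as.integer(names(split(anchors[, "i"], d))),
                   vapply(split(anchors[, "i"], d), function(ii) {
                     sum(diff(sort(ii)) != 1L) + 1L
                   }, integer(1)))
    segs <- data.frame(a_start = segs[, "a_start"], len = segs[, "len"],
                       diag = diag_of)
    segs <- segs[segs$len >= min_len, , drop = FALSE]
    if (!nrow(segs)) return(NULL)
    b_pos <- segs$a_start + segs$diag
    if (strand == "+") {
      data.frame(a_start = segs$a_start, b_start = b_pos,
                 length = segs$len, strand = "+")
    } else {
      nb <- nchar(bseq)
      # position on the reverse complement -> top-strand leftmost coord
      data.frame(a_start = segs$a_start,
                 b_start = nb - (b_pos + segs$len - 1L) + 1L,
                 length = segs$len, strand = "-")
    }
  }
  out <- rbind(run_strand(b$seq, "+"),
               run_strand(rev_comp(b$seq), "-"))
  if (is.null(out))
    return(data.frame(a_start = integer(0), b_start = integer(0),
                      length = integer(0), strand = character(0)))
  out <- out[order(out$a_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Base-level difference report between two genome versions
#'
#' Anchors the two sequences on shared unique words, chains the
#' anchors, aligns the gaps between them globally, and reports
#' substitution and indel events; runs of adjacent gap columns are
#' merged into single indel events, so an 18-base indel counts once.
#'
#' @param old,new [genome] objects (near-identical versions of the
#'   same genome, >= 95 percent identical).
#' @param word Anchor word size (default 20).
#' @return Object of class `"diff_report"`: list with `substitutions`,
#'   `indels_1nt`, `indels_multi` (integer vector of lengths),
#'   `total_bases_affected` and an `events` data.frame.
#' @export
genome_diff <- function(old, new, word = 20L) {
  sa <- old$seq; sb <- new$seq
  wa <- seq_words(sa, word); wb <- seq_words(sb, word)
  ua <- wa %in% names(which(table(wa) == 1L))
  tb <- table(wb)
  ub <- wb %in% names(tb[tb == 1L])
  common <- intersect(wa[ua], wb[ub])
  if (length(common) < 2L)
    stop("too few unique anchors; genomes too divergent for a diff")
  pa <- match(common, wa); pb <- match(common, wb)
  ord <- order(pa)
  pa <- pa[ord]; pb <- pb[ord]
  # longest increasing subsequence in pb to keep a collinear chain
  lis <- function(x) {
    n <- length(x); prev <- integer(n); tails <- integer(0); tpos <- integer(0)
    for (i in seq_len(n)) {
      k <- findInterval(x[i] - 1L, tails) + 1L
      tails[k] <- x[i]; tpos[k] <- i
      prev[i] <- if (k > 1L) tpos[k - 1L] else 0L
      length(tails) <- k; length(tpos) <- k
    }
    out <- integer(0); i <- tpos[length(tpos)]
    while (i > 0L) { out <- c(i, out); i <- prev[i] }
    out
  }
  keep <- lis(pb)
  pa <- pa[keep]; pb <- pb[keep]
  # drop overlapping anchors
  ok <- c(TRUE, diff(pa) >= word & diff(pb) >= word)
  pa <- pa[ok]; pb <- pb[ok]
  events <- list()
  seg_diff <- function(xa, xb, off_a) {
    if (!nchar(xa) && !nchar(xb)) return(NULL)
    if (!nchar(xa))
      return(data.frame(pos = off_a, type = "insertion",
                        length = nchar(xb)))
    if (!nchar(xb))
      return(data.frame(pos = off_a, type = "deletion",
                        length = nchar(xa)))
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(xa), Biostrings::DNAString(xb),
      type = "global", substitutionMatrix = nt_submat(),
      gapOpening = 4, gapExtension = 1)
    ca <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    cb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    out <- list(); i <- 1L; apos <- off_a
    while (i <= length(ca)) {
      if (ca[i] == "-" || cb[i] == "-") {
        gap_in_a <- ca[i] == "-"
        j <- i
        while (j < length(ca) &&
               (if (gap_in_a) ca[j + 1L] == "-" else cb[j + 1L] == "-")) j <- j + 1L
        out[[length(out) + 1L]] <- data.frame(
          pos = apos, type = if (gap_in_a) "insertion" else "deletion",
          length = j - i + 1L)
        if (!gap_in_a) apos <- apos + (j - i + 1L)
        i <- j + 1L
      } else {
        if (ca[i] != cb[i])
          out[[length(out) + 1L]] <- data.frame(pos = apos,
                                                type = "substitution",
                                                length = 1L)
        apos <- apos + 1L
        i <- i + 1L
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  starts_a <- c(1L, pa + word); ends_a <- c(pa - 1L, nchar(sa))
  starts_b <- c(1L, pb + word); ends_b <- c(pb - 1L, nchar(sb))
  for (k in seq_along(starts_a)) {
    xa <- if (starts_a[k] <= ends_a[k]) substr(sa, starts_a[k], ends_a[k]) else ""
    xb <- if (starts_b[k] <= ends_b[k]) substr(sb, starts_b[k], ends_b[k]) else ""
    ev <- seg_diff(xa, xb, starts_a[k])
    if (!is.null(ev)) events[[length(events) + 1L]] <- ev
  }
  events <- if (length(events)) do.call(rbind, events)
            else data.frame(pos = integer(0), type = character(0),
                            length = integer(0))
  ind <- events$type != "substitution"
  structure(list(
    substitutions = sum(!ind),
    indels_1nt = sum(ind & events$length == 1L),
    indels_multi = as.integer(events$length[ind & events$length > 1L]),
    total_bases_affected = sum(!ind) + sum(events$length[ind]),
    events = events), class = "diff_report")
}

#' @export
print.diff_report <- function(x, ...) {
  cat(sprintf(
    "<diff_report> %d substitutions, %d one-base indels, %d longer indel(s)%s; %d bases affected\n",
    x$substitutions, x$indels_1nt, length(x$indels_multi),
    if (length(x$indels_multi))
      paste0(" (", paste(x$indels_multi, collapse = ", "), " nt)") else "",
    x$total_bases_affected))
  invisible(x)
}

#' Transfer a pac site from reference genomes by alignment
#'
#' The pac site of headful-packaged viruses sits inside the
#' small-terminase gene near its stop codon, at a conserved GC-rich
#' motif, so it can be located in a new genome by aligning the
#' pac-proximal window of a reference with a known pac position and
#' reading the target coordinate of the reference pac terminal base
#' through the alignment columns.
#'
#' @param references List of `list(genome =, pac =)` entries with known
#'   pac positions.
#' @param target Target [genome].
#' @param terS_region Integer vector `c(start, stop)` of the
#'   terminase small-subunit region on the target (wrap-around allowed,
#'   `stop < start`).
#' @param flank Window half-width around the reference pac (default
#'   300 nt).
#' @param min_identity Minimum alignment identity for a call (default
#'   0.5).
#' @return Integer target coordinate of the pac terminal base, with
#'   attribute `"calls"` (per-reference votes); `NA` when no reference
#'   window aligns above `min_identity`.
#' @export
locate_pac <- function(references, target, terS_region, flank = 300L,
                       min_identity = 0.5) {
  Lt <- genome_length(target)
  t_from <- ((terS_region[1] - 1L - flank) %% Lt) + 1L
  t_to <- ((terS_region[2] - 1L + flank) %% Lt) + 1L
  t_win <- circ_substr(target$seq, t_from, t_to)
  calls <- vapply(references, function(ref) {
    Lr <- genome_length(ref$genome)
    r_from <- ((ref$pac - 1L - flank) %% Lr) + 1L
    r_to <- ((ref$pac - 1L + flank) %% Lr) + 1L
    r_win <- circ_substr(ref$genome$seq, r_from, r_to)
    pac_off <- (ref$pac - r_from) %% Lr + 1L  # position of pac inside r_win
    al <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(r_win), Biostrings::DNAString(t_win),
      type = "local", substitutionMatrix = nt_submat(2, -1),
      gapOpening = 5, gapExtension = 2)
    alen <- Biostrings::nchar(al)
    if (alen == 0 || Biostrings::nmatch(al) / alen < min_identity)
      return(NA_integer_)
    ca <- strsplit(as.character(Biostrings::alignedPattern(al)), "")[[1]]
    cb <- strsplit(as.character(Biostrings::alignedSubject(al)), "")[[1]]
    rpos <- Biostrings::start(Biostrings::pattern(al)) - 1L
    tpos <- Biostrings::start(Biostrings::subject(al)) - 1L
    for (k in seq_along(ca)) {
      if (ca[k] != "-") rpos <- rpos + 1L
      if (cb[k] != "-") tpos <- tpos + 1L
      if (ca[k] != "-" && rpos == pac_off) {
        if (cb[k] == "-") return(NA_integer_)
        return(as.integer(((t_from - 1L + tpos - 1L) %% Lt) + 1L))
      }
    }
    NA_integer_
  }, integer(1))
  ok <- calls[!is.na(calls)]
  out <- if (!length(ok)) NA_integer_
         else as.integer(names(sort(table(ok), decreasing = TRUE))[1])
  attr(out, "calls") <- calls
  out
}

#' Scan a genome for CRISPR spacer protospacers
#'
#' Reports every position (both strands) matching each spacer with at
#' most `max_mm` mismatches (no indels), annotated with the genome arm
#' (left/right of the configurable boundary between the morphogenesis
#' and replication arms).
#'
#' @param spacers Named character vector of spacer sequences
#'   (20-50 nt).
#' @param g A [genome].
#' @param max_mm Maximum mismatches (default 2).
#' @param arm_boundary Left/right arm boundary in nt (default 28000).
#' @return Data.frame with columns `spacer_id`, `position` (1-based
#'   top-strand leftmost), `strand`, `mismatches`, `arm`.
#' @export
spacer_scan <- function(spacers, g, max_mm = 2L, arm_boundary = 28000L) {
  if (is.null(names(spacers)))
    names(spacers) <- paste0("spacer", seq_along(spacers))
  lens <- nchar(spacers)
  if (any(lens < 20L | lens > 50L))
    stop("spacer lengths must be 20-50 nt")
  subj <- Biostrings::DNAString(g$seq)
  hits <- lapply(names(spacers), function(id) {
    sp <- Biostrings::DNAString(spacers[[id]])
    out <- list()
    for (strand in c("+", "-")) {
      pat <- if (strand == "+") sp else Biostrings::reverseComplement(sp)
      m <- Biostrings::matchPattern(pat, subj, max.mismatch = max_mm)
      if (length(m)) {
        mm <- vapply(as.character(m), function(s) {
          sum(strsplit(s, "")[[1]] !=
              strsplit(as.character(pat), "")[[1]])
        }, integer(1), USE.NAMES = FALSE)
        out[[strand]] <- data.frame(spacer_id = id,
                                    position = Biostrings::start(m),
                                    strand = strand, mismatches = mm)
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  })
  hits <- do.call(rbind, hits)
  if (is.null(hits))
    hits <- data.frame(spacer_id = character(0), position = integer(0),
                       strand = character(0), mismatches = integer(0))
  hits$arm <- ifelse(hits$position <= arm_boundary, "left", "right")
  rownames(hits) <- NULL
  hits
}
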