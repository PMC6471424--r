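#' G+C content of a genome
#'
#' Percentage of G+C among unambiguous bases; `N` is excluded from the
#' denominator.
#'
#' @param g A [genome].
#' @return G+C percentage (0-100).
#' @export
gc_content <- function(g) {
  counts <- base_counts(g$seq)
  denom <- sum(counts[c("A", "C", "G", "T")])
  if (denom == 0) stop("sequence contains no unambiguous bases")
  100 * sum(counts[c("G", "C")]) / denom
}

base_counts <- function(seq) {
  tab <- table(strsplit(seq, "", fixed = TRUE)[[1]])
  out <- stats::setNames(integer(5), c("A", "C", "G", "T", "N"))
  out[names(tab)[names(tab) %in% names(out)]] <-
    as.integer(tab[names(tab) %in% names(out)])
  out
}

#' Cumulative AT-skew profile
#'
#' Per-window AT skew is `(A - T) / (A + T)` (0 for windows without A or
#' T), accumulated in genome order from base 1.  The cumulative profile
#' of a virus genome tends to parallel the transcription direction of
#' its gene modules: a forward-strand arm rises, a reverse-strand arm
#' falls, so the inflection points flag strand-switch boundaries.
#'
#' @param g A [genome].
#' @param window Window size in nt (default 500).
#' @param step Step between window starts in nt (default `window`,
#'   i.e. non-overlapping windows).
#' @return An object of class `"skew_profile"`: a data.frame with
#'   columns `position` (window midpoint), `skew` (per-window) and
#'   `cumulative`.
#' @export
cumulative_at_skew <- function(g, window = 500L, step = window) {
  window <- as.integer(window); step <- as.integer(step)
  if (window <= 0L || step <= 0L) stop("window and step must be positive")
  n <- genome_length(g)
  if (window > n) stop("window larger than genome")
  starts <- seq(1L, n - window + 1L, by = step)
  skew <- vapply(starts, function(s) {
    counts <- base_counts(substr(g$seq, s, s + window - 1L))
    at <- counts[["A"]] + counts[["T"]]
    if (at == 0) 0 else (counts[["A"]] - counts[["T"]]) / at
  }, numeric(1))
  out <- data.frame(position = starts + (window - 1L) / 2,
                    skew = skew, cumulative = cumsum(skew))
  attr(out, "window") <- window
  attr(out, "step") <- step
  attr(out, "genome_id") <- g$id
  class(out) <- c("skew_profile", "data.frame")
  out
}

#' Stop-codon usage of annotated CDS
#'
#' Reads the final codon of every CDS on its coding strand
#' (reverse-complemented for minus-strand records, concatenated across
#' the origin for wrapping records) and tallies `TGA`, `TAA` and `TAG`.
#' CDS whose final codon is not a stop are excluded from the counts and
#' reported in the `"flagged"` attribute.
#'
#' @param g A [genome].
#' @param ft A [feature_table]; every record must have length divisible
#'   by 3.
#' @return Named integer vector of counts over `TGA`, `TAA`, `TAG`,
#'   with attribute `"flagged"` listing loci without a terminal stop.
#' @export
stop_codon_usage <- function(g, ft) {
  if (any(ft$length %% 3L != 0L))
    stop("CDS length not divisible by 3: ",
         paste(ft$locus_tag[ft$length %% 3L != 0L], collapse = ", "))
  last <- vapply(seq_len(nrow(ft)), function(i) {
    s <- cds_seq(g, ft[i, ])
    substr(s, nchar(s) - 2L, nchar(s))
  }, "")
  stops <- c("TGA", "TAA", "TAG")
  flagged <- ft$locus_tag[!last %in% stops]
  counts <- vapply(stops, function(cod) sum(last == cod), integer(1))
  attr(counts, "flagged") <- flagged
  counts
}

#' Census of spacing between consecutive CDS
#'
#' For records sorted by leftmost coordinate (both strands pooled), the
#' signed gap between consecutive records is
#' `start[i+1] - stop[i] - 1`; negative gaps are overlaps.  The census
#' is linear: the circular closure pair across the origin is not added,
#' so a table of n records yields n-1 pairs.  A record that wraps the
#' origin sorts by its `start` (it is the rightmost record) and its
#' leftmost coordinate is used when it is the second member of a pair.
#'
#' @param ft A [feature_table] with at least 2 records.
#' @return An object of class `"spacing_census"`: list with `pairs`
#'   (data.frame locus_i, locus_j, gap) and `counts` (overlapping,
#'   gap_0_15, larger).
#' @export
spacing_census <- function(ft) {
  if (nrow(ft) < 2L) stop("need at least 2 records")
  if (is.unsorted(ft$start)) {
    warning("feature table not sorted by start; sorting")
    ft <- ft[order(ft$start), , drop = FALSE]
  }
  n <- nrow(ft)
  i <- seq_len(n - 1L)
  # stop of the left member; a wrapping record never sorts first
  gap <- ft$start[i + 1L] - ft$stop[i] - 1L
  pairs <- data.frame(locus_i = ft$locus_tag[i],
                      locus_j = ft$locus_tag[i + 1L],
                      gap = gap)
  counts <- c(overlapping = sum(gap < 0L),
              gap_0_15 = sum(gap >= 0L & gap <= 15L),
              larger = sum(gap > 15L))
  structure(list(pairs = pairs, counts = counts), class = "spacing_census")
}

#' @export
print.spacing_census <- function(x, ...) {
  cat("<spacing_census>", nrow(x$pairs), "consecutive pairs:",
      x$counts["overlapping"], "overlapping,",
      x$counts["gap_0_15"], "separated by 0-15 nt,",
      x$counts["larger"], "further apart\n")
  invisible(x)
}

#' Codon usage over all annotated CDS
#'
#' Counts codons on the coding strand of every CDS and derives
#' per-amino-acid synonymous-codon fractions.  Codons containing
#' ambiguous bases are skipped (and counted in the `"skipped"`
#' attribute).
#'
#' @param g A [genome].
#' @param ft A [feature_table] with CDS lengths divisible by 3.
#' @return A data.frame of class `"codon_usage"` with columns `codon`,
#'   `aa` (one-letter, `*` for stop), `count` and `fraction` (of all
#'   codons translating to the same amino acid).
#' @export
codon_usage <- function(g, ft) {
  if (any(ft$length %% 3L != 0L))
    stop("CDS length not divisible by 3: ",
         paste(ft$locus_tag[ft$length %% 3L != 0L], collapse = ", "))
  all_cod <- unlist(lapply(seq_len(nrow(ft)), function(i) {
    s <- cds_seq(g, ft[i, ])
    substring(s, seq(1L, nchar(s) - 2L, by = 3L),
              seq(3L, nchar(s), by = 3L))
  }))
  code <- Biostrings::GENETIC_CODE
  skipped <- sum(!all_cod %in% names(code))
  all_cod <- all_cod[all_cod %in% names(code)]
  counts <- vapply(names(code), function(cd) sum(all_cod == cd), integer(1))
  out <- data.frame(codon = names(code), aa = unname(code),
                    count = unname(counts))
  aa_tot <- tapply(out$count, out$aa, sum)
  out$fraction <- ifelse(aa_tot[out$aa] > 0,
                         out$count / aa_tot[out$aa], NA_real_)
  out$fraction <- as.numeric(out$fraction)
  attr(out, "skipped") <- skipped
  class(out) <- c("codon_usage", "data.frame")
  out
}
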