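# Independent oracles used by the tests.  These deliberately use naive
# brute-force implementations (or third-party code) so that they stay
# independent of the package's own algorithms.

fixture_path <- function(name) {
  system.file("extdata", name, package = "chaovir", mustWork = TRUE)
}

chaos9_table <- function() {
  read_feature_table(fixture_path("chaos9_cds_table.tsv"),
                     unit_length = 55145L, genome_id = "ChaoS9")
}

# brute-force scan for a spacer with mismatch counting, both strands
oracle_spacer_scan <- function(spacer, seq, max_mm) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(spacer)))
  m <- nchar(spacer)
  out <- list()
  for (strand in c("+", "-")) {
    pat <- strsplit(if (strand == "+") spacer else rc, "")[[1]]
    for (p in seq_len(nchar(seq) - m + 1L)) {
      winchars <- strsplit(substr(seq, p, p + m - 1L), "")[[1]]
      mm <- sum(winchars != pat)
      if (mm <= max_mm)
        out[[length(out) + 1L]] <- data.frame(position = p,
                                              strand = strand,
                                              mismatches = mm)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(position = integer(0), strand = character(0),
                  mismatches = integer(0))
}

# brute-force circular digest via the doubled linear sequence: find
# every site occurrence by sliding-window IUPAC comparison, keep one
# period of cut points, and derive fragment lengths
oracle_circular_digest <- function(seq, site, cut_top) {
  iupac <- list(A = "A", C = "C", G = "G", T = "T", R = c("A", "G"),
                Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
                K = c("G", "T"), M = c("A", "C"), B = c("C", "G", "T"),
                D = c("A", "G", "T"), H = c("A", "C", "T"),
                V = c("A", "C", "G"), N = c("A", "C", "G", "T"))
  n <- nchar(seq)
  doubled <- paste0(seq, seq)
  pat <- strsplit(site, "")[[1]]
  cuts <- integer(0)
  for (p in seq_len(n)) {
    win <- strsplit(substr(doubled, p, p + length(pat) - 1L), "")[[1]]
    if (all(mapply(function(w, s) w %in% iupac[[s]], win, pat))) {
      cuts <- c(cuts, ((p + cut_top - 1L - 1L) %% n) + 1L)
    }
  }
  cuts <- sort(unique(cuts))
  if (!length(cuts)) return(n)
  diff(c(cuts, cuts[1] + n))
}

# full-matrix Smith-Waterman with affine gaps under BLOSUM62 (score
# only); the package's aligner must reproduce these scores
oracle_local_score <- function(a, b, gap_open = 11, gap_ext = 1) {
  e <- new.env(); utils::data("BLOSUM62", package = "Biostrings", envir = e)
  sub <- get("BLOSUM62", envir = e)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  la <- length(A); lb <- length(B)
  M <- X <- Y <- matrix(-Inf, la + 1, lb + 1)
  M[1, ] <- 0; M[, 1] <- 0
  best <- 0
  for (i in seq_len(la)) for (j in seq_len(lb)) {
    X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_ext,
                           X[i, j + 1] - gap_ext)
    Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_ext,
                           Y[i + 1, j] - gap_ext)
    M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) +
      sub[A[i], B[j]]
    best <- max(best, M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
  }
  best
}

# random protein sequence
r_protein <- function(n) {
  paste(sample(c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I", "L",
                 "K", "M", "F", "P", "S", "T", "W", "Y", "V"), n,
               replace = TRUE), collapse = "")
}

random_dna <- function(n, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# global-alignment identity of two ungapped-comparable sequences using
# Biostrings (used to verify mutate_family targets independently)
oracle_global_identity <- function(a, b) {
  make <- getExportedValue("Biostrings",
                           if (grepl("[^ACGT]", a)) "AAString"
                           else "DNAString")
  al <- Biostrings::pairwiseAlignment(make(a), make(b), type = "global")
  Biostrings::nmatch(al) / Biostrings::nchar(al)
}
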