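# run expr with a private, seeded RNG stream, restoring global state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Specify a synthetic virus genome
#'
#' The generator emulates the architecture of a headful-packaged
#' halovirus unit genome: a left arm of forward-strand morphogenesis
#' genes, an optional invertible tail-fiber region (an expressed fiber
#' gene and an inverted, frame-disrupted paralog flanking an
#' integrase), a reverse-strand replication arm, and a short
#' forward-strand accessory module; genes are closely spaced with a
#' controlled share of 4-nt `ATGA` stop/start overlaps, codons are
#' sampled so that both the G+C target and the stop-codon bias are
#' honoured, and everything is deterministic under the seed.
#'
#' @param unit_length Circular genome length in nt.
#' @param gc_target Target G+C fraction (default 0.65, the halovirus
#'   range).
#' @param module_layout Optional data.frame with columns `module`,
#'   `strand`, `n_genes`, `mean_len` overriding the default layout.
#' @param stop_codon_bias Probabilities over `TGA`, `TAA`, `TAG`
#'   (default 0.65/0.22/0.12, renormalised; the haloarchaeal
#'   preference).
#' @param coding_at_skew A/T asymmetry of coding-strand codons in
#'   `[-0.9, 0.9]`: P(A) and P(T) become `(1-gc)/2 * (1 +- skew)`.
#'   The default 0.15 reproduces the empirical pattern that cumulative
#'   AT-skew parallels transcription direction; set 0 for a fully
#'   uniform codon sampler.
#' @param invertible_region Emit the invertible tail-fiber module?
#' @param seed Integer seed.
#' @param id Genome identifier.
#' @return Object of class `"genome_spec"`.
#' @export
genome_spec <- function(unit_length, gc_target = 0.65,
                        module_layout = NULL,
                        stop_codon_bias = c(TGA = 0.65, TAA = 0.22, TAG = 0.12),
                        invertible_region = FALSE, seed = 1L,
                        id = "synth", coding_at_skew = 0.15) {
  unit_length <- as.integer(unit_length)
  stopifnot(unit_length >= 3000L, gc_target > 0, gc_target < 1)
  stopifnot(abs(coding_at_skew) <= 0.9)
  stop_codon_bias <- stop_codon_bias / sum(stop_codon_bias)
  if (!all(c("TGA", "TAA", "TAG") %in% names(stop_codon_bias)))
    stop("stop_codon_bias must name TGA, TAA and TAG")
  if (is.null(module_layout)) {
    # default layout scaled to the genome: ~40% morphogenesis (+),
    # ~26% replication (-), ~10% accessory (+); the rest is the
    # invertible region (if any), gene spacing and intergenic sequence
    n_morph <- max(2L, round(unit_length * 0.40 / 900))
    n_rep <- max(2L, round(unit_length * 0.26 / 700))
    n_acc <- max(1L, round(unit_length * 0.10 / 500))
    module_layout <- data.frame(
      module = c("morphogenesis", "replication", "accessory"),
      strand = c("+", "-", "+"),
      n_genes = c(n_morph, n_rep, n_acc),
      mean_len = c(900, 700, 500))
  }
  budget <- sum(module_layout$n_genes * module_layout$mean_len) +
    (if (invertible_region) 2600 else 0)
  if (budget > unit_length * 0.95)
    stop("layout overflow: modules exceed unit_length")
  structure(list(unit_length = unit_length, gc_target = gc_target,
                 module_layout = module_layout,
                 stop_codon_bias = stop_codon_bias,
                 invertible_region = invertible_region,
                 seed = as.integer(seed), id = id,
                 coding_at_skew = coding_at_skew),
            class = "genome_spec")
}

# expected G+C fraction of a non-stop codon when bases are drawn iid
# with per-base G+C weight gc and A/T asymmetry at_skew
codon_gc_mean <- function(gc, at_skew = 0) {
  p <- c(A = (1 - gc) / 2 * (1 + at_skew), C = gc / 2, G = gc / 2,
         T = (1 - gc) / 2 * (1 - at_skew))
  bases <- names(p)
  tot <- 0; totp <- 0
  for (b1 in bases) for (b2 in bases) for (b3 in bases) {
    if (paste0(b1, b2, b3) %in% c("TGA", "TAA", "TAG")) next
    pr <- p[[b1]] * p[[b2]] * p[[b3]]
    tot <- tot + pr * sum(c(b1, b2, b3) %in% c("G", "C")) / 3
    totp <- totp + pr
  }
  tot / totp
}

# per-base G+C weight that makes stop-free codon sampling hit the
# target (rejecting AT-rich stop codons would otherwise inflate G+C
# by about one percent)
adjust_codon_gc <- function(target, at_skew = 0) {
  stats::uniroot(function(g) codon_gc_mean(g, at_skew) - target,
                 c(0.02, 0.98), tol = 1e-9)$root
}

# one random codon, GC-weighted per base with optional A/T asymmetry,
# never a stop codon
r_codon <- function(n, gc, at_skew = 0) {
  p <- c(A = (1 - gc) / 2 * (1 + at_skew), C = gc / 2, G = gc / 2,
         T = (1 - gc) / 2 * (1 - at_skew))
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      cod <- paste(sample(names(p), 3L, replace = TRUE, prob = p),
                   collapse = "")
      if (!cod %in% c("TGA", "TAA", "TAG")) break
    }
    out[i] <- cod
  }
  out
}

r_bases <- function(n, gc) {
  if (n <= 0L) return("")
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# one coding sequence of len nt (multiple of 3, incl. stop), ATG start
r_gene <- function(len, gc, stop_bias, end_atga = FALSE, start_a4 = FALSE,
                   at_skew = 0) {
  ncod <- len / 3L
  stopifnot(ncod >= 3L)
  body <- r_codon(ncod - 1L, gc, at_skew)
  body[1] <- "ATG"
  stop_cod <- sample(names(stop_bias), 1L, prob = stop_bias)
  if (end_atga) {
    stop_cod <- "TGA"
    # force the base before the stop codon to A (and keep no stop)
    last <- body[length(body)]
    repeat {
      cand <- paste0(substr(last, 1, 2), "A")
      if (!cand %in% c("TGA", "TAA", "TAG")) break
      last <- r_codon(1L, gc, at_skew)
    }
    body[length(body)] <- paste0(substr(last, 1, 2), "A")
  }
  if (start_a4 && length(body) >= 2L) {
    # second codon starts with A so a 4-nt ATGA overlap stays consistent
    body[2] <- paste0("A", substr(body[2], 2, 3))
  }
  paste0(paste(body, collapse = ""), stop_cod)
}

#' Simulate a synthetic virus genome and its annotation
#'
#' @param spec A [genome_spec].
#' @return List with elements `genome` (a circular [genome]) and
#'   `features` (a [feature_table]).  When the spec asks for an
#'   invertible region, the ground truth (bounds and the loci of the
#'   fiber gene, its inverted paralog fragments and the integrase) is
#'   attached to the feature table as attribute
#'   `"invertible_region"`.
#' @export
simulate_genome <- function(spec) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, {
    # genes use a stop-rejection-corrected base weight; intergenic
    # sequence uses the raw target
    gc <- adjust_codon_gc(spec$gc_target, spec$coding_at_skew)
    gc_nc <- spec$gc_target
    pieces <- character(0)
    feats <- list()
    inv_truth <- NULL
    pos <- 1L
    add_piece <- function(s) {
      pieces[[length(pieces) + 1L]] <<- s
      pos <<- pos + nchar(s)
    }
    add_piece(r_bases(60L, gc_nc))  # leader after the origin
    locus_i <- 0L
    next_tag <- function() {
      locus_i <<- locus_i + 5L
      sprintf("%s_%03d", spec$id, locus_i)
    }
    emit_module <- function(mod) {
      lens <- pmax(150L, round(stats::rnorm(mod$n_genes, mod$mean_len,
                                            0.25 * mod$mean_len)))
      lens <- as.integer(3L * round(lens / 3L))
      # plan gaps: ~35% ATGA overlaps (forward modules), ~40% 0-15 nt
      gaps <- integer(mod$n_genes - 1L)
      if (mod$n_genes > 1L) for (i in seq_len(mod$n_genes - 1L)) {
        u <- stats::runif(1)
        gaps[i] <- if (u < 0.35 && mod$strand == "+") -4L
                   else if (u < 0.75) sample(0:15, 1L)
                   else sample(16:120, 1L)
      }
      # ATGA overlaps force a TGA stop on the upstream gene; deflate
      # TGA for the remaining genes so the module-wide stop usage
      # still matches the requested bias
      bias <- spec$stop_codon_bias
      k_forced <- sum(gaps == -4L)
      if (k_forced > 0L && mod$n_genes > k_forced) {
        adj <- max(0.02, (bias[["TGA"]] * mod$n_genes - k_forced) /
                           (mod$n_genes - k_forced))
        oth <- bias[c("TAA", "TAG")] / sum(bias[c("TAA", "TAG")])
        bias <- c(TGA = adj, (1 - adj) * oth)
      }
      if (mod$strand == "+") {
        for (i in seq_len(mod$n_genes)) {
          ov_prev <- i > 1L && gaps[i - 1L] == -4L
          ov_next <- i < mod$n_genes && gaps[i] == -4L
          gene <- r_gene(lens[i], gc, bias,
                         end_atga = ov_next, start_a4 = ov_prev,
                         at_skew = spec$coding_at_skew)
          if (ov_prev) {
            # gene starts 4 nt before the previous stop's end
            start <- pos - 4L
            add_piece(substr(gene, 5L, lens[i]))
          } else {
            if (i > 1L) add_piece(r_bases(gaps[i - 1L], gc_nc))
            start <- pos
            add_piece(gene)
          }
          feats[[length(feats) + 1L]] <<- data.frame(
            locus_tag = next_tag(), start = start,
            stop = start + lens[i] - 1L, strand = "+",
            gene = NA_character_,
            product = paste0(mod$module, " protein"))
        }
      } else {
        gaps[gaps == -4L] <- 4L
        for (i in seq_len(mod$n_genes)) {
          if (i > 1L) add_piece(r_bases(gaps[i - 1L], gc_nc))
          gene <- r_gene(lens[i], gc, spec$stop_codon_bias,
                         at_skew = spec$coding_at_skew)
          start <- pos
          add_piece(rev_comp(gene))
          feats[[length(feats) + 1L]] <<- data.frame(
            locus_tag = next_tag(), start = start,
            stop = start + lens[i] - 1L, strand = "-",
            gene = NA_character_,
            product = paste0(mod$module, " protein"))
        }
      }
    }
    layout <- spec$module_layout
    for (m in seq_len(nrow(layout))) {
      emit_module(layout[m, ])
      if (layout$module[m] == layout$module[1] && spec$invertible_region) {
        # invertible tail-fiber region right after the left arm
        add_piece(r_bases(40L, gc_nc))
        fiber_len <- 900L
        fiber <- r_gene(fiber_len, gc, spec$stop_codon_bias,
                        at_skew = spec$coding_at_skew)
        fib_start <- pos
        add_piece(fiber)
        fib_tag <- next_tag()
        feats[[length(feats) + 1L]] <- data.frame(
          locus_tag = fib_tag, start = fib_start,
          stop = fib_start + fiber_len - 1L, strand = "+",
          gene = "fib", product = "repeat-containing tail fiber protein")
        add_piece(r_bases(30L, gc_nc))
        int_len <- 675L
        int_start <- pos
        add_piece(r_gene(int_len, gc, spec$stop_codon_bias,
                         at_skew = spec$coding_at_skew))
        int_tag <- next_tag()
        feats[[length(feats) + 1L]] <- data.frame(
          locus_tag = int_tag, start = int_start,
          stop = int_start + int_len - 1L, strand = "+",
          gene = "int1", product = "tyrosine integrase/recombinase")
        add_piece(r_bases(30L, gc_nc))
        # inverted, frame-disrupted paralog of the fiber gene: the two
        # pseudogene fragments sit on the minus strand, so the protein
        # C-term fragment is genome-left; a 2-nt spacer breaks the frame
        par_nt <- mutate_cds(fiber, 0.80)
        kcod <- floor(nchar(par_nt) / 3 * 0.4)
        nterm_nt <- substr(par_nt, 1L, 3L * kcod)
        cterm_nt <- substr(par_nt, 3L * kcod + 1L, nchar(par_nt) - 3L)
        c_start <- pos
        add_piece(rev_comp(cterm_nt))
        c_tag <- next_tag()
        feats[[length(feats) + 1L]] <- data.frame(
          locus_tag = c_tag, start = c_start,
          stop = c_start + nchar(cterm_nt) - 1L, strand = "-",
          gene = NA_character_,
          product = "repeat-containing tail fiber protein (C-term part, nonfunctional)")
        add_piece("GG")
        n_start <- pos
        add_piece(rev_comp(nterm_nt))
        n_tag <- next_tag()
        feats[[length(feats) + 1L]] <- data.frame(
          locus_tag = n_tag, start = n_start,
          stop = n_start + nchar(nterm_nt) - 1L, strand = "-",
          gene = NA_character_,
          product = "repeat-containing tail fiber protein (N-term part, nonfunctional)")
        inv_truth <- list(start = fib_start, end = pos - 1L,
                          fiber = fib_tag, integrase = int_tag,
                          paralog = c(n_tag, c_tag))
      }
      if (m < nrow(layout)) add_piece(r_bases(80L, gc_nc))
    }
    total <- pos - 1L
    if (total > spec$unit_length) stop("layout overflow: assembled ",
                                       total, " nt > unit_length")
    add_piece(r_bases(spec$unit_length - total, gc_nc))
    g <- genome(spec$id, paste(pieces, collapse = ""), "circular")
    ft <- feature_table(do.call(rbind, feats), genome_id = spec$id,
                        unit_length = spec$unit_length)
    attr(ft, "invertible_region") <- inv_truth
    list(genome = g, features = ft)
  })
}

# codon-aware mutant of a coding sequence: substitutes bases toward a
# target nt identity but never creates an in-frame stop codon (uses the
# current RNG stream)
mutate_cds <- function(nt, target_identity) {
  chars <- strsplit(nt, "", fixed = TRUE)[[1]]
  n <- length(chars)
  m <- round((1 - target_identity) * n)
  for (i in sample.int(n, m)) {
    cod_i <- (i - 1L) %/% 3L
    for (b in sample(setdiff(c("A", "C", "G", "T"), chars[i]))) {
      old <- chars[i]
      chars[i] <- b
      cod <- paste(chars[(3L * cod_i + 1L):(3L * cod_i + 3L)],
                   collapse = "")
      if (!cod %in% c("TGA", "TAA", "TAG")) break
      chars[i] <- old
    }
  }
  paste(chars, collapse = "")
}

#' Derive a diverged family member from an ancestor sequence
#'
#' Substitution-only by default, so the realised identity to the
#' ancestor under a global alignment is exactly the target (up to
#' rounding to whole sites).  With a positive `indel_rate`, insertions
#' and deletions of 1-3 residues are also applied and the identity
#' becomes approximate.
#'
#' @param ancestor Protein or nucleotide sequence (auto-detected, or
#'   set `alphabet`).
#' @param target_identity Target fractional identity in `(0, 1]`.
#' @param indel_rate Per-site indel probability (default 0).
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param alphabet `"auto"`, `"protein"` or `"dna"`.
#' @return The mutated sequence (character scalar).
#' @export
mutate_family <- function(ancestor, target_identity, indel_rate = 0,
                          seed = NULL, alphabet = c("auto", "protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (!nzchar(ancestor)) stop("empty ancestor sequence")
  if (alphabet == "auto") {
    alphabet <- if (grepl("[^ACGTN]", toupper(ancestor))) "protein" else "dna"
  }
  letters_ <- if (alphabet == "protein") names(AA_RESIDUE_MASS)
              else c("A", "C", "G", "T")
  floor_id <- if (alphabet == "protein") 0.08 else 0.3
  if (target_identity <= floor_id)
    stop("target_identity below the ", alphabet, " noise floor (",
         floor_id, ")")
  if (target_identity > 1) stop("target_identity must be <= 1")
  run <- function() {
    chars <- strsplit(toupper(ancestor), "", fixed = TRUE)[[1]]
    n <- length(chars)
    m <- round((1 - target_identity) * n)
    if (m > 0) {
      idx <- sample.int(n, m)
      for (i in idx) {
        chars[i] <- sample(setdiff(letters_, chars[i]), 1L)
      }
    }
    if (indel_rate > 0) {
      k <- stats::rbinom(1L, n, indel_rate)
      for (j in seq_len(k)) {
        at <- sample.int(length(chars), 1L)
        if (stats::runif(1) < 0.5) {
          chars <- chars[-at]
        } else {
          ins <- sample(letters_, sample(1:3, 1L), replace = TRUE)
          chars <- append(chars, ins, after = at)
        }
      }
    }
    paste(chars, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Simulate a headful virion population
#'
#' Packaging series are drawn from the model's series-length
#' distribution; the first virion of each series starts at the pac
#' position and each subsequent virion starts where the previous one
#' ended (processive headfuls), so start offsets advance by
#' `L * (1 + r) mod L`.  Every virion has length `L * (1 + r)`.
#'
#' @param g A circular [genome].
#' @param pm A [packaging_model] with `unit_length` equal to the genome
#'   length.
#' @param n Number of virions (> 0).
#' @param seed Integer seed (`NULL` uses the current RNG stream).
#' @param return `"sequences"` (default) or `"starts"` (just the
#'   1-based start positions; cheap for large n).
#' @return Character vector of virion sequences with attribute
#'   `"starts"`, or an integer vector of starts.
#' @export
simulate_virion_population <- function(g, pm, n, seed = NULL,
                                       return = c("sequences", "starts")) {
  return <- match.arg(return)
  if (n <= 0) stop("n must be positive")
  L <- genome_length(g)
  if (pm$unit_length != L)
    stop("packaging model unit_length does not match genome length")
  w <- virion_length(pm)
  draw <- function() {
    ks <- as.integer(names(pm$series_dist))
    starts <- integer(0)
    while (length(starts) < n) {
      s_len <- sample(ks, 1L, prob = pm$series_dist)
      starts <- c(starts,
                  ((pm$pac_position - 1L + (seq_len(s_len) - 1L) * w) %% L) + 1L)
    }
    starts[seq_len(n)]
  }
  starts <- if (is.null(seed)) draw() else with_seed(seed, draw())
  if (return == "starts") return(starts)
  big <- paste0(g$seq, g$seq)
  out <- substring(big, starts, starts + w - 1L)
  attr(out, "starts") <- starts
  out
}

#' Insert a mobile element into a CDS
#'
#' Splits the target CDS into N-terminal and C-terminal pseudogene
#' fragments (trimmed to codon boundaries on the coding strand),
#' shifts every downstream coordinate by the element length, and
#' optionally adds the element's own features.
#'
#' @param g A [genome].
#' @param ft A [feature_table] for `g`.
#' @param elem Element sequence (character).
#' @param target_locus Locus tag of the CDS to disrupt.
#' @param elem_features Optional data.frame of features relative to the
#'   element (columns as for [feature_table]).
#' @return List with updated `genome` and `features`.
#' @export
insert_is_element <- function(g, ft, elem, target_locus,
                              elem_features = NULL) {
  i <- match(target_locus, ft$locus_tag)
  if (is.na(i)) stop("target locus not found: ", target_locus)
  rec <- ft[i, ]
  if (rec$wraps_origin)
    stop("cannot target a CDS spanning the genome origin")
  L <- genome_length(g)
  el <- nchar(elem)
  # insertion point: mid-CDS, on a codon boundary of the coding strand
  half <- 3L * floor((rec$length / 2) / 3)
  pos <- rec$start + half  # element inserted before this base
  new_seq <- paste0(substr(g$seq, 1L, pos - 1L), toupper(elem),
                    substr(g$seq, pos, L))
  g2 <- genome(g$id, new_seq, g$topology)
  shift <- function(x) ifelse(x >= pos, x + el, x)
  df <- as.data.frame(ft)[, c("locus_tag", "start", "stop", "strand",
                              "gene", "product")]
  df <- df[-i, , drop = FALSE]
  df$start <- shift(df$start)
  df$stop <- shift(df$stop)
  left_len <- 3L * floor((pos - rec$start) / 3)
  right_start <- pos + el + (rec$stop - pos + 1L) %% 3L
  lab <- if (rec$strand == "+") c("N-term", "C-term") else c("C-term", "N-term")
  fragments <- data.frame(
    locus_tag = paste0(rec$locus_tag, c("_N", "_C")[match(lab, c("N-term", "C-term"))]),
    start = c(rec$start, right_start),
    stop = c(rec$start + left_len - 1L, rec$stop + el),
    strand = rec$strand, gene = rec$gene,
    product = paste0(sub(" \\(.*$", "", rec$product),
                     " (", lab, " part, nonfunctional)"))
  df <- rbind(df, fragments)
  if (!is.null(elem_features)) {
    ef <- elem_features
    ef$start <- ef$start + pos - 1L
    ef$stop <- ef$stop + pos - 1L
    if (is.null(ef$gene)) ef$gene <- NA_character_
    if (is.null(ef$product)) ef$product <- "transposase"
    df <- rbind(df, ef[, c("locus_tag", "start", "stop", "strand",
                           "gene", "product")])
  }
  ft2 <- feature_table(df, genome_id = attr(ft, "genome_id"),
                       unit_length = L + el)
  attr(ft2, "invertible_region") <- attr(ft, "invertible_region")
  list(genome = g2, features = ft2)
}
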