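#' Construct a genome object
#'
#' A genome is a single nucleotide sequence with an identifier and a
#' topology.  Unit genomes of headful-packaged viruses are circular: the
#' deposited linear sequence is one arbitrary (but conventional) opening
#' of the circle, and base 1 defines the origin used by all coordinate
#' arithmetic in the package.
#'
#' @param id Character scalar identifier.
#' @param seq Nucleotide sequence as a single character string.  Only
#'   `A`, `C`, `G`, `T` and `N` are allowed; lower case and `U` are
#'   normalised on input.
#' @param topology `"circular"` (default) or `"linear"`.
#' @return An object of class `"genome"`: a list with elements `id`,
#'   `seq` and `topology`.
#' @examples
#' g <- genome("toy", "ACGTACGT")
#' genome_length(g)
#' @export
genome <- function(id, seq, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  seq <- gsub("U", "T", seq, fixed = TRUE)
  if (!nzchar(seq)) stop("genome '", id, "': empty sequence")
  bad <- regexpr("[^ACGTN]", seq)
  if (bad > 0L) {
    stop("genome '", id, "': non-IUPAC character '",
         substr(seq, bad, bad), "' at position ", bad)
  }
  structure(list(id = id, seq = seq, topology = topology), class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat(sprintf("<genome> %s: %s nt, %s\n", x$id,
              format(nchar(x$seq), big.mark = ","), x$topology))
  invisible(x)
}

#' Genome length in nucleotides
#' @param g A [genome] object.
#' @return Integer length.
#' @export
genome_length <- function(g) nchar(g$seq)

#' Read genomes from a FASTA file
#'
#' Sequences are uppercased and `U` is converted to `T`.  Topology
#' defaults to circular because the package's subject matter is unit
#' genomes of circularly permuted viruses.
#'
#' @param path Path to a (multi-record) FASTA file.
#' @param topology Topology assigned to every record.
#' @return A named list of [genome] objects.
#' @export
read_fasta <- function(path, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    genome(ids[i], as.character(set[[i]]), topology)
  })
  names(out) <- ids
  out
}

#' Write genomes to a FASTA file
#' @param genomes A [genome] or list of genomes.
#' @param path Output path.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genomes, path, width = 70L) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  con <- file(path, "w")
  on.exit(close(con))
  for (g in genomes) {
    writeLines(paste0(">", g$id), con)
    n <- nchar(g$seq)
    starts <- seq(1L, n, by = width)
    writeLines(substring(g$seq, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Construct a feature table
#'
#' A feature table is an ordered set of CDS records in the 1-based,
#' inclusive coordinate convention of published virus annotation tables:
#' `start` is always the leftmost genome coordinate except for a record
#' that wraps the circular origin, which has `stop < start` (for example
#' a terminase small-subunit gene spanning the join).  Strand is encoded
#' as `"+"`/`"-"` in the `strand` column; minus-strand records still
#' store leftmost-first coordinates.
#'
#' @param df A data.frame with columns `locus_tag`, `start`, `stop`,
#'   `strand`; optional `gene` and `product`.
#' @param genome_id Identifier of the genome the features belong to.
#' @param unit_length Length of the (circular) genome; required to
#'   validate wrap-around records.
#' @return A data.frame of class `"feature_table"` with the additional
#'   columns `wraps_origin` and `length`, sorted by leftmost coordinate.
#' @export
feature_table <- function(df, genome_id = NA_character_, unit_length = NULL) {
  req <- c("locus_tag", "start", "stop", "strand")
  miss <- setdiff(req, names(df))
  if (length(miss)) stop("feature table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) stop("empty feature table")
  if (anyDuplicated(df$locus_tag))
    stop("duplicate locus_tag: ",
         paste(unique(df$locus_tag[duplicated(df$locus_tag)]), collapse = ", "))
  df$start <- as.integer(df$start)
  df$stop <- as.integer(df$stop)
  if (anyNA(df$start) || anyNA(df$stop))
    stop("non-numeric coordinates in feature table")
  if (any(df$start < 1L) || any(df$stop < 1L))
    stop("coordinates must be >= 1")
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  if (is.null(df$gene)) df$gene <- NA_character_
  if (is.null(df$product)) df$product <- NA_character_
  df$wraps_origin <- df$stop < df$start
  if (any(df$wraps_origin) && is.null(unit_length))
    stop("wrap-around record present but unit_length not given")
  if (!is.null(unit_length)) {
    unit_length <- as.integer(unit_length)
    if (any(df$start > unit_length) || any(df$stop > unit_length))
      stop("coordinates exceed unit_length")
    df$length <- ifelse(df$wraps_origin,
                        unit_length - df$start + 1L + df$stop,
                        df$stop - df$start + 1L)
  } else {
    df$length <- df$stop - df$start + 1L
  }
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  keep <- c("locus_tag", "start", "stop", "strand", "gene", "product",
            "wraps_origin", "length")
  extra <- setdiff(names(df), keep)
  df <- df[, c(keep, extra), drop = FALSE]
  attr(df, "genome_id") <- genome_id
  attr(df, "unit_length") <- unit_length
  class(df) <- c("feature_table", "data.frame")
  df
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d records", attr(x, "genome_id"), nrow(x)))
  if (!is.null(attr(x, "unit_length")))
    cat(sprintf(" (unit length %s nt)",
                format(attr(x, "unit_length"), big.mark = ",")))
  cat("\n")
  print.data.frame(utils::head(as.data.frame(x), 8))
  if (nrow(x) > 8) cat("... ", nrow(x) - 8, " more rows\n", sep = "")
  invisible(x)
}

#' Read a CDS feature table from TSV
#'
#' Expects tab-separated columns `start`, `stop`, `locus_tag`,
#' `direction` (or `strand`), and optionally `length`, `gene`,
#' `product`.  A record whose `stop` is smaller than its `start` is
#' interpreted as wrapping the circular origin (the published
#' `"54915> <63"` convention); any `>`/`<` decorations are stripped.
#' If a `length` column is present it is checked against the length
#' implied by the coordinates (modulo the unit length for a wrapping
#' record).
#'
#' @param path Path to the TSV file.
#' @param unit_length Circular unit-genome length (needed for
#'   wrap-around records and length validation).
#' @param genome_id Identifier stored on the returned table.
#' @return A [feature_table].
#' @export
read_feature_table <- function(path, unit_length = NULL,
                               genome_id = NA_character_) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, quote = "",
                          comment.char = "#")
  if (nrow(df) == 0L) stop("empty feature table: ", path)
  names(df) <- tolower(names(df))
  if ("direction" %in% names(df) && !"strand" %in% names(df))
    names(df)[names(df) == "direction"] <- "strand"
  for (col in c("start", "stop")) {
    if (is.character(df[[col]])) {
      df[[col]] <- gsub("[<>]", "", df[[col]])
      suppressWarnings(df[[col]] <- as.integer(df[[col]]))
      if (anyNA(df[[col]])) stop("non-numeric '", col, "' in ", path)
    }
  }
  ft <- feature_table(df, genome_id = genome_id, unit_length = unit_length)
  if ("length" %in% names(df)) {
    given <- as.integer(df$length[match(ft$locus_tag, df$locus_tag)])
    bad <- which(!is.na(given) & given != ft$length)
    if (length(bad))
      stop("length column disagrees with coordinates for: ",
           paste(ft$locus_tag[bad], collapse = ", "))
  }
  ft
}

#' Write a feature table to TSV
#' @param ft A [feature_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path) {
  out <- as.data.frame(ft)[, c("start", "stop", "locus_tag", "length",
                               "strand", "gene", "product")]
  names(out)[names(out) == "strand"] <- "direction"
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Define a restriction enzyme
#'
#' Recognition sites use IUPAC ambiguity codes.  Cut offsets count bases
#' 3' of the site start on each strand, so EcoRI is
#' `enzyme_def("EcoRI", "GAATTC", 1, 5)` (G^AATTC).
#'
#' @param name Enzyme name.
#' @param site Recognition site (IUPAC, length >= 4).
#' @param cut_top,cut_bottom Cut offsets for the top and bottom strand,
#'   in `[0, nchar(site)]` for within-site cutters.
#' @return A one-row data.frame of class `"enzyme_def"`.
#' @export
enzyme_def <- function(name, site, cut_top, cut_bottom) {
  site <- toupper(site)
  if (nchar(site) < 4L) stop("recognition site shorter than 4 nt: ", name)
  iupac <- "ACGTRYSWKMBDHVN"
  bad <- regexpr(sprintf("[^%s]", iupac), site)
  if (bad > 0L) stop("unknown IUPAC code '", substr(site, bad, bad),
                     "' in site of ", name)
  cut_top <- as.integer(cut_top); cut_bottom <- as.integer(cut_bottom)
  if (anyNA(c(cut_top, cut_bottom)))
    stop("non-numeric cut offsets for ", name)
  if (cut_top < 0L || cut_top > nchar(site) ||
      cut_bottom < 0L || cut_bottom > nchar(site))
    stop("cut offsets outside [0, site length] for ", name)
  structure(data.frame(name = name, site = site, cut_top = cut_top,
                       cut_bottom = cut_bottom, stringsAsFactors = FALSE),
            class = c("enzyme_def", "data.frame"))
}

#' Is a recognition site palindromic?
#' @param e An [enzyme_def].
#' @return Logical: `TRUE` when the site equals its reverse complement
#'   (IUPAC-aware).
#' @export
is_palindromic <- function(e) {
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAString(e$site)))
  identical(rc, e$site)
}

#' Read restriction-enzyme definitions
#'
#' One whitespace-separated definition per line: name, IUPAC site, top
#' cut offset, bottom cut offset.  Lines starting with `#` are skipped.
#'
#' @param path Path to the definitions file.
#' @return A list of [enzyme_def] objects, named by enzyme.
#' @export
read_enzymes <- function(path) {
  lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no enzyme definitions in ", path)
  out <- lapply(lines, function(ln) {
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 4L) stop("malformed enzyme line: ", ln)
    enzyme_def(f[1], f[2], f[3], f[4])
  })
  names(out) <- vapply(out, function(e) e$name, "")
  out
}

#' Construct a band list
#'
#' Observed or predicted gel band sizes, stored sorted in descending
#' order.  Units are tagged (`"nt"` for DNA fragment lengths, `"kda"`
#' for protein bands) so that mismatched comparisons fail loudly.
#'
#' @param sizes Numeric vector of positive sizes.
#' @param unit `"nt"` or `"kda"`.
#' @param source `"observed"` or `"predicted"`.
#' @return A numeric vector of class `"band_list"`.
#' @export
band_list <- function(sizes, unit = c("nt", "kda"),
                      source = c("observed", "predicted")) {
  unit <- match.arg(unit); source <- match.arg(source)
  sizes <- as.numeric(sizes)
  if (!length(sizes)) stop("empty band list")
  if (any(!is.finite(sizes)) || any(sizes <= 0))
    stop("band sizes must be positive")
  sizes <- sort(sizes, decreasing = TRUE)
  structure(sizes, unit = unit, source = source, class = "band_list")
}

#' @export
print.band_list <- function(x, ...) {
  cat(sprintf("<band_list> %d %s band(s) (%s): %s\n", length(x),
              attr(x, "source"), attr(x, "unit"),
              paste(signif(unclass(x), 4), collapse = ", ")))
  invisible(x)
}

#' Write a phylogenetic tree in Newick format
#' @param tree An [ape::phylo] tree (internal node labels carry
#'   bootstrap supports).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  if (!inherits(tree, "phylo")) stop("not a phylo tree")
  ape::write.tree(tree, file = path)
  invisible(path)
}

#' Read a Newick tree
#' @param path Path to a Newick file.
#' @return An [ape::phylo] object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("could not parse Newick file: ", path)
  tr
}

#' Write an analysis result to TSV or JSON
#'
#' Data frames round-trip through TSV; arbitrary (list-like) results are
#' serialised as JSON.
#'
#' @param result A data.frame (for TSV) or list/data.frame (for JSON).
#' @param path Output path.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_report <- function(result, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    if (!is.data.frame(result)) stop("TSV reports require a data.frame")
    utils::write.table(result, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(result, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  }
  invisible(path)
}

# -- internal coordinate helpers ------------------------------------------

# substring of a circular sequence; from..to inclusive 1-based, wrapping
# allowed (to < from reads across the origin)
circ_substr <- function(seq, from, to) {
  n <- nchar(seq)
  from <- ((from - 1L) %% n) + 1L
  to <- ((to - 1L) %% n) + 1L
  if (from <= to) substr(seq, from, to)
  else paste0(substr(seq, from, n), substr(seq, 1L, to))
}

rev_comp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

#' Extract the coding-strand sequence of a CDS
#'
#' Handles origin-wrapping records (concatenated across the join) and
#' minus-strand records (reverse-complemented), returning the sequence
#' as read by the ribosome.
#'
#' @param g A [genome].
#' @param rec One row of a [feature_table] (data.frame or list).
#' @return Character string of the coding-strand nucleotide sequence.
#' @export
cds_seq <- function(g, rec) {
  s <- if (isTRUE(rec$wraps_origin)) {
    if (g$topology != "circular")
      stop("wrap-around CDS on a linear genome: ", rec$locus_tag)
    paste0(substr(g$seq, rec$start, nchar(g$seq)),
           substr(g$seq, 1L, rec$stop))
  } else {
    substr(g$seq, rec$start, rec$stop)
  }
  if (rec$strand == "-") s <- rev_comp(s)
  s
}
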