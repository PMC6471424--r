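# Average (isotope-averaged) residue masses in Da, Expasy convention,
# and the mass of one water added per chain.
AA_RESIDUE_MASS <- c(
  A = 71.0788, R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519, H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782, T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
WATER_MASS <- 18.01528

#' Translate a CDS to protein
#'
#' Standard genetic code; the initiator codon is translated as M
#' whatever its identity (GTG/TTG starts are common in haloarchaea),
#' the terminal stop codon is removed, minus-strand records are
#' reverse-complemented first and origin-wrapping records are
#' concatenated across the join.  An internal stop codon is an error
#' naming the locus.
#'
#' @param g A [genome].
#' @param rec One row of a [feature_table].
#' @return Amino-acid string.
#' @export
translate_cds <- function(g, rec) {
  s <- cds_seq(g, rec)
  if (nchar(s) %% 3L != 0L)
    stop("CDS length not divisible by 3: ", rec$locus_tag)
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(s),
                                           if.fuzzy.codon = "X"))
  substr(aa, 1L, 1L) <- "M"
  n <- nchar(aa)
  if (substr(aa, n, n) == "*") aa <- substr(aa, 1L, n - 1L)
  if (grepl("*", aa, fixed = TRUE))
    stop("internal stop codon in ", rec$locus_tag)
  aa
}

#' Average molecular weight of a protein sequence
#'
#' Sum of average residue masses plus one water.  Average (not
#' monoisotopic) masses are used because the quantity is compared with
#' SDS-PAGE sizing.
#'
#' @param p Amino-acid string (standard 20-letter alphabet).
#' @return Mass in Da.
#' @export
average_mw <- function(p) {
  if (!nzchar(p)) stop("empty protein sequence")
  aa <- strsplit(p, "", fixed = TRUE)[[1]]
  unknown <- setdiff(unique(aa), names(AA_RESIDUE_MASS))
  if (length(unknown))
    stop("unknown amino acid letter(s): ", paste(unknown, collapse = ", "))
  sum(AA_RESIDUE_MASS[aa]) + WATER_MASS
}

#' Acidic-residue fraction
#' @param p Amino-acid string.
#' @return Fraction of residues that are Asp or Glu.
#' @export
acidic_fraction <- function(p) {
  aa <- strsplit(p, "", fixed = TRUE)[[1]]
  sum(aa %in% c("D", "E")) / length(aa)
}

#' SDS-PAGE mobility shift for acidic proteins
#'
#' Acidic proteins migrate anomalously slowly on SDS-PAGE; the apparent
#' molecular weight exceeds the sequence-derived one by a shift that is
#' linear in the acidic-residue fraction:
#' `shift = len * (276.5 * x - 31.33)` Da, where `len` is the protein
#' length in residues and `x` the fraction of Asp+Glu.  The shift is
#' negative below the zero-crossing at `x = 31.33/276.5` (about 11.3%
#' acidic residues).
#'
#' @param len Protein length in residues (> 0).
#' @param x Acidic fraction in `[0, 1]`.
#' @return Shift in Da (added to the real MW to give the apparent MW).
#' @export
sds_shift <- function(len, x) {
  if (any(len <= 0)) stop("len must be positive")
  if (any(x < 0 | x > 1)) stop("x must be in [0, 1]")
  len * (276.5 * x - 31.33)
}

#' Apparent SDS-PAGE molecular weight of an annotated CDS
#'
#' Composes translation, sequence MW, acidic fraction and the acidic
#' mobility-shift correction.
#'
#' @param g A [genome].
#' @param rec One row of a [feature_table].
#' @return A one-row data.frame of class `"protein_record"` with
#'   columns `locus_tag`, `len`, `x`, `mw_real`, `shift`, `mw_app`
#'   (Da) and the sequence in attribute `"seq"`.
#' @export
apparent_mw <- function(g, rec) {
  p <- translate_cds(g, rec)
  len <- nchar(p)
  x <- acidic_fraction(p)
  mw_real <- average_mw(p)
  shift <- sds_shift(len, x)
  out <- data.frame(locus_tag = rec$locus_tag, len = len, x = x,
                    mw_real = mw_real, shift = shift,
                    mw_app = mw_real + shift)
  attr(out, "seq") <- p
  class(out) <- c("protein_record", "data.frame")
  out
}

#' Apparent molecular weights for a whole feature table
#'
#' CDS that do not translate cleanly (internal stops, e.g. pseudogene
#' fragments) are skipped with a warning and listed in the
#' `"skipped"` attribute.
#'
#' @param g A [genome].
#' @param ft A [feature_table].
#' @return Data.frame with one row per translatable CDS (columns as in
#'   [apparent_mw()]).
#' @export
apparent_mw_table <- function(g, ft) {
  rows <- lapply(seq_len(nrow(ft)), function(i) {
    tryCatch(as.data.frame(apparent_mw(g, ft[i, ])),
             error = function(e) NULL)
  })
  skipped <- ft$locus_tag[vapply(rows, is.null, TRUE)]
  if (length(skipped))
    warning("skipped untranslatable CDS: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}

#' Assign predicted proteins to observed gel bands
#'
#' Nearest match in log-MW space within a relative tolerance; each
#' observed band takes at most one prediction (the closest), and
#' observed bands heavier than every prediction are flagged as possible
#' multimers or unannotated proteins.
#'
#' @param proteins Data.frame from [apparent_mw_table()] (columns
#'   `locus_tag`, `mw_app` in Da).
#' @param observed A [band_list] in kDa, or numeric vector of kDa.
#' @param rel_tol Relative tolerance in `(0, 0.2]` (default 0.05).
#' @return List of class `"band_assignment"`: `assigned` (data.frame
#'   band_kda, locus_tag, mw_app_kda, rel_error), `unassigned_observed`
#'   (data.frame band_kda, note), `unassigned_proteins` (locus tags).
#' @export
assign_bands <- function(proteins, observed, rel_tol = 0.05) {
  if (rel_tol <= 0 || rel_tol > 0.2) stop("rel_tol must be in (0, 0.2]")
  obs <- sort(as.numeric(observed), decreasing = TRUE)
  pred_kda <- proteins$mw_app / 1000
  taken <- rep(FALSE, nrow(proteins))
  assigned <- data.frame(band_kda = numeric(0), locus_tag = character(0),
                         mw_app_kda = numeric(0), rel_error = numeric(0))
  un_obs <- data.frame(band_kda = numeric(0), note = character(0))
  for (b in obs) {
    err <- abs(log(pred_kda) - log(b))
    err[taken] <- Inf
    j <- which.min(err)
    if (length(j) && is.finite(err[j]) && err[j] <= log1p(rel_tol)) {
      assigned <- rbind(assigned, data.frame(
        band_kda = b, locus_tag = proteins$locus_tag[j],
        mw_app_kda = pred_kda[j],
        rel_error = abs(pred_kda[j] - b) / b))
      taken[j] <- TRUE
    } else {
      note <- if (all(b > pred_kda)) "possible multimer/unannotated"
              else "no prediction within tolerance"
      un_obs <- rbind(un_obs, data.frame(band_kda = b, note = note))
    }
  }
  structure(list(assigned = assigned, unassigned_observed = un_obs,
                 unassigned_proteins = proteins$locus_tag[!taken]),
            class = "band_assignment")
}

#' @export
print.band_assignment <- function(x, ...) {
  cat("<band_assignment>", nrow(x$assigned), "band(s) assigned,",
      nrow(x$unassigned_observed), "observed unassigned\n")
  if (nrow(x$assigned)) print.data.frame(x$assigned)
  if (nrow(x$unassigned_observed)) print.data.frame(x$unassigned_observed)
  invisible(x)
}
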