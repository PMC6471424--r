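#' Describe a headful packaging model
#'
#' Headful packaging fills capsids processively from a concatemer,
#' starting at the pac site.  Each virion receives slightly more than
#' one unit genome (`unit_length * (1 + redundancy)` nt), so virion ends
#' are terminally redundant and, after the first headful of a series,
#' circularly permuted.
#'
#' @param unit_length Unit (circular) genome length L in nt.
#' @param redundancy Terminal redundancy r as a fraction of L, in
#'   `[0, 1)`.
#' @param pac_position 1-based position of the packaging-initiation
#'   terminal base; the first virion of every series starts here.
#' @param series_dist Probability distribution over the number of
#'   headfuls packaged per concatemer series: a named numeric vector
#'   (names = headful counts).  Default: uniform over 1..5.
#' @return An object of class `"packaging_model"`.
#' @export
packaging_model <- function(unit_length, redundancy, pac_position,
                            series_dist = NULL) {
  unit_length <- as.integer(unit_length)
  stopifnot(unit_length > 0)
  if (redundancy < 0 || redundancy >= 1)
    stop("redundancy must be in [0, 1)")
  pac_position <- as.integer(pac_position)
  if (pac_position < 1L || pac_position > unit_length)
    stop("pac_position must be in [1, unit_length]")
  if (is.null(series_dist))
    series_dist <- stats::setNames(rep(1 / 5, 5), 1:5)
  if (is.null(names(series_dist)) ||
      any(is.na(suppressWarnings(as.integer(names(series_dist))))))
    stop("series_dist must be named by headful counts")
  if (any(series_dist < 0) || abs(sum(series_dist) - 1) > 1e-8)
    stop("series_dist must be a probability distribution")
  structure(list(unit_length = unit_length, redundancy = redundancy,
                 pac_position = pac_position, series_dist = series_dist),
            class = "packaging_model")
}

#' @export
print.packaging_model <- function(x, ...) {
  cat(sprintf(
    "<packaging_model> L = %d nt, r = %.3f (virion %d nt), pac at %d\n",
    x$unit_length, x$redundancy, virion_length(x), x$pac_position))
  invisible(x)
}

# packaged virion length in nt
virion_length <- function(pm) as.integer(round(pm$unit_length * (1 + pm$redundancy)))

#' Find restriction sites on a genome
#'
#' Returns 1-based top-strand cut coordinates: a cut coordinate `c`
#' means the phosphodiester bond after base `c` is broken (`c = L` is
#' the bond between base L and base 1 of a circular genome).  IUPAC
#' ambiguity codes in the recognition site are honoured, sites spanning
#' the origin of a circular genome are found, and for non-palindromic
#' sites both strands are searched (the top-strand cut implied by the
#' bottom-strand geometry is reported).
#'
#' @param g A [genome].
#' @param e An [enzyme_def].
#' @return Sorted integer vector of cut coordinates (possibly empty).
#' @export
find_sites <- function(g, e) {
  n <- genome_length(g)
  len <- nchar(e$site)
  if (g$topology == "circular" && len > 1L) {
    subject <- paste0(g$seq, substr(g$seq, 1L, len - 1L))
  } else {
    subject <- g$seq
  }
  subject <- Biostrings::DNAString(subject)
  hit_starts <- function(pattern) {
    m <- Biostrings::matchPattern(Biostrings::DNAString(pattern), subject,
                                  fixed = FALSE)
    Biostrings::start(m)
  }
  p_top <- hit_starts(e$site)
  cuts <- p_top + e$cut_top - 1L
  if (!is_palindromic(e)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(e$site)))
    p_bot <- hit_starts(rc)
    cuts <- c(cuts, p_bot + len - e$cut_bottom - 1L)
  }
  if (g$topology == "circular") {
    cuts <- ((cuts - 1L) %% n) + 1L
  } else {
    cuts <- cuts[cuts >= 1L & cuts < n]
  }
  sort(unique(as.integer(cuts)))
}

#' In-silico digest of a circular genome
#'
#' n cut sites yield n fragments whose lengths sum to the genome
#' length; with no sites the full circle is returned as one fragment.
#'
#' @param g A circular [genome].
#' @param e An [enzyme_def].
#' @return Data.frame of class `"digest"` with columns `start` (first
#'   base of the fragment) and `length`.
#' @export
digest_circular <- function(g, e) {
  n <- genome_length(g)
  cuts <- find_sites(g, e)
  if (length(cuts) == 0L) {
    out <- data.frame(start = 1L, length = n)
  } else {
    k <- length(cuts)
    nxt <- c(cuts[-1L], cuts[1L] + n)
    out <- data.frame(start = ((cuts) %% n) + 1L,
                      length = as.integer(nxt - cuts))
  }
  attr(out, "enzyme") <- e$name
  attr(out, "cuts") <- cuts
  attr(out, "unit_length") <- n
  class(out) <- c("digest", "data.frame")
  out
}

# start-position distribution of virions implied by a packaging model:
# data.frame(start, weight).  A fraction P(S >= k)/E[S] of all virions
# is the k-th headful of its series, which starts (k-1) virion lengths
# past pac (mod L).
virion_start_dist <- function(pm, model = c("series", "uniform", "fixed")) {
  model <- match.arg(model)
  L <- pm$unit_length
  if (model == "fixed")
    return(data.frame(start = pm$pac_position, weight = 1))
  if (model == "uniform")
    return(data.frame(start = seq_len(L), weight = rep(1 / L, L)))
  ks <- as.integer(names(pm$series_dist))
  probs <- as.numeric(pm$series_dist)
  es <- sum(ks * probs)
  w <- virion_length(pm)
  # weight of a virion being the j-th headful of its series: P(S >= j)/E[S]
  jmax <- max(ks)
  starts <- ((pm$pac_position - 1L + (seq_len(jmax) - 1L) * w) %% L) + 1L
  weights <- vapply(seq_len(jmax), function(j) sum(probs[ks >= j]) / es,
                    numeric(1))
  agg <- tapply(weights, starts, sum)
  data.frame(start = as.integer(names(agg)), weight = as.numeric(agg),
             row.names = NULL)
}

# probability that a circular fragment (first base a, length len) is
# present intact in a virion window of w bases whose start follows
# `dist`; t = offset of the fragment copy from the virion start
fragment_molarity <- function(a, len, L, w, dist) {
  if (len > w) return(0)
  if (identical(attr(dist, "uniform"), TRUE)) {
    return(min(1, max(0, (w - len + 1)) / L))
  }
  t <- (a - dist$start) %% L
  sum(dist$weight[t <= (w - len)])
}

#' Predict the restriction band table of a headful virion population
#'
#' Classifies each circular-digest fragment and computes its molarity
#' (the probability that a randomly drawn virion contains the fragment
#' intact) under a model of virion start positions:
#' \describe{
#'   \item{`"series"`}{(default) processive headful series: the first
#'     virion of a series starts at pac, virion k starts where virion
#'     k-1 ended, and series lengths follow the packaging model's
#'     distribution.}
#'   \item{`"uniform"`}{fully circularly permuted starts; molarity has
#'     the closed form `min(1, (w - len + 1)/L)` with `w` the virion
#'     length.}
#'   \item{`"fixed"`}{every virion starts at pac; the two deterministic
#'     end pieces are emitted explicitly.}
#' }
#' Classes: `core` fragments are present in every virion; `terminal_submolar`
#' fragments are truncated at virion ends in part of the population
#' (faint or invisible on gels -- the "white triangle" bands);
#' `junction_only` fragments span the packaging origin, are absent from
#' the unit-length linear rendition of the genome, and can only appear
#' when the packaged length exceeds one unit (`r > 0` -- the "blue
#' triangle" bands).  Fragments with zero molarity are not emitted.
#'
#' @param g A circular [genome].
#' @param e An [enzyme_def].
#' @param pm A [packaging_model] consistent with `g`.
#' @param start_model One of `"series"`, `"uniform"`, `"fixed"`.
#' @return Data.frame of class `"band_table"` with columns `start`,
#'   `length`, `cls`, `molarity` and `resolvable` (FALSE for fragments
#'   under 100 nt, which agarose gels do not resolve).
#' @export
predict_band_table <- function(g, e, pm,
                               start_model = c("series", "uniform", "fixed")) {
  start_model <- match.arg(start_model)
  L <- genome_length(g)
  if (pm$unit_length != L)
    stop("packaging model unit_length does not match genome length")
  dg <- digest_circular(g, e)
  cuts <- attr(dg, "cuts")
  w <- virion_length(pm)
  if (length(cuts) == 0L) {
    # uncut virions run as one molecule of the full packaged length
    out <- data.frame(start = pm$pac_position, length = w,
                      cls = if (pm$redundancy > 0) "junction_only" else "core",
                      molarity = 1, resolvable = w >= 100L)
    attr(out, "enzyme") <- e$name
    attr(out, "unit_length") <- L
    attr(out, "redundancy") <- pm$redundancy
    attr(out, "pac_position") <- pm$pac_position
    attr(out, "start_model") <- start_model
    class(out) <- c("band_table", "data.frame")
    return(out)
  }
  dist <- virion_start_dist(pm, start_model)
  if (start_model == "uniform") attr(dist, "uniform") <- TRUE
  boundary <- ((pm$pac_position - 2L) %% L) + 1L  # cut coord before pac
  frag_cut <- ((dg$start - 2L) %% L) + 1L         # cut opening each fragment
  spans <- ((boundary - frag_cut) %% L) > 0L &
    ((boundary - frag_cut) %% L) < dg$length
  if (length(cuts) == 0L) spans <- TRUE  # full circle always spans
  mol <- vapply(seq_len(nrow(dg)), function(i) {
    fragment_molarity(dg$start[i], dg$length[i], L, w, dist)
  }, numeric(1))
  cls <- ifelse(spans & pm$redundancy > 0, "junction_only",
                ifelse(mol >= 1 - 1e-9, "core", "terminal_submolar"))
  out <- data.frame(start = dg$start, length = dg$length, cls = cls,
                    molarity = mol)
  out <- out[out$molarity > 0, , drop = FALSE]
  if (start_model == "fixed" && length(cuts) > 0L) {
    # deterministic terminal pieces of the pac-anchored virion
    oc <- (cuts - (pm$pac_position - 1L)) %% L
    inside <- oc[oc > 0L & oc <= w]
    ends <- numeric(0)
    if (length(inside)) {
      first_cut <- min(inside)
      maxoff <- max(vapply(unique(oc), function(o) {
        cand <- o + L * (0:floor((w - o) / L))
        max(cand[cand <= w & cand > 0], -Inf)
      }, numeric(1)))
      left_len <- first_cut
      right_len <- w - maxoff
      pieces <- data.frame(start = integer(0), length = integer(0))
      if (left_len > 0)
        pieces <- rbind(pieces, data.frame(start = pm$pac_position,
                                           length = as.integer(left_len)))
      if (right_len > 0)
        pieces <- rbind(pieces, data.frame(
          start = as.integer(((pm$pac_position - 1L + maxoff) %% L) + 1L),
          length = as.integer(right_len)))
      if (nrow(pieces)) {
        pieces$cls <- "terminal_submolar"
        pieces$molarity <- 1
        out <- rbind(out, pieces)
      }
    }
  }
  out$resolvable <- out$length >= 100L
  out <- out[order(-out$length), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "enzyme") <- e$name
  attr(out, "unit_length") <- L
  attr(out, "redundancy") <- pm$redundancy
  attr(out, "pac_position") <- pm$pac_position
  attr(out, "start_model") <- start_model
  class(out) <- c("band_table", "data.frame")
  out
}

#' @export
print.band_table <- function(x, ...) {
  cat(sprintf("<band_table> %s: %d band(s) (L = %d, r = %.3f, %s starts)\n",
              attr(x, "enzyme"), nrow(x), attr(x, "unit_length"),
              attr(x, "redundancy"), attr(x, "start_model")))
  print.data.frame(as.data.frame(x))
  invisible(x)
}

#' Match predicted fragments to observed gel bands
#'
#' Greedy best-first one-to-one matching in log-size space (each
#' observed band is consumed at most once); afterwards, a predicted
#' fragment that co-migrates with an already-matched fragment may
#' share that fragment's band (flagged `shared`).  Unmatched
#' predictions are reported with their class, so submolar terminal
#' fragments invisible on the gel show up explicitly.
#'
#' @param predicted A `band_table` (from [predict_band_table()]) or
#'   numeric vector of fragment lengths.
#' @param observed A [band_list] or numeric vector of observed sizes in
#'   the same unit as `predicted`.
#' @param rel_tol Relative size tolerance in `(0, 0.2]` (default 0.05,
#'   typical agarose sizing error).
#' @return List of class `"gel_match"`: `matches` (data.frame of
#'   predicted length, class, observed size, `shared` co-migration
#'   flag and relative error), `unmatched_predicted` (data.frame with
#'   class) and `unmatched_observed` (numeric).
#' @export
match_gel <- function(predicted, observed, rel_tol = 0.05) {
  if (rel_tol <= 0 || rel_tol > 0.2) stop("rel_tol must be in (0, 0.2]")
  if (is.data.frame(predicted)) {
    sizes <- predicted$length
    cls <- if ("cls" %in% names(predicted)) predicted$cls
           else rep(NA_character_, length(sizes))
  } else {
    sizes <- as.numeric(predicted)
    cls <- rep(NA_character_, length(sizes))
  }
  obs <- sort(as.numeric(observed), decreasing = TRUE)
  if (!length(sizes) || !length(obs)) stop("empty inputs")
  ord <- order(-sizes)
  sizes <- sizes[ord]; cls <- cls[ord]
  tol <- log1p(rel_tol)
  # greedy best-first one-to-one assignment in log-size space
  pairs <- expand.grid(pi = seq_along(sizes), oi = seq_along(obs))
  pairs$err <- abs(log(sizes[pairs$pi]) - log(obs[pairs$oi]))
  pairs <- pairs[pairs$err <= tol, , drop = FALSE]
  pairs <- pairs[order(pairs$err), , drop = FALSE]
  obs_of <- rep(NA_integer_, length(sizes))
  o_taken <- logical(length(obs))
  for (i in seq_len(nrow(pairs))) {
    if (is.na(obs_of[pairs$pi[i]]) && !o_taken[pairs$oi[i]]) {
      obs_of[pairs$pi[i]] <- pairs$oi[i]
      o_taken[pairs$oi[i]] <- TRUE
    }
  }
  # co-migration: a leftover predicted fragment may share the band of
  # an already-matched fragment of indistinguishable size
  shared <- logical(length(sizes))
  for (p in which(is.na(obs_of))) {
    cand <- which(o_taken)
    if (!length(cand)) break
    errs <- abs(log(sizes[p]) - log(obs[cand]))
    j <- cand[which.min(errs)]
    if (min(errs) <= tol) {
      obs_of[p] <- j
      shared[p] <- TRUE
    }
  }
  matched <- !is.na(obs_of)
  matches <- data.frame(
    length = sizes[matched], cls = cls[matched],
    observed = obs[obs_of[matched]], shared = shared[matched])
  matches$rel_error <- abs(matches$length - matches$observed) / matches$observed
  unmatched_p <- data.frame(length = sizes[!matched], cls = cls[!matched])
  structure(list(matches = matches,
                 unmatched_predicted = unmatched_p,
                 unmatched_observed = obs[!o_taken]),
            class = "gel_match")
}

#' @export
print.gel_match <- function(x, ...) {
  cat("<gel_match>", nrow(x$matches), "predicted fragment(s) matched,",
      nrow(x$unmatched_predicted), "predicted and",
      length(x$unmatched_observed), "observed unmatched\n")
  invisible(x)
}

#' Estimate packaging parameters from observed restriction bands
#'
#' Grid search over candidate pac positions and terminal redundancies:
#' for each candidate the band table of every enzyme is predicted (at
#' the given start model), restricted to gel-visible fragments
#' (molarity at or above `min_molarity` and length at or above 100 nt),
#' and matched against the observed bands; the score is the total count
#' of unmatched predicted plus unmatched observed bands.  The
#' minimum-score candidate is returned.
#'
#' @param g A circular [genome].
#' @param enzymes List of [enzyme_def] objects.
#' @param observed List of observed [band_list]s (nt), parallel to
#'   `enzymes`.
#' @param pac_grid Integer vector of candidate pac positions.
#' @param r_grid Numeric vector of candidate redundancies in `[0, 1)`.
#' @param rel_tol Gel size tolerance passed to [match_gel()].
#' @param min_molarity Visibility threshold on predicted molarity.
#' @param series_dist Series-length distribution for the candidate
#'   packaging models.
#' @param start_model Start-position model for prediction.
#' @return Object of class `"packaging_fit"` with elements `par`
#'   (named vector pac, r), `score`, and the full `grid` of scores.
#' @export
fit_packaging <- function(g, enzymes, observed, pac_grid, r_grid,
                          rel_tol = 0.05, min_molarity = 0.15,
                          series_dist = NULL,
                          start_model = "series") {
  stopifnot(length(enzymes) == length(observed))
  grid <- expand.grid(pac = as.integer(pac_grid), r = as.numeric(r_grid))
  grid$score <- vapply(seq_len(nrow(grid)), function(i) {
    pm <- packaging_model(genome_length(g), grid$r[i], grid$pac[i],
                          series_dist)
    tot <- 0L
    for (j in seq_along(enzymes)) {
      bt <- predict_band_table(g, enzymes[[j]], pm, start_model)
      vis <- bt[bt$molarity >= min_molarity & bt$resolvable, , drop = FALSE]
      if (nrow(vis) == 0L) { tot <- tot + length(observed[[j]]); next }
      gm <- match_gel(vis, observed[[j]], rel_tol)
      tot <- tot + nrow(gm$unmatched_predicted) +
        length(gm$unmatched_observed)
    }
    as.integer(tot)
  }, integer(1))
  best <- which.min(grid$score)
  structure(list(par = c(pac = grid$pac[best], r = grid$r[best]),
                 score = grid$score[best], grid = grid,
                 genome_id = g$id),
            class = "packaging_fit")
}

#' @export
print.packaging_fit <- function(x, ...) {
  cat(sprintf(
    "<packaging_fit> %s: pac = %d, r = %.3f (%d unmatched bands; grid %d points)\n",
    x$genome_id, x$par[["pac"]], x$par[["r"]], x$score, nrow(x$grid)))
  invisible(x)
}

#' @method coef packaging_fit
#' @export
coef.packaging_fit <- function(object, ...) object$par
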