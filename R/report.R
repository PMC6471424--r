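#' Derive per-stage seeds from one top-level seed
#'
#' Every stochastic stage of [run_report()] gets its own seed derived
#' deterministically from the pipeline seed (`seed * 101 + stage index`,
#' kept below 2^31), so each stage is independently reproducible.
#'
#' @param seed Integer top-level seed.
#' @return Named integer vector of stage seeds.
#' @export
stage_seeds <- function(seed) {
  stages <- c("simulate", "virions", "bootstrap")
  s <- (as.numeric(seed) * 101 + seq_along(stages)) %% 2147483647
  stats::setNames(as.integer(s), stages)
}

#' Run the full comparative-genomics report
#'
#' Orchestrates the whole pipeline over one or more annotated genomes:
#' genome statistics (G+C, cumulative AT-skew, stop-codon usage,
#' spacing census), predicted restriction band tables and gel matches,
#' the apparent-MW table, pairwise ANIb/dotplot comparisons, homolog
#' maps with synteny blocks and invertible-region reports, translated
#' similarity shading, and a bootstrap NJ tree of a chosen marker
#' protein family.  Each stage writes TSV/JSON files into `out_dir`
#' and a manifest records package version, parameters and seeds.
#' A failing stage aborts with the stage name; protein-level stages
#' are skipped with a warning for genomes without a feature table.
#'
#' @param genomes Named list of [genome] objects.
#' @param features Named list of [feature_table]s (names matching
#'   `genomes`; may omit genomes).
#' @param enzymes Optional list of [enzyme_def]s for digest prediction.
#' @param pm Optional [packaging_model] (applied to the first genome).
#' @param observed_bands Optional list of [band_list]s parallel to
#'   `enzymes`.
#' @param marker Optional locus tag prefix or gene name used to pick
#'   one protein per genome for the tree stage.
#' @param out_dir Output directory (created if needed).
#' @param seed Top-level seed.
#' @param skew_window AT-skew window in nt.
#' @param tree_reps Bootstrap replicates for the tree stage.
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_report <- function(genomes, features = list(), enzymes = NULL,
                       pm = NULL, observed_bands = NULL, marker = NULL,
                       out_dir, seed = 1L, skew_window = 500L,
                       tree_reps = 100L) {
  if (inherits(genomes, "genome")) genomes <- list(genomes)
  if (is.null(names(genomes)))
    names(genomes) <- vapply(genomes, function(g) g$id, "")
  if (!length(genomes)) stop("no genomes given")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- stage_seeds(seed)
  results <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  # per-genome composition statistics
  results$stats <- stage("stats", {
    rows <- lapply(names(genomes), function(id) {
      g <- genomes[[id]]
      row <- data.frame(genome = id, length = genome_length(g),
                        gc = gc_content(g))
      sk <- cumulative_at_skew(g, skew_window)
      write_report(as.data.frame(sk),
                   file.path(out_dir, paste0(id, "_at_skew.tsv")), "tsv")
      if (!is.null(features[[id]])) {
        st <- stop_codon_usage(g, features[[id]])
        cen <- spacing_census(features[[id]])
        row <- cbind(row, as.data.frame(as.list(st)),
                     as.data.frame(as.list(cen$counts)))
      } else {
        warning("no feature table for ", id,
                "; annotation statistics skipped")
      }
      row
    })
    tab <- do.call(rbind, lapply(rows, function(r) {
      miss <- setdiff(unique(unlist(lapply(rows, names))), names(r))
      for (mcol in miss) r[[mcol]] <- NA
      r
    }))
    write_report(tab, file.path(out_dir, "genome_stats.tsv"), "tsv")
    tab
  })
  # digest prediction for the first genome
  if (!is.null(enzymes) && !is.null(pm)) {
    results$digest <- stage("digest", {
      g <- genomes[[1]]
      out <- lapply(seq_along(enzymes), function(k) {
        bt <- predict_band_table(g, enzymes[[k]], pm)
        write_report(as.data.frame(bt),
                     file.path(out_dir, paste0("bands_",
                                               enzymes[[k]]$name, ".tsv")),
                     "tsv")
        gm <- NULL
        if (!is.null(observed_bands)) {
          gm <- match_gel(bt, observed_bands[[k]])
          write_report(list(matches = gm$matches,
                            unmatched_predicted = gm$unmatched_predicted,
                            unmatched_observed = gm$unmatched_observed),
                       file.path(out_dir, paste0("gel_match_",
                                                 enzymes[[k]]$name,
                                                 ".json")), "json")
        }
        list(bands = bt, gel_match = gm)
      })
      names(out) <- vapply(enzymes, function(e) e$name, "")
      out
    })
  }
  # apparent molecular weights
  results$mw <- stage("mw", {
    out <- list()
    for (id in names(genomes)) {
      if (is.null(features[[id]])) next
      tab <- apparent_mw_table(genomes[[id]], features[[id]])
      write_report(tab, file.path(out_dir, paste0(id, "_mw.tsv")), "tsv")
      out[[id]] <- tab
    }
    out
  })
  # pairwise genome comparisons
  if (length(genomes) > 1) {
    ids <- names(genomes)
    results$ani <- stage("ani", {
      m <- matrix(NA_real_, length(ids), length(ids),
                  dimnames = list(ids, ids))
      for (qi in ids) for (ri in ids) {
        m[qi, ri] <- if (qi == ri) 100 else
          anib(genomes[[qi]], genomes[[ri]])$anib
      }
      write_report(as.data.frame(m), file.path(out_dir, "ani_matrix.tsv"),
                   "tsv")
      m
    })
    results$dotplot <- stage("dotplot", {
      segs <- dotplot_segments(genomes[[1]], genomes[[2]])
      write_report(segs, file.path(out_dir, "dotplot_segments.tsv"), "tsv")
      segs
    })
    both_ft <- ids[!vapply(features[ids], is.null, TRUE)]
    if (length(both_ft) >= 2) {
      a <- both_ft[1]; b <- both_ft[2]
      results$homologs <- stage("homologs", {
        hm <- map_homologs(
          proteome(genomes[[a]], features[[a]], skip_disrupted = TRUE),
          proteome(genomes[[b]], features[[b]], skip_disrupted = TRUE))
        tab <- hm$matches
        orph <- data.frame(locus_a = hm$orphans_a, locus_b = "ORPHAN",
                           identity = NA, bitscore = NA, evalue = NA,
                           aligned_length = NA, accepted_via = NA,
                           block = NA)
        write_report(rbind(tab, orph),
                     file.path(out_dir, "homolog_table.tsv"), "tsv")
        hm
      })
      results$shading <- stage("shading", {
        segs <- similarity_segments(genomes[[a]], genomes[[b]])
        write_report(as.data.frame(segs),
                     file.path(out_dir, "shading_segments.tsv"), "tsv")
        segs
      })
    } else if (length(both_ft) < 2) {
      warning("fewer than two annotated genomes; homolog stages skipped")
    }
  }
  # marker-protein bootstrap tree
  if (!is.null(marker)) {
    results$tree <- stage("tree", {
      seqs <- character(0)
      for (id in names(genomes)) {
        ftab <- features[[id]]
        if (is.null(ftab)) next
        hit <- which(ftab$gene %in% marker |
                     grepl(marker, ftab$locus_tag, fixed = TRUE))[1]
        if (is.na(hit)) next
        seqs[[id]] <- translate_cds(genomes[[id]], ftab[hit, ])
      }
      if (length(seqs) < 4) {
        warning("fewer than 4 marker sequences; tree skipped")
        NULL
      } else {
        aln <- progressive_align(seqs)
        tr <- bootstrap_consensus(aln, reps = tree_reps,
                                  seed = seeds[["bootstrap"]])
        write_newick(tr, file.path(out_dir, "marker_tree.nwk"))
        tr
      }
    })
  }
  manifest <- list(
    package = "chaovir",
    version = as.character(utils::packageVersion("chaovir")),
    seed = seed, stage_seeds = as.list(seeds),
    parameters = list(skew_window = skew_window, tree_reps = tree_reps),
    genomes = lapply(genomes, function(g)
      list(id = g$id, length = genome_length(g), topology = g$topology)))
  write_report(manifest, file.path(out_dir, "manifest.json"), "json")
  results$manifest <- manifest
  invisible(results)
}
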