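# Virtual screening: score a library with a trained model, apply the
# applicability-domain rule, attach external docking affinities, and write a
# ranked hit report.

#' Screening configuration
#'
#' @param p_threshold minimum predicted probability of activity (default
#'   0.64, applied to the random-forest vote fraction).
#' @param ad_threshold applicability-domain Tanimoto threshold (default
#'   0.195; similarity equal to the threshold is in-domain).
#' @param dock_dg_cutoff optional docking free-energy cutoff in kcal/mol
#'   (e.g. -11); `NULL` (default) disables the docking criterion.
#' @return list of class `screening_config`.
#' @export
screening_config <- function(p_threshold = 0.64, ad_threshold = 0.195,
                             dock_dg_cutoff = NULL) {
  stopifnot(p_threshold >= 0, p_threshold <= 1,
            ad_threshold > 0, ad_threshold < 1)
  structure(list(p_threshold = p_threshold, ad_threshold = ad_threshold,
                 dock_dg_cutoff = dock_dg_cutoff),
            class = "screening_config")
}

#' Screen a compound library
#'
#' Scores every library molecule with the trained model, evaluates
#' applicability-domain membership against the cluster centroids, optionally
#' attaches docking affinities, and ranks the hits.  A molecule passes when
#' its predicted probability of activity reaches `p_threshold` *and* it lies
#' inside the applicability domain (and, when a docking cutoff is configured
#' and a score is present, its affinity is at least as favourable).
#'
#' @param model a `qsar_model`.
#' @param library_matrix descriptor matrix of the library (must contain the
#'   model's columns; ids as row names).
#' @param library_fps fingerprint matrix used for the AD rule (same family as
#'   the cluster model).
#' @param cluster_model a `cluster_model` with centroids.
#' @param config a [screening_config].
#' @param docking optional named numeric vector id -> docking dG (kcal/mol),
#'   e.g. from [ingest_docking_scores].
#' @param smiles optional named character vector id -> SMILES carried through
#'   to the report.
#' @return data.frame of class `screening_hits`, sorted by (passed desc,
#'   p_active desc, dock_dg asc, max_centroid_similarity desc, id).
#' @export
screen_library <- function(model, library_matrix, library_fps, cluster_model,
                           config = screening_config(), docking = NULL,
                           smiles = NULL) {
  if (nrow(library_matrix) == 0L) stop("empty library")
  ids <- rownames(library_matrix)
  if (is.null(ids)) stop("library matrix needs molecule ids as row names")
  cluster_model$ad_threshold <- config$ad_threshold
  p <- predict(model, library_matrix, type = "prob")
  ad <- in_applicability_domain(library_fps[ids, , drop = FALSE], cluster_model)
  dg <- rep(NA_real_, length(ids))
  if (!is.null(docking)) dg <- unname(docking[ids])
  if (any(dg > 0, na.rm = TRUE)) {
    warning("positive docking free energies found; check the affinity table")
  }
  passed <- p >= config$p_threshold & ad$in_ad
  if (!is.null(config$dock_dg_cutoff)) {
    passed <- passed & !is.na(dg) & dg <= config$dock_dg_cutoff
  }
  hits <- data.frame(id = ids,
                     smiles = if (!is.null(smiles)) unname(smiles[ids]) else NA_character_,
                     p_active = p, in_ad = ad$in_ad,
                     nearest_cluster = ad$nearest_cluster,
                     max_centroid_similarity = ad$max_similarity,
                     dock_dg = dg, passed = passed,
                     stringsAsFactors = FALSE)
  ord <- order(-hits$passed, -hits$p_active, hits$dock_dg,
               -hits$max_centroid_similarity, hits$id)
  hits <- hits[ord, , drop = FALSE]
  rownames(hits) <- NULL
  class(hits) <- c("screening_hits", "data.frame")
  attr(hits, "config") <- config
  hits
}

#' Ingest a docking-score table
#'
#' Reads a TSV with molecule ids and docking free energies (kcal/mol).
#' Duplicate ids keep the most negative (most favourable) score; malformed
#' rows are reported with their line numbers.
#'
#' @param path TSV file with columns id and dg (header optional).
#' @return named numeric vector id -> dG, with `attr(, "rejected_lines")`
#'   listing malformed rows.
#' @export
ingest_docking_scores <- function(path) {
  if (!file.exists(path)) stop("docking table not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  out <- numeric(0)
  rejected <- data.frame(line = integer(0), content = character(0),
                         stringsAsFactors = FALSE)
  for (i in seq_along(lines)) {
    p <- strsplit(trimws(lines[i]), "[ \t]+")[[1L]]
    if (i == 1L && length(p) >= 2L && is.na(suppressWarnings(as.numeric(p[[2L]])))) {
      next  # header row
    }
    dg <- suppressWarnings(as.numeric(p[[min(2L, length(p))]]))
    if (length(p) < 2L || is.na(dg)) {
      rejected <- rbind(rejected, data.frame(line = i, content = lines[i],
                                             stringsAsFactors = FALSE))
      next
    }
    id <- p[[1L]]
    if (!id %in% names(out) || dg < out[[id]]) out[id] <- dg
  }
  attr(out, "rejected_lines") <- rejected
  out
}

#' Write the screening report
#'
#' Writes the full per-molecule table as CSV plus a JSON/text summary with
#' the counts passing each criterion and the applicability-domain breakdown
#' by nearest cluster.
#'
#' @param hits a [screen_library] result.
#' @param dir output directory (created if needed).
#' @return named list of the written file paths, invisibly.
#' @export
write_screening_report <- function(hits, dir) {
  if (nrow(hits) == 0L) stop("no hits to report")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv <- file.path(dir, "screening_hits.csv")
  utils::write.csv(hits, csv, row.names = FALSE)
  cfg <- attr(hits, "config")
  outside <- hits[!hits$in_ad, , drop = FALSE]
  summary <- list(
    n_library = nrow(hits),
    n_in_ad = sum(hits$in_ad),
    n_outside_ad = sum(!hits$in_ad),
    outside_ad_by_cluster = as.list(table(outside$nearest_cluster)),
    n_above_probability = sum(hits$p_active >= cfg$p_threshold),
    n_passed = sum(hits$passed),
    p_threshold = cfg$p_threshold,
    ad_threshold = cfg$ad_threshold,
    dock_dg_cutoff = cfg$dock_dg_cutoff)
  js <- file.path(dir, "screening_summary.json")
  jsonlite::write_json(summary, js, auto_unbox = TRUE, digits = NA, null = "null")
  txt <- file.path(dir, "screening_summary.txt")
  byc <- table(outside$nearest_cluster)
  writeLines(c(
    sprintf("Library molecules screened: %d", summary$n_library),
    sprintf("Outside applicability domain: %d (%s)", summary$n_outside_ad,
            if (length(byc)) paste(sprintf("%d in cluster %s", byc, names(byc)),
                                   collapse = ", ") else "none"),
    sprintf("Probability >= %.2f: %d", cfg$p_threshold, summary$n_above_probability),
    sprintf("Passing all criteria: %d", summary$n_passed)), txt)
  invisible(list(csv = csv, json = js, txt = txt))
}
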