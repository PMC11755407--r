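# Fingerprint-similarity clustering (Taylor-Butina sphere exclusion),
# centroid extraction, X-category pruning, Murcko scaffold analysis and the
# centroid-based applicability-domain rule.

#' Cluster a fingerprint set by sphere exclusion
#'
#' Taylor-Butina-style leader clustering on Tanimoto similarity: molecules
#' are ranked by neighbor count at `sim_cutoff`; the densest unassigned
#' molecule becomes a leader and captures its unassigned neighbors.  The four
#' largest resulting clusters are labelled `A` to `D` by decreasing size
#' (ties by leader id); molecules in smaller residual clusters are attached
#' to the most similar of the four leaders, so every molecule carries exactly
#' one label.  Deterministic and independent of input order.
#'
#' @param fps 0/1 fingerprint matrix with molecule ids as row names.
#' @param smiles optional named character vector (id -> canonical SMILES)
#'   used for deterministic centroid tie-breaking.
#' @param n_target_clusters number of named clusters (default 4, labels A-D).
#' @param sim_cutoff Tanimoto similarity defining the exclusion sphere.
#' @param ad_threshold applicability-domain similarity threshold stored on
#'   the model (default 0.195).
#' @return object of class `cluster_model`: `labels` (named character),
#'   `centroids` (list per cluster: id + fingerprint), `ad_threshold`,
#'   `similarity_fp_family`.
#' @export
cluster_dataset <- function(fps, smiles = NULL, n_target_clusters = 4L,
                            sim_cutoff = 0.35, ad_threshold = 0.195) {
  n <- nrow(fps)
  if (n < n_target_clusters) stop("fewer molecules than requested clusters")
  ids <- rownames(fps)
  if (is.null(ids)) stop("fingerprint matrix needs molecule ids as row names")
  sim <- tanimoto_matrix(fps)
  nbr <- sim >= sim_cutoff
  diag(nbr) <- FALSE
  counts <- rowSums(nbr)
  assigned <- rep(NA_integer_, n)
  leaders <- integer(0)
  # process molecules in deterministic order: neighbor count desc, id asc
  order_idx <- order(-counts, ids)
  cl <- 0L
  for (i in order_idx) {
    if (!is.na(assigned[i])) next
    cl <- cl + 1L
    leaders[cl] <- i
    members <- which(nbr[i, ] & is.na(assigned))
    assigned[c(i, members)] <- cl
  }
  sizes <- tabulate(assigned, nbins = cl)
  major <- order(-sizes, ids[leaders])[seq_len(min(n_target_clusters, cl))]
  letters_ <- LETTERS[seq_along(major)]
  labels <- rep(NA_character_, n)
  for (k in seq_along(major)) labels[assigned == major[k]] <- letters_[k]
  stray <- which(is.na(labels))
  if (length(stray) > 0L) {
    lead_sim <- sim[stray, leaders[major], drop = FALSE]
    labels[stray] <- letters_[max.col(lead_sim, ties.method = "first")]
  }
  names(labels) <- ids
  model <- structure(list(labels = labels, centroids = list(),
                          ad_threshold = ad_threshold,
                          similarity_fp_family = "morgan",
                          sim_cutoff = sim_cutoff),
                     class = "cluster_model")
  recompute_centroids(model, fps, smiles)
}

#' Select the centroid of a cluster
#'
#' The centroid is the member maximizing the mean Tanimoto similarity to all
#' other members; ties are broken by canonical SMILES order, then id.
#'
#' @param cluster_fps fingerprint matrix of the cluster members (ids as row
#'   names).
#' @param smiles optional named SMILES vector for tie-breaking.
#' @return the centroid molecule id.
#' @export
find_centroid <- function(cluster_fps, smiles = NULL) {
  n <- nrow(cluster_fps)
  if (is.null(n) || n == 0L) stop("empty cluster")
  ids <- rownames(cluster_fps)
  if (n == 1L) return(ids[[1L]])
  sim <- tanimoto_matrix(cluster_fps)
  diag(sim) <- 0
  mean_sim <- rowSums(sim) / (n - 1)
  best <- which(mean_sim == max(mean_sim))
  if (length(best) > 1L && !is.null(smiles)) {
    best <- best[order(smiles[ids[best]], ids[best])]
  } else {
    best <- best[order(ids[best])]
  }
  ids[best[[1L]]]
}

recompute_centroids <- function(model, fps, smiles = NULL) {
  cls <- sort(unique(model$labels))
  cents <- list()
  for (cl in cls) {
    members <- names(model$labels)[model$labels == cl]
    if (length(members) == 0L) next
    cid <- find_centroid(fps[members, , drop = FALSE], smiles)
    cents[[cl]] <- list(id = cid, fp = as.integer(fps[cid, ]))
  }
  model$centroids <- cents
  model
}

#' @export
print.cluster_model <- function(x, ...) {
  tab <- table(x$labels)
  cat("<cluster_model>\n  sizes:",
      paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      sprintf("\n  centroids: %s\n  ad_threshold: %.3f\n",
              paste(names(x$centroids), collapse = ""), x$ad_threshold))
  invisible(x)
}

#' Prune dissimilar molecules into category X
#'
#' Every molecule whose Tanimoto similarity to its own cluster centroid is
#' below `threshold` is moved to category `X`.  Centroids of the named
#' clusters are then recomputed once (a single pass, keeping the procedure
#' deterministic and terminating), and X receives its own centroid.
#'
#' @param model a [cluster_dataset] result.
#' @param fps the fingerprint matrix used for clustering.
#' @param threshold similarity cutoff in (0,1); default 0.195.
#' @param smiles optional named SMILES vector for centroid tie-breaks.
#' @return updated `cluster_model` with labels in `A..D, X`.
#' @export
prune_to_x <- function(model, fps, threshold = 0.195, smiles = NULL) {
  if (threshold <= 0 || threshold >= 1) stop("threshold must be in (0,1)")
  labels <- model$labels
  for (cl in setdiff(sort(unique(labels)), "X")) {
    cent <- model$centroids[[cl]]
    if (is.null(cent)) next
    members <- names(labels)[labels == cl]
    sims <- as.vector(tanimoto_matrix(fps[members, , drop = FALSE],
                                      matrix(cent$fp, nrow = 1)))
    labels[members[sims < threshold]] <- "X"
  }
  model$labels <- labels
  model$ad_threshold <- threshold
  recompute_centroids(model, fps, smiles)
}

#' Applicability-domain membership
#'
#' A molecule belongs to the model's applicability domain when its maximum
#' Tanimoto similarity to the cluster centroids (A-D and X when present) is
#' at least `ad_threshold` — similarity exactly at the threshold is inside
#' the domain.
#'
#' @param fps fingerprint matrix (or single vector) of query molecules.
#' @param model a `cluster_model` with centroids.
#' @return data.frame: `in_ad` (logical), `max_similarity`,
#'   `nearest_cluster`.
#' @export
in_applicability_domain <- function(fps, model) {
  if (is.null(dim(fps))) fps <- matrix(fps, nrow = 1)
  if (length(model$centroids) == 0L) stop("cluster model has no centroids")
  cents <- do.call(rbind, lapply(model$centroids, function(ct) ct$fp))
  rownames(cents) <- names(model$centroids)
  sims <- tanimoto_matrix(fps, cents)
  best <- max.col(sims, ties.method = "first")
  data.frame(id = rownames(fps) %||% seq_len(nrow(fps)),
             in_ad = sims[cbind(seq_len(nrow(fps)), best)] >= model$ad_threshold,
             max_similarity = sims[cbind(seq_len(nrow(fps)), best)],
             nearest_cluster = rownames(cents)[best],
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Persist / restore a cluster model as JSON
#' @param model a `cluster_model`.
#' @param path JSON file path.
#' @return `path` (write) or the restored `cluster_model` (read).
#' @export
write_cluster_model <- function(model, path) {
  jsonlite::write_json(list(labels = as.list(model$labels),
                            centroids = model$centroids,
                            ad_threshold = model$ad_threshold,
                            similarity_fp_family = model$similarity_fp_family,
                            sim_cutoff = model$sim_cutoff),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_cluster_model
#' @export
read_cluster_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  cents <- lapply(obj$centroids, function(ct) list(id = ct$id, fp = as.integer(ct$fp)))
  structure(list(labels = unlist(obj$labels), centroids = cents,
                 ad_threshold = obj$ad_threshold,
                 similarity_fp_family = obj$similarity_fp_family,
                 sim_cutoff = obj$sim_cutoff),
            class = "cluster_model")
}

# ---- Murcko scaffolds ----------------------------------------------------

#' Murcko framework of a molecule
#'
#' Classic ring-plus-linker framework: terminal atoms are deleted iteratively
#' until only ring systems and the linkers connecting them remain.  Acyclic
#' molecules have an empty scaffold (`""`).
#'
#' @param smiles character vector of standardized SMILES.
#' @return character vector of canonical scaffold SMILES (`""` for acyclic).
#' @export
murcko_scaffold <- function(smiles) {
  sdf <- ob_smi_to_sdf(smiles)
  cfs <- parse_sdf_text(sdf)
  pos <- match(names(cfs), ob_titles(length(smiles)))
  out <- rep(NA_character_, length(smiles))
  scaff_cfs <- list(); scaff_pos <- integer(0)
  for (k in seq_along(cfs)) {
    cf <- cfs[[k]]
    keep <- which(cf$elem != "H")
    bonds <- cf$bonds
    repeat {
      deg <- tabulate(c(bonds$a1, bonds$a2), nbins = length(cf$elem))
      term <- intersect(keep, which(deg <= 1L))
      if (length(term) == 0L) break
      keep <- setdiff(keep, term)
      bonds <- bonds[!(bonds$a1 %in% term | bonds$a2 %in% term), , drop = FALSE]
      if (length(keep) == 0L) break
    }
    if (length(keep) == 0L) { out[pos[k]] <- ""; next }
    remap <- match(seq_along(cf$elem), keep)
    sub <- conformer(cf$id, cf$elem[keep], cf$xyz[keep, , drop = FALSE],
                     data.frame(a1 = remap[bonds$a1], a2 = remap[bonds$a2],
                                order = bonds$order),
                     formal_charge = cf$formal_charge[keep])
    scaff_cfs[[length(scaff_cfs) + 1L]] <- sub
    scaff_pos <- c(scaff_pos, pos[k])
  }
  if (length(scaff_cfs) > 0L) {
    for (k in seq_along(scaff_cfs)) scaff_cfs[[k]]$id <- sprintf("s%07d", k)
    tmp <- tempfile(fileext = ".sdf")
    on.exit(unlink(tmp))
    write_sdf(scaff_cfs, tmp)
    res <- suppressWarnings(system2(ob_exe(), c(shQuote(tmp), "-ocan"),
                                    stdout = TRUE, stderr = FALSE))
    parts <- strsplit(res, "[ \t]+")
    for (p in parts) {
      if (length(p) < 2L) next
      k <- match(p[[length(p)]], sprintf("s%07d", seq_along(scaff_cfs)))
      if (!is.na(k)) out[scaff_pos[k]] <- p[[1L]]
    }
  }
  out
}

#' Per-cluster Murcko scaffold summary
#'
#' @param records curated records (with `id`, `smiles`).
#' @param model a `cluster_model` labelling the records.
#' @return data.frame: cluster, n_molecules, n_scaffolds, scaffold_pct.
#' @export
murcko_summary <- function(records, model) {
  scaff <- murcko_scaffold(records$smiles)
  labs <- model$labels[records$id]
  agg <- lapply(split(scaff, labs), function(s) {
    c(n = length(s), k = length(unique(s)))
  })
  data.frame(cluster = names(agg),
             n_molecules = vapply(agg, `[[`, numeric(1), "n"),
             n_scaffolds = vapply(agg, `[[`, numeric(1), "k"),
             scaffold_pct = 100 * vapply(agg, function(x) x[["k"]] / x[["n"]],
                                         numeric(1)),
             row.names = NULL, stringsAsFactors = FALSE)
}
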