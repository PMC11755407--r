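# Dataset curation: reading raw molecule tables, structure standardization,
# stereochemistry-aware InChI deduplication, label-conflict resolution and
# stratified train/test splitting.

.label_tokens <- stats::setNames(
  c("active", "active", "active", "active",
    "inactive", "inactive", "inactive", "inactive",
    "unknown", "unknown", "unknown"),
  c("active", "a", "act", "1", "inactive", "i", "inact", "0",
    "unknown", "na", ""))

normalize_labels <- function(x) {
  x[is.na(x)] <- ""
  out <- .label_tokens[tolower(trimws(as.character(x)))]
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("unknown label token(s): ", paste(bad, collapse = ", "))
  }
  unname(out)
}

new_records <- function(id, smiles, label, source, inchi = NA_character_,
                        assay_note = "") {
  n <- length(id)
  data.frame(id = as.character(id), smiles = as.character(smiles),
             inchi = rep_len(inchi, n), label = rep_len(label, n),
             source = rep_len(source, n),
             assay_note = rep_len(assay_note, n), stringsAsFactors = FALSE)
}

#' Read a raw molecule table
#'
#' Reads molecules with identifiers and activity labels from CSV/TSV, SMILES
#' (`.smi`, one molecule per line with an optional id) or SDF files.  Every
#' structure is parsed; rows whose SMILES Open Babel cannot interpret are
#' returned in a rejection table with the reason rather than silently dropped.
#'
#' @param path input file.
#' @param format one of `"csv"`, `"tsv"`, `"smi"`, `"sdf"` (default: guessed
#'   from the file extension).
#' @param column_map named list mapping the roles `id`, `smiles`, `label` to
#'   column names (CSV/TSV only).
#' @param source provenance tag stored on each record.
#' @return list with `records` (data.frame: id, smiles, inchi, label, source,
#'   assay_note) and `rejects` (data.frame: id, smiles, reason).
#' @export
parse_molecule_table <- function(path, format = NULL,
                                 column_map = list(id = "id", smiles = "smiles",
                                                   label = "label"),
                                 source = "literature") {
  if (!file.exists(path)) stop("input file not found: ", path)
  if (is.null(format)) {
    format <- switch(tolower(tools::file_ext(path)),
                     csv = "csv", tsv = "tsv", txt = "tsv", smi = "smi",
                     smiles = "smi", sdf = "sdf",
                     stop("cannot guess format of ", path))
  }
  format <- match.arg(format, c("csv", "tsv", "smi", "sdf"))
  if (format %in% c("csv", "tsv")) {
    tab <- utils::read.table(path, header = TRUE, sep = if (format == "csv") "," else "\t",
                             stringsAsFactors = FALSE, comment.char = "",
                             quote = "\"", check.names = FALSE)
    need <- unlist(column_map[c("id", "smiles")])
    if (!all(need %in% names(tab))) {
      stop("column_map names missing from table: ",
           paste(setdiff(need, names(tab)), collapse = ", "))
    }
    id <- as.character(tab[[column_map$id]])
    smiles <- as.character(tab[[column_map$smiles]])
    label <- if (!is.null(column_map$label) && column_map$label %in% names(tab)) {
      normalize_labels(tab[[column_map$label]])
    } else rep("unknown", nrow(tab))
  } else if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    parts <- strsplit(trimws(lines), "[ \t]+")
    smiles <- vapply(parts, `[[`, character(1), 1L)
    id <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) > 1L) parts[[i]][[2L]] else sprintf("mol%06d", i)
    }, character(1))
    label <- rep("unknown", length(smiles))
  } else {  # sdf
    cfs <- read_sdf(path)
    id <- names(cfs)
    smiles <- vapply(cfs, function(cf) {
      tryCatch(conformer_smiles(cf), error = function(e) NA_character_)
    }, character(1))
    label <- rep("unknown", length(smiles))
  }
  if (length(smiles) == 0L) stop("no rows in ", path)

  can <- ob_canonical_smiles(smiles)
  heavy_ok <- !is.na(can) & vapply(can, function(s) {
    any(grepl("[A-Za-z]", gsub("\\[H\\]|H", "", s)))
  }, logical(1))
  ok <- !is.na(can) & heavy_ok
  rejects <- data.frame(id = id[!ok], smiles = smiles[!ok],
                        reason = ifelse(is.na(can[!ok]), "unparseable SMILES",
                                        "no heavy atoms"),
                        stringsAsFactors = FALSE)
  if (!any(ok)) stop("no parseable rows in ", path)
  records <- new_records(id[ok], can[ok], label[ok], source)
  list(records = records, rejects = rejects)
}

conformer_smiles <- function(cf) {
  tmp <- tempfile(fileext = ".sdf")
  on.exit(unlink(tmp))
  write_sdf(cf, tmp)
  out <- suppressWarnings(system2(ob_exe(), c(shQuote(tmp), "-ocan"),
                                  stdout = TRUE, stderr = FALSE))
  if (length(out) == 0L) stop("cannot convert conformer to SMILES")
  strsplit(out[[1L]], "[ \t]+")[[1L]][[1L]]
}

# ---- standardization ------------------------------------------------------

# largest organic fragment; ties by heavy-atom count broken lexicographically
largest_organic_fragment <- function(smiles) {
  frags_list <- strsplit(smiles, ".", fixed = TRUE)
  all_frags <- unique(unlist(frags_list))
  counts <- ob_properties(all_frags)$atoms
  names(counts) <- all_frags
  has_c <- grepl("C|c", gsub("\\[(Ca|Cl|Cd|Co|Cr|Cu|Cs|Sc)[^]]*\\]", "", all_frags))
  names(has_c) <- all_frags
  vapply(frags_list, function(fr) {
    fr <- fr[has_c[fr] %in% TRUE]
    if (length(fr) == 0L) return(NA_character_)
    hv <- counts[fr]
    fr <- fr[hv == max(hv, na.rm = TRUE)]
    sort(fr)[[1L]]
  }, character(1))
}

# Deterministic 1,3-tautomer normalization: acyclic enols are rewritten to
# ketones and iminols to amides, always at the lowest-index match first,
# until no pattern remains.  Ring double bonds are never touched, so aromatic
# systems (e.g. phenols) are preserved.
taut_canonical <- function(smiles) {
  hit <- ob_smarts_match(smiles, "[OX2H1][#6]=[#6,#7]")
  if (!any(hit)) return(smiles)
  out <- smiles
  sdf <- ob_smi_to_sdf(smiles[hit])
  cfs <- parse_sdf_text(sdf)
  pos <- which(hit)[match(names(cfs), ob_titles(sum(hit)))]
  for (k in seq_along(cfs)) {
    cf <- cfs[[k]]
    for (iter in 1:20) {
      mg <- mol_graph(cf)
      edited <- FALSE
      # O with one H, single-bonded to C that is double-bonded to acyclic C/N
      for (o in which(mg$elem == "O" & mg$nH == 1L & mg$degree == 1L)) {
        co <- which((mg$bonds$a1 == o | mg$bonds$a2 == o) & mg$bonds$order == 1L)
        if (length(co) != 1L) next
        cpos <- setdiff(c(mg$bonds$a1[co], mg$bonds$a2[co]), o)
        if (mg$elem[cpos] != "C") next
        dbl <- which(((mg$bonds$a1 == cpos | mg$bonds$a2 == cpos) &
                        mg$bonds$order == 2L) & !mg$ring_edge)
        if (length(dbl) == 0L) next
        dbl <- dbl[[1L]]
        far <- setdiff(c(mg$bonds$a1[dbl], mg$bonds$a2[dbl]), cpos)
        if (!mg$elem[far] %in% c("C", "N")) next
        # shift: O-H,C=X  ->  O=C,X-H  (bond orders swap; H moves implicitly)
        cf$bonds$order[which(cf$bonds$a1 %in% mg$heavy_index[c(o, cpos)] &
                               cf$bonds$a2 %in% mg$heavy_index[c(o, cpos)])] <- 2L
        cf$bonds$order[which(cf$bonds$a1 %in% mg$heavy_index[c(cpos, far)] &
                               cf$bonds$a2 %in% mg$heavy_index[c(cpos, far)])] <- 1L
        edited <- TRUE
        break
      }
      if (!edited) break
    }
    out[pos[k]] <- conformer_smiles(cf)
  }
  out
}

#' Standardize molecule records
#'
#' Keeps the largest organic fragment (counter-ions and small co-fragments are
#' stripped), normalizes acyclic 1,3-tautomers to their carbonyl form,
#' perceives aromaticity, rewrites the SMILES in canonical form and attaches
#' the stereochemistry-aware standard InChI.  The operation is idempotent.
#'
#' @param records data.frame of records as returned by [parse_molecule_table].
#' @return the records with standardized `smiles` and populated `inchi`.
#'   Records that lose all organic fragments (pure salts) raise an error
#'   unless `on_empty = "drop"`.
#' @param on_empty `"error"` (default) or `"drop"` for structures that vanish
#'   after fragment stripping.
#' @export
standardize_records <- function(records, on_empty = c("error", "drop")) {
  on_empty <- match.arg(on_empty)
  frag <- largest_organic_fragment(records$smiles)
  if (anyNA(frag)) {
    if (on_empty == "error") {
      stop("empty structure after fragment stripping: ",
           paste(records$id[is.na(frag)], collapse = ", "))
    }
    records <- records[!is.na(frag), , drop = FALSE]
    frag <- frag[!is.na(frag)]
  }
  taut <- taut_canonical(frag)
  can <- ob_canonical_smiles(taut)
  if (anyNA(can)) stop("standardization failed for: ",
                       paste(records$id[is.na(can)], collapse = ", "))
  records$smiles <- can
  records$inchi <- ob_inchi(can)
  if (anyNA(records$inchi) || any(!nzchar(records$inchi))) {
    stop("InChI generation failed for: ",
         paste(records$id[is.na(records$inchi) | !nzchar(records$inchi)],
               collapse = ", "))
  }
  rownames(records) <- NULL
  records
}

#' Convenience wrapper: standardize bare SMILES strings
#' @param smiles character vector.
#' @return standardized canonical SMILES.
#' @export
standardize_smiles <- function(smiles) {
  recs <- new_records(sprintf("s%06d", seq_along(smiles)), smiles, "unknown",
                      "literature")
  standardize_records(recs)$smiles
}

# ---- deduplication --------------------------------------------------------

#' Deduplicate records by stereochemistry-aware InChI
#'
#' Records sharing a standard InChI (which encodes chirality, so enantiomers
#' stay distinct) are collapsed to one representative — the member with the
#' lexicographically smallest id, making the result independent of input
#' order.  Groups whose members disagree on the activity label are returned
#' separately for explicit resolution.
#'
#' @param records standardized records (`inchi` populated).
#' @return list with `records` (conflict-free survivors), `conflicts` (list of
#'   data.frames, one per disagreeing InChI group).
#' @export
deduplicate_records <- function(records) {
  if (anyNA(records$inchi)) stop("records must be standardized first")
  groups <- split(seq_len(nrow(records)), records$inchi)
  keep <- integer(0)
  conflicts <- list()
  for (g in groups) {
    labs <- unique(records$label[g])
    if (length(labs) == 1L) {
      keep <- c(keep, g[order(records$id[g])][1L])
    } else {
      conflicts[[length(conflicts) + 1L]] <- records[g[order(records$id[g])], ,
                                                     drop = FALSE]
    }
  }
  out <- records[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  list(records = out, conflicts = conflicts)
}

#' Resolve label-conflicting duplicate groups
#'
#' @param conflicts list of conflict groups from [deduplicate_records].
#' @param policy `"drop"` (default, conservative), `"prefer_active"`,
#'   `"prefer_inactive"` or `"majority"` (ties fall back to drop).
#' @return data.frame of surviving records (possibly zero rows); the applied
#'   resolution is recorded in `assay_note`.
#' @export
resolve_conflicts <- function(conflicts,
                              policy = c("drop", "prefer_active",
                                         "prefer_inactive", "majority")) {
  policy <- match.arg(policy)
  out <- list()
  for (grp in conflicts) {
    pick <- switch(policy,
      drop = NULL,
      prefer_active = grp[grp$label == "active", , drop = FALSE][1, , drop = FALSE],
      prefer_inactive = grp[grp$label == "inactive", , drop = FALSE][1, , drop = FALSE],
      majority = {
        tab <- table(grp$label)
        top <- names(tab)[tab == max(tab)]
        if (length(top) > 1L) NULL else grp[grp$label == top, , drop = FALSE][1, , drop = FALSE]
      })
    if (!is.null(pick) && nrow(pick) == 1L && !is.na(pick$id)) {
      pick$assay_note <- sprintf("label conflict resolved by policy '%s' (%d records)",
                                 policy, nrow(grp))
      out[[length(out) + 1L]] <- pick
    }
  }
  if (length(out) == 0L) {
    return(new_records(character(0), character(0), character(0), character(0)))
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# ---- splitting ------------------------------------------------------------

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

sample_stratified <- function(ids, labels, n_by_class) {
  picked <- character(0)
  for (cls in names(n_by_class)) {
    pool <- sort(ids[labels == cls])
    k <- n_by_class[[cls]]
    if (k > length(pool)) stop("not enough '", cls, "' records to sample ", k)
    picked <- c(picked, sample(pool, k))
  }
  picked
}

#' Stratified train/test split with an optional nested second test set
#'
#' Splits records into a training set and `test1` stratified by activity
#' label; optionally carves a second test set (`test2`) out of the remaining
#' training molecules, mirroring study designs where an inner validation set
#' is held out from the training pool.  Deterministic for a fixed seed.
#'
#' @param records curated records (both classes must be present).
#' @param test_fraction fraction of records assigned to `test1` (per class,
#'   rounded; at least one molecule of each class).
#' @param seed integer seed.
#' @param carve_test2 number of molecules to carve from the training set into
#'   `test2` (0 = none), allocated proportionally by class.
#' @param counts optional explicit per-class test sizes overriding the
#'   proportional allocation: a list with elements `test1` and/or `test2`,
#'   each a named vector like `c(active = 14, inactive = 864)` — useful when
#'   reproducing a published partition whose exact class counts are known.
#' @return object of class `dataset_split` with id vectors `train`, `test1`,
#'   `test2`, plus the seed and realized fractions.
#' @export
split_dataset <- function(records, test_fraction = 0.03, seed = 1L,
                          carve_test2 = 0L, counts = NULL) {
  labs <- records$label
  if (!all(c("active", "inactive") %in% labs)) {
    stop("both activity classes must be present before splitting")
  }
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must be in (0,1)")
  tab <- table(labs)
  n1 <- counts$test1
  if (is.null(n1)) {
    n1 <- pmax(1L, round(test_fraction * tab[c("active", "inactive")]))
    names(n1) <- c("active", "inactive")
  }
  with_seed(seed, {
    test1 <- sample_stratified(records$id, labs, as.list(n1))
    rest <- !(records$id %in% test1)
    train_ids <- records$id[rest]
    train_labs <- labs[rest]
    test2 <- character(0)
    if (!is.null(counts$test2) || carve_test2 > 0L) {
      n2 <- counts$test2
      if (is.null(n2)) {
        tab2 <- table(train_labs)
        n2 <- pmax(1L, round(carve_test2 * tab2[c("active", "inactive")] /
                               sum(tab2)))
        names(n2) <- c("active", "inactive")
      }
      test2 <- sample_stratified(train_ids, train_labs, as.list(n2))
      sel <- !(train_ids %in% test2)
      train_ids <- train_ids[sel]
    }
    structure(list(train = sort(train_ids), test1 = sort(test1),
                   test2 = sort(test2), seed = seed,
                   fractions = c(train = length(train_ids) / nrow(records),
                                 test1 = length(test1) / nrow(records))),
              class = "dataset_split")
  })
}

#' @export
print.dataset_split <- function(x, ...) {
  cat(sprintf("<dataset_split: train=%d, test1=%d, test2=%d, seed=%d>\n",
              length(x$train), length(x$test1), length(x$test2), x$seed))
  invisible(x)
}
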