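# Binary fingerprint families: MACCS structural keys (166), hashed circular
# (Morgan/ECFP-style) fingerprints, and hashed linear-path fingerprints.

fp_named <- function(mat, prefix, ids) {
  colnames(mat) <- sprintf("%s_%0*d", prefix, nchar(ncol(mat)), seq_len(ncol(mat)))
  rownames(mat) <- ids
  storage.mode(mat) <- "integer"
  mat
}

fp_check <- function(mat, smiles) {
  bad <- apply(mat, 1L, anyNA)
  if (any(bad)) stop("fingerprint computation failed for: ",
                     paste(utils::head(smiles[bad], 5L), collapse = ", "))
  mat
}

#' MACCS structural-key fingerprints (166 bits)
#'
#' Column `MACCS_k` corresponds to MACCS key `k` in the 166-key public set as
#' matched by Open Babel's SMARTS definitions.
#'
#' @param smiles character vector of standardized SMILES.
#' @param ids row names (defaults to the SMILES).
#' @return integer 0/1 matrix, n x 166.
#' @export
fp_maccs <- function(smiles, ids = smiles) {
  mat <- ob_fingerprint(smiles, "MACCS")[, 1:166, drop = FALSE]
  fp_named(fp_check(mat, smiles), "MACCS", ids)
}

#' Hashed circular (Morgan) fingerprints
#'
#' Extended-connectivity fingerprints of the given radius (diameter
#' `2*radius` in ECFP nomenclature), computed by Open Babel in 4096-bit space
#' and folded to `n_bits` by bitwise OR.  The set of bits grows monotonically
#' with radius for a fixed molecule.
#'
#' @param smiles character vector of standardized SMILES.
#' @param n_bits fingerprint length (must divide 4096); default 1024.
#' @param radius circular-environment radius in bonds; default 2 (ECFP4).
#' @param ids row names.
#' @return integer 0/1 matrix, n x n_bits.
#' @export
fp_morgan <- function(smiles, n_bits = 1024L, radius = 2L, ids = smiles) {
  if (4096L %% n_bits != 0L) stop("n_bits must divide 4096")
  raw <- ob_fingerprint(smiles, paste0("ECFP", 2L * radius))
  folds <- ncol(raw) / n_bits
  mat <- matrix(0L, nrow(raw), n_bits)
  for (k in seq_len(folds)) {
    blk <- raw[, ((k - 1L) * n_bits + 1L):(k * n_bits), drop = FALSE]
    mat <- pmax(mat, blk)
  }
  mat[apply(raw, 1L, anyNA), ] <- NA_integer_
  fp_named(fp_check(mat, smiles), "MORGAN", ids)
}

# deterministic string hash (31-adic, modulo a Mersenne prime, exact in doubles)
.hash_string <- function(s, mod = 2147483647) {
  v <- utf8ToInt(s)
  h <- 0
  for (x in v) h <- (h * 31 + x) %% mod
  h
}

path_strings <- function(mg, max_len = 7L) {
  if (mg$n == 0L) return(character(0))
  nb <- vector("list", mg$n)
  for (i in seq_len(mg$n)) nb[[i]] <- list()
  if (nrow(mg$bonds) > 0L) {
    for (k in seq_len(nrow(mg$bonds))) {
      a <- mg$bonds$a1[k]; b <- mg$bonds$a2[k]; o <- mg$bonds$order[k]
      nb[[a]][[length(nb[[a]]) + 1L]] <- c(b, o)
      nb[[b]][[length(nb[[b]]) + 1L]] <- c(a, o)
    }
  }
  tok <- function(atoms, orders) {
    paste(mg$elem[atoms], collapse = paste0("", orders, ""))
  }
  seen <- new.env(hash = TRUE)
  walk <- function(path, orders) {
    last <- path[[length(path)]]
    if (length(path) > 1L) {
      fwd <- paste(mg$elem[path], c(orders, ""), collapse = "", sep = "")
      rev_ <- paste(mg$elem[rev(path)], c(rev(orders), ""), collapse = "", sep = "")
      key <- if (fwd <= rev_) fwd else rev_
      assign(key, TRUE, envir = seen)
    }
    if (length(orders) >= max_len) return(invisible())
    for (step in nb[[last]]) {
      if (step[[1L]] %in% path) next
      walk(c(path, step[[1L]]), c(orders, step[[2L]]))
    }
  }
  for (i in seq_len(mg$n)) walk(i, integer(0))
  ls(seen)
}

#' Hashed linear-path fingerprints
#'
#' Enumerates all simple linear paths of 1 to `max_len` bonds over the
#' heavy-atom graph, canonicalizes each path string (minimum of the forward
#' and reverse reading of element symbols and bond orders) and hashes it into
#' `n_bits` positions with a deterministic 31-adic string hash.
#'
#' @param smiles character vector of standardized SMILES.
#' @param n_bits fingerprint length; default 2048.
#' @param max_len maximum path length in bonds; default 7.
#' @param ids row names.
#' @return integer 0/1 matrix, n x n_bits.
#' @export
fp_path <- function(smiles, n_bits = 2048L, max_len = 7L, ids = smiles) {
  mgs <- mol_graph_from_smiles(smiles)
  mat <- matrix(0L, length(smiles), n_bits)
  for (i in seq_along(mgs)) {
    if (is.null(mgs[[i]])) { mat[i, ] <- NA_integer_; next }
    ps <- path_strings(mgs[[i]], max_len)
    if (length(ps)) {
      bits <- vapply(ps, .hash_string, numeric(1)) %% n_bits + 1
      mat[i, unique(as.integer(bits))] <- 1L
    }
  }
  fp_named(fp_check(mat, smiles), "PATHFP", ids)
}

#' Tanimoto similarity of two bit vectors
#'
#' `|a AND b| / |a OR b|`; defined as 0 (with a warning) when both vectors are
#' all-zero.
#'
#' @param fp_a,fp_b equal-length 0/1 vectors.
#' @return similarity in `[0, 1]`.
#' @export
tanimoto <- function(fp_a, fp_b) {
  if (length(fp_a) != length(fp_b)) stop("fingerprints differ in length")
  inter <- sum(fp_a & fp_b)
  uni <- sum(fp_a | fp_b)
  if (uni == 0) {
    warning("both fingerprints are all-zero; Tanimoto defined as 0")
    return(0)
  }
  inter / uni
}

#' Pairwise Tanimoto similarity matrix
#'
#' @param a 0/1 matrix (rows = molecules).
#' @param b optional second matrix; defaults to `a`.
#' @return `nrow(a)` x `nrow(b)` similarity matrix. All-zero rows yield 0.
#' @export
tanimoto_matrix <- function(a, b = a) {
  a <- as.matrix(a); b <- as.matrix(b)
  inter <- tcrossprod(a, b)
  pa <- rowSums(a); pb <- rowSums(b)
  uni <- outer(pa, pb, "+") - inter
  sim <- ifelse(uni > 0, inter / uni, 0)
  dimnames(sim) <- list(rownames(a), rownames(b))
  sim
}
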