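# Assembly of per-family descriptor blocks into one named matrix.

.family_sizes <- c(maccs = 166L, morgan = 1024L, pathfp = 2048L, d2d = 242L,
                   autocorr3d = 80L, morse = 224L, rdf = 210L, whim = 114L)
.families_3d <- c("autocorr3d", "morse", "rdf", "whim")

#' Assemble a multi-family descriptor matrix
#'
#' Computes the requested descriptor families for a set of records and binds
#' them column-wise into a dense numeric matrix with unique, deterministic
#' column names and a per-column family tag.
#'
#' @param records curated records data.frame (`id`, `smiles`).
#' @param families character vector from `maccs`, `morgan`, `pathfp`, `d2d`,
#'   `autocorr3d`, `morse`, `rdf`, `whim`, `voxel`.
#' @param conformers named list of [conformer] objects (required for the 3D
#'   and voxel families; names must cover all record ids).
#' @param grid_specs list of [grid_spec] objects, one voxel block per spec
#'   (used when `"voxel"` is requested).
#' @param morgan_bits,morgan_radius,path_bits fingerprint options.
#' @return numeric matrix (molecules x descriptors) with
#'   `attr(, "family_tags")` (named character vector column -> family) and
#'   `attr(, "flag_fraction")` (per-column fraction of imputed values).
#' @export
assemble_descriptor_matrix <- function(records, families,
                                       conformers = NULL, grid_specs = NULL,
                                       morgan_bits = 1024L, morgan_radius = 2L,
                                       path_bits = 2048L) {
  if (nrow(records) == 0L) stop("no records supplied")
  known <- c(names(.family_sizes), "voxel")
  if (!all(families %in% known)) {
    stop("unknown family: ", paste(setdiff(families, known), collapse = ", "))
  }
  ids <- records$id
  need3d <- intersect(families, c(.families_3d, "voxel"))
  if (length(need3d) > 0L) {
    if (is.null(conformers) || !all(ids %in% names(conformers))) {
      stop("families ", paste(need3d, collapse = ", "),
           " require a conformer for every record")
    }
    conformers <- conformers[ids]
  }
  blocks <- list(); tags <- character(0); flagfrac <- numeric(0)
  d3 <- NULL
  for (fam in families) {
    blk <- switch(fam,
      maccs = fp_maccs(records$smiles, ids = ids),
      morgan = fp_morgan(records$smiles, n_bits = morgan_bits,
                         radius = morgan_radius, ids = ids),
      pathfp = fp_path(records$smiles, n_bits = path_bits, ids = ids),
      d2d = compute_2d(records$smiles, ids = ids),
      autocorr3d = , morse = , rdf = , whim = {
        if (is.null(d3)) d3 <- compute_3d_many(conformers)
        pref <- toupper(fam)
        d3[, startsWith(colnames(d3), paste0(pref, "_")), drop = FALSE]
      },
      voxel = {
        specs <- grid_specs
        if (is.null(specs)) specs <- list(grid_spec())
        if (inherits(specs, "grid_spec")) specs <- list(specs)
        do.call(cbind, lapply(specs, function(sp) compute_voxel_many(conformers, sp)))
      })
    fl <- attr(blk, "flags")
    ff <- if (is.null(fl)) numeric(ncol(blk)) else colMeans(fl)
    blocks[[fam]] <- blk
    tags <- c(tags, stats::setNames(rep(fam, ncol(blk)), colnames(blk)))
    flagfrac <- c(flagfrac, stats::setNames(ff, colnames(blk)))
  }
  mat <- do.call(cbind, blocks)
  if (anyDuplicated(colnames(mat))) stop("duplicate descriptor column names")
  rownames(mat) <- ids
  attr(mat, "family_tags") <- tags
  attr(mat, "flag_fraction") <- flagfrac
  mat
}
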