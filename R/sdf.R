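# Minimal V2000 SDF reader/writer and the conformer container.
#
# The package keeps its own light SDF layer because docked poses arrive as
# plain V2000 records (including single-atom and bond-less edge cases) and the
# descriptor code needs direct access to elements, coordinates, bond orders
# and formal charges.

#' Create a conformer object
#'
#' A conformer holds one molecule with explicit 3D coordinates: the element
#' symbols, an n x 3 coordinate matrix in Angstrom, the bond list and the
#' provenance of the pose (freshly embedded or taken from a docking run).
#'
#' @param id molecule identifier.
#' @param elem character vector of element symbols.
#' @param xyz numeric matrix (n atoms x 3) of coordinates in Angstrom.
#' @param bonds data.frame with integer columns `a1`, `a2`, `order`.
#' @param pose_source `"embedded"` or `"docked"`.
#' @param formal_charge integer vector of per-atom formal charges.
#' @return an object of class `conformer`.
#' @export
conformer <- function(id, elem, xyz, bonds, pose_source = "embedded",
                      formal_charge = integer(length(elem))) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  stopifnot(length(elem) >= 1L, nrow(xyz) == length(elem),
            all(is.finite(xyz)), pose_source %in% c("embedded", "docked"))
  if (sum(elem != "H") < 1L) stop("conformer needs at least one heavy atom")
  structure(list(id = as.character(id), elem = as.character(elem), xyz = xyz,
                 bonds = bonds, pose_source = pose_source,
                 formal_charge = as.integer(formal_charge)),
            class = "conformer")
}

#' @export
print.conformer <- function(x, ...) {
  cat(sprintf("<conformer %s: %d atoms (%d heavy), %d bonds, pose=%s>\n",
              x$id, length(x$elem), sum(x$elem != "H"), nrow(x$bonds),
              x$pose_source))
  invisible(x)
}

sdf_split_blocks <- function(lines) {
  idx <- cumsum(c(0L, head(lines, -1L) == "$$$$"))
  blocks <- split(lines, idx)
  Filter(function(b) {
    b <- b[b != "$$$$"]
    length(b) >= 4L && any(nzchar(trimws(b)))
  }, blocks)
}

parse_sdf_block <- function(lines, pose_source = "embedded", fallback_id = "mol") {
  lines <- lines[lines != "$$$$"]
  title <- trimws(lines[[1L]])
  counts <- lines[[4L]]
  natoms <- as.integer(substr(counts, 1L, 3L))
  nbonds <- as.integer(substr(counts, 4L, 6L))
  if (is.na(natoms) || natoms < 1L) stop("malformed SDF counts line")
  at <- lines[4L + seq_len(natoms)]
  xyz <- cbind(as.numeric(substr(at, 1L, 10L)),
               as.numeric(substr(at, 11L, 20L)),
               as.numeric(substr(at, 21L, 30L)))
  elem <- trimws(substr(at, 32L, 34L))
  bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (nbonds > 0L) {
    bl <- lines[4L + natoms + seq_len(nbonds)]
    bonds <- data.frame(a1 = as.integer(substr(bl, 1L, 3L)),
                        a2 = as.integer(substr(bl, 4L, 6L)),
                        order = as.integer(substr(bl, 7L, 9L)))
  }
  chg <- integer(natoms)
  for (line in grep("^M  CHG", lines, value = TRUE)) {
    p <- as.integer(strsplit(trimws(sub("^M  CHG", "", line)), "[ ]+")[[1L]])
    k <- p[[1L]]
    for (i in seq_len(k)) chg[p[2L * i]] <- p[2L * i + 1L]
  }
  conformer(if (nzchar(title)) title else fallback_id,
            elem, xyz, bonds, pose_source, chg)
}

parse_sdf_text <- function(text, pose_source = "embedded") {
  lines <- strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE)[[1L]]
  blocks <- sdf_split_blocks(lines)
  out <- vector("list", length(blocks))
  for (i in seq_along(blocks)) {
    out[[i]] <- parse_sdf_block(blocks[[i]], pose_source,
                                fallback_id = sprintf("mol%04d", i))
  }
  names(out) <- vapply(out, function(cf) cf$id, character(1))
  out
}

#' Read conformers from an SDF (V2000) file
#'
#' @param path path to the SDF file.
#' @param pose_source provenance tag stored on each conformer, `"embedded"`
#'   (default) or `"docked"` for poses coming out of a docking engine.
#' @return named list of [conformer] objects (names are molecule titles).
#' @export
read_sdf <- function(path, pose_source = c("embedded", "docked")) {
  pose_source <- match.arg(pose_source)
  if (!file.exists(path)) stop("SDF file not found: ", path)
  parse_sdf_text(readLines(path, warn = FALSE), pose_source)
}

format_sdf_block <- function(cf) {
  n <- length(cf$elem)
  nb <- nrow(cf$bonds)
  head <- c(cf$id, "  qsarscreen", "",
            sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb))
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   cf$xyz[, 1], cf$xyz[, 2], cf$xyz[, 3], cf$elem)
  bonds <- if (nb > 0L) {
    sprintf("%3d%3d%3d  0  0  0  0", cf$bonds$a1, cf$bonds$a2, cf$bonds$order)
  } else character(0)
  chg <- which(cf$formal_charge != 0L)
  mlines <- if (length(chg) > 0L) {
    sprintf("M  CHG%3d%s", length(chg),
            paste(sprintf("%4d%4d", chg, cf$formal_charge[chg]), collapse = ""))
  } else character(0)
  c(head, atoms, bonds, mlines, "M  END", "$$$$")
}

#' Write conformers to an SDF (V2000) file
#'
#' @param conformers a [conformer] or list of conformers.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sdf <- function(conformers, path) {
  if (inherits(conformers, "conformer")) conformers <- list(conformers)
  writeLines(unlist(lapply(conformers, format_sdf_block)), path)
  invisible(path)
}

#' Embed 3D conformers for SMILES strings
#'
#' Uses Open Babel's 3D builder (with hydrogens added) to produce one
#' conformer per molecule.
#'
#' @param smiles character vector of SMILES.
#' @param ids molecule identifiers (defaults to names or positions).
#' @return named list of [conformer] objects; entries Open Babel could not
#'   embed are dropped with a warning.
#' @export
embed_conformers <- function(smiles, ids = NULL) {
  if (is.null(ids)) ids <- if (!is.null(names(smiles))) names(smiles) else
    sprintf("mol%04d", seq_along(smiles))
  sdf <- ob_smi_to_sdf(smiles, gen3d = TRUE)
  cfs <- parse_sdf_text(sdf, pose_source = "embedded")
  # obabel titles are the positional m%07d tags; map back to requested ids
  pos <- match(names(cfs), ob_titles(length(smiles)))
  keep <- !is.na(pos)
  cfs <- cfs[keep]; pos <- pos[keep]
  for (i in seq_along(cfs)) cfs[[i]]$id <- ids[pos[i]]
  names(cfs) <- ids[pos]
  if (length(cfs) < length(smiles)) {
    warning(sprintf("3D embedding failed for %d of %d molecules",
                    length(smiles) - length(cfs), length(smiles)))
  }
  cfs
}
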