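#' @keywords internal
"_PACKAGE"

# Internal batch interface to the Open Babel command-line tool.
#
# All chemistry primitives that the package does not own scientifically
# (SMILES parsing and canonicalization, InChI, SMARTS matching, MACCS/ECFP
# fingerprints, logP/TPSA/MR estimation, 3D embedding, partial charges) are
# delegated to the `obabel` executable.  Molecules are always passed through
# positionally: inputs get synthetic titles m0000001, m0000002, ... and
# outputs are mapped back by title, so records that Open Babel rejects come
# back as NA instead of silently shifting the alignment.

ob_exe <- function() {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) stop("Open Babel executable 'obabel' not found on PATH")
  unname(exe)
}

ob_titles <- function(n) sprintf("m%07d", seq_len(n))

# Run obabel with an input file written from `input_lines` (extension decides
# the format) and return stdout lines. stderr (Open Babel chatter) is dropped.
ob_run <- function(input_lines, in_ext, args) {
  infile <- tempfile(fileext = in_ext)
  on.exit(unlink(infile), add = TRUE)
  writeLines(input_lines, infile)
  out <- suppressWarnings(system2(ob_exe(), c(shQuote(infile), args),
                                  stdout = TRUE, stderr = FALSE))
  if (is.null(attr(out, "status"))) out else out
}

ob_smi_lines <- function(smiles) paste(smiles, ob_titles(length(smiles)), sep = "\t")

# Convert SMILES to another line-oriented format ("can", "inchi", "smi").
# Returns a character vector aligned with `smiles`; NA for failures.
ob_smi_convert <- function(smiles, to = c("can", "inchi")) {
  to <- match.arg(to)
  n <- length(smiles)
  if (n == 0L) return(character(0))
  args <- c("-o", to)
  if (to == "inchi") args <- c(args, "-xt")  # append the molecule title
  out <- ob_run(ob_smi_lines(smiles), ".smi", args)
  res <- rep(NA_character_, n)
  if (length(out) == 0L) return(res)
  # both formats emit "value<sep>title" with no whitespace inside the value
  value <- sub("[ \t].*$", "", out)
  title <- sub("^.*[ \t]", "", out)
  idx <- match(title, ob_titles(n))
  ok <- !is.na(idx) & title != out
  res[idx[ok]] <- value[ok]
  res
}

ob_canonical_smiles <- function(smiles) ob_smi_convert(smiles, "can")

ob_inchi <- function(smiles) ob_smi_convert(smiles, "inchi")

# SMARTS substructure test, vectorized over molecules (single obabel call).
ob_smarts_match <- function(smiles, smarts) {
  n <- length(smiles)
  if (n == 0L) return(logical(0))
  out <- ob_run(ob_smi_lines(smiles), ".smi", c("-osmi", "-s", shQuote(smarts)))
  hit <- rep(FALSE, n)
  if (length(out) == 0L) return(hit)
  title <- sub("^.*[ \t]", "", out)
  idx <- match(title, ob_titles(n))
  hit[idx[!is.na(idx)]] <- TRUE
  hit
}

# Molecular property block computed by Open Babel's descriptor plugins.
ob_properties <- function(smiles) {
  n <- length(smiles)
  fields <- c("MW", "logP", "TPSA", "MR", "HBD", "HBA1", "HBA2", "nF",
              "rotors", "atoms", "bonds", "sbonds", "dbonds", "tbonds", "abonds")
  res <- matrix(NA_real_, n, length(fields), dimnames = list(NULL, fields))
  if (n == 0L) return(as.data.frame(res))
  out <- ob_run(ob_smi_lines(smiles), ".smi",
                c("-otxt", "--append", shQuote(paste(fields, collapse = " "))))
  parts <- strsplit(out, "[ \t]+")
  keep <- lengths(parts) == length(fields) + 1L
  parts <- parts[keep]
  if (length(parts) > 0L) {
    pm <- matrix(unlist(parts), nrow = length(parts), byrow = TRUE)
    idx <- match(pm[, 1L], ob_titles(n))
    ok <- !is.na(idx)
    vals <- suppressWarnings(matrix(as.numeric(pm[, -1L, drop = FALSE]),
                                    nrow = nrow(pm)))
    res[idx[ok], ] <- vals[ok, , drop = FALSE]
  }
  as.data.frame(res)
}

# Parse Open Babel FPS output (hex, byte-major, least-significant bit first
# within each byte).  Bit b (0-based) corresponds to MACCS key b+1 for the
# MACCS type; ECFP types hash into num_bits positions.
ob_parse_fps <- function(lines, n) {
  nbits <- NA_integer_
  rows <- list()
  for (line in lines) {
    if (startsWith(line, "#")) {
      if (startsWith(line, "#num_bits=")) nbits <- as.integer(sub("#num_bits=", "", line))
      next
    }
    p <- strsplit(line, "\t", fixed = TRUE)[[1L]]
    if (length(p) >= 2L) rows[[p[[2L]]]] <- p[[1L]]
  }
  if (is.na(nbits)) stop("malformed FPS output from obabel")
  mat <- matrix(NA_integer_, n, nbits)
  nibble <- matrix(0L, 16L, 4L)
  for (v in 0:15) nibble[v + 1L, ] <- bitwAnd(bitwShiftR(v, 0:3), 1L)
  idxs <- match(names(rows), ob_titles(n))
  for (r in seq_along(rows)) {
    if (is.na(idxs[r])) next
    vals <- strtoi(strsplit(rows[[r]], "")[[1L]], 16L)
    nbytes <- length(vals) %/% 2L
    # hex chars come in byte pairs (high nibble first) but the bit order
    # within each byte is LSB-first, so byte k = low nibble bits then high
    lo <- t(nibble[vals[2L * seq_len(nbytes)] + 1L, , drop = FALSE])
    hi <- t(nibble[vals[2L * seq_len(nbytes) - 1L] + 1L, , drop = FALSE])
    bits <- as.integer(rbind(lo, hi))
    mat[idxs[r], ] <- bits[seq_len(nbits)]
  }
  mat
}

# Raw Open Babel fingerprint of a named type ("MACCS", "ECFP2", "ECFP4", ...).
ob_fingerprint <- function(smiles, type) {
  n <- length(smiles)
  if (n == 0L) stop("no molecules supplied")
  out <- ob_run(ob_smi_lines(smiles), ".smi", c("-ofps", paste0("-xf", type)))
  ob_parse_fps(out, n)
}

# SMILES -> SDF text (V2000).  gen3d embeds a 3D conformer with hydrogens.
ob_smi_to_sdf <- function(smiles, gen3d = FALSE) {
  if (length(smiles) == 0L) return(character(0))
  args <- "-osdf"
  if (gen3d) args <- c(args, "--gen3d")
  paste(ob_run(ob_smi_lines(smiles), ".smi", args), collapse = "\n")
}

# Partial charges for an SDF block; returns a list (one numeric vector per
# molecule, atom order preserved) keyed by the molecule title.
ob_partial_charges <- function(sdf_text, model = c("gasteiger", "mmff94")) {
  model <- match.arg(model)
  infile <- tempfile(fileext = ".sdf")
  on.exit(unlink(infile), add = TRUE)
  writeLines(sdf_text, infile)
  out <- suppressWarnings(system2(ob_exe(),
    c(shQuote(infile), "-omol2", "--partialcharge", model),
    stdout = TRUE, stderr = FALSE))
  res <- list(); cur <- NULL; section <- ""; title <- NULL
  for (line in out) {
    if (startsWith(line, "@<TRIPOS>")) {
      if (identical(section, "ATOM") && !is.null(title)) res[[title]] <- cur
      section <- sub("@<TRIPOS>", "", line)
      if (section == "MOLECULE") { title <- NA; cur <- numeric(0) }
      next
    }
    if (section == "MOLECULE" && identical(title, NA)) { title <- trimws(line); next }
    if (section == "ATOM") {
      p <- strsplit(trimws(line), "[ \t]+")[[1L]]
      if (length(p) >= 9L) cur <- c(cur, as.numeric(p[[length(p)]]))
    }
  }
  if (identical(section, "ATOM") && !is.null(title)) res[[title]] <- cur
  res
}
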