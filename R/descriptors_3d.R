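# Geometry-based descriptor families computed on one conformer:
#   AUTOCORR3D (80) - topological-lag autocorrelation of 3D distances
#   MORSE      (224) - electron-diffraction style sin(s r)/(s r) spectrum
#   RDF        (210) - Gaussian-smoothed radial distribution function
#   WHIM       (114) - statistics of the weighted principal axes
# All are functions of interatomic distances or of PCA eigenstructure, hence
# invariant to rigid rotation and translation of the pose.

.w3d_pair <- c("u", "m", "v", "e", "p", "i", "s")     # MORSE / RDF weights
.w3d_auto <- c("u", "m", "v", "e", "p", "i", "s", "r") # AUTOCORR3D weights

#' Names of the 3D descriptor panel (628 entries)
#' @return character vector: AUTOCORR3D_01..80, MORSE_001..224, RDF_001..210,
#'   WHIM_001..114.
#' @export
manifest_3d <- function() {
  c(sprintf("AUTOCORR3D_%02d", 1:80), sprintf("MORSE_%03d", 1:224),
    sprintf("RDF_%03d", 1:210), sprintf("WHIM_%03d", 1:114))
}

# per-atom weights for all atoms of a conformer (H included; the intrinsic
# state is a heavy-atom concept, hydrogens get 0)
conf_weights <- function(cf, scheme) {
  if (scheme == "s") {
    mg <- mol_graph(cf)
    w <- numeric(length(cf$elem))
    w[mg$heavy_index] <- intrinsic_state(mg)
    w
  } else {
    atom_weight(cf$elem, scheme)
  }
}

morse_vector <- function(dists, wprod) {
  s <- 0:31
  vapply(s, function(sv) {
    if (sv == 0L) sum(wprod) else sum(wprod * sin(sv * dists) / (sv * dists))
  }, numeric(1))
}

rdf_vector <- function(dists, wprod, beta = 100) {
  r <- seq(0.5, 15, by = 0.5)
  vapply(r, function(rk) sum(wprod * exp(-beta * (rk - dists)^2)), numeric(1))
}

whim_vector <- function(xyz, w) {
  n <- nrow(xyz)
  sw <- sum(w)
  if (n < 3L || sw <= 0) return(numeric(19))
  mu <- colSums(xyz * w) / sw
  xc <- sweep(xyz, 2L, mu)
  covm <- crossprod(xc * w, xc) / sw
  eg <- eigen(covm, symmetric = TRUE)
  lam <- pmax(eg$values, 0)
  scores <- xc %*% eg$vectors
  tot <- sum(lam)
  th <- if (tot > 0) lam / tot else rep(0, 3)
  gam <- eta <- numeric(3)
  for (m in 1:3) {
    s <- scores[, m]
    sdv <- sqrt(sum(w * s^2) / sw)
    if (sdv > 1e-10) {
      skew <- sum(w * s^3) / sw / sdv^3
      kurt <- sum(w * s^4) / sw / sdv^4
      gam[m] <- 1 / (1 + abs(skew))
      eta[m] <- if (kurt > 0) 1 / kurt else 0
    }
  }
  A <- lam[1] * lam[2] + lam[1] * lam[3] + lam[2] * lam[3]
  V <- tot + A + prod(lam)
  K <- sum(abs(th - 1 / 3)) / (4 / 3)
  G <- prod(lam)^(1 / 3)
  c(lam, th, gam, eta, tot, A, V, K, G, lam[1] - lam[2], lam[2] - lam[3])
}

autocorr3d_vector <- function(cf) {
  mg <- mol_graph(cf)
  out <- numeric(80)
  if (mg$n < 2L) return(out)
  Dtop <- mol_distances(mg)
  xyz <- cf$xyz[mg$heavy_index, , drop = FALSE]
  D3 <- as.matrix(stats::dist(xyz))
  col <- 0L
  for (scheme in .w3d_auto) {
    w <- if (scheme == "s") intrinsic_state(mg) else atom_weight(mg$elem, scheme)
    for (lag in 1:10) {
      col <- col + 1L
      sel <- which(Dtop == lag, arr.ind = TRUE)
      sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
      if (nrow(sel) > 0L) {
        out[col] <- sum(w[sel[, 1]] * w[sel[, 2]] * D3[sel]) / nrow(sel)
      }
    }
  }
  out
}

#' Compute the 3D descriptor panel for one conformer
#'
#' @param cf a [conformer].
#' @return named numeric vector of length 628 (see [manifest_3d()]).  For
#'   degenerate geometry (fewer than two atoms) families are zero-filled and
#'   flagged via `attr(, "flagged")`.
#' @export
compute_3d <- function(cf) {
  stopifnot(inherits(cf, "conformer"))
  nm <- manifest_3d()
  na <- length(cf$elem)
  flagged <- FALSE
  if (na < 2L) {
    out <- stats::setNames(numeric(length(nm)), nm)
    attr(out, "flagged") <- TRUE
    return(out)
  }
  Dm <- as.matrix(stats::dist(cf$xyz))
  pair <- which(upper.tri(Dm), arr.ind = TRUE)
  dists <- Dm[pair]
  dists[dists < 1e-6] <- 1e-6
  wlist <- lapply(.w3d_pair, function(s) conf_weights(cf, s))
  morse <- unlist(lapply(wlist, function(w) {
    morse_vector(dists, w[pair[, 1]] * w[pair[, 2]])
  }))
  rdf <- unlist(lapply(wlist, function(w) {
    rdf_vector(dists, w[pair[, 1]] * w[pair[, 2]])
  }))
  whim <- unlist(lapply(c("u", "m", "v", "e", "p", "s"), function(s) {
    whim_vector(cf$xyz, conf_weights(cf, s))
  }))
  out <- c(autocorr3d_vector(cf), morse, rdf, whim)
  names(out) <- nm
  if (any(!is.finite(out))) {
    out[!is.finite(out)] <- 0
    flagged <- TRUE
  }
  attr(out, "flagged") <- flagged
  out
}

#' Compute 3D descriptors for a list of conformers
#' @param conformers named list of [conformer] objects.
#' @return matrix (molecules x 628).
#' @export
compute_3d_many <- function(conformers) {
  rows <- lapply(conformers, compute_3d)
  mat <- do.call(rbind, rows)
  rownames(mat) <- names(conformers)
  mat
}
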