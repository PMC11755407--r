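# Frozen 242-column 1D & 2D descriptor panel.
#
# Blocks: 42 MQN-style atom/bond/polarity/topology counts, 20 physicochemical
# values (Open Babel estimators plus simple graph counts), 16 element counts,
# 20 topological indices, and 144 2D autocorrelations (Broto-Moreau ATS,
# centered ATSC and Geary GATS over lags 1-8 and six atomic weighting
# schemes).  The column manifest is fixed: names and order never change
# between runs, which matters more for downstream model reuse than numeric
# parity with any external descriptor program.

.ac_weights <- c("m", "v", "e", "p", "i", "s")

#' Names of the 242-descriptor 1D & 2D panel
#' @return character vector of length 242 (stable across runs).
#' @export
manifest_2d <- function() {
  c(sprintf("MQN_%02d", 1:42),
    paste0("PHYS_", c("MW", "LOGP", "TPSA", "MR", "HBD", "HBA1", "HBA2", "NF",
                      "ROTORS", "HEAVY", "NBONDS", "SBONDS", "DBONDS", "TBONDS",
                      "ABONDS", "NRINGS", "CHARGE_NET", "CHARGE_ABS",
                      "FRAC_RING", "FRAC_HETERO")),
    paste0("ELEM_", c("B", "C", "N", "O", "F", "SI", "P", "S", "CL", "SE",
                      "BR", "I", "OTHER", "H", "HETERO", "HALOGEN")),
    paste0("TOPO_", c("WIENER", "RADIUS", "DIAMETER", "MEAN_ECC", "MEAN_DIST",
                      "ZAGREB1", "ZAGREB2", "RANDIC", "CHI0", "CHI1",
                      "KAPPA1", "KAPPA2", "KAPPA3", "CYCLOMATIC", "DENSITY",
                      "MEAN_DEG", "MAX_DEG", "N_TERMINAL", "N_BRANCH",
                      "BALABAN_J")),
    as.vector(outer(1:8, .ac_weights, function(d, w) sprintf("ATS_%s_%d", w, d))),
    as.vector(outer(1:8, .ac_weights, function(d, w) sprintf("ATSC_%s_%d", w, d))),
    as.vector(outer(1:8, .ac_weights, function(d, w) sprintf("GATS_%s_%d", w, d))))
}

mqn_block <- function(mg) {
  e <- mg$elem; ring <- mg$ring_atom; deg <- mg$degree
  b <- mg$bonds; rb <- mg$ring_edge
  acy <- !rb
  is_no <- e %in% c("N", "O")
  # ring-degree of each atom = number of incident ring bonds
  rdeg <- integer(mg$n)
  if (nrow(b) > 0L) for (k in which(rb)) {
    rdeg[b$a1[k]] <- rdeg[b$a1[k]] + 1L
    rdeg[b$a2[k]] <- rdeg[b$a2[k]] + 1L
  }
  rsz <- ring_size_counts(mg, max_size = 10L)  # sizes 3..9 and >=10
  rotatable <- 0L
  if (nrow(b) > 0L) {
    rotatable <- sum(acy & b$order == 1L & deg[b$a1] > 1L & deg[b$a2] > 1L)
  }
  c(sum(e == "C"), sum(e == "F"), sum(e == "Cl"), sum(e == "Br"), sum(e == "I"),
    sum(e == "S"), sum(e == "P"),
    sum(e == "N" & !ring), sum(e == "N" & ring),
    sum(e == "O" & !ring), sum(e == "O" & ring), mg$n,
    sum(acy & b$order == 1L), sum(acy & b$order == 2L), sum(acy & b$order == 3L),
    sum(rb & b$order == 1L), sum(rb & b$order == 2L), sum(rb & b$order == 3L),
    rotatable,
    sum(is_no & mg$charge <= 0L),                       # acceptor atoms
    sum((e == "O") * 2L + (e == "N" & mg$charge <= 0L)),# acceptor sites
    sum(is_no & mg$nH > 0L),                            # donor atoms
    sum(mg$nH[is_no]),                                  # donor sites
    sum(mg$charge < 0L), sum(mg$charge > 0L),
    sum(!ring & deg == 1L), sum(!ring & deg == 2L),
    sum(!ring & deg == 3L), sum(!ring & deg >= 4L),
    sum(ring & deg == 2L), sum(ring & deg == 3L), sum(ring & deg >= 4L),
    rsz[1:7], rsz[8],
    sum(rdeg >= 3L), if (nrow(b)) sum(rb & rdeg[b$a1] >= 3L & rdeg[b$a2] >= 3L) else 0L)
}

topo_block <- function(mg) {
  n <- mg$n; deg <- mg$degree; m <- nrow(mg$bonds)
  if (n < 2L || m == 0L) {
    return(c(0, 0, 0, 0, 0, sum(deg^2), 0, 0,
             sum(ifelse(deg > 0, 1 / sqrt(deg), 0)), 0,
             0, 0, 0, n_rings(mg), 0, mean(deg), max(deg, 0),
             sum(deg == 1L), sum(deg >= 3L), 0))
  }
  D <- mol_distances(mg)
  fin <- is.finite(D) & D > 0
  wiener <- sum(D[fin]) / 2
  ecc <- apply(D, 1L, function(r) max(r[is.finite(r)]))
  si <- rowSums(ifelse(is.finite(D), D, 0))
  mu <- m - n + igraph::components(mg$graph)$no
  bj <- 0
  if (all(is.finite(D))) {
    terms <- 1 / sqrt(si[mg$bonds$a1] * si[mg$bonds$a2])
    bj <- m / (mu + 1) * sum(terms)
  }
  z2 <- sum(deg[mg$bonds$a1] * deg[mg$bonds$a2])
  randic <- sum(1 / sqrt(deg[mg$bonds$a1] * deg[mg$bonds$a2]))
  p2 <- sum(choose(deg, 2))
  p3 <- 0
  if (m > 0L) {
    for (k in seq_len(m)) {
      a <- mg$bonds$a1[k]; bb <- mg$bonds$a2[k]
      p3 <- p3 + (deg[a] - 1L) * (deg[bb] - 1L)
    }
    p3 <- p3 - 3L * sum(ring_size_counts(mg)[1])  # discount 3-ring closures
  }
  kap1 <- if (m > 0) n * (n - 1)^2 / m^2 else 0
  kap2 <- if (p2 > 0) (n - 1) * (n - 2)^2 / p2^2 else 0
  kap3 <- if (p3 > 0) {
    if (n %% 2L == 1L) (n - 1) * (n - 3)^2 / p3^2 else (n - 3) * (n - 2)^2 / p3^2
  } else 0
  c(wiener, min(ecc), max(ecc), mean(ecc), mean(D[fin]),
    sum(deg^2), z2, randic, sum(1 / sqrt(deg)), randic,
    kap1, kap2, kap3, n_rings(mg), m / choose(n, 2), mean(deg), max(deg),
    sum(deg == 1L), sum(deg >= 3L), bj)
}

autocorr_block <- function(mg) {
  n <- mg$n
  out <- numeric(3L * 8L * length(.ac_weights))
  if (n < 2L) return(out)
  D <- mol_distances(mg)
  wmats <- lapply(.ac_weights, function(s) {
    if (s == "s") intrinsic_state(mg) else atom_weight(mg$elem, s)
  })
  k <- 0L
  blocks <- list(ats = 1, atsc = 2, gats = 3)
  res <- matrix(0, 8L, 3L * length(.ac_weights))
  col <- 0L
  for (w in wmats) {
    col <- col + 1L
    wc <- w - mean(w)
    varw <- sum(wc^2) / (n - 1)
    for (d in 1:8) {
      sel <- which(D == d, arr.ind = TRUE)
      sel <- sel[sel[, 1] < sel[, 2], , drop = FALSE]
      nd <- nrow(sel)
      if (nd > 0L) {
        res[d, col] <- sum(w[sel[, 1]] * w[sel[, 2]])
        res[d, col + length(.ac_weights)] <- sum(wc[sel[, 1]] * wc[sel[, 2]])
        res[d, col + 2L * length(.ac_weights)] <-
          if (varw > 0) (sum((w[sel[, 1]] - w[sel[, 2]])^2) / (2 * nd)) / varw else 0
      }
    }
  }
  as.vector(res)
}

#' Compute the 242-column 1D & 2D descriptor panel
#'
#' @param smiles character vector of standardized SMILES.
#' @param ids row names.
#' @return numeric matrix n x 242 with columns [manifest_2d()]. Values
#'   undefined for a molecule are imputed as 0 and recorded in the logical
#'   `attr(, "flags")` matrix (a warning summarizes how many).
#' @export
compute_2d <- function(smiles, ids = smiles) {
  man <- manifest_2d()
  n <- length(smiles)
  mat <- matrix(0, n, length(man), dimnames = list(ids, man))
  props <- ob_properties(smiles)
  mgs <- mol_graph_from_smiles(smiles)
  halogens <- c("F", "Cl", "Br", "I")
  for (i in seq_len(n)) {
    mg <- mgs[[i]]
    if (is.null(mg)) { mat[i, ] <- NA_real_; next }
    e <- mg$elem
    phys <- c(props$MW[i], props$logP[i], props$TPSA[i], props$MR[i],
              props$HBD[i], props$HBA1[i], props$HBA2[i], props$nF[i],
              props$rotors[i], mg$n, nrow(mg$bonds),
              sum(mg$bonds$order == 1L), sum(mg$bonds$order == 2L),
              sum(mg$bonds$order == 3L), props$abonds[i], n_rings(mg),
              sum(mg$charge), sum(abs(mg$charge)),
              mean(mg$ring_atom), mean(!e %in% c("C", "H")))
    elem <- c(sum(e == "B"), sum(e == "C"), sum(e == "N"), sum(e == "O"),
              sum(e == "F"), sum(e == "Si"), sum(e == "P"), sum(e == "S"),
              sum(e == "Cl"), sum(e == "Se"), sum(e == "Br"), sum(e == "I"),
              sum(!e %in% rownames(.atom_table)), sum(mg$nH),
              sum(!e %in% c("C", "H")), sum(e %in% halogens))
    mat[i, ] <- c(mqn_block(mg), phys, elem, topo_block(mg), autocorr_block(mg))
  }
  flags <- !is.finite(mat)
  if (any(flags)) {
    warning(sprintf("%d descriptor value(s) undefined; imputed as 0",
                    sum(flags)))
    mat[flags] <- 0
  }
  attr(mat, "flags") <- flags
  mat
}
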