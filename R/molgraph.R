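# Heavy-atom molecular graph built from a conformer's bond list.
# Used by the 2D descriptor panel, path fingerprints, Murcko scaffolds and
# the docked-pose atom matcher.

.std_valence <- list(B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = c(3, 5),
                     S = c(2, 4, 6), Cl = 1, Br = 1, I = 1, Se = c(2, 4, 6))

# Build the heavy-atom graph.  Hydrogens (explicit or implicit) are folded
# into a per-atom nH count.
mol_graph <- function(cf) {
  heavy <- which(cf$elem != "H")
  idx <- match(seq_along(cf$elem), heavy)  # orig -> heavy position (NA for H)
  elem <- cf$elem[heavy]
  chg <- cf$formal_charge[heavy]
  n <- length(heavy)
  b <- cf$bonds
  expl_h <- integer(n)
  hb <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
  if (nrow(b) > 0L) {
    h1 <- cf$elem[b$a1] == "H"; h2 <- cf$elem[b$a2] == "H"
    for (k in which(h1 & !h2)) expl_h[idx[b$a2[k]]] <- expl_h[idx[b$a2[k]]] + 1L
    for (k in which(h2 & !h1)) expl_h[idx[b$a1[k]]] <- expl_h[idx[b$a1[k]]] + 1L
    keep <- !h1 & !h2
    hb <- data.frame(a1 = idx[b$a1[keep]], a2 = idx[b$a2[keep]],
                     order = b$order[keep])
  }
  # bond-order sum per heavy atom (aromatic SDF input is Kekule, order 4 not
  # expected from Open Babel output; treat 4 as 1.5 defensively)
  ord <- ifelse(hb$order == 4L, 1.5, hb$order)
  bosum <- numeric(n)
  for (k in seq_len(nrow(hb))) {
    bosum[hb$a1[k]] <- bosum[hb$a1[k]] + ord[k]
    bosum[hb$a2[k]] <- bosum[hb$a2[k]] + ord[k]
  }
  imp_h <- integer(n)
  for (i in seq_len(n)) {
    vals <- .std_valence[[elem[i]]]
    if (is.null(vals)) next
    target <- vals[vals >= ceiling(bosum[i] - chg[i] * (elem[i] %in% c("N", "P")))]
    target <- if (length(target)) min(target) else max(vals)
    # charge adjustments: cationic N/P gain a bond slot, anions lose one
    target <- target + ifelse(chg[i] > 0 & elem[i] %in% c("N", "P"), chg[i], 0) +
      ifelse(chg[i] < 0, chg[i], 0)
    imp_h[i] <- max(0L, as.integer(round(target - bosum[i] - expl_h[i])))
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(hb) > 0L) {
    g <- igraph::add_edges(g, rbind(hb$a1, hb$a2))
  }
  ring_edge <- rep(FALSE, nrow(hb))
  if (nrow(hb) > 0L) {
    br <- igraph::bridges(g)
    ring_edge[-as.integer(br)] <- TRUE
    if (length(br) == 0L) ring_edge[] <- TRUE
    # isolated edges in acyclic components: bridges() marks them, fine
  }
  ring_atom <- rep(FALSE, n)
  if (any(ring_edge)) {
    ra <- unique(c(hb$a1[ring_edge], hb$a2[ring_edge]))
    ring_atom[ra] <- TRUE
  }
  list(n = n, elem = elem, charge = chg, nH = expl_h + imp_h,
       bonds = hb, graph = g, ring_edge = ring_edge, ring_atom = ring_atom,
       degree = igraph::degree(g), bosum = bosum, heavy_index = heavy)
}

mol_graph_from_smiles <- function(smiles) {
  sdf <- ob_smi_to_sdf(smiles, gen3d = FALSE)
  cfs <- parse_sdf_text(sdf)
  pos <- match(names(cfs), ob_titles(length(smiles)))
  out <- vector("list", length(smiles))
  for (k in seq_along(cfs)) if (!is.na(pos[k])) out[[pos[k]]] <- mol_graph(cfs[[k]])
  out
}

# Topological distance matrix (heavy atoms); unreachable pairs = Inf.
mol_distances <- function(mg) igraph::distances(mg$graph)

# Smallest-ring-size histogram, approximated from the shortest cycle through
# each ring bond: a ring of size s contributes s such bonds.
ring_size_counts <- function(mg, max_size = 10L) {
  counts <- integer(max_size - 2L)  # sizes 3 .. max_size ("max" bin = >= max)
  if (!any(mg$ring_edge)) return(counts)
  sizes <- integer(0)
  for (k in which(mg$ring_edge)) {
    g2 <- igraph::delete_edges(mg$graph, k)
    d <- igraph::distances(g2, v = mg$bonds$a1[k], to = mg$bonds$a2[k])[1, 1]
    if (is.finite(d)) sizes <- c(sizes, d + 1L)
  }
  for (s in 3:(max_size - 1L)) {
    counts[s - 2L] <- round(sum(sizes == s) / s)
  }
  big <- sizes[sizes >= max_size]
  counts[max_size - 2L] <- if (length(big)) max(1L, round(length(big) / mean(big))) else 0L
  counts
}

# number of rings in the SSSR sense (cyclomatic number)
n_rings <- function(mg) {
  comps <- igraph::components(mg$graph)$no
  nrow(mg$bonds) - mg$n + comps
}

# Kier-Hall intrinsic state per heavy atom
intrinsic_state <- function(mg) {
  period <- ifelse(atomic_number(mg$elem) <= 10, 2,
                   ifelse(atomic_number(mg$elem) <= 18, 3,
                          ifelse(atomic_number(mg$elem) <= 36, 4, 5)))
  zv <- c(B = 3, C = 4, N = 5, O = 6, F = 7, Si = 4, P = 5, S = 6, Cl = 7,
          Se = 6, Br = 7, I = 7)[mg$elem]
  zv[is.na(zv)] <- 4
  dv <- zv - mg$nH
  d <- pmax(mg$degree, 1L)
  ((2 / period)^2 * dv + 1) / d
}
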