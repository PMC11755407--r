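# Transfer of docked-pose coordinates onto a reference atom ordering.
# Docking engines routinely permute atoms, so the pre- and post-docking
# records are reconciled by iterative neighborhood-label refinement (a
# Morgan-style canonical ranking); residual automorphic ties are broken by
# coordinate proximity and then by atom index, which is chemically neutral.

inchi_connectivity <- function(inchi) {
  sub("/(b|t|m|s).*$", "", inchi)
}

conformer_inchi <- function(cf) {
  smi <- conformer_smiles(cf)
  ob_inchi(smi)
}

refine_ranks <- function(cf) {
  n <- length(cf$elem)
  lab <- paste(cf$elem, cf$formal_charge, sep = "/")
  nb <- vector("list", n)
  if (nrow(cf$bonds) > 0L) {
    for (k in seq_len(nrow(cf$bonds))) {
      a <- cf$bonds$a1[k]; b <- cf$bonds$a2[k]; o <- cf$bonds$order[k]
      nb[[a]] <- c(nb[[a]], list(c(b, o)))
      nb[[b]] <- c(nb[[b]], list(c(a, o)))
    }
  }
  for (iter in seq_len(n)) {
    ranks <- match(lab, sort(unique(lab)))
    new <- vapply(seq_len(n), function(i) {
      env <- vapply(nb[[i]], function(e) paste0(e[[2L]], ":", ranks[e[[1L]]]),
                    character(1))
      paste(ranks[i], paste(sort(env), collapse = ","), sep = "|")
    }, character(1))
    if (length(unique(new)) == length(unique(lab)) && iter > 1L) break
    lab <- new
  }
  match(lab, sort(unique(lab)))
}

#' Adopt docked coordinates onto a reference conformer
#'
#' Given the same molecule before and after docking (the docking engine may
#' have permuted atoms), returns a conformer with the reference (pre) atom
#' order and bond list but the docked (post) coordinates.
#'
#' @param pre [conformer] with the reference atom order.
#' @param post [conformer] carrying the docked coordinates.
#' @return a [conformer] with `pose_source = "docked"`.
#' @export
adopt_docked_pose <- function(pre, post) {
  stopifnot(inherits(pre, "conformer"), inherits(post, "conformer"))
  if (length(pre$elem) != length(post$elem)) {
    stop("atom-count mismatch between pre- and post-docking records")
  }
  ic_pre <- inchi_connectivity(conformer_inchi(pre))
  ic_post <- inchi_connectivity(conformer_inchi(post))
  if (is.na(ic_pre) || is.na(ic_post) || ic_pre != ic_post) {
    stop("InChI mismatch: pre- and post-docking records are different molecules")
  }
  r_pre <- refine_ranks(pre)
  r_post <- refine_ranks(post)
  mapping <- integer(length(r_pre))  # pre index -> post index
  for (cls in sort(unique(r_pre))) {
    ip <- which(r_pre == cls)
    iq <- which(r_post == cls)
    if (length(ip) != length(iq)) {
      stop("atom environments do not match between the two records")
    }
    if (length(ip) == 1L) {
      mapping[ip] <- iq
    } else {
      # automorphic class: assign by coordinate proximity, greedily
      remaining <- iq
      for (i in ip) {
        d <- sqrt(colSums((t(post$xyz[remaining, , drop = FALSE]) -
                             pre$xyz[i, ])^2))
        pick <- remaining[which.min(d)]
        mapping[i] <- pick
        remaining <- setdiff(remaining, pick)
      }
    }
  }
  conformer(pre$id, pre$elem, post$xyz[mapping, , drop = FALSE], pre$bonds,
            pose_source = "docked", formal_charge = pre$formal_charge)
}
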