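# Synthetic SMILES datasets with a planted structure-activity rule.
#
# Molecules are assembled combinatorially from decorated ring scaffolds,
# linkers and substituents.  Actives contain a biphenyl system plus an amide
# or a 1,3-oxazole (motifs repeatedly associated with PD-L1 inhibition);
# inactive fragments can contain any single motif but never the full
# conjunction, and every generated label is verified post hoc by SMARTS
# matching, so the planted rule is exact before label noise is applied.

.rule_smarts <- list(biphenyl = "c1ccccc1-c1ccccc1",
                     amide = "[CX3](=O)[NX3]",
                     oxazole = "c1ocnc1")

.syn_heads <- c("", "C", "CC", "CO", "N", "O", "F", "Cl", "Br", "N#C",
                "FC(F)(F)", "CC(C)")
.syn_active_tails <- c("C(=O)NC", "C(=O)NCC", "C(=O)N(C)C", "CC(=O)NC",
                       "NC(=O)C", "NC(=O)CC", "CNC(=O)C", "CC(=O)N(C)C",
                       "-c2ocnc2", "-c2oc(C)nc2", "Cc2ocnc2", "OCC(=O)NC",
                       "C(=O)NCCO", "NC(=O)COC")
.syn_active_templates <- c("%sc1ccc(-c2ccc(%s)cc2)cc1",
                           "%sc1cccc(-c2ccc(%s)cc2)c1",
                           "%sc1ccc(-c2cc(C)cc(%s)c2)cc1",
                           "%sc1cc(F)cc(-c2ccc(%s)cc2)c1")
.syn_cores <- c("%sc1ccc(%s)cc1", "%sc1cc(%s)ccn1", "%sc1ccc(%s)s1",
                "%sc1ccc(%s)o1", "%sc1ncc(%s)cn1", "%sC1CCC(%s)CC1",
                "%sC1CCC(%s)CN1", "%sC1COC(%s)CN1", "%sc1ccc2ccc(%s)cc2c1",
                "%sc1cc(%s)n(C)c1", "%sC1CCC(%s)C1")
.syn_plain_tails <- c("C", "CC", "O", "OC", "N", "F", "Cl", "Br", "C#N",
                      "C(F)(F)F", "S(C)(=O)=O", "C(=O)OC", "C(=O)O",
                      "C(=O)NC", "NC(=O)C", "CC(=O)NC")
.syn_linkers <- c("", "C", "CC", "O", "OC", "N")
.syn_ring2_plain <- c("c2ccccc2", "c2ccncc2", "c2cccs2", "c2ccco2", "C2CCCCC2")
.syn_ring2_slot <- c("c2ccc(%s)cc2", "c2ccc(%s)cn2", "c2ccc(%s)s2",
                     "c2ccc(%s)o2", "C2CCC(%s)CC2")
.syn_ring2_subs <- c("C", "CC", "O", "OC", "F", "Cl", "C#N", "C(F)(F)F",
                     "C(=O)OC", "S(C)(=O)=O", "CCO", "OC(C)C")

# deliberately out-of-domain scaffolds: acyclic aliphatics (plain, alcohol,
# amine, acid), isoprenoids, adamantanes, pyranose sugars and crown ethers —
# none share ring systems or substituent chemistry with the training pool
.syn_unrelated_pool <- function() {
  chains <- as.vector(outer(8:18, c("", "O", "N", "C(=O)O"),
                            function(len, end) paste0(strrep("C", len), end)))
  diols <- sprintf("OC%sO", strrep("C", 8:14))
  c(chains, diols,
    "CC(C)CCCC(C)CCCC(C)CCCC(C)C", "CC(C)CCCC(C)CCCC(C)C",
    "CCC(C)CCCC(C)CCCC(C)C",
    "C1C2CC3CC1CC(C2)C3", "CC1(C)C2CC3CC1CC(C2)C3", "OC1C2CC3CC1CC(C2)C3",
    "NC1C2CC3CC1CC(C2)C3", "CCC1C2CC3CC1CC(C2)C3",
    "OCC1OC(O)C(O)C(O)C1O", "OCC1OC(OC)C(O)C(O)C1O",
    "OCC1OC(O)C(O)C(O)C1N", "OCC1OC(OCC)C(O)C(O)C1O",
    "C1COCCOCCOCCO1", "C1COCCOCCOCCOCCO1", "COCCOCCOCCOCCOC",
    "COCCOCCOCCOC", "COCCOCCOCCOCCOCCOC")
}

#' Specification of a synthetic activity dataset
#'
#' @param n_total number of molecules.
#' @param active_fraction fraction of true actives (default 0.014,
#'   mirroring a 403-in-28319 class balance).
#' @param label_noise per-record label flip probability (default 0.01).
#' @param seed integer seed; the whole dataset is a deterministic function of
#'   the spec.
#' @return list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_total = 3000L, active_fraction = 0.014,
                           label_noise = 0.01, seed = 1L) {
  stopifnot(n_total >= 10L, active_fraction > 0, active_fraction < 0.5,
            label_noise >= 0, label_noise < 0.1)
  structure(list(n_total = as.integer(n_total),
                 active_fraction = active_fraction,
                 label_noise = label_noise, seed = as.integer(seed),
                 planted_rule = "biphenyl AND (amide OR 1,3-oxazole)"),
            class = "synthetic_spec")
}

syn_active_space <- function() {
  g <- expand.grid(head = .syn_heads, tail = .syn_active_tails,
                   tpl = .syn_active_templates, stringsAsFactors = FALSE)
  sprintf(g$tpl, g$head, g$tail)
}

syn_inactive_space <- function() {
  tails <- c(.syn_plain_tails,
             as.vector(outer(.syn_linkers, .syn_ring2_plain, paste0)),
             as.vector(outer(.syn_linkers,
                             as.vector(outer(.syn_ring2_slot, .syn_ring2_subs,
                                             function(t, s) sprintf(t, s))),
                             paste0)))
  g <- expand.grid(head = .syn_heads, core = .syn_cores, tail = tails,
                   stringsAsFactors = FALSE)
  sprintf(g$core, g$head, g$tail)
}

syn_matches_rule <- function(smiles) {
  ob_smarts_match(smiles, .rule_smarts$biphenyl) &
    (ob_smarts_match(smiles, .rule_smarts$amide) |
       ob_smarts_match(smiles, .rule_smarts$oxazole))
}

# sample k distinct canonical SMILES from a candidate pool, keeping only
# those whose rule status matches `want_active`
syn_draw <- function(candidates, k, want_active, exclude = character(0)) {
  cand <- unique(candidates)
  if (length(cand) < k) stop("infeasible synthetic spec: scaffold space too small")
  picked <- character(0)
  offset <- 0L
  order_ <- sample(length(cand))
  while (length(picked) < k && offset < length(cand)) {
    take <- cand[order_[(offset + 1L):min(length(cand), offset + 2L * k)]]
    offset <- offset + length(take)
    can <- ob_canonical_smiles(take)
    can <- can[!is.na(can)]
    ok <- syn_matches_rule(can) == want_active
    picked <- unique(c(picked, setdiff(can[ok], exclude)))
  }
  if (length(picked) < k) stop("infeasible synthetic spec: cannot assemble enough ",
                               if (want_active) "actives" else "inactives")
  picked[seq_len(k)]
}

#' Generate a synthetic activity dataset
#'
#' Builds `n_total` distinct, guaranteed-parseable molecules of which
#' `active_fraction` carry the planted substructure rule (verified by SMARTS
#' matching), then flips each observed label with probability `label_noise`.
#' The noiseless truth is returned alongside.
#'
#' @param spec a [synthetic_spec].
#' @return list of class `synthetic_dataset`: `records` (curation-ready
#'   data.frame with noisy labels), `truth` (named vector of noiseless
#'   labels), `spec`.
#' @export
generate_dataset <- function(spec = synthetic_spec()) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n_act <- max(1L, round(spec$n_total * spec$active_fraction))
  n_inact <- spec$n_total - n_act
  with_seed(spec$seed, {
    actives <- syn_draw(syn_active_space(), n_act, want_active = TRUE)
    inactives <- syn_draw(syn_inactive_space(), n_inact, want_active = FALSE,
                          exclude = actives)
    smiles <- c(actives, inactives)
    truth <- c(rep("active", n_act), rep("inactive", n_inact))
    ord <- sample(length(smiles))
    smiles <- smiles[ord]; truth <- truth[ord]
    ids <- sprintf("SYN%06d", seq_along(smiles))
    flip <- stats::runif(length(smiles)) < spec$label_noise
    observed <- ifelse(flip, ifelse(truth == "active", "inactive", "active"),
                       truth)
    records <- new_records(ids, smiles, observed, "synthetic")
    names(truth) <- ids
    structure(list(records = records, truth = truth, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset: %d molecules, %d true actives, noise=%.3f, seed=%d>\n",
              nrow(x$records), sum(x$truth == "active"), x$spec$label_noise,
              x$spec$seed))
  invisible(x)
}

#' Generate a synthetic screening library
#'
#' A library of unlabelled molecules drawn from the same scaffold space as
#' [generate_dataset], with `n_hits_planted` rule-matching actives hidden
#' inside and a block of deliberately unrelated molecules (steroid-like fused
#' aliphatics, long chains, sugars, crown ethers) whose maximum Tanimoto
#' similarity to the training scaffold space is verified to be below
#' `unrelated_max_sim` at generation time — these exercise the
#' applicability-domain filter.
#'
#' @param n_total library size.
#' @param n_hits_planted number of hidden actives.
#' @param n_unrelated size of the unrelated block.
#' @param seed integer seed.
#' @param unrelated_max_sim Tanimoto ceiling for the unrelated block
#'   (circular fingerprints, default 0.15).
#' @return `synthetic_dataset` whose records carry `label = "unknown"`; the
#'   truth vector marks planted hits as `"active"`, unrelated molecules get
#'   `assay_note = "unrelated"`.
#' @export
generate_screen_library <- function(n_total = 200L, n_hits_planted = 2L,
                                    n_unrelated = 30L, seed = 1L,
                                    unrelated_max_sim = 0.15) {
  stopifnot(n_hits_planted < n_total / 4, n_unrelated < n_total)
  with_seed(seed, {
    n_main <- n_total - n_hits_planted - n_unrelated
    hits <- syn_draw(syn_active_space(), n_hits_planted, want_active = TRUE)
    main <- syn_draw(syn_inactive_space(), n_main, want_active = FALSE,
                     exclude = hits)
    # unrelated block: decorate the base set and keep only molecules far
    # (in circular-fingerprint Tanimoto) from the training scaffold space
    unrel_cand <- unique(ob_canonical_smiles(.syn_unrelated_pool()))
    unrel_cand <- unrel_cand[!is.na(unrel_cand)]
    exemplars <- c(main[seq_len(min(60L, length(main)))], hits)
    fp_ex <- fp_morgan(exemplars)
    fp_un <- fp_morgan(unrel_cand)
    maxsim <- apply(tanimoto_matrix(fp_un, fp_ex), 1L, max)
    unrel_pool <- unrel_cand[maxsim < unrelated_max_sim]
    if (length(unrel_pool) < n_unrelated) {
      stop("cannot assemble ", n_unrelated, " sufficiently unrelated molecules")
    }
    unrelated <- sample(unrel_pool, n_unrelated)
    smiles <- c(hits, main, unrelated)
    truth <- c(rep("active", n_hits_planted), rep("inactive", n_main),
               rep("inactive", n_unrelated))
    note <- c(rep("", n_hits_planted + n_main), rep("unrelated", n_unrelated))
    ord <- sample(length(smiles))
    smiles <- smiles[ord]; truth <- truth[ord]; note <- note[ord]
    ids <- sprintf("LIB%06d", seq_along(smiles))
    records <- new_records(ids, smiles, "unknown", "library",
                           assay_note = note)
    names(truth) <- ids
    structure(list(records = records, truth = truth,
                   spec = list(n_total = n_total,
                               n_hits_planted = n_hits_planted,
                               n_unrelated = n_unrelated, seed = seed)),
              class = "synthetic_dataset")
  })
}
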