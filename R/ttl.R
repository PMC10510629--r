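# The triple-predictor single-step loop: for one product, enumerate
# candidate disconnection sites, predict starting materials (T1) for each
# tagged variant, reagents (T2) for each starting-material set, and validate
# each (SM, R) combination with the forward model (T3). A step is kept only
# when T3's top-1 product equals the query product (canonical string
# equality, stereochemistry included); the step's confidence is T3's score.

#' A validated single retrosynthetic step
#'
#' @param product `molecule`: the disconnected product.
#' @param sm_set List of `molecule` starting materials (canonically sorted).
#' @param reagent_set List of `molecule` reagents (possibly empty).
#' @param confidence Forward-validation (T3) score in (0, 1].
#' @param site The `tagged_molecule` that steered the prediction.
#' @param provenance Character vector of site strategies.
#' @return An object of class `single_step`.
#' @export
single_step <- function(product, sm_set, reagent_set, confidence, site,
                        provenance = character()) {
  sm_smiles <- vapply(sm_set, function(m) m$smiles, character(1L))
  ord <- order(sm_smiles)
  structure(list(product = product, sm_set = sm_set[ord],
                 reagent_set = reagent_set,
                 confidence = as.numeric(confidence), site = site,
                 provenance = provenance,
                 sm_key = paste(sm_smiles[ord], collapse = ".")),
            class = "single_step")
}

#' @export
print.single_step <- function(x, ...) {
  cat("<single step> ", x$product$smiles, " => ", x$sm_key,
      sprintf("  (CS = %.3f)\n", x$confidence), sep = "")
  invisible(x)
}

#' Run the triple-predictor loop on one product
#'
#' For each enumerated site, T1 proposes up to `beam_t1` starting-material
#' sets; each is combined with up to `beam_t2` reagent sets from T2 and
#' validated by T3. Among validated reagent alternatives for one
#' starting-material set the highest forward confidence wins; results are
#' deduplicated on the starting-material key (keeping maximal confidence)
#' and sorted by descending confidence.
#'
#' Steps that merely return the product itself among the starting materials
#' are rejected.
#'
#' @param p Product `molecule` (or SMILES string).
#' @param cfg Full configuration, see [default_config()]; uses `$ttl`
#'   (beams, `min_confidence`) and `$tagging`.
#' @param models List with contracts `t1`, `t2`, `t3`, optionally `tagger`
#'   and `templates` (used by site enumeration).
#' @return List of `single_step` objects (possibly empty). Attribute
#'   `n_sites` carries the number of enumerated sites for the
#'   tagging-efficiency diagnostic.
#' @export
run_ttl <- function(p, cfg = default_config(), models) {
  p <- canonicalize(p)
  sites <- enumerate_sites(p, cfg$tagging, templates = models$templates,
                           tagger = models$tagger)
  B <- cfg$ttl$beam_t1
  B2 <- cfg$ttl$beam_t2
  best <- list()   # sm_key -> single_step
  for (site in sites) {
    preds <- validate_predictions(models$t1$predict(site, B), B,
                                  context = "T1")
    for (pr in preds) {
      sm <- pr$payload
      sm_smiles <- vapply(sm, function(m) m$smiles, character(1L))
      if (p$smiles %in% sm_smiles) next      # identity/no-op step
      rsets <- validate_predictions(models$t2$predict(sm, p, B2), B2,
                                    allow_empty = TRUE, context = "T2")
      step_best <- NULL
      for (rr in rsets) {
        fwd <- models$t3$predict(sm, rr$payload)
        if (length(fwd) == 0L) next
        top <- fwd[[1L]]
        if (top$payload[[1L]]$smiles != p$smiles) next
        if (top$score < cfg$ttl$min_confidence) next
        cand <- single_step(p, sm, rr$payload, top$score, site,
                            provenance = attr(site, "provenance"))
        if (is.null(step_best) || cand$confidence > step_best$confidence)
          step_best <- cand
      }
      if (!is.null(step_best)) {
        k <- step_best$sm_key
        if (is.null(best[[k]]) || step_best$confidence > best[[k]]$confidence)
          best[[k]] <- step_best
      }
    }
  }
  out <- unname(best)
  if (length(out) > 1L) {
    conf <- vapply(out, function(s) s$confidence, numeric(1L))
    keys <- vapply(out, function(s) s$sm_key, character(1L))
    out <- out[order(-conf, keys)]
  }
  attr(out, "n_sites") <- length(sites)
  out
}

#' Tagging efficiency diagnostic
#'
#' Number of unique validated retrosynthetic steps divided by the number of
#' tagging rounds (enumerated sites) spent to obtain them.
#'
#' @param results List of `single_step` objects from one [run_ttl()] call.
#' @param n_sites Number of enumerated sites (> 0).
#' @return A single number; 0 when nothing validated.
#' @export
tagging_efficiency <- function(results, n_sites) {
  if (!is.numeric(n_sites) || n_sites <= 0)
    stop("n_sites must be positive")
  length(unique(vapply(results, function(s) s$sm_key, character(1L)))) /
    n_sites
}
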