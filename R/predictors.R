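# Predictor contracts for the single-step loop. A contract wraps a predict
# function and a name; any backend (the built-in rule-based mock chemistry,
# or an adapter around a trained sequence-to-sequence model) can stand
# behind it. Implementations must be pure: identical inputs (and seed)
# return identical prediction lists, with scores in (0, 1] sorted
# descending.

new_predictor <- function(predict, name, class) {
  stopifnot(is.function(predict))
  structure(list(predict = predict, name = name),
            class = c(class, "predictor_model"))
}

#' Predictor contract constructors
#'
#' `retro_model()` wraps a single-step retrosynthesis predictor: tagged
#' product in, up to `beam` scored starting-material sets out.
#' `reagent_model()` wraps a reagent predictor: starting materials plus
#' product in, scored reagent sets out (a reagent set may be empty).
#' `forward_model()` wraps a forward reaction predictor: starting materials
#' plus reagents in, scored single products out, best first.
#' `tagger_model()` wraps a reactive-site tagger: molecule in, scored tagged
#' SMILES strings out.
#'
#' @param predict The backend function. Signatures:
#'   `function(tagged_product, beam)` for retro,
#'   `function(sm, product, beam)` for reagents,
#'   `function(sm, reagents)` for forward,
#'   `function(molecule, beam)` for the tagger.
#' @param name Backend name used in configuration and logs.
#' @return A predictor contract object.
#' @name predictor_contracts
NULL

#' @rdname predictor_contracts
#' @export
retro_model <- function(predict, name = "custom")
  new_predictor(predict, name, "retro_model")

#' @rdname predictor_contracts
#' @export
reagent_model <- function(predict, name = "custom")
  new_predictor(predict, name, "reagent_model")

#' @rdname predictor_contracts
#' @export
forward_model <- function(predict, name = "custom")
  new_predictor(predict, name, "forward_model")

#' @rdname predictor_contracts
#' @export
tagger_model <- function(predict, name = "custom")
  new_predictor(predict, name, "tagger_model")

#' @export
print.predictor_model <- function(x, ...) {
  cat("<", class(x)[1L], "> backend: ", x$name, "\n", sep = "")
  invisible(x)
}

#' Construct a scored prediction
#'
#' @param payload List of `molecule` objects (starting materials, reagents,
#'   or a single product, depending on the contract).
#' @param score Confidence in (0, 1].
#' @param allow_empty Whether an empty payload is legal (reagent contract
#'   only).
#' @return An object of class `scored_prediction`.
#' @export
scored_prediction <- function(payload, score, allow_empty = FALSE) {
  if (!allow_empty && length(payload) == 0L)
    stop("prediction payload must be non-empty")
  if (!is.numeric(score) || score <= 0 || score > 1)
    stop("confidence score must lie in (0, 1], got ", score)
  structure(list(payload = payload, score = as.numeric(score)),
            class = "scored_prediction")
}

## check and normalize a predictor's output list
validate_predictions <- function(preds, beam, allow_empty = FALSE,
                                 context = "predictor") {
  if (length(preds) > beam)
    stop(context, " returned more than beam = ", beam, " predictions")
  scores <- vapply(preds, function(p) p$score, numeric(1L))
  if (any(scores <= 0 | scores > 1))
    stop(context, " returned a score outside (0, 1]")
  if (length(scores) > 1L && is.unsorted(rev(scores)))
    stop(context, " scores are not sorted descending")
  if (!allow_empty && any(vapply(preds, function(p)
    length(p$payload) == 0L, logical(1L))))
    stop(context, " returned an empty payload")
  preds
}
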