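# Internal helpers shared across pipeline stages.

#' Derive a per-stage random seed from a master seed
#'
#' All randomized procedures in the pipeline draw their seed from one master
#' seed plus a fixed per-stage offset, so that stages are individually
#' reproducible and mutually independent.
#'
#' @param seed master integer seed.
#' @param offset fixed non-negative integer offset identifying the stage.
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, offset) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  as.integer((abs(seed) + 1009L * offset) %% .Machine$integer.max)
}

logit <- function(p) log(p / (1 - p))

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

# Clamp a proportion into [eps, 1 - eps] (empirical-logit correction).
clamp_prop <- function(p, eps) pmin(pmax(p, eps), 1 - eps)

`%||%` <- function(a, b) if (is.null(a)) b else a

# Normalise species names for matching against Newick tip labels:
# trim whitespace; spaces and underscores are interchangeable.
canon_species <- function(x) gsub(" ", "_", trimws(x))

stop_mf <- function(...) stop(sprintf(...), call. = FALSE)

msg <- function(verbose, ...) if (isTRUE(verbose)) message(sprintf(...))
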