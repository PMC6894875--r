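# Internal helpers shared across modules.

# round() in R rounds half to even; stratum sizes use round-half-up so that
# remainders are assigned deterministically to subtype 1.
round_half_up <- function(x) floor(x + 0.5)

# Map arbitrary cluster labels to 1..k in order of first appearance, so that
# stochastic methods yield a canonical labelling.
relabel_first_appearance <- function(labels) {
  u <- unique(labels)
  match(labels, u)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
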