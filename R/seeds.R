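#' Derive a child seed from a master seed and a label
#'
#' All stochastic stages of the pipeline receive their own child seed derived
#' deterministically from one master seed and a stage label, so that stages
#' can be re-run (or parallelised) independently while the whole experiment
#' stays reproducible from a single integer.
#'
#' The splitting rule is a simple 32-bit multiplicative hash of the label
#' folded into the master seed; results are always in `[1, 2^31 - 2]` so they
#' are valid arguments to [set.seed()].
#'
#' @param master integer master seed.
#' @param label character stage label (e.g. `"meiosis"`, `"trial3"`).
#' @return a single integer seed.
#' @export
#' @examples
#' child_seed(1, "founders")
child_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label))
  m <- 2147483647  # 2^31 - 1, prime
  h <- as.numeric(master) %% m
  bytes <- utf8ToInt(paste(label, collapse = "/"))
  for (b in bytes) h <- (h * 131 + b) %% m
  h <- (h * 48271) %% m
  as.integer(if (h < 1) 1 else h)
}

# internal: set RNG from a (master, label) pair
.with_child_seed <- function(master, label) {
  if (!is.null(master)) set.seed(child_seed(master, label))
  invisible(NULL)
}
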