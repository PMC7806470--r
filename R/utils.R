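#' @keywords internal
"_PACKAGE"

# Deterministic seed derivation: every randomized stage draws its seed from
# (master seed, stage name) so that stages and subjects are reproducible
# independently of execution order. Kept in plain modular arithmetic so the
# derived seed is a valid 32-bit R integer.
MOD31 <- 2147483647

#' Derive a child seed from a master seed and a label
#'
#' @param master integer master seed.
#' @param label character or integer label (stage name, subject number, ...).
#' @return an integer in \[1, 2^31 - 2\].
#' @export
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1, is.finite(master))
  key <- if (is.character(label)) {
    sum(utf8ToInt(label) * (seq_along(utf8ToInt(label)) %% 97 + 1))
  } else {
    as.numeric(label)
  }
  s <- (abs(master) %% MOD31) * 69069 + (key %% MOD31) * 40503 + 12345
  as.integer(s %% (MOD31 - 1) + 1)
}

# run expr with a temporary RNG state seeded at `seed`
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

`%||%` <- function(a, b) if (is.null(a)) b else a
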