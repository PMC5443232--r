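# Shared internal helpers.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
DNA4 <- c("A", "C", "G", "T")

# Evaluate `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG stream is restored afterwards. seed = NULL runs in the current stream.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random protein/DNA strings (uniform over the alphabet).
random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

random_dna <- function(length) {
  paste(sample(DNA4, length, replace = TRUE), collapse = "")
}

stop_if_empty_seq <- function(x, arg) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) {
    stop("`", arg, "` must be a single non-empty sequence", call. = FALSE)
  }
}
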