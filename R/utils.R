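# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# DNA/RNA complement preserving alphabet; x is a single uppercase string
complement_seq <- function(x, alphabet = c("DNA", "RNA")) {
  alphabet <- match.arg(alphabet)
  from <- if (alphabet == "DNA") "ACGT" else "ACGU"
  to <- if (alphabet == "DNA") "TGCA" else "UGCA"
  chartr(from, to, x)
}

reverse_seq <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1]]), collapse = "")
}

revcomp_seq <- function(x, alphabet = c("DNA", "RNA")) {
  reverse_seq(complement_seq(x, alphabet))
}

alphabet_letters <- function(alphabet) {
  switch(alphabet, DNA = c("A", "C", "G", "T"), RNA = c("A", "C", "G", "U"),
         stop("unknown alphabet: ", alphabet))
}

# run code with a private RNG state seeded from `seed`; the caller's
# .Random.seed is restored afterwards so generators do not perturb
# user-level random streams
with_local_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

stop_format <- function(...) {
  stop(errorCondition(paste0(...), class = c("npscreen_format_error", "error")))
}

stop_value <- function(...) {
  stop(errorCondition(paste0(...), class = c("npscreen_value_error", "error")))
}

stop_config <- function(...) {
  stop(errorCondition(paste0(...), class = c("npscreen_config_error", "error")))
}
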