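#' Round half away from zero
#'
#' Base R's `round()` rounds half to even; cytometric tables in this field are
#' printed with conventional "half up" rounding, which this helper implements
#' for positive and negative values alike.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

# Set the RNG locally; prior state is restored when the calling frame exits.
local_seed <- function(seed, envir = parent.frame()) {
  if (is.null(seed)) return(invisible(NULL))
  stopifnot(is.numeric(seed), length(seed) == 1L)
  restore <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    bquote(assign(".Random.seed", .(get(".Random.seed", globalenv())),
                  envir = globalenv()))
  } else {
    quote(suppressWarnings(rm(".Random.seed", envir = globalenv())))
  }
  do.call(on.exit, list(restore, add = TRUE), envir = envir)
  set.seed(as.integer(seed))
  invisible(NULL)
}

# Random DNA string of length n under a base composition.
random_dna <- function(n, base_composition = rep(0.25, 4)) {
  stopifnot(length(base_composition) == 4L,
            abs(sum(base_composition) - 1) < 1e-8)
  if (n == 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = base_composition), collapse = "")
}

# Substitute bases i.i.d. at rate `rate`, never to the original base.
mutate_sequence <- function(seq, rate) {
  if (rate <= 0) return(seq)
  n <- nchar(seq)
  k <- rbinom(1L, n, rate)
  if (k == 0L) return(seq)
  pos <- sample.int(n, k)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  bases <- c("A", "C", "G", "T")
  for (p in pos) {
    chars[p] <- sample(setdiff(bases, chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
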