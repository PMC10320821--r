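#' Derive a reproducible substream seed for a named pipeline stage
#'
#' All randomness in the package flows from one top-level seed; each stage
#' (corpus generation, participants, reading times, bootstrap, ...) draws from
#' its own substream so that, e.g., increasing the bootstrap replicates does
#' not perturb the simulated data.
#'
#' @param seed Top-level integer seed.
#' @param stream Character stage name, e.g. `"corpus"`, `"bootstrap"`.
#' @return An integer seed in `[0, 2^31 - 1)`, a deterministic function of
#'   `(seed, stream)`.
#' @export
#' @examples
#' substream_seed(1, "corpus")
substream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  # 32-bit multiplicative string hash, kept in double precision (exact below 2^53)
  h <- 0
  for (k in utf8ToInt(stream)) h <- (h * 131 + k) %% 2147483647
  as.integer((abs(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

#' Significance star codes
#'
#' The conventional coding used throughout the result tables:
#' `'***'` p < 0.001, `'**'` p < 0.01, `'*'` p < 0.05, `'(.)'` otherwise.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Character vector of star codes.
#' @export
p_stars <- function(p) {
  stopifnot(all(is.na(p) | (p >= 0 & p <= 1)))
  dplyr::case_when(
    is.na(p) ~ NA_character_,
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ "(.)"
  )
}

#' Short stable hash of a configuration object
#'
#' Used to stamp result tables so that any output can be traced back to the
#' configuration that produced it. Not cryptographic.
#'
#' @param x Any R object serializable by [jsonlite::toJSON()].
#' @return An 8-hex-digit character scalar.
#' @export
config_hash <- function(x) {
  s <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, force = TRUE)
  h1 <- 5381; h2 <- 52711
  for (k in utf8ToInt(as.character(s))) {
    h1 <- (h1 * 33 + k) %% 4294967291
    h2 <- (h2 * 37 + k) %% 4294967279
  }
  sprintf("%04x%04x", h1 %% 65536, h2 %% 65536)
}

# Evaluate code under a local RNG state (restores the caller's state).
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_lexcon <- function(msg, class) {
  rlang::abort(msg, class = c(class, "lexcon_error"))
}
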